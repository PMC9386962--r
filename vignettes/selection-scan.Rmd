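---
title: "Methods: two-population selection scans and diversity estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-population selection scans and diversity estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altiscan)
```

## The problem

When a population colonises a contrasting environment — here the motivating
setting is soil invertebrates living at high altitude (HA) versus low
altitude (LA) — genes under divergent selection are expected to show two
joint signatures in variant data: elevated allele-frequency differentiation
between the demes, and reduced within-deme diversity in the selected deme
where a favoured haplotype has risen in frequency. `altiscan` implements a
gene-level outlier scan built on those two signatures, together with the
alignment-based diversity estimators (segregating sites, Watterson's
$\theta_W$, nucleotide diversity $\pi$, Tajima's D) used to characterise a
population's overall genetic diversity, and a simulator that generates
complete two-population datasets with known ground truth so that every stage
can be calibrated without sequencing data.

## Estimators

### Alignment statistics

For an alignment of $n$ sequences over $L$ columns, columns containing a gap
(`-`) or ambiguous base (`N`, any non-ACGT symbol) are removed before any
statistic is computed (*complete deletion*), and $L_\mathrm{eff}$ is the
number of retained columns. This policy is deterministic and matches the
common default of alignment tools; it is appropriate for the clean trimmed
alignment blocks the statistics are usually run on.

* Segregating sites $S$: retained columns with $\ge 2$ distinct bases
  (multi-allelic columns count once).
* Mean pairwise differences $\bar k$: averaged over all $\binom{n}{2}$
  sequence pairs, accumulated in integer arithmetic before the single final
  division.
* $\hat\theta_W = S / (a_1 L_\mathrm{eff})$ with
  $a_1 = \sum_{i=1}^{n-1} 1/i$.
* $\pi = \bar k / L_\mathrm{eff}$.
* Tajima's
  $D = (\bar k - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}$ with the standard
  constants returned by `harmonic_constants()`. When $S = 0$, $D$ is
  undefined and reported as `NA`, never as 0 — zero is a meaningful value
  of the statistic (equality of the two estimators), not a degenerate one.

### Per-site statistics from genotypes

Diploid genotypes are treated as allele counts; heterozygote phase never
enters. For a population with $j$ alternate alleles among $n_{chr}$ called
chromosomes,
$\pi_{site} = 2j(n_{chr}-j)/(n_{chr}(n_{chr}-1))$, the fraction of
haplotype pairs differing at the site. Windowed Tajima's D
(`windowed_tajimas_d()`) sums these per-site values into $\bar k$ and counts
within-population segregating sites per window; windows default to 30 kb and
are non-overlapping (step = window size), the simplest reproducible reading
of a "sliding window"; a smaller `step_bp` gives overlapping windows at the
cost of pseudo-replication between neighbours. Windows with no segregating
site are reported with a missing D.

### Weir–Cockerham fixation index

Between-population differentiation is estimated per site with the Weir &
Cockerham (1984) method-of-moments variance components for two populations:
$a$ (among populations), $b$ (among individuals within populations) and $c$
(within individuals), with $\hat F_{ST} = a/(a+b+c)$. Observed
heterozygosity is taken from the genotype counts ($h_i = $ het$/n_i$), as
the individual-level estimator requires, not from a Hardy–Weinberg
expectation. Two numerical choices matter downstream:

* **Negative estimates are kept.** Per-site $\hat F_{ST}$ is slightly
  negative at undifferentiated sites by construction of the moment
  estimator; clamping at zero would bias per-gene means upward, so negative
  values enter the gene averages as computed.
* **Monomorphic sites are missing, not zero.** When a site is monomorphic
  across both populations, $a+b+c = 0$ and the ratio is undefined; such
  sites are excluded from per-gene $F_{ST}$ means (they carry no
  information about differentiation) but still contribute $\pi_{site} = 0$
  to the per-population diversity means when they passed the joint filters,
  because excluding them would inflate the apparent diversity of the
  population in which they are monomorphic.

## Variant filtering

Raw records pass through two per-record filters:

* **Hard-quality removal**: a record is removed when `DP < 10`, `QD < 5`,
  `MQ < 40` or `SOR > 3` (defaults of `hard_filter_thresholds()`). The
  inequalities are strict — these are removal conditions, so a record
  sitting exactly on a boundary (DP = 10, SOR = 3.0) is retained. A record
  whose annotation is absent fails the corresponding rule: an unannotated
  site cannot be shown to pass, which is the conservative convention of
  hard-filtering practice.
* **Minor-allele count**: with the minor count taken over all called
  chromosomes of both populations combined, records with
  $\mathrm{MAC} \ge 8$ are retained (boundary retained, matching the
  documented semantics of the count option in standard VCF tooling).

Both verdicts depend only on the record itself, so the two filters commute;
`filter_variants()` applies them together and attaches a removal ledger in
which every input record appears exactly once, under the full set of rules
it violated. Multi-allelic records are dropped on reading (the scan is
defined on biallelic SNPs; splitting them would create artificial sites),
and missing genotypes are excluded from all allele counts.

## The gene-level outlier scan

Sites are assigned to genes by interval overlap (1-based site positions
against 0-based half-open BED intervals); a site inside two overlapping
genes contributes to both, since no transcript-aware assignment is
attempted. Per gene, the scan computes the number of retained SNPs, the mean
of non-missing per-site $F_{ST}$, the per-population means of
$\pi_{site}$, and the diversity ratio
$R = -\log_{10}(\bar\pi_{HA}/\bar\pi_{LA})$. Per-gene diversity is the
*SNP-mean* (mean over assigned sites), not a per-bp rate; the scan contrasts
the two populations at the same sites, so the shared denominator cancels.

Candidates must then pass three stages in order:

1. **Dual top decile**: the gene is at or above the nearest-rank top-10%
   threshold of *both* mean $F_{ST}$ and $R$. The nearest-rank rule
   (threshold = $k$-th largest eligible value, $k = \lceil 0.1 N \rceil$) is
   interpolation-free and deterministic; ties at the threshold are all
   included.
2. **Half-diversity**: $\bar\pi_{HA} \le \tfrac12 \bar\pi_{LA}$, boundary
   inclusive. For genes with positive means this is equivalent to
   $R \ge \log_{10} 2$, which is asserted as an internal cross-check in the
   test suite.
3. **Minimum SNPs**: $n_{snps} \ge 5$, so a 5-SNP gene passes. Applying
   this stage *last* means the decile thresholds are computed over all
   genes with at least one retained SNP, which matches a workflow in which
   sparse genes are pruned from an already-ranked list.

Ratio sentinels: a gene with $\bar\pi_{LA} = 0$ has an undefined ratio and
is ineligible for the ratio decile (flagged `FALSE`); a gene with
$\bar\pi_{HA} = 0$ and $\bar\pi_{LA} > 0$ receives $R = +\infty$, ranked
above every finite value — zero HA diversity is the strongest possible form
of the signal the ratio is designed to detect.

```{r example}
sim <- simulate_two_pop_dataset(
  sim_config(seed = 1, n_genes = 120, n_ha = 10, n_la = 10),
  out_dir = tempfile("vignette_sim")
)
scan <- run_selection_scan(sim$paths[["vcf"]], sim$paths[["bed"]],
                           sim$paths[["pop"]])
scan
glance(scan)
```

## What the simulator emulates

`simulate_two_pop_dataset()` writes a VCF, BED intervals, a population
table and a truth table for a configurable number of genes, each on its own
scaffold with `max(1, Poisson(snps_per_gene_mean))` biallelic SNPs. The
statistical structure is:

* **Balding–Nichols frequencies.** Per SNP an ancestral alternate-allele
  frequency $p \sim U(0.05, 0.95)$ is drawn, and each deme's frequency
  follows $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ — the standard
  exchangeable $F$-model, whose expected $F_{ST}$ is approximately $F$, so
  parameter recovery is checkable. Neutral genes use `f_neutral` (default
  0.05), selected genes `f_selected` (default 0.5).
* **HA diversity reduction.** At selected genes the HA frequency is pushed
  toward its *nearer* fixation boundary by a power transform:
  $p \mapsto p^{1/f}$ for $p \le 0.5$ and $p \mapsto 1-(1-p)^{1/f}$ for
  $p > 0.5$, with $f$ = `ha_diversity_factor` (default 0.3). The transform
  is the identity at $f = 1$ and depresses expected HA heterozygosity
  monotonically as $f$ decreases — a cheap, monotone stand-in for a sweep,
  not a model of one.
* **Annotation values.** DP/QD/MQ/SOR are drawn from clean ranges, except
  that 5% of records per field violate exactly one threshold and a further
  2% carry exact boundary values (DP = 10 vs 9, SOR = 3.00 vs 3.01, ...),
  so every simulated dataset exercises the strict-inequality semantics of
  the hard filter.
* **Determinism.** All randomness derives from the config seed; identical
  configs give byte-identical files.

Defaults (1,000 genes, 5% selected, 20 + 20 diploids, Poisson-10 SNPs per
gene, 2-kb genes) describe a transcriptome-scale two-deme contrast of the
kind the scan is designed for; genotypes are fully called by default, with
a missingness-rate option for robustness checks.

The simulator deliberately omits linkage, recombination, coalescent
genealogies, demographic history and sequencing-read noise. Passing the
calibration checks therefore shows that the *estimators and the filter/scan
logic* behave correctly on data with the assumed independence structure; it
does not show that the scan's decile thresholds have any particular
false-discovery behaviour on real, linked, demographically structured data.

`simulate_neutral_alignment()` generates equilibrium infinite-sites
alignments ($S \sim$ Poisson$(\theta L a_1)$, derived-allele counts
$\propto 1/i$, carriers uniform) used to calibrate the alignment
estimators; the capped-at-$L$ edge case for extreme $\theta$ is flagged
with a warning.

## Interaction of filters with the recovery signal

One behaviour of the scan is worth stating plainly, because it bounds what
the pipeline can recover under strong-drift simulation settings. With
`f_selected = 0.5` *both* demes' frequencies at selected genes are strongly
U-shaped, and the HA push makes many selected-gene sites nearly or fully
fixed. A substantial fraction of exactly those sites then fails the
combined MAC $\ge 8$ filter — the most differentiated, lowest-HA-diversity
sites are the most likely to be near-monomorphic overall. Combined with the
~20% loss to the simulated hard-filter violations, a Poisson-10 selected
gene retains on average only about 4 SNPs, and the final $n_{snps} \ge 5$
stage then removes the majority of true positives: on the default
configuration the acceptance script measures sensitivity of roughly
0.3–0.4 at precision near 1.0 (the few candidates that survive are almost
all real). This is a property of the scan design itself — MAC filtering and
a minimum-SNP rule both select *against* the strongest sweep-like signals —
and practitioners applying such scans with small per-gene SNP counts should
expect conservative recovery. Raising `snps_per_gene_mean` (denser genes)
or relaxing `min_snps` restores high sensitivity, but those are different
study conditions, not defaults.

## Numerical and edge-case conventions

* Decile thresholds with fewer eligible genes than $1/(1-q)$ degrade to the
  maximum, with a warning.
* Genes with all-missing $F_{ST}$ are ineligible for the $F_{ST}$ decile
  and can never be candidates.
* The final candidate list is ordered by mean $F_{ST}$ descending, then
  `gene_id` — presentation plumbing only.
* Windowed D uses $n$ = the largest per-site called-chromosome count in the
  window, which equals $2 \times$ population size whenever genotypes are
  fully called; with heavy missingness the constants are approximate.
* `run_all()` writes every stage output as TSV plus a manifest of MD5
  content hashes, so end-to-end determinism is checkable byte-for-byte.

## Problem sizes used in the checks

The test suite calibrates against exhaustive oracles at small sizes
(alignments with $n \le 8$, $L \le 50$; all $(j, n_{chr} \le 12)$ pairs;
gene tables of $\le 50$ genes against a brute-force sort-cut-filter), uses
1,000 random genotype-count sites against an independent nested-ANOVA
transcription of the Weir–Cockerham components, 500 neutral alignments
($n = 20$, $L = 1000$, $\theta = 0.01$) for Watterson calibration, and a
1,000-gene simulated study (seed 42) for end-to-end recovery. These sizes
give stable Monte-Carlo estimates while keeping the default suite fast.

## Known limitations

* The scan has no significance machinery: "top 10%" is an outlier cut, not
  a test, and carries no false-discovery guarantee.
* Per-site $F_{ST}$ for two small demes is noisy; per-gene averaging over
  few SNPs remains noisy, which is precisely why the minimum-SNP rule
  exists and why it trades sensitivity for stability (see above).
* Tajima's D significance (beta-distribution approximation) is not
  implemented; the statistic is reported raw.
* Gene assignment is purely positional; transcript structure, strand and
  overlapping isoforms are out of scope.
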