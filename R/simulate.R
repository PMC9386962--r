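#' Annotation model for simulated variant-quality fields
#'
#' Controls how the simulator draws the `DP`, `QD`, `MQ` and `SOR` INFO
#' values attached to each simulated record. Most records draw from the
#' "clean" ranges, which comfortably satisfy the default hard filters. A
#' configurable fraction of records instead violates exactly one threshold,
#' and a further fraction sits exactly on a threshold boundary (e.g. DP = 10
#' or SOR = 3.00, which pass, versus DP = 9 or SOR = 3.01, which fail), so
#' that the strict-inequality semantics of downstream filtering are exercised
#' by every simulated dataset.
#'
#' @param violate_frac Named numeric: per-field probability (fields `dp`,
#'   `qd`, `mq`, `sor`) that a record is drawn as a violator of that single
#'   field.
#' @param boundary_frac Probability that an otherwise clean record carries an
#'   exact boundary value in one randomly chosen field (half of these pass on
#'   the boundary, half just fail).
#' @param dp_pass,qd_pass,mq_pass,sor_pass Length-2 numeric ranges from which
#'   clean values are drawn uniformly.
#' @return A list of class `annotation_model`.
#' @export
annotation_model <- function(violate_frac = c(dp = 0.05, qd = 0.05, mq = 0.05, sor = 0.05),
                             boundary_frac = 0.02,
                             dp_pass = c(15, 120),
                             qd_pass = c(6, 35),
                             mq_pass = c(41, 60),
                             sor_pass = c(0.2, 2.9)) {
  fields <- c("dp", "qd", "mq", "sor")
  if (!all(fields %in% names(violate_frac))) {
    abort_input("`violate_frac` must name all of dp, qd, mq, sor.")
  }
  if (sum(violate_frac) > 1) {
    abort_input("Per-field violation fractions must sum to at most 1.")
  }
  structure(
    list(
      violate_frac = violate_frac[fields], boundary_frac = boundary_frac,
      dp_pass = dp_pass, qd_pass = qd_pass, mq_pass = mq_pass,
      sor_pass = sor_pass
    ),
    class = "annotation_model"
  )
}

#' Simulation configuration for the two-population generator
#'
#' Bundles and validates the parameters of [simulate_two_pop_dataset()]. The
#' defaults describe the scenario used throughout the package's calibration
#' checks: 1,000 genes, 5% of them under divergent selection, two demes of
#' 20 diploid individuals, background differentiation F = 0.05 against
#' F = 0.5 at selected genes, and a strong within-HA diversity reduction
#' (`ha_diversity_factor = 0.3`).
#'
#' @param seed Integer seed; the simulator derives all randomness from it.
#' @param n_genes Number of genes (one interval per gene). Must be >= 1.
#' @param frac_selected Proportion of genes simulated as selected, in [0, 1].
#' @param snps_per_gene_mean Poisson mean for SNPs per gene (at least one SNP
#'   is always placed).
#' @param n_ha,n_la Diploid individuals in the high-altitude (HA) and
#'   low-altitude (LA) populations.
#' @param f_neutral,f_selected Balding-Nichols differentiation parameters in
#'   (0, 1) for neutral and selected genes; `f_selected` must exceed
#'   `f_neutral`.
#' @param ha_diversity_factor Multiplier in (0, 1] controlling how strongly
#'   HA allele frequencies at selected genes are pushed toward fixation
#'   (1 = no push; smaller = stronger loss of HA heterozygosity).
#' @param gene_length_bp Length of each gene interval in bp.
#' @param missing_rate Per-genotype missingness probability (default 0).
#' @param annotation Annotation-value model, see [annotation_model()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_genes = 1000L,
                       frac_selected = 0.05,
                       snps_per_gene_mean = 10,
                       n_ha = 20L,
                       n_la = 20L,
                       f_neutral = 0.05,
                       f_selected = 0.5,
                       ha_diversity_factor = 0.3,
                       gene_length_bp = 2000L,
                       missing_rate = 0,
                       annotation = annotation_model()) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (n_genes < 1) abort_input("`n_genes` must be >= 1.")
  if (frac_selected < 0 || frac_selected > 1) {
    abort_input("`frac_selected` must lie in [0, 1].")
  }
  if (snps_per_gene_mean <= 0) abort_input("`snps_per_gene_mean` must be > 0.")
  if (n_ha < 1 || n_la < 1) abort_input("Both populations need >= 1 individual.")
  if (f_neutral <= 0 || f_neutral >= 1 || f_selected <= 0 || f_selected >= 1) {
    abort_input("`f_neutral` and `f_selected` must lie in (0, 1).")
  }
  if (f_selected <= f_neutral) {
    abort_input("`f_selected` must exceed `f_neutral`.")
  }
  if (ha_diversity_factor <= 0 || ha_diversity_factor > 1) {
    abort_input("`ha_diversity_factor` must lie in (0, 1].")
  }
  if (gene_length_bp < 1) abort_input("`gene_length_bp` must be >= 1.")
  if (missing_rate < 0 || missing_rate >= 1) {
    abort_input("`missing_rate` must lie in [0, 1).")
  }
  stopifnot(inherits(annotation, "annotation_model"))
  structure(
    list(
      seed = as.integer(seed), n_genes = as.integer(n_genes),
      frac_selected = frac_selected,
      snps_per_gene_mean = snps_per_gene_mean,
      n_ha = as.integer(n_ha), n_la = as.integer(n_la),
      f_neutral = f_neutral, f_selected = f_selected,
      ha_diversity_factor = ha_diversity_factor,
      gene_length_bp = as.integer(gene_length_bp),
      missing_rate = missing_rate,
      annotation = annotation
    ),
    class = "sim_config"
  )
}

# Balding-Nichols draw: population frequency around ancestral p with
# differentiation F, Beta(p(1-F)/F, (1-p)(1-F)/F); E[freq] = p, E[Fst] ~ F.
rbalding_nichols <- function(p, f) {
  rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

# push a frequency toward its nearer fixation boundary: exponent
# 1/factor >= 1 shrinks p (toward 0) below 0.5 and shrinks 1-p (toward 1)
# above 0.5, so factor = 1 is the identity and smaller factors depress
# expected heterozygosity 2p(1-p) more strongly
push_to_fixation <- function(p, factor) {
  ifelse(p > 0.5, 1 - (1 - p)^(1 / factor), p^(1 / factor))
}

draw_annotations <- function(n, model) {
  vf <- model$violate_frac
  # each record violates at most one field; category drawn once per record
  cat <- sample(
    c("dp", "qd", "mq", "sor", "clean"),
    n,
    replace = TRUE,
    prob = c(vf, 1 - sum(vf))
  )
  dp <- round(runif(n, model$dp_pass[1], model$dp_pass[2]))
  qd <- runif(n, model$qd_pass[1], model$qd_pass[2])
  mq <- runif(n, model$mq_pass[1], model$mq_pass[2])
  sor <- runif(n, model$sor_pass[1], model$sor_pass[2])
  dp[cat == "dp"] <- sample(1:9, sum(cat == "dp"), replace = TRUE)
  qd[cat == "qd"] <- runif(sum(cat == "qd"), 0, 4.99)
  mq[cat == "mq"] <- runif(sum(cat == "mq"), 10, 39.99)
  sor[cat == "sor"] <- runif(sum(cat == "sor"), 3.01, 9)
  # boundary pins on clean records: exact threshold values, pass or just-fail
  clean <- which(cat == "clean")
  n_b <- rbinom(1, length(clean), model$boundary_frac)
  if (n_b > 0) {
    idx <- sample(clean, n_b)
    field <- sample(c("dp", "qd", "mq", "sor"), n_b, replace = TRUE)
    pass <- runif(n_b) < 0.5
    dp[idx[field == "dp"]] <- ifelse(pass[field == "dp"], 10, 9)
    qd[idx[field == "qd"]] <- ifelse(pass[field == "qd"], 5, 4.99)
    mq[idx[field == "mq"]] <- ifelse(pass[field == "mq"], 40, 39.99)
    sor[idx[field == "sor"]] <- ifelse(pass[field == "sor"], 3, 3.01)
  }
  tibble(
    dp = as.integer(dp), qd = round(qd, 2), mq = round(mq, 2),
    sor = round(sor, 2)
  )
}

#' Simulate a two-population variant dataset
#'
#' Generates a complete file set — VCF, BED gene intervals, population table
#' and per-gene truth table — for a two-deme study contrasting a
#' high-altitude (HA) with a low-altitude (LA) population. Each gene sits on
#' its own scaffold and receives `max(1, Poisson(snps_per_gene_mean))`
#' biallelic SNPs. Per SNP, an ancestral alternate-allele frequency is drawn
#' uniformly on (0.05, 0.95) and the two population frequencies follow the
#' Balding-Nichols model with differentiation `f_neutral` at neutral genes or
#' `f_selected` at selected genes; at selected genes the HA frequency is
#' additionally pushed toward the nearer fixation boundary to depress HA
#' heterozygosity. Diploid genotypes are binomial draws from the population
#' frequencies, and DP/QD/MQ/SOR annotations follow [annotation_model()].
#'
#' @param config A [sim_config()].
#' @param out_dir Directory in which to write `variants.vcf`, `genes.bed`,
#'   `populations.tsv` and `truth.tsv`. Created if needed.
#' @return Invisibly, a list with element `paths` (named file paths),
#'   `truth` (per-gene tibble: `gene_id`, `status`, `n_snps`, `mean_p_anc`,
#'   `mean_p_ha`, `mean_p_la`), `sites` (per-SNP tibble including the drawn
#'   frequencies and annotations), `genotypes` (sites x samples integer
#'   dosage matrix, `NA` = missing), and `config`.
#' @examples
#' out <- simulate_two_pop_dataset(
#'   sim_config(seed = 1, n_genes = 5, n_ha = 4, n_la = 4),
#'   out_dir = tempfile("sim")
#' )
#' out$truth
#' @export
simulate_two_pop_dataset <- function(config = sim_config(), out_dir) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(out_dir) || !is.character(out_dir) || length(out_dir) != 1) {
    abort_input("`out_dir` must be a single path.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort_input(paste0("Cannot create output directory: ", out_dir))
  }

  set.seed(config$seed)
  ng <- config$n_genes
  gene_id <- sprintf("gene_%04d", seq_len(ng))
  contig <- sprintf("scaffold_%04d", seq_len(ng))
  n_sel <- round(ng * config$frac_selected)
  status <- rep("neutral", ng)
  if (n_sel > 0) status[sample.int(ng, n_sel)] <- "selected"

  offset <- 1000L # 0-based interval start on each scaffold
  glen <- config$gene_length_bp
  k <- pmax(1L, rpois(ng, config$snps_per_gene_mean))

  gene_idx <- rep(seq_len(ng), k)
  pos <- unlist(lapply(k, function(ki) sort(sample.int(glen, ki)))) + offset
  n_snp <- length(gene_idx)

  p_anc <- runif(n_snp, 0.05, 0.95) # ancestral ALT frequency
  f <- ifelse(status[gene_idx] == "selected", config$f_selected, config$f_neutral)
  p_ha <- rbalding_nichols(p_anc, f)
  p_la <- rbalding_nichols(p_anc, f)
  sel <- status[gene_idx] == "selected"
  p_ha[sel] <- push_to_fixation(p_ha[sel], config$ha_diversity_factor)

  n_ha <- config$n_ha
  n_la <- config$n_la
  geno <- matrix(
    NA_integer_,
    nrow = n_snp, ncol = n_ha + n_la,
    dimnames = list(NULL, c(sprintf("HA_%02d", seq_len(n_ha)),
                            sprintf("LA_%02d", seq_len(n_la))))
  )
  geno[, seq_len(n_ha)] <- rbinom(n_snp * n_ha, 2, rep(p_ha, n_ha))
  geno[, n_ha + seq_len(n_la)] <- rbinom(n_snp * n_la, 2, rep(p_la, n_la))
  if (config$missing_rate > 0) {
    miss <- runif(length(geno)) < config$missing_rate
    geno[miss] <- NA_integer_
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snp, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  ann <- draw_annotations(n_snp, config$annotation)

  sites <- tibble(
    contig = contig[gene_idx], pos = as.integer(pos),
    gene_id = gene_id[gene_idx], status = status[gene_idx],
    ref = ref, alt = alt,
    p_anc = p_anc, p_ha = p_ha, p_la = p_la,
    dp = ann$dp, qd = ann$qd, mq = ann$mq, sor = ann$sor
  )

  truth <- sites |>
    group_by(gene_id) |>
    summarise(
      status = .data$status[1],
      n_snps = dplyr::n(),
      mean_p_anc = mean(.data$p_anc),
      mean_p_ha = mean(.data$p_ha),
      mean_p_la = mean(.data$p_la),
      .groups = "drop"
    )

  paths <- c(
    vcf = file.path(out_dir, "variants.vcf"),
    bed = file.path(out_dir, "genes.bed"),
    pop = file.path(out_dir, "populations.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )

  write_sim_vcf(paths[["vcf"]], sites, geno,
                contig_lengths = setNames(rep(offset + glen + 1000L, ng), contig))
  writeLines(
    sprintf("%s\t%d\t%d\t%s", contig, offset, offset + glen, gene_id),
    paths[["bed"]]
  )
  writeLines(
    c("sample_id\tpopulation",
      sprintf("%s\t%s", colnames(geno),
              rep(c("HA", "LA"), c(n_ha, n_la)))),
    paths[["pop"]]
  )
  writeLines(
    c(paste(names(truth), collapse = "\t"),
      sprintf("%s\t%s\t%d\t%.6f\t%.6f\t%.6f",
              truth$gene_id, truth$status, truth$n_snps,
              truth$mean_p_anc, truth$mean_p_ha, truth$mean_p_la)),
    paths[["truth"]]
  )

  invisible(list(
    paths = paths, truth = truth, sites = sites, genotypes = geno,
    config = config
  ))
}

# minimal deterministic VCF 4.2 writer for simulator output
write_sim_vcf <- function(path, sites, geno, contig_lengths) {
  gt <- matrix("./.", nrow = nrow(geno), ncol = ncol(geno))
  gt[!is.na(geno) & geno == 0L] <- "0/0"
  gt[!is.na(geno) & geno == 1L] <- "0/1"
  gt[!is.na(geno) & geno == 2L] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=altiscan_simulate",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths), contig_lengths),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Combined depth\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(geno)), collapse = "\t")
  )
  info <- sprintf("DP=%d;QD=%.2f;MQ=%.2f;SOR=%.2f",
                  sites$dp, sites$qd, sites$mq, sites$sor)
  body <- paste(
    sites$contig, sites$pos, ".", sites$ref, sites$alt, ".", ".", info, "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
}

#' Simulate a neutral sequence alignment
#'
#' Generates an `n_seqs` x `n_sites` alignment under the infinite-sites
#' neutral model at equilibrium: the number of segregating sites is drawn as
#' \eqn{S \sim Poisson(\theta L a_1(n))}, sites are placed at distinct
#' columns, each site's derived-allele count `i` is drawn with probability
#' proportional to `1/i` (the neutral frequency spectrum) and carriers are
#' chosen uniformly. All remaining columns are monomorphic.
#'
#' @param n_seqs Number of sequences (>= 2).
#' @param n_sites Alignment length in columns (>= 1).
#' @param theta_per_site Population mutation rate per site (>= 0).
#' @param seed Optional integer seed for reproducibility.
#' @param file Optional path: when given, the alignment is also written as
#'   FASTA.
#' @return A character matrix alignment with row names `seq_1 ...`.
#' @examples
#' aln <- simulate_neutral_alignment(20, 1000, 0.01, seed = 7)
#' alignment_stats(aln)
#' @export
simulate_neutral_alignment <- function(n_seqs, n_sites, theta_per_site,
                                       seed = NULL, file = NULL) {
  if (n_seqs < 2) abort_input("`n_seqs` must be >= 2.")
  if (n_sites < 1) abort_input("`n_sites` must be >= 1.")
  if (theta_per_site < 0) abort_input("`theta_per_site` must be >= 0.")
  if (!is.null(seed)) set.seed(seed)

  bases <- c("A", "C", "G", "T")
  ancestral <- sample(bases, n_sites, replace = TRUE)
  aln <- matrix(rep(ancestral, each = n_seqs), nrow = n_seqs)
  rownames(aln) <- sprintf("seq_%d", seq_len(n_seqs))

  a1 <- harmonic_constants(n_seqs)$a1
  S <- rpois(1, theta_per_site * n_sites * a1)
  if (S > n_sites) {
    warn(sprintf(
      "Drew %d segregating sites for %d columns; capping at %d.",
      S, n_sites, n_sites
    ))
    S <- n_sites
  }
  if (S > 0) {
    cols <- sample.int(n_sites, S)
    i_max <- n_seqs - 1
    counts <- sample.int(i_max, S, replace = TRUE, prob = 1 / seq_len(i_max))
    for (s in seq_len(S)) {
      j <- cols[s]
      derived <- sample(setdiff(bases, ancestral[j]), 1)
      carriers <- sample.int(n_seqs, counts[s])
      aln[carriers, j] <- derived
    }
  }
  if (!is.null(file)) {
    lines <- character(2 * n_seqs)
    lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln))
    lines[c(FALSE, TRUE)] <- apply(aln, 1, paste, collapse = "")
    writeLines(lines, file)
  }
  aln
}
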