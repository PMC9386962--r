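# Independent test-side oracles. Each one deliberately takes a different
# computational route from the package implementation it checks.

# brute-force alignment statistics: explicit loops over pairs and columns,
# complete deletion of any column containing a non-ACGT symbol
oracle_alignment <- function(aln) {
  aln <- toupper(aln)
  keep <- apply(aln, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  aln <- aln[, keep, drop = FALSE]
  n <- nrow(aln)
  S <- 0L
  for (j in seq_len(ncol(aln))) {
    if (length(unique(aln[, j])) >= 2) S <- S + 1L
  }
  total <- 0L
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      total <- total + sum(aln[i, ] != aln[k, ])
    }
  }
  n_pairs <- n * (n - 1) / 2
  list(
    S = S, k_bar = total / n_pairs,
    pi_per_site = if (ncol(aln) > 0) total / (n_pairs * ncol(aln)) else NA_real_,
    L_effective = ncol(aln)
  )
}

# direct-summation constants (frozen reference route for harmonic_constants)
oracle_a1 <- function(n) {
  s <- 0
  for (i in seq_len(n - 1)) s <- s + 1 / i
  s
}

# per-site pi by exhaustive haplotype-pair comparison: j alt haplotypes
# among n_chr, count differing pairs directly
oracle_site_pi <- function(j, n_chr) {
  hap <- c(rep(1L, j), rep(0L, n_chr - j))
  diff <- 0L
  for (a in seq_len(n_chr - 1)) {
    for (b in (a + 1):n_chr) {
      if (hap[a] != hap[b]) diff <- diff + 1L
    }
  }
  diff / (n_chr * (n_chr - 1) / 2)
}

# Weir-Cockerham (1984) variance components via the nested-ANOVA
# (sums-of-squares) route on per-allele indicator variables: populations /
# individuals within populations / alleles within individuals. Agrees with
# the moment formulas to machine precision but shares no code path.
oracle_wc_anova <- function(counts) {
  dos <- integer(0)
  pop <- integer(0)
  for (i in seq_along(counts)) {
    g <- counts[[i]]
    dos <- c(dos, rep(c(2L, 1L, 0L), g)) # reference-allele copies
    pop <- c(pop, rep(i, sum(g)))
  }
  n_i <- tabulate(pop)
  r <- length(n_i)
  N <- sum(n_i)
  xbar_ij <- dos / 2
  xbar_i <- tapply(xbar_ij, pop, mean)
  xbar <- sum(dos) / (2 * N)
  SSP <- sum(2 * n_i * (xbar_i - xbar)^2)
  SSI <- sum(2 * (xbar_ij - xbar_i[pop])^2)
  SSG <- sum(ifelse(dos == 1L, 0.5, 0)) # within-individual SS: het only
  MSP <- SSP / (r - 1)
  MSI <- SSI / (N - r)
  MSG <- SSG / N
  n_c <- (N - sum(n_i^2) / N) / (r - 1)
  a <- (MSP - MSI) / (2 * n_c)
  b <- (MSI - MSG) / 2
  cc <- MSG
  denom <- a + b + cc
  list(a = a, b = b, c = cc, fst = if (denom == 0) NA_real_ else a / denom)
}

# brute-force site-in-interval membership (1-based site, 0-based half-open)
oracle_assign <- function(sites, genes) {
  out <- list()
  for (i in seq_len(nrow(sites))) {
    for (g in seq_len(nrow(genes))) {
      if (sites$contig[i] == genes$contig[g] &&
            sites$pos[i] - 1 >= genes$start[g] &&
            sites$pos[i] - 1 < genes$end[g]) {
        out[[length(out) + 1]] <- data.frame(
          contig = sites$contig[i], pos = sites$pos[i],
          gene_id = genes$gene_id[g]
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(contig = character(), pos = integer(),
                      gene_id = character()))
  }
  do.call(rbind, out)
}

# brute-force scan: plain sort-cut-filter over a gene-summary table
oracle_scan <- function(summaries, q = 0.9, half = 0.5, min_snps = 5) {
  top_set <- function(x) {
    elig <- which(!is.na(x))
    k <- max(1, ceiling((1 - q) * length(elig)))
    thr <- sort(x[elig], decreasing = TRUE)[k]
    elig[x[elig] >= thr]
  }
  dual <- intersect(top_set(summaries$mean_fst), top_set(summaries$ratio))
  half_ok <- dual[summaries$mean_pi_ha[dual] <=
                    half * summaries$mean_pi_la[dual]]
  final <- half_ok[summaries$n_snps[half_ok] >= min_snps]
  list(
    dual = sort(summaries$gene_id[dual]),
    half = sort(summaries$gene_id[half_ok]),
    candidates = sort(summaries$gene_id[final]),
    counts = c(length(dual), length(half_ok), length(final))
  )
}

# absolute-difference comparison that treats two NAs as equal (relative
# tolerances misbehave for statistics that are legitimately ~0)
expect_close <- function(actual, expected, tol = 1e-10) {
  if (is.na(actual) && is.na(expected)) {
    return(testthat::succeed())
  }
  testthat::expect_lt(abs(actual - expected), tol)
}

# random alignment generator for oracle-equivalence loops
random_alignment <- function(n, L, p_gap = 0) {
  pool <- c("A", "C", "G", "T")
  aln <- matrix(sample(pool, n * L, replace = TRUE), nrow = n)
  # make columns realistically correlated: most columns near-monomorphic
  for (j in seq_len(L)) {
    if (runif(1) < 0.6) aln[, j] <- sample(pool, 1)
  }
  if (p_gap > 0) {
    idx <- runif(n * L) < p_gap
    aln[idx] <- sample(c("-", "N"), sum(idx), replace = TRUE)
  }
  aln
}

# small simulated dataset shared by several test files
small_sim <- function(seed = 11, n_genes = 40, ...) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  sim <- simulate_two_pop_dataset(
    sim_config(seed = seed, n_genes = n_genes, n_ha = 10, n_la = 10, ...),
    out_dir = dir
  )
  sim
}
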