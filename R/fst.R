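# Vectorised Weir-Cockerham (1984) variance components for r = 2
# populations from per-population genotype counts. Inputs are integer
# vectors of equal length (one element per site).
wc_components <- function(hom_ref_1, het_1, hom_alt_1,
                          hom_ref_2, het_2, hom_alt_2) {
  n1 <- hom_ref_1 + het_1 + hom_alt_1
  n2 <- hom_ref_2 + het_2 + hom_alt_2
  r <- 2
  # reference-allele frequency and observed heterozygosity per population
  p1 <- (2 * hom_ref_1 + het_1) / (2 * n1)
  p2 <- (2 * hom_ref_2 + het_2) / (2 * n2)
  h1 <- het_1 / n1
  h2 <- het_2 / n2
  nsum <- n1 + n2
  nbar <- nsum / r
  nc <- (nsum - (n1^2 + n2^2) / nsum) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  denom <- a + b + cc
  fst <- ifelse(denom == 0, NA_real_, a / denom)
  # monomorphic-overall sites: all components are exactly zero, Fst undefined
  tibble(
    a = a, b = b, c = cc, fst = fst,
    n_ha = n1, n_la = n2, p_ha = p1, p_la = p2, h_ha = h1, h_la = h2
  )
}

#' Per-site Weir-Cockerham fixation index between two populations
#'
#' Computes the Weir & Cockerham (1984) method-of-moments variance
#' components for a single biallelic site observed in two populations:
#' `a` (among populations), `b` (among individuals within populations) and
#' `c` (within individuals), and the per-site estimate
#' `fst = a / (a + b + c)`. Observed heterozygosity enters through the
#' genotype counts, as required by the individual-level estimator. Negative
#' estimates are reported as computed (not clamped); sites monomorphic
#' across both populations have all components zero and a missing `fst`.
#'
#' @param geno_ha,geno_la Genotype counts `(hom_ref, het, hom_alt)` for the
#'   two populations: either numeric vectors of length 3 (one site) or
#'   3-column matrices / data frames (one row per site).
#' @return A tibble with one row per site and columns `a`, `b`, `c`, `fst`,
#'   `n_ha`, `n_la`, `p_ha`, `p_la` (reference-allele frequencies), `h_ha`,
#'   `h_la` (observed heterozygosities).
#' @examples
#' wc_fst_site(c(6, 4, 0), c(1, 4, 5)) # fst ~ 0.3728
#' wc_fst_site(c(10, 0, 0), c(0, 0, 10)) # fixed difference: fst = 1
#' @export
wc_fst_site <- function(geno_ha, geno_la) {
  as3 <- function(x, nm) {
    if (is.data.frame(x)) x <- as.matrix(x)
    if (is.numeric(x) && is.null(dim(x))) {
      if (length(x) != 3) abort_input(paste0("`", nm, "` must have 3 counts."))
      x <- matrix(x, nrow = 1)
    }
    if (!is.matrix(x) || ncol(x) != 3) {
      abort_input(paste0("`", nm, "` must be a length-3 vector or 3-column matrix."))
    }
    x
  }
  ha <- as3(geno_ha, "geno_ha")
  la <- as3(geno_la, "geno_la")
  if (nrow(ha) != nrow(la)) {
    abort_input("`geno_ha` and `geno_la` must describe the same sites.")
  }
  if (any(rowSums(ha) < 1) || any(rowSums(la) < 1)) {
    abort_input("Each population needs >= 1 called individual per site.")
  }
  wc_components(ha[, 1], ha[, 2], ha[, 3], la[, 1], la[, 2], la[, 3])
}

#' Per-site nucleotide diversity from allele counts
#'
#' Unbiased per-site heterozygosity of a population sample:
#' \eqn{\pi = 2 j (n_{chr} - j) / (n_{chr} (n_{chr} - 1))}, the proportion
#' of haplotype pairs differing at the site, where `j` is the alternate
#' allele count and `n_chr` the number of called chromosomes.
#'
#' @param j Alternate-allele count(s), `0 <= j <= n_chr`.
#' @param n_chr Called chromosomes (2 x called diploid individuals).
#' @return Numeric vector of per-site diversities; `NA` where `n_chr < 2`.
#' @examples
#' site_pi(2, 4) # 4 of 6 pairs differ -> 0.667
#' @export
site_pi <- function(j, n_chr) {
  len <- max(length(j), length(n_chr))
  j <- rep_len(j, len)
  n_chr <- rep_len(n_chr, len)
  if (any(j < 0 | j > n_chr, na.rm = TRUE)) {
    abort_input("`j` must lie in [0, n_chr].")
  }
  ifelse(n_chr < 2, NA_real_, 2 * j * (n_chr - j) / (n_chr * (n_chr - 1)))
}

#' Per-site statistics table for a two-population variant set
#'
#' Joins the per-site Weir-Cockerham fixation index and the per-population
#' per-site nucleotide diversities over all records of a (typically already
#' filtered) variant table, in genomic order.
#'
#' @param variants A variant table with the per-population genotype count
#'   columns of [read_variants()], usually after [filter_variants()].
#' @return A tibble with one row per site: `contig`, `pos`, `fst` (possibly
#'   negative or missing), `pi_ha`, `pi_la`, `mac`.
#' @export
site_table <- function(variants) {
  if (nrow(variants) == 0) {
    return(tibble(
      contig = character(), pos = integer(), fst = numeric(),
      pi_ha = numeric(), pi_la = numeric(), mac = integer()
    ))
  }
  fst <- wc_components(
    variants$hom_ref_ha, variants$het_ha, variants$hom_alt_ha,
    variants$hom_ref_la, variants$het_la, variants$hom_alt_la
  )$fst
  n_chr_ha <- 2L * (variants$hom_ref_ha + variants$het_ha + variants$hom_alt_ha)
  n_chr_la <- 2L * (variants$hom_ref_la + variants$het_la + variants$hom_alt_la)
  j_ha <- variants$het_ha + 2L * variants$hom_alt_ha
  j_la <- variants$het_la + 2L * variants$hom_alt_la
  mac <- if ("mac" %in% names(variants)) {
    variants$mac
  } else {
    mac_filter(variants)$mac
  }
  out <- tibble(
    contig = variants$contig, pos = variants$pos,
    fst = fst,
    pi_ha = site_pi(j_ha, n_chr_ha),
    pi_la = site_pi(j_la, n_chr_la),
    mac = mac
  )
  arrange(out, .data$contig, .data$pos)
}
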