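#' Harmonic constants for diversity estimators
#'
#' Computes the sample-size-dependent constants used by Watterson's theta and
#' by the variance normalisation of Tajima's D: the harmonic sums
#' \eqn{a_1 = \sum_{i=1}^{n-1} 1/i} and \eqn{a_2 = \sum_{i=1}^{n-1} 1/i^2},
#' the coefficients \eqn{b_1, b_2}, their bias-corrected forms
#' \eqn{c_1, c_2}, and the variance weights \eqn{e_1 = c_1/a_1} and
#' \eqn{e_2 = c_2/(a_1^2 + a_2)}.
#'
#' @param n Sample size(s): number of sequences (or chromosomes). Must be
#'   >= 2. Vectorised.
#' @return A tibble with one row per element of `n` and columns `n`, `a1`,
#'   `a2`, `b1`, `b2`, `c1`, `c2`, `e1`, `e2`.
#' @examples
#' harmonic_constants(4)
#' harmonic_constants(c(2, 20, 165))
#' @export
harmonic_constants <- function(n) {
  if (length(n) == 0 || any(!is.finite(n)) || any(n < 2) || any(n != floor(n))) {
    abort_input("`n` must contain integers >= 2.")
  }
  a1 <- vapply(n, function(ni) sum(1 / seq_len(ni - 1)), numeric(1))
  a2 <- vapply(n, function(ni) sum(1 / seq_len(ni - 1)^2), numeric(1))
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  tibble(
    n = as.integer(n), a1 = a1, a2 = a2, b1 = b1, b2 = b2,
    c1 = c1, c2 = c2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2)
  )
}

#' Coerce sequences to an alignment matrix
#'
#' Accepts a character matrix (one base per cell), a named or unnamed
#' character vector of equal-length sequence strings, or an `ape::DNAbin`
#' matrix, and returns an upper-case character matrix with one row per
#' sequence.
#'
#' @param x Sequences in any of the accepted forms.
#' @return A character matrix (rows = sequences, columns = sites).
#' @export
as_alignment <- function(x) {
  if (inherits(x, "DNAbin")) {
    x <- as.character(x)
    if (!is.matrix(x)) {
      abort_input("DNAbin input must be a rectangular alignment.")
    }
  }
  if (is.character(x) && !is.matrix(x)) {
    lens <- nchar(x)
    if (length(unique(lens)) != 1) {
      abort_input("Ragged alignment: sequences differ in length.")
    }
    x <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  }
  if (!is.matrix(x) || !is.character(x)) {
    abort_input("Cannot interpret input as an alignment matrix.")
  }
  toupper(x)
}

#' Read a FASTA alignment
#'
#' @param path Path to a FASTA file whose sequences are all the same length.
#' @return A character matrix with sequence identifiers as row names.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) {
    abort_input(paste0("Alignment file not found: ", path))
  }
  seqs <- ape::read.FASTA(path)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1) {
    abort_input("Ragged alignment: sequences differ in length.")
  }
  as_alignment(as.matrix(seqs))
}

# Complete-deletion policy: keep only columns in which every base is an
# unambiguous A/C/G/T. Gaps ('-') and ambiguity codes ('N', IUPAC letters)
# remove the whole column from every statistic.
retained_columns <- function(aln) {
  ok <- aln %in% c("A", "C", "G", "T")
  dim(ok) <- dim(aln)
  which(colSums(ok) == nrow(aln))
}

# per-column allele counts on retained columns; returns list of tables
column_counts <- function(aln) {
  keep <- retained_columns(aln)
  lapply(keep, function(j) table(aln[, j]))
}

#' Count segregating sites
#'
#' Number of retained alignment columns carrying two or more distinct bases.
#' Columns containing gaps or ambiguous bases are excluded first (complete
#' deletion).
#'
#' @param aln An alignment accepted by [as_alignment()].
#' @return Integer count of segregating sites.
#' @export
count_segregating_sites <- function(aln) {
  aln <- as_alignment(aln)
  if (nrow(aln) < 2) abort_input("At least 2 sequences are required.")
  counts <- column_counts(aln)
  sum(vapply(counts, function(tb) length(tb) >= 2, logical(1)))
}

#' Watterson's theta per site
#'
#' \eqn{\hat\theta_W = S / (a_1(n) \, L)} where `S` is the number of
#' segregating sites, `n` the number of sequences and `L` the number of
#' sites surveyed.
#'
#' @param S Segregating-site count(s).
#' @param n Number of sequences.
#' @param L Number of sites (use the post-deletion effective length when the
#'   alignment contained gaps).
#' @return Numeric estimate(s) of theta per site.
#' @examples
#' watterson_theta(3, n = 4, L = 100)
#' @export
watterson_theta <- function(S, n, L) {
  if (any(L < 1)) abort_input("`L` must be >= 1.")
  if (any(S < 0)) abort_input("`S` must be >= 0.")
  S / (harmonic_constants(n)$a1 * L)
}

#' Nucleotide diversity of an alignment
#'
#' Mean number of pairwise differences `k_bar` over all sequence pairs
#' (counted with integer arithmetic before any division) and the per-site
#' diversity `pi = k_bar / L_effective`, where `L_effective` is the number of
#' columns retained under complete deletion.
#'
#' @inheritParams count_segregating_sites
#' @return A one-row tibble with columns `k_bar`, `pi_per_site`, `n`,
#'   `L_effective`.
#' @export
nucleotide_diversity <- function(aln) {
  aln <- as_alignment(aln)
  n <- nrow(aln)
  if (n < 2) abort_input("At least 2 sequences are required.")
  counts <- column_counts(aln)
  n_pairs <- choose(n, 2)
  # per column, number of differing pairs = C(n,2) - sum_a C(count_a, 2)
  diff_pairs <- vapply(
    counts,
    function(tb) n_pairs - sum(choose(as.numeric(tb), 2)),
    numeric(1)
  )
  total <- sum(diff_pairs)
  L_eff <- length(counts)
  tibble(
    k_bar = total / n_pairs,
    pi_per_site = if (L_eff > 0) total / (n_pairs * L_eff) else NA_real_,
    n = n,
    L_effective = L_eff
  )
}

# shared core: D from (n, S, k_bar); NA when S == 0
tajimas_d_from_counts <- function(n, S, k_bar) {
  if (S == 0) {
    return(NA_real_)
  }
  k <- harmonic_constants(n)
  (k_bar - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Tajima's D of an alignment
#'
#' Normalised difference between the pairwise-difference estimator and the
#' segregating-site estimator of the population mutation rate:
#' \eqn{D = (\bar k - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}}.
#' Negative values indicate an excess of rare variants; positive values an
#' excess of intermediate-frequency variants.
#'
#' @inheritParams count_segregating_sites
#' @return A single numeric value; `NA` (with a message) when the alignment
#'   has no segregating sites, where D is undefined.
#' @examples
#' tajimas_d(c("AAA", "ATT", "TAT", "TTA"))
#' @export
tajimas_d <- function(aln) {
  aln <- as_alignment(aln)
  S <- count_segregating_sites(aln)
  if (S == 0) {
    inform("Tajima's D undefined: no segregating sites; returning NA.")
    return(NA_real_)
  }
  nd <- nucleotide_diversity(aln)
  tajimas_d_from_counts(nrow(aln), S, nd$k_bar)
}

#' Summary diversity statistics for an alignment
#'
#' One-stop computation of the alignment-level estimators: segregating sites
#' `S`, mean pairwise differences `k_bar`, Watterson's theta per site,
#' nucleotide diversity per site and Tajima's D, after complete deletion of
#' gapped/ambiguous columns.
#'
#' @inheritParams count_segregating_sites
#' @return A one-row tibble with columns `n`, `L_effective`, `S`, `k_bar`,
#'   `theta_w_per_site`, `pi_per_site`, `tajimas_d`.
#' @examples
#' aln <- simulate_neutral_alignment(n_seqs = 10, n_sites = 500,
#'                                   theta_per_site = 0.01, seed = 1)
#' alignment_stats(aln)
#' @export
alignment_stats <- function(aln) {
  aln <- as_alignment(aln)
  S <- count_segregating_sites(aln)
  nd <- nucleotide_diversity(aln)
  theta <- if (nd$L_effective > 0) {
    watterson_theta(S, nrow(aln), nd$L_effective)
  } else {
    NA_real_
  }
  tibble(
    n = nrow(aln),
    L_effective = nd$L_effective,
    S = S,
    k_bar = nd$k_bar,
    theta_w_per_site = theta,
    pi_per_site = nd$pi_per_site,
    tajimas_d = tajimas_d_from_counts(nrow(aln), S, nd$k_bar)
  )
}
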