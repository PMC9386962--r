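#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a selection-scan result
#'
#' @param x An `altiscan_scan` object from [run_selection_scan()].
#' @param ... Unused.
#' @return The per-gene summary tibble with one row per gene and all flag
#'   columns (`in_top_decile_fst`, `in_top_decile_ratio`, `passes_half_pi`,
#'   `passes_min_snps`, `candidate`).
#' @method tidy altiscan_scan
#' @export
tidy.altiscan_scan <- function(x, ...) {
  x$genes
}

#' One-row summary of a selection-scan result
#'
#' @inheritParams tidy.altiscan_scan
#' @return A one-row tibble: `n_genes`, `n_sites`, `n_dual_decile`,
#'   `n_half_pi`, `n_candidates`, `fst_threshold`, `ratio_threshold`.
#' @method glance altiscan_scan
#' @export
glance.altiscan_scan <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes),
    n_sites = nrow(x$sites),
    n_dual_decile = x$ledger$surviving[x$ledger$stage == "dual_top_decile"],
    n_half_pi = x$ledger$surviving[x$ledger$stage == "half_pi"],
    n_candidates = nrow(x$candidates),
    fst_threshold = x$thresholds[["fst"]],
    ratio_threshold = x$thresholds[["ratio"]]
  )
}
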