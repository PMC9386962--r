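#' Selection-scan configuration
#'
#' Parameters of the gene-level outlier procedure: genes must fall in the
#' top `1 - quantile` fraction of both the per-gene mean fixation index and
#' the per-gene \eqn{-\log_{10}(\pi_{HA}/\pi_{LA})} diversity ratio, have a
#' mean HA diversity at most `half_factor` times the LA mean, and carry at
#' least `min_snps` retained SNPs.
#'
#' @param quantile Decile cut `q` in (0, 1); genes at or above the
#'   nearest-rank top `1 - q` threshold are flagged (default 0.90, i.e. the
#'   top 10%).
#' @param half_factor Maximum allowed `mean_pi_ha / mean_pi_la` (default
#'   0.5; the boundary passes).
#' @param min_snps Minimum retained SNPs per gene (default 5; a gene with
#'   exactly 5 passes).
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(quantile = 0.90, half_factor = 0.5, min_snps = 5) {
  if (quantile <= 0 || quantile >= 1) abort_input("`quantile` must be in (0, 1).")
  if (half_factor <= 0 || half_factor > 1) {
    abort_input("`half_factor` must be in (0, 1].")
  }
  if (min_snps < 1) abort_input("`min_snps` must be >= 1.")
  structure(
    list(quantile = quantile, half_factor = half_factor,
         min_snps = as.integer(min_snps)),
    class = "scan_config"
  )
}

#' Read gene intervals from a BED file
#'
#' Minimal 4-column BED reader (contig, 0-based start, end, gene_id) with
#' per-line validation so malformed lines are reported by number.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `contig`, `start` (0-based), `end`
#'   (exclusive), `gene_id`.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) abort_input(paste0("BED file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    ok <- length(p) >= 4 &&
      !is.na(suppressWarnings(as.numeric(p[2]))) &&
      !is.na(suppressWarnings(as.numeric(p[3]))) &&
      as.numeric(p[2]) < as.numeric(p[3])
    if (!ok) {
      abort_input(sprintf("Malformed BED line %d: '%s'", i, lines[i]))
    }
  }
  tibble(
    contig = vapply(parts, `[`, character(1), 1),
    start = as.integer(vapply(parts, `[`, character(1), 2)),
    end = as.integer(vapply(parts, `[`, character(1), 3)),
    gene_id = vapply(parts, `[`, character(1), 4)
  )
}

#' Assign variant sites to gene intervals
#'
#' Maps each 1-based site position onto every 0-based half-open gene
#' interval `[start, end)` containing it (a site overlapping two genes
#' contributes to both). Sites falling in no interval are dropped from the
#' scan; their count is attached as attribute `"n_unassigned"`.
#'
#' @param sites A tibble with `contig` and `pos` columns (e.g. from
#'   [site_table()]).
#' @param genes Gene intervals: a tibble as from [read_gene_bed()] or a path
#'   to a BED file.
#' @return `sites` with a `gene_id` column; rows are duplicated where genes
#'   overlap.
#' @export
assign_sites_to_genes <- function(sites, genes) {
  if (is.character(genes)) genes <- read_gene_bed(genes)
  if (nrow(sites) == 0) {
    out <- sites
    out$gene_id <- character(0)
    attr(out, "n_unassigned") <- 0L
    return(out)
  }
  site_gr <- GenomicRanges::GRanges(
    sites$contig, IRanges::IRanges(start = sites$pos, width = 1)
  )
  # BED is 0-based half-open; GRanges is 1-based inclusive
  gene_gr <- GenomicRanges::GRanges(
    genes$contig, IRanges::IRanges(start = genes$start + 1L, end = genes$end)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(site_gr, gene_gr))
  out <- sites[S4Vectors::queryHits(hits), , drop = FALSE]
  out$gene_id <- genes$gene_id[S4Vectors::subjectHits(hits)]
  n_unassigned <- nrow(sites) - length(unique(S4Vectors::queryHits(hits)))
  if (n_unassigned > 0) {
    inform(sprintf("%d site(s) fell in no gene interval and were dropped.",
                   n_unassigned))
  }
  attr(out, "n_unassigned") <- n_unassigned
  out
}

#' Per-gene summaries of site statistics
#'
#' Aggregates gene-assigned site statistics: SNP count, mean fixation index
#' over non-missing per-site values (negative values included), mean
#' per-population diversity over all assigned sites (sites monomorphic
#' within one population contribute zero), and the diversity ratio
#' `R = -log10(mean_pi_ha / mean_pi_la)`. `R` is `Inf` when the HA mean is
#' zero but the LA mean positive (the strongest possible signal) and `NA`
#' when the LA mean is zero (ratio undefined; such genes are ineligible for
#' the ratio decile).
#'
#' @param assigned Output of [assign_sites_to_genes()]: site statistics with
#'   a `gene_id` column.
#' @return A tibble with one row per gene: `gene_id`, `n_snps`, `mean_fst`,
#'   `mean_pi_ha`, `mean_pi_la`, `ratio`.
#' @export
summarise_genes <- function(assigned) {
  out <- assigned |>
    group_by(.data$gene_id) |>
    summarise(
      n_snps = dplyr::n(),
      mean_fst = if (all(is.na(.data$fst))) NA_real_ else
        mean(.data$fst, na.rm = TRUE),
      mean_pi_ha = mean(.data$pi_ha),
      mean_pi_la = mean(.data$pi_la),
      .groups = "drop"
    )
  out$ratio <- dplyr::case_when(
    out$mean_pi_la == 0 ~ NA_real_,
    out$mean_pi_ha == 0 ~ Inf,
    TRUE ~ -log10(out$mean_pi_ha / out$mean_pi_la)
  )
  out
}

# nearest-rank top-(1-q) threshold: the k-th largest eligible value with
# k = ceiling((1-q) * n); ties at the threshold are all included upstream
nearest_rank_threshold <- function(x, q) {
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    return(NA_real_)
  }
  k <- max(1L, ceiling((1 - q) * length(x)))
  sort(x, decreasing = TRUE)[k]
}

#' Flag genes in the top decile of each scan metric
#'
#' Computes, for the mean fixation index and for the diversity ratio, the
#' nearest-rank top-`(1 - quantile)` threshold over eligible genes (those
#' with a non-missing value of the metric) and flags genes whose value is at
#' or above it — ties at the threshold are all included, and `Inf` ratio
#' sentinels rank above every finite value. Genes with a missing metric are
#' ineligible and flagged `FALSE`.
#'
#' @param summaries Per-gene summaries from [summarise_genes()].
#' @param config A [scan_config()].
#' @return `summaries` with logical columns `in_top_decile_fst`,
#'   `in_top_decile_ratio`, plus the thresholds as attributes
#'   `"fst_threshold"` and `"ratio_threshold"`.
#' @export
decile_flags <- function(summaries, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  q <- config$quantile
  n_needed <- ceiling(1 / (1 - q))
  if (sum(!is.na(summaries$mean_fst)) < n_needed ||
        sum(!is.na(summaries$ratio)) < n_needed) {
    warn(paste0(
      "Fewer than ", n_needed, " eligible genes: top-decile thresholds are ",
      "degenerate (reduce to the maximum)."
    ))
  }
  thr_fst <- nearest_rank_threshold(summaries$mean_fst, q)
  thr_ratio <- nearest_rank_threshold(summaries$ratio, q)
  summaries$in_top_decile_fst <-
    !is.na(summaries$mean_fst) & !is.na(thr_fst) & summaries$mean_fst >= thr_fst
  summaries$in_top_decile_ratio <-
    !is.na(summaries$ratio) & !is.na(thr_ratio) & summaries$ratio >= thr_ratio
  attr(summaries, "fst_threshold") <- thr_fst
  attr(summaries, "ratio_threshold") <- thr_ratio
  summaries
}

#' Apply the staged candidate filters of the selection scan
#'
#' Runs the outlier filters in order: (1) dual top decile — both
#' `in_top_decile_fst` and `in_top_decile_ratio`; (2) half-diversity —
#' `mean_pi_ha <= half_factor * mean_pi_la` (the boundary passes);
#' (3) minimum SNPs — `n_snps >= min_snps` (a gene with exactly `min_snps`
#' passes). Survivor counts for each stage are reported in a ledger.
#'
#' @param summaries Output of [decile_flags()].
#' @param config A [scan_config()].
#' @return A list with `genes` (all summaries with flag columns
#'   `passes_half_pi`, `passes_min_snps` and `candidate`), `candidates`
#'   (candidate rows sorted by `mean_fst` descending then `gene_id`) and
#'   `ledger` (tibble of `stage`, `entering`, `surviving`).
#' @export
apply_scan_filters <- function(summaries, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  if (!all(c("in_top_decile_fst", "in_top_decile_ratio") %in% names(summaries))) {
    abort_input("Run decile_flags() before apply_scan_filters().")
  }
  s <- summaries
  s$passes_half_pi <- s$mean_pi_ha <= config$half_factor * s$mean_pi_la
  s$passes_min_snps <- s$n_snps >= config$min_snps
  dual <- s$in_top_decile_fst & s$in_top_decile_ratio
  half <- dual & s$passes_half_pi
  final <- half & s$passes_min_snps
  s$candidate <- final
  ledger <- tibble(
    stage = c("dual_top_decile", "half_pi", "min_snps"),
    entering = c(nrow(s), sum(dual), sum(half)),
    surviving = c(sum(dual), sum(half), sum(final))
  )
  candidates <- s[s$candidate, , drop = FALSE] |>
    arrange(desc(.data$mean_fst), .data$gene_id)
  list(genes = s, candidates = candidates, ledger = ledger)
}

#' Run the full two-population selection scan
#'
#' End-to-end composition: read the VCF and population table, apply
#' hard-quality and minor-allele-count filters, compute per-site fixation
#' index and per-population diversity, assign sites to genes, summarise per
#' gene, flag the dual top deciles and apply the staged candidate filters.
#'
#' @param vcf Path to a multi-sample VCF, or a variant table from
#'   [read_variants()].
#' @param bed Path to a 4-column BED of gene intervals, or a tibble from
#'   [read_gene_bed()].
#' @param pops Path to a population table, or a tibble from
#'   [read_pop_table()].
#' @param config A [scan_config()].
#' @param thresholds A [hard_filter_thresholds()].
#' @param mac_min Minimum minor allele count (default 8).
#' @return An object of class `altiscan_scan`: a list with `genes` (per-gene
#'   summary tibble with all flags), `candidates`, `ledger` (scan-stage
#'   counts), `sites` (gene-assigned per-site statistics), `filter_ledger`
#'   (per-reason removal counts), `thresholds` (the two decile cutoffs) and
#'   `config`. Use [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()] on it.
#' @examples
#' sim <- simulate_two_pop_dataset(
#'   sim_config(seed = 3, n_genes = 60, n_ha = 10, n_la = 10),
#'   out_dir = tempfile("scan")
#' )
#' scan <- run_selection_scan(sim$paths[["vcf"]], sim$paths[["bed"]],
#'                            sim$paths[["pop"]])
#' scan$ledger
#' @export
run_selection_scan <- function(vcf, bed, pops,
                               config = scan_config(),
                               thresholds = hard_filter_thresholds(),
                               mac_min = 8) {
  variants <- if (is.character(vcf)) read_variants(vcf, pops) else vcf
  retained <- filter_variants(variants, thresholds, mac_min)
  sites <- site_table(retained)
  assigned <- assign_sites_to_genes(sites, bed)
  summaries <- summarise_genes(assigned)
  flagged <- decile_flags(summaries, config)
  res <- apply_scan_filters(flagged, config)
  structure(
    list(
      genes = res$genes,
      candidates = res$candidates,
      ledger = res$ledger,
      sites = assigned,
      filter_ledger = filter_ledger(retained),
      thresholds = c(
        fst = attr(flagged, "fst_threshold"),
        ratio = attr(flagged, "ratio_threshold")
      ),
      config = config
    ),
    class = "altiscan_scan"
  )
}

#' @export
print.altiscan_scan <- function(x, ...) {
  cat("Two-population selection scan\n")
  cat(sprintf("  genes summarised : %d\n", nrow(x$genes)))
  cat(sprintf("  retained sites   : %d\n", nrow(x$sites)))
  cat(sprintf(
    "  decile cutoffs   : mean_fst >= %.4f, ratio >= %.4f\n",
    x$thresholds[["fst"]], x$thresholds[["ratio"]]
  ))
  for (i in seq_len(nrow(x$ledger))) {
    cat(sprintf(
      "  %-16s : %d -> %d\n", x$ledger$stage[i],
      x$ledger$entering[i], x$ledger$surviving[i]
    ))
  }
  cat(sprintf("  candidate genes  : %d\n", nrow(x$candidates)))
  invisible(x)
}
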