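#' Read a run configuration from YAML
#'
#' A flat YAML file with optional blocks `simulation` (fields of
#' [sim_config()]), `scan` ([scan_config()]), `hard_filter`
#' ([hard_filter_thresholds()]) and top-level keys `vcf`, `bed`, `pops`,
#' `fasta`, `mac_min`, `window_bp`, `out_dir`, `seed`. Keys that are absent
#' fall back to the package defaults; a `seed` at top level overrides the
#' simulation seed.
#'
#' @param path Path to the YAML file.
#' @return A named list suitable for `do.call(run_all, ...)`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_input(paste0("Config file not found: ", path))
  raw <- yaml::read_yaml(path)
  out <- list()
  for (key in c("vcf", "bed", "pops", "fasta", "out_dir")) {
    if (!is.null(raw[[key]])) out[[key]] <- raw[[key]]
  }
  if (!is.null(raw$mac_min)) out$mac_min <- raw$mac_min
  if (!is.null(raw$window_bp)) out$window_bp <- raw$window_bp
  if (!is.null(raw$simulation)) {
    sim_args <- raw$simulation
    if (!is.null(raw$seed)) sim_args$seed <- raw$seed
    out$sim <- do.call(sim_config, sim_args)
  }
  if (!is.null(raw$scan)) out$config <- do.call(scan_config, raw$scan)
  if (!is.null(raw$hard_filter)) {
    out$thresholds <- do.call(hard_filter_thresholds, raw$hard_filter)
  }
  out
}

write_stage_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates an end-to-end reproducible run: optionally simulate a
#' dataset, then filter variants, compute per-site statistics, run the
#' gene-level selection scan, and compute windowed Tajima's D for both
#' populations (plus alignment diversity statistics when a FASTA alignment
#' is supplied). All stage outputs are written as tab-separated files under
#' `out_dir` together with a manifest listing each file with its MD5
#' content hash, so two runs on identical configuration can be compared
#' byte-for-byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param sim Optional [sim_config()]; when given, the dataset is simulated
#'   into `out_dir` and its files are used as inputs.
#' @param vcf,bed,pops Input paths, required when `sim` is `NULL`.
#' @param fasta Optional FASTA alignment for [alignment_stats()].
#' @param config A [scan_config()].
#' @param thresholds A [hard_filter_thresholds()].
#' @param mac_min Minimum minor allele count (default 8).
#' @param window_bp Window size for windowed Tajima's D (default 30000).
#' @return Invisibly, a list with the `altiscan_scan` object (`scan`), the
#'   window tibble (`windows`), optional `alignment` stats, the `manifest`
#'   tibble (`file`, `bytes`, `md5`) and `paths` of all written files.
#' @export
run_all <- function(out_dir,
                    sim = NULL,
                    vcf = NULL, bed = NULL, pops = NULL, fasta = NULL,
                    config = scan_config(),
                    thresholds = hard_filter_thresholds(),
                    mac_min = 8,
                    window_bp = 30000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sim)) {
    simulated <- simulate_two_pop_dataset(sim, out_dir)
    vcf <- simulated$paths[["vcf"]]
    bed <- simulated$paths[["bed"]]
    pops <- simulated$paths[["pop"]]
  }
  for (input in c(vcf = vcf, bed = bed, pops = pops, fasta = fasta)) {
    if (!file.exists(input)) {
      abort_input(paste0("Missing input file: ", input))
    }
  }
  if (is.null(vcf) || is.null(bed) || is.null(pops)) {
    abort_input("Provide either `sim` or all of `vcf`, `bed`, `pops`.")
  }

  variants <- read_variants(vcf, pops)
  retained <- filter_variants(variants, thresholds, mac_min)
  scan <- run_selection_scan(variants, bed, pops, config, thresholds, mac_min)
  windows <- bind_rows(
    windowed_tajimas_d(retained, "HA", window_bp),
    windowed_tajimas_d(retained, "LA", window_bp)
  )

  paths <- c(
    gene_summary = write_stage_tsv(
      scan$genes, file.path(out_dir, "gene_summary.tsv")
    ),
    candidates = write_stage_tsv(
      scan$candidates, file.path(out_dir, "candidates.tsv")
    ),
    scan_ledger = write_stage_tsv(
      scan$ledger, file.path(out_dir, "scan_ledger.tsv")
    ),
    filter_ledger = write_stage_tsv(
      scan$filter_ledger, file.path(out_dir, "filter_ledger.tsv")
    ),
    site_stats = write_stage_tsv(
      scan$sites, file.path(out_dir, "site_stats.tsv")
    ),
    tajima_windows = write_stage_tsv(
      windows, file.path(out_dir, "tajima_windows.tsv")
    )
  )
  alignment <- NULL
  if (!is.null(fasta)) {
    alignment <- alignment_stats(read_alignment(fasta))
    paths <- c(paths, alignment_stats = write_stage_tsv(
      alignment, file.path(out_dir, "alignment_stats.tsv")
    ))
  }
  if (!is.null(sim)) {
    paths <- c(
      paths,
      vcf = vcf, bed = bed, pops = pops,
      truth = file.path(out_dir, "truth.tsv")
    )
  }

  manifest <- tibble(
    file = basename(unname(paths)),
    bytes = unname(file.size(paths)),
    md5 = unname(tools::md5sum(paths))
  ) |>
    arrange(.data$file)
  write_stage_tsv(manifest, file.path(out_dir, "manifest.tsv"))

  inform(sprintf(
    "Pipeline complete: %d retained sites, %d genes, %d candidates.",
    nrow(scan$sites), nrow(scan$genes), nrow(scan$candidates)
  ))
  invisible(list(
    scan = scan, windows = windows, alignment = alignment,
    manifest = manifest, paths = paths
  ))
}
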