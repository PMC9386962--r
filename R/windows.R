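#' Windowed Tajima's D from genotype data
#'
#' Computes Tajima's D in windows along each contig for one population,
#' treating genotypes as allele counts (heterozygote phase is irrelevant).
#' Within a window, `S` is the number of sites segregating within the
#' population, the mean pairwise difference is
#' \eqn{\bar k = \sum_{sites} 2 j (n_{chr} - j) / (n_{chr} (n_{chr} - 1))}
#' with `j` the within-population alternate-allele count, and D uses
#' `n = n_chr` chromosomes (the largest per-site called-chromosome count in
#' the window, which equals 2 x population size when no genotypes are
#' missing). Windows with `S = 0` are reported with a missing D (zero would
#' be a meaningful value). Windows are non-overlapping by default; a smaller
#' `step_bp` gives sliding windows.
#'
#' @param variants A variant table with per-population genotype counts (see
#'   [read_variants()]), sorted by position within contig.
#' @param population `"HA"` or `"LA"`.
#' @param window_bp Window size in bp (default 30000).
#' @param step_bp Step between window starts (default: `window_bp`, i.e.
#'   non-overlapping).
#' @param contig_lengths Optional named vector of contig lengths; defaults
#'   to the `"contig_lengths"` attribute of `variants` when present,
#'   otherwise to the largest observed position per contig. Every contig is
#'   tiled with `ceiling(length / step)` windows, including empty ones.
#' @return A tibble with one row per window: `contig`, `start`, `end`
#'   (1-based inclusive), `population`, `n_sites`, `S`, `k_bar`,
#'   `tajimas_d`.
#' @export
windowed_tajimas_d <- function(variants, population = c("HA", "LA"),
                               window_bp = 30000, step_bp = window_bp,
                               contig_lengths = NULL) {
  population <- match.arg(population)
  if (window_bp < 1 || step_bp < 1) {
    abort_input("`window_bp` and `step_bp` must be >= 1.")
  }
  unsorted <- variants |>
    group_by(.data$contig) |>
    summarise(bad = is.unsorted(.data$pos), .groups = "drop")
  if (any(unsorted$bad)) {
    abort_input("Variant positions must be sorted within each contig.")
  }
  sfx <- if (population == "HA") "_ha" else "_la"
  hom_ref <- variants[[paste0("hom_ref", sfx)]]
  het <- variants[[paste0("het", sfx)]]
  hom_alt <- variants[[paste0("hom_alt", sfx)]]
  called <- hom_ref + het + hom_alt
  if (nrow(variants) > 0 && max(called) < 2) {
    abort_input("Population needs >= 2 called individuals somewhere.")
  }
  j <- het + 2L * hom_alt
  n_chr <- 2L * called

  if (is.null(contig_lengths)) {
    contig_lengths <- attr(variants, "contig_lengths")
  }
  if (is.null(contig_lengths)) {
    lens <- tapply(variants$pos, variants$contig, max)
    contig_lengths <- setNames(as.integer(lens), names(lens))
  }

  out <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    starts <- seq(1L, by = as.integer(step_bp),
                  length.out = max(1L, ceiling(len / step_bp)))
    ends <- starts + as.integer(window_bp) - 1L
    on_ctg <- which(variants$contig == ctg)
    rows <- lapply(seq_along(starts), function(w) {
      in_w <- on_ctg[variants$pos[on_ctg] >= starts[w] &
                       variants$pos[on_ctg] <= ends[w]]
      seg <- in_w[j[in_w] > 0 & j[in_w] < n_chr[in_w] & n_chr[in_w] >= 2]
      S <- length(seg)
      k_bar <- sum(site_pi(j[seg], n_chr[seg]))
      d <- if (S == 0) {
        NA_real_
      } else {
        tajimas_d_from_counts(max(n_chr[seg]), S, k_bar)
      }
      tibble(
        contig = ctg, start = starts[w], end = ends[w],
        population = population, n_sites = length(in_w),
        S = S, k_bar = k_bar, tajimas_d = d
      )
    })
    bind_rows(rows)
  })
  bind_rows(out)
}
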