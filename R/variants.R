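#' Hard-filter thresholds
#'
#' The hard-quality removal rules applied to raw variant records: a record is
#' removed when `DP < dp_min` or `QD < qd_min` or `MQ < mq_min` or
#' `SOR > sor_max`, with strict inequalities, so records sitting exactly on a
#' threshold are retained. A record whose annotation is absent fails the
#' corresponding rule (it cannot be shown to pass).
#'
#' @param dp_min Minimum combined depth (default 10).
#' @param qd_min Minimum quality-by-depth (default 5).
#' @param mq_min Minimum RMS mapping quality (default 40).
#' @param sor_max Maximum strand odds ratio (default 3).
#' @return A list of class `hard_filter_thresholds`.
#' @export
hard_filter_thresholds <- function(dp_min = 10, qd_min = 5, mq_min = 40,
                                   sor_max = 3) {
  if (any(c(dp_min, qd_min, mq_min, sor_max) <= 0)) {
    abort_input("All thresholds must be positive.")
  }
  structure(
    list(dp_min = dp_min, qd_min = qd_min, mq_min = mq_min, sor_max = sor_max),
    class = "hard_filter_thresholds"
  )
}

#' Read a population-assignment table
#'
#' Two-column tab-separated file with header `sample_id`, `population` and
#' populations coded `HA` / `LA`. Both populations must be non-empty and no
#' sample may appear twice.
#'
#' @param path Path to the table.
#' @return A tibble with columns `sample_id`, `population`.
#' @export
read_pop_table <- function(path) {
  if (!file.exists(path)) {
    abort_input(paste0("Population table not found: ", path))
  }
  pops <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "population") %in% names(pops))) {
    abort_input("Population table needs columns `sample_id` and `population`.")
  }
  pops <- as_tibble(pops[, c("sample_id", "population")])
  if (anyDuplicated(pops$sample_id)) {
    abort_input("Population table assigns a sample more than once.")
  }
  if (!all(pops$population %in% c("HA", "LA"))) {
    abort_input("Populations must be coded HA or LA.")
  }
  if (length(unique(pops$population)) < 2) {
    abort_input("Both populations (HA and LA) must be non-empty.")
  }
  pops
}

# "0/0"-style GT strings (phased or not) -> alternate-allele dosage
gt_to_dosage <- function(gt) {
  core <- sub(":.*", "", gt)
  dosage <- rep(NA_integer_, length(core))
  dosage[core %in% c("0/0", "0|0")] <- 0L
  dosage[core %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dosage[core %in% c("1/1", "1|1")] <- 2L
  dosage
}

empty_variant_table <- function() {
  tibble(
    contig = character(), pos = integer(), ref = character(),
    alt = character(), dp = numeric(), qd = numeric(), mq = numeric(),
    sor = numeric(),
    hom_ref_ha = integer(), het_ha = integer(), hom_alt_ha = integer(),
    miss_ha = integer(),
    hom_ref_la = integer(), het_la = integer(), hom_alt_la = integer(),
    miss_la = integer()
  )
}

#' Read a two-population variant table from a VCF
#'
#' Parses a multi-sample VCF (via \pkg{vcfR}) together with a population
#' assignment, collapsing per-sample genotypes into the per-population
#' genotype counts that all downstream statistics consume. Multi-allelic
#' records are dropped (the scan is defined on biallelic SNPs) with a
#' message reporting how many. Records are sorted by contig then position.
#'
#' @param vcf_path Path to a VCF 4.2 file with a GT FORMAT field and
#'   DP/QD/MQ/SOR INFO annotations (any of which may be absent).
#' @param pops A population table as returned by [read_pop_table()], or a
#'   path to one. Every VCF sample must be assigned.
#' @param genotypes If `TRUE`, attach the full sites-by-samples alternate
#'   allele dosage matrix as attribute `"genotypes"`.
#' @return A tibble with one row per biallelic record and columns `contig`,
#'   `pos`, `ref`, `alt`, `dp`, `qd`, `mq`, `sor` and per-population
#'   genotype counts `hom_ref_ha`, `het_ha`, `hom_alt_ha`, `miss_ha` (and
#'   the `_la` counterparts). Attribute `"contig_lengths"` carries contig
#'   lengths parsed from the VCF header when present; attribute
#'   `"n_multiallelic_dropped"` the number of dropped records.
#' @export
read_variants <- function(vcf_path, pops, genotypes = FALSE) {
  if (!file.exists(vcf_path)) {
    abort_input(paste0("VCF not found: ", vcf_path))
  }
  if (is.character(pops)) pops <- read_pop_table(pops)

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)

  contig_lengths <- parse_contig_lengths(vcf@meta)

  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(vcf@fix) == 0) {
    out <- empty_variant_table()
    attr(out, "contig_lengths") <- contig_lengths
    attr(out, "n_multiallelic_dropped") <- 0L
    return(out)
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt_raw)
  unknown <- setdiff(samples, pops$sample_id)
  if (length(unknown) > 0) {
    abort_input(paste0(
      "Sample(s) missing from population table: ",
      paste(unknown, collapse = ", ")
    ))
  }

  multi <- !is.na(fix$ALT) & grepl(",", fix$ALT, fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0) {
    inform(sprintf("Dropped %d multi-allelic record(s).", n_multi))
  }
  keep <- which(!multi)

  info_num <- function(field) {
    suppressWarnings(
      as.numeric(vcfR::extract.info(vcf, element = field))
    )[keep]
  }

  dosage <- apply(gt_raw[keep, , drop = FALSE], 2, gt_to_dosage)
  dosage <- matrix(dosage,
    ncol = length(samples),
    dimnames = list(NULL, samples)
  )

  pop_of <- setNames(pops$population, pops$sample_id)[samples]
  count_pop <- function(pop, value) {
    cols <- which(pop_of == pop)
    m <- dosage[, cols, drop = FALSE]
    if (is.na(value)) {
      as.integer(rowSums(is.na(m)))
    } else {
      as.integer(rowSums(!is.na(m) & m == value))
    }
  }

  out <- tibble(
    contig = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    dp = info_num("DP"),
    qd = info_num("QD"),
    mq = info_num("MQ"),
    sor = info_num("SOR"),
    hom_ref_ha = count_pop("HA", 0L),
    het_ha = count_pop("HA", 1L),
    hom_alt_ha = count_pop("HA", 2L),
    miss_ha = count_pop("HA", NA),
    hom_ref_la = count_pop("LA", 0L),
    het_la = count_pop("LA", 1L),
    hom_alt_la = count_pop("LA", 2L),
    miss_la = count_pop("LA", NA)
  )
  ord <- order(out$contig, out$pos)
  out <- out[ord, ]
  attr(out, "contig_lengths") <- contig_lengths
  attr(out, "n_multiallelic_dropped") <- n_multi
  if (genotypes) {
    attr(out, "genotypes") <- dosage[ord, , drop = FALSE]
  }
  out
}

parse_contig_lengths <- function(meta) {
  lines <- grep("^##contig=", meta, value = TRUE)
  if (length(lines) == 0) {
    return(NULL)
  }
  ids <- sub('.*ID=([^,>"]+).*', "\\1", lines)
  lens <- suppressWarnings(as.integer(sub('.*length=([0-9]+).*', "\\1", lines)))
  setNames(lens, ids)
}

#' Apply hard-quality verdicts to a variant table
#'
#' Evaluates the removal rules of [hard_filter_thresholds()] on every record
#' and annotates the table rather than subsetting it, so that callers can
#' inspect the reasons. A record fails when any of `DP < dp_min`,
#' `QD < qd_min`, `MQ < mq_min`, `SOR > sor_max` holds (strict
#' inequalities: boundary values pass) or when the needed annotation is
#' missing.
#'
#' @param variants A variant table from [read_variants()] (or any tibble
#'   with `dp`, `qd`, `mq`, `sor` columns).
#' @param thresholds A [hard_filter_thresholds()].
#' @return The input with two extra columns: `hard_pass` (logical) and
#'   `hard_reasons` (comma-joined names of the violated rules, `NA` when the
#'   record passes).
#' @examples
#' tb <- tibble::tibble(dp = c(9, 10), qd = 20, mq = 60, sor = 1)
#' hard_filter(tb)
#' @export
hard_filter <- function(variants, thresholds = hard_filter_thresholds()) {
  stopifnot(inherits(thresholds, "hard_filter_thresholds"))
  fail_dp <- is.na(variants$dp) | variants$dp < thresholds$dp_min
  fail_qd <- is.na(variants$qd) | variants$qd < thresholds$qd_min
  fail_mq <- is.na(variants$mq) | variants$mq < thresholds$mq_min
  fail_sor <- is.na(variants$sor) | variants$sor > thresholds$sor_max
  reasons <- cbind(DP = fail_dp, QD = fail_qd, MQ = fail_mq, SOR = fail_sor)
  variants$hard_pass <- rowSums(reasons) == 0
  variants$hard_reasons <- apply(reasons, 1, function(r) {
    if (!any(r)) NA_character_ else paste(colnames(reasons)[r], collapse = ",")
  })
  variants
}

# combined-population alternate-allele count and called chromosomes
allele_counts <- function(variants) {
  alt <- with(variants, het_ha + 2L * hom_alt_ha + het_la + 2L * hom_alt_la)
  called <- with(
    variants,
    hom_ref_ha + het_ha + hom_alt_ha + hom_ref_la + het_la + hom_alt_la
  )
  list(alt = alt, n_chr = 2L * called)
}

#' Apply the minor-allele-count verdict to a variant table
#'
#' Computes, over all called genotypes of both populations combined, the
#' minor allele count `MAC = min(alt, n_chr - alt)` and flags records with
#' `MAC >= mac_min` as passing (boundary retained). Records with no called
#' genotypes get `mac = NA` and fail.
#'
#' @inheritParams hard_filter
#' @param mac_min Minimum minor allele count to retain (default 8).
#' @return The input with extra columns `mac` and `mac_pass`.
#' @export
mac_filter <- function(variants, mac_min = 8) {
  ac <- allele_counts(variants)
  mac <- pmin(ac$alt, ac$n_chr - ac$alt)
  mac[ac$n_chr == 0] <- NA_integer_
  variants$mac <- as.integer(mac)
  variants$mac_pass <- !is.na(mac) & mac >= mac_min
  variants
}

#' Filter a variant table and account for every removal
#'
#' Composes [hard_filter()] and [mac_filter()] (the two verdicts are
#' per-record, so their order is immaterial) and subsets to the records that
#' pass both, attaching a removal ledger in which every input record appears
#' exactly once: either as retained or under the full comma-joined set of
#' rules it violated.
#'
#' @inheritParams hard_filter
#' @inheritParams mac_filter
#' @return The retained records (with `mac` column kept), with attribute
#'   `"ledger"`: a tibble of `reason` (`"retained"` or a reason set such as
#'   `"DP,SOR"` or `"MAC"`) and `n`. Retrieve it with [filter_ledger()].
#' @export
filter_variants <- function(variants,
                            thresholds = hard_filter_thresholds(),
                            mac_min = 8) {
  flagged <- mac_filter(hard_filter(variants, thresholds), mac_min)
  reason <- ifelse(is.na(flagged$hard_reasons), "", flagged$hard_reasons)
  reason <- ifelse(
    flagged$mac_pass, reason,
    ifelse(reason == "", "MAC", paste0(reason, ",MAC"))
  )
  reason[reason == ""] <- "retained"
  ledger <- as_tibble(as.data.frame(table(reason = reason),
                                    stringsAsFactors = FALSE))
  names(ledger) <- c("reason", "n")
  ledger$n <- as.integer(ledger$n)
  out <- flagged[flagged$hard_pass & flagged$mac_pass, , drop = FALSE]
  out$hard_pass <- out$hard_reasons <- out$mac_pass <- NULL
  attr(out, "ledger") <- ledger
  attr(out, "contig_lengths") <- attr(variants, "contig_lengths")
  out
}

#' Retrieve the removal ledger of a filtered variant table
#'
#' @param variants The result of [filter_variants()].
#' @return A tibble with columns `reason` and `n`.
#' @export
filter_ledger <- function(variants) {
  ledger <- attr(variants, "ledger")
  if (is.null(ledger)) {
    abort_input("No ledger attached; was this produced by filter_variants()?")
  }
  ledger
}
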