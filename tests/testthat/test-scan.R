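make_summaries <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    n_snps = sample(1:20, n, replace = TRUE),
    mean_fst = runif(n, -0.05, 0.8),
    mean_pi_ha = runif(n, 0, 0.5),
    mean_pi_la = runif(n, 0.001, 0.5)
  ) |>
    dplyr::mutate(ratio = -log10(mean_pi_ha / mean_pi_la))
}

test_that("site-to-gene assignment pins the coordinate convention", {
  genes <- tibble::tibble(
    contig = "c1", start = 100L, end = 200L, gene_id = "gA"
  )
  inside <- assign_sites_to_genes(
    tibble::tibble(contig = "c1", pos = 101L), genes
  )
  expect_equal(inside$gene_id, "gA") # first base of a [100, 200) interval
  outside <- suppressMessages(assign_sites_to_genes(
    tibble::tibble(contig = "c1", pos = 100L), genes
  ))
  expect_equal(nrow(outside), 0L) # pos 100 is base 99 in 0-based coordinates
  last <- assign_sites_to_genes(
    tibble::tibble(contig = "c1", pos = 200L), genes
  )
  expect_equal(last$gene_id, "gA")
  past <- suppressMessages(assign_sites_to_genes(
    tibble::tibble(contig = "c1", pos = 201L), genes
  ))
  expect_equal(nrow(past), 0L)
})

test_that("assignment matches brute-force membership, duplicating overlaps", {
  set.seed(33)
  genes <- tibble::tibble(
    contig = sample(c("c1", "c2"), 30, replace = TRUE),
    start = sample(0:900, 30),
    gene_id = sprintf("g%02d", 1:30)
  )
  genes$end <- genes$start + sample(50:300, 30, replace = TRUE)
  sites <- tibble::tibble(
    contig = sample(c("c1", "c2"), 200, replace = TRUE),
    pos = sample(1:1200, 200)
  )
  got <- suppressMessages(assign_sites_to_genes(sites, genes))
  want <- oracle_assign(sites, genes)
  key <- function(d) sort(paste(d$contig, d$pos, d$gene_id))
  expect_identical(key(got), key(want))
})

test_that("malformed BED lines are rejected by line number", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("c1\t0\t100\tg1", "c1\t200\tnope\tg2"), f)
  expect_error(read_gene_bed(f), "line 2")
  writeLines(c("c1\t300\t100\tg1"), f)
  expect_error(read_gene_bed(f), "line 1")
})

test_that("gene summaries handle ratio sentinels and missing fst", {
  sites <- tibble::tibble(
    gene_id = c("a", "a", "b", "c", "d"),
    fst = c(0.5, NA, 1, 0.2, NA),
    pi_ha = c(0.002, 0, 0, 0.004, 0.1),
    pi_la = c(0.01, 0.01, 0.5, 0.005, 0)
  )
  g <- summarise_genes(sites)
  a <- g[g$gene_id == "a", ]
  expect_equal(a$mean_fst, 0.5) # NA fst excluded from the mean
  expect_equal(a$ratio, 1.0) # -log10(0.001/0.010)
  b <- g[g$gene_id == "b", ]
  expect_identical(b$ratio, Inf) # zero HA diversity, positive LA
  cc <- g[g$gene_id == "c", ]
  expect_equal(cc$ratio, -log10(0.8), tolerance = 1e-12)
  d <- g[g$gene_id == "d", ]
  expect_true(is.na(d$ratio)) # zero LA diversity: ratio undefined
  expect_true(is.na(d$mean_fst))
})

test_that("decile flags use nearest-rank thresholds with tie inclusion", {
  s <- make_summaries(20, seed = 2)
  s$mean_fst <- seq(0.01, 0.96, length.out = 20) # distinct
  flagged <- decile_flags(s)
  expect_equal(sum(flagged$in_top_decile_fst), 2L) # top 10% of 20
  # tie at the threshold: ranks 2 and 3 share the cutoff value -> 3 flagged
  s$mean_fst[18] <- s$mean_fst[19]
  flagged <- decile_flags(s)
  expect_equal(sum(flagged$in_top_decile_fst), 3L)
  # Inf sentinel ranks above all finite ratios
  s$ratio[5] <- Inf
  flagged <- decile_flags(s)
  expect_true(flagged$in_top_decile_ratio[5])
  # degenerate table: warning, threshold reduces to the maximum
  expect_warning(decile_flags(make_summaries(4)), "degenerate")
})

test_that("staged filters match the brute-force oracle on random tables", {
  cfg <- scan_config()
  set.seed(9)
  for (rep in 1:50) {
    n <- sample(5:50, 1)
    s <- make_summaries(n, seed = rep + 100)
    # inject sentinel and tie cases
    if (rep %% 3 == 0) s$mean_pi_ha[1] <- 0
    if (rep %% 4 == 0) s$mean_pi_la[2] <- s$mean_pi_ha[2] * 2 # boundary
    if (rep %% 5 == 0) s$mean_fst[3] <- max(s$mean_fst)
    s$ratio <- dplyr::case_when(
      s$mean_pi_la == 0 ~ NA_real_,
      s$mean_pi_ha == 0 ~ Inf,
      TRUE ~ -log10(s$mean_pi_ha / s$mean_pi_la)
    )
    res <- apply_scan_filters(suppressWarnings(decile_flags(s, cfg)), cfg)
    o <- oracle_scan(s)
    expect_identical(sort(res$candidates$gene_id), o$candidates)
    expect_identical(res$ledger$surviving, as.integer(o$counts))
  }
})

test_that("boundary semantics: half-pi boundary passes, 4-SNP genes fail", {
  s <- tibble::tibble(
    gene_id = c("exact_half", "four_snps", "strong"),
    n_snps = c(10L, 4L, 20L),
    mean_fst = c(0.9, 0.8, 0.7),
    mean_pi_ha = c(0.005, 0.001, 0.001),
    mean_pi_la = c(0.010, 0.100, 0.100)
  )
  s$ratio <- -log10(s$mean_pi_ha / s$mean_pi_la)
  cfg <- scan_config(quantile = 0.1) # flag (almost) everything top-decile
  res <- apply_scan_filters(suppressWarnings(decile_flags(s, cfg)), cfg)
  g <- res$genes
  expect_true(g$passes_half_pi[g$gene_id == "exact_half"])
  expect_false(g$passes_min_snps[g$gene_id == "four_snps"])
  expect_true(all(c("exact_half", "strong") %in% res$candidates$gene_id))
  expect_false("four_snps" %in% res$candidates$gene_id)
  # candidate implies every flag
  expect_true(all(
    g$in_top_decile_fst[g$candidate] & g$in_top_decile_ratio[g$candidate] &
      g$passes_half_pi[g$candidate] & g$passes_min_snps[g$candidate]
  ))
})

test_that("half-pi verdict is consistent with the ratio threshold log10(2)", {
  s <- make_summaries(200, seed = 4)
  flagged <- decile_flags(s)
  res <- apply_scan_filters(flagged)
  g <- res$genes
  pos <- g$mean_pi_ha > 0 & g$mean_pi_la > 0
  expect_equal(
    g$passes_half_pi[pos],
    g$ratio[pos] >= log10(2) - 1e-12
  )
})

test_that("label swap negates finite ratios and keeps fst", {
  sim <- small_sim(seed = 61, n_genes = 50)
  # swap population labels in the table
  pops <- read_pop_table(sim$paths[["pop"]])
  pops_swapped <- pops
  pops_swapped$population <- ifelse(pops$population == "HA", "LA", "HA")
  v1 <- read_variants(sim$paths[["vcf"]], pops)
  v2 <- read_variants(sim$paths[["vcf"]], pops_swapped)
  g1 <- summarise_genes(assign_sites_to_genes(site_table(v1), sim$paths[["bed"]]))
  g2 <- summarise_genes(assign_sites_to_genes(site_table(v2), sim$paths[["bed"]]))
  expect_equal(g1$mean_fst, g2$mean_fst, tolerance = 1e-12)
  finite <- is.finite(g1$ratio) & is.finite(g2$ratio)
  expect_equal(g1$ratio[finite], -g2$ratio[finite], tolerance = 1e-12)
})

test_that("survivor counts are monotone and candidates nest in earlier stages", {
  sim <- small_sim(seed = 71, n_genes = 60)
  scan <- run_selection_scan(sim$paths[["vcf"]], sim$paths[["bed"]],
                             sim$paths[["pop"]])
  expect_true(all(diff(scan$ledger$surviving) <= 0))
  expect_true(all(scan$ledger$surviving <= scan$ledger$entering))
  dual <- scan$genes$gene_id[scan$genes$in_top_decile_fst &
                               scan$genes$in_top_decile_ratio]
  expect_true(all(scan$candidates$gene_id %in% dual))
  # deterministic on identical inputs
  scan2 <- run_selection_scan(sim$paths[["vcf"]], sim$paths[["bed"]],
                              sim$paths[["pop"]])
  expect_identical(scan$genes, scan2$genes)
  expect_identical(scan$candidates, scan2$candidates)
})

test_that("tidy, glance and autoplot expose the scan result", {
  sim <- small_sim(seed = 81, n_genes = 40)
  scan <- run_selection_scan(sim$paths[["vcf"]], sim$paths[["bed"]],
                             sim$paths[["pop"]])
  td <- generics::tidy(scan)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("gene_id", "mean_fst", "ratio", "candidate") %in% names(td)))
  gl <- generics::glance(scan)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_candidates, nrow(scan$candidates))
  p <- ggplot2::autoplot(scan)
  expect_s3_class(p, "ggplot")
  expect_output(print(scan), "candidate genes")
})
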