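test_that("pausing regions follow the TSS-30..TSS+300 / TSS+300..TES definitions", {
  gp <- tibble::tibble(gene_id = "p", chrom = "chr1", strand = "+",
                       start = 1000, end = 3000, tss = 1000, tes = 2999)
  pr <- promoter_region(gp)
  expect_equal(c(pr$start, pr$end), c(970, 1300))
  br <- body_region(gp)
  expect_equal(c(br$start, br$end), c(1300, 3000))
  gm <- tibble::tibble(gene_id = "m", chrom = "chr1", strand = "-",
                       start = 3001, end = 5001, tss = 5000, tes = 3001)
  prm <- promoter_region(gm)
  expect_equal(c(prm$start, prm$end), c(4701, 5031))
  brm <- body_region(gm)
  expect_equal(c(brm$start, brm$end), c(3001, 4701))
  # strand-mirror oracle: widths match and regions abut at the same offset
  expect_equal(prm$end - prm$start, pr$end - pr$start)
  expect_equal(brm$end - brm$start, br$end - br$start)
  # clipping at the chromosome start
  g0 <- tibble::tibble(gene_id = "z", chrom = "chr1", strand = "+",
                       start = 10, end = 2000, tss = 10, tes = 1999)
  expect_equal(promoter_region(g0)$start, 0)
  # genes too short for a body get an empty region
  gshort <- tibble::tibble(gene_id = "s", chrom = "chr1", strand = "+",
                           start = 0, end = 250, tss = 0, tes = 249)
  bs <- body_region(gshort)
  expect_equal(bs$end - bs$start, 0)
})

test_that("region density averages overlapping bins unweighted", {
  track <- tibble::tibble(chrom = "chr1", start = c(0, 100), end = c(100, 200),
                          value = c(1, 3))
  region <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
  expect_equal(region_density(track, region), 2.0)
  # length-weighted option: 50 bp of each bin -> also 2 here, but asymmetric
  # overlap discriminates
  region2 <- tibble::tibble(chrom = "chr1", start = 90, end = 200)
  expect_equal(region_density(track, region2), 2.0)
  expect_equal(region_density(track, region2, weighted = TRUE),
               (1 * 10 + 3 * 100) / 110)
  # uniform track, any region
  expect_equal(region_density(tibble::tibble(chrom = "chr1", start = 0,
                                             end = 1e6, value = 2),
                              tibble::tibble(chrom = "chr1", start = 12345,
                                             end = 23456)), 2.0)
  # uncovered gap
  expect_equal(region_density(track, tibble::tibble(chrom = "chr1",
                                                    start = 5000, end = 6000)), 0)
  expect_equal(region_density(track, tibble::tibble(chrom = "chr2",
                                                    start = 0, end = 100)), 0)
})

test_that("the filter cascade reproduces the worked examples", {
  # gene shorter than 1 kb is discarded with reason short_gene
  fx <- make_pi_fixture(c(1, 1.1, 1.2, 1.3, 10))
  short <- tibble::tibble(gene_id = "tiny", chrom = "chr1", start = 400000,
                          strand = "+") |>
    dplyr::mutate(end = start + 900, tss = start, tes = end - 1,
                  length = 900)
  genes <- dplyr::bind_rows(fx$genes, short)
  track <- dplyr::bind_rows(
    fx$track,
    tibble::tibble(chrom = "chr1", start = 400000 - 30, end = 400000 + 300, value = 2),
    tibble::tibble(chrom = "chr1", start = 400000 + 300, end = 400000 + 900, value = 1)
  )
  pt <- pausing_pipeline(list(cellA = track), genes)
  expect_equal(pt$excluded_reason[pt$gene_id == "tiny"], "short_gene")
  # Tukey fences from Q1 = 1.1, Q3 = 1.3 remove exactly the PI of 10
  expect_equal(pt$excluded_reason[pt$pi_raw == 10], "outlier")
  expect_setequal(pt$excluded_reason[pt$gene_id %in% fx$genes$gene_id[1:4]],
                  "none")
  # survivors {1, 1.1, 1.2, 1.3} min-max normalize with endpoints 0 and 1
  surv <- pt |> dplyr::filter(excluded_reason == "none") |> dplyr::arrange(pi_raw)
  expect_equal(surv$pi_norm, (surv$pi_raw - 1) / 0.3)
  expect_equal(range(surv$pi_norm), c(0, 1))
})

test_that("min-max normalization maps {0.2, 0.7, 1.2} to {0, 0.5, 1}", {
  fx <- make_pi_fixture(c(0.2, 0.7, 1.2))
  pt <- pausing_pipeline(list(cellA = fx$track), fx$genes)
  expect_equal(sort(pt$pi_norm), c(0, 0.5, 1))
})

test_that("genes with zero body density are undefined, not infinite", {
  fx <- make_pi_fixture(c(1, 1.1, 1.2))
  # zero out one gene's body
  track <- fx$track
  body3 <- body_region(fx$genes[3, ])
  track$value[track$start == body3$start & track$end == body3$end] <- 0
  pt <- pausing_pipeline(list(cellA = track), fx$genes)
  expect_equal(pt$excluded_reason[pt$gene_id == "g03"], "undefined")
  expect_true(all(is.finite(pt$pi_raw) | is.na(pt$pi_raw)))
})

test_that("the unexpressed-sum filter drops genes below the floor across cells", {
  fx <- make_pi_fixture(c(0.03, 1, 1.1))
  # three identical cell states: gene 1 sums to 0.09 < 0.2
  pt <- pausing_pipeline(list(a = fx$track, b = fx$track, c = fx$track),
                         fx$genes)
  expect_true(all(pt$excluded_reason[pt$gene_id == "g01"] == "unexpressed"))
  expect_true(all(pt$excluded_reason[pt$gene_id != "g01"] == "none"))
})

test_that("multiplying a track by a constant leaves pi_raw unchanged", {
  fx <- make_pi_fixture(c(0.5, 1, 1.5, 2))
  pt1 <- pausing_pipeline(list(a = fx$track), fx$genes)
  scaled <- dplyr::mutate(fx$track, value = value * 7.3)
  pt2 <- pausing_pipeline(list(a = scaled), fx$genes)
  expect_equal(pt1$pi_raw, pt2$pi_raw, tolerance = 1e-12)
})

test_that("exclusion accounting is exhaustive per cell state", {
  cfg <- sim_config(n_genes = 200, seed = 25, noise_sd = 0.1)
  g <- sim_genome(cfg)
  tracks <- sim_coverage(g$genes, g$ages, cfg)
  pt <- pausing_pipeline(tracks, g$genes)
  per_cell <- pt |> dplyr::count(cell, excluded_reason) |>
    dplyr::group_by(cell) |> dplyr::summarise(total = sum(n))
  expect_true(all(per_cell$total == nrow(g$genes)))
  expect_true(all(pt$excluded_reason %in%
                    c("none", "short_gene", "undefined", "outlier", "unexpressed")))
  norm <- pt$pi_norm[pt$excluded_reason == "none"]
  expect_true(all(norm >= 0 & norm <= 1))
  expect_true(all(is.na(pt$pi_norm[pt$excluded_reason != "none"])))
})

test_that("a genome mirror transform leaves pausing indices unchanged", {
  fx <- make_pi_fixture(c(0.8, 1.3, 2))
  M <- 1e6
  m_genes <- fx$genes |>
    dplyr::mutate(s2 = M - end, end = M - start, start = s2,
                  strand = "-",
                  tss = end - 1, tes = start, length = end - start) |>
    dplyr::select(-s2)
  m_track <- fx$track |>
    dplyr::mutate(s2 = M - end, end = M - start, start = s2) |>
    dplyr::select(-s2)
  pt <- pausing_pipeline(list(a = fx$track), fx$genes)
  mpt <- pausing_pipeline(list(a = m_track), m_genes)
  expect_equal(mpt$pi_raw[match(pt$gene_id, mpt$gene_id)], pt$pi_raw,
               tolerance = 1e-12)
})

test_that("rank-sum comparisons match exact small-sample enumeration", {
  # {1,2,3} vs {4,5,6}: U = 0, exact two-sided p = 0.1
  pt <- tibble::tibble(
    gene_id = paste0("g", 1:6), cell = "a",
    promoter_density = 1, body_density = 1,
    pi_raw = 1, excluded_reason = "none",
    pi_norm = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  )
  ages <- tibble::tibble(gene_id = paste0("g", 1:6),
                         category = rep(c("UC", "MM"), each = 3))
  class(pt) <- c("pausing_table", class(pt))
  cmp <- compare_pi_distributions(pt, ages)
  expect_equal(cmp$U, 0)
  expect_equal(cmp$p_value, 0.1)
  # identical groups give p = 1
  pt2 <- pt |> dplyr::mutate(pi_norm = rep(c(0.1, 0.2, 0.3), 2))
  class(pt2) <- c("pausing_table", class(pt2))
  cmp2 <- compare_pi_distributions(pt2, ages)
  expect_equal(cmp2$p_value, 1)
})

test_that("planted category differences are detected with high power", {
  cfg <- sim_config(n_genes = 900, n_chromosomes = 6, chrom_length = 1.5e7,
                    seed = 26, noise_sd = 0.1,
                    pi_mean_by_category = c(UC = 2, EM = 1.5, MM = 1),
                    cell_states = "stem", cell_pi_factor = c(stem = 1))
  g <- sim_genome(cfg)
  tracks <- sim_coverage(g$genes, g$ages, cfg)
  pt <- pausing_pipeline(tracks, g$genes)
  cmp <- compare_pi_distributions(pt, g$ages)
  uc_mm <- cmp |> dplyr::filter(comparison == "category_within_cell",
                                group_a == "UC", group_b == "MM")
  expect_lt(uc_mm$p_value, 1e-4)
})
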