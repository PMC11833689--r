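test_that("age categories respect inclusive/exclusive bounds", {
  expect_equal(age_category(2, c(3, 9)), "UC")
  expect_equal(age_category(3, c(3, 9)), "UC")
  expect_equal(age_category(9, c(3, 9)), "EM")
  expect_equal(age_category(10, c(3, 9)), "MM")
  expect_equal(age_category(c(1, 16), c(5, 10)), c("UC", "MM"))
  expect_error(age_category(0), "1..16")
  expect_error(age_category(17), "1..16")
})

test_that("polycomb targeting uses the single TSS base with half-open peaks", {
  genes <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                          chrom = "chr1",
                          start = c(500, 600, 100), end = c(1500, 1600, 900),
                          strand = c("+", "+", "-")) |>
    dplyr::mutate(tss = ifelse(strand == "+", start, end - 1))
  peaks <- tibble::tibble(chrom = "chr1", start = c(400, 850), end = c(600, 950))
  pc <- polycomb_targets(genes, peaks)
  expect_equal(pc$polycomb, c(1L, 0L, 1L)) # tss 500 in [400,600); 600 out; 899 in [850,950)
})

test_that("LAD genes require >= 1 base of body overlap and honor the mode filter", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          start = c(1000, 1000), end = c(2000, 2000),
                          strand = "+") |>
    dplyr::mutate(tss = start)
  lads_touch <- tibble::tibble(chrom = "chr1", start = 2000, end = 2100)
  expect_equal(lad_genes(genes, lads_touch)$lad, c(0L, 0L))
  lads_in <- tibble::tibble(chrom = "chr1", start = 1900, end = 2500,
                            type = "facultative")
  expect_equal(lad_genes(genes, lads_in)$lad, c(1L, 1L))
  expect_equal(lad_genes(genes, lads_in, mode = "constitutive")$lad, c(0L, 0L))
  expect_equal(lad_genes(genes, lads_in, mode = "facultative")$lad, c(1L, 1L))
  expect_error(lad_genes(genes, lads_in, mode = "sometimes"))
})

test_that("promoter windows are strand-aware mirrors and include the TSS", {
  gp <- tibble::tibble(gene_id = "p", chrom = "chr1", strand = "+", tss = 1000)
  wp <- promoter_window(gp, upstream = 1000, downstream = 1000)
  expect_equal(c(wp$start, wp$end), c(0, 2000))
  gm <- tibble::tibble(gene_id = "m", chrom = "chr1", strand = "-", tss = 5000)
  wm <- promoter_window(gm, upstream = 300, downstream = 30)
  expect_equal(c(wm$start, wm$end), c(4971, 5301))
  # zero-width request still yields the single TSS base
  w0p <- promoter_window(gp, 0, 0)
  expect_equal(c(w0p$start, w0p$end), c(1000, 1001))
  w0m <- promoter_window(gm, 0, 0)
  expect_equal(c(w0m$start, w0m$end), c(5000, 5001))
  # mirror-image oracle: the minus window contains position tss - k iff the
  # plus window contains tss + k
  wply <- promoter_window(tibble::tibble(gene_id = "p", chrom = "c",
                                         strand = "+", tss = 5000), 300, 30)
  k <- -400:400
  in_plus <- (5000 + k) >= wply$start & (5000 + k) < wply$end
  in_minus <- (5000 - k) >= wm$start & (5000 - k) < wm$end
  expect_equal(in_minus, in_plus)
})

test_that("promoter site counts and methylation aggregate per gene and category", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          start = c(5000, 50000), end = c(8000, 53000),
                          strand = "+") |>
    dplyr::mutate(tss = start)
  sites <- tibble::tibble(chrom = "chr1",
                          pos = c(4500, 5000, 5999, 6001, 49000, 70000))
  counts <- count_promoter_sites(genes, sites, upstream = 1000, downstream = 1000)
  expect_equal(counts$cpg_count, c(3L, 1L)) # 4500,5000,5999 in g1; 49000 in g2
  scores <- tibble::tibble(chrom = "chr1", pos = c(4500, 5000), score = c(0.2, 0.4))
  meth <- promoter_methylation(genes, scores)
  expect_equal(meth$meth_mean, c(0.3, NA_real_))
  # no sites at all
  empty <- count_promoter_sites(genes, sites[0, ])
  expect_equal(empty$cpg_count, c(0L, 0L))
})

test_that("DE classification matches the log2FC and adjusted-p rules", {
  de <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    log2FC = c(2.5, 2.5, -3, 1.9, -2.5, 3),
    padj = c(0.05, 0.2, 0.01, 0.001, NA, 0.099)
  )
  cls <- classify_de(de)
  expect_equal(cls$de_label, c("up", "none", "down", "none", "none", "up"))
  expect_setequal(unique(cls$de_label), c("up", "down", "none"))
})

test_that("interval annotations agree exactly with a brute-force scan", {
  for (s in 1:8) {
    withr::with_seed(s, {
      n_g <- 60; n_p <- 80
      genes <- tibble::tibble(
        gene_id = sprintf("g%02d", 1:n_g),
        chrom = sample(c("chr1", "chr2"), n_g, TRUE),
        start = sample.int(10000, n_g),
        strand = sample(c("+", "-"), n_g, TRUE)
      ) |>
        dplyr::mutate(end = start + sample.int(500, n_g),
                      tss = ifelse(strand == "+", start, end - 1))
      peaks <- tibble::tibble(
        chrom = sample(c("chr1", "chr2"), n_p, TRUE),
        start = sample.int(10000, n_p)
      ) |>
        dplyr::mutate(end = start + sample.int(400, n_p))
      pc <- polycomb_targets(genes, peaks)
      brute_pc <- purrr::map_int(seq_len(n_g), function(i) {
        as.integer(any(peaks$chrom == genes$chrom[i] &
                         peaks$start <= genes$tss[i] & genes$tss[i] < peaks$end))
      })
      expect_identical(pc$polycomb, brute_pc)
      lg <- lad_genes(genes, peaks)
      brute_lg <- purrr::map_int(seq_len(n_g), function(i) {
        as.integer(any(peaks$chrom == genes$chrom[i] &
                         peaks$start < genes$end[i] & genes$start[i] < peaks$end))
      })
      expect_identical(lg$lad, brute_lg)
    })
  }
})

test_that("adding peaks or LADs never flips an annotation from 1 to 0", {
  withr::with_seed(21, {
    genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:40), chrom = "chr1",
                            start = sample.int(50000, 40), strand = "+") |>
      dplyr::mutate(end = start + 1000, tss = start)
    peaks1 <- tibble::tibble(chrom = "chr1", start = sample.int(50000, 20)) |>
      dplyr::mutate(end = start + 500)
    peaks2 <- dplyr::bind_rows(peaks1,
                               tibble::tibble(chrom = "chr1", start = sample.int(50000, 20)) |>
                                 dplyr::mutate(end = start + 500))
    expect_true(all(polycomb_targets(genes, peaks2)$polycomb >=
                      polycomb_targets(genes, peaks1)$polycomb))
    expect_true(all(lad_genes(genes, peaks2)$lad >= lad_genes(genes, peaks1)$lad))
  })
})

test_that("mirroring all coordinates and strands leaves annotations invariant", {
  withr::with_seed(22, {
    M <- 100000
    genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:30), chrom = "chr1",
                            start = sample.int(50000, 30),
                            strand = sample(c("+", "-"), 30, TRUE)) |>
      dplyr::mutate(end = start + sample.int(2000, 30),
                    tss = ifelse(strand == "+", start, end - 1),
                    tes = ifelse(strand == "+", end - 1, start))
    peaks <- tibble::tibble(chrom = "chr1", start = sample.int(50000, 40)) |>
      dplyr::mutate(end = start + sample.int(1000, 40))
    mirror_iv <- function(d) dplyr::mutate(d, s2 = M - end, end = M - start,
                                           start = s2)[, setdiff(names(d), "s2")]
    m_genes <- genes |>
      dplyr::mutate(s2 = M - end, end = M - start, start = s2,
                    strand = ifelse(strand == "+", "-", "+"),
                    tss = ifelse(strand == "+", start, end - 1),
                    tes = ifelse(strand == "+", end - 1, start)) |>
      dplyr::select(-s2)
    m_peaks <- mirror_iv(peaks)
    expect_identical(polycomb_targets(genes, peaks)$polycomb,
                     polycomb_targets(m_genes, m_peaks)$polycomb)
    expect_identical(lad_genes(genes, peaks)$lad,
                     lad_genes(m_genes, m_peaks)$lad)
  })
})
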