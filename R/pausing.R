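#' Pol II pausing regions
#'
#' The promoter region is TSS - 30 bp to TSS + 300 bp and the gene body
#' TSS + 300 bp to TES, both in transcript orientation.  In genome
#' coordinates on the minus strand these become `[tss - 300 + 1, tss + 31)`
#' and `[tes, tss - 299)` respectively.  Regions are clipped at coordinate
#' 0; a gene too short to have a body (length <= 300) gets an empty body
#' region and its pausing index is undefined.
#'
#' @param genes Gene-model tibble.
#' @return Tibble (`gene_id`, `chrom`, `start`, `end`).
#' @examples
#' g <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
#'                     start = 1000, end = 3000, tss = 1000, tes = 2999)
#' promoter_region(g)
#' body_region(g)
#' @export
promoter_region <- function(genes) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - 30, genes$tss - 300 + 1)
  end <- ifelse(plus, genes$tss + 300, genes$tss + 30 + 1)
  tibble(gene_id = genes$gene_id, chrom = genes$chrom,
         start = pmax(0, start), end = pmax(0, end))
}

#' @rdname promoter_region
#' @export
body_region <- function(genes) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss + 300, genes$tes)
  end <- ifelse(plus, genes$tes + 1, genes$tss - 300 + 1)
  tibble(gene_id = genes$gene_id, chrom = genes$chrom,
         start = pmax(0, start), end = pmax(0, pmax(start, end)))
}

#' Mean signal over a region
#'
#' Unweighted arithmetic mean of the values of all track bins overlapping
#' the region by at least one base (a bin half inside the region counts
#' with full weight, the literal "overlapping bins averaged" rule).
#' Returns 0 when no bin overlaps.  `weighted = TRUE` switches to an
#' overlap-length-weighted mean.
#'
#' @param track Signal tibble (`chrom`, `start`, `end`, `value`), 0-based
#'   half-open non-overlapping bins.
#' @param regions Tibble (`chrom`, `start`, `end`), one row per region.
#' @param weighted Length-weight the overlapping bins?
#' @return Numeric vector, one mean per region row.
#' @export
region_density <- function(track, regions, weighted = FALSE) {
  out <- numeric(nrow(regions))
  nonempty <- which(regions$end > regions$start)
  hits <- overlap_pairs(regions[nonempty, c("chrom", "start", "end"), drop = FALSE],
                        track)
  if (nrow(hits) == 0) return(out)
  q <- nonempty[hits$query]
  if (weighted) {
    w <- pmin(regions$end[q], track$end[hits$subject]) -
      pmax(regions$start[q], track$start[hits$subject])
    num <- tapply(track$value[hits$subject] * w, q, sum)
    den <- tapply(w, q, sum)
    out[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
  } else {
    m <- tapply(track$value[hits$subject], q, mean)
    out[as.integer(names(m))] <- as.numeric(m)
  }
  out
}

#' Pol II pausing-index pipeline
#'
#' Computes per-gene, per-cell-state pausing indices (PI = mean promoter
#' density / mean gene-body density) and applies the filter cascade:
#' (1) genes shorter than `min_gene_length` (default 1 kb) are discarded;
#' (2) PI is undefined when the body density is 0 (never infinity);
#' (3) within each cell state, PIs outside the Tukey fences
#' `[Q1 - iqr_k * IQR, Q3 + iqr_k * IQR]` (linear-interpolation quartiles,
#' `iqr_k = 1.5`) are removed as outliers;
#' (4) genes whose surviving PIs sum to less than `expression_floor`
#' (default 0.2) across cell states are excluded as unexpressed;
#' (5) each cell state's surviving PIs are min-max rescaled to `[0, 1]`.
#' Every exclusion is recorded with its reason, so per cell state
#' `n(input) = n(surviving) + sum over reasons`.
#'
#' @param tracks Named list of signal tibbles, one per cell state.
#' @param genes Gene-model tibble.
#' @param min_gene_length,expression_floor,iqr_k Filter parameters.
#' @param weighted Length-weighted densities? (default FALSE).
#' @param filter_order `"outlier_first"` (default: outlier removal before
#'   the unexpressed-sum filter) or `"sum_first"`.
#' @return A `pausing_table` tibble: `gene_id`, `cell`,
#'   `promoter_density`, `body_density`, `pi_raw`, `excluded_reason`
#'   (none/short_gene/undefined/outlier/unexpressed), `pi_norm`.
#' @export
pausing_pipeline <- function(tracks, genes, min_gene_length = 1000,
                             expression_floor = 0.2, iqr_k = 1.5,
                             weighted = FALSE,
                             filter_order = c("outlier_first", "sum_first")) {
  filter_order <- match.arg(filter_order)
  if (length(tracks) < 1) abort("At least one cell-state track is required.")
  if (is.null(names(tracks))) names(tracks) <- paste0("cell", seq_along(tracks))
  prom <- promoter_region(genes)
  body <- body_region(genes)
  pt <- purrr::imap_dfr(tracks, function(track, cell) {
    tibble(
      gene_id = genes$gene_id, cell = cell, length = genes$length,
      promoter_density = region_density(track, prom, weighted),
      body_density = region_density(track, body, weighted)
    )
  }) |>
    mutate(
      pi_raw = ifelse(.data$body_density > 0,
                      .data$promoter_density / .data$body_density, NA_real_),
      excluded_reason = case_when(
        length < min_gene_length ~ "short_gene",
        is.na(pi_raw) ~ "undefined",
        TRUE ~ "none"
      )
    ) |>
    select(-"length")
  flag_outliers <- function(pt) {
    pt |>
      group_by(.data$cell) |>
      mutate(excluded_reason = {
        ok <- .data$excluded_reason == "none"
        x <- .data$pi_raw[ok]
        reason <- .data$excluded_reason
        if (sum(ok) >= 4) {
          q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
          fence <- c(q[1] - iqr_k * (q[2] - q[1]), q[2] + iqr_k * (q[2] - q[1]))
          reason[ok & (.data$pi_raw < fence[1] | .data$pi_raw > fence[2])] <- "outlier"
        }
        reason
      }) |>
      ungroup()
  }
  flag_unexpressed <- function(pt) {
    pt |>
      group_by(.data$gene_id) |>
      mutate(expr_sum = sum(.data$pi_raw[.data$excluded_reason == "none"])) |>
      ungroup() |>
      mutate(excluded_reason = ifelse(.data$excluded_reason == "none" &
                                        .data$expr_sum < expression_floor,
                                      "unexpressed", .data$excluded_reason)) |>
      select(-"expr_sum")
  }
  pt <- if (filter_order == "outlier_first") {
    flag_unexpressed(flag_outliers(pt))
  } else {
    flag_outliers(flag_unexpressed(pt))
  }
  pt <- pt |>
    group_by(.data$cell) |>
    mutate(pi_norm = {
      ok <- .data$excluded_reason == "none"
      x <- .data$pi_raw
      rng <- range(x[ok])
      norm <- rep(NA_real_, length(x))
      if (any(ok)) {
        norm[ok] <- if (diff(rng) > 0) (x[ok] - rng[1]) / diff(rng) else 0.5
      }
      norm
    }) |>
    ungroup()
  if (!any(pt$excluded_reason == "none")) {
    counts <- table(pt$excluded_reason)
    abort(paste0("All genes excluded (",
                 paste(names(counts), counts, sep = ": ", collapse = ", "), ")."))
  }
  class(pt) <- c("pausing_table", class(pt))
  pt
}

#' Rank-sum comparisons of pausing-index distributions
#'
#' Two-sided Wilcoxon-Mann-Whitney tests on normalized pausing indices:
#' between age categories within each cell state, and between cell states
#' within each age category.  Exact p-values for small untied samples,
#' normal approximation with tie correction otherwise (the default
#' behaviour of [stats::wilcox.test()]).
#'
#' @param pt A `pausing_table` from [pausing_pipeline()].
#' @param ages Age table (`gene_id`, `category`).
#' @return Tibble (`comparison`, `stratum`, `group_a`, `group_b`, `U`,
#'   `p_value`); empty groups yield a warning and are skipped.
#' @export
compare_pi_distributions <- function(pt, ages) {
  dat <- pt |>
    filter(.data$excluded_reason == "none") |>
    inner_join(ages |> select("gene_id", "category"), by = "gene_id")
  pair_test <- function(xa, xb) {
    w <- suppressWarnings(stats::wilcox.test(xa, xb, exact = NULL))
    c(U = unname(w$statistic), p = w$p.value)
  }
  rows <- list()
  for (cell in unique(dat$cell)) {
    cats <- intersect(c("UC", "EM", "MM"), unique(dat$category[dat$cell == cell]))
    for (pr in utils::combn(cats, 2, simplify = FALSE)) {
      xa <- dat$pi_norm[dat$cell == cell & dat$category == pr[1]]
      xb <- dat$pi_norm[dat$cell == cell & dat$category == pr[2]]
      if (length(xa) == 0 || length(xb) == 0) { warn("Empty group; comparison skipped."); next }
      s <- pair_test(xa, xb)
      rows[[length(rows) + 1]] <- tibble(
        comparison = "category_within_cell", stratum = cell,
        group_a = pr[1], group_b = pr[2], U = s[["U"]], p_value = s[["p"]])
    }
  }
  for (cat in unique(dat$category)) {
    cells <- unique(dat$cell[dat$category == cat])
    if (length(cells) < 2) next
    for (pr in utils::combn(cells, 2, simplify = FALSE)) {
      xa <- dat$pi_norm[dat$category == cat & dat$cell == pr[1]]
      xb <- dat$pi_norm[dat$category == cat & dat$cell == pr[2]]
      if (length(xa) == 0 || length(xb) == 0) { warn("Empty group; comparison skipped."); next }
      s <- pair_test(xa, xb)
      rows[[length(rows) + 1]] <- tibble(
        comparison = "cell_within_category", stratum = cat,
        group_a = pr[1], group_b = pr[2], U = s[["U"]], p_value = s[["p"]])
    }
  }
  bind_rows(rows)
}
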