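#' Spearman correlation between age class and a gene-level quantity
#'
#' The class-mean design (default) averages the quantity within each of
#' the 16 age classes and correlates the class indices with the class
#' means — the design behind class-level trends such as expression
#' decreasing (rho near -1) and expression variability increasing (rho
#' near +1) with evolutionary youth.  `level = "gene"` instead correlates
#' per-gene class index against per-gene values.  Average ranks are used
#' for ties; p-values come from the t approximation (ties-safe).
#'
#' @param ages Age table (`gene_id`, `age_class`).
#' @param values Tibble (`gene_id`, `value`) or named vector.
#' @param level `"class_mean"` or `"gene"`.
#' @return Tibble (`rho`, `p_value`, `n`).
#' @export
spearman_age_trend <- function(ages, values, level = c("class_mean", "gene")) {
  level <- match.arg(level)
  if (!is.data.frame(values)) {
    values <- tibble(gene_id = names(values), value = as.numeric(values))
  }
  dat <- inner_join(ages, values, by = "gene_id") |>
    filter(!is.na(.data$value))
  if (level == "class_mean") {
    dat <- dat |>
      group_by(age_class = .data$age_class) |>
      summarise(value = mean(.data$value), .groups = "drop")
  }
  if (nrow(dat) < 3) abort("Need at least 3 paired observations.")
  if (sd(dat$value) == 0) abort("Values are constant; Spearman rho undefined.")
  ct <- suppressWarnings(
    stats::cor.test(dat$age_class, dat$value, method = "spearman", exact = FALSE)
  )
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(dat))
}

#' Fisher's exact gene-set overlap test
#'
#' Two-sided Fisher's exact test of the overlap between two gene sets
#' within a universe, from the 2x2 table
#' `[[overlap, |A|-overlap], [|B|-overlap, |U|-|A|-|B|+overlap]]`.
#' The odds ratio is the sample cross-product ratio of that table; when a
#' cell is zero the raw ratio is 0 or infinite and a Haldane-corrected
#' (+0.5 to every cell) ratio is also reported, with the result flagged.
#'
#' @param set_a,set_b Character vectors of gene ids (subsets of `universe`).
#' @param universe Character vector of all gene ids considered.
#' @return One-row tibble: sizes, `overlap`, `odds_ratio`,
#'   `odds_ratio_haldane`, `p_value`, `zero_cell` flag.
#' @examples
#' u <- sprintf("g%03d", 1:100)
#' fisher_enrichment(u[1:20], u[c(1:15, 26:40)], u)
#' @export
fisher_enrichment <- function(set_a, set_b, universe) {
  if (length(universe) == 0) abort("Empty universe.")
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("Both sets must be subsets of the universe.")
  }
  n11 <- length(intersect(set_a, set_b))
  n12 <- length(set_a) - n11
  n21 <- length(set_b) - n11
  n22 <- length(universe) - length(set_a) - length(set_b) + n11
  tab <- matrix(c(n11, n12, n21, n22), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  zero_cell <- any(tab == 0)
  or_raw <- (n11 * n22) / (n12 * n21) # 0/0 -> NaN, x/0 -> Inf by design
  or_h <- ((n11 + 0.5) * (n22 + 0.5)) / ((n12 + 0.5) * (n21 + 0.5))
  tibble(
    n_a = length(set_a), n_b = length(set_b), n_universe = length(universe),
    overlap = n11, odds_ratio = or_raw, odds_ratio_haldane = or_h,
    p_value = p, zero_cell = zero_cell
  )
}

#' Rank-based decile groups
#'
#' Assigns genes to 10 near-equal groups by increasing value (group 1 =
#' lowest decile).  Ties are broken by stable gene-id order, so the
#' assignment is deterministic even for constant input.
#'
#' @param values Tibble (`gene_id`, `value`) or named vector.
#' @return Tibble (`gene_id`, `group` in 1..10).
#' @export
decile_groups <- function(values) {
  if (!is.data.frame(values)) {
    values <- tibble(gene_id = names(values), value = as.numeric(values))
  }
  if (nrow(values) < 10) abort("Need at least 10 values for decile grouping.")
  ord <- order(values$value, values$gene_id)
  group <- integer(nrow(values))
  group[ord] <- sort(rep_len(1:10, nrow(values)))
  tibble(gene_id = values$gene_id, group = group)
}
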