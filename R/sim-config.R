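#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the synthetic genome, network, peak, LAD,
#' coverage and expression generators into one validated object.  The
#' defaults emulate the conditions of the real datasets the pipeline is
#' meant for: ~38/45/17% of genes in the unicellular (UC), early-metazoan
#' (EM) and mammal-specific (MM) age categories, Polycomb-target rates of
#' 16/34/14% per category, LADs covering ~30% of the genome with overlap
#' odds rising towards young genes, and Pol II pausing indices declining
#' from old to young genes.
#'
#' @param n_genes Number of genes to simulate.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in base pairs.
#' @param class_weights Non-negative weights of the 16 age classes; must sum
#'   to 1 (tolerance 1e-9).  Class 1 is the oldest (unicellular ancestor),
#'   class 16 the youngest.
#' @param category_bounds Two strictly increasing cut points in 1..16:
#'   classes `<= bounds[1]` are UC, classes in `(bounds[1], bounds[2]]` EM,
#'   the rest MM.
#' @param n_edges Number of network edges to sample.
#' @param p_within Probability that an edge is drawn preferentially between
#'   two genes of the same age category.  Either a single value or a named
#'   vector with entries `UC`, `EM`, `MM` for per-category preferences.
#' @param trans_fraction Fraction of edges drawn between chromosomes.
#' @param peak_prob_by_category Named probabilities (`UC`, `EM`, `MM`) that a
#'   gene's TSS is covered by a repressive peak.
#' @param background_peak_rate Background (non-TSS) peaks per gene.
#' @param lad_fraction Fraction of the genome covered by simulated LADs.
#' @param lad_enrichment_by_category Named relative odds (`UC`, `EM`, `MM`)
#'   that a gene's neighbourhood is chosen as LAD.
#' @param pi_mean_by_category Named target pausing indices (`UC`, `EM`,
#'   `MM`): the planted promoter/body density ratio.
#' @param cell_states Character vector of simulated cell states; one
#'   coverage track is produced per state.
#' @param cell_pi_factor Named multiplier applied to the planted pausing
#'   index in each cell state (pausing drops on differentiation and rises
#'   again in the cancerous state).
#' @param coverage_binsize Width in bp of coverage-track bins.
#' @param fragment_halfwidth Half-width in bp of the promoter fragment
#'   generated around each TSS.
#' @param multi_gene_fraction Fraction of fragments hosting two genes, to
#'   exercise multi-gene node aggregation (0 disables).
#' @param noise_sd Standard deviation of the truncated Gaussian noise added
#'   to coverage bins.
#' @param rho_target Target magnitude of the class-level Spearman
#'   correlation between age class and expression (negative) and between
#'   age class and expression variability (positive).
#' @param seed Master seed.  Each generator derives its own independent
#'   stream from `(seed, generator name)`, so adding a generator never
#'   perturbs the output of the others.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 7)
#' cfg$category_bounds
#' @export
sim_config <- function(n_genes = 1000,
                       n_chromosomes = 4,
                       chrom_length = 1e7,
                       class_weights = default_class_weights(),
                       category_bounds = c(3L, 9L),
                       n_edges = 3L * n_genes,
                       p_within = 0.6,
                       trans_fraction = 0.05,
                       peak_prob_by_category = c(UC = 0.16, EM = 0.34, MM = 0.14),
                       background_peak_rate = 0.2,
                       lad_fraction = 0.3,
                       lad_enrichment_by_category = c(UC = 1, EM = 2, MM = 2.3),
                       pi_mean_by_category = c(UC = 2, EM = 1.5, MM = 1.2),
                       cell_states = c("stem", "somatic", "cancer"),
                       cell_pi_factor = c(stem = 1, somatic = 0.7, cancer = 1.2),
                       coverage_binsize = 10L,
                       fragment_halfwidth = 2000L,
                       multi_gene_fraction = 0,
                       noise_sd = 0.1,
                       rho_target = 0.95,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.numeric(chrom_length),
    class_weights = as.numeric(class_weights),
    category_bounds = as.integer(category_bounds),
    n_edges = as.integer(n_edges),
    p_within = p_within,
    trans_fraction = trans_fraction,
    peak_prob_by_category = peak_prob_by_category,
    background_peak_rate = background_peak_rate,
    lad_fraction = lad_fraction,
    lad_enrichment_by_category = lad_enrichment_by_category,
    pi_mean_by_category = pi_mean_by_category,
    cell_states = cell_states,
    cell_pi_factor = cell_pi_factor,
    coverage_binsize = as.integer(coverage_binsize),
    fragment_halfwidth = as.integer(fragment_halfwidth),
    multi_gene_fraction = multi_gene_fraction,
    noise_sd = noise_sd,
    rho_target = rho_target,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Default age-class weights
#'
#' Splits the three category proportions (UC 0.3812, EM 0.4475, MM 0.1714,
#' mirroring 7397/8682/3325 of 19404 genes) uniformly over the classes each
#' category spans under the default bounds (3, 9).
#'
#' @return Numeric vector of length 16 summing to 1.
#' @export
default_class_weights <- function() {
  w <- c(rep(0.3812 / 3, 3), rep(0.4475 / 6, 6), rep(0.1713 / 7, 7))
  w / sum(w)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1) abort("`n_genes` must be positive.")
  if (cfg$n_chromosomes < 1) abort("`n_chromosomes` must be positive.")
  if (length(cfg$class_weights) != 16 || any(cfg$class_weights < 0)) {
    abort("`class_weights` must be 16 non-negative values.")
  }
  if (abs(sum(cfg$class_weights) - 1) > 1e-9) {
    abort("`class_weights` must sum to 1 (tolerance 1e-9).")
  }
  b <- cfg$category_bounds
  if (length(b) != 2 || b[1] >= b[2] || b[1] < 1 || b[2] > 16) {
    abort("`category_bounds` must be two strictly increasing cut points in 1..16.")
  }
  probs <- c(cfg$p_within, cfg$trans_fraction, cfg$peak_prob_by_category,
             cfg$lad_fraction, cfg$multi_gene_fraction)
  if (any(probs < 0 | probs > 1)) abort("All probabilities must lie in [0, 1].")
  for (nm in c("peak_prob_by_category", "lad_enrichment_by_category",
               "pi_mean_by_category")) {
    if (!all(c("UC", "EM", "MM") %in% names(cfg[[nm]]))) {
      abort(paste0("`", nm, "` must be named with UC, EM, MM."))
    }
  }
  if (length(cfg$p_within) > 1 && is.null(names(cfg$p_within))) {
    abort("A vector `p_within` must be named by clustering label.")
  }
  if (any(cfg$pi_mean_by_category <= 0)) abort("`pi_mean_by_category` must be positive.")
  if (cfg$noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (abs(cfg$rho_target) > 1) abort("`rho_target` must lie in [-1, 1].")
  if (!all(cfg$cell_states %in% names(cfg$cell_pi_factor))) {
    abort("`cell_pi_factor` must name every cell state.")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  genes:", x$n_genes, "on", x$n_chromosomes, "chromosomes of",
      format(x$chrom_length, big.mark = ","), "bp\n")
  cat("  edges:", x$n_edges, " p_within:",
      paste(format(x$p_within), collapse = "/"), "\n")
  cat("  cell states:", paste(x$cell_states, collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Independent per-generator RNG stream: a small deterministic hash of the
# master seed and the generator name, kept under 2^31.
stream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
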