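#' ChAs z-score against a distance-matched null
#'
#' Computes the observed ChAs of a node feature and its z-score against a
#' null distribution obtained from `n_rand` distance-matched randomizations
#' of the network ([randomize_distmatch()]), with feature values held fixed
#' on the nodes.  `z = (observed - null_mean) / null_sd`, with the sample
#' (n-1) standard deviation; 100 randomizations and |z| > 2 (roughly
#' p = 0.05) are the conventional settings for calling a feature
#' significantly assortative.
#'
#' @param net A [chromatin_network].
#' @param f Node feature (see [chas()]).
#' @param n_rand Number of randomizations (default 100).
#' @param seed Optional integer seed.
#' @param bin_width Log10 distance bin width for the null.
#' @param null `"distmatch"` (edge randomization preserving distances, the
#'   default) or `"permute"` (plain feature shuffle, for comparison).
#' @param feature_name Label recorded on the result.
#' @return A `chas_result`: observed value, null mean/sd, z, counts, and
#'   the full null sample (`$null_sample`) for diagnostics.  If the null
#'   sd is zero the result is flagged `degenerate` and z is `NA`.
#' @examples
#' cfg <- sim_config(n_genes = 40, n_edges = 80, p_within = 1, seed = 2)
#' g <- sim_genome(cfg)
#' net <- sim_network(g$genes, g$ages, cfg)
#' f <- map_feature(net, tibble::tibble(gene_id = g$ages$gene_id,
#'                  value = as.numeric(g$ages$category == "UC")), "binary")
#' chas_zscore(net, f, n_rand = 20, seed = 1)
#' @export
chas_zscore <- function(net, f, n_rand = 100, seed = NULL, bin_width = 0.1,
                        null = c("distmatch", "permute"),
                        feature_name = NULL) {
  null <- match.arg(null)
  if (n_rand < 1) abort("`n_rand` must be at least 1.")
  v <- feature_values(net, f)
  feature_name <- feature_name %||% attr(f, "name") %||% "feature"
  res <- chas_null(net, list(v), n_rand = n_rand, seed = seed,
                   bin_width = bin_width, null = null)
  new_chas_result(feature_name, net, v, res$observed[1], res$null_sample[, 1],
                  n_rand)
}

# Shared null machinery: one set of randomized networks evaluated on a
# list of feature-value vectors (common random numbers across features).
chas_null <- function(net, v_list, n_rand, seed = NULL, bin_width = 0.1,
                      null = "distmatch") {
  em <- edge_index(net)
  observed <- vapply(v_list, function(v) chas_values(em, v), numeric(1))
  prep <- if (null == "distmatch") null_prep(net, bin_width) else NULL
  run <- function() {
    ns <- matrix(NA_real_, nrow = n_rand, ncol = length(v_list))
    for (r in seq_len(n_rand)) {
      if (null == "distmatch") {
        em_r <- randomize_edges(prep)$em
        for (k in seq_along(v_list)) {
          ns[r, k] <- chas_values_safe(em_r, v_list[[k]])
        }
      } else {
        for (k in seq_along(v_list)) {
          ns[r, k] <- chas_values_safe(em, permute_feature(v_list[[k]]))
        }
      }
    }
    ns
  }
  ns <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(observed = observed, null_sample = ns)
}

new_chas_result <- function(feature, net, v, observed, null_sample, n_rand) {
  em <- edge_index(net)
  ok <- !is.na(v[em[, 1]]) & !is.na(v[em[, 2]])
  null_mean <- mean(null_sample, na.rm = TRUE)
  null_sd <- sd(null_sample[!is.na(null_sample)])
  degenerate <- is.na(null_sd) || null_sd == 0
  structure(list(
    feature = feature,
    observed = observed,
    null_mean = null_mean,
    null_sd = null_sd,
    z = if (degenerate) NA_real_ else (observed - null_mean) / null_sd,
    n_rand = n_rand,
    n_nodes_used = length(unique(as.vector(em[ok, , drop = FALSE]))),
    n_edges_used = sum(ok),
    degenerate = degenerate,
    null_sample = as.numeric(null_sample)
  ), class = "chas_result")
}

#' @export
print.chas_result <- function(x, ...) {
  cat("<chas_result>", x$feature, "\n")
  cat(sprintf("  observed %.4f  null %.4f +/- %.4f  z %.2f  (%d randomizations)\n",
              x$observed, x$null_mean, x$null_sd,
              ifelse(is.na(x$z), NaN, x$z), x$n_rand))
  cat("  nodes used:", x$n_nodes_used, " edges used:", x$n_edges_used,
      if (x$degenerate) " [degenerate null]" else "", "\n")
  invisible(x)
}

#' Categorical ChAs z-scores
#'
#' [chas_zscore()] applied to the binary indicator of every category, all
#' against the same set of randomized networks (common random numbers).
#'
#' @inheritParams chas_zscore
#' @param assignment Tibble from [node_categories()].
#' @param categories Categories to evaluate; defaults to all observed.
#' @return Tibble (`category`, `observed`, `null_mean`, `null_sd`, `z`,
#'   `n_rand`).
#' @export
chas_zscore_categorical <- function(net, assignment, n_rand = 100, seed = NULL,
                                    bin_width = 0.1, categories = NULL) {
  categories <- categories %||% sort(unique(unlist(assignment$categories)))
  annotated <- lengths(assignment$categories) > 0
  v_list <- purrr::map(categories, function(cc) {
    v <- ifelse(annotated,
                purrr::map_dbl(assignment$categories, ~ as.numeric(cc %in% .x)),
                NA_real_)
    v[match(net$nodes$node_id, assignment$node_id)]
  })
  res <- chas_null(net, v_list, n_rand = n_rand, seed = seed,
                   bin_width = bin_width)
  purrr::map2_dfr(seq_along(categories), categories, function(k, cc) {
    r <- new_chas_result(cc, net, v_list[[k]], res$observed[k],
                         res$null_sample[, k], n_rand)
    tibble(category = cc, observed = r$observed, null_mean = r$null_mean,
           null_sd = r$null_sd, z = r$z, n_rand = n_rand)
  })
}

#' Delta-ChAs: does a chromatin feature drive a gene group's clustering?
#'
#' Splits a gene group (e.g. an age category) into feature-positive
#' (`group` intersected with `feature`) and feature-negative (`group`
#' minus `feature`) subgroups, computes the ChAs z-score of each
#' subgroup's binary node indicator against a shared set of
#' distance-matched randomizations (common random numbers, which reduces
#' the variance of the difference), and reports
#' `delta = z_with - z_without`.  Positive delta implicates the feature in
#' the group's 3D clustering; negative delta says the feature-negative
#' genes cluster more.
#'
#' @param net A [chromatin_network].
#' @param group Character vector of gene ids forming the group.
#' @param feature Character vector of feature-positive gene ids.
#' @param n_rand,seed,bin_width As in [chas_zscore()].
#' @param group_name,feature_name Labels recorded on the result.
#' @return A `delta_chas_result` with `z_with`, `z_without`, `delta`,
#'   subgroup sizes, and the two underlying `chas_result`s.
#' @export
delta_chas <- function(net, group, feature, n_rand = 100, seed = NULL,
                       bin_width = 0.1, group_name = "group",
                       feature_name = "feature") {
  with_set <- intersect(group, feature)
  without_set <- setdiff(group, feature)
  genes_on_net <- unique(unlist(net$nodes$genes))
  if (length(intersect(with_set, genes_on_net)) == 0) {
    abort("Empty subgroup: no feature-positive group genes on the network.")
  }
  if (length(intersect(without_set, genes_on_net)) == 0) {
    abort("Empty subgroup: no feature-negative group genes on the network.")
  }
  indicator <- function(set) {
    f <- map_feature(net, tibble(gene_id = genes_on_net,
                                 value = as.numeric(genes_on_net %in% set)),
                     kind = "binary")
    feature_values(net, f)
  }
  v_list <- list(indicator(with_set), indicator(without_set))
  res <- chas_null(net, v_list, n_rand = n_rand, seed = seed,
                   bin_width = bin_width)
  r_with <- new_chas_result(paste0(group_name, "+", feature_name), net,
                            v_list[[1]], res$observed[1], res$null_sample[, 1],
                            n_rand)
  r_without <- new_chas_result(paste0(group_name, "-", feature_name), net,
                               v_list[[2]], res$observed[2], res$null_sample[, 2],
                               n_rand)
  structure(list(
    group = group_name, feature = feature_name,
    z_with = r_with$z, z_without = r_without$z,
    delta = r_with$z - r_without$z,
    n_with = length(with_set), n_without = length(without_set),
    with_result = r_with, without_result = r_without
  ), class = "delta_chas_result")
}

#' @export
print.delta_chas_result <- function(x, ...) {
  cat("<delta_chas_result>", x$group, "x", x$feature, "\n")
  cat(sprintf("  z(with) %.2f  z(without) %.2f  delta %.2f  (n %d / %d)\n",
              x$z_with, x$z_without, x$delta, x$n_with, x$n_without))
  invisible(x)
}
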