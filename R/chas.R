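#' Chromatin assortativity (ChAs)
#'
#' Pearson correlation of a node feature across the endpoints of the
#' network's edges.  Each undirected edge contributes both orientations
#' `(f(a), f(b))` and `(f(b), f(a))`, so the statistic is symmetric in the
#' endpoints and bounded in `[-1, 1]`.  Edges with an undefined endpoint
#' are excluded (never imputed).  High ChAs means fragments sharing the
#' feature preferentially contact each other.
#'
#' @param net A [chromatin_network].
#' @param f A node feature from [map_feature()], or a tibble
#'   (`node_id`, `value`), or a named vector.
#' @return A single correlation value.
#' @examples
#' g <- sim_genome(sim_config(n_genes = 60, n_edges = 150, seed = 1))
#' cfg <- sim_config(n_genes = 60, n_edges = 150, p_within = 1, seed = 1)
#' net <- sim_network(g$genes, g$ages, cfg)
#' uc <- tibble::tibble(gene_id = g$ages$gene_id,
#'                      value = as.numeric(g$ages$category == "UC"))
#' chas(net, map_feature(net, uc, "binary"))
#' @export
chas <- function(net, f) {
  v <- feature_values(net, f)
  chas_values(edge_index(net), v)
}

# node feature -> numeric vector aligned with net$nodes
feature_values <- function(net, f) {
  if (is.data.frame(f)) {
    v <- f$value[match(net$nodes$node_id, f$node_id)]
  } else {
    v <- as.numeric(f[net$nodes$node_id])
  }
  as.numeric(v)
}

# edges as an integer two-column matrix over node row indices
edge_index <- function(net) {
  cbind(match(net$edges$node_a, net$nodes$node_id),
        match(net$edges$node_b, net$nodes$node_id))
}

# Core computation on an integer edge matrix and a value vector.
chas_values <- function(em, v) {
  ok <- !is.na(v[em[, 1]]) & !is.na(v[em[, 2]])
  em <- em[ok, , drop = FALSE]
  if (nrow(em) < 2) abort("Fewer than 2 edges with both endpoints defined.")
  x <- c(v[em[, 1]], v[em[, 2]])
  y <- c(v[em[, 2]], v[em[, 1]])
  if (sd(x) == 0) abort("Feature is constant on the nodes used; ChAs undefined.")
  cor(x, y)
}

# Variant returning NA instead of erroring, for per-category sweeps.
chas_values_safe <- function(em, v) {
  tryCatch(chas_values(em, v), error = function(e) NA_real_)
}

#' Categorical ChAs
#'
#' Treats each category as a separate binary feature (1 iff the node
#' carries the category; multi-label nodes contribute 1 to every category
#' they carry) and computes [chas()] on each indicator — the categorical
#' assortativity mode used for gene age classes.
#'
#' @param net A [chromatin_network].
#' @param assignment Tibble (`node_id`, `categories` list-column) as from
#'   [node_categories()].
#' @param categories Categories to evaluate; defaults to all observed.
#' @return Tibble (`category`, `chas`); categories whose indicator is
#'   degenerate (constant, or fewer than 2 usable edges) get `NA` with a
#'   warning rather than being dropped silently.
#' @export
chas_categorical <- function(net, assignment, categories = NULL) {
  categories <- categories %||% sort(unique(unlist(assignment$categories)))
  em <- edge_index(net)
  annotated <- lengths(assignment$categories) > 0
  res <- purrr::map_dbl(categories, function(cc) {
    v <- ifelse(annotated,
                purrr::map_dbl(assignment$categories, ~ as.numeric(cc %in% .x)),
                NA_real_)
    v <- v[match(net$nodes$node_id, assignment$node_id)]
    chas_values_safe(em, v)
  })
  if (anyNA(res)) {
    warn(paste("Degenerate indicator for:",
               paste(categories[is.na(res)], collapse = ", ")))
  }
  tibble(category = categories, chas = res)
}
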