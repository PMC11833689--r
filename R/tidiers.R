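#' Tidy ChAs and delta-ChAs results
#'
#' Broom-style accessors: `tidy()` returns the statistic(s) as one row per
#' term, `glance()` a one-row model-level summary.
#'
#' @param x A `chas_result` or `delta_chas_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name chromage-tidiers
NULL

#' @rdname chromage-tidiers
#' @method tidy chas_result
#' @export
tidy.chas_result <- function(x, ...) {
  tibble(feature = x$feature, observed = x$observed, null_mean = x$null_mean,
         null_sd = x$null_sd, z = x$z, n_rand = x$n_rand)
}

#' @rdname chromage-tidiers
#' @method glance chas_result
#' @export
glance.chas_result <- function(x, ...) {
  tibble(n_nodes_used = x$n_nodes_used, n_edges_used = x$n_edges_used,
         n_rand = x$n_rand, degenerate = x$degenerate)
}

#' @rdname chromage-tidiers
#' @method tidy delta_chas_result
#' @export
tidy.delta_chas_result <- function(x, ...) {
  tibble(group = x$group, feature = x$feature, z_with = x$z_with,
         z_without = x$z_without, delta = x$delta,
         n_with = x$n_with, n_without = x$n_without)
}

#' @rdname chromage-tidiers
#' @method glance delta_chas_result
#' @export
glance.delta_chas_result <- function(x, ...) {
  tibble(n_with = x$n_with, n_without = x$n_without,
         n_rand = x$with_result$n_rand,
         degenerate = x$with_result$degenerate || x$without_result$degenerate)
}
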