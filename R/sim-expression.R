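#' Simulate expression and expression-variability trends over age classes
#'
#' Builds a strictly decreasing class-level mean-expression trend and a
#' strictly increasing expression-variability (EV) trend over the 16 age
#' classes, then adds class-level Gaussian noise scaled so the realized
#' class-mean Spearman correlation with class index is approximately
#' `-rho_target` for expression and `+rho_target` for EV.  With
#' `noise_sd = 0` the trends are noise-free and the class-level
#' correlations are exactly -1 and +1.
#'
#' @param genes,ages As from [sim_genome()].
#' @param config A [sim_config()].
#' @return Tibble (`gene_id`, `expression`, `ev`).
#' @export
sim_expression <- function(genes, ages, config) {
  config <- validate_sim_config(config)
  withr::with_seed(stream_seed(config$seed, "expression"), {
    cls <- ages$age_class[match(genes$gene_id, ages$gene_id)]
    expr_trend <- 10 - 0.4 * (1:16 - 1)
    ev_trend <- 0.2 + 0.05 * (1:16 - 1)
    class_noise_sd <- function(trend) {
      if (config$noise_sd == 0) return(0)
      rho <- max(abs(config$rho_target), 0.05)
      sd(trend) * sqrt(1 / rho^2 - 1)
    }
    expr_class <- expr_trend + rnorm(16, 0, class_noise_sd(expr_trend))
    ev_class <- ev_trend + rnorm(16, 0, class_noise_sd(ev_trend))
    tibble(
      gene_id = genes$gene_id,
      expression = expr_class[cls] + rnorm(nrow(genes), 0, config$noise_sd),
      ev = pmax(0, ev_class[cls] + rnorm(nrow(genes), 0, config$noise_sd / 4))
    )
  })
}
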