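#' Planted end-to-end scenarios: differentiation vs oncogenesis
#'
#' Generates a complete, internally consistent input bundle in which each
#' age category's 3D clustering is driven by its own chromatin feature,
#' emulating the organization observed in differentiated cells and its
#' rewiring in cancer:
#'
#' * UC genes cluster through Pol II: a pol2-positive UC subset (planted
#'   with high pausing indices) is preferentially wired together;
#' * EM genes cluster through Polycomb: H3K27me3-target EM genes are
#'   preferentially wired together;
#' * MM genes cluster through the lamina: LAD-overlapping MM genes are
#'   preferentially wired together.
#'
#' The `"differentiated"` scenario wires UC strongest, then EM, then MM;
#' the `"oncogenesis"` scenario keeps UC, breaks the EM/Polycomb
#' clustering and strengthens the MM/lamina clustering — so ChAs z-scores
#' recomputed from the bundle reproduce the qualitative pattern z(UC) high
#' in both, z(EM) dropping and z(MM) rising across the transition.
#'
#' @param name `"differentiated"` or `"oncogenesis"`.
#' @param config A [sim_config()]; the same config and seed give the two
#'   scenarios identical genomes, features and planted subsets, differing
#'   only in network wiring strengths.
#' @param p_cluster Named wiring strengths for the clustered subsets
#'   (`UCc`, `EMc`, `MMc`) and the background (`bg`); defaults depend on
#'   the scenario.
#' @param pol2_prob Per-category probability of being pol2-positive.
#' @return List: `name`, `config`, `genes`, `ages`, `network`, `peaks`,
#'   `lads`, `tracks`, `expression`, `de`, and `truth` (the planted
#'   feature gene sets and wiring labels).
#' @examples
#' sc <- sim_scenario("differentiated", sim_config(n_genes = 120, n_edges = 240, seed = 3))
#' sc$network
#' @export
sim_scenario <- function(name = c("differentiated", "oncogenesis"),
                         config = sim_config(),
                         p_cluster = NULL,
                         pol2_prob = c(UC = 0.6, EM = 0.35, MM = 0.3)) {
  name <- match.arg(name)
  config <- validate_sim_config(config)
  p_cluster <- p_cluster %||% switch(name,
    differentiated = c(UCc = 0.75, EMc = 0.7, MMc = 0.2, bg = 0),
    oncogenesis = c(UCc = 0.75, EMc = 0.15, MMc = 0.7, bg = 0)
  )
  g <- sim_genome(config)
  genes <- g$genes; ages <- g$ages
  cat <- as.character(ages$category[match(genes$gene_id, ages$gene_id)])
  pol2_pos <- withr::with_seed(stream_seed(config$seed, "pol2"), {
    runif(nrow(genes)) < pol2_prob[cat]
  })
  pol2_set <- genes$gene_id[pol2_pos]
  polycomb_draw <- withr::with_seed(stream_seed(config$seed, "polycomb"), {
    runif(nrow(genes)) < config$peak_prob_by_category[cat]
  })
  polycomb_set <- genes$gene_id[polycomb_draw]
  peaks <- sim_peaks(genes, ages, config, targets = polycomb_set)
  lads <- sim_lads(genes, ages, config)
  lad_set <- lad_genes(genes, lads)$gene_id[lad_genes(genes, lads)$lad == 1]
  labels <- dplyr::case_when(
    cat == "UC" & genes$gene_id %in% pol2_set ~ "UCc",
    cat == "EM" & genes$gene_id %in% polycomb_set ~ "EMc",
    cat == "MM" & genes$gene_id %in% lad_set ~ "MMc",
    TRUE ~ "bg"
  )
  net_config <- config
  net_config$p_within <- p_cluster
  network <- sim_network(genes, ages, net_config, labels = labels)
  pi_gene <- tibble(
    gene_id = genes$gene_id,
    pi = unname(config$pi_mean_by_category[cat]) *
      ifelse(genes$gene_id %in% pol2_set, 1.5, 0.7)
  )
  tracks <- sim_coverage(genes, ages, config, pi_gene = pi_gene)
  expression <- sim_expression(genes, ages, config)
  de <- sim_de(genes, ages, config)
  list(
    name = name, config = config, genes = genes, ages = ages,
    network = network, peaks = peaks, lads = lads, tracks = tracks,
    expression = expression, de = de,
    truth = list(pol2_genes = pol2_set, polycomb_genes = polycomb_set,
                 lad_genes = lad_set, labels = labels,
                 p_cluster = p_cluster, pi_gene = pi_gene)
  )
}
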