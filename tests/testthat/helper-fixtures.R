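# Small fixture builders shared across test files.

# A hand-specified gene table; coordinates 0-based half-open.
toy_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC", "gD"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1000, 10000, 20000, 5000),
    end = c(5000, 12000, 26000, 9000),
    strand = c("+", "-", "+", "-")
  ) |>
    dplyr::mutate(
      tss = ifelse(strand == "+", start, end - 1),
      tes = ifelse(strand == "+", end - 1, start),
      length = end - start
    )
}

# Minimal network: nodes at given midpoints on one chromosome, explicit
# edges by index pair.
toy_network <- function(n_nodes = 6, edges = cbind(c(1, 2, 3), c(2, 3, 4)),
                        chrom = rep("chr1", n_nodes),
                        genes = NULL, width = 1000) {
  mids <- seq(10000, by = 50000, length.out = n_nodes)
  if (is.null(genes)) genes <- lapply(seq_len(n_nodes), function(i) paste0("g", i))
  nodes <- tibble::tibble(
    node_id = paste0("n", seq_len(n_nodes)),
    chrom = chrom,
    start = mids - width / 2, end = mids + width / 2,
    genes = genes,
    is_promoter = lengths(genes) > 0
  )
  dist <- ifelse(chrom[edges[, 1]] == chrom[edges[, 2]],
                 abs(mids[edges[, 1]] - mids[edges[, 2]]), NA_real_)
  edges_tbl <- tibble::tibble(
    node_a = paste0("n", edges[, 1]),
    node_b = paste0("n", edges[, 2]),
    distance = dist, trans = is.na(dist)
  )
  new_chromatin_network(nodes, edges_tbl)
}

# Random graph with a random binary or continuous node feature, for oracle
# comparisons.  Nodes get random positions on 2 chromosomes.
random_network <- function(n_nodes, n_edges, seed) {
  withr::with_seed(seed, {
    chrom <- sample(c("chr1", "chr2"), n_nodes, replace = TRUE)
    mids <- round(runif(n_nodes, 1e4, 5e6))
    nodes <- tibble::tibble(
      node_id = sprintf("n%03d", seq_len(n_nodes)),
      chrom = chrom, start = mids - 500, end = mids + 500,
      genes = lapply(seq_len(n_nodes), function(i) sprintf("g%03d", i)),
      is_promoter = TRUE
    )
    pairs <- t(utils::combn(n_nodes, 2))
    take <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
    ed <- pairs[take, , drop = FALSE]
    edges <- tibble::tibble(
      node_a = nodes$node_id[ed[, 1]], node_b = nodes$node_id[ed[, 2]],
      distance = ifelse(chrom[ed[, 1]] == chrom[ed[, 2]],
                        abs(mids[ed[, 1]] - mids[ed[, 2]]), NA_real_),
      trans = chrom[ed[, 1]] != chrom[ed[, 2]]
    )
    new_chromatin_network(nodes, edges)
  })
}

# Brute-force ChAs oracle: Pearson over the explicitly duplicated oriented
# edge list, computed from sum formulas (independent of cor()).
chas_oracle <- function(net, values_by_node) {
  v <- values_by_node[net$nodes$node_id]
  ia <- match(net$edges$node_a, net$nodes$node_id)
  ib <- match(net$edges$node_b, net$nodes$node_id)
  keep <- !is.na(v[ia]) & !is.na(v[ib])
  x <- c(v[ia][keep], v[ib][keep])
  y <- c(v[ib][keep], v[ia][keep])
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y)
  sxx <- sum(x^2); syy <- sum(y^2)
  (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
}

# Genes on one chromosome whose noiseless tracks give exactly the requested
# pausing indices (promoter bins at pi, body bins at 1).
make_pi_fixture <- function(pis, length = 2000) {
  n <- length(pis)
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)),
    chrom = "chr1",
    start = (seq_len(n) - 1) * 50000 + 1000,
    strand = "+"
  ) |>
    dplyr::mutate(end = start + length, tss = start, tes = end - 1,
                  length = end - start)
  prom <- promoter_region(genes)
  body <- body_region(genes)
  track <- dplyr::bind_rows(
    dplyr::mutate(prom, value = pis)[, c("chrom", "start", "end", "value")],
    dplyr::mutate(body, value = 1)[, c("chrom", "start", "end", "value")]
  )
  list(genes = genes, track = track)
}
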