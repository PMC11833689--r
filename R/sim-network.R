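#' Simulate a promoter chromatin network with planted assortativity
#'
#' Gives every gene one promoter fragment (a window around its TSS) and
#' samples `n_edges` contacts between fragments.  For each edge a source
#' gene is drawn uniformly; with probability `p_within` (overall or for the
#' source gene's category) the partner is drawn from the same age category,
#' otherwise uniformly.  The realized fraction of same-category edges is
#' therefore approximately `p_within + (1 - p_within) * q`, where `q` is the
#' expected same-category rate under random pairing.  A configurable
#' fraction of edges is inter-chromosomal; cis edges carry the genomic
#' distance between fragment midpoints.  All interaction scores are drawn
#' above the significance threshold of 5 so every simulated contact
#' survives score filtering.
#'
#' @param genes,ages As returned by [sim_genome()].
#' @param config A [sim_config()].
#' @param labels Optional character vector (parallel to `genes`) overriding
#'   the age category as the clustering label; `p_within` may then be named
#'   by these labels.  Used to plant clustering in arbitrary gene subsets.
#' @return A [chromatin_network] whose edges carry `score` in addition to
#'   distance.
#' @examples
#' g <- sim_genome(sim_config(n_genes = 60, n_edges = 120, seed = 1))
#' net <- sim_network(g$genes, g$ages, sim_config(n_genes = 60, n_edges = 120, seed = 1))
#' net
#' @export
sim_network <- function(genes, ages, config, labels = NULL) {
  config <- validate_sim_config(config)
  n <- nrow(genes)
  if (config$n_edges > n * (n - 1) / 2) {
    abort("Edge budget exceeds the number of distinct gene pairs.")
  }
  if (is.null(labels)) {
    labels <- as.character(ages$category[match(genes$gene_id, ages$gene_id)])
  }
  labels <- as.character(labels)
  withr::with_seed(stream_seed(config$seed, "network"), {
    frag <- promoter_fragments(genes, config)
    ep <- sample_edge_pairs(
      chrom = genes$chrom, label = labels,
      n_edges = config$n_edges, p_within = config$p_within,
      trans_fraction = config$trans_fraction
    )
    mid <- (frag$frag_start + frag$frag_end) / 2
    trans <- genes$chrom[ep$a] != genes$chrom[ep$b]
    edges <- tibble(
      node_a = frag$node_id[ep$a],
      node_b = frag$node_id[ep$b],
      distance = ifelse(trans, NA_real_, abs(mid[ep$a] - mid[ep$b])),
      trans = trans,
      score = runif(nrow(ep), 5.01, 30)
    ) |>
      filter(.data$node_a != .data$node_b) |>
      distinct(.data$node_a, .data$node_b, .keep_all = TRUE)
    nodes <- frag |>
      group_by(.data$node_id) |>
      summarise(
        chrom = .data$chrom[1], start = .data$frag_start[1],
        end = .data$frag_end[1],
        genes = list(sort(unique(.data$gene_id))), .groups = "drop"
      ) |>
      mutate(is_promoter = TRUE)
  })
  new_chromatin_network(nodes, edges)
}

# One promoter fragment per gene; with multi_gene_fraction > 0 a share of
# genes is re-assigned to the fragment of the nearest upstream neighbour so
# some nodes host two genes.
promoter_fragments <- function(genes, config) {
  hw <- config$fragment_halfwidth
  frag <- genes |>
    mutate(
      frag_start = pmax(0, .data$tss - hw),
      frag_end = pmin(config$chrom_length, .data$tss + hw)
    )
  if (config$multi_gene_fraction > 0 && nrow(frag) > 1) {
    idx <- which(seq_len(nrow(frag)) > 1 &
                   frag$chrom == dplyr::lag(frag$chrom, default = ""))
    n_multi <- min(length(idx), round(config$multi_gene_fraction * nrow(frag)))
    if (n_multi > 0) {
      take <- sample(idx, n_multi)
      frag$frag_start[take] <- frag$frag_start[take - 1]
      frag$frag_end[take] <- pmax(frag$frag_end[take - 1], frag$tss[take] + 1)
      frag$frag_end[take - 1] <- frag$frag_end[take]
    }
  }
  frag |>
    mutate(node_id = paste0(.data$chrom, ":", .data$frag_start, "-", .data$frag_end)) |>
    select("gene_id", "chrom", "frag_start", "frag_end", "node_id")
}

# Rejection sampler for distinct, loop-free edge index pairs with planted
# same-label preference and a controlled trans fraction.
sample_edge_pairs <- function(chrom, label, n_edges, p_within, trans_fraction) {
  n <- length(chrom)
  if (length(p_within) == 1) {
    p_within <- setNames(rep(p_within, length(unique(label))), unique(label))
  }
  by_label <- split(seq_len(n), label)
  by_chrom <- split(seq_len(n), chrom)
  by_label_chrom <- split(seq_len(n), paste(label, chrom))
  seen <- new.env(hash = TRUE, size = 2L * n_edges)
  a_out <- integer(n_edges); b_out <- integer(n_edges)
  got <- 0L; attempts <- 0L; max_attempts <- 200L * n_edges + 10000L
  while (got < n_edges) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort("Could not place the requested number of edges; reduce `n_edges` or constraints.")
    }
    a <- sample.int(n, 1L)
    p_a <- p_within[label[a]]
    if (is.na(p_a)) p_a <- 0 # labels absent from p_within get no preference
    within <- runif(1) < p_a
    trans <- runif(1) < trans_fraction
    pool <- if (within && !trans) {
      by_label_chrom[[paste(label[a], chrom[a])]]
    } else if (within && trans) {
      setdiff(by_label[[label[a]]], by_chrom[[chrom[a]]])
    } else if (!within && !trans) {
      by_chrom[[chrom[a]]]
    } else {
      setdiff(seq_len(n), by_chrom[[chrom[a]]])
    }
    pool <- pool[pool != a]
    if (length(pool) == 0) next
    b <- pool[sample.int(length(pool), 1L)]
    key <- paste0(min(a, b), "_", max(a, b))
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    got <- got + 1L
    a_out[got] <- a; b_out[got] <- b
  }
  tibble(a = a_out, b = b_out)
}
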