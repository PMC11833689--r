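#' Distance-matched network randomization
#'
#' Generates a null network with the same node set and edge count in which
#' every cis edge is replaced by a uniformly sampled same-chromosome node
#' pair whose genomic distance (between fragment midpoints) falls in the
#' same log10-distance bin as the original edge, and every trans edge by a
#' uniformly sampled inter-chromosomal pair.  No self-loops or duplicate
#' edges are produced and the per-bin distance histogram is preserved
#' exactly: when no alternative pair can be found for a bin (after capped
#' rejection sampling) the original edge is kept and counted in the
#' `n_fallback` attribute.  This is the null model behind ChAs z-scores:
#' it destroys topology while preserving the genomic-distance profile, so
#' significance is not driven by linear proximity.
#'
#' @param net A [chromatin_network].
#' @param seed Optional integer seed.
#' @param bin_width Width of the log10 distance bins (default 0.1);
#'   distances below 1 kb are pooled into a single bin.
#' @return A [chromatin_network] with attribute `n_fallback`.
#' @export
randomize_distmatch <- function(net, seed = NULL, bin_width = 0.1) {
  if (!any(!net$edges$trans)) abort("Network has no cis edges to distance-match.")
  prep <- null_prep(net, bin_width)
  draw <- function() {
    r <- randomize_edges(prep)
    edges <- tibble(
      node_a = net$nodes$node_id[r$em[, 1]],
      node_b = net$nodes$node_id[r$em[, 2]],
      distance = r$distance,
      trans = is.na(r$distance)
    )
    out <- new_chromatin_network(net$nodes, edges)
    attr(out, "n_fallback") <- r$n_fallback
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

dist_bin <- function(d, bin_width = 0.1) {
  ifelse(is.na(d), NA_integer_,
         ifelse(d < 1000, -1L, as.integer(floor(log10(pmax(d, 1)) / bin_width))))
}

# Precomputed state reused across many randomizations of one network.
null_prep <- function(net, bin_width = 0.1) {
  em <- edge_index(net)
  mid <- (net$nodes$start + net$nodes$end) / 2
  chrom <- as.integer(factor(net$nodes$chrom))
  by_chrom <- split(seq_len(nrow(net$nodes)), chrom)
  sizes <- lengths(by_chrom)
  list(
    em = em, mid = mid, chrom = chrom, by_chrom = by_chrom,
    pair_weight = sizes * (sizes - 1),
    trans = net$edges$trans,
    distance = net$edges$distance,
    bin = dist_bin(net$edges$distance, bin_width),
    bin_width = bin_width,
    n_nodes = nrow(net$nodes)
  )
}

# One randomization: integer edge matrix + distances + fallback count.
randomize_edges <- function(prep) {
  n_edges <- nrow(prep$em)
  out_a <- integer(n_edges); out_b <- integer(n_edges)
  out_d <- rep(NA_real_, n_edges)
  n_fallback <- 0L
  cis_idx <- which(!prep$trans)
  for (grp in split(cis_idx, prep$bin[cis_idx])) {
    b <- prep$bin[grp[1]]
    k <- length(grp)
    acc_i <- integer(0); acc_j <- integer(0); keys <- character(0)
    for (round in seq_len(50)) {
      need <- k - length(acc_i)
      if (need == 0) break
      m <- max(need * 6L, 64L)
      cand <- sample_same_chrom_pairs(prep, m)
      d <- abs(prep$mid[cand$i] - prep$mid[cand$j])
      ok <- cand$i != cand$j & dist_bin(d, prep$bin_width) == b
      ck <- paste0(pmin(cand$i, cand$j), "_", pmax(cand$i, cand$j))
      ok <- ok & !duplicated(ck) & !(ck %in% keys)
      take <- head(which(ok), need)
      acc_i <- c(acc_i, cand$i[take]); acc_j <- c(acc_j, cand$j[take])
      keys <- c(keys, ck[take])
    }
    short <- k - length(acc_i)
    if (short > 0) { # fall back to unused original edges of this bin
      ok_orig <- paste0(pmin(prep$em[grp, 1], prep$em[grp, 2]), "_",
                        pmax(prep$em[grp, 1], prep$em[grp, 2]))
      free <- which(!(ok_orig %in% keys))
      take <- head(free, short)
      acc_i <- c(acc_i, prep$em[grp[take], 1])
      acc_j <- c(acc_j, prep$em[grp[take], 2])
      n_fallback <- n_fallback + length(take)
    }
    out_a[grp] <- acc_i; out_b[grp] <- acc_j
    out_d[grp] <- abs(prep$mid[acc_i] - prep$mid[acc_j])
  }
  trans_idx <- which(prep$trans)
  if (length(trans_idx) > 0) {
    k <- length(trans_idx)
    acc_i <- integer(0); acc_j <- integer(0); keys <- character(0)
    for (round in seq_len(50)) {
      need <- k - length(acc_i)
      if (need == 0) break
      m <- max(need * 4L, 32L)
      i <- sample.int(prep$n_nodes, m, replace = TRUE)
      j <- sample.int(prep$n_nodes, m, replace = TRUE)
      ok <- prep$chrom[i] != prep$chrom[j]
      ck <- paste0(pmin(i, j), "_", pmax(i, j))
      ok <- ok & !duplicated(ck) & !(ck %in% keys)
      take <- head(which(ok), need)
      acc_i <- c(acc_i, i[take]); acc_j <- c(acc_j, j[take])
      keys <- c(keys, ck[take])
    }
    short <- k - length(acc_i)
    if (short > 0) {
      ok_orig <- paste0(pmin(prep$em[trans_idx, 1], prep$em[trans_idx, 2]), "_",
                        pmax(prep$em[trans_idx, 1], prep$em[trans_idx, 2]))
      free <- which(!(ok_orig %in% keys))
      take <- head(free, short)
      acc_i <- c(acc_i, prep$em[trans_idx[take], 1])
      acc_j <- c(acc_j, prep$em[trans_idx[take], 2])
      n_fallback <- n_fallback + length(take)
    }
    out_a[trans_idx] <- acc_i; out_b[trans_idx] <- acc_j
  }
  list(em = cbind(out_a, out_b), distance = out_d, n_fallback = n_fallback)
}

# m candidate same-chromosome pairs, chromosomes weighted by ordered pair
# count so pairs are uniform over all same-chromosome pairs.
sample_same_chrom_pairs <- function(prep, m) {
  eligible <- which(prep$pair_weight > 0)
  cs <- eligible[sample.int(length(eligible), m, replace = TRUE,
                            prob = prep$pair_weight[eligible])]
  i <- integer(m); j <- integer(m)
  for (c in unique(cs)) {
    sel <- which(cs == c)
    pool <- prep$by_chrom[[c]]
    i[sel] <- pool[sample.int(length(pool), length(sel), replace = TRUE)]
    j[sel] <- pool[sample.int(length(pool), length(sel), replace = TRUE)]
  }
  list(i = i, j = j)
}

#' Feature-permutation null (for comparison)
#'
#' Shuffles feature values among the defined nodes, leaving topology
#' untouched.  Unlike the distance-matched null this does not preserve the
#' relationship between feature placement and genomic position; it is
#' exposed for comparison only.
#'
#' @keywords internal
permute_feature <- function(v) {
  def <- which(!is.na(v))
  v[def] <- v[def][sample.int(length(def))]
  v
}
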