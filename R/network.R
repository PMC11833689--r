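#' Chromatin fragment-contact networks
#'
#' A `chromatin_network` holds restriction fragments as nodes and
#' significant contacts between them as undirected edges.  Nodes live in a
#' tibble (`node_id`, `chrom`, `start`, `end`, `genes` list-column,
#' `is_promoter`); edges in a tibble (`node_a`, `node_b`, `distance`,
#' `trans`, plus any extra columns such as interaction scores).  The
#' constructor enforces the class invariants: no self-loops, no duplicate
#' edges (edges are canonically ordered by node id), and every edge
#' referencing an existing node.
#'
#' @param nodes,edges Tibbles as described above.
#' @return A `chromatin_network`.
#' @name chromatin_network
NULL

#' @rdname chromatin_network
#' @export
new_chromatin_network <- function(nodes, edges) {
  stopifnot(all(c("node_id", "chrom", "start", "end", "genes", "is_promoter")
                %in% names(nodes)),
            all(c("node_a", "node_b") %in% names(edges)))
  if (anyDuplicated(nodes$node_id)) abort("Duplicate node ids.")
  if (!"distance" %in% names(edges)) edges$distance <- NA_real_
  if (!"trans" %in% names(edges)) edges$trans <- is.na(edges$distance)
  swap <- edges$node_a > edges$node_b
  tmp <- edges$node_a[swap]
  edges$node_a[swap] <- edges$node_b[swap]
  edges$node_b[swap] <- tmp
  edges <- edges |>
    filter(.data$node_a != .data$node_b) |>
    distinct(.data$node_a, .data$node_b, .keep_all = TRUE)
  missing <- setdiff(c(edges$node_a, edges$node_b), nodes$node_id)
  if (length(missing) > 0) {
    abort(paste("Edges reference unknown nodes:", paste(head(missing, 3), collapse = ", ")))
  }
  structure(list(nodes = as_tibble(nodes), edges = as_tibble(edges)),
            class = "chromatin_network")
}

#' @export
print.chromatin_network <- function(x, ...) {
  cat("<chromatin_network>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges (",
      sum(x$edges$trans), "trans );", sum(x$nodes$is_promoter), "promoter nodes\n")
  invisible(x)
}

#' Read CHiCAGO-style interaction calls (ibed dialect)
#'
#' Parses a tab-separated interaction table with columns `bait_chr`,
#' `bait_start`, `bait_end`, `bait_name`, `oe_chr`, `oe_start`, `oe_end`,
#' `oe_name`, `N_reads`, `score` (a header line, optionally `#`-prefixed,
#' is allowed) and keeps calls whose CHiCAGO score is strictly greater than
#' `score_threshold` (default 5, the conventional significance cut-off).
#' Input coordinates are 1-based inclusive and are converted to the
#' package-wide 0-based half-open convention.
#'
#' @param path Path to the interaction file (may be gzip-compressed).
#' @param score_threshold Minimum (exclusive) CHiCAGO score.
#' @return A tibble of interaction records (bait and other-end coordinates,
#'   semicolon-separated gene annotations, distance, trans flag, score) with
#'   a `parse_report` attribute counting kept and dropped rows.
#' @examples
#' f <- tempfile(fileext = ".ibed")
#' writeLines(c("# bait_chr\tbait_start\tbait_end\tbait_name\toe_chr\toe_start\toe_end\toe_name\tN_reads\tscore",
#'              "chr1\t1\t4000\tgA\tchr1\t9001\t12000\t.\t12\t7.3",
#'              "chr1\t1\t4000\tgA\tchr1\t20001\t24000\t.\t5\t4.2"), f)
#' load_interactions(f)
#' @export
load_interactions <- function(path, score_threshold = 5) {
  cols <- c("bait_chr", "bait_start", "bait_end", "bait_name",
            "oe_chr", "oe_start", "oe_end", "oe_name", "N_reads", "score")
  raw <- readr::read_tsv(path, comment = "#", col_names = cols,
                         col_types = readr::cols(.default = "c"), progress = FALSE)
  # tolerate an unprefixed header line
  if (nrow(raw) > 0 && is.na(suppressWarnings(as.numeric(raw$score[1])))) {
    raw <- raw[-1, ]
  }
  raw <- raw |>
    mutate(across(c("bait_start", "bait_end", "oe_start", "oe_end"),
                  ~ suppressWarnings(as.numeric(.x))),
           score = suppressWarnings(as.numeric(.data$score)))
  bad <- which(is.na(raw$bait_start) | is.na(raw$bait_end) | is.na(raw$oe_start) |
                 is.na(raw$oe_end) | is.na(raw$score))
  if (length(bad) > 0) {
    abort(paste0("Malformed interaction row(s) at line(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  rec <- raw |>
    mutate(
      bait_start = .data$bait_start - 1, # 1-based inclusive -> 0-based half-open
      oe_start = .data$oe_start - 1,
      trans = .data$bait_chr != .data$oe_chr,
      distance = ifelse(.data$trans, NA_real_,
                        abs((.data$bait_start + .data$bait_end) / 2 -
                              (.data$oe_start + .data$oe_end) / 2))
    )
  kept <- rec |> filter(.data$score > score_threshold)
  if (nrow(kept) == 0) warn("No interactions above the score threshold.")
  attr(kept, "parse_report") <- c(kept = nrow(kept), dropped = nrow(rec) - nrow(kept))
  kept
}

#' Build a fragment-contact network from interaction records
#'
#' Merges identical fragments (same chromosome, start and end) into single
#' nodes carrying the union of gene labels, collapses duplicate contacts,
#' and drops self-contacts.  When `genes` is supplied, a fragment is
#' (re-)annotated as the promoter node of every gene whose TSS it contains;
#' coordinates win over any name annotations carried by the interaction
#' file.  A node is flagged `is_promoter` iff its gene list is non-empty.
#'
#' @param records Interaction tibble as from [load_interactions()].
#' @param genes Optional gene-model tibble used for TSS-based promoter
#'   assignment.
#' @return A [chromatin_network].
#' @export
build_network <- function(records, genes = NULL) {
  frag <- bind_rows(
    records |>
      transmute(chrom = .data$bait_chr, start = .data$bait_start,
                end = .data$bait_end, name = .data$bait_name),
    records |>
      transmute(chrom = .data$oe_chr, start = .data$oe_start,
                end = .data$oe_end, name = .data$oe_name)
  ) |>
    mutate(node_id = paste0(.data$chrom, ":", .data$start, "-", .data$end))
  nodes <- frag |>
    group_by(.data$node_id) |>
    summarise(
      chrom = .data$chrom[1], start = .data$start[1], end = .data$end[1],
      genes = list(sort(setdiff(unique(unlist(
        strsplit(.data$name, ";", fixed = TRUE))), c(".", "", NA)))),
      .groups = "drop"
    )
  if (!is.null(genes)) {
    hits <- overlap_pairs(
      nodes |> select("chrom", "start", "end"),
      genes |> transmute(chrom = .data$chrom, start = .data$tss,
                         end = .data$tss + 1)
    )
    gene_by_node <- split(genes$gene_id[hits$subject], nodes$node_id[hits$query])
    nodes$genes <- purrr::map(nodes$node_id,
                              ~ sort(unique(gene_by_node[[.x]] %||% character())))
  }
  nodes <- nodes |> mutate(is_promoter = lengths(.data$genes) > 0)
  edges <- records |>
    transmute(
      node_a = paste0(.data$bait_chr, ":", .data$bait_start, "-", .data$bait_end),
      node_b = paste0(.data$oe_chr, ":", .data$oe_start, "-", .data$oe_end),
      distance = .data$distance, trans = .data$trans, score = .data$score
    )
  new_chromatin_network(nodes, edges)
}

#' Promoter-only subnetwork
#'
#' Induced subgraph on promoter nodes: fragments containing at least one
#' gene TSS, with edges kept only when both endpoints are promoter nodes —
#' the promoter–promoter interaction network on which gene-age clustering
#' is assessed.  `mode = "inclusive"` instead keeps every edge incident to
#' at least one promoter node (and the non-promoter partners).
#'
#' @param net A [chromatin_network].
#' @param mode `"strict"` (promoter–promoter only, the default) or
#'   `"inclusive"`.
#' @return A [chromatin_network].
#' @export
promoter_subnetwork <- function(net, mode = c("strict", "inclusive")) {
  mode <- match.arg(mode)
  prom <- net$nodes$node_id[net$nodes$is_promoter]
  if (mode == "strict") {
    edges <- net$edges |>
      filter(.data$node_a %in% prom & .data$node_b %in% prom)
    nodes <- net$nodes |> filter(.data$node_id %in% prom)
  } else {
    edges <- net$edges |>
      filter(.data$node_a %in% prom | .data$node_b %in% prom)
    keep <- union(prom, c(edges$node_a, edges$node_b))
    nodes <- net$nodes |> filter(.data$node_id %in% keep)
  }
  new_chromatin_network(nodes, edges)
}

#' Map a gene-level feature onto network nodes
#'
#' Lifts per-gene values to per-node values: for `kind = "binary"` a node is
#' positive iff any resident gene is positive (logical OR); for
#' `kind = "continuous"` the node value is the arithmetic mean over resident
#' genes with values.  Nodes none of whose genes carry a value are left
#' undefined (`NA`) and are excluded edgewise from assortativity, never
#' imputed.
#'
#' @param net A [chromatin_network].
#' @param gene_feature Tibble with columns `gene_id` and `value`, or a named
#'   vector.
#' @param kind `"binary"` or `"continuous"`.
#' @param name Feature name recorded on the result.
#' @return A tibble (`node_id`, `value`) of class `node_feature` with
#'   attributes `name` and `kind`.
#' @export
map_feature <- function(net, gene_feature, kind = c("binary", "continuous"),
                        name = "feature") {
  kind <- match.arg(kind)
  if (!is.data.frame(gene_feature)) {
    gene_feature <- tibble(gene_id = names(gene_feature),
                           value = as.numeric(gene_feature))
  }
  if (nrow(gene_feature) == 0) warn("Empty gene feature: all nodes undefined.")
  lut <- setNames(as.numeric(gene_feature$value), gene_feature$gene_id)
  value <- purrr::map_dbl(net$nodes$genes, function(gs) {
    v <- lut[gs[gs %in% names(lut)]]
    if (length(v) == 0) return(NA_real_)
    if (kind == "binary") max(v) else mean(v)
  })
  out <- tibble(node_id = net$nodes$node_id, value = value)
  attr(out, "name") <- name
  attr(out, "kind") <- kind
  class(out) <- c("node_feature", class(out))
  out
}

#' Per-node age-category sets
#'
#' @param net A [chromatin_network].
#' @param ages Age table (`gene_id`, `age_class`, `category`).
#' @return Tibble (`node_id`, `categories` list-column); multi-gene nodes
#'   carry every resident gene's category.
#' @export
node_categories <- function(net, ages) {
  lut <- setNames(ages$category, ages$gene_id)
  tibble(
    node_id = net$nodes$node_id,
    categories = purrr::map(net$nodes$genes,
                            ~ sort(unique(unname(lut[.x[.x %in% names(lut)]]))))
  )
}

#' Export a network's interactions in the ibed dialect
#'
#' Inverse of [load_interactions()] + [build_network()]: writes one row per
#' edge with 1-based inclusive coordinates, semicolon-joined gene names
#' (`.` when empty) and the stored score (99 when absent).
#'
#' @param net A [chromatin_network].
#' @param path Output path.
#' @export
write_ibed <- function(net, path) {
  nd <- net$nodes
  ia <- match(net$edges$node_a, nd$node_id)
  ib <- match(net$edges$node_b, nd$node_id)
  nm <- purrr::map_chr(nd$genes, ~ if (length(.x) == 0) "." else paste(.x, collapse = ";"))
  score <- net$edges[["score"]] %||% rep(99, nrow(net$edges))
  lines <- paste(nd$chrom[ia], nd$start[ia] + 1, nd$end[ia], nm[ia],
                 nd$chrom[ib], nd$start[ib] + 1, nd$end[ib], nm[ib],
                 10L, format(score, trim = TRUE, digits = 10), sep = "\t")
  writeLines(c(paste0("# ", paste(c("bait_chr", "bait_start", "bait_end", "bait_name",
                                    "oe_chr", "oe_start", "oe_end", "oe_name",
                                    "N_reads", "score"), collapse = "\t")), lines), path)
  invisible(path)
}
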