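#' Age class to age category
#'
#' Collapses the 16 phylostratigraphy age classes into the three broad
#' categories: unicellular ancestor (UC), early metazoan (EM) and
#' mammal-specific (MM).  With cut points `(b1, b2)`, classes `<= b1` are
#' UC, classes in `(b1, b2]` EM, and classes `> b2` MM.  The default bounds
#' `(3, 9)` are a documented choice, configurable because the class-to-
#' category mapping is dataset-dependent.
#'
#' @param age_class Integer vector of classes in 1..16.
#' @param bounds Two strictly increasing cut points.
#' @return Character vector of categories (`"UC"`, `"EM"`, `"MM"`).
#' @examples
#' age_category(c(2, 9, 10))
#' @export
age_category <- function(age_class, bounds = c(3, 9)) {
  if (any(age_class < 1 | age_class > 16, na.rm = TRUE)) {
    abort("Age classes must lie in 1..16.")
  }
  ifelse(age_class <= bounds[1], "UC",
         ifelse(age_class <= bounds[2], "EM", "MM"))
}

# All pairwise overlaps (>= 1 shared base) between two 0-based half-open
# interval tables, via GenomicRanges.  Returns tibble(query, subject) row
# indices.
overlap_pairs <- function(query, subject) {
  gr <- function(d) {
    GenomicRanges::GRanges(d$chrom, IRanges::IRanges(start = d$start + 1, end = d$end))
  }
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble(query = integer(), subject = integer()))
  }
  h <- suppressWarnings(GenomicRanges::findOverlaps(gr(query), gr(subject)))
  tibble(query = S4Vectors::queryHits(h), subject = S4Vectors::subjectHits(h))
}

#' Polycomb-target annotation
#'
#' A gene is a Polycomb target iff its single TSS base falls inside an
#' H3K27me3 peak (`peak.start <= tss < peak.end`, half-open); gene bodies
#' are ignored.  Genes on chromosomes with no peaks are 0.
#'
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `tss`, ...).
#' @param peaks Peak tibble (`chrom`, `start`, `end`), 0-based half-open.
#' @return Tibble (`gene_id`, `polycomb` in 0/1).
#' @examples
#' genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 500)
#' peaks <- tibble::tibble(chrom = "chr1", start = 400, end = 600)
#' polycomb_targets(genes, peaks)
#' @export
polycomb_targets <- function(genes, peaks) {
  hits <- overlap_pairs(
    genes |> transmute(chrom = .data$chrom, start = .data$tss, end = .data$tss + 1),
    peaks
  )
  tibble(gene_id = genes$gene_id,
         polycomb = as.integer(seq_len(nrow(genes)) %in% hits$query))
}

#' LAD-associated genes
#'
#' A gene is lamina-associated iff at least part of its body overlaps a
#' lamina-associated domain (>= 1 shared base, half-open semantics).  LADs
#' may carry a `type` column labelling them constitutive or facultative;
#' `mode` selects which subset to use, together or separately.
#'
#' @param genes Gene-model tibble.
#' @param lads LAD tibble (`chrom`, `start`, `end`, optional `type`).
#' @param mode One of `"all"`, `"constitutive"`, `"facultative"`.
#' @return Tibble (`gene_id`, `lad` in 0/1).
#' @export
lad_genes <- function(genes, lads, mode = c("all", "constitutive", "facultative")) {
  mode <- match.arg(mode)
  if (mode != "all") {
    if (!"type" %in% names(lads)) {
      lads <- lads[0, , drop = FALSE]
    } else {
      lads <- lads |> filter(.data$type == mode)
    }
  }
  hits <- overlap_pairs(genes |> select("chrom", "start", "end"), lads)
  tibble(gene_id = genes$gene_id,
         lad = as.integer(seq_len(nrow(genes)) %in% hits$query))
}

#' Strand-aware promoter window
#'
#' Window around the TSS covering `upstream` bases 5' of the TSS and
#' `downstream` bases starting at (and including) the TSS base, in
#' transcript orientation.  On the plus strand this is
#' `[tss - upstream, tss + downstream)`; on the minus strand the mirror
#' image `[tss - downstream + 1, tss + upstream + 1)`.  `downstream = 0` is
#' coerced to 1 so the TSS base itself is always included; windows are
#' clipped at coordinate 0.
#'
#' @param genes Gene-model tibble.
#' @param upstream,downstream Window extents in bp (default 1 kb each).
#' @return Tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @examples
#' g <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "-", tss = 5000)
#' promoter_window(g, upstream = 300, downstream = 30)
#' @export
promoter_window <- function(genes, upstream = 1000, downstream = 1000) {
  if (upstream < 0 || downstream < 0) abort("Window sizes must be non-negative.")
  downstream <- max(downstream, 1)
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream + 1)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream + 1)
  tibble(gene_id = genes$gene_id, chrom = genes$chrom,
         start = pmax(0, start), end = pmax(0, end), strand = genes$strand)
}

#' Promoter CpG-site counts
#'
#' Counts point sites (e.g. methylated CpG positions or CpG-island
#' midpoints) falling inside each gene's promoter window and, when an age
#' table is given, reports the per-category mean count.
#'
#' @param genes Gene-model tibble.
#' @param sites Tibble (`chrom`, `pos`) of point coordinates.
#' @param upstream,downstream Promoter window (see [promoter_window()]).
#' @param ages Optional age table for category means.
#' @return Tibble (`gene_id`, `cpg_count`); with `ages`, an attribute
#'   `category_means` tibble (`category`, `mean_count`).
#' @export
count_promoter_sites <- function(genes, sites, upstream = 1000,
                                 downstream = 1000, ages = NULL) {
  win <- promoter_window(genes, upstream, downstream)
  hits <- overlap_pairs(win |> select("chrom", "start", "end"),
                        sites |> transmute(chrom = .data$chrom,
                                           start = .data$pos, end = .data$pos + 1))
  counts <- tabulate(hits$query, nbins = nrow(genes))
  out <- tibble(gene_id = genes$gene_id, cpg_count = counts)
  if (!is.null(ages)) {
    attr(out, "category_means") <- out |>
      inner_join(ages, by = "gene_id") |>
      group_by(category = .data$category) |>
      summarise(mean_count = mean(.data$cpg_count), .groups = "drop")
  }
  out
}

#' Promoter methylation aggregate
#'
#' Unweighted mean of methylation scores (each in `[0, 1]`) at sites inside
#' each gene's promoter window.  Genes with no sites in the window get `NA`
#' and are excluded from category means.
#'
#' @param genes Gene-model tibble.
#' @param scores Tibble (`chrom`, `pos`, `score`).
#' @inheritParams count_promoter_sites
#' @return Tibble (`gene_id`, `meth_mean`); with `ages`, an attribute
#'   `category_means`.
#' @export
promoter_methylation <- function(genes, scores, upstream = 1000,
                                 downstream = 1000, ages = NULL) {
  if (nrow(scores) > 0 && any(scores$score < 0 | scores$score > 1)) {
    abort("Methylation scores must lie in [0, 1].")
  }
  win <- promoter_window(genes, upstream, downstream)
  hits <- overlap_pairs(win |> select("chrom", "start", "end"),
                        scores |> transmute(chrom = .data$chrom,
                                            start = .data$pos, end = .data$pos + 1))
  means <- rep(NA_real_, nrow(genes))
  if (nrow(hits) > 0) {
    agg <- tapply(scores$score[hits$subject], hits$query, mean)
    means[as.integer(names(agg))] <- as.numeric(agg)
  }
  out <- tibble(gene_id = genes$gene_id, meth_mean = means)
  if (!is.null(ages)) {
    attr(out, "category_means") <- out |>
      inner_join(ages, by = "gene_id") |>
      filter(!is.na(.data$meth_mean)) |>
      group_by(category = .data$category) |>
      summarise(mean_score = mean(.data$meth_mean), .groups = "drop")
  }
  out
}

#' Differential-expression classification
#'
#' Labels genes up-regulated when `log2FC > lfc_threshold` and
#' `padj < padj_threshold`, down-regulated when `log2FC < -lfc_threshold`
#' and `padj < padj_threshold`, and unchanged otherwise (missing adjusted p
#' counts as unchanged).  Defaults are |log2FC| > 2 with adjusted p < 0.1.
#'
#' @param de Tibble (`gene_id`, `log2FC`, `padj`).
#' @param lfc_threshold,padj_threshold Positive thresholds.
#' @param ages Optional age table; adds a `category_proportions` attribute
#'   with the per-category share of up/down/none labels.
#' @return Tibble (`gene_id`, `de_label` in up/down/none).
#' @export
classify_de <- function(de, lfc_threshold = 2, padj_threshold = 0.1, ages = NULL) {
  if (lfc_threshold <= 0 || padj_threshold <= 0) abort("Thresholds must be positive.")
  sig <- !is.na(de$padj) & de$padj < padj_threshold
  label <- ifelse(sig & de$log2FC > lfc_threshold, "up",
                  ifelse(sig & de$log2FC < -lfc_threshold, "down", "none"))
  out <- tibble(gene_id = de$gene_id, de_label = label)
  if (!is.null(ages)) {
    attr(out, "category_proportions") <- out |>
      inner_join(ages, by = "gene_id") |>
      count(category = .data$category, .data$de_label) |>
      group_by(.data$category) |>
      mutate(proportion = .data$n / sum(.data$n)) |>
      ungroup()
  }
  out
}

#' Annotate genes with every feature layer
#'
#' Convenience wrapper joining age class/category, Polycomb-target status,
#' LAD overlap, promoter CpG counts, promoter methylation and DE labels
#' into one gene-level table; layers whose inputs are `NULL` are skipped.
#'
#' @param genes Gene-model tibble.
#' @param ages Age table.
#' @param peaks,lads,cpg_sites,meth_scores,de Optional inputs for the
#'   respective layers.
#' @param upstream,downstream Promoter window for the CpG/methylation layers.
#' @return One row per gene.
#' @export
annotate_genes <- function(genes, ages, peaks = NULL, lads = NULL,
                           cpg_sites = NULL, meth_scores = NULL, de = NULL,
                           upstream = 1000, downstream = 1000) {
  out <- genes |>
    select("gene_id", "chrom", "start", "end", "strand", "tss", "length") |>
    left_join(ages, by = "gene_id")
  if (!is.null(peaks)) out <- left_join(out, polycomb_targets(genes, peaks), by = "gene_id")
  if (!is.null(lads)) out <- left_join(out, lad_genes(genes, lads), by = "gene_id")
  if (!is.null(cpg_sites)) {
    out <- left_join(out, count_promoter_sites(genes, cpg_sites, upstream, downstream),
                     by = "gene_id")
  }
  if (!is.null(meth_scores)) {
    out <- left_join(out, promoter_methylation(genes, meth_scores, upstream, downstream),
                     by = "gene_id")
  }
  if (!is.null(de)) out <- left_join(out, classify_de(de), by = "gene_id")
  out
}
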