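#' Read and write the package's tab-separated formats
#'
#' All writers emit tab-separated text with a single `#`-prefixed header
#' line naming the columns; all readers accept that dialect (and plain
#' headerless files) and gzip-compressed input.  Coordinates are 0-based
#' half-open throughout, except the ibed interaction dialect
#' ([load_interactions()] / [write_ibed()]) which is 1-based inclusive on
#' disk, as exported by CHiCAGO.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @param col_names Column names expected in the file.
#' @name chromage_io
NULL

write_commented_tsv <- function(x, path) {
  writeLines(paste0("# ", paste(names(x), collapse = "\t")), path)
  readr::write_tsv(x, path, append = TRUE, col_names = FALSE, progress = FALSE)
  invisible(path)
}

read_commented_tsv <- function(path, col_names, col_types = NULL) {
  readr::read_tsv(path, comment = "#", col_names = col_names,
                  col_types = col_types, progress = FALSE)
}

#' @rdname chromage_io
#' @export
write_genes_tsv <- function(x, path) {
  write_commented_tsv(x[, c("gene_id", "chrom", "start", "end", "strand")], path)
}

#' @rdname chromage_io
#' @export
read_genes_tsv <- function(path) {
  read_commented_tsv(path, c("gene_id", "chrom", "start", "end", "strand"),
                     "ccddc") |>
    mutate(
      tss = ifelse(.data$strand == "+", .data$start, .data$end - 1),
      tes = ifelse(.data$strand == "+", .data$end - 1, .data$start),
      length = .data$end - .data$start
    )
}

#' @rdname chromage_io
#' @export
write_ages_tsv <- function(x, path) {
  write_commented_tsv(x[, c("gene_id", "age_class")], path)
}

#' @rdname chromage_io
#' @param bounds Category bounds applied on read (see [age_category()]).
#' @export
read_ages_tsv <- function(path, bounds = c(3, 9)) {
  read_commented_tsv(path, c("gene_id", "age_class"), "ci") |>
    mutate(category = age_category(.data$age_class, bounds))
}

#' @rdname chromage_io
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "type"), names(x))
  readr::write_tsv(x[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname chromage_io
#' @export
read_bed <- function(path) {
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  n_fields <- length(strsplit(first, "\t")[[1]])
  cols <- c("chrom", "start", "end", "type")[seq_len(min(n_fields, 4))]
  types <- substr("cddc", 1, min(n_fields, 4))
  readr::read_tsv(path, comment = "#", col_names = cols,
                  col_types = types, progress = FALSE)
}

#' @rdname chromage_io
#' @export
write_bedgraph <- function(x, path) {
  readr::write_tsv(x[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname chromage_io
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path, comment = "#",
                  col_names = c("chrom", "start", "end", "value"),
                  col_types = "cddd", progress = FALSE)
}

#' @rdname chromage_io
#' @export
write_de_tsv <- function(x, path) {
  write_commented_tsv(x[, c("gene_id", "log2FC", "padj")], path)
}

#' @rdname chromage_io
#' @export
read_de_tsv <- function(path) {
  read_commented_tsv(path, c("gene_id", "log2FC", "padj"), "cdd")
}

#' @rdname chromage_io
#' @export
write_expression_tsv <- function(x, path) {
  write_commented_tsv(x[, c("gene_id", "expression", "ev")], path)
}

#' @rdname chromage_io
#' @export
read_expression_tsv <- function(path) {
  read_commented_tsv(path, c("gene_id", "expression", "ev"), "cdd")
}

#' Write all synthetic inputs of a scenario or config to a directory
#'
#' Materializes the full input bundle as plain-text files (gene TSV, age
#' TSV, ibed interactions, peak/LAD BED, per-cell bedGraph tracks,
#' expression and DE TSVs), the on-disk interface every reader of this
#' package consumes.
#'
#' @param bundle A list as returned by [sim_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; files are named `genes.tsv`, `ages.tsv`,
#'   `interactions.ibed`, `peaks.bed`, `lads.bed`,
#'   `coverage_<cell>.bedgraph`, `expression.tsv`, `de.tsv`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genes_tsv(bundle$genes, file.path(dir, "genes.tsv"))
  write_ages_tsv(bundle$ages, file.path(dir, "ages.tsv"))
  write_ibed(bundle$network, file.path(dir, "interactions.ibed"))
  write_bed(bundle$peaks, file.path(dir, "peaks.bed"))
  write_bed(bundle$lads, file.path(dir, "lads.bed"))
  for (cell in names(bundle$tracks)) {
    write_bedgraph(bundle$tracks[[cell]],
                   file.path(dir, paste0("coverage_", cell, ".bedgraph")))
  }
  write_expression_tsv(bundle$expression, file.path(dir, "expression.tsv"))
  write_de_tsv(bundle$de, file.path(dir, "de.tsv"))
  invisible(dir)
}
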