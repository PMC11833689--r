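#' Metagene signal profile around TSSs
#'
#' Averages a binned signal track into fixed-width bins centred on each
#' gene's TSS, covering `[-flank, +flank)` in transcript orientation
#' (profiles of minus-strand genes are flipped so "left" is always
#' upstream), then averages over genes within each age category.  Bin
#' values are overlap-length-weighted means of the track over the bin;
#' bins reaching past the covered part of a chromosome contribute only
#' their covered positions.
#'
#' @param track Signal tibble (`chrom`, `start`, `end`, `value`).
#' @param genes Gene-model tibble.
#' @param ages Age table used for grouping.
#' @param flank Half-width of the profiled window in bp.
#' @param binsize Profile bin width; must divide `2 * flank`.
#' @return Tibble (`category`, `position`, `signal`) where `position` is
#'   the bin's offset from the TSS (bin left edge, transcript
#'   orientation); `2 * flank / binsize` rows per category.
#' @export
metagene_profile <- function(track, genes, ages, flank = 2000, binsize = 100) {
  if ((2 * flank) %% binsize != 0) abort("`binsize` must divide 2 * flank.")
  n_bins <- 2 * flank / binsize
  offsets <- seq(-flank, flank - binsize, by = binsize)
  regions <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    plus <- genes$strand[i] == "+"
    start <- if (plus) genes$tss[i] + offsets else genes$tss[i] - offsets - binsize + 1
    tibble(gene = i, bin = seq_len(n_bins),
           chrom = genes$chrom[i], start = pmax(0, start))
  }) |>
    mutate(end = .data$start + binsize)
  hits <- overlap_pairs(regions |> select("chrom", "start", "end"), track)
  ov <- pmin(regions$end[hits$query], track$end[hits$subject]) -
    pmax(regions$start[hits$query], track$start[hits$subject])
  num <- tapply(track$value[hits$subject] * ov, hits$query, sum)
  den <- tapply(ov, hits$query, sum)
  regions$signal <- NA_real_
  regions$signal[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
  regions |>
    mutate(gene_id = genes$gene_id[.data$gene]) |>
    inner_join(ages |> select("gene_id", "category"), by = "gene_id") |>
    group_by(category = .data$category, bin = .data$bin) |>
    summarise(signal = mean(.data$signal, na.rm = TRUE), .groups = "drop") |>
    mutate(position = offsets[.data$bin]) |>
    select("category", "position", "signal")
}
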