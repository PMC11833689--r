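#' Simulate Pol II coverage tracks with planted pausing ratios
#'
#' Produces one binned signal track per cell state.  Each gene gets a body
#' signal around base level 1 and a promoter signal (the strand-aware
#' TSS - 30 .. TSS + 300 window) around `base * PI`, where the planted PI
#' is the per-category `pi_mean_by_category` times the cell state's
#' `cell_pi_factor` — or a per-gene value when `pi_gene` is supplied.
#' Bins (default 10 bp) are anchored at the promoter edge so promoter and
#' body bins never straddle the region boundary; truncated Gaussian noise
#' of sd `noise_sd` is added per bin, and near-zero intergenic bins are
#' interspersed.  In the noiseless limit the pausing pipeline recovers the
#' planted PI exactly.
#'
#' @param genes,ages As from [sim_genome()].
#' @param config A [sim_config()].
#' @param pi_gene Optional tibble (`gene_id`, `pi`) of per-gene planted
#'   pausing indices overriding the category means.
#' @return Named list (one per cell state) of tibbles
#'   (`chrom`, `start`, `end`, `value`).
#' @export
sim_coverage <- function(genes, ages, config, pi_gene = NULL) {
  config <- validate_sim_config(config)
  w <- config$coverage_binsize
  cat <- as.character(ages$category[match(genes$gene_id, ages$gene_id)])
  pi_base <- if (is.null(pi_gene)) {
    unname(config$pi_mean_by_category[cat])
  } else {
    pi_gene$pi[match(genes$gene_id, pi_gene$gene_id)]
  }
  n_prom <- as.integer(ceiling(330 / w))
  bins <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    plus <- genes$strand[i] == "+"
    body_len <- max(0, genes$length[i] - 330)
    n_body <- as.integer(ceiling(body_len / w))
    if (plus) {
      starts <- (genes$tss[i] - 30) + (seq_len(n_prom + n_body) - 1) * w
      is_prom <- seq_len(n_prom + n_body) <= n_prom
    } else {
      top <- genes$tss[i] + 31
      starts <- top - seq_len(n_prom + n_body) * w
      is_prom <- seq_len(n_prom + n_body) <= n_prom
    }
    tibble(gene = i, chrom = genes$chrom[i], start = starts, is_prom = is_prom)
  })
  # sparse intergenic bins, one per inter-gene gap midpoint
  inter <- genes |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    reframe(mid = floor((head(.data$end, -1) + utils::tail(.data$start, -1)) / 2)) |>
    transmute(gene = NA_integer_, chrom = .data$chrom, start = .data$mid,
              is_prom = FALSE)
  bins <- bind_rows(bins, inter)
  out <- withr::with_seed(stream_seed(config$seed, "coverage"), {
    purrr::map(config$cell_states, function(cell) {
      fac <- config$cell_pi_factor[[cell]]
      base <- ifelse(is.na(bins$gene), 0,
                     ifelse(bins$is_prom, pi_base[bins$gene] * fac, 1))
      noise <- if (config$noise_sd > 0) {
        rnorm(nrow(bins), 0, config$noise_sd)
      } else 0
      bins |>
        transmute(chrom = .data$chrom, start = .data$start, end = .data$start + w,
                  value = pmax(0, base + noise)) |>
        arrange(.data$chrom, .data$start)
    })
  })
  names(out) <- config$cell_states
  out
}
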