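#' Simulate gene models and an age table
#'
#' Places non-overlapping genes at uniformly spaced (jittered) positions on
#' each chromosome, draws gene lengths from a log-normal so that a sizeable
#' minority (>= 10%) is shorter than 1 kb — exercising the pausing-pipeline
#' length filter — assigns strands at random and samples one of 16
#' evolutionary age classes per gene from `class_weights`.
#'
#' @param config A [sim_config()].
#' @return A list with `genes` (tibble: gene_id, chrom, start, end, strand,
#'   tss, tes, length; 0-based half-open) and `ages` (tibble: gene_id,
#'   age_class, category).
#' @examples
#' g <- sim_genome(sim_config(n_genes = 50, seed = 1))
#' head(g$genes)
#' @export
sim_genome <- function(config) {
  config <- validate_sim_config(config)
  per_chrom <- diff(round(seq(0, config$n_genes,
                              length.out = config$n_chromosomes + 1)))
  min_spacing <- 1000
  if (max(per_chrom) * min_spacing > config$chrom_length) {
    abort("Genome too small: gene count times minimum spacing exceeds chromosome length.")
  }
  withr::with_seed(stream_seed(config$seed, "genome"), {
    genes <- purrr::map2_dfr(seq_len(config$n_chromosomes), per_chrom,
                             function(ci, n) {
      if (n == 0) return(tibble())
      spacing <- config$chrom_length / n
      anchor <- (seq_len(n) - 1) * spacing
      start <- round(anchor + runif(n, 0, 0.2 * spacing))
      len <- round(rlnorm(n, meanlog = log(2500), sdlog = 1))
      len <- pmin(pmax(len, 200), round(0.6 * spacing))
      tibble(
        chrom = paste0("chr", ci),
        start = start,
        end = start + len,
        strand = sample(c("+", "-"), n, replace = TRUE)
      )
    })
    genes <- genes |>
      mutate(
        gene_id = sprintf("g%05d", seq_len(n())),
        tss = ifelse(.data$strand == "+", .data$start, .data$end - 1),
        tes = ifelse(.data$strand == "+", .data$end - 1, .data$start),
        length = .data$end - .data$start
      ) |>
      select("gene_id", "chrom", "start", "end", "strand", "tss", "tes", "length")
    ages <- tibble(
      gene_id = genes$gene_id,
      age_class = sample(1:16, nrow(genes), replace = TRUE,
                         prob = config$class_weights)
    ) |>
      mutate(category = age_category(.data$age_class, config$category_bounds))
  })
  list(genes = genes, ages = ages)
}
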