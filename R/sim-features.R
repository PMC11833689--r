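#' Simulate repressive (H3K27me3-like) peaks
#'
#' For each gene, with the per-category probability
#' `peak_prob_by_category` (or deterministically for an explicit `targets`
#' set), emits one peak of width 500-3000 bp containing the TSS, plus
#' background peaks placed away from every TSS.  Downstream,
#' [polycomb_targets()] recovers exactly the genes given a TSS peak.
#'
#' @param genes,ages As from [sim_genome()].
#' @param config A [sim_config()].
#' @param targets Optional character vector of gene ids that get a TSS
#'   peak with probability 1 (all other genes get none).
#' @return Tibble (`chrom`, `start`, `end`), 0-based half-open.
#' @export
sim_peaks <- function(genes, ages, config, targets = NULL) {
  config <- validate_sim_config(config)
  withr::with_seed(stream_seed(config$seed, "peaks"), {
    if (nrow(genes) == 0) {
      fg <- tibble(chrom = character(), start = numeric(), end = numeric())
    } else {
      if (is.null(targets)) {
        cat <- as.character(ages$category[match(genes$gene_id, ages$gene_id)])
        hit <- runif(nrow(genes)) < config$peak_prob_by_category[cat]
      } else {
        hit <- genes$gene_id %in% targets
      }
      width <- round(runif(sum(hit), 500, 3000))
      offset <- floor(runif(sum(hit)) * width) # 0 .. width-1, so TSS inside
      fg <- tibble(
        chrom = genes$chrom[hit],
        start = pmax(0, genes$tss[hit] - offset),
        end = genes$tss[hit] - offset + width
      )
    }
    n_bg <- round(config$background_peak_rate * config$n_genes)
    bg <- tibble(chrom = character(), start = numeric(), end = numeric())
    if (n_bg > 0) {
      tss_tbl <- genes |>
        transmute(chrom = .data$chrom, start = .data$tss, end = .data$tss + 1)
      for (round in 1:10) {
        need <- n_bg - nrow(bg)
        if (need == 0) break
        cand <- tibble(
          chrom = paste0("chr", sample.int(config$n_chromosomes, need, replace = TRUE)),
          start = round(runif(need, 0, config$chrom_length - 3000))
        ) |>
          mutate(end = .data$start + round(runif(need, 500, 3000)))
        drop <- overlap_pairs(cand, tss_tbl)$query
        bg <- bind_rows(bg, cand[setdiff(seq_len(need), drop), ])
      }
    }
    bind_rows(fg, bg) |> arrange(.data$chrom, .data$start)
  })
}

#' Simulate lamina-associated domains
#'
#' Tiles the genome into segments and samples segments without replacement
#' with probability proportional to the LAD odds of the resident genes'
#' categories (`lad_enrichment_by_category`; gene-free segments get weight
#' 1) until the requested `lad_fraction` of the genome is covered
#' (tolerance well inside +/- 0.02).  Adjacent selected segments are
#' merged; each resulting domain is labelled constitutive or facultative
#' at random.
#'
#' @inheritParams sim_peaks
#' @param segment_size Tiling segment size in bp.
#' @return Tibble (`chrom`, `start`, `end`, `type`).
#' @export
sim_lads <- function(genes, ages, config, segment_size = NULL) {
  config <- validate_sim_config(config)
  segment_size <- segment_size %||% max(10000, round(config$chrom_length / 200))
  withr::with_seed(stream_seed(config$seed, "lads"), {
    segs <- purrr::map_dfr(seq_len(config$n_chromosomes), function(ci) {
      starts <- seq(0, config$chrom_length - 1, by = segment_size)
      tibble(chrom = paste0("chr", ci), start = starts,
             end = pmin(starts + segment_size, config$chrom_length))
    })
    if (config$lad_fraction == 0) {
      return(tibble(chrom = character(), start = numeric(), end = numeric(),
                    type = character()))
    }
    w <- rep(1, nrow(segs))
    hits <- overlap_pairs(segs, genes |> select("chrom", "start", "end"))
    if (nrow(hits) > 0) {
      cat <- as.character(ages$category[match(genes$gene_id[hits$subject], ages$gene_id)])
      odds <- config$lad_enrichment_by_category[cat]
      agg <- tapply(odds, hits$query, mean)
      w[as.integer(names(agg))] <- as.numeric(agg)
    }
    n_pick <- max(1, round(config$lad_fraction * nrow(segs)))
    pick <- if (n_pick >= nrow(segs)) seq_len(nrow(segs)) else {
      sample.int(nrow(segs), n_pick, prob = w)
    }
    lads <- segs[sort(pick), ] |>
      group_by(.data$chrom) |>
      group_modify(~ merge_adjacent(.x)) |>
      ungroup()
    lads$type <- sample(c("constitutive", "facultative"), nrow(lads), replace = TRUE)
    lads
  })
}

merge_adjacent <- function(d) {
  d <- d[order(d$start), ]
  grp <- cumsum(c(1, as.integer(d$start[-1] > d$end[-nrow(d)])))
  tibble(start = tapply(d$start, grp, min)[unique(grp)] |> as.numeric(),
         end = tapply(d$end, grp, max)[unique(grp)] |> as.numeric())
}

#' Simulate promoter CpG sites and methylation scores
#'
#' Places Poisson-distributed point sites in each gene's promoter window
#' (TSS +/- 1 kb) at per-category rates (mean sites per promoter), and
#' assigns each site a methylation score in `[0, 1]` drawn around the
#' per-category mean — CpG density falling, and methylation rising, from
#' old to young genes by default.
#'
#' @inheritParams sim_peaks
#' @param rate_by_category Mean promoter site count per category.
#' @param meth_by_category Mean methylation score per category.
#' @return List with `sites` (`chrom`, `pos`) and `scores`
#'   (`chrom`, `pos`, `score`).
#' @export
sim_cpg <- function(genes, ages, config,
                    rate_by_category = c(UC = 5, EM = 3, MM = 1),
                    meth_by_category = c(UC = 0.2, EM = 0.5, MM = 0.8)) {
  config <- validate_sim_config(config)
  withr::with_seed(stream_seed(config$seed, "cpg"), {
    cat <- as.character(ages$category[match(genes$gene_id, ages$gene_id)])
    n_sites <- stats::rpois(nrow(genes), rate_by_category[cat])
    win <- promoter_window(genes, 1000, 1000)
    idx <- rep(seq_len(nrow(genes)), n_sites)
    pos <- floor(win$start[idx] + runif(length(idx)) * (win$end[idx] - win$start[idx]))
    score <- pmin(1, pmax(0, rnorm(length(idx), meth_by_category[cat[idx]], 0.05)))
    list(
      sites = tibble(chrom = win$chrom[idx], pos = pos),
      scores = tibble(chrom = win$chrom[idx], pos = pos, score = score)
    )
  })
}

#' Simulate a differential-expression result table
#'
#' Emits per-gene log2 fold changes and adjusted p-values with planted
#' per-category up/down-regulation rates mirroring a differentiation
#' contrast: up-regulation rising sharply with evolutionary youth
#' (defaults 14/32/59% for UC/EM/MM) and down-regulation rare and
#' declining (5/3/2%).
#'
#' @inheritParams sim_peaks
#' @param up_prob,down_prob Named per-category probabilities.
#' @return Tibble (`gene_id`, `log2FC`, `padj`).
#' @export
sim_de <- function(genes, ages, config,
                   up_prob = c(UC = 0.14, EM = 0.32, MM = 0.59),
                   down_prob = c(UC = 0.05, EM = 0.03, MM = 0.02)) {
  config <- validate_sim_config(config)
  withr::with_seed(stream_seed(config$seed, "de"), {
    cat <- as.character(ages$category[match(genes$gene_id, ages$gene_id)])
    u <- runif(nrow(genes))
    state <- ifelse(u < up_prob[cat], "up",
                    ifelse(u < up_prob[cat] + down_prob[cat], "down", "none"))
    lfc <- dplyr::case_when(
      state == "up" ~ runif(nrow(genes), 2.1, 6),
      state == "down" ~ runif(nrow(genes), -6, -2.1),
      TRUE ~ pmin(1.9, pmax(-1.9, rnorm(nrow(genes), 0, 0.8)))
    )
    padj <- ifelse(state == "none", runif(nrow(genes), 0.1, 1),
                   runif(nrow(genes), 1e-8, 0.09))
    tibble(gene_id = genes$gene_id, log2FC = lfc, padj = padj)
  })
}
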