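#' End-to-end analysis report
#'
#' Runs the full analysis chain on an input bundle: gene annotation,
#' promoter-subnetwork extraction, categorical ChAs z-scores for the age
#' categories, delta-ChAs for every age category against every available
#' chromatin feature (Pol II pausing, Polycomb targets, LAD overlap), the
#' Pol II pausing pipeline with rank-sum comparisons, class-level age
#' trends for expression and expression variability, and Fisher
#' enrichment of age categories in EV decile groups (low = groups 1-6,
#' high = groups 8-10).  All ChAs-based statistics share one set of
#' distance-matched null networks (common random numbers).  Analyses
#' whose optional inputs are absent are skipped with a logged reason;
#' Benjamini-Hochberg adjusted p-values are added within each family of
#' comparisons.
#'
#' @param bundle List with `genes` and `ages` plus any of `network`,
#'   `peaks`, `lads`, `tracks`, `expression`, `de` (the shape returned by
#'   [sim_scenario()]).
#' @param n_rand Randomizations for the ChAs nulls (default 100).
#' @param seed Integer seed for the nulls.
#' @param pol2_threshold A gene is pol2-positive when its mean raw
#'   pausing index across cell states exceeds this value.
#' @return A `chromage_report` list: `annotation`, `chas_age`, `delta`,
#'   `pausing`, `pi_comparisons`, `trends`, `enrichment`, `log`,
#'   `settings`.
#' @export
run_report <- function(bundle, n_rand = 100, seed = 1L, pol2_threshold = 1.5) {
  if (is.null(bundle$genes) || is.null(bundle$ages)) {
    abort("The bundle must contain `genes` and `ages`.")
  }
  genes <- bundle$genes; ages <- bundle$ages
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))

  annotation <- annotate_genes(genes, ages, peaks = bundle$peaks,
                               lads = bundle$lads, de = bundle$de)
  note("annotated ", nrow(annotation), " genes")

  # gene-level binary features for delta-ChAs
  features <- list()
  if (!is.null(bundle$peaks)) {
    pc <- polycomb_targets(genes, bundle$peaks)
    features$polycomb <- pc$gene_id[pc$polycomb == 1]
  } else note("skipped polycomb feature: no peaks input")
  if (!is.null(bundle$lads)) {
    ld <- lad_genes(genes, bundle$lads)
    features$lad <- ld$gene_id[ld$lad == 1]
  } else note("skipped lad feature: no LAD input")

  pausing <- NULL; pi_comparisons <- NULL
  if (!is.null(bundle$tracks)) {
    pausing <- pausing_pipeline(bundle$tracks, genes)
    pi_comparisons <- compare_pi_distributions(pausing, ages) |>
      group_by(.data$comparison) |>
      mutate(p_adj = stats::p.adjust(.data$p_value, "BH")) |>
      ungroup()
    pol2_mean <- pausing |>
      filter(!is.na(.data$pi_raw)) |>
      group_by(.data$gene_id) |>
      summarise(mean_pi = mean(.data$pi_raw), .groups = "drop")
    features$pol2 <- pol2_mean$gene_id[pol2_mean$mean_pi > pol2_threshold]
    excl <- pausing |> count(.data$cell, .data$excluded_reason)
    note("pausing pipeline: ",
         paste(excl$cell, excl$excluded_reason, excl$n, collapse = "; "))
  } else note("skipped pausing pipeline: no coverage tracks")

  chas_age <- NULL; delta <- NULL
  if (!is.null(bundle$network)) {
    pnet <- promoter_subnetwork(bundle$network)
    note("promoter subnetwork: ", nrow(pnet$nodes), " nodes, ",
         nrow(pnet$edges), " of ", nrow(bundle$network$edges), " edges")
    assign_cat <- node_categories(pnet, ages)
    cats <- intersect(c("UC", "EM", "MM"), unique(unlist(assign_cat$categories)))
    annotated <- lengths(assign_cat$categories) > 0
    v_list <- purrr::map(cats, function(cc) {
      v <- ifelse(annotated,
                  purrr::map_dbl(assign_cat$categories, ~ as.numeric(cc %in% .x)),
                  NA_real_)
      v[match(pnet$nodes$node_id, assign_cat$node_id)]
    })
    names(v_list) <- paste0("age_", cats)
    genes_on_net <- unique(unlist(pnet$nodes$genes))
    cat_genes <- purrr::map(cats, ~ ages$gene_id[ages$category == .x])
    names(cat_genes) <- cats
    delta_spec <- list()
    for (cc in cats) {
      for (fn in names(features)) {
        with_set <- intersect(cat_genes[[cc]], features[[fn]])
        without_set <- setdiff(cat_genes[[cc]], features[[fn]])
        if (length(intersect(with_set, genes_on_net)) == 0 ||
            length(intersect(without_set, genes_on_net)) == 0) {
          note("skipped delta ", cc, " x ", fn, ": empty subgroup on network")
          next
        }
        ind <- function(set) {
          f <- map_feature(pnet, tibble(gene_id = genes_on_net,
                                        value = as.numeric(genes_on_net %in% set)),
                           kind = "binary")
          feature_values(pnet, f)
        }
        v_list[[paste0("delta_", cc, "_", fn, "_with")]] <- ind(with_set)
        v_list[[paste0("delta_", cc, "_", fn, "_without")]] <- ind(without_set)
        delta_spec[[length(delta_spec) + 1]] <- list(
          group = cc, feature = fn,
          n_with = length(with_set), n_without = length(without_set))
      }
    }
    res <- chas_null(pnet, v_list, n_rand = n_rand, seed = seed)
    zs <- purrr::map_dbl(seq_along(v_list), function(k) {
      ns <- res$null_sample[, k]
      s <- sd(ns[!is.na(ns)])
      if (is.na(s) || s == 0) return(NA_real_)
      (res$observed[k] - mean(ns, na.rm = TRUE)) / s
    })
    names(zs) <- names(v_list)
    chas_age <- tibble(
      category = cats,
      observed = res$observed[seq_along(cats)],
      z = zs[paste0("age_", cats)]
    )
    delta <- purrr::map_dfr(delta_spec, function(d) {
      kw <- paste0("delta_", d$group, "_", d$feature, "_with")
      ko <- paste0("delta_", d$group, "_", d$feature, "_without")
      tibble(group = d$group, feature = d$feature,
             z_with = zs[[kw]], z_without = zs[[ko]],
             delta = zs[[kw]] - zs[[ko]],
             n_with = d$n_with, n_without = d$n_without)
    })
  } else note("skipped network analyses: no network input")

  trends <- NULL; enrichment <- NULL
  if (!is.null(bundle$expression)) {
    expr <- bundle$expression
    trends <- bind_rows(
      spearman_age_trend(ages, expr |> select("gene_id", value = "expression")) |>
        mutate(quantity = "expression", .before = 1),
      spearman_age_trend(ages, expr |> select("gene_id", value = "ev")) |>
        mutate(quantity = "ev", .before = 1)
    )
    dec <- decile_groups(expr |> select("gene_id", value = "ev"))
    low <- dec$gene_id[dec$group <= 6]
    high <- dec$gene_id[dec$group >= 8]
    enrichment <- bind_rows(
      fisher_enrichment(ages$gene_id[ages$category == "UC"], low, ages$gene_id) |>
        mutate(set_a = "UC", set_b = "EV_low_1_6", .before = 1),
      fisher_enrichment(ages$gene_id[ages$category == "EM"], high, ages$gene_id) |>
        mutate(set_a = "EM", set_b = "EV_high_8_10", .before = 1)
    ) |>
      mutate(p_adj = stats::p.adjust(.data$p_value, "BH"))
  } else note("skipped expression analyses: no expression input")

  structure(list(
    annotation = annotation, chas_age = chas_age, delta = delta,
    pausing = pausing, pi_comparisons = pi_comparisons,
    trends = trends, enrichment = enrichment, log = log,
    settings = list(n_rand = n_rand, seed = seed,
                    pol2_threshold = pol2_threshold)
  ), class = "chromage_report")
}

#' @export
print.chromage_report <- function(x, ...) {
  cat("<chromage_report>\n")
  if (!is.null(x$chas_age)) {
    cat("  age-category ChAs z:",
        paste(sprintf("%s %.1f", x$chas_age$category, x$chas_age$z),
              collapse = ", "), "\n")
  }
  if (!is.null(x$delta)) {
    cat("  delta-ChAs rows:", nrow(x$delta), "\n")
  }
  if (!is.null(x$trends)) {
    cat("  age trends:",
        paste(sprintf("%s rho %.2f", x$trends$quantity, x$trends$rho),
              collapse = ", "), "\n")
  }
  cat("  log:", length(x$log), "entries\n")
  invisible(x)
}
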