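# End-to-end orchestration: normalize -> DE -> validate -> classify ->
# coexpress -> enrich -> report, with a machine-readable run manifest.

#' Reload a study written by [write_study()]
#'
#' Reconstructs the `sim_study` structure from the plain-text fixtures,
#' including the per-module structure from the truth table's
#' `module_id` / `module_role` columns.
#'
#' @param dir directory written by [write_study()].
#' @param cfg the [sim_config()] used to write it (carries platform and
#'   dataset roles).
#' @return a `sim_study` list.
#' @export
load_study <- function(dir, cfg) {
  p <- function(...) file.path(dir, paste0(...))
  rnaseq <- list()
  arrays <- list()
  for (id in names(cfg$datasets)) {
    if (cfg$datasets[[id]]$platform == "rnaseq") {
      rnaseq[[id]] <- read_expression(p(id, "_counts.tsv"), "rnaseq",
                                      p(id, "_samples.tsv"), dataset_id = id)
    } else {
      probes <- utils::read.delim(p(id, "_probes.tsv"), check.names = FALSE)
      m <- as.matrix(probes[, -1, drop = FALSE])
      rownames(m) <- probes[[1]]
      samples <- utils::read.delim(p(id, "_samples.tsv"), stringsAsFactors = FALSE)
      arrays[[id]] <- list(probes = m,
                           probe_map = read_probe_map(p(id, "_probe_map.tsv")),
                           samples = samples[, c("sample_id", "group")],
                           platform = "microarray", dataset_id = id)
    }
  }
  truth <- utils::read.delim(p("truth.tsv"), stringsAsFactors = FALSE)
  rownames(truth) <- truth$gene_id
  modules <- list()
  for (mid in unique(stats::na.omit(truth$module_id))) {
    rows <- truth[!is.na(truth$module_id) & truth$module_id == mid, ]
    modules[[mid]] <- list(
      module_id = mid, category = mid,
      lncrna = rows$gene_id[rows$module_role == "lncrna"],
      partners = rows$gene_id[rows$module_role == "partner"],
      term_id = rows$planted_term[1],
      dataset_id = if (mid == "specific_ATC") cfg$array_id else cfg$primary_rnaseq
    )
  }
  attr(truth, "modules") <- modules
  class(truth) <- c("sim_truth", "data.frame")
  structure(
    list(config = cfg, truth = truth,
         annotation = read_annotation(p("annotation.tsv")),
         rnaseq = rnaseq, arrays = arrays,
         gmt = read_gmt(p("gene_sets.gmt"))),
    class = "sim_study"
  )
}

# lncRNA gene ids according to an annotation table.
.lnc_ids <- function(annotation) {
  annotation$gene_id[canon_biotype(annotation$biotype) %in% LNCRNA_BIOTYPES]
}

#' Score category recovery against the planted truth
#'
#' @param assignments data.frame from [assign_categories()].
#' @param truth a truth table with `gene_id` and `true_category`.
#' @return data.frame with per-category planted/predicted counts, true
#'   positives, sensitivity and precision (precision is NA when nothing
#'   was predicted).
#' @export
score_recovery <- function(assignments, truth) {
  rows <- lapply(CATEGORY_LEVELS, function(cc) {
    truth_set <- truth$gene_id[truth$true_category == cc]
    pred_set <- assignments$gene_id[assignments$category == cc]
    tp <- length(intersect(truth_set, pred_set))
    data.frame(
      category = cc,
      n_planted = length(truth_set), n_predicted = length(pred_set),
      tp = tp,
      sensitivity = if (length(truth_set)) tp / length(truth_set) else NA_real_,
      precision = if (length(pred_set)) tp / length(pred_set) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Run the full landscape pipeline on a (simulated) study
#'
#' Stages, in order: platform-specific normalization (low-count filter,
#' TMM and precision weights for counts; quantile normalization and
#' probe collapse for arrays), per-dataset linear modelling with
#' empirical-Bayes moderation, vs-reference and between-subtype DE
#' tables restricted to the lncRNA universe, cross-dataset validation of
#' the two PTC variants, the category cascade plus the ATC funnel,
#' per-category top-DE selection, coexpression and gene-set enrichment,
#' and (when truth is present) recovery scoring. A manifest records the
#' seed, a configuration digest, per-stage wall time and output file
#' digests.
#'
#' @param study a `sim_study` from [simulate_study()] or [load_study()].
#' @param fdr_max,min_fc DE call thresholds (defaults 0.01 and 2).
#' @param min_count named per-dataset low-count thresholds; unnamed
#'   datasets use 2, except the second RNA-seq dataset which defaults
#'   to 1 (a shallower cohort).
#' @param top_k lncRNAs taken per category for functional inference.
#' @param r_min,p_max coexpression gates.
#' @param validation_mode `"three_dataset"` (default; requires a
#'   microarray dataset) or `"two_dataset"` (both RNA-seq datasets
#'   suffice; for configurations without an array).
#' @param out_dir optional directory; when given, result tables are
#'   written as TSV and the manifest as JSON.
#' @return list (class `landscape_run`) with elements `de_tables`,
#'   `between_tables`, `normalized`, `validation`, `assignments`,
#'   `report`, `atc_funnel`, `top_lncrnas`, `coexpression`,
#'   `enrichment`, `recovery`, `manifest`.
#' @export
run_landscape_pipeline <- function(study,
                                   fdr_max = 0.01, min_fc = 2,
                                   min_count = NULL, top_k = 5,
                                   r_min = 0.7, p_max = 0.05,
                                   validation_mode = c("three_dataset", "two_dataset"),
                                   out_dir = NULL) {
  validation_mode <- match.arg(validation_mode)
  cfg <- study$config
  t0 <- Sys.time()
  stage_time <- numeric(0)
  tick <- function(name) {
    now <- Sys.time()
    stage_time[name] <<- as.numeric(difftime(now, t0, units = "secs"))
    t0 <<- now
  }
  primary <- cfg$primary_rnaseq
  second <- cfg$second_rnaseq
  array_id <- cfg$array_id
  if (validation_mode == "three_dataset" &&
      (is.na(array_id %||% NA) || !length(study$arrays)))
    stop("three-dataset validation requires a microarray dataset; ",
         "set validation_mode = \"two_dataset\" to run without one")
  lnc <- .lnc_ids(study$annotation)
  coding <- setdiff(study$annotation$gene_id, lnc)

  # -- normalization + per-dataset fits ------------------------------
  if (is.null(min_count)) {
    min_count <- stats::setNames(rep(2, length(study$rnaseq)), names(study$rnaseq))
    if (!is.na(second %||% NA) && second %in% names(min_count)) min_count[second] <- 1
  }
  normalized <- list()
  fits <- list()
  measured_genes <- list()
  for (id in names(study$rnaseq)) {
    ds <- filter_low_counts(
      study$rnaseq[[id]],
      min_count = if (id %in% names(min_count)) min_count[[id]] else 2
    )
    nd <- voom_weights(ds)
    normalized[[id]] <- nd
    fits[[id]] <- ebayes_moderate(fit_group_means(nd))
    measured_genes[[id]] <- rownames(nd$log2_expr)
  }
  for (id in names(study$arrays)) {
    a <- study$arrays[[id]]
    gene_expr <- collapse_probes(quantile_normalize(a$probes), a$probe_map)
    nd <- normalized_dataset(gene_expr, a$samples, "microarray", id,
                             provenance = list(normalization = "quantile+median-collapse"))
    normalized[[id]] <- nd
    fits[[id]] <- ebayes_moderate(fit_group_means(nd))
    measured_genes[[id]] <- rownames(gene_expr)
  }
  tick("normalize_fit")

  # -- DE tables (lncRNA universe) -----------------------------------
  de_tables <- list()       # de_tables[[dataset]][[subtype]] vs NT
  between_tables <- list()  # between_tables[[dataset]]: long data.frame
  for (id in names(fits)) {
    fit <- fits[[id]]
    groups <- setdiff(fit$groups, "NT")
    lnc_here <- intersect(measured_genes[[id]], lnc)
    de_tables[[id]] <- lapply(stats::setNames(groups, groups), function(g) {
      contrast_table(fit, g, "NT", genes = lnc_here,
                     fdr_max = fdr_max, min_fc = min_fc)
    })
    pairs <- if (identical(id, array_id)) {
      if ("ATC" %in% fit$groups) {
        list(c("ATC", "clPTC"), c("ATC", "fvPTC"))
      } else list()
    } else if (identical(id, primary)) {
      utils::combn(groups, 2, simplify = FALSE)
    } else {
      list()
    }
    if (length(pairs)) {
      between_tables[[id]] <- do.call(rbind, lapply(pairs, function(pr) {
        contrast_table(fit, pr[1], pr[2], genes = lnc_here,
                       fdr_max = fdr_max, min_fc = min_fc)
      }))
    }
  }
  tick("de")

  # -- cross-dataset validation (clPTC, fvPTC) -----------------------
  measured_array <- if (length(study$arrays)) measured_genes[[array_id]] else character(0)
  validation <- lapply(stats::setNames(c("clPTC", "fvPTC"), c("clPTC", "fvPTC")),
                       function(st) {
    if (validation_mode == "two_dataset") {
      de_flag <- function(id) lnc %in% with(de_tables[[id]][[st]],
                                            gene_id[is_de])
      data.frame(gene_id = lnc,
                 validated = de_flag(primary) & de_flag(second),
                 stringsAsFactors = FALSE)
    } else {
      validate_subtype(
        list(rnaseqA = de_tables[[primary]][[st]],
             rnaseqB = de_tables[[second]][[st]],
             array = de_tables[[array_id]][[st]]),
        genes = lnc, measured_array = measured_array
      )
    }
  })
  tick("validate")

  # -- category cascade + ATC funnel ---------------------------------
  prim_genes <- intersect(measured_genes[[primary]], lnc)
  subtypes4 <- c("FA", "FTC", "fvPTC", "clPTC")
  vsnt <- sapply(subtypes4, function(st) {
    tab <- de_tables[[primary]][[st]]
    prim_genes %in% tab$gene_id[tab$is_de]
  })
  rownames(vsnt) <- prim_genes
  validated <- cbind(
    clPTC = validation$clPTC$validated[match(prim_genes, validation$clPTC$gene_id)],
    fvPTC = validation$fvPTC$validated[match(prim_genes, validation$fvPTC$gene_id)]
  )
  rownames(validated) <- prim_genes
  diff_assign <- classify_differentiated(vsnt, validated,
                                         between_tables[[primary]])
  de_vs_nt_any <- function(st) {
    unique(unlist(lapply(names(de_tables), function(id) {
      tab <- de_tables[[id]][[st]]
      if (is.null(tab)) character(0) else tab$gene_id[tab$is_de]
    })))
  }
  differentiated_union <- unique(unlist(lapply(subtypes4, de_vs_nt_any)))
  if (length(study$arrays) && "ATC" %in% names(de_tables[[array_id]])) {
    bt_arr <- between_tables[[array_id]]
    funnel <- classify_atc(
      atc_vs_nt = with(de_tables[[array_id]]$ATC, gene_id[is_de]),
      differentiated_union = differentiated_union,
      atc_vs_clptc = with(bt_arr, gene_id[is_de & contrast == "ATC_vs_clPTC"]),
      atc_vs_fvptc = with(bt_arr, gene_id[is_de & contrast == "ATC_vs_fvPTC"])
    )
  } else {
    funnel <- list(stage1 = character(0), stage2 = character(0),
                   stage3 = character(0), specific_atc = character(0))
  }
  assignments <- assign_categories(diff_assign, funnel$specific_atc,
                                   all_genes = lnc)
  lfc_lookup <- do.call(rbind, lapply(names(de_tables), function(id) {
    do.call(rbind, lapply(names(de_tables[[id]]), function(st) {
      use <- if (st == "ATC") identical(id, array_id) else identical(id, primary)
      if (!use) return(NULL)
      data.frame(gene_id = de_tables[[id]][[st]]$gene_id, subtype = st,
                 log2fc = de_tables[[id]][[st]]$log2fc,
                 stringsAsFactors = FALSE)
    }))
  }))
  report <- intersection_report(assignments, lfc_lookup)
  tick("classify")

  # -- functional inference ------------------------------------------
  top_lncrnas <- list()
  coexpression <- list()
  enrichment <- list()
  universe_of <- function(id) intersect(rownames(normalized[[id]]$log2_expr), coding)
  for (cc in CATEGORY_LEVELS) {
    genes_cc <- assignments$gene_id[assignments$category == cc]
    if (!length(genes_cc)) next
    ds_id <- if (cc == "specific_ATC") array_id else primary
    if (is.null(ds_id) || is.na(ds_id %||% NA) || is.null(normalized[[ds_id]])) next
    def_tab <- de_tables[[ds_id]][[.category_defining[[cc]]]]
    genes_cc <- intersect(genes_cc, def_tab$gene_id)
    if (!length(genes_cc)) next
    top <- top_de(genes_cc, def_tab, k = top_k)
    top_lncrnas[[cc]] <- top
    uni <- universe_of(ds_id)
    for (g in top) {
      cx <- coexpressed_genes(g, normalized[[ds_id]], uni,
                              r_min = r_min, p_max = p_max)
      if (nrow(cx)) {
        cx$category <- cc
        cx$dataset_id <- ds_id
        coexpression[[paste(cc, g)]] <- cx
        en <- fisher_enrichment(cx$gene_id, study$gmt, uni)
        en$lncrna_id <- g
        en$category <- cc
        enrichment[[paste(cc, g)]] <- en
      }
    }
  }
  coexpression <- if (length(coexpression)) do.call(rbind, coexpression) else
    data.frame(lncrna_id = character(0), gene_id = character(0),
               r = numeric(0), p = numeric(0))
  enrichment <- if (length(enrichment)) do.call(rbind, enrichment) else
    data.frame(term_id = character(0), p = numeric(0), p_adj = numeric(0),
               significant = logical(0))
  rownames(coexpression) <- rownames(enrichment) <- NULL
  tick("function_inference")

  recovery <- if (!is.null(study$truth)) score_recovery(assignments, study$truth)
  manifest <- list(
    seed = cfg$seed,
    config_digest = object_digest(cfg),
    parameters = list(fdr_max = fdr_max, min_fc = min_fc,
                      min_count = as.list(min_count), top_k = top_k,
                      r_min = r_min, p_max = p_max,
                      validation_mode = validation_mode),
    n_genes = stats::setNames(lapply(measured_genes, length), names(measured_genes)),
    stage_seconds = as.list(stage_time),
    version = as.character(utils::packageVersion("lncLandscape"))
  )
  result <- structure(
    list(de_tables = de_tables, between_tables = between_tables,
         normalized = normalized, validation = validation,
         assignments = assignments, report = report, atc_funnel = funnel,
         top_lncrnas = top_lncrnas, coexpression = coexpression,
         enrichment = enrichment, recovery = recovery, manifest = manifest),
    class = "landscape_run"
  )
  if (!is.null(out_dir)) result <- .write_run(result, out_dir)
  result
}

# Write the run's result tables + manifest; records file digests in the
# manifest.
.write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  long_de <- do.call(rbind, lapply(names(result$de_tables), function(id) {
    tab <- do.call(rbind, result$de_tables[[id]])
    tab$dataset_id <- id
    tab
  }))
  rownames(long_de) <- NULL
  long_between <- do.call(rbind, lapply(names(result$between_tables), function(id) {
    tab <- result$between_tables[[id]]
    tab$dataset_id <- id
    tab
  }))
  write_table(long_de, p("de_calls.tsv"))
  if (!is.null(long_between)) write_table(long_between, p("between_calls.tsv"))
  write_table(result$assignments, p("categories.tsv"))
  write_table(result$report$counts, p("category_counts.tsv"))
  val <- do.call(rbind, lapply(names(result$validation), function(st) {
    v <- result$validation[[st]]; v$subtype <- st; v
  }))
  write_table(val, p("validation.tsv"))
  write_table(result$coexpression, p("coexpression.tsv"))
  write_table(result$enrichment, p("enrichment.tsv"))
  if (!is.null(result$recovery)) write_table(result$recovery, p("truth_recovery.tsv"))
  files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  result$manifest$output_digests <- as.list(stats::setNames(
    unname(tools::md5sum(files)), basename(files)))
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  result
}

#' @export
print.landscape_run <- function(x, ...) {
  cat("<landscape_run>\n")
  print(x$report$counts)
  if (!is.null(x$recovery)) {
    cat("recovery vs planted truth:\n")
    print(x$recovery)
  }
  invisible(x)
}
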