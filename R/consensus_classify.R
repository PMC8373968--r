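# Cross-dataset validation of DE calls and assignment of every lncRNA to
# one of the seven common/subtype-specific categories.

#' Category labels assigned by the classification cascade
#' @format character vector of the seven category names (plus "none"
#'   for unassigned genes).
#' @export
CATEGORY_LEVELS <- c(
  "common_FA_WDTC", "common_WDTC", "common_papillary",
  "specific_FTC", "specific_fvPTC", "specific_clPTC", "specific_ATC"
)

#' Cross-dataset validation rule for a DE call
#'
#' A subtype's DE-vs-reference call for a gene is validated when the gene
#' is DE in all three datasets (two RNA-seq, one microarray), or DE in
#' both RNA-seq datasets while having no probe on the microarray
#' platform. Being measured on the array but not DE there fails the rule.
#' All arguments are vectorised.
#'
#' @param de_a,de_b logical: DE in the first / second RNA-seq dataset.
#' @param de_array logical: DE in the microarray dataset.
#' @param measured_array logical: covered by microarray probes.
#' @return logical vector of validation flags.
#' @export
validate_gene <- function(de_a, de_b, de_array, measured_array) {
  (de_a & de_b & de_array) | (de_a & de_b & !measured_array)
}

#' Validate a subtype's DE calls across three datasets
#'
#' @param de_tables named list of the subtype's vs-reference DE tables
#'   (as from [contrast_table()]) for the datasets named in `rnaseq_ids`
#'   and `array_id`; a gene absent from a table counts as not DE there.
#' @param genes character vector: the gene universe to report.
#' @param measured_array character vector of genes covered by array
#'   probes.
#' @param rnaseq_ids names of the two RNA-seq datasets in `de_tables`.
#' @param array_id name of the microarray dataset in `de_tables`.
#' @return data.frame with columns `gene_id`, `validated`.
#' @export
validate_subtype <- function(de_tables, genes, measured_array,
                             rnaseq_ids = c("rnaseqA", "rnaseqB"),
                             array_id = "array") {
  need <- c(rnaseq_ids, array_id)
  missing <- setdiff(need, names(de_tables))
  if (length(missing))
    stop("missing DE table(s) for dataset(s): ", paste(missing, collapse = ", "))
  de_flag <- function(id) {
    tab <- de_tables[[id]]
    genes %in% tab$gene_id[tab$is_de]
  }
  data.frame(
    gene_id = genes,
    validated = validate_gene(
      de_flag(rnaseq_ids[1]), de_flag(rnaseq_ids[2]), de_flag(array_id),
      genes %in% measured_array
    ),
    stringsAsFactors = FALSE
  )
}

# Lookup of between-subtype DE flags; contrasts are symmetric for the DE
# flag (|log2FC| and p are orientation-invariant), so either orientation
# in `between` satisfies a request.
.between_lookup <- function(between) {
  stopifnot(all(c("gene_id", "contrast", "is_de") %in% names(between)))
  key <- paste(between$gene_id, between$contrast)
  flag <- between$is_de
  names(flag) <- key
  function(gene, a, b) {
    k1 <- paste(gene, paste0(a, "_vs_", b))
    k2 <- paste(gene, paste0(b, "_vs_", a))
    if (!is.na(flag[k1])) return(unname(flag[k1]))
    if (!is.na(flag[k2])) return(unname(flag[k2]))
    stop("missing between-subtype contrast ", a, " vs ", b, " for gene ", gene)
  }
}

#' Classify lncRNAs of the differentiated subtypes
#'
#' Decision cascade over the vs-reference DE pattern
#' `P` within \{FA, FTC, fvPTC, clPTC\} (from the primary RNA-seq
#' dataset, the only one covering all four), the cross-dataset validation
#' flags for the two PTC variants, and between-subtype DE calls:
#'
#' 1. `P` = all four, validated in clPTC and fvPTC: common to FA + WDTC.
#' 2. `P` = \{FTC, fvPTC, clPTC\}, validated in both PTC variants, and
#'    each PTC variant DE vs FA: common to WDTC.
#' 3. `P` = \{fvPTC, clPTC\}, validated in both, and each PTC variant DE
#'    vs FA and vs FTC: common to papillary carcinomas.
#' 4. `P` = \{clPTC\} (resp. \{fvPTC\}), validated in that variant, DE vs
#'    each of the other three subtypes: specific to clPTC (resp. fvPTC).
#' 5. `P` = \{FTC\}, DE vs clPTC and vs fvPTC: specific to FTC (no
#'    validation possible for FTC, and no FA requirement).
#' 6. anything else: none.
#'
#' @param vsnt logical gene-by-subtype matrix (columns FA, FTC, fvPTC,
#'   clPTC) of vs-reference DE flags in the primary RNA-seq dataset.
#' @param validated logical gene-by-variant matrix (columns clPTC,
#'   fvPTC) of cross-dataset validation flags.
#' @param between data.frame of between-subtype DE calls in the primary
#'   RNA-seq dataset with columns `gene_id`, `contrast`
#'   (`"A_vs_B"`), `is_de`. A contrast needed by a triggered rule but
#'   absent is a hard error naming the contrast.
#' @return data.frame with columns `gene_id`, `category`,
#'   `criteria_trace`.
#' @export
classify_differentiated <- function(vsnt, validated, between) {
  stopifnot(all(c("FA", "FTC", "fvPTC", "clPTC") %in% colnames(vsnt)),
            all(c("clPTC", "fvPTC") %in% colnames(validated)))
  genes <- rownames(vsnt)
  stopifnot(!is.null(genes), identical(genes, rownames(validated)))
  bt <- .between_lookup(between)
  category <- rep("none", length(genes))
  trace <- character(length(genes))
  subtypes <- c("FA", "FTC", "fvPTC", "clPTC")
  for (i in seq_along(genes)) {
    g <- genes[i]
    P <- subtypes[vsnt[i, subtypes]]
    v_cl <- validated[i, "clPTC"]
    v_fv <- validated[i, "fvPTC"]
    steps <- sprintf("P={%s}", paste(P, collapse = ","))
    cat_i <- "none"
    if (setequal(P, subtypes)) {
      ok <- v_cl && v_fv
      steps <- c(steps, sprintf("validated_clPTC=%s", v_cl),
                 sprintf("validated_fvPTC=%s", v_fv))
      if (ok) cat_i <- "common_FA_WDTC"
    } else if (setequal(P, c("FTC", "fvPTC", "clPTC"))) {
      ok <- v_cl && v_fv
      steps <- c(steps, sprintf("validated_clPTC=%s", v_cl),
                 sprintf("validated_fvPTC=%s", v_fv))
      if (ok) {
        fv_fa <- bt(g, "fvPTC", "FA"); cl_fa <- bt(g, "clPTC", "FA")
        steps <- c(steps, sprintf("de_fvPTC_vs_FA=%s", fv_fa),
                   sprintf("de_clPTC_vs_FA=%s", cl_fa))
        if (fv_fa && cl_fa) cat_i <- "common_WDTC"
      }
    } else if (setequal(P, c("fvPTC", "clPTC"))) {
      ok <- v_cl && v_fv
      steps <- c(steps, sprintf("validated_clPTC=%s", v_cl),
                 sprintf("validated_fvPTC=%s", v_fv))
      if (ok) {
        checks <- c(
          de_fvPTC_vs_FA = bt(g, "fvPTC", "FA"),
          de_fvPTC_vs_FTC = bt(g, "fvPTC", "FTC"),
          de_clPTC_vs_FA = bt(g, "clPTC", "FA"),
          de_clPTC_vs_FTC = bt(g, "clPTC", "FTC")
        )
        steps <- c(steps, sprintf("%s=%s", names(checks), checks))
        if (all(checks)) cat_i <- "common_papillary"
      }
    } else if (identical(P, "clPTC") || identical(P, "fvPTC")) {
      this <- P
      other_ptc <- if (this == "clPTC") "fvPTC" else "clPTC"
      v_this <- validated[i, this]
      steps <- c(steps, sprintf("validated_%s=%s", this, v_this))
      if (v_this) {
        checks <- c(bt(g, this, other_ptc), bt(g, this, "FTC"), bt(g, this, "FA"))
        names(checks) <- sprintf("de_%s_vs_%s", this, c(other_ptc, "FTC", "FA"))
        steps <- c(steps, sprintf("%s=%s", names(checks), checks))
        if (all(checks)) cat_i <- paste0("specific_", this)
      }
    } else if (identical(P, "FTC")) {
      checks <- c(de_FTC_vs_clPTC = bt(g, "FTC", "clPTC"),
                  de_FTC_vs_fvPTC = bt(g, "FTC", "fvPTC"))
      steps <- c(steps, sprintf("%s=%s", names(checks), checks))
      if (all(checks)) cat_i <- "specific_FTC"
    }
    category[i] <- cat_i
    trace[i] <- paste(steps, collapse = ";")
  }
  data.frame(gene_id = genes, category = category, criteria_trace = trace,
             stringsAsFactors = FALSE)
}

#' Select lncRNAs specific to the anaplastic subtype
#'
#' Starting from genes DE in ATC vs reference on the microarray (the only
#' platform with ATC samples), removes every gene DE in any
#' differentiated subtype in any dataset, then keeps genes DE in ATC vs
#' both PTC variants on the array. The three funnel stages are returned
#' so their monotone shrinkage can be inspected.
#'
#' @param atc_vs_nt character vector: genes DE in ATC vs reference.
#' @param differentiated_union character vector: genes DE vs reference in
#'   any of FA/FTC/fvPTC/clPTC in any dataset.
#' @param atc_vs_clptc,atc_vs_fvptc character vectors: genes DE in ATC vs
#'   each PTC variant on the array.
#' @return list with `stage1` (DE vs reference), `stage2` (after removing
#'   the differentiated union), `stage3` (= `specific_atc`, after the
#'   ATC-vs-PTC filter).
#' @export
classify_atc <- function(atc_vs_nt, differentiated_union,
                         atc_vs_clptc, atc_vs_fvptc) {
  stage1 <- unique(atc_vs_nt)
  stage2 <- setdiff(stage1, differentiated_union)
  stage3 <- intersect(stage2, intersect(atc_vs_clptc, atc_vs_fvptc))
  list(stage1 = stage1, stage2 = stage2, stage3 = stage3,
       specific_atc = stage3)
}

#' Merge differentiated and ATC assignments into one category table
#'
#' @param diff_assign data.frame from [classify_differentiated()].
#' @param atc_genes character vector of ATC-specific genes (disjoint from
#'   every differentiated category by construction; enforced).
#' @param all_genes optional full lncRNA universe; genes absent from both
#'   inputs get category "none".
#' @return data.frame with `gene_id`, `category`, `criteria_trace`.
#' @export
assign_categories <- function(diff_assign, atc_genes, all_genes = NULL) {
  clash <- intersect(atc_genes, diff_assign$gene_id[diff_assign$category != "none"])
  if (length(clash))
    stop("gene(s) assigned both an ATC-specific and a differentiated category: ",
         paste(clash, collapse = ", "))
  out <- diff_assign
  add <- setdiff(atc_genes, out$gene_id)
  out$category[out$gene_id %in% atc_genes] <- "specific_ATC"
  out$criteria_trace[out$gene_id %in% atc_genes] <- "ATC_funnel=pass"
  if (length(add)) {
    out <- rbind(out, data.frame(gene_id = add, category = "specific_ATC",
                                 criteria_trace = "ATC_funnel=pass",
                                 stringsAsFactors = FALSE))
  }
  if (!is.null(all_genes)) {
    rest <- setdiff(all_genes, out$gene_id)
    if (length(rest)) {
      out <- rbind(out, data.frame(gene_id = rest, category = "none",
                                   criteria_trace = "not_tested",
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-category counts and ordered gene lists
#'
#' Gene lists are ordered by the absolute log2FC of the category's
#' defining vs-reference contrast, descending (fvPTC for the fvPTC
#' category, ATC for the anaplastic one, clPTC for the remaining
#' categories that include clPTC, FTC for the FTC category).
#'
#' @param assignments data.frame from [assign_categories()].
#' @param lfc_lookup data.frame with columns `gene_id`, `subtype`,
#'   `log2fc` providing defining-contrast fold changes.
#' @return list with `counts` (data.frame category/n) and `gene_lists`
#'   (named list of data.frames ordered by `abs(log2fc)`).
#' @export
intersection_report <- function(assignments, lfc_lookup = NULL) {
  defining <- c(
    common_FA_WDTC = "clPTC", common_WDTC = "clPTC",
    common_papillary = "clPTC", specific_FTC = "FTC",
    specific_fvPTC = "fvPTC", specific_clPTC = "clPTC",
    specific_ATC = "ATC"
  )
  counts <- data.frame(
    category = CATEGORY_LEVELS,
    n = vapply(CATEGORY_LEVELS,
               function(cc) sum(assignments$category == cc), integer(1)),
    stringsAsFactors = FALSE
  )
  gene_lists <- lapply(CATEGORY_LEVELS, function(cc) {
    g <- assignments$gene_id[assignments$category == cc]
    df <- data.frame(gene_id = g, category = rep(cc, length(g)),
                     stringsAsFactors = FALSE)
    if (!is.null(lfc_lookup) && nrow(df)) {
      sub <- lfc_lookup[lfc_lookup$subtype == defining[[cc]], ]
      df$log2fc <- sub$log2fc[match(df$gene_id, sub$gene_id)]
      df <- df[order(-abs(df$log2fc), df$gene_id), , drop = FALSE]
      rownames(df) <- NULL
    }
    df
  })
  names(gene_lists) <- CATEGORY_LEVELS
  list(counts = counts, gene_lists = gene_lists)
}
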