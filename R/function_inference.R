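# Guilt-by-association functional inference: top DE lncRNAs per
# category, Pearson coexpression with coding genes, Fisher exact
# gene-set enrichment.

#' Top differentially expressed genes of a category
#'
#' Ranks a category's genes by absolute log2FC in the designated
#' vs-reference contrast, breaking ties by smaller FDR and then by gene
#' id, and returns the top `k`. A category smaller than `k` returns all
#' of its genes; an empty category returns an empty vector with a
#' warning.
#'
#' @param category_genes character vector of the category's gene ids.
#' @param de_table data.frame (as from [contrast_table()]) holding
#'   `gene_id`, `log2fc`, `fdr` for the designated contrast.
#' @param k number of genes to return (default 5).
#' @return character vector of at most `k` gene ids, ranked.
#' @export
top_de <- function(category_genes, de_table, k = 5) {
  if (!length(category_genes)) {
    warning("empty category; returning no genes")
    return(character(0))
  }
  idx <- match(category_genes, de_table$gene_id)
  if (anyNA(idx))
    stop("gene(s) missing from the DE table: ",
         paste(category_genes[is.na(idx)], collapse = ", "))
  ord <- order(-abs(de_table$log2fc[idx]), de_table$fdr[idx],
               category_genes)
  category_genes[ord][seq_len(min(k, length(category_genes)))]
}

#' Pearson correlation with a two-sided p-value
#'
#' `r` is the sample Pearson correlation; the p-value is two-sided from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Perfect correlation (`|r| = 1`) returns `p = 0`.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, each with
#'   nonzero variance.
#' @return list with elements `r` and `p`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the vectors")
  r <- stats::cor(x, y)
  list(r = r, p = .r_to_p(r, n))
}

# Vectorised two-sided p for Pearson r at sample size n.
.r_to_p <- function(r, n) {
  p <- numeric(length(r))
  exact <- abs(r) >= 1
  p[exact] <- 0
  if (any(!exact)) {
    tt <- r[!exact] * sqrt((n - 2) / (1 - r[!exact]^2))
    p[!exact] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  p
}

#' Coding genes coexpressed with a lncRNA
#'
#' Computes the Pearson correlation between the query lncRNA and every
#' candidate coding gene across all samples of the designated dataset,
#' and retains partners passing both gates: `|r| >= r_min` and
#' `p < p_max` (both positive and negative correlations qualify).
#' Candidates with zero variance are skipped with a message. The query
#' never appears among its own partners.
#'
#' @param lncrna gene id of the query lncRNA.
#' @param nd a [normalized_dataset()] containing the query and the
#'   candidates.
#' @param coding_ids character vector of candidate coding gene ids
#'   (intersected with the dataset's genes).
#' @param r_min absolute-correlation gate (default 0.7).
#' @param p_max p-value gate (default 0.05).
#' @return data.frame with columns `lncrna_id`, `gene_id`, `r`, `p`,
#'   ordered by decreasing `|r|`.
#' @export
coexpressed_genes <- function(lncrna, nd, coding_ids, r_min = 0.7,
                              p_max = 0.05) {
  E <- nd$log2_expr
  if (!lncrna %in% rownames(E)) stop("lncRNA not in dataset: ", lncrna)
  if (!length(coding_ids)) stop("no candidate coding genes supplied")
  coding_ids <- setdiff(intersect(coding_ids, rownames(E)), lncrna)
  x <- E[lncrna, ]
  n <- length(x)
  if (stats::sd(x) == 0) stop("query lncRNA has zero variance")
  cand <- E[coding_ids, , drop = FALSE]
  v <- apply(cand, 1, stats::sd)
  if (any(v == 0)) {
    message("skipping ", sum(v == 0), " zero-variance candidate(s)")
    cand <- cand[v > 0, , drop = FALSE]
  }
  r <- as.vector(stats::cor(x, t(cand)))
  p <- .r_to_p(r, n)
  keep <- abs(r) >= r_min & p < p_max
  out <- data.frame(
    lncrna_id = rep(lncrna, sum(keep)),
    gene_id = rownames(cand)[keep],
    r = r[keep],
    p = p[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(-abs(out$r), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fisher exact over-representation test against a gene-set collection
#'
#' For each term, members are intersected with the universe and the
#' one-sided (over-representation) Fisher exact p-value is the
#' hypergeometric upper tail `P(X >= overlap)`. Adjusted p-values are BH
#' within the collection; terms with `p_adj <= alpha` are flagged
#' significant. A two-sided test is available via `alternative`.
#'
#' @param gene_list character vector of query genes (must lie within the
#'   universe).
#' @param collection a `gene_set_collection` from [read_gmt()] or
#'   [simulate_gmt()].
#' @param universe character vector: the background gene universe.
#' @param alpha significance threshold on adjusted p (default 0.05).
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"`.
#' @return data.frame with columns `term_id`, `term_name`,
#'   `overlap_count`, `list_size`, `term_size`, `universe_size`, `p`,
#'   `p_adj`, `significant`.
#' @export
fisher_enrichment <- function(gene_list, collection, universe,
                              alpha = 0.05,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  gene_list <- unique(gene_list)
  if (!length(gene_list)) stop("empty gene list")
  bad <- setdiff(gene_list, universe)
  if (length(bad))
    stop("gene list not contained in universe: ", paste(bad, collapse = ", "))
  N <- length(universe)
  k <- length(gene_list)
  rows <- lapply(names(collection$sets), function(id) {
    members <- intersect(collection$sets[[id]], universe)
    m <- length(members)
    ov <- length(intersect(members, gene_list))
    p <- if (m == 0) {
      1
    } else if (alternative == "greater") {
      stats::phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
    } else {
      stats::fisher.test(
        matrix(c(ov, m - ov, k - ov, N - m - k + ov), 2, 2),
        alternative = "two.sided"
      )$p.value
    }
    data.frame(
      term_id = id,
      term_name = unname(collection$term_names[id]),
      overlap_count = ov, list_size = k, term_size = m, universe_size = N,
      p = p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj <= alpha
  out[order(out$p, out$term_id), , drop = FALSE]
}
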