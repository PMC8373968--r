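# Platform-specific preprocessing: low-count filtering, TMM scaling,
# log-CPM, mean-variance precision weights (counts); quantile
# normalization (arrays).

#' Filter genes with low counts
#'
#' Keeps gene g iff the number of samples with count >= `min_count` is at
#' least the size of the smallest sample group — the standard reading of
#' "fewer than k counts in a number of samples exceeding the smallest
#' group" style filters.
#'
#' @param ds an [expression_dataset()] with platform `"rnaseq"`.
#' @param min_count positive integer count threshold (2 is typical for a
#'   deeply sequenced cohort, 1 for a shallower one).
#' @return the filtered [expression_dataset()] (provenance recorded in
#'   the `"filter"` attribute).
#' @export
filter_low_counts <- function(ds, min_count = 2) {
  stopifnot(inherits(ds, "expression_dataset"), ds$platform == "rnaseq",
            min_count >= 1)
  tab <- table(ds$samples$group)
  if (length(tab) < 2) stop("need >=2 sample groups to define the filter")
  min_group <- min(tab)
  keep <- rowSums(ds$values >= min_count) >= min_group
  if (!any(keep)) stop("all genes filtered: no gene has >=", min_count,
                       " counts in >=", min_group, " samples")
  out <- ds
  out$values <- ds$values[keep, , drop = FALSE]
  attr(out, "filter") <- list(min_count = min_count, min_group = min_group,
                              n_removed = sum(!keep))
  out
}

#' Trimmed mean of M-values scaling factors
#'
#' Composition-robust per-sample scaling factors for count libraries
#' (Robinson & Oshlack 2010). The reference sample is the one whose
#' 75th-percentile count fraction is closest to the mean of those
#' fractions. For every sample, per-gene M (log2 ratio of library-size
#' normalised counts vs the reference) and A (average log abundance) are
#' formed on genes with positive counts in both; the M tails are trimmed
#' by `logratio_trim` on each side and the A tails by `sum_trim`; the
#' factor is 2 to the precision-weighted mean of the remaining M, with
#' weights from the asymptotic binomial variance. Factors are rescaled so
#' that their geometric mean is 1.
#'
#' @param counts integer gene-by-sample matrix.
#' @param logratio_trim two-sided trim fraction on M (default 0.3).
#' @param sum_trim two-sided trim fraction on A (default 0.05).
#' @param do_weighting use inverse asymptotic-variance weights (default
#'   TRUE).
#' @param a_cutoff drop genes with A below this cutoff.
#' @return named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05,
                        do_weighting = TRUE, a_cutoff = -1e10) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need >=2 samples for TMM")
  lib <- colSums(counts)
  zero <- which(lib == 0)
  if (length(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero] %||% zero, collapse = ", "))
  f75 <- vapply(seq_len(ncol(counts)),
                function(j) stats::quantile(counts[, j], 0.75) / lib[j],
                numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
              logratio_trim, sum_trim, do_weighting, a_cutoff)
  }, numeric(1))
  f <- f / geo_mean(f)
  names(f) <- colnames(counts)
  f
}

# One sample's TMM factor against the reference column.
.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim,
                      do_weighting, a_cutoff) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE) & (absE > a_cutoff)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR)) stop("no gene with positive counts in both samples")
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1;      hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
          (rank(absE) >= loS & rank(absE) <= hiS)
  fbar <- if (do_weighting) {
    sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  } else {
    mean(logR[keep], na.rm = TRUE)
  }
  if (is.na(fbar)) fbar <- 0
  2^fbar
}

#' log2 counts per million with a pseudo-count
#'
#' `log2((count + prior) / (lib_size * tmm_factor + 2 * prior) * 1e6)`,
#' with `lib_size` the column sum of counts — the defining transform of
#' the precision-weights method.
#'
#' @param counts integer gene-by-sample matrix.
#' @param tmm_factor per-sample positive scaling factors (default all 1).
#' @param prior pseudo-count (default 0.5).
#' @return numeric gene-by-sample matrix of log2-CPM values.
#' @export
log_cpm <- function(counts, tmm_factor = rep(1, ncol(counts)), prior = 0.5) {
  counts <- as.matrix(counts)
  stopifnot(length(tmm_factor) == ncol(counts), all(tmm_factor > 0))
  eff <- colSums(counts) * tmm_factor
  t(log2(t(counts + prior) / (eff + 2 * prior) * 1e6))
}

#' A normalized dataset (log2 expression plus optional precision weights)
#'
#' @param log2_expr gene-by-sample matrix of log2 expression.
#' @param samples per-sample data.frame (`sample_id`, `group`).
#' @param platform `"rnaseq"` or `"microarray"`.
#' @param dataset_id dataset identifier.
#' @param weights optional gene-by-sample matrix of strictly positive
#'   precision weights (count platforms).
#' @param lib_size per-sample library sizes (count platforms).
#' @param tmm_factor per-sample TMM factors (count platforms).
#' @param provenance list of processing parameters.
#' @return an object of class `normalized_dataset`.
#' @export
normalized_dataset <- function(log2_expr, samples, platform, dataset_id,
                               weights = NULL, lib_size = NULL,
                               tmm_factor = NULL, provenance = list()) {
  if (!is.null(weights)) {
    stopifnot(identical(dim(weights), dim(log2_expr)))
    if (!all(is.finite(weights)) || any(weights <= 0))
      stop("precision weights must be strictly positive and finite")
  }
  structure(
    list(log2_expr = log2_expr, samples = samples, platform = platform,
         dataset_id = dataset_id, weights = weights, lib_size = lib_size,
         tmm_factor = tmm_factor, provenance = provenance),
    class = "normalized_dataset"
  )
}

#' @export
print.normalized_dataset <- function(x, ...) {
  cat(sprintf("<normalized_dataset '%s'> platform=%s, %d genes x %d samples, weights: %s\n",
              x$dataset_id, x$platform, nrow(x$log2_expr), ncol(x$log2_expr),
              if (is.null(x$weights)) "none" else "present"))
  invisible(x)
}

#' Mean-variance precision weights for count data
#'
#' Computes log2-CPM, fits per-gene group means, smooths the square root
#' of the residual standard deviation against average log count with
#' lowess (span `span`), and converts each observation's predicted
#' square-root standard deviation into an inverse-fourth-power precision
#' weight. Predictions are clamped to the lowess curve's range at the
#' extremes so extrapolation cannot blow up a weight.
#'
#' @param ds an [expression_dataset()] with platform `"rnaseq"`, or a raw
#'   count matrix (then `groups` and ids are required).
#' @param tmm_factor per-sample TMM factors (computed via
#'   [tmm_factors()] when NULL).
#' @param groups per-sample group labels (taken from `ds$samples` when
#'   `ds` is an expression dataset).
#' @param span lowess span (default 0.5).
#' @param prior pseudo-count for [log_cpm()].
#' @return a [normalized_dataset()] with `log2_expr` and `weights`.
#' @export
voom_weights <- function(ds, tmm_factor = NULL, groups = NULL, span = 0.5,
                         prior = 0.5) {
  if (inherits(ds, "expression_dataset")) {
    counts <- ds$values
    groups <- groups %||% ds$samples$group
    samples <- ds$samples
    dataset_id <- ds$dataset_id
  } else {
    counts <- as.matrix(ds)
    if (is.null(groups)) stop("groups required when ds is a plain matrix")
    samples <- data.frame(sample_id = colnames(counts) %||% paste0("s", seq_len(ncol(counts))),
                          group = as.character(groups), stringsAsFactors = FALSE)
    dataset_id <- "matrix"
  }
  groups <- factor(groups)
  n <- ncol(counts); k <- nlevels(groups)
  if (n - k < 2) stop("fewer than 2 residual degrees of freedom overall")
  if (is.null(tmm_factor)) tmm_factor <- tmm_factors(counts)
  lib <- colSums(counts)
  eff <- lib * tmm_factor
  y <- t(log2(t(counts + prior) / (eff + 2 * prior) * 1e6))

  fit <- .group_means_fit(y, groups, weights = NULL)
  # mean log2 count per gene: shift log-CPM back to the count scale
  sx <- rowMeans(y) + mean(log2(eff + 2 * prior)) - log2(1e6)
  sy <- sqrt(sqrt(fit$s2))
  keep <- is.finite(sx) & is.finite(sy)
  l <- stats::lowess(sx[keep], sy[keep], f = span)
  predfun <- stats::approxfun(l, rule = 2, ties = mean)
  fitted_logcpm <- fit$coef[, as.character(groups), drop = FALSE]
  fitted_logcount <- t(t(fitted_logcpm) + log2(eff + 2 * prior)) - log2(1e6)
  w <- matrix(predfun(fitted_logcount), nrow(y), ncol(y),
              dimnames = dimnames(y))^-4
  normalized_dataset(
    y, samples, "rnaseq", dataset_id, weights = w, lib_size = lib,
    tmm_factor = tmm_factor,
    provenance = list(span = span, prior = prior)
  )
}

#' Quantile-normalize a log-intensity matrix
#'
#' Each column's sorted values are replaced by the across-column mean of
#' sorted values; ties within a column receive the mean of the reference
#' values at their tied ranks. Afterwards (absent ties) all column value
#' multisets are identical.
#'
#' @param log_matrix numeric gene-by-sample matrix, no missing values.
#' @return the normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(log_matrix) {
  m <- as.matrix(log_matrix)
  if (ncol(m) < 2) stop("need >=2 samples to quantile-normalize")
  if (anyNA(m)) stop("missing values are not allowed")
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    # average ranks can be half-integers; interpolate the two flanking
    # reference values (mean of the reference values at the tied ranks)
    out[, j] <- (ref[floor(r)] + ref[ceiling(r)]) / 2
  }
  out
}
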