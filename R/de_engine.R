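# Per-gene linear modelling with empirical-Bayes variance moderation,
# two-group contrasts, BH-FDR, and the DE call rule.

# Workhorse: per-gene (weighted) group-means fit on a log2 matrix.
# Returns coef (gene x group), s2, df_resid, sw (gene x group sum of
# weights, giving the unscaled contrast variance 1/swA + 1/swB).
.group_means_fit <- function(E, groups, weights = NULL) {
  groups <- factor(groups)
  lev <- levels(groups)
  n <- ncol(E); k <- length(lev)
  if (is.null(weights)) weights <- matrix(1, nrow(E), n)
  coef <- matrix(NA_real_, nrow(E), k, dimnames = list(rownames(E), lev))
  sw <- matrix(NA_real_, nrow(E), k, dimnames = list(rownames(E), lev))
  rss <- numeric(nrow(E))
  for (g in lev) {
    j <- which(groups == g)
    Wg <- weights[, j, drop = FALSE]
    sw[, g] <- rowSums(Wg)
    coef[, g] <- rowSums(Wg * E[, j, drop = FALSE]) / sw[, g]
    rss <- rss + rowSums(Wg * (E[, j, drop = FALSE] - coef[, g])^2)
  }
  df <- n - k
  list(coef = coef, s2 = if (df > 0) rss / df else rep(NA_real_, nrow(E)),
       df_resid = rep(df, nrow(E)), sw = sw)
}

#' Fit per-gene group means
#'
#' Weighted least squares per gene under a group-means design: the
#' coefficient for each group is the (precision-weighted) mean of that
#' group's samples, and the residual variance pools across all groups
#' with `n - k` degrees of freedom. One model covers all groups; every
#' two-group contrast is then read off the same fit.
#'
#' @param x a [normalized_dataset()] (weights used when present) or a
#'   plain log2 matrix.
#' @param groups per-sample group labels (taken from `x$samples` for a
#'   normalized dataset).
#' @param weights optional gene-by-sample precision weights (overrides
#'   the dataset's).
#' @return an object of class `lnc_fit` with fields `coef`, `s2`,
#'   `df_resid`, `sw`, `groups`; `d0`/`s0_2` are filled by
#'   [ebayes_moderate()].
#' @export
fit_group_means <- function(x, groups = NULL, weights = NULL) {
  if (inherits(x, "normalized_dataset")) {
    E <- x$log2_expr
    groups <- groups %||% x$samples$group
    weights <- weights %||% x$weights
  } else {
    E <- as.matrix(x)
    if (is.null(groups)) stop("groups required when x is a plain matrix")
  }
  groups <- factor(groups)
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (length(small))
    stop("group(s) with <2 samples: ", paste(small, collapse = ", "))
  if (nrow(E) == 0) stop("empty expression matrix")
  fit <- .group_means_fit(E, groups, weights)
  structure(
    list(coef = fit$coef, s2 = fit$s2, df_resid = fit$df_resid,
         sw = fit$sw, groups = levels(groups),
         d0 = NA_real_, s0_2 = NA_real_, s2_post = NULL, moderated = FALSE),
    class = "lnc_fit"
  )
}

# Newton solver for trigamma(y) = x (monotone decreasing), with the
# asymptotic branches used for extreme x.
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_2`
#' of a scaled inverse chi-square prior by the closed-form method of
#' moments on log sample variances: with
#' `e_g = log(s2_g) - digamma(df_g/2) + log(df_g/2)`, the excess of
#' `var(e)` over the pure-sampling expectation `trigamma(df/2)` pins down
#' `d0` via the inverse trigamma, and `s0_2` follows from `mean(e)`. If
#' the observed spread does not exceed the sampling expectation, `d0` is
#' infinite and all genes share `s0_2`. The posterior (moderated)
#' variance is `(d0*s0_2 + df_g*s2_g) / (d0 + df_g)`.
#'
#' Forcing `d0 = 0` reproduces the classical per-gene t-test; forcing
#' `d0 = Inf` pools every gene to the common prior variance.
#'
#' @param fit an `lnc_fit` from [fit_group_means()].
#' @param d0 optional forced prior degrees of freedom (0, finite, or Inf).
#' @param s0_2 optional forced prior variance.
#' @return the fit with `d0`, `s0_2`, `s2_post` and `df_total` filled.
#' @export
ebayes_moderate <- function(fit, d0 = NULL, s0_2 = NULL) {
  stopifnot(inherits(fit, "lnc_fit"))
  s2 <- fit$s2
  df <- fit$df_resid
  use <- is.finite(s2) & df > 0
  if (is.null(d0) || is.null(s0_2)) {
    if (sum(use) < 10)
      stop("need >=10 genes with positive residual df for moment estimation")
    x <- pmax(s2[use], 0)
    m <- stats::median(x)
    if (m == 0) stop("residual variances are all (essentially) zero")
    x <- pmax(x, 1e-5 * m)
    dfu <- df[use]
    e <- log(x) - digamma(dfu / 2) + log(dfu / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(dfu / 2))
    if (is.null(d0)) {
      d0 <- if (evar > 0) 2 * .trigamma_inverse(evar) else Inf
    }
    if (is.null(s0_2)) {
      s0_2 <- if (is.finite(d0) && d0 > 0) {
        exp(emean + digamma(d0 / 2) - log(d0 / 2))
      } else {
        mean(x)
      }
    }
  }
  stopifnot(d0 >= 0, is.infinite(d0) || s0_2 > 0 || d0 == 0)
  s2_post <- if (is.infinite(d0)) {
    rep(s0_2, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0_2 + df * s2) / (d0 + df)
  }
  fit$d0 <- d0
  fit$s0_2 <- s0_2
  fit$s2_post <- s2_post
  fit$df_total <- df + d0
  fit$moderated <- TRUE
  fit
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `q_(i) = min_{j>=i} m * p_(j) / j` on the
#' ascending-sorted p-values, mapped back to input order and capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and within [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Apply the DE call rule to a contrast table
#'
#' A gene is differentially expressed iff `fdr <= fdr_max` and
#' `|log2fc| >= log2(min_fc)`; the fold-change gate is two-sided, so
#' strong down-regulation (negative log2FC) qualifies. Direction is the
#' sign of log2FC.
#'
#' @param det data.frame with columns `log2fc` and `fdr`.
#' @param fdr_max FDR threshold (default 0.01).
#' @param min_fc fold-change threshold on the natural scale (default 2).
#' @return `det` with logical `is_de` and character `direction` columns.
#' @export
call_de <- function(det, fdr_max = 0.01, min_fc = 2) {
  stopifnot(all(c("log2fc", "fdr") %in% names(det)))
  det$is_de <- det$fdr <= fdr_max & abs(det$log2fc) >= log2(min_fc)
  det$direction <- ifelse(det$log2fc > 0, "up", ifelse(det$log2fc < 0, "down", "none"))
  det
}

#' Differential-expression table for a two-group contrast
#'
#' log2FC is the difference of fitted group means; the moderated t uses
#' the empirical-Bayes posterior variance and the contrast's unscaled
#' standard-error multiplier `sqrt(1/swA + 1/swB)`; two-sided p from the
#' t distribution with `d0 + df_resid` degrees of freedom; FDR by BH
#' within the tested gene universe (optionally restricted via `genes`);
#' the DE flag via [call_de()].
#'
#' @param fit an `lnc_fit`; moderated automatically (default moment
#'   estimates) when [ebayes_moderate()] has not been applied.
#' @param group_a numerator group.
#' @param group_b denominator group.
#' @param genes optional character vector restricting the tested
#'   universe (FDR is computed within it).
#' @param fdr_max,min_fc DE call thresholds, see [call_de()].
#' @return data.frame with columns `gene_id`, `contrast`, `log2fc`, `t`,
#'   `p`, `fdr`, `is_de`, `direction`.
#' @export
contrast_table <- function(fit, group_a, group_b, genes = NULL,
                           fdr_max = 0.01, min_fc = 2) {
  stopifnot(inherits(fit, "lnc_fit"))
  if (identical(group_a, group_b)) stop("contrast groups must differ: ", group_a)
  for (g in c(group_a, group_b)) {
    if (!g %in% fit$groups) stop("group not in fit: ", g)
  }
  if (!fit$moderated) fit <- ebayes_moderate(fit)
  idx <- seq_len(nrow(fit$coef))
  if (!is.null(genes)) {
    idx <- match(genes, rownames(fit$coef))
    if (anyNA(idx))
      stop("gene(s) not in fit: ", paste(genes[is.na(idx)], collapse = ", "))
  }
  lfc <- fit$coef[idx, group_a] - fit$coef[idx, group_b]
  stdu <- sqrt(1 / fit$sw[idx, group_a] + 1 / fit$sw[idx, group_b])
  se <- sqrt(fit$s2_post[idx]) * stdu
  tstat <- lfc / se
  df_total <- fit$df_total[idx] %||% (fit$df_resid[idx] + fit$d0)
  if (length(df_total) == 1L) df_total <- rep(df_total, length(tstat))
  p <- 2 * stats::pt(-abs(tstat), df = pmin(df_total, .Machine$double.xmax))
  # zero posterior variance with nonzero effect: certain call
  p[se == 0 & lfc != 0] <- 0
  p[se == 0 & lfc == 0] <- 1
  det <- data.frame(
    gene_id = rownames(fit$coef)[idx],
    contrast = paste0(group_a, "_vs_", group_b),
    log2fc = unname(lfc),
    t = unname(tstat),
    p = unname(p),
    stringsAsFactors = FALSE
  )
  det$fdr <- bh_adjust(det$p)
  call_de(det, fdr_max = fdr_max, min_fc = min_fc)
}
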