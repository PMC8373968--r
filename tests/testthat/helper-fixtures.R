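# Shared fixtures and independent oracles for the test suite.

# A scaled-down study configuration for fast end-to-end tests: same group
# sizes as the default design (these drive statistical power), fewer
# genes and planted lncRNAs.
small_cfg <- function(seed = 7, ...) {
  args <- list(seed = seed, n_coding = 240, n_lncrna = 160,
               planted_per_category = 6, module_size = 10,
               gmt_n_background = 15, gmt_term_size = c(10, 30))
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Write a gene-by-sample matrix + metadata pair as TSV fixtures.
write_expr_fixture <- function(values, groups, dir = NULL,
                               dataset_id = "fix") {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  mat_path <- file.path(dir, "expr.tsv")
  meta_path <- file.path(dir, "meta.tsv")
  df <- data.frame(gene_id = rownames(values), values, check.names = FALSE)
  write.table(df, mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(sample_id = colnames(values), dataset_id = dataset_id,
               group = groups),
    meta_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  list(matrix = mat_path, metadata = meta_path)
}

# O(m^2) brute-force BH step-up: q_(i) = min_{j >= i} m * p_(j) / j on
# sorted p, mapped back to input order, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Exhaustive hypergeometric upper tail P(X >= ov) via choose() sums.
hyper_tail_brute <- function(ov, term_size, universe_size, list_size) {
  xs <- ov:min(term_size, list_size)
  sum(choose(term_size, xs) * choose(universe_size - term_size, list_size - xs)) /
    choose(universe_size, list_size)
}

# Classical equal-variance two-sample t statistic per gene (rows), as an
# oracle for the d0 = 0 limit of the moderated t.
classic_t <- function(E, groups, a, b) {
  ja <- which(groups == a); jb <- which(groups == b)
  na <- length(ja); nb <- length(jb)
  ma <- rowMeans(E[, ja, drop = FALSE]); mb <- rowMeans(E[, jb, drop = FALSE])
  sp2 <- (rowSums((E[, ja, drop = FALSE] - ma)^2) +
            rowSums((E[, jb, drop = FALSE] - mb)^2)) / (na + nb - 2)
  (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Hand-enumerated truth table of the cross-dataset validation rule over
# the 16 combinations of (DE in RNA-seq A, DE in RNA-seq B, DE on the
# array, measured on the array). Frozen by hand, not recomputed.
validation_truth_table <- data.frame(
  de_a     = c(TRUE,TRUE,TRUE,TRUE,  TRUE,TRUE,TRUE,TRUE,  FALSE,FALSE,FALSE,FALSE, FALSE,FALSE,FALSE,FALSE),
  de_b     = c(TRUE,TRUE,FALSE,FALSE,TRUE,TRUE,FALSE,FALSE,TRUE,TRUE,FALSE,FALSE,   TRUE,TRUE,FALSE,FALSE),
  de_m     = c(TRUE,TRUE,TRUE,TRUE,  FALSE,FALSE,FALSE,FALSE,TRUE,TRUE,TRUE,TRUE,   FALSE,FALSE,FALSE,FALSE),
  measured = c(TRUE,FALSE,TRUE,FALSE,TRUE,FALSE,TRUE,FALSE, TRUE,FALSE,TRUE,FALSE,  TRUE,FALSE,TRUE,FALSE),
  expected = c(TRUE,TRUE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE)
)

# Minimal hand-built linear fit for moderation tests.
fake_fit <- function(coef, s2, df, sw) {
  structure(
    list(coef = coef, s2 = s2, df_resid = df, sw = sw,
         groups = colnames(coef), d0 = NA_real_, s0_2 = NA_real_,
         s2_post = NULL, moderated = FALSE),
    class = "lnc_fit"
  )
}
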