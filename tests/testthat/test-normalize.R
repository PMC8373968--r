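make_counts_ds <- function(counts, groups, id = "d") {
  expression_dataset(
    counts,
    data.frame(sample_id = colnames(counts), group = groups),
    "rnaseq", id
  )
}

test_that("low-count filter keeps genes detected in at least the smallest group", {
  counts <- rbind(a = c(0L, 1L, 5L, 7L),   # 2 samples >= 2: kept at min_count 2
                  b = c(0L, 1L, 1L, 3L),   # 1 sample  >= 2: removed
                  c = c(0L, 0L, 1L, 1L),   # 2 samples >= 1: kept at min_count 1
                  d = c(9L, 9L, 9L, 9L))
  colnames(counts) <- paste0("s", 1:4)
  ds <- make_counts_ds(counts, c("NT", "NT", "T", "T"))  # smallest group = 2
  expect_identical(rownames(filter_low_counts(ds, 2)$values), c("a", "d"))
  expect_identical(rownames(filter_low_counts(ds, 1)$values),
                   c("a", "b", "c", "d"))

  # invariant to sample and gene order
  perm_s <- c(3, 1, 4, 2); perm_g <- c(4, 2, 1, 3)
  ds_perm <- make_counts_ds(counts[perm_g, perm_s],
                            c("NT", "NT", "T", "T")[perm_s])
  expect_setequal(rownames(filter_low_counts(ds_perm, 2)$values),
                  rownames(filter_low_counts(ds, 2)$values))

  # everything filtered is a hard error
  expect_error(filter_low_counts(ds, 100), "all genes filtered")
})

test_that("TMM factors have the published invariances and match edgeR", {
  set.seed(11)
  mu <- 2^rnorm(800, 6, 1.5)
  counts <- matrix(rnbinom(800 * 4, mu = rep(mu, 4), size = 10), 800, 4)
  colnames(counts) <- paste0("s", 1:4)

  # identical samples -> all factors 1
  dup <- cbind(s1 = counts[, 1], s2 = counts[, 1], s3 = counts[, 1])
  expect_equal(unname(tmm_factors(dup)), rep(1, 3), tolerance = 1e-10)

  # pure library-size scaling is absorbed: all M-values are zero
  sc <- cbind(s1 = counts[, 1], s2 = 3L * counts[, 1])
  expect_equal(unname(tmm_factors(sc)), c(1, 1), tolerance = 1e-10)

  # geometric mean is 1; permutation of samples permutes factors
  f <- tmm_factors(counts)
  expect_equal(prod(f)^(1 / length(f)), 1, tolerance = 1e-8)
  perm <- c(3, 1, 2, 4)
  expect_equal(unname(tmm_factors(counts[, perm])), unname(f[perm]),
               tolerance = 1e-12)

  # agrees with the reference implementation
  expect_equal(unname(f), unname(edgeR::calcNormFactors(counts, method = "TMM")),
               tolerance = 1e-10)

  # composition distortion: moving 10% of a sample's counts into one
  # dominant gene under-represents its other genes, so its factor drops
  # below 1 (checked against edgeR as the published-formula oracle)
  distorted <- counts
  extra <- round(0.1 * sum(distorted[, 2]))
  distorted[, 2] <- distorted[, 2] - round(distorted[, 2] * 0.1)
  distorted[1, 2] <- distorted[1, 2] + extra
  f2 <- tmm_factors(distorted)
  f2_ref <- edgeR::calcNormFactors(distorted, method = "TMM")
  expect_lt(f2[2] / exp(mean(log(f2))), 1)
  expect_equal(unname(f2), unname(f2_ref), tolerance = 1e-10)

  # all-zero sample is a hard error
  bad <- counts; bad[, 3] <- 0L
  expect_error(tmm_factors(bad), "all-zero")
})

test_that("log-CPM matches its defining arithmetic", {
  # library of 999,999 with a zero-count gene: log2(0.5/1e6 * 1e6) = -1
  counts <- matrix(c(0, 999999), 2, 1, dimnames = list(c("a", "b"), "s1"))
  lc <- log_cpm(counts, tmm_factor = 1)
  expect_equal(lc["a", 1], -1)

  # one-gene library: count = lib_size gives ~ log2(1e6)
  one <- matrix(50000, 1, 1, dimnames = list("a", "s1"))
  expect_equal(log_cpm(one, tmm_factor = 1)[1, 1], log2(1e6), tolerance = 1e-3)

  # scale invariance in the large-count limit: doubling counts and
  # libraries changes values only through the vanishing prior
  set.seed(3)
  counts <- matrix(rpois(400, 5000), 100, 4)
  d <- abs(log_cpm(2 * counts, tmm_factor = rep(1, 4)) -
             log_cpm(counts, tmm_factor = rep(1, 4)))
  expect_lt(max(d), 1e-3)
})

test_that("precision weights track the mean-variance trend", {
  set.seed(21)
  groups <- rep(c("NT", "T"), each = 6)

  # homoscedastic Gaussian data: weights approximately constant
  E <- matrix(rnorm(600 * 12, 8, 0.4), 600, 12)
  counts <- matrix(as.integer(pmax(0, round(2^E))), 600, 12,
                   dimnames = list(paste0("g", 1:600), paste0("s", 1:12)))
  # build counts whose log is roughly homoscedastic at high abundance
  nd <- voom_weights(counts, tmm_factor = rep(1, 12), groups = groups)
  expect_true(all(nd$weights > 0))
  expect_lt(sd(nd$weights) / mean(nd$weights), 0.2)

  # NB counts: predicted sqrt-sd falls with abundance over the bulk
  mu <- 2^runif(800, 3, 10)
  counts2 <- matrix(rnbinom(800 * 12, mu = rep(mu, 12), size = 10), 800, 12,
                    dimnames = list(paste0("g", 1:800), paste0("s", 1:12)))
  counts2 <- counts2[rowSums(counts2 >= 1) >= 6, ]
  nd2 <- voom_weights(counts2, groups = groups)
  fit <- lncLandscape:::.group_means_fit(nd2$log2_expr, groups)
  sx <- rowMeans(nd2$log2_expr) +
    mean(log2(colSums(counts2) * nd2$tmm_factor + 1)) - log2(1e6)
  l <- lowess(sx, sqrt(sqrt(fit$s2)), f = 0.5)
  lo <- mean(l$y[l$x <= quantile(l$x, 0.25)])
  hi <- mean(l$y[l$x >= quantile(l$x, 0.75)])
  expect_gt(lo, hi)

  # identical count vectors get identical weights
  counts3 <- counts2
  counts3[2, ] <- counts3[1, ]
  nd3 <- voom_weights(counts3, groups = groups)
  expect_identical(nd3$weights[1, ], nd3$weights[2, ])

  # matches the reference implementation
  f <- tmm_factors(counts2)
  v <- limma::voom(counts2, model.matrix(~ 0 + factor(groups)),
                   lib.size = colSums(counts2) * f)
  expect_equal(nd2$log2_expr, v$E, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(nd2$weights, v$weights, ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("quantile normalization equalises column distributions with the tie rule", {
  # two sorted columns -> both become the row means of sorted values
  m <- cbind(s1 = c(1, 2), s2 = c(3, 4))
  expect_equal(unname(quantile_normalize(m)), cbind(c(2, 3), c(2, 3)))

  # identical columns are a fixed point
  m2 <- cbind(a = c(5, 1, 3), b = c(5, 1, 3))
  expect_equal(quantile_normalize(m2), m2)

  # tie rule: tied pair receives the mean of the two smallest reference values
  m3 <- cbind(a = c(1, 1, 2), b = c(0, 4, 8))
  out <- quantile_normalize(m3)
  expect_equal(unname(out[, "a"]), c(1.5, 1.5, 5))
  expect_equal(unname(out[, "b"]), c(0.5, 2.5, 5))

  # without ties all columns share the same sorted values, exactly
  set.seed(5)
  m4 <- matrix(rnorm(200), 50, 4)
  out4 <- quantile_normalize(m4)
  ref <- sort(out4[, 1])
  for (j in 2:4) expect_identical(sort(out4[, j]), ref)
})
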