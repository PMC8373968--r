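test_that("the generator is fully deterministic given config and seed", {
  cfg <- small_cfg(seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
  # a different seed changes the data
  s3 <- simulate_study(small_cfg(seed = 100))
  expect_false(identical(s1$rnaseq$rnaseqA$values, s3$rnaseq$rnaseqA$values))
})

test_that("planted truth carries the archetypal effect patterns", {
  cfg <- small_cfg(seed = 1, planted_per_category = 1, module_size = 2)
  truth <- generate_truth(cfg)
  pattern_cols <- paste0("lfc_", c("FA", "FTC", "fvPTC", "clPTC", "ATC"))
  expected <- list(
    common_FA_WDTC   = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    common_WDTC      = c(FALSE, TRUE, TRUE, TRUE, FALSE),
    common_papillary = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    specific_FTC     = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    specific_fvPTC   = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    specific_clPTC   = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    specific_ATC     = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  for (cc in names(expected)) {
    rows <- truth[truth$true_category == cc, pattern_cols]
    expect_identical(unname(unlist(rows) != 0), expected[[cc]],
                     info = cc)
    # one sign per gene across its affected subtypes
    nz <- unlist(rows)[unlist(rows) != 0]
    expect_true(all(nz > 0) || all(nz < 0))
    expect_true(all(abs(nz) >= cfg$effect_range[1] &
                      abs(nz) <= cfg$effect_range[2]))
  }
  # over-planting is a hard error
  expect_error(sim_config(n_lncrna = 10, planted_per_category = 2),
               "exceed")
})

test_that("count simulation respects the negative-binomial mean structure", {
  # near-zero dispersion and high baseline: empirical log2FC within 0.2
  cfg <- small_cfg(seed = 2, nb_dispersion = 1e-6, baseline_log2_mean = 10,
                   baseline_log2_sd = 0.5)
  truth <- generate_truth(cfg)
  ds <- simulate_rnaseq(truth, cfg, "rnaseqA")
  lc <- log_cpm(ds$values, tmm_factors(ds$values))
  planted <- truth$gene_id[truth$true_category == "specific_clPTC" &
                             is.na(truth$module_id)]
  g <- ds$samples$group
  emp <- rowMeans(lc[planted, g == "clPTC", drop = FALSE]) -
    rowMeans(lc[planted, g == "NT", drop = FALSE])
  expect_lt(max(abs(emp - truth[planted, "lfc_clPTC"])), 0.2)

  # null genes: groups equal within sampling error
  nulls <- head(truth$gene_id[truth$true_category == "none" &
                                truth$role == "lncrna" &
                                is.na(truth$module_id)], 50)
  empn <- rowMeans(lc[nulls, g == "clPTC", drop = FALSE]) -
    rowMeans(lc[nulls, g == "NT", drop = FALSE])
  expect_lt(max(abs(empn)), 0.2)
})

test_that("library-size scaling doubles expected column sums", {
  cfg1 <- small_cfg(seed = 3, n_coding = 1200, n_lncrna = 800)
  cfg2 <- small_cfg(seed = 3, n_coding = 1200, n_lncrna = 800, lib_scale = 2)
  t1 <- generate_truth(cfg1)
  d1 <- simulate_rnaseq(t1, cfg1, "rnaseqB")
  d2 <- simulate_rnaseq(generate_truth(cfg2), cfg2, "rnaseqB")
  ratio <- mean(colSums(d2$values)) / mean(colSums(d1$values))
  expect_gt(ratio, 1.9); expect_lt(ratio, 2.1)
})

test_that("empirical NB dispersion tracks the configured value", {
  cfg <- sim_config(seed = 4, n_coding = 1200, n_lncrna = 800,
                    planted_per_category = 0,
                    datasets = list(rnaseqA = list(platform = "rnaseq",
                                                   groups = c(NT = 120))),
                    nb_dispersion = 0.1)
  truth <- generate_truth(cfg)
  ds <- simulate_rnaseq(truth, cfg, "rnaseqA")
  # undo the per-sample size factors before moment estimation
  sf <- colSums(ds$values) / mean(colSums(ds$values))
  y <- t(t(ds$values) / sf)
  mu <- rowMeans(y)
  v <- apply(y, 1, var)
  keep <- mu > 20
  disp_hat <- median((v[keep] - mu[keep]) / mu[keep]^2)
  expect_gt(disp_hat, 0.08); expect_lt(disp_hat, 0.12)
})

test_that("array simulation collapses to baseline + effect in the noiseless limit", {
  cfg <- small_cfg(seed = 5, array_sigma = 1e-12)
  truth <- generate_truth(cfg)
  a <- simulate_microarray(truth, cfg, "array")
  collapsed <- collapse_probes(a$probes, a$probe_map)
  g <- a$samples$group
  tm <- truth[rownames(collapsed), ]
  expected <- tm$baseline_array_log2 +
    lncLandscape:::.effect_matrix(tm, g)
  expect_equal(unname(collapsed), unname(expected), tolerance = 1e-8)
})

test_that("probe coverage honours the missing fraction and planted roles", {
  cfg <- small_cfg(seed = 6, probe_missing_frac = 0)
  truth <- generate_truth(cfg)
  a <- simulate_microarray(truth, cfg, "array")
  expect_setequal(unique(a$probe_map$gene_id), truth$gene_id)

  cfg2 <- small_cfg(seed = 6, probe_missing_frac = 0.15)
  truth2 <- generate_truth(cfg2)
  a2 <- simulate_microarray(truth2, cfg2, "array")
  measured <- unique(a2$probe_map$gene_id)
  expect_equal(length(setdiff(truth2$gene_id, measured)),
               round(0.15 * nrow(truth2)))
  # ATC-planted genes are always probe-covered (their effects exist only
  # on the array platform)
  atc <- truth2$gene_id[truth2$true_category == "specific_ATC"]
  expect_true(all(atc %in% measured))
  # the truth table agrees with the emitted map
  expect_setequal(truth2$gene_id[truth2$measured_on_array], measured)
})

test_that("a probe-missing planted PTC gene exercises the validation branch", {
  # at a high missing fraction some clPTC/fvPTC-planted genes lose their
  # probes; these are the genes the missing-probe validation branch is for
  cfg <- small_cfg(seed = 8, probe_missing_frac = 0.3,
                   planted_per_category = 10)
  truth <- generate_truth(cfg)
  cand <- truth[!truth$measured_on_array &
                  truth$true_category %in% c("specific_clPTC", "common_papillary"), ]
  expect_gt(nrow(cand), 0)
  a <- simulate_microarray(truth, cfg, "array")
  expect_false(any(cand$gene_id %in% a$probe_map$gene_id))
})

test_that("planted modules hit the target correlation and spare bystanders", {
  # one large reference group isolates the latent-factor correlation
  # from group-mean structure: pairwise r should concentrate near 0.8
  cfg <- sim_config(
    seed = 9, n_coding = 300, n_lncrna = 100,
    planted_per_category = 2, module_size = 15, module_loading = 0.8,
    datasets = list(
      rnaseqA = list(platform = "rnaseq",
                     groups = c(NT = 60, FA = 2, FTC = 2, fvPTC = 2, clPTC = 2)),
      rnaseqB = list(platform = "rnaseq",
                     groups = c(NT = 4, fvPTC = 2, clPTC = 2)),
      array = list(platform = "microarray",
                   groups = c(NT = 4, fvPTC = 2, clPTC = 2, ATC = 2))
    )
  )
  study <- simulate_study(cfg)
  ds <- study$rnaseq$rnaseqA
  nt <- ds$samples$group == "NT"
  lc <- log_cpm(ds$values, tmm_factors(ds$values))[, nt]
  mods <- attr(study$truth, "modules")
  rnaseq_mods <- Filter(function(m) m$dataset_id == "rnaseqA", mods)
  rs <- unlist(lapply(rnaseq_mods, function(m) {
    as.vector(cor(lc[m$lncrna, ], t(lc[m$partners, ])))
  }))
  expect_gte(mean(rs >= 0.65 & rs <= 0.9), 0.9)

  # non-module genes stay uncorrelated with the anchors
  set.seed(1)
  bystanders <- sample(study$truth$gene_id[is.na(study$truth$module_id) &
                                             study$truth$role == "coding"], 150)
  r0 <- unlist(lapply(rnaseq_mods, function(m) {
    as.vector(cor(lc[m$lncrna, ], t(lc[bystanders, ])))
  }))
  expect_lte(mean(abs(r0) >= 0.7), 0.02)
})

test_that("planted gene-set terms overlap their module as configured", {
  cfg <- small_cfg(seed = 10)
  study <- simulate_study(cfg)
  mods <- attr(study$truth, "modules")
  for (m in mods) {
    members <- study$gmt$sets[[m$term_id]]
    expect_identical(length(intersect(members, m$partners)),
                     as.integer(ceiling(cfg$gmt_planted_overlap *
                                          length(m$partners))))
  }
  expect_length(grep("^TERMBG", names(study$gmt$sets)), cfg$gmt_n_background)
})
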