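# Synthetic multi-dataset generator with planted category structure,
# coexpression modules and enriched gene sets, plus the ground-truth
# table every downstream stage is scored against.

# Subtypes (beyond the NT reference) affected by each planted category.
.category_subtypes <- list(
  common_FA_WDTC   = c("FA", "FTC", "fvPTC", "clPTC"),
  common_WDTC      = c("FTC", "fvPTC", "clPTC"),
  common_papillary = c("fvPTC", "clPTC"),
  specific_FTC     = "FTC",
  specific_fvPTC   = "fvPTC",
  specific_clPTC   = "clPTC",
  specific_ATC     = "ATC"
)

# Defining subtype used to pick each category's module lncRNA and to
# order report gene lists.
.category_defining <- c(
  common_FA_WDTC = "clPTC", common_WDTC = "clPTC",
  common_papillary = "clPTC", specific_FTC = "FTC",
  specific_fvPTC = "fvPTC", specific_clPTC = "clPTC", specific_ATC = "ATC"
)

#' Simulation configuration
#'
#' Defaults emulate a three-dataset thyroid-neoplasm study at desk
#' scale: a primary RNA-seq cohort covering all differentiated subtypes,
#' a second RNA-seq cohort covering the two PTC variants, and a
#' microarray cohort that is the only source of ATC samples; 2000 genes
#' (1200 coding / 800 lncRNA) with 20 lncRNAs planted per category at
#' |log2FC| drawn from [1.5, 3].
#'
#' @param seed master integer seed; every stage draws from a named
#'   substream derived from it.
#' @param n_coding,n_lncrna numbers of coding and lncRNA genes.
#' @param datasets named list; each element has `platform`
#'   (`"rnaseq"`/`"microarray"`) and `groups` (named vector of per-group
#'   sample sizes; must include NT).
#' @param planted_per_category planted lncRNAs per category.
#' @param effect_range range of |log2FC| for planted effects.
#' @param nb_dispersion negative-binomial dispersion (scalar, or length-2
#'   range for per-gene values).
#' @param array_sigma per-observation noise sd of log2 array intensities.
#' @param baseline_log2_mean,baseline_log2_sd normal parameters of
#'   per-gene baseline log2 expression.
#' @param lib_scale multiplies all expected RNA-seq counts (library
#'   depth knob).
#' @param lib_sigma sd of per-sample log library-size factors.
#' @param probe_missing_frac fraction of genes carrying no array probe.
#' @param probes_per_gene candidate probe counts per measured gene.
#' @param module_size coding partners per coexpression module.
#' @param module_loading target pairwise population correlation within a
#'   module.
#' @param gmt_planted_overlap fraction of a module's partners included in
#'   its planted term.
#' @param gmt_n_background number of background (non-planted) terms.
#' @param gmt_term_size range of term sizes.
#' @return a validated `sim_config` list (with `primary_rnaseq`,
#'   `second_rnaseq` and `array_id` resolved).
#' @export
sim_config <- function(seed = 1,
                       n_coding = 1200, n_lncrna = 800,
                       datasets = list(
                         rnaseqA = list(platform = "rnaseq",
                                        groups = c(NT = 20, FA = 10, FTC = 10,
                                                   fvPTC = 12, clPTC = 15)),
                         rnaseqB = list(platform = "rnaseq",
                                        groups = c(NT = 15, fvPTC = 12, clPTC = 15)),
                         array = list(platform = "microarray",
                                      groups = c(NT = 15, fvPTC = 10,
                                                 clPTC = 10, ATC = 10))
                       ),
                       planted_per_category = 20,
                       effect_range = c(1.5, 3),
                       nb_dispersion = 0.1,
                       array_sigma = 0.5,
                       baseline_log2_mean = 7, baseline_log2_sd = 1.5,
                       lib_scale = 1, lib_sigma = 0.15,
                       probe_missing_frac = 0.1,
                       probes_per_gene = 1:3,
                       module_size = 20, module_loading = 0.8,
                       gmt_planted_overlap = 0.6,
                       gmt_n_background = 40,
                       gmt_term_size = c(20, 80)) {
  stopifnot(n_coding > 0, n_lncrna > 0,
            planted_per_category >= 0,
            length(effect_range) == 2, effect_range[1] > 0,
            probe_missing_frac >= 0, probe_missing_frac < 1,
            module_loading > 0, module_loading < 1)
  if (7 * planted_per_category > n_lncrna)
    stop("planted counts (7 x ", planted_per_category,
         ") exceed the number of lncRNA genes (", n_lncrna, ")")
  for (id in names(datasets)) {
    d <- datasets[[id]]
    if (!"NT" %in% names(d$groups))
      stop("dataset ", id, " has no NT (reference) group")
    if (any(d$groups < 2)) stop("dataset ", id, " has a group with <2 samples")
  }
  platforms <- vapply(datasets, function(d) d$platform, character(1))
  covers <- function(id, gg) all(gg %in% names(datasets[[id]]$groups))
  rnaseq_ids <- names(datasets)[platforms == "rnaseq"]
  primary <- rnaseq_ids[vapply(rnaseq_ids, covers, logical(1),
                               gg = c("FA", "FTC", "fvPTC", "clPTC"))]
  if (planted_per_category > 0 && !length(primary))
    stop("no RNA-seq dataset covers all four differentiated subtypes")
  primary <- primary[1]
  second <- setdiff(rnaseq_ids, primary)[1]
  array_id <- names(datasets)[platforms == "microarray"][1]
  if (planted_per_category > 0) {
    if (is.na(second) || !covers(second, c("fvPTC", "clPTC")))
      stop("validation needs a second RNA-seq dataset covering fvPTC and clPTC")
    if (is.na(array_id) || !covers(array_id, c("fvPTC", "clPTC", "ATC")))
      stop("ATC planting needs a microarray dataset with fvPTC, clPTC and ATC")
  }
  cfg <- list(
    seed = as.integer(seed), n_coding = n_coding, n_lncrna = n_lncrna,
    datasets = datasets, planted_per_category = planted_per_category,
    effect_range = effect_range, nb_dispersion = nb_dispersion,
    array_sigma = array_sigma, baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd, lib_scale = lib_scale,
    lib_sigma = lib_sigma, probe_missing_frac = probe_missing_frac,
    probes_per_gene = probes_per_gene, module_size = module_size,
    module_loading = module_loading,
    gmt_planted_overlap = gmt_planted_overlap,
    gmt_n_background = gmt_n_background, gmt_term_size = gmt_term_size,
    primary_rnaseq = primary, second_rnaseq = second, array_id = array_id
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Generate the ground-truth table
#'
#' Assigns planted lncRNAs to the seven categories with per-subtype
#' log2 effects whose pattern makes the intended classification
#' recoverable in the infinite-sample limit (e.g. a clPTC-specific gene
#' has a nonzero effect in clPTC only, with one sign shared across a
#' gene's affected subtypes). One coexpression module per category is
#' anchored on the category's strongest planted lncRNA, with
#' `module_size` coding partners inheriting the lncRNA's effect profile.
#' Genes without a planted role on the array platform may lose their
#' probes (fraction `probe_missing_frac`), which exercises the
#' missing-probe branch of the validation rule; genes whose planted
#' structure exists only on the array (ATC effects, the array-designated
#' module) are always probe-covered.
#'
#' @param cfg a [sim_config()].
#' @return data.frame (class `sim_truth`) with one row per gene:
#'   `gene_id`, `role`, `true_category`, `lfc_<subtype>` columns,
#'   `module_id`, `module_role`, `planted_term`, `measured_on_array`,
#'   `baseline_rnaseq_log2`, `baseline_array_log2`; the per-module
#'   structure is in the `"modules"` attribute.
#' @export
generate_truth <- function(cfg) {
  with_seed(substream_seed(cfg$seed, "truth"), {
    coding <- sprintf("ENSGSIMC%05d", seq_len(cfg$n_coding))
    lnc <- sprintf("ENSGSIML%05d", seq_len(cfg$n_lncrna))
    genes <- c(coding, lnc)
    subtypes <- c("FA", "FTC", "fvPTC", "clPTC", "ATC")
    lfc <- matrix(0, length(genes), length(subtypes),
                  dimnames = list(genes, subtypes))
    truth <- data.frame(
      gene_id = genes,
      role = rep(c("coding", "lncrna"), c(cfg$n_coding, cfg$n_lncrna)),
      true_category = "none",
      stringsAsFactors = FALSE
    )
    rownames(truth) <- genes
    k <- cfg$planted_per_category
    cats <- names(.category_subtypes)
    planted <- if (k > 0) sample(lnc, length(cats) * k) else character(0)
    for (ci in seq_along(cats)) {
      cc <- cats[ci]
      ids <- planted[seq((ci - 1) * k + 1, length.out = k)]
      truth$true_category[match(ids, genes)] <- cc
      for (g in ids) {
        sgn <- sample(c(-1, 1), 1)
        aff <- .category_subtypes[[cc]]
        lfc[g, aff] <- sgn * stats::runif(length(aff), cfg$effect_range[1],
                                          cfg$effect_range[2])
      }
    }
    # coexpression modules: one per planted category, anchored on the
    # category's largest-|effect| lncRNA in its defining subtype
    modules <- list()
    free_coding <- coding
    if (k > 0) {
      for (cc in cats) {
        ids <- truth$gene_id[truth$true_category == cc]
        def <- .category_defining[[cc]]
        anchor <- ids[which.max(abs(lfc[ids, def]))]
        partners <- sample(free_coding, cfg$module_size)
        free_coding <- setdiff(free_coding, partners)
        # partners inherit the anchor's effect profile (co-regulation)
        lfc[partners, ] <- matrix(lfc[anchor, ], length(partners),
                                  length(subtypes), byrow = TRUE)
        modules[[cc]] <- list(
          module_id = cc, category = cc, lncrna = anchor,
          partners = partners, term_id = paste0("TERM_", cc),
          dataset_id = if (cc == "specific_ATC") cfg$array_id else cfg$primary_rnaseq
        )
      }
    }
    truth$module_id <- NA_character_
    truth$module_role <- NA_character_
    truth$planted_term <- NA_character_
    for (m in modules) {
      truth[m$lncrna, c("module_id", "module_role", "planted_term")] <-
        c(m$module_id, "lncrna", m$term_id)
      truth[m$partners, "module_id"] <- m$module_id
      truth[m$partners, "module_role"] <- "partner"
      truth[m$partners, "planted_term"] <- m$term_id
    }
    # probe coverage: planted structure that exists only on the array
    # must stay measurable there
    array_bound <- genes[lfc[, "ATC"] != 0 &
                           rowSums(lfc[, c("FA", "FTC", "fvPTC", "clPTC")] != 0) == 0]
    for (m in modules) {
      if (identical(m$dataset_id, cfg$array_id))
        array_bound <- union(array_bound, c(m$lncrna, m$partners))
    }
    eligible <- setdiff(genes, array_bound)
    n_missing <- round(cfg$probe_missing_frac * length(genes))
    missing <- sample(eligible, min(n_missing, length(eligible)))
    truth$measured_on_array <- !(genes %in% missing)
    truth$baseline_rnaseq_log2 <- stats::rnorm(length(genes),
                                               cfg$baseline_log2_mean,
                                               cfg$baseline_log2_sd)
    truth$baseline_array_log2 <- stats::rnorm(length(genes),
                                              cfg$baseline_log2_mean,
                                              cfg$baseline_log2_sd)
    for (s in subtypes) truth[[paste0("lfc_", s)]] <- lfc[, s]
    attr(truth, "modules") <- modules
    class(truth) <- c("sim_truth", "data.frame")
    truth
  })
}

# True per-gene log2 effect for each sample's group (0 for NT).
.effect_matrix <- function(truth, groups) {
  eff <- matrix(0, nrow(truth), length(groups),
                dimnames = list(truth$gene_id, NULL))
  for (s in c("FA", "FTC", "fvPTC", "clPTC", "ATC")) {
    j <- which(groups == s)
    if (length(j)) eff[, j] <- truth[[paste0("lfc_", s)]]
  }
  eff
}

.expand_groups <- function(cfg, dataset_id) {
  gg <- cfg$datasets[[dataset_id]]$groups
  rep(names(gg), gg)
}

#' Simulate an RNA-seq count dataset from the truth table
#'
#' Counts are negative binomial with mean
#' `baseline * 2^(true log2FC of the sample's group) * size factor`,
#' with log-normal per-sample size factors and dispersion from the
#' configuration. Deterministic given the configuration seed.
#'
#' @param truth a [generate_truth()] table.
#' @param cfg the [sim_config()].
#' @param dataset_id which configured dataset to simulate (platform must
#'   be `"rnaseq"`).
#' @return an [expression_dataset()].
#' @export
simulate_rnaseq <- function(truth, cfg, dataset_id) {
  stopifnot(cfg$datasets[[dataset_id]]$platform == "rnaseq")
  with_seed(substream_seed(cfg$seed, paste0("rnaseq:", dataset_id)), {
    groups <- .expand_groups(cfg, dataset_id)
    n <- length(groups)
    sf <- cfg$lib_scale * exp(stats::rnorm(n, 0, cfg$lib_sigma))
    base <- 2^truth$baseline_rnaseq_log2
    mu <- (base * 2^.effect_matrix(truth, groups)) %*% diag(sf)
    disp <- if (length(cfg$nb_dispersion) == 2) {
      stats::runif(nrow(truth), cfg$nb_dispersion[1], cfg$nb_dispersion[2])
    } else {
      rep(cfg$nb_dispersion, nrow(truth))
    }
    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu),
                     size = rep(1 / pmax(disp, 1e-12), n)),
      nrow(truth), n
    )
    rownames(counts) <- truth$gene_id
    samples <- data.frame(
      sample_id = sprintf("%s_s%03d", dataset_id, seq_len(n)),
      group = groups, stringsAsFactors = FALSE
    )
    colnames(counts) <- samples$sample_id
    expression_dataset(counts, samples, "rnaseq", dataset_id)
  })
}

#' Simulate a microarray dataset (probe level) from the truth table
#'
#' Gene-level log2 signal is `baseline + true log2FC(group)`; each
#' measured gene gets 1-3 probes whose values add a per-probe offset
#' (sd `0.5 * array_sigma`) and per-observation noise (sd
#' `array_sigma`). Genes flagged unmeasured in the truth table are
#' absent from the probe map, exercising the missing-probe branch of the
#' validation rule. As `array_sigma` goes to 0 the collapsed values
#' equal baseline + effect exactly.
#'
#' @inheritParams simulate_rnaseq
#' @return list with `probes` (probe-by-sample matrix), `probe_map`
#'   (data.frame `probe_id`, `gene_id`), `samples`, `platform`,
#'   `dataset_id`.
#' @export
simulate_microarray <- function(truth, cfg, dataset_id) {
  stopifnot(cfg$datasets[[dataset_id]]$platform == "microarray")
  with_seed(substream_seed(cfg$seed, paste0("array:", dataset_id)), {
    groups <- .expand_groups(cfg, dataset_id)
    n <- length(groups)
    measured <- truth$gene_id[truth$measured_on_array]
    tm <- truth[truth$measured_on_array, , drop = FALSE]
    signal <- tm$baseline_array_log2 + .effect_matrix(tm, groups)
    nprobe <- sample(cfg$probes_per_gene, length(measured), replace = TRUE)
    gene_of_probe <- rep(measured, nprobe)
    probe_ids <- sprintf("PR%06d", seq_along(gene_of_probe))
    offset <- stats::rnorm(length(probe_ids), 0, 0.5 * cfg$array_sigma)
    row_of <- match(gene_of_probe, measured)
    probes <- signal[row_of, , drop = FALSE] + offset +
      matrix(stats::rnorm(length(probe_ids) * n, 0, cfg$array_sigma),
             length(probe_ids), n)
    rownames(probes) <- probe_ids
    samples <- data.frame(
      sample_id = sprintf("%s_s%03d", dataset_id, seq_len(n)),
      group = groups, stringsAsFactors = FALSE
    )
    colnames(probes) <- samples$sample_id
    list(
      probes = probes,
      probe_map = data.frame(probe_id = probe_ids, gene_id = gene_of_probe,
                             stringsAsFactors = FALSE),
      samples = samples, platform = "microarray", dataset_id = dataset_id
    )
  })
}

#' Plant coexpression-module structure into a simulated dataset
#'
#' For each module designated to this dataset, a per-sample latent
#' factor `z ~ N(0, 1)` is injected into the module's lncRNA and coding
#' partners with a per-gene loading `lambda_g = sd_g * sqrt(r/(1-r))`,
#' where `sd_g` approximates the gene's log2-scale noise sd and `r` is
#' the target pairwise correlation (`cfg$module_loading`); two module
#' genes then correlate at about `r` within a sample group. Counts are
#' scaled multiplicatively by `2^(lambda * z)` and re-rounded; array
#' probe values shift additively.
#'
#' @param x an [expression_dataset()] (RNA-seq) or the probe-level list
#'   from [simulate_microarray()].
#' @param truth a [generate_truth()] table.
#' @param cfg the [sim_config()].
#' @return `x` with module structure planted.
#' @export
plant_coexpression <- function(x, truth, cfg) {
  modules <- attr(truth, "modules")
  r <- cfg$module_loading
  c_target <- sqrt(r / (1 - r))
  dataset_id <- x$dataset_id
  for (m in modules) {
    if (!identical(m$dataset_id, dataset_id)) next
    members <- c(m$lncrna, m$partners)
    z <- with_seed(
      substream_seed(cfg$seed, paste0("module:", dataset_id, ":", m$module_id)),
      stats::rnorm(nrow(x$samples))
    )
    if (x$platform == "rnaseq") {
      absent <- setdiff(members, rownames(x$values))
      if (length(absent))
        stop("module member(s) not in dataset ", dataset_id, ": ",
             paste(absent, collapse = ", "))
      disp <- if (length(cfg$nb_dispersion) == 2) mean(cfg$nb_dispersion) else cfg$nb_dispersion
      mu_hat <- 2^truth[members, "baseline_rnaseq_log2"]
      sd_g <- sqrt(1 / mu_hat + disp) / log(2)
      lambda <- c_target * sd_g
      x$values[members, ] <- round(x$values[members, , drop = FALSE] *
                                     2^outer(lambda, z))
    } else {
      absent <- setdiff(members, x$probe_map$gene_id)
      if (length(absent))
        stop("module member(s) not on the array ", dataset_id, ": ",
             paste(absent, collapse = ", "))
      # median collapse of k probes shrinks the per-gene noise; match
      # the loading to the collapsed-scale sd (var factors for the
      # median of 1..3 iid normals)
      med_factor <- c(1, 0.5, 0.449)
      rows <- which(x$probe_map$gene_id %in% members)
      k_probes <- table(x$probe_map$gene_id[rows])
      gene_of_row <- x$probe_map$gene_id[rows]
      sd_g <- sqrt(1.25 * med_factor[pmin(as.integer(k_probes[gene_of_row]), 3)]) *
        cfg$array_sigma
      lambda <- c_target * sd_g
      x$probes[rows, ] <- x$probes[rows, , drop = FALSE] + outer(lambda, z)
    }
  }
  x
}

#' Simulate a gene-set collection with planted enriched terms
#'
#' Each module gets one planted term containing
#' `gmt_planted_overlap` of its coding partners plus random background
#' coding genes; `gmt_n_background` background terms are uniform random
#' draws from the coding universe. Deterministic given the seed.
#'
#' @inheritParams simulate_rnaseq
#' @return a `gene_set_collection`.
#' @export
simulate_gmt <- function(truth, cfg) {
  with_seed(substream_seed(cfg$seed, "gmt"), {
    coding <- truth$gene_id[truth$role == "coding"]
    modules <- attr(truth, "modules")
    sets <- list()
    term_names <- character()
    for (m in modules) {
      core <- sample(m$partners, ceiling(cfg$gmt_planted_overlap * length(m$partners)))
      size <- round(stats::runif(1, cfg$gmt_term_size[1], cfg$gmt_term_size[2]))
      fill <- sample(setdiff(coding, m$partners),
                     max(0, size - length(core)))
      sets[[m$term_id]] <- c(core, fill)
      term_names[m$term_id] <- paste0("planted module term (", m$category, ")")
    }
    for (i in seq_len(cfg$gmt_n_background)) {
      id <- sprintf("TERMBG%03d", i)
      size <- round(stats::runif(1, cfg$gmt_term_size[1], cfg$gmt_term_size[2]))
      sets[[id]] <- sample(coding, size)
      term_names[id] <- "background term"
    }
    structure(list(sets = sets, term_names = term_names),
              class = "gene_set_collection")
  })
}

#' Simulate the gene annotation table
#'
#' Coding genes are `protein_coding`; lncRNAs draw a biotype from the
#' whitelist using the mixed spelling dialects (case, separators) seen in
#' real annotation exports, which exercises label normalization.
#'
#' @inheritParams simulate_rnaseq
#' @return annotation data.frame (`gene_id`, `symbol`, `biotype`).
#' @export
simulate_annotation <- function(truth, cfg) {
  with_seed(substream_seed(cfg$seed, "annotation"), {
    dialects <- c(
      "lincRNA", "antisense", "Antisense", "sense_intronic",
      "Sense_intronic", "sense intronic", "processed_transcript",
      "Processed_transcript", "bidirectional_promoter_lncRNA",
      "Bidirectional_promoter_lncRNA", "3prime_overlapping_ncRNA",
      "3-prime overlapping ncRNA", "misc_RNA", "sense_overlapping",
      "Sense_overlapping"
    )
    is_lnc <- truth$role == "lncrna"
    biotype <- ifelse(is_lnc, sample(dialects, nrow(truth), replace = TRUE),
                      "protein_coding")
    data.frame(
      gene_id = truth$gene_id,
      symbol = ifelse(is_lnc, sub("^ENSGSIML", "LNC-", truth$gene_id),
                      sub("^ENSGSIMC", "CG-", truth$gene_id)),
      biotype = biotype, stringsAsFactors = FALSE
    )
  })
}

#' Simulate a complete multi-dataset study
#'
#' Runs [generate_truth()], simulates every configured dataset (with
#' module structure planted), the annotation table and the gene-set
#' collection.
#'
#' @param cfg a [sim_config()].
#' @return list (class `sim_study`) with `config`, `truth`,
#'   `annotation`, `rnaseq` (named list of [expression_dataset()]),
#'   `arrays` (named list of probe-level simulations), `gmt`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  truth <- generate_truth(cfg)
  rnaseq <- list()
  arrays <- list()
  for (id in names(cfg$datasets)) {
    if (cfg$datasets[[id]]$platform == "rnaseq") {
      rnaseq[[id]] <- plant_coexpression(simulate_rnaseq(truth, cfg, id), truth, cfg)
    } else {
      arrays[[id]] <- plant_coexpression(simulate_microarray(truth, cfg, id), truth, cfg)
    }
  }
  structure(
    list(config = cfg, truth = truth,
         annotation = simulate_annotation(truth, cfg),
         rnaseq = rnaseq, arrays = arrays,
         gmt = simulate_gmt(truth, cfg)),
    class = "sim_study"
  )
}

#' Write a simulated study to plain-text fixtures
#'
#' Emits, per RNA-seq dataset, `<id>_counts.tsv` and `<id>_samples.tsv`;
#' per array, `<id>_probes.tsv`, `<id>_probe_map.tsv`,
#' `<id>_samples.tsv`; plus `annotation.tsv`, `truth.tsv` and
#' `gene_sets.gmt`.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))
  for (id in names(study$rnaseq)) {
    write_expression(study$rnaseq[[id]], p(id, "_counts.tsv"),
                     p(id, "_samples.tsv"))
  }
  for (id in names(study$arrays)) {
    a <- study$arrays[[id]]
    df <- data.frame(probe_id = rownames(a$probes), a$probes,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_table(df, p(id, "_probes.tsv"))
    write_table(a$probe_map, p(id, "_probe_map.tsv"))
    write_table(cbind(a$samples, dataset_id = id), p(id, "_samples.tsv"))
  }
  write_table(study$annotation, p("annotation.tsv"))
  write_table(as.data.frame(study$truth), p("truth.tsv"))
  write_gmt(study$gmt, p("gene_sets.gmt"))
  invisible(dir)
}
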