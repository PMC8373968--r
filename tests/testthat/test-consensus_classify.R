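# Helpers to build call structures for the cascade.
make_vsnt <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- c("FA", "FTC", "fvPTC", "clPTC")
  rownames(m) <- names(rows)
  m
}

make_between <- function(genes, de_pairs = list()) {
  pairs <- list(c("FA", "FTC"), c("FA", "fvPTC"), c("FA", "clPTC"),
                c("FTC", "fvPTC"), c("FTC", "clPTC"), c("fvPTC", "clPTC"))
  rows <- do.call(rbind, lapply(genes, function(g) {
    do.call(rbind, lapply(pairs, function(pr) {
      key <- paste(pr, collapse = ":")
      data.frame(gene_id = g, contrast = paste0(pr[1], "_vs_", pr[2]),
                 is_de = key %in% (de_pairs[[g]] %||% character(0)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rows
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the validation rule matches its hand-enumerated truth table", {
  tt <- validation_truth_table
  got <- validate_gene(tt$de_a, tt$de_b, tt$de_m, tt$measured)
  expect_identical(got, tt$expected)
})

test_that("validation is monotone: removing a DE call never validates a gene", {
  tt <- validation_truth_table
  for (i in seq_len(nrow(tt))) {
    base <- validate_gene(tt$de_a[i], tt$de_b[i], tt$de_m[i], tt$measured[i])
    for (col in c("de_a", "de_b", "de_m")) {
      if (!tt[[col]][i]) next
      row <- tt[i, ]
      row[[col]] <- FALSE
      flipped <- validate_gene(row$de_a, row$de_b, row$de_m, row$measured)
      expect_false(!base && flipped)
    }
  }
})

test_that("validate_subtype reads DE flags out of contrast tables", {
  det <- function(de_genes) {
    data.frame(gene_id = c("g1", "g2", "g3"),
               is_de = c("g1", "g2", "g3") %in% de_genes)
  }
  v <- validate_subtype(
    list(rnaseqA = det(c("g1", "g2")), rnaseqB = det(c("g1", "g2")),
         array = det("g1")),
    genes = c("g1", "g2", "g3"),
    measured_array = c("g1", "g3")      # g2 has no probe
  )
  # g1: all three; g2: both RNA-seq and unmeasured; g3: nothing
  expect_identical(v$validated, c(TRUE, TRUE, FALSE))
  expect_error(validate_subtype(list(rnaseqA = det("g1")), "g1", "g1"),
               "missing DE table")
})

test_that("the category cascade assigns the archetypal patterns", {
  vsnt <- make_vsnt(
    g_all  = c(TRUE, TRUE, TRUE, TRUE),     # all four subtypes
    g_wdtc = c(FALSE, TRUE, TRUE, TRUE),    # WDTC only
    g_pap  = c(FALSE, FALSE, TRUE, TRUE),   # both PTC variants
    g_cl   = c(FALSE, FALSE, FALSE, TRUE),  # clPTC only
    g_ftc  = c(FALSE, TRUE, FALSE, FALSE),  # FTC only
    g_orph = c(TRUE, FALSE, FALSE, TRUE),   # pattern with no category
    g_none = c(FALSE, FALSE, FALSE, FALSE)
  )
  genes <- rownames(vsnt)
  validated <- matrix(TRUE, length(genes), 2,
                      dimnames = list(genes, c("clPTC", "fvPTC")))
  between <- make_between(genes, list(
    g_wdtc = c("FA:fvPTC", "FA:clPTC"),
    g_pap  = c("FA:fvPTC", "FA:clPTC", "FTC:fvPTC", "FTC:clPTC"),
    g_cl   = c("fvPTC:clPTC", "FTC:clPTC", "FA:clPTC"),
    g_ftc  = c("FTC:clPTC", "FTC:fvPTC")
  ))
  out <- classify_differentiated(vsnt, validated, between)
  expect_identical(
    out$category,
    c("common_FA_WDTC", "common_WDTC", "common_papillary",
      "specific_clPTC", "specific_FTC", "none", "none")
  )
  # traces record what was checked
  expect_match(out$criteria_trace[1], "validated_clPTC=TRUE")
  expect_match(out$criteria_trace[5], "de_FTC_vs_clPTC=TRUE")

  # permuting gene order never changes the assignment
  perm <- c(5, 2, 7, 1, 4, 6, 3)
  out_perm <- classify_differentiated(vsnt[perm, ], validated[perm, ],
                                      between)
  expect_identical(out_perm$category[match(genes, out_perm$gene_id)],
                   out$category)
})

test_that("cascade clause failures fall through to none, not to other categories", {
  # both PTC variants DE but not distinguishable from FTC: fails rule 3
  # and does not reach a specific category (pattern is not a singleton)
  vsnt <- make_vsnt(g = c(FALSE, FALSE, TRUE, TRUE))
  validated <- matrix(TRUE, 1, 2, dimnames = list("g", c("clPTC", "fvPTC")))
  between <- make_between("g", list(g = c("FA:fvPTC", "FA:clPTC", "FTC:fvPTC")))
  expect_identical(classify_differentiated(vsnt, validated, between)$category,
                   "none")

  # unvalidated singleton clPTC: none
  vsnt2 <- make_vsnt(g = c(FALSE, FALSE, FALSE, TRUE))
  validated2 <- matrix(c(FALSE, TRUE), 1, 2,
                       dimnames = list("g", c("clPTC", "fvPTC")))
  between2 <- make_between("g", list(g = c("fvPTC:clPTC", "FTC:clPTC", "FA:clPTC")))
  expect_identical(classify_differentiated(vsnt2, validated2, between2)$category,
                   "none")

  # a between-contrast needed by a triggered rule but absent: hard error
  vsnt3 <- make_vsnt(g = c(FALSE, TRUE, FALSE, FALSE))
  validated3 <- matrix(TRUE, 1, 2, dimnames = list("g", c("clPTC", "fvPTC")))
  between3 <- make_between("g")
  between3 <- between3[between3$contrast != "FTC_vs_clPTC", ]
  expect_error(
    classify_differentiated(vsnt3, validated3, between3),
    "FTC vs clPTC"
  )
})

test_that("exactly one label per gene over random call patterns", {
  set.seed(41)
  for (rep in 1:20) {
    n <- 12L
    genes <- paste0("g", seq_len(n))
    vsnt <- matrix(runif(n * 4) < 0.4, n, 4,
                   dimnames = list(genes, c("FA", "FTC", "fvPTC", "clPTC")))
    validated <- matrix(runif(n * 2) < 0.7, n, 2,
                        dimnames = list(genes, c("clPTC", "fvPTC")))
    pairs <- combn(c("FA", "FTC", "fvPTC", "clPTC"), 2, simplify = FALSE)
    between <- do.call(rbind, lapply(genes, function(g) {
      do.call(rbind, lapply(pairs, function(pr) {
        data.frame(gene_id = g, contrast = paste0(pr[1], "_vs_", pr[2]),
                   is_de = runif(1) < 0.6, stringsAsFactors = FALSE)
      }))
    }))
    out <- classify_differentiated(vsnt, validated, between)
    expect_identical(nrow(out), n)
    expect_true(all(out$category %in% c(CATEGORY_LEVELS, "none")))
  }
})

test_that("the ATC funnel is a monotone set filtration disjoint from the rest", {
  res <- classify_atc(
    atc_vs_nt = c("a", "b", "c", "d"),
    differentiated_union = c("b", "x"),
    atc_vs_clptc = c("a", "c", "d"),
    atc_vs_fvptc = c("a", "d")
  )
  expect_identical(res$stage1, c("a", "b", "c", "d"))
  expect_identical(res$stage2, c("a", "c", "d"))  # b removed: DE elsewhere
  expect_identical(res$stage3, c("a", "d"))       # c fails the fvPTC filter
  expect_true(all(res$stage3 %in% res$stage2) && all(res$stage2 %in% res$stage1))
  expect_length(intersect(res$specific_atc, c("b", "x")), 0)

  # random instances keep the monotone structure
  set.seed(42)
  for (i in 1:20) {
    u <- paste0("g", 1:30)
    res <- classify_atc(sample(u, 15), sample(u, 10),
                        sample(u, 12), sample(u, 12))
    expect_true(all(res$stage2 %in% res$stage1))
    expect_true(all(res$stage3 %in% res$stage2))
  }
})

test_that("assignment merge enforces disjointness and reports count tables", {
  diff_assign <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    category = c("specific_clPTC", "none", "none"),
    criteria_trace = ""
  )
  out <- assign_categories(diff_assign, atc_genes = "g3",
                           all_genes = paste0("g", 1:5))
  expect_identical(out$category[match(c("g1", "g3", "g4"), out$gene_id)],
                   c("specific_clPTC", "specific_ATC", "none"))
  expect_error(assign_categories(diff_assign, atc_genes = "g1"), "both")

  lfc <- data.frame(gene_id = c("g1", "g3"), subtype = c("clPTC", "ATC"),
                    log2fc = c(2.5, -4))
  rep <- intersection_report(out, lfc)
  expect_identical(rep$counts$n[rep$counts$category == "specific_clPTC"], 1L)
  expect_identical(rep$counts$n[rep$counts$category == "specific_ATC"], 1L)
  expect_identical(sum(rep$counts$n), 2L)
  expect_identical(rep$gene_lists$specific_ATC$gene_id, "g3")

  # empty assignment set: all counts zero
  none <- assign_categories(
    data.frame(gene_id = "g1", category = "none", criteria_trace = ""),
    character(0)
  )
  expect_identical(sum(intersection_report(none)$counts$n), 0L)
})

test_that("report gene lists are ordered by |log2FC| of the defining contrast", {
  assign <- data.frame(
    gene_id = c("a", "b", "c"),
    category = "specific_ATC",
    criteria_trace = ""
  )
  lfc <- data.frame(gene_id = c("a", "b", "c"), subtype = "ATC",
                    log2fc = c(1.5, -5.7, 3.2))
  lists <- intersection_report(assign, lfc)$gene_lists
  expect_identical(lists$specific_ATC$gene_id, c("b", "c", "a"))
})
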