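# Sex-linked gene classification: expressed rule, decision tree, summaries.

test_that("expressed_at_stage applies both thresholds", {
  # mean 1.8 > 1 and 3 cells >= 1 -> expressed
  tbl <- structure(list(
    mean_tpm = matrix(c(1.8, 2, 0.6), 3, 1,
                      dimnames = list(c("a", "b", "c"), "L")),
    n_ge1 = matrix(c(3, 1, 3), 3, 1, dimnames = list(c("a", "b", "c"), "L")),
    n_cells = c(L = 5)), class = "stage_expr")
  expect_true(expressed_at_stage(tbl, "a", "L"))
  expect_false(expressed_at_stage(tbl, "b", "L")) # only 1 cell >= 1
  expect_false(expressed_at_stage(tbl, "c", "L")) # mean 0.6 <= 1

  small <- tbl; small$n_cells <- c(L = 2)
  expect_error(expressed_matrix(small), class = "spermdyn_staging_error")
})

test_that("stage_expression_table summarises TPM per stage", {
  expr <- cbind(c(0, 2), c(4, 0), c(10, 0.5))
  rownames(expr) <- c("g1", "g2")
  colnames(expr) <- c("c1", "c2", "c3")
  tbl <- stage_expression_table(expr, c("A1", "A1", "A1"))
  expect_equal(tbl$mean_tpm["g1", "A1"], 14 / 3)
  expect_equal(tbl$n_ge1["g2", "A1"], 1)
  expect_equal(unname(tbl$n_cells["A1"]), 3)
})

test_that("the decision tree reproduces the category definitions", {
  profiles <- list(
    # expressed at L and Z only, silent from eP onward
    msci1 = c("L", "Z"),
    # expressed at G1 and mP, silent at D, re-expressed at RS2
    msci2 = c("G1", "mP", "RS2"),
    rs = "RS6",
    escape = c("A1", "D"))
  lab <- classify_msci(profile_matrix(profiles))
  expect_equal(lab$category,
               c("MSCI_PMSC", "MSCI_ESCAPE_PMSC", "RS_SPECIFIC",
                 "ESCAPE_MSCI"))
  expect_equal(lab$subtype, c("TYPE_I", "TYPE_II", NA, NA))

  # the alternative naming convention flips the two MSCI subcategories
  lab2 <- classify_msci(profile_matrix(profiles),
                        pmsc_semantics = "expressed_postmeiotic")
  expect_equal(lab2$category[1:2], c("MSCI_ESCAPE_PMSC", "MSCI_PMSC"))
  expect_equal(lab2$subtype, lab$subtype)
})

test_that("classifier equals the brute-force rule evaluator on random profiles", {
  set.seed(101)
  n <- 300
  E <- matrix(runif(n * 20) < 0.3, n, 20,
              dimnames = list(sprintf("g%03d", 1:n), stage_codes()))
  E <- E[rowSums(E) > 0, , drop = FALSE]
  lab <- classify_msci(E)
  oracle <- t(apply(E, 1, oracle_classify))
  expect_identical(lab$category, unname(oracle[, 1]))
  expect_identical(lab$subtype, unname(oracle[, 2]))
})

test_that("categories partition the expressed universe", {
  set.seed(102)
  E <- matrix(runif(200 * 20) < 0.25, 200, 20,
              dimnames = list(sprintf("g%03d", 1:200), stage_codes()))
  E <- E[rowSums(E) > 0, , drop = FALSE]
  lab <- classify_msci(E)
  cats <- c("MSCI_PMSC", "MSCI_ESCAPE_PMSC", "ESCAPE_MSCI", "RS_SPECIFIC",
            "OTHER")
  expect_true(all(lab$category %in% cats)) # exhaustive
  # subtype present iff MSCI
  is_msci <- lab$category %in% c("MSCI_PMSC", "MSCI_ESCAPE_PMSC")
  expect_identical(!is.na(lab$subtype), is_msci)
  # genes with no expressed stage are rejected
  E0 <- rbind(E, none = rep(FALSE, 20))
  expect_error(classify_msci(E0), class = "spermdyn_validation_error")
})

test_that("noiseless simulation is classified exactly as planted", {
  sim <- simulate_dataset(sim_spec(noiseless = TRUE, seed = 202))
  tp <- tpm(sim$counts)
  tbl <- stage_expression_table(tp, setNames(sim$cell_meta$stage,
                                             sim$cell_meta$cell_id))
  truth <- sim$truth$msci
  lab <- classify_msci(expressed_matrix(tbl)[truth$gene_id, , drop = FALSE])
  expect_identical(lab$category, truth$category)
  expect_identical(lab$subtype, truth$subtype)
})

test_that("the lncRNA mode applies the same rules to the lncRNA biotype", {
  set.seed(103)
  genes <- c("lnc1", "lnc2", "pc1")
  anno <- data.frame(gene_id = genes, chromosome = c("X", "X", "X"),
                     biotype = c("lncRNA", "lncRNA", "protein_coding"))
  # lnc1 expressed at L only (silent at D): MSCI; lnc2 silent everywhere
  stages <- rep(stage_codes(), each = 4)
  expr <- matrix(0, 3, length(stages),
                 dimnames = list(genes, sprintf("c%03d", seq_along(stages))))
  expr["lnc1", stages == "L"] <- 5
  expr["pc1", stages == "L"] <- 5
  lab <- lncrna_msci_mode(anno, expr, stages)
  expect_equal(lab$gene_id, "lnc1") # protein-coding gene excluded
  expect_equal(lab$category, "MSCI_PMSC")
})

test_that("summary percentages follow the half-up arithmetic", {
  lab <- data.frame(
    gene_id = sprintf("g%03d", 1:575),
    category = rep(c("MSCI_PMSC", "MSCI_ESCAPE_PMSC", "ESCAPE_MSCI"),
                   c(140, 285, 150)),
    subtype = c(rep(c("TYPE_I", "TYPE_II"), c(154, 271)), rep(NA, 150)))
  s <- msci_summary(lab)
  expect_equal(s$n_msci, 425)
  expect_equal(s$n_pre_ep, 575)
  expect_equal(s$percentages$msci, 73.9)
  expect_equal(s$percentages$escape_msci, 26.1)
  expect_equal(s$percentages$msci + s$percentages$escape_msci, 100,
               tolerance = 0.1 / 100)
  expect_equal(s$percentages$pmsc_silent, 32.9)
  expect_equal(s$percentages$pmsc_escape, 67.1)
  expect_equal(s$percentages$type_i, 36.2)
  expect_equal(s$percentages$type_ii, 63.8)

  empty <- msci_summary(lab[0, ])
  expect_true(all(vapply(empty$percentages, is.na, logical(1))))
  expect_equal(empty$counts$MSCI_PMSC, 0)
})
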