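# Quality control, spike-in normalization, TPM and log transforms.

test_that("gene detection uses the strict UMI > 1 rule", {
  expect_equal(genes_detected(c(0, 1, 2, 5)), 2)
  expect_equal(genes_detected(rep(0, 100)), 0)
  expect_equal(genes_detected(rep(2, 10000)), 10000)
})

test_that("qc_filter applies the three criteria with the stated strictness", {
  # 2501 endogenous genes so the > 2000 detected rule is attainable
  n_genes <- 2501
  counts <- cbind(
    keep   = c(rep(10, 2500), 0),  # 2500 detected, 25,000 UMI
    border = c(rep(10, 2000), rep(1, 500), 0), # exactly 2000 detected
    lowumi = c(rep(2, 2500), 0),   # 2500 detected but 5,000 UMI
    edge   = c(rep(8, 2500), 0))   # 20,000 UMI exactly -> kept (inclusive)
  cm <- count_matrix(counts, sprintf("g%04d", 1:n_genes), colnames(counts))
  meta <- data.frame(cell_id = colnames(counts),
                     stage = "A1",
                     mapping_rate = c(0.5, 0.5, 0.5, 0.5))
  res <- qc_filter(cm, meta)
  expect_setequal(res$kept, c("keep", "edge"))
  expect_equal(res$rejected$reasons[res$rejected$cell_id == "border"],
               "genes_detected")
  expect_equal(res$rejected$reasons[res$rejected$cell_id == "lowumi"],
               "total_umi")

  # mapping rate exactly at the bound fails (strict > 40%)
  meta$mapping_rate <- c(0.40, 0.5, 0.5, 0.5)
  res2 <- qc_filter(cm, meta)
  expect_true("mapping_rate" %in%
                strsplit(res2$rejected$reasons[
                  res2$rejected$cell_id == "keep"], ";")[[1]])

  meta$mapping_rate[1] <- NA
  expect_error(qc_filter(cm, meta), class = "spermdyn_validation_error")
})

test_that("qc is monotone: raising any threshold never grows the kept set", {
  set.seed(42)
  cm <- make_counts(50, 30, seed = 42, lambda = 3)
  meta <- data.frame(cell_id = cm$cells, stage = "A1",
                     mapping_rate = runif(30, 0.3, 0.6))
  base <- qc_thresholds(min_mapping_rate = 0.35, min_genes_detected = 20,
                        umi_min = 100, umi_max = 300)
  kept0 <- qc_filter(cm, meta, base)$kept
  tighter <- list(
    qc_thresholds(0.45, 20, 100, 300),
    qc_thresholds(0.35, 30, 100, 300),
    qc_thresholds(0.35, 20, 150, 300),
    qc_thresholds(0.35, 20, 100, 250))
  for (th in tighter) {
    expect_true(all(qc_filter(cm, meta, th)$kept %in% kept0))
  }
})

test_that("spike size factors are spike totals over their mean", {
  counts <- rbind(g1 = c(5, 5, 5), `ERCC-1` = c(100, 100, 100))
  cm <- count_matrix(counts, rownames(counts), c("a", "b", "c"))
  expect_equal(unname(spike_size_factors(cm)), c(1, 1, 1))

  counts2 <- rbind(g1 = c(5, 5), `ERCC-1` = c(50, 150))
  cm2 <- count_matrix(counts2, rownames(counts2), c("a", "b"))
  expect_equal(unname(spike_size_factors(cm2)), c(0.5, 1.5))
  expect_equal(mean(spike_size_factors(cm2)), 1)

  counts3 <- rbind(g1 = c(5, 5), `ERCC-1` = c(0, 100))
  cm3 <- count_matrix(counts3, rownames(counts3), c("a", "b"))
  err <- tryCatch(spike_size_factors(cm3), condition = identity)
  expect_s3_class(err, "spermdyn_normalization_error")
  expect_match(conditionMessage(err), "a") # names the offending cell
})

test_that("factors recover planted per-cell scaling from simulated spikes", {
  sim <- simulate_dataset(sim_spec(stages = "L", cells_per_stage = 60,
                                   noiseless = TRUE, seed = 11))
  f <- spike_size_factors(sim$counts)
  expect_gt(cor(f, sim$truth$factors[names(f)]), 0.999)
})

test_that("normalization divides by factors and preserves zeros", {
  cm <- make_counts(6, 4, spikes = 2, seed = 3)
  raw <- as.matrix(cm$counts)
  norm1 <- as.matrix(normalize_counts(cm, rep(1, 4)))
  expect_equal(norm1, raw)
  f <- c(2, 1, 1, 1)
  norm2 <- as.matrix(normalize_counts(cm, f))
  expect_equal(norm2[, 1], raw[, 1] / 2)
  expect_identical(norm2 == 0, raw == 0)
  expect_error(normalize_counts(cm, c(-1, 1, 1, 1)),
               class = "spermdyn_validation_error")
})

test_that("TPM normalizes per cell over endogenous genes only", {
  counts <- rbind(g1 = c(7, 10), g2 = c(0, 10), `ERCC-1` = c(3, 5))
  cm <- count_matrix(counts, rownames(counts), c("a", "b"))
  tp <- tpm(cm)
  expect_equal(tp["g1", "a"], 1e6) # single expressed endogenous gene
  expect_equal(unname(colSums(tp)), c(1e6, 1e6))
  # scale invariance: doubling a cell's counts leaves TPM unchanged
  cm2 <- count_matrix(counts * 2, rownames(counts), c("a", "b"))
  expect_equal(tpm(cm2), tpm(cm))
  # spike rows reported separately, not in the denominator
  expect_equal(nrow(attr(tp, "spike")), 1)

  cm3 <- count_matrix(rbind(g1 = c(0, 5), `ERCC-1` = c(3, 3)),
                      c("g1", "ERCC-1"), c("a", "b"))
  expect_error(tpm(cm3), class = "spermdyn_validation_error")
})

test_that("log transform is log2(TPM/10 + 1) and strictly monotone", {
  expect_equal(log_expr(matrix(c(0, 10, 70), 1)),
               matrix(c(0, 1, 3), 1))
  x <- matrix(sort(runif(50, 0, 100)), 1)
  expect_true(all(diff(log_expr(x)[1, ]) > 0))
  expect_error(log_expr(matrix(-1, 1, 1)),
               class = "spermdyn_validation_error")
})
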