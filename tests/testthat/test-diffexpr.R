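# Differential expression: the average-difference formula, BH adjustment,
# the calling rule, and the two screens.

test_that("avg_log_diff matches its closed form", {
  expect_equal(avg_log_diff(c(1, 1), c(0, 0)), 1)
  expect_equal(avg_log_diff(c(2, 0.7, 1.1), c(2, 0.7, 1.1)), 0)
  # hand evaluation: log2(mean(2^c(2,0) - 1) + 1) = log2(2.5)
  expect_equal(avg_log_diff(c(2, 0), c(0, 0)), log2(2.5))
  expect_equal(avg_log_diff(c(0, 0), c(2, 0)), -log2(2.5))
  expect_error(avg_log_diff(numeric(), c(1)),
               class = "spermdyn_validation_error")
})

test_that("bh_adjust equals the brute-force step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(9)
  for (n in c(2, 5, 20)) {
    p <- runif(n)
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "spermdyn_validation_error")
})

test_that("the row-wise t-test equals stats::t.test with equal variances", {
  set.seed(4)
  mat <- matrix(rnorm(12 * 20, mean = 2), 12, 20,
                dimnames = list(sprintf("g%02d", 1:12),
                                sprintf("c%02d", 1:20)))
  a <- mat[, 1:8]; b <- mat[, 9:20]
  got <- spermdyn:::row_t_test(a, b)
  ref <- vapply(1:12, function(i) {
    t.test(a[i, ], b[i, ], var.equal = TRUE)$p.value
  }, numeric(1))
  expect_equal(unname(got$p), ref)
})

test_that("deg_test calls, handles ties, and is antisymmetric", {
  set.seed(5)
  mat <- matrix(abs(rnorm(30 * 24, 2)), 30, 24,
                dimnames = list(sprintf("g%02d", 1:30),
                                sprintf("c%02d", 1:24)))
  mat[1, ] <- 3 # zero variance in both groups -> ns with p = 1
  a <- colnames(mat)[1:12]; b <- colnames(mat)[13:24]
  # identical groups: feed the same values to both sides
  same <- cbind(mat[, 1:12], mat[, 1:12])
  colnames(same) <- sprintf("c%02d", 1:24)
  rsame <- deg_test(same, colnames(same)[1:12], colnames(same)[13:24])
  expect_true(all(rsame$call == "ns"))
  expect_equal(rsame$avg_diff, rep(0, 30))

  r1 <- deg_test(mat, a, b)
  r2 <- deg_test(mat, b, a)
  expect_equal(r1$avg_diff, -r2$avg_diff)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$p_value[1], 1)
  expect_equal(r1$call[1], "ns")

  expect_error(deg_test(mat, a, c(b, a[1])),
               class = "spermdyn_validation_error")
  expect_error(deg_test(mat, a[1], b), class = "spermdyn_validation_error")
})

test_that("planted fold changes are recovered and flip under group swap", {
  sim <- simulate_dataset(sim_spec(
    stages = c("eP", "mP"), cells_per_stage = 200,
    n_x_genes = 0, n_y_genes = 0,
    msci_counts = c(MSCI_PMSC = 0, MSCI_ESCAPE_PMSC = 0, ESCAPE_MSCI = 0,
                    RS_SPECIFIC = 0, OTHER = 0),
    degs_per_transition = 20, seed = 21))
  lg <- log_expr(tpm(sim$counts))
  pair <- sim$truth$degs[["eP->mP"]]
  latter <- sim$cell_meta$cell_id[sim$cell_meta$stage == "mP"]
  former <- sim$cell_meta$cell_id[sim$cell_meta$stage == "eP"]
  d <- deg_test(lg, latter, former)
  recall <- mean(c(d$call[match(pair$up, d$gene_id)] == "up",
                   d$call[match(pair$down, d$gene_id)] == "down"))
  expect_gte(recall, 0.9)
  # swapping groups flips up <-> down exactly
  d2 <- deg_test(lg, former, latter)
  flip <- c(up = "down", down = "up", ns = "ns")
  expect_identical(unname(flip[d$call]), d2$call)
})

test_that("the splicing-regulator screen restricts to the flagged set", {
  sim <- simulate_dataset(sim_spec(
    stages = c("Z", "eP"), cells_per_stage = 200,
    n_x_genes = 0, n_y_genes = 0,
    msci_counts = c(MSCI_PMSC = 0, MSCI_ESCAPE_PMSC = 0, ESCAPE_MSCI = 0,
                    RS_SPECIFIC = 0, OTHER = 0),
    degs_per_transition = 20, seed = 31))
  lg <- log_expr(tpm(sim$counts))
  pair <- sim$truth$degs[["Z->eP"]]
  regulators <- pair$up[1:5] # flag a subset of planted DEGs as regulators
  latter <- sim$cell_meta$cell_id[sim$cell_meta$stage == "eP"]
  former <- sim$cell_meta$cell_id[sim$cell_meta$stage == "Z"]
  res <- splicing_regulator_screen(lg, latter, former, regulators)
  expect_setequal(res$gene_id, regulators)
  expect_gte(mean(res$call == "up"), 0.8) # planted regulator DEGs recovered
  expect_false(any(pair$down %in% res$gene_id)) # non-regulators excluded

  expect_warning(res0 <- splicing_regulator_screen(lg, latter, former,
                                                   c("nope1", "nope2")))
  expect_equal(nrow(res0), 0)
  expect_error(splicing_regulator_screen(lg, latter, former, character()),
               class = "spermdyn_config_error")
})

test_that("the surface-marker screen ranks cluster-specific markers first", {
  set.seed(6)
  n <- 60
  mat <- matrix(abs(rnorm(20 * n, 2, 0.3)), 20, n,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:n)))
  clusters <- setNames(rep(c("C6", "C7"), each = n / 2), colnames(mat))
  mat["g01", clusters == "C7"] <- mat["g01", clusters == "C7"] + 4 # planted marker
  res <- surface_marker_screen(mat, clusters, c("g01", "g02", "g03"))
  expect_equal(res$C7$gene_id[1], "g01")
  expect_equal(res$C7$call[res$C7$gene_id == "g01"], "up")

  expect_warning(surface_marker_screen(mat, clusters, "absent"))
  expect_error(surface_marker_screen(mat, setNames(rep("C1", n), colnames(mat)),
                                     "g01"),
               class = "spermdyn_validation_error")
  # two identical clusters: no significant markers
  dup <- cbind(mat[, 1:30], mat[, 1:30])
  colnames(dup) <- sprintf("c%02d", 1:60)
  cl2 <- setNames(rep(c("C6", "C7"), each = 30), colnames(dup))
  res2 <- surface_marker_screen(dup, cl2, c("g01", "g02"))
  expect_true(all(res2$C6$call == "ns"))
  expect_true(all(res2$C7$call == "ns"))
})
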