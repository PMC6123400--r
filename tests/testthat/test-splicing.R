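# Event consideration, AS-gene calls, the five-situation transition
# classifier, and the expression-splicing association.

test_that("the consideration rule honors both branches as quoted", {
  expect_equal(consideration_threshold(50), 5L)
  expect_equal(consideration_threshold(66), 7L)
  # n_cov = 50, exactly 5 in band -> considered through the 10% branch
  psi <- c(rep(50, 5), rep(95, 45), rep(NA, 16))
  cov <- c(rep(TRUE, 50), rep(FALSE, 16))
  expect_true(event_considered(psi, cov))
  # everything out of band -> not considered
  expect_false(event_considered(rep(95, 50), rep(TRUE, 50)))
  # n_cov = 60, k = 3 < ceil(6): considered through the OR branch
  expect_true(event_considered(c(rep(50, 3), rep(95, 57)), rep(TRUE, 60)))
  expect_false(event_considered(c(rep(50, 2), rep(95, 58)), rep(TRUE, 60)))
  # no covered samples: not considered, no error
  expect_false(event_considered(rep(50, 5), rep(FALSE, 5)))
  # small n_cov: the 10% branch can bind below 3
  expect_true(event_considered(c(50, 95, 95, 95, 95), rep(TRUE, 5)))
})

test_that("AS genes need considered events of at least two types", {
  samples <- c("s1", "s2", "x", "y")
  ev <- data.frame(gene_id = c("gA", "gA", "gA", "gB", "gB"),
                   event_id = c("e1", "e2", "e3", "e1", "e2"),
                   event_type = c("EEJ", "EEJ", "EEJ", "EEJ", "IR"))
  act <- list(1:4, 1:4, 1:4, 1:4, 1:4)
  st <- make_splice_fixture(ev, act, samples)
  expect_equal(as_genes(st, "x"), "gB") # gA has one type only
  # empty sample
  st2 <- make_splice_fixture(ev, list(1:2, 1:2, 1:2, 1:2, 1:2), samples)
  expect_equal(as_genes(st2, "y"), character())
})

test_that("the five situations match their defining examples", {
  samples <- c("s1", "s2", "x", "y")
  fixture <- function(types, act) {
    ev <- data.frame(gene_id = "g",
                     event_id = sprintf("e%d", seq_along(types)),
                     event_type = types)
    make_splice_fixture(ev, act, samples)
  }
  # EEJ in x, IR in y -> situation 3
  st <- fixture(c("EEJ", "IR"), list(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(classify_transition(st, "g", "x", "y")$situation, 3)
  # EEJ to nothing -> situation 4
  st <- fixture("EEJ", list(c(1, 2, 3)))
  r <- classify_transition(st, "g", "x", "y")
  expect_equal(r$situation, 4)
  expect_true(r$is_splicing_regulated)
  # nothing to EEJ -> situation 5
  st <- fixture("EEJ", list(c(1, 2, 4)))
  expect_equal(classify_transition(st, "g", "x", "y")$situation, 5)
  # identical non-empty sets -> situation 1, not splicing-regulated
  st <- fixture(c("EEJ", "IR"), list(c(1, 3, 4), c(1, 3, 4)))
  r <- classify_transition(st, "g", "x", "y")
  expect_equal(r$situation, 1)
  expect_false(r$is_splicing_regulated)
  # same type, different events -> situation 2
  st <- fixture(c("EEJ", "EEJ"), list(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(classify_transition(st, "g", "x", "y")$situation, 2)
  # nothing in either sample: not emitted
  st <- fixture("EEJ", list(c(1, 2)))
  expect_equal(nrow(classify_transition(st, "g", "x", "y")), 0)
  # non-consecutive samples are an error
  expect_error(classify_transition(st, "g", "s1", "y"),
               class = "spermdyn_validation_error")
})

test_that("classification equals brute-force enumeration over small event sets", {
  # all pairs of subsets of 3 events with all type assignments over 2 types
  samples <- c("s1", "s2", "x", "y")
  subsets <- lapply(0:7, function(m) which(bitwAnd(m, c(1, 2, 4)) > 0))
  type_grids <- expand.grid(t1 = c("EEJ", "IR"), t2 = c("EEJ", "IR"),
                            t3 = c("EEJ", "IR"), stringsAsFactors = FALSE)
  for (ti in seq_len(nrow(type_grids))) {
    types <- unlist(type_grids[ti, ])
    ev <- data.frame(gene_id = "g", event_id = c("e1", "e2", "e3"),
                     event_type = unname(types))
    for (sx in subsets) for (sy in subsets) {
      act <- lapply(1:3, function(e) {
        c(1, 2, if (e %in% sx) 3, if (e %in% sy) 4)
      })
      st <- make_splice_fixture(ev, act, samples)
      got <- classify_transition(st, "g", "x", "y")
      want <- oracle_situation(ev$event_id[sx], types[sx],
                               ev$event_id[sy], types[sy])
      if (is.na(want)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(got$situation, want)
      }
    }
  }
})

test_that("transitions are invariant to event row order", {
  samples <- c("s1", "s2", "x", "y")
  ev <- data.frame(gene_id = rep("g", 3), event_id = c("e1", "e2", "e3"),
                   event_type = c("EEJ", "IR", "ALTD"))
  act <- list(c(1, 2, 3), c(1, 2, 3, 4), c(1, 2, 4))
  st <- make_splice_fixture(ev, act, samples)
  perm <- c(3, 1, 2)
  st2 <- make_splice_fixture(ev[perm, ], act[perm], samples)
  expect_equal(classify_transition(st, "g", "x", "y")$situation,
               classify_transition(st2, "g", "x", "y")$situation)
})

test_that("event-level changes are tallied by latter-stage status", {
  samples <- c("s1", "s2", "x", "y")
  ev <- data.frame(gene_id = c("g1", "g1", "g2"),
                   event_id = c("e1", "e2", "e1"),
                   event_type = c("EEJ", "IR", "ALTD"))
  # e1 drops out (EEJ -> NA), e2 appears (-> IR), g2/e1 appears (-> ALTD)
  act <- list(c(1, 2, 3), c(1, 2, 4), c(1, 2, 4))
  st <- make_splice_fixture(ev, act, samples)
  tally <- event_change_tally(st, "x", "y")
  expect_equal(unname(tally[c("IR", "ALTD", "NA")]), c(1, 1, 1))
  expect_equal(unname(tally["EEJ"]), 0)
})

test_that("expression changes are associated with the correct flanking sample", {
  samples <- c("s1", "s2", "x", "y")
  ev <- data.frame(gene_id = c("up1", "up2", "down1"),
                   event_id = rep("e1", 3),
                   event_type = c("IR", "EEJ", "IR"))
  # up1 has IR in the latter sample; up2 has nothing in y; down1 has IR in x
  act <- list(c(1, 2, 4), c(1, 2, 3), c(1, 2, 3))
  st <- make_splice_fixture(ev, act, samples)
  deg <- data.frame(gene_id = c("up1", "up2", "down1"),
                    call = c("up", "up", "down"))
  res <- expression_splicing_association(deg, st, "x", "y")
  got <- setNames(res$status$as_status, res$status$gene_id)
  expect_equal(unname(got[c("up1", "up2", "down1")]), c("IR", "NA", "IR"))
  expect_equal(unname(res$fractions$up["IR"]), 0.5)
})

test_that("planted transition situations are recovered from simulated tables", {
  ps <- simulate_psi_table(seed = 7, coverage_missing_rate = 0)
  tr <- splicing_transitions(ps$table)
  m <- merge(ps$truth, tr, by = c("gene_id", "sample_x", "sample_y"),
             suffixes = c(".truth", ".obs"))
  expect_equal(nrow(m), nrow(ps$truth))
  expect_equal(m$situation.obs, m$situation.truth)
  # with default coverage dropout the planted labels are still preserved
  ps2 <- simulate_psi_table(seed = 7)
  tr2 <- splicing_transitions(ps2$table)
  m2 <- merge(ps2$truth, tr2, by = c("gene_id", "sample_x", "sample_y"),
              suffixes = c(".truth", ".obs"))
  expect_equal(m2$situation.obs, m2$situation.truth)
})
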