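# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data files.

# tiny integer count matrix with optional spike rows
make_counts <- function(n_genes = 5, n_cells = 3, spikes = 0, seed = 1,
                        lambda = 5) {
  set.seed(seed)
  genes <- c(sprintf("g%03d", seq_len(n_genes)),
             if (spikes > 0) sprintf("ERCC-%05d", seq_len(spikes)))
  m <- matrix(rpois((n_genes + spikes) * n_cells, lambda),
              n_genes + spikes, n_cells)
  count_matrix(m, genes, sprintf("c%02d", seq_len(n_cells)))
}

# expressed-profile matrix over the 20 stages from a list of expressed stage
# code vectors
profile_matrix <- function(profiles) {
  E <- matrix(FALSE, length(profiles), 20,
              dimnames = list(names(profiles), stage_codes()))
  for (g in names(profiles)) E[g, profiles[[g]]] <- TRUE
  E
}

# a stage_expr table where `expressed` entries satisfy the rule with margin
# (mean 5, 5 cells >= 1) and others fail it (mean 0.1, 0 cells)
stage_table_from_profiles <- function(profiles, n_cells = 10) {
  E <- profile_matrix(profiles)
  structure(list(
    mean_tpm = ifelse(E, 5, 0.1),
    n_ge1 = ifelse(E, 5, 0),
    n_cells = stats::setNames(rep(n_cells, 20), stage_codes())),
    class = "stage_expr")
}

# independent brute-force re-statement of the sex-linked classification
# rules, written directly from the stage-window definitions (the oracle for
# classify_msci)
oracle_classify <- function(e) {
  stopifnot(length(e) == 20)
  names(e) <- stage_codes()
  pre <- any(e[1:10]); pach <- any(e[11:13]); d <- e["D"]
  post <- any(e[16:20]); premii <- any(e[1:15])
  if (pre && !d) {
    cat <- if (!post) "MSCI_PMSC" else "MSCI_ESCAPE_PMSC"
    sub <- if (!pach) "TYPE_I" else "TYPE_II"
    return(c(cat, sub))
  }
  if (pre && d) return(c("ESCAPE_MSCI", NA))
  if (!premii && post) return(c("RS_SPECIFIC", NA))
  c("OTHER", NA)
}

# brute-force BH from the step-up definition: q_i = min over j >= rank(i)
# of p_(j) * n / j, capped at 1
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  sorted <- p[o] * n / seq_len(n)
  running <- rev(cummin(rev(sorted)))
  q[o] <- pmin(running, 1)
  q
}

# brute-force five-situation classifier over explicit event-id/type sets
oracle_situation <- function(sx_ids, sx_types, sy_ids, sy_types) {
  if (!length(sx_ids) && !length(sy_ids)) return(NA_integer_)
  if (length(sx_ids) && !length(sy_ids)) return(4L)
  if (!length(sx_ids) && length(sy_ids)) return(5L)
  if (length(sx_ids) == length(sy_ids) && all(sort(sx_ids) == sort(sy_ids)))
    return(1L)
  tx <- sort(unique(sx_types)); ty <- sort(unique(sy_types))
  if (length(tx) != length(ty) || any(tx != ty)) return(3L)
  2L
}

# splice table in which each event is active exactly in the given samples
# (in-band PSI 50 there, out-of-band 2 elsewhere, full coverage); two
# leading support samples keep every event globally considered
make_splice_fixture <- function(events, active_samples, samples) {
  psi <- matrix(2, nrow(events), length(samples),
                dimnames = list(NULL, samples))
  for (i in seq_len(nrow(events))) psi[i, active_samples[[i]]] <- 50
  covered <- matrix(TRUE, nrow(events), length(samples),
                    dimnames = list(NULL, samples))
  splice_table(events, psi, covered)
}
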