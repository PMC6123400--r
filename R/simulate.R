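# Synthetic staged single-cell datasets with planted ground truth.
#
# Counts are negative binomial around stage-specific mean-TPM profiles scaled
# by a per-cell size factor, with spike-in rows drawn around fixed expected
# totals times the same factor. Sex-linked genes are planted into MSCI
# categories by constructing expressed/silent stage profiles that satisfy the
# classifier's rules with margin; DEGs are planted as persistent fold-change
# steps between consecutive stages.

#' Simulation specification
#'
#' Defaults are the study conditions the generator emulates, scaled down for
#' quick runs: all 20 stages, 25 cells per stage, NB size (dispersion) 0.5,
#' dropout 0.1, mean sequencing depth 3e5 UMI per cell, 92 spike-ins.
#' Planted expressed stages get mean TPM 10 (comfortably above the >1 /
#' >=3-cells expressed rule) and silent stages 0.1.
#'
#' @param stages Stage codes to simulate.
#' @param cells_per_stage Cells per stage.
#' @param n_autosomal_genes,n_x_genes,n_y_genes,n_spikeins Gene counts.
#' @param dispersion NB size parameter (variance = mu + mu^2 / dispersion).
#' @param spike_dispersion NB size parameter for spike-in rows; larger than
#'   the endogenous dispersion because spike-ins carry technical noise only.
#' @param dropout Extra Bernoulli zeroing probability after the NB draw.
#' @param base_depth Expected endogenous UMI per cell at size factor 1.
#' @param spike_total Expected spike-in UMI per cell at size factor 1.
#' @param factor_sdlog Log-sd of the per-cell size factors (mean 1).
#' @param msci_counts Named counts of planted sex-linked categories
#'   (MSCI_PMSC, MSCI_ESCAPE_PMSC, ESCAPE_MSCI, RS_SPECIFIC, OTHER).
#' @param type2_fraction Fraction of planted MSCI genes of subtype TYPE_II.
#' @param degs_per_transition Planted DEGs per consecutive stage pair (half
#'   up, half down).
#' @param deg_log2fc Planted log2 effect size.
#' @param expressed_tpm,silent_tpm Planted stage-mean TPM for expressed and
#'   silent stages of sex-linked genes.
#' @param tf_fraction,regulator_fraction,marker_fraction Fractions of
#'   autosomal genes flagged as TFs, splicing regulators, surface markers.
#' @param tf_module_size Number of co-regulated TFs per planted program (0
#'   disables). Two programs emulate the co-expressed TF sets that drive the
#'   major transitions: a mitotic program that switches off at meiotic entry
#'   and a meiotic program that switches off at spermiogenesis.
#' @param tf_module_tpm On-state mean TPM of the planted TF programs. The
#'   large on/off contrast mirrors the near-complete silencing of
#'   transition-specific TFs and keeps their pairwise correlations above the
#'   network thresholds despite the NB noise.
#' @param noiseless If TRUE, counts are the rounded expected values
#'   (no NB noise, no dropout).
#' @param seed Optional seed applied by the generators.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(stages = stage_codes(),
                     cells_per_stage = 25,
                     n_autosomal_genes = 1000,
                     n_x_genes = 120,
                     n_y_genes = 20,
                     n_spikeins = 92,
                     dispersion = 0.5,
                     spike_dispersion = 10,
                     dropout = 0.1,
                     base_depth = 3e5,
                     spike_total = 1e4,
                     factor_sdlog = 0.25,
                     msci_counts = c(MSCI_PMSC = 30, MSCI_ESCAPE_PMSC = 30,
                                     ESCAPE_MSCI = 20, RS_SPECIFIC = 15,
                                     OTHER = 15),
                     type2_fraction = 0.5,
                     degs_per_transition = 15,
                     deg_log2fc = 2,
                     expressed_tpm = 10,
                     silent_tpm = 0.1,
                     tf_fraction = 0.10,
                     regulator_fraction = 0.05,
                     marker_fraction = 0.03,
                     tf_module_size = 12,
                     tf_module_tpm = 1000,
                     noiseless = FALSE,
                     seed = NULL) {
  stage_index(stages)
  spec <- structure(as.list(environment()), class = "sim_spec")
  if (sum(msci_counts) > n_x_genes + n_y_genes) {
    sd_stop("more planted sex-linked categories than sex-linked genes",
            "spermdyn_config_error")
  }
  rates <- c(dropout = dropout, type2 = type2_fraction, tf = tf_fraction,
             reg = regulator_fraction, marker = marker_fraction)
  if (any(rates < 0 | rates > 1)) {
    sd_stop("rates must lie in [0, 1]", "spermdyn_config_error")
  }
  if (deg_log2fc <= 0) sd_stop("effect size must be > 0", "spermdyn_config_error")
  if (dispersion <= 0) sd_stop("dispersion must be > 0", "spermdyn_config_error")
  spec
}

# sample k stages from a pool (at least min_k, scalar-safe)
sample_stages <- function(pool, k) {
  if (length(pool) == 1) pool else sample(pool, k)
}

# Build the planted expressed/silent stage profile (logical over the 20
# stages) for one gene of a given category+subtype. Expressed requirements
# are planted at >= 2 qualifying stages wherever the category allows, so a
# single noisy stage cannot flip the label.
plant_profile <- function(category, subtype) {
  e <- stats::setNames(rep(FALSE, 20), stage_codes())
  pre <- stages_before_ep(); pach <- stages_pachytene()
  post <- stages_postmeiotic()
  if (category %in% c("MSCI_PMSC", "MSCI_ESCAPE_PMSC")) {
    e[sample_stages(pre, sample(2:4, 1))] <- TRUE
    if (subtype == "TYPE_II") e[sample_stages(pach, 2)] <- TRUE
    if (category == "MSCI_ESCAPE_PMSC") e[sample_stages(post, 2)] <- TRUE
    # D and MI stay silent
  } else if (category == "ESCAPE_MSCI") {
    e[sample_stages(pre, sample(2:4, 1))] <- TRUE
    e["D"] <- TRUE
    # free stages: pachytene and postmeiotic presence is unconstrained
    e[pach] <- stats::runif(3) < 0.5
    e[post] <- stats::runif(5) < 0.5
    e["MI"] <- stats::runif(1) < 0.5
  } else if (category == "RS_SPECIFIC") {
    e[sample_stages(post, 2)] <- TRUE
  } else { # OTHER: expressed only between eP and MI, never before eP,
           # and if D is silent it must not look MSCI (no pre expression holds)
    e[sample_stages(c(pach, "D", "MI"), sample(1:2, 1))] <- TRUE
  }
  e
}

#' Simulate a staged single-cell UMI dataset with planted truth
#'
#' @param spec A [sim_spec()].
#' @param seed Seed (overrides `spec$seed`).
#' @return List with `counts` (a [count_matrix()]), `cell_meta`,
#'   `gene_annotation`, and `truth` (planted MSCI labels, DEG sets per
#'   transition, per-cell size factors, and the stage-mean TPM matrix).
#' @export
simulate_dataset <- function(spec = sim_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  stages <- spec$stages
  n_stage <- length(stages)

  auto_ids <- sprintf("gA%04d", seq_len(spec$n_autosomal_genes))
  x_ids <- sprintf("gX%03d", seq_len(spec$n_x_genes))
  y_ids <- sprintf("gY%03d", seq_len(spec$n_y_genes))
  spike_ids <- sprintf("ERCC-%05d", seq_len(spec$n_spikeins))
  endo_ids <- c(auto_ids, x_ids, y_ids)

  anno <- data.frame(
    gene_id = c(endo_ids, spike_ids),
    chromosome = c(sample(as.character(1:19), spec$n_autosomal_genes, TRUE),
                   rep("X", spec$n_x_genes), rep("Y", spec$n_y_genes),
                   rep("ERCC", spec$n_spikeins)),
    biotype = c(rep("protein_coding", length(endo_ids)),
                rep("spike_in", spec$n_spikeins)),
    stringsAsFactors = FALSE)
  anno$is_tf <- anno$biotype == "protein_coding" &
    stats::runif(nrow(anno)) < spec$tf_fraction
  anno$is_splicing_regulator <- anno$biotype == "protein_coding" &
    stats::runif(nrow(anno)) < spec$regulator_fraction
  anno$is_surface_marker <- anno$biotype == "protein_coding" &
    stats::runif(nrow(anno)) < spec$marker_fraction

  # stage-mean TPM matrix over endogenous genes
  base <- stats::rlnorm(spec$n_autosomal_genes, meanlog = log(20), sdlog = 1.2)
  M <- matrix(rep(base, n_stage), ncol = n_stage,
              dimnames = list(auto_ids, stages))

  # planted DEGs: persistent fold-change steps from the latter stage onward
  truth_degs <- list()
  if (n_stage > 1 && spec$degs_per_transition > 0) {
    pool <- auto_ids
    for (i in seq_len(n_stage - 1)) {
      k <- min(spec$degs_per_transition, length(pool))
      if (k < 2) break
      genes <- sample(pool, k)
      pool <- setdiff(pool, genes)
      n_up <- ceiling(k / 2)
      up <- genes[seq_len(n_up)]; down <- genes[-seq_len(n_up)]
      M[up, ] <- stats::runif(length(up), 30, 60)        # detectable baseline
      M[down, ] <- stats::runif(length(down), 30, 60)
      later <- seq(i + 1, n_stage)
      M[up, later] <- M[up, later] * 2^spec$deg_log2fc
      M[down, later] <- M[down, later] / 2^spec$deg_log2fc
      truth_degs[[paste(stages[i], stages[i + 1], sep = "->")]] <-
        list(up = up, down = down)
    }
    # stage transitions are driven in part by TFs, so stage-regulated genes
    # are enriched for the TF flag
    deg_ids <- unlist(lapply(truth_degs, unlist), use.names = FALSE)
    tf_extra <- deg_ids[stats::runif(length(deg_ids)) < 0.3]
    anno$is_tf[match(tf_extra, anno$gene_id)] <- TRUE
  }

  # planted co-regulated TF programs: on/off steps at the two major
  # transitions (mitotic cells lose one program at meiotic entry, meiotic
  # cells lose the other at spermiogenesis)
  tf_module <- list(mitotic = character(), meiotic = character())
  if (spec$tf_module_size > 0 && n_stage > 1) {
    pool <- setdiff(auto_ids, unlist(lapply(truth_degs, unlist),
                                     use.names = FALSE))
    n_mod <- min(2 * spec$tf_module_size, length(pool))
    picked <- sample(pool, n_mod)
    tf_module$mitotic <- picked[seq_len(ceiling(n_mod / 2))]
    tf_module$meiotic <- setdiff(picked, tf_module$mitotic)
    anno$is_tf[match(picked, anno$gene_id)] <- TRUE
    on_until <- function(last) stages %in%
      stage_codes()[seq_len(match(last, stage_codes()))]
    prof <- function(on) ifelse(on, spec$tf_module_tpm, 1) *
      stats::runif(1, 0.5, 1.5)
    for (g in tf_module$mitotic) M[g, ] <- prof(on_until("ePL"))
    on_meiotic <- stages %in% stage_codes()[11:15] # eP .. MI
    for (g in tf_module$meiotic) M[g, ] <- prof(on_meiotic)
  }

  # planted sex-linked categories
  sex_ids <- c(x_ids, y_ids)
  msci_truth <- data.frame(gene_id = character(), category = character(),
                           subtype = character(), stringsAsFactors = FALSE)
  Msex <- matrix(spec$silent_tpm, length(sex_ids), n_stage,
                 dimnames = list(sex_ids, stages))
  if (sum(spec$msci_counts) > 0) {
    planted <- sample(sex_ids, sum(spec$msci_counts))
    offset <- 0
    for (cat in names(spec$msci_counts)) {
      k <- spec$msci_counts[[cat]]
      if (k == 0) next
      genes <- planted[offset + seq_len(k)]; offset <- offset + k
      is_msci <- cat %in% c("MSCI_PMSC", "MSCI_ESCAPE_PMSC")
      n2 <- if (is_msci) round(k * spec$type2_fraction) else 0
      subtypes <- if (is_msci) {
        sample(rep(c("TYPE_II", "TYPE_I"), c(n2, k - n2)))
      } else rep(NA_character_, k)
      for (j in seq_len(k)) {
        prof <- plant_profile(cat, subtypes[j])
        Msex[genes[j], names(prof)[prof & names(prof) %in% stages]] <-
          spec$expressed_tpm
      }
      msci_truth <- rbind(msci_truth,
                          data.frame(gene_id = genes, category = cat,
                                     subtype = subtypes,
                                     stringsAsFactors = FALSE))
    }
  }
  M <- rbind(M, Msex)[endo_ids, , drop = FALSE]

  # rescale each stage column so endogenous TPM sums to 1e6, then re-impose
  # the planted sex-linked values exactly (their total is negligible)
  for (s in seq_len(n_stage)) {
    sex_sum <- sum(Msex[, s])
    M[auto_ids, s] <- M[auto_ids, s] * (1e6 - sex_sum) / sum(M[auto_ids, s])
  }

  # cells, size factors, expected counts
  n_cells <- n_stage * spec$cells_per_stage
  cell_stage <- rep(stages, each = spec$cells_per_stage)
  cell_ids <- sprintf("c%s_%03d", cell_stage,
                      sequence(rep(spec$cells_per_stage, n_stage)))
  factors <- stats::rlnorm(n_cells, meanlog = 0, sdlog = spec$factor_sdlog)
  factors <- factors / mean(factors)

  spike_profile <- stats::rlnorm(spec$n_spikeins, log(5), 1.0)
  spike_profile <- spike_profile / sum(spike_profile) * spec$spike_total

  lam_endo <- M[, cell_stage, drop = FALSE] *
    rep(spec$base_depth / 1e6 * factors, each = length(endo_ids))
  lam_spike <- outer(spike_profile, factors)

  draw <- function(lam, size) {
    if (spec$noiseless) round(lam)
    else {
      x <- matrix(stats::rnbinom(length(lam), mu = lam, size = size),
                  nrow(lam), ncol(lam))
      if (spec$dropout > 0) {
        x[stats::runif(length(x)) < spec$dropout] <- 0L
      }
      x
    }
  }
  counts <- rbind(draw(lam_endo, spec$dispersion),
                  draw(lam_spike, spec$spike_dispersion))
  cm <- count_matrix(counts, c(endo_ids, spike_ids), cell_ids)

  meta <- data.frame(
    cell_id = cell_ids,
    stage = cell_stage,
    cluster = unname(stage_cluster_map()[cell_stage]),
    mapping_rate = stats::runif(n_cells, 0.55, 0.95),
    batch = "b1",
    stringsAsFactors = FALSE)

  list(counts = cm, cell_meta = meta, gene_annotation = anno,
       truth = list(msci = msci_truth, degs = truth_degs,
                    tf_module = tf_module,
                    factors = stats::setNames(factors, cell_ids),
                    stage_mean_tpm = M))
}

#' Simulate a splice-event inclusion table with planted transitions
#'
#' Builds a merged-sample PSI table in which, for each planted
#' (gene, transition, situation) triple, the gene's considered event sets in
#' the two flanking samples satisfy that situation's definition exactly.
#' In-band values are drawn within \[15, 85\] and out-of-band within
#' \[0, 8\], so PSI noise never crosses the \[10, 90\] consideration band and
#' labels are preserved. Coverage flags are dropped at `coverage_missing_rate`
#' everywhere except the samples that define a planted label.
#'
#' @param psi_stages Ordered merged-sample (stage) names; default 13 stages
#'   spanning mitotic, meiotic and postmeiotic phases.
#' @param per_situation Planted genes per situation (1..5).
#' @param background_genes Extra genes with two stable in-band events
#'   everywhere (situation 1 at every transition).
#' @param coverage_missing_rate Probability a non-critical coverage flag is
#'   dropped.
#' @param seed Optional seed.
#' @return List with `table` (a [splice_table()]) and `truth` (data.frame of
#'   planted gene_id, sample_x, sample_y, situation).
#' @export
simulate_psi_table <- function(psi_stages = c("A1", "In", "BS", "G1", "mPL",
                                              "L", "Z", "eP", "mP", "lP",
                                              "D", "MII", "RS2"),
                               per_situation = 6,
                               background_genes = 20,
                               coverage_missing_rate = 0.05,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stage_index(psi_stages)
  n_s <- length(psi_stages)
  if (n_s < 4) sd_stop("need at least 4 merged samples", "spermdyn_config_error")

  inband <- function(n) stats::runif(n, 15, 85)
  outband <- function(n) stats::runif(n, 0, 8)

  events <- list(); psi <- list(); critical <- list()
  add_event <- function(gene, eid, type, in_samples) {
    v <- outband(n_s)
    v[in_samples] <- inband(length(in_samples))
    events[[length(events) + 1L]] <<- data.frame(
      gene_id = gene, event_id = eid, event_type = type,
      stringsAsFactors = FALSE)
    psi[[length(psi) + 1L]] <<- v
    critical[[length(critical) + 1L]] <<- in_samples
  }

  truth <- list()
  g <- 0
  for (sit in 1:5) {
    for (r in seq_len(per_situation)) {
      g <- g + 1
      gene <- sprintf("asg%03d", g)
      ix <- sample(seq_len(n_s - 1), 1); iy <- ix + 1
      support <- setdiff(seq_len(n_s), c(ix, iy))[1:2]
      if (sit == 1) {        # same non-empty sets in x and y
        add_event(gene, "e1", "EEJ", c(support, ix, iy))
        add_event(gene, "e2", "IR", c(support, ix, iy))
      } else if (sit == 2) { # same types, different event sets
        add_event(gene, "e1", "EEJ", c(support, ix))
        add_event(gene, "e2", "EEJ", c(support, iy))
      } else if (sit == 3) { # type change
        add_event(gene, "e1", "EEJ", c(support, ix))
        add_event(gene, "e2", "IR", c(support, iy))
      } else if (sit == 4) { # events to none
        add_event(gene, "e1", "EEJ", c(support, ix))
      } else {               # none to events
        add_event(gene, "e1", "EEJ", c(support, iy))
      }
      truth[[length(truth) + 1L]] <-
        data.frame(gene_id = gene, sample_x = psi_stages[ix],
                   sample_y = psi_stages[iy], situation = sit,
                   stringsAsFactors = FALSE)
      # the transition samples are critical for every event of this gene
      n_ev <- if (sit %in% 1:3) 2 else 1
      for (e in seq_len(n_ev)) {
        k <- length(critical) - n_ev + e
        critical[[k]] <- union(critical[[k]], c(ix, iy))
      }
    }
  }
  for (b in seq_len(background_genes)) {
    gene <- sprintf("bg%03d", b)
    add_event(gene, "e1", "EEJ", seq_len(n_s))
    critical[[length(critical)]] <- integer(0) # background coverage may drop
    add_event(gene, "e2", "ALTD", seq_len(n_s))
    critical[[length(critical)]] <- integer(0)
  }

  events <- do.call(rbind, events)
  psi <- do.call(rbind, psi)
  covered <- matrix(TRUE, nrow(psi), n_s)
  if (coverage_missing_rate > 0) {
    drop <- matrix(stats::runif(length(covered)) < coverage_missing_rate,
                   nrow(covered), ncol(covered))
    for (k in seq_len(nrow(covered))) drop[k, critical[[k]]] <- FALSE
    covered[drop] <- FALSE
  }
  colnames(psi) <- psi_stages
  colnames(covered) <- psi_stages
  list(table = splice_table(events, psi, covered),
       truth = do.call(rbind, truth))
}

#' Simulate spermatid populations with or without transcript sharing
#'
#' Half the cells are X-bearing, half Y-bearing. With sharing, every cell
#' draws X- and Y-linked counts from the same means (transcripts equalized
#' through intercellular bridges). Without sharing, the producing cells
#' retain `x_ratio` times the common mean while the other half get
#' (2 - `x_ratio`) times it, conserving the total output: at the default
#' ratio 2 this is complete non-sharing (X-bearing cells have 2x the common
#' X-linked means and zero Y-linked means, and symmetrically), while ratios
#' between 1 and 2 model partial sharing.
#'
#' @param n_cells Cells per stage (even).
#' @param stages Spermatid/metaphase stage codes to simulate.
#' @param sharing Logical: transcripts shared between spermatids?
#' @param n_x_genes,n_y_genes,n_autosomal_genes Gene counts.
#' @param x_ratio Load ratio retained by the producing cells under no
#'   sharing, in (1, 2]; 2 = complete non-sharing.
#' @param dispersion,dropout NB noise parameters; `noiseless` disables both.
#' @param noiseless If TRUE, counts are rounded expected values.
#' @param seed Optional seed.
#' @return List with `counts`, `cell_meta`, `gene_annotation` and `truth`
#'   (per-cell gamete chromosome and the sharing flag).
#' @export
simulate_sharing_scenario <- function(n_cells = 100, stages = "RS2",
                                      sharing = TRUE,
                                      n_x_genes = 30, n_y_genes = 10,
                                      n_autosomal_genes = 200,
                                      x_ratio = 2,
                                      dispersion = 0.5, dropout = 0.1,
                                      noiseless = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stage_index(stages)
  if (x_ratio <= 1 || x_ratio > 2) {
    sd_stop("x_ratio must lie in (1, 2]", "spermdyn_config_error")
  }
  auto_ids <- sprintf("gA%04d", seq_len(n_autosomal_genes))
  x_ids <- sprintf("gX%03d", seq_len(n_x_genes))
  y_ids <- sprintf("gY%03d", seq_len(n_y_genes))
  anno <- data.frame(
    gene_id = c(auto_ids, x_ids, y_ids),
    chromosome = c(sample(as.character(1:19), n_autosomal_genes, TRUE),
                   rep("X", n_x_genes), rep("Y", n_y_genes)),
    biotype = "protein_coding",
    is_tf = FALSE, is_splicing_regulator = FALSE, is_surface_marker = FALSE,
    stringsAsFactors = FALSE)

  mu_auto <- stats::rlnorm(n_autosomal_genes, log(30), 1)
  mu_x <- stats::rlnorm(n_x_genes, log(30), 0.6)
  mu_y <- stats::rlnorm(n_y_genes, log(30), 0.6)

  all_cells <- character(); all_stage <- character(); gamete <- character()
  blocks <- list()
  for (s in stages) {
    ids <- sprintf("c%s_%03d", s, seq_len(n_cells))
    gam <- rep(c("X-bearing", "Y-bearing"), length.out = n_cells)
    lam <- matrix(0, n_autosomal_genes + n_x_genes + n_y_genes, n_cells,
                  dimnames = list(c(auto_ids, x_ids, y_ids), ids))
    lam[auto_ids, ] <- mu_auto
    if (sharing) {
      lam[x_ids, ] <- mu_x
      lam[y_ids, ] <- mu_y
    } else {
      xb <- gam == "X-bearing"
      lam[x_ids, xb] <- mu_x * x_ratio
      lam[y_ids, xb] <- mu_y * (2 - x_ratio)
      lam[x_ids, !xb] <- mu_x * (2 - x_ratio)
      lam[y_ids, !xb] <- mu_y * x_ratio
    }
    blocks[[s]] <- lam
    all_cells <- c(all_cells, ids)
    all_stage <- c(all_stage, rep(s, n_cells))
    gamete <- c(gamete, gam)
  }
  lam <- do.call(cbind, blocks)
  counts <- if (noiseless) round(lam) else {
    x <- matrix(stats::rnbinom(length(lam), mu = lam, size = dispersion),
                nrow(lam), ncol(lam))
    if (dropout > 0) x[stats::runif(length(x)) < dropout] <- 0L
    x
  }
  cm <- count_matrix(counts, rownames(lam), all_cells)
  meta <- data.frame(cell_id = all_cells, stage = all_stage,
                     mapping_rate = stats::runif(length(all_cells), 0.55, 0.95),
                     batch = "b1", stringsAsFactors = FALSE)
  list(counts = cm, cell_meta = meta, gene_annotation = anno,
       truth = list(gamete = stats::setNames(gamete, all_cells),
                    sharing = sharing))
}
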