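DECOY_CATEGORIES <- c("mre_below_min", "single_database_only",
                      "direction_discordant", "correlation_below_threshold",
                      "not_differential")

#' Configuration for the synthetic paired-design ceRNA dataset
#'
#' The generator emulates the study conditions of a paired tumour/normal
#' profiling experiment: six patients, three RNA layers measured as raw
#' counts, planted concordant differential expression (lncRNA and mRNA with
#' the same sign, miRNA opposite), latent-factor-coupled lncRNA-mRNA profiles
#' for planted ceRNA triads, interaction records with >= 3 MREs on true edges,
#' and decoy triads each violating exactly one ceRNA filter.
#'
#' Counts follow a hierarchical negative-binomial model: a per-gene,
#' per-patient gamma biological factor with squared coefficient of variation
#' `dispersion` is shared between the tumour and normal sample of a patient
#' (tissue pairs from one patient share their biological state), and counts
#' are Poisson around the resulting mean — so each sample is marginally
#' NB(`dispersion`) while within-pair tumour/normal ratios carry only
#' counting noise, as expected for a paired design.
#'
#' @param n_pairs number of tumour/normal pairs (default 6).
#' @param n_features named vector: features per layer (defaults 2000 lncRNA,
#'   300 miRNA, 5000 mRNA).
#' @param n_triads planted ceRNA triads (default 20).
#' @param n_decoys_per_filter decoy triads per violated filter (default 20).
#' @param n_extra_de additional planted DE features per layer, outside any
#'   triad (defaults 25 lncRNA, 40 miRNA, 150 mRNA).
#' @param de_lfc_range |log2FC| range for the extra planted DE features
#'   (default `[1.5, 6]`; the lower bound exceeds the DE cut-off of 1).
#' @param corr_decoy_lfc_range |log2FC| range for the lncRNA and mRNA of
#'   correlation decoys (default `[3.5, 4]`, up-regulated; bounded so the
#'   decorrelating patient factors keep counts well away from zero).
#' @param triad_lfc_range |log2FC| range for triad and decoy members (default
#'   `[3.5, 6]`): surviving ceRNA triads are by construction the strongly and
#'   consistently dysregulated ones, and effects in this range are reliably
#'   detected by the fixed-dispersion exact test in every pair.
#' @param dispersion NB dispersion of the count model (default 0.16).
#' @param libsize_range per-sample library-size range (default 8e5-1.2e6).
#' @param coupling_sd latent-factor coupling strength: sd (log2 scale) of the
#'   per-patient multiplier shared by a triad's lncRNA and mRNA in tumour
#'   samples (default 0.35, which keeps the tumour-only lncRNA-mRNA
#'   correlation above 0.8 while leaving per-pair fold changes dominated by
#'   the planted effect); the triad miRNA receives the reciprocal effect
#'   attenuated by `mi_attenuation`.
#' @param mi_attenuation attenuation of the reciprocal miRNA effect (default 0.5).
#' @param planted_cpm_range baseline abundance range (CPM) of planted
#'   features (default 200-1500; planted features emulate robustly expressed
#'   transcripts).
#' @param background_meanlog,background_sdlog log-normal parameters of
#'   background relative abundances.
#' @param mre_extra_mean true-edge MRE counts are `3 + Poisson(mre_extra_mean)`.
#' @param n_background_edges random interaction records among non-planted
#'   features, per edge type (default 300).
#' @param n_terms named vector: annotation terms per category.
#' @param term_size_range term sizes (default 10-120 genes).
#' @param n_signal_terms terms per category enriched for triad mRNAs (default 3).
#' @param ct_pairs tumour/normal pairs in the simulated Ct table (default 16).
#' @param ct_noise_sd Gaussian noise sd on target Ct values, in cycles
#'   (default 0.2).
#' @param ct_patient_sd sd of an optional per-patient baseline delta-Ct
#'   shift, shared within a pair (default 0: measurement noise is the qPCR
#'   model's only stochastic term; set > 0 to probe robustness against
#'   patient-level baseline variation, which cancels in ddCt but not in
#'   cross-sample comparisons such as ROC).
#' @param ct_reference_ct reference-gene Ct (default 16 cycles).
#' @param ct_base_dct baseline target-minus-reference delta-Ct in normal
#'   tissue (default 10 cycles).
#' @param n_validation validation genes drawn from triad members for the Ct
#'   table (defaults 4 lncRNA, 8 mRNA).
#' @param seed RNG seed (Mersenne-Twister, pinned by the generator).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 6,
                       n_features = c(lncRNA = 2000, miRNA = 300, mRNA = 5000),
                       n_triads = 20, n_decoys_per_filter = 20,
                       n_extra_de = c(lncRNA = 25, miRNA = 40, mRNA = 150),
                       de_lfc_range = c(1.5, 6),
                       triad_lfc_range = c(3.5, 6),
                       corr_decoy_lfc_range = c(3.5, 4),
                       dispersion = 0.16,
                       libsize_range = c(8e5, 1.2e6),
                       coupling_sd = 0.35, mi_attenuation = 0.5,
                       planted_cpm_range = c(200, 1500),
                       background_meanlog = log(100), background_sdlog = 1.3,
                       mre_extra_mean = 2, n_background_edges = 300,
                       n_terms = c(pathway = 60, GO_BP = 40, GO_MF = 30, GO_CC = 30),
                       term_size_range = c(10, 120), n_signal_terms = 3,
                       ct_pairs = 16, ct_noise_sd = 0.2, ct_patient_sd = 0,
                       ct_reference_ct = 16, ct_base_dct = 10,
                       n_validation = c(lncRNA = 4, mRNA = 8),
                       seed = 1) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  stopifnot(n_pairs >= 1, all(cfg$n_features > 0), n_triads >= 0,
            n_decoys_per_filter >= 0, all(n_extra_de >= 0),
            dispersion >= 0, all(libsize_range > 0),
            de_lfc_range[1] > 1, diff(de_lfc_range) >= 0,
            triad_lfc_range[1] > 1, diff(triad_lfc_range) >= 0,
            coupling_sd >= 0, ct_pairs >= 2, ct_noise_sd >= 0)
  n_dec <- 5L * n_decoys_per_filter
  need <- c(lncRNA = n_triads + n_dec + unname(n_extra_de["lncRNA"]),
            miRNA = n_triads + n_dec + unname(n_extra_de["miRNA"]),
            mRNA = n_triads + n_dec + unname(n_extra_de["mRNA"]))
  over <- need > cfg$n_features[names(need)]
  if (any(over))
    stop_named("infeasible config: ", need[over][1], " planted features exceed ",
               cfg$n_features[names(need)[over][1]], " available in layer ",
               names(need)[over][1])
  cfg
}

# Internal: assign planted roles within one layer.
# Returns a data frame feature_id/role/idx aligned with planting order:
# triads first, then decoys by category, then extra DE.
.assign_roles <- function(ids, n_triads, n_dec_per, n_extra) {
  n_planted <- n_triads + 5L * n_dec_per + n_extra
  planted <- sample(ids, n_planted)
  role <- c(rep("triad", n_triads),
            rep(paste0("decoy:", DECOY_CATEGORIES), each = n_dec_per),
            rep("extra", n_extra))
  data.frame(feature_id = planted, role = role, stringsAsFactors = FALSE)
}

#' Simulate a full multi-layer paired dataset with known planted structure
#'
#' See [sim_config()] for the generative model. The returned `truth` is the
#' oracle for recovery tests: the planted DE feature sets with signs, the
#' planted triads, the decoy records with the single filter each violates,
#' and the validation genes with their planted fold changes.
#'
#' @param config a [sim_config()].
#' @return List with `matrices` (named list of [expression_matrix()]),
#'   `design` ([paired_design()]), `interactions`
#'   ([interaction_records()]), `annotations` ([annotation_set()]), `truth`
#'   (list: `de`, `triads`, `decoys`, `validation`) and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_pinned_seed(config$seed, .simulate_dataset_impl(config))
}

.simulate_dataset_impl <- function(cfg) {
  n_pairs <- cfg$n_pairs
  patients <- sprintf("P%02d", seq_len(n_pairs))
  design <- paired_design(patients, paste0("T_", patients), paste0("N_", patients))
  samples <- c(design$tumor, design$normal)
  is_tumor <- c(rep(TRUE, n_pairs), rep(FALSE, n_pairs))
  patient_of <- rep(seq_len(n_pairs), 2L)

  ids <- list(lncRNA = sprintf("lnc%05d", seq_len(cfg$n_features["lncRNA"])),
              miRNA = sprintf("miR%04d", seq_len(cfg$n_features["miRNA"])),
              mRNA = sprintf("gene%05d", seq_len(cfg$n_features["mRNA"])))
  roles <- list(
    lncRNA = .assign_roles(ids$lncRNA, cfg$n_triads, cfg$n_decoys_per_filter,
                           cfg$n_extra_de["lncRNA"]),
    miRNA = .assign_roles(ids$miRNA, cfg$n_triads, cfg$n_decoys_per_filter,
                          cfg$n_extra_de["miRNA"]),
    mRNA = .assign_roles(ids$mRNA, cfg$n_triads, cfg$n_decoys_per_filter,
                         cfg$n_extra_de["mRNA"]))

  n_tri <- cfg$n_triads
  n_dec <- cfg$n_decoys_per_filter
  n_units <- n_tri + 5L * n_dec  # triads + decoys, in planting order
  unit_cat <- c(rep("triad", n_tri), rep(DECOY_CATEGORIES, each = n_dec))
  unit_sign <- sample(c(1, -1), n_units, replace = TRUE)
  rmag <- function(k) stats::runif(k, cfg$triad_lfc_range[1], cfg$triad_lfc_range[2])
  unit_lfc <- data.frame(lnc = unit_sign * rmag(n_units),
                         mi = -unit_sign * rmag(n_units),
                         m = unit_sign * rmag(n_units))
  # per-category tweaks
  notdiff_member <- (seq_len(n_dec) - 1L) %% 3L + 1L  # 1=lnc, 2=mi, 3=m
  for (u in seq_len(n_units)) {
    cat_u <- unit_cat[u]
    if (cat_u == "direction_discordant") unit_lfc$m[u] <- -unit_lfc$m[u]
    if (cat_u == "correlation_below_threshold") {
      # up-regulated with a bounded effect, so the anti-correlated patient
      # factors below cannot push any sample into the low-count regime
      unit_lfc$lnc[u] <- stats::runif(1, cfg$corr_decoy_lfc_range[1],
                                      cfg$corr_decoy_lfc_range[2])
      unit_lfc$m[u] <- stats::runif(1, cfg$corr_decoy_lfc_range[1],
                                    cfg$corr_decoy_lfc_range[2])
      unit_lfc$mi[u] <- -abs(unit_lfc$mi[u])
    }
    if (cat_u == "not_differential") {
      j <- notdiff_member[u - match("not_differential", unit_cat) + 1L]
      unit_lfc[u, j] <- 0
    }
  }
  extra_lfc <- lapply(cfg$n_extra_de, function(k)
    sample(c(1, -1), k, replace = TRUE) *
      stats::runif(k, cfg$de_lfc_range[1], cfg$de_lfc_range[2]))

  # latent per-patient factors: one coupling vector per triad-like unit;
  # correlation decoys instead use a balanced +/- patient assignment whose
  # magnitude is chosen so that cov(lnc, m) = d_l*d_m/4 - sigma^2 = -1,
  # i.e. the true lnc-mRNA correlation is slightly negative
  z_unit <- matrix(stats::rnorm(n_units * n_pairs), n_units, n_pairs)
  for (u in which(unit_cat == "correlation_below_threshold"))
    z_unit[u, ] <- sample(rep(c(1, -1), length.out = n_pairs))
  corr_sigma <- sqrt(abs(unit_lfc$lnc * unit_lfc$m) / 4 + 1)

  layer_lfc <- function(layer, col) {
    r <- roles[[layer]]
    lfc <- numeric(nrow(r))
    lfc[r$role != "extra"] <- unit_lfc[[col]][seq_len(n_units)]
    lfc[r$role == "extra"] <- extra_lfc[[layer]]
    stats::setNames(lfc, r$feature_id)
  }
  planted_lfc <- list(lncRNA = layer_lfc("lncRNA", "lnc"),
                      miRNA = layer_lfc("miRNA", "mi"),
                      mRNA = layer_lfc("mRNA", "m"))

  matrices <- list()
  for (layer in c("lncRNA", "miRNA", "mRNA")) {
    n_feat <- length(ids[[layer]])
    r <- roles[[layer]]
    planted_idx <- match(r$feature_id, ids[[layer]])
    cpm <- stats::rlnorm(n_feat, cfg$background_meanlog, cfg$background_sdlog)
    planted_cpm <- exp(stats::runif(nrow(r), log(cfg$planted_cpm_range[1]),
                                    log(cfg$planted_cpm_range[2])))
    cpm[planted_idx] <- 0
    cpm <- cpm / sum(cpm) * (1e6 - sum(planted_cpm))
    cpm[planted_idx] <- planted_cpm

    lib <- stats::runif(length(samples), cfg$libsize_range[1], cfg$libsize_range[2])
    mean_mat <- cpm %o% (lib * 1e-6)
    dimnames(mean_mat) <- list(ids[[layer]], samples)

    # tumour fold changes
    lfc_vec <- numeric(n_feat)
    lfc_vec[planted_idx] <- planted_lfc[[layer]]
    mean_mat[, is_tumor] <- mean_mat[, is_tumor] * 2^lfc_vec

    # biological patient factors (gamma, CV^2 = phi), shared within a pair;
    # triad-like units use the structured latent factors instead
    structured <- planted_idx[r$role != "extra"]
    if (cfg$dispersion > 0) {
      b <- matrix(stats::rgamma(n_feat * n_pairs, shape = 1 / cfg$dispersion,
                                rate = 1 / cfg$dispersion), n_feat, n_pairs)
      b[structured, ] <- 1
      mean_mat <- mean_mat * b[, patient_of]
    }

    # structured latent factors
    member_col <- c(lncRNA = "lnc", miRNA = "mi", mRNA = "m")[layer]
    for (u in seq_len(n_units)) {
      g <- planted_idx[u]
      cat_u <- unit_cat[u]
      z <- z_unit[u, ]
      if (cat_u == "correlation_below_threshold" && member_col != "mi") {
        # anti-correlated patient-shared factors on lncRNA (+) and mRNA (-)
        # in ALL samples: cancels within pairs, decouples the two profiles
        s_dir <- if (member_col == "lnc") 1 else -1
        mean_mat[g, ] <- mean_mat[g, ] * 2^(s_dir * corr_sigma[u] * z[patient_of])
      } else {
        # tumour-only coupling shared by lncRNA and mRNA, reciprocal
        # (attenuated) on the miRNA
        eff <- if (member_col == "mi") -cfg$mi_attenuation * cfg$coupling_sd
               else cfg$coupling_sd
        mean_mat[g, is_tumor] <- mean_mat[g, is_tumor] *
          2^(eff * z[patient_of[is_tumor]])
      }
    }

    counts <- matrix(stats::rpois(length(mean_mat), mean_mat),
                     n_feat, length(samples),
                     dimnames = list(ids[[layer]], samples))
    matrices[[layer]] <- expression_matrix(counts, layer)
  }

  # interaction records -------------------------------------------------
  units <- data.frame(unit = seq_len(n_units), category = unit_cat,
                      lncRNA_id = roles$lncRNA$feature_id[seq_len(n_units)],
                      miRNA_id = roles$miRNA$feature_id[seq_len(n_units)],
                      mRNA_id = roles$mRNA$feature_id[seq_len(n_units)],
                      stringsAsFactors = FALSE)
  mre_true <- function(k) 3L + stats::rpois(k, cfg$mre_extra_mean)
  rec <- list()
  dec_i <- 0L
  for (u in seq_len(n_units)) {
    cat_u <- units$category[u]
    if (cat_u == "triad") dec_i <- 0L else if (u == match(cat_u, unit_cat)) dec_i <- 0L
    dec_i <- dec_i + 1L
    mre_lm <- mre_true(1L)
    mre_m1 <- mre_true(1L)
    mre_m2 <- mre_true(1L)
    dbs <- c("miranda_like", "targetscan_like")
    if (cat_u == "mre_below_min") {
      if (dec_i %% 2L == 1L) mre_lm <- sample(0:2, 1L)
      else mre_m1 <- sample(0:2, 1L)  # min across databases then < 3
    }
    rec[[length(rec) + 1L]] <-
      data.frame(source = units$lncRNA_id[u], target = units$miRNA_id[u],
                 edge_type = "lnc_mi", mre_count = mre_lm,
                 database = "mircode_like", stringsAsFactors = FALSE)
    if (cat_u == "single_database_only") {
      rec[[length(rec) + 1L]] <-
        data.frame(source = units$miRNA_id[u], target = units$mRNA_id[u],
                   edge_type = "mi_m", mre_count = mre_m1,
                   database = dbs[dec_i %% 2L + 1L], stringsAsFactors = FALSE)
    } else {
      rec[[length(rec) + 1L]] <-
        data.frame(source = rep(units$miRNA_id[u], 2L),
                   target = rep(units$mRNA_id[u], 2L),
                   edge_type = "mi_m",
                   mre_count = c(min(mre_m1, mre_m2), max(mre_m1, mre_m2)),
                   database = dbs, stringsAsFactors = FALSE)
    }
  }
  # background records among non-planted features only (they can never form
  # a fully differential triad, so they exercise the filters without adding
  # accidental true positives)
  bg_ids <- lapply(c("lncRNA", "miRNA", "mRNA"), function(layer)
    setdiff(ids[[layer]], roles[[layer]]$feature_id))
  names(bg_ids) <- c("lncRNA", "miRNA", "mRNA")
  nbg <- cfg$n_background_edges
  if (nbg > 0) {
    rec[[length(rec) + 1L]] <-
      data.frame(source = sample(bg_ids$lncRNA, nbg, replace = TRUE),
                 target = sample(bg_ids$miRNA, nbg, replace = TRUE),
                 edge_type = "lnc_mi",
                 mre_count = stats::rpois(nbg, 3),
                 database = "mircode_like", stringsAsFactors = FALSE)
    both <- stats::runif(nbg) < 0.5
    db_pick <- sample(c("miranda_like", "targetscan_like"), nbg, replace = TRUE)
    mi_src <- sample(bg_ids$miRNA, nbg, replace = TRUE)
    m_tgt <- sample(bg_ids$mRNA, nbg, replace = TRUE)
    rec[[length(rec) + 1L]] <-
      data.frame(source = c(mi_src, mi_src[both]),
                 target = c(m_tgt, m_tgt[both]),
                 edge_type = "mi_m",
                 mre_count = stats::rpois(nbg + sum(both), 3),
                 database = c(db_pick, ifelse(db_pick[both] == "miranda_like",
                                              "targetscan_like", "miranda_like")),
                 stringsAsFactors = FALSE)
  }
  interactions <- interaction_records(do.call(rbind, rec))
  interactions <- interactions[!duplicated(paste(interactions$source,
                                                 interactions$target,
                                                 interactions$database)), ]
  rownames(interactions) <- NULL
  interactions <- interaction_records(interactions)

  # annotations ----------------------------------------------------------
  triad_m <- units$mRNA_id[units$category == "triad"]
  ann <- list()
  for (cat in names(cfg$n_terms)) {
    k <- cfg$n_terms[[cat]]
    sizes <- sample(seq(cfg$term_size_range[1], cfg$term_size_range[2]), k,
                    replace = TRUE)
    members <- vector("list", k)
    for (i in seq_len(k)) {
      base <- sample(ids$mRNA, sizes[i])
      if (i <= cfg$n_signal_terms && length(triad_m) > 0) {
        hit <- sample(triad_m, max(1L, ceiling(length(triad_m) / 2)))
        base <- unique(c(hit, base))
      }
      members[[i]] <- base
    }
    ann[[cat]] <- annotation_set(
      term_id = sprintf("%s_T%03d", cat, seq_len(k)),
      term_name = sprintf("synthetic %s term %d", cat, seq_len(k)),
      category = cat, members = members)
  }
  annotations <- do.call(c_annotation_sets, ann)

  # truth ----------------------------------------------------------------
  de_truth <- do.call(rbind, lapply(c("lncRNA", "miRNA", "mRNA"), function(layer) {
    r <- roles[[layer]]
    if (nrow(r) == 0) return(NULL)
    lfc <- planted_lfc[[layer]]
    data.frame(feature_id = r$feature_id, layer = layer,
               log2fc = unname(lfc[r$feature_id]),
               direction = ifelse(lfc[r$feature_id] > 0, "up",
                                  ifelse(lfc[r$feature_id] < 0, "down", "none")),
               role = r$role, stringsAsFactors = FALSE)
  }))
  if (is.null(de_truth))
    de_truth <- data.frame(feature_id = character(0), layer = character(0),
                           log2fc = numeric(0), direction = character(0),
                           role = character(0), stringsAsFactors = FALSE)
  de_truth <- de_truth[de_truth$log2fc != 0, , drop = FALSE]
  rownames(de_truth) <- NULL

  tri_sel <- units$category == "triad"
  triads_truth <- data.frame(
    triad_id = sprintf("triad%03d", seq_len(sum(tri_sel))),
    units[tri_sel, c("lncRNA_id", "miRNA_id", "mRNA_id")],
    lfc_lnc = unit_lfc$lnc[tri_sel], lfc_mi = unit_lfc$mi[tri_sel],
    lfc_m = unit_lfc$m[tri_sel], stringsAsFactors = FALSE)
  rownames(triads_truth) <- NULL
  dec_sel <- units$category != "triad"
  decoys_truth <- data.frame(
    decoy_id = sprintf("decoy%03d", seq_len(sum(dec_sel))),
    category = units$category[dec_sel],
    units[dec_sel, c("lncRNA_id", "miRNA_id", "mRNA_id")],
    stringsAsFactors = FALSE)
  rownames(decoys_truth) <- NULL

  val <- rbind(
    if (cfg$n_validation["lncRNA"] > 0 && sum(tri_sel) > 0)
      data.frame(gene_id = sample(triads_truth$lncRNA_id,
                                  min(cfg$n_validation["lncRNA"], sum(tri_sel))),
                 layer = "lncRNA", stringsAsFactors = FALSE),
    if (cfg$n_validation["mRNA"] > 0 && sum(tri_sel) > 0)
      data.frame(gene_id = sample(triads_truth$mRNA_id,
                                  min(cfg$n_validation["mRNA"], sum(tri_sel))),
                 layer = "mRNA", stringsAsFactors = FALSE))
  if (!is.null(val) && nrow(val) > 0) {
    all_lfc <- c(planted_lfc$lncRNA, planted_lfc$mRNA)
    val$fold <- 2^unname(all_lfc[val$gene_id])
    rownames(val) <- NULL
  } else {
    val <- data.frame(gene_id = character(0), layer = character(0),
                      fold = numeric(0), stringsAsFactors = FALSE)
  }

  list(matrices = matrices, design = design, interactions = interactions,
       annotations = annotations,
       truth = list(de = de_truth, triads = triads_truth,
                    decoys = decoys_truth, validation = val,
                    rng = "Mersenne-Twister/Inversion/Rejection",
                    note = paste("distributional choices are synthetic stand-ins;",
                                 "no real-data noise structure is emulated")),
       config = cfg)
}

#' Simulate a qPCR Ct table from planted truth
#'
#' Constructs Ct values whose 2^(-ddCt) fold changes recover the planted
#' validation folds up to Gaussian Ct noise: for patient i and gene g with
#' planted fold F, the normal-sample delta-Ct is `ct_base_dct + b_gi` (with a
#' per-patient baseline shift b shared by the pair) and the tumour delta-Ct
#' subtracts log2(F); target Ct values then receive independent N(0,
#' `noise_sd`) measurement noise. With zero noise the fold is recovered
#' exactly.
#'
#' @param config a [sim_config()]; `ct_pairs`, `ct_noise_sd`,
#'   `ct_patient_sd`, `ct_reference_ct`, `ct_base_dct` are used.
#' @param truth the `truth` element of [simulate_dataset()] (its
#'   `validation` table supplies genes and folds), or `NULL` when `folds` is
#'   given.
#' @param folds optional data frame `gene_id`, `fold` overriding the
#'   validation genes.
#' @param noise_sd Ct noise sd in cycles (default `config$ct_noise_sd`).
#' @param seed RNG seed (default `config$seed + 1`).
#' @return A [ct_table()].
#' @export
simulate_ct_table <- function(config = sim_config(), truth = NULL, folds = NULL,
                              noise_sd = config$ct_noise_sd,
                              seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(folds)) {
    if (is.null(truth) || is.null(truth$validation) || nrow(truth$validation) == 0)
      stop_named("truth contains no validation genes; supply `folds`")
    folds <- truth$validation[, c("gene_id", "fold")]
  }
  stopifnot(all(c("gene_id", "fold") %in% names(folds)), all(folds$fold > 0))
  with_pinned_seed(seed, {
    n <- config$ct_pairs
    patients <- sprintf("ctP%02d", seq_len(n))
    rows <- list()
    for (g in seq_len(nrow(folds))) {
      b <- stats::rnorm(n, 0, config$ct_patient_sd)
      dct_n <- config$ct_base_dct + b
      dct_t <- dct_n - log2(folds$fold[g])
      noise_t <- stats::rnorm(n, 0, noise_sd)
      noise_n <- stats::rnorm(n, 0, noise_sd)
      rows[[g]] <- data.frame(
        sample_id = c(paste0(patients, "_T"), paste0(patients, "_N")),
        patient_id = rep(patients, 2L),
        group = rep(c("tumor", "normal"), each = n),
        gene_id = folds$gene_id[g],
        ct_target = config$ct_reference_ct + c(dct_t + noise_t, dct_n + noise_n),
        ct_reference = config$ct_reference_ct,
        stringsAsFactors = FALSE)
    }
    ct_table(do.call(rbind, rows))
  })
}

#' Write / read a simulated dataset as plain-text files
#'
#' Serializes every component in the formats the pipeline consumes (count
#' TSVs, design TSV, interaction TSV, one GMT per category) plus the truth
#' manifest (`truth_de.tsv`, `truth_triads.tsv`, `truth_decoys.tsv`,
#' `truth_validation.tsv`), so recovery tests can run from files without
#' sharing memory with the generator.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (layer in names(dataset$matrices))
    write_expression_matrix(dataset$matrices[[layer]],
                            file.path(dir, paste0("counts_", layer, ".tsv")))
  write_design(dataset$design, file.path(dir, "design.tsv"))
  write_interactions(dataset$interactions, file.path(dir, "interactions.tsv"))
  ann <- dataset$annotations
  for (cat in unique(ann$category)) {
    sel <- ann$category == cat
    write_gmt(annotation_set(ann$term_id[sel], ann$term_name[sel], cat,
                             ann$members[sel]),
              file.path(dir, paste0(cat, ".gmt")))
  }
  write_truth(dataset$truth, dir)
  invisible(dir)
}

#' @rdname write_dataset
#' @param truth the truth component of a dataset.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(truth$de, file.path(dir, "truth_de.tsv"))
  write_tsv(truth$triads, file.path(dir, "truth_triads.tsv"))
  write_tsv(truth$decoys, file.path(dir, "truth_decoys.tsv"))
  write_tsv(truth$validation, file.path(dir, "truth_validation.tsv"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_truth <- function(dir) {
  list(de = read_tsv_strict(file.path(dir, "truth_de.tsv"),
                            c("feature_id", "layer", "log2fc", "direction", "role"),
                            "truth"),
       triads = read_tsv_strict(file.path(dir, "truth_triads.tsv"),
                                c("triad_id", "lncRNA_id", "miRNA_id", "mRNA_id"),
                                "truth"),
       decoys = read_tsv_strict(file.path(dir, "truth_decoys.tsv"),
                                c("decoy_id", "category", "lncRNA_id", "miRNA_id",
                                  "mRNA_id"), "truth"),
       validation = read_tsv_strict(file.path(dir, "truth_validation.tsv"),
                                    c("gene_id", "layer", "fold"), "truth"))
}
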