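#' Parameters for ceRNA triad assembly
#'
#' @param min_mre minimum miRNA response element (MRE) count required on both
#'   the lncRNA-miRNA and the miRNA-mRNA edge (default 3).
#' @param min_pearson_r correlation threshold; a triad survives only if the
#'   Pearson correlation between its lncRNA and mRNA strictly exceeds this
#'   value (default 0.8).
#' @param target_dbs the two miRNA-target database tags whose intersection
#'   defines usable miRNA-mRNA pairs (default `miranda_like`,
#'   `targetscan_like`).
#' @param require_both_target_dbs require miRNA-mRNA pairs to be present under
#'   both tags (default `TRUE`); when `FALSE` a single database suffices and
#'   the pair's MRE count is the maximum observed.
#' @param corr_samples compute the lncRNA-mRNA correlation across `"all"`
#'   samples (tumour + normal, the default) or across `"tumor"` samples only.
#' @return A list of class `cerna_params`.
#' @export
cerna_params <- function(min_mre = 3, min_pearson_r = 0.8,
                         target_dbs = c("miranda_like", "targetscan_like"),
                         require_both_target_dbs = TRUE,
                         corr_samples = c("all", "tumor")) {
  corr_samples <- match.arg(corr_samples)
  stopifnot(min_mre >= 0, min_pearson_r >= -1, min_pearson_r <= 1,
            length(target_dbs) == 2L)
  structure(list(min_mre = min_mre, min_pearson_r = min_pearson_r,
                 target_dbs = target_dbs,
                 require_both_target_dbs = require_both_target_dbs,
                 corr_samples = corr_samples),
            class = "cerna_params")
}

#' Intersect miRNA-mRNA pairs across the two target databases
#'
#' Only mRNAs targeted by a miRNA according to both configured databases are
#' usable for the ceRNA network. The retained MRE count for an intersected
#' pair is the minimum of the counts reported by the two databases (the
#' conservative choice).
#'
#' @param records [interaction_records()] of edge type `mi_m`.
#' @param target_dbs the two database tags (see [cerna_params()]).
#' @return Data frame of surviving pairs with columns `source`, `target`,
#'   `edge_type`, `mre_count`, `database = "both"`.
#' @export
intersect_target_dbs <- function(records,
                                 target_dbs = c("miranda_like", "targetscan_like")) {
  stopifnot(length(target_dbs) == 2L)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) > 0 && any(records$edge_type != "mi_m"))
    stop_named("intersect_target_dbs expects mi_m records only")
  unknown <- setdiff(unique(records$database), target_dbs)
  if (length(unknown) > 0)
    stop_named("unknown database tag '", unknown[1], "'; known tags: ",
               paste(target_dbs, collapse = ", "))
  empty <- data.frame(source = character(0), target = character(0),
                      edge_type = character(0), mre_count = integer(0),
                      database = character(0), stringsAsFactors = FALSE)
  if (nrow(records) == 0) return(empty)
  key <- paste(records$source, records$target, sep = "\r")
  in1 <- records$database == target_dbs[1]
  mre1 <- tapply(records$mre_count[in1], key[in1], max)
  mre2 <- tapply(records$mre_count[!in1], key[!in1], max)
  shared <- intersect(names(mre1), names(mre2))
  if (length(shared) == 0) return(empty)
  parts <- strsplit(shared, "\r", fixed = TRUE)
  out <- data.frame(source = vapply(parts, `[[`, "", 1L),
                    target = vapply(parts, `[[`, "", 2L),
                    edge_type = "mi_m",
                    mre_count = as.integer(pmin(mre1[shared], mre2[shared])),
                    database = "both", stringsAsFactors = FALSE)
  out[order(out$source, out$target), , drop = FALSE]
}

#' Pearson correlation between two expression profiles
#'
#' Plain product-moment correlation, with the degenerate cases the triad
#' filter must handle: fewer than 3 observations or a zero-variance profile
#' give `NA` (the triad is then excluded with reason
#' `correlation_undefined`).
#'
#' @param x,y numeric vectors of equal length.
#' @return Pearson r in `[-1, 1]`, or `NA` if undefined.
#' @export
pairwise_pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

#' Assemble surviving ceRNA triads from DE calls and interaction tables
#'
#' Candidate lncRNA-miRNA-mRNA triples are formed by joining lncRNA-miRNA
#' records with miRNA-mRNA records on the shared miRNA. Each candidate is then
#' audited against the ceRNA filters in order, and the first failing rule is
#' recorded as its exclusion reason:
#'
#' 1. all three members differentially expressed (`not_differential`);
#' 2. the miRNA-mRNA pair present in both target databases
#'    (`single_database_only`);
#' 3. lncRNA and mRNA with the same direction and the miRNA opposite
#'    (`direction_discordant`);
#' 4. Pearson correlation between the lncRNA and mRNA log2(CPM+1) profiles
#'    strictly greater than `min_pearson_r` (`correlation_below_threshold`,
#'    or `correlation_undefined` if the correlation does not exist);
#' 5. at least `min_mre` MREs on both edges (`mre_below_min`).
#'
#' @param de named list of `de_result` objects for layers `lncRNA`, `miRNA`
#'   and `mRNA` (see [call_de()]).
#' @param interactions an [interaction_records()] data frame holding both
#'   `lnc_mi` and `mi_m` records.
#' @param matrices named list of [expression_matrix()] objects (at least
#'   `lncRNA` and `mRNA`), used for the correlation filter.
#' @param design the [paired_design()] (defines which samples enter the
#'   correlation).
#' @param params a [cerna_params()] object.
#' @return An object of class `cerna_result`: list with `triads` (data frame
#'   `lncRNA_id`, `miRNA_id`, `mRNA_id`, `mre_lnc_mi`, `mre_mi_m`,
#'   `pearson_r`, `lnc_direction`, `mi_direction`, `m_direction`),
#'   `exclusions` (candidate ids + `reason`), and `params`.
#' @export
assemble_triads <- function(de, interactions, matrices, design,
                            params = cerna_params()) {
  stopifnot(inherits(params, "cerna_params"),
            all(c("lncRNA", "miRNA", "mRNA") %in% names(de)))
  interactions <- interaction_records(interactions)
  lnc_mi <- interactions[interactions$edge_type == "lnc_mi", , drop = FALSE]
  mi_m <- interactions[interactions$edge_type == "mi_m", , drop = FALSE]

  # collapse duplicate lnc_mi records (e.g. one per database) keeping max MRE
  if (nrow(lnc_mi) > 0) {
    key <- paste(lnc_mi$source, lnc_mi$target, sep = "\r")
    mre <- tapply(lnc_mi$mre_count, key, max)
    parts <- strsplit(names(mre), "\r", fixed = TRUE)
    lnc_mi <- data.frame(lncRNA_id = vapply(parts, `[[`, "", 1L),
                         miRNA_id = vapply(parts, `[[`, "", 2L),
                         mre_lnc_mi = as.integer(mre), stringsAsFactors = FALSE)
  } else {
    lnc_mi <- data.frame(lncRNA_id = character(0), miRNA_id = character(0),
                         mre_lnc_mi = integer(0))
  }

  both <- intersect_target_dbs(mi_m, params$target_dbs)
  both_key <- paste(both$source, both$target, sep = "\r")
  mre_both <- stats::setNames(both$mre_count, both_key)
  # union of mi_m pairs (any database) defines the candidate space, so that
  # single-database pairs are logged rather than silently absent
  if (nrow(mi_m) > 0) {
    ukey <- unique(paste(mi_m$source, mi_m$target, sep = "\r"))
    mre_any <- tapply(mi_m$mre_count, paste(mi_m$source, mi_m$target, sep = "\r"), max)
    parts <- strsplit(ukey, "\r", fixed = TRUE)
    mi_m_pairs <- data.frame(miRNA_id = vapply(parts, `[[`, "", 1L),
                             mRNA_id = vapply(parts, `[[`, "", 2L),
                             in_both = ukey %in% both_key,
                             mre_mi_m = as.integer(ifelse(ukey %in% both_key,
                                                          mre_both[ukey],
                                                          mre_any[ukey])),
                             stringsAsFactors = FALSE)
  } else {
    mi_m_pairs <- data.frame(miRNA_id = character(0), mRNA_id = character(0),
                             in_both = logical(0), mre_mi_m = integer(0))
  }
  if (!params$require_both_target_dbs) mi_m_pairs$in_both <- TRUE

  cand <- merge(lnc_mi, mi_m_pairs, by = "miRNA_id", sort = FALSE)
  cand <- cand[order(cand$lncRNA_id, cand$miRNA_id, cand$mRNA_id), , drop = FALSE]

  empty_triads <- data.frame(lncRNA_id = character(0), miRNA_id = character(0),
                             mRNA_id = character(0), mre_lnc_mi = integer(0),
                             mre_mi_m = integer(0), pearson_r = numeric(0),
                             lnc_direction = character(0),
                             mi_direction = character(0),
                             m_direction = character(0), stringsAsFactors = FALSE)
  empty_excl <- data.frame(lncRNA_id = character(0), miRNA_id = character(0),
                           mRNA_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  if (nrow(cand) == 0)
    return(structure(list(triads = empty_triads, exclusions = empty_excl,
                          params = params), class = "cerna_result"))

  dir_of <- function(res) stats::setNames(res$table$direction, res$table$feature_id)
  de_of <- function(res) stats::setNames(res$table$is_de, res$table$feature_id)
  dir_lnc <- dir_of(de$lncRNA); de_lnc <- de_of(de$lncRNA)
  dir_mi <- dir_of(de$miRNA); de_mi <- de_of(de$miRNA)
  dir_m <- dir_of(de$mRNA); de_m <- de_of(de$mRNA)

  samples <- if (params$corr_samples == "tumor") design$tumor
             else c(design$tumor, design$normal)
  logcpm_lnc <- cpm_matrix(matrices$lncRNA, tmm_factors(matrices$lncRNA), log = TRUE)
  logcpm_m <- cpm_matrix(matrices$mRNA, tmm_factors(matrices$mRNA), log = TRUE)

  n <- nrow(cand)
  reason <- character(n)
  rvals <- rep(NA_real_, n)
  is_de3 <- function(id, map) !is.na(map[id]) && map[id]
  for (i in seq_len(n)) {
    l <- cand$lncRNA_id[i]; mi <- cand$miRNA_id[i]; m <- cand$mRNA_id[i]
    if (!(is_de3(l, de_lnc) && is_de3(mi, de_mi) && is_de3(m, de_m))) {
      reason[i] <- "not_differential"; next
    }
    if (!cand$in_both[i]) { reason[i] <- "single_database_only"; next }
    if (!(dir_lnc[l] == dir_m[m] && dir_mi[mi] != dir_lnc[l])) {
      reason[i] <- "direction_discordant"; next
    }
    r <- pairwise_pearson(logcpm_lnc[l, samples], logcpm_m[m, samples])
    rvals[i] <- r
    if (is.na(r)) { reason[i] <- "correlation_undefined"; next }
    if (!(r > params$min_pearson_r)) { reason[i] <- "correlation_below_threshold"; next }
    if (cand$mre_lnc_mi[i] < params$min_mre || cand$mre_mi_m[i] < params$min_mre) {
      reason[i] <- "mre_below_min"; next
    }
    reason[i] <- ""
  }
  keep <- reason == ""
  triads <- data.frame(lncRNA_id = cand$lncRNA_id[keep],
                       miRNA_id = cand$miRNA_id[keep],
                       mRNA_id = cand$mRNA_id[keep],
                       mre_lnc_mi = cand$mre_lnc_mi[keep],
                       mre_mi_m = cand$mre_mi_m[keep],
                       pearson_r = rvals[keep],
                       lnc_direction = unname(dir_lnc[cand$lncRNA_id[keep]]),
                       mi_direction = unname(dir_mi[cand$miRNA_id[keep]]),
                       m_direction = unname(dir_m[cand$mRNA_id[keep]]),
                       stringsAsFactors = FALSE)
  exclusions <- data.frame(lncRNA_id = cand$lncRNA_id[!keep],
                           miRNA_id = cand$miRNA_id[!keep],
                           mRNA_id = cand$mRNA_id[!keep],
                           reason = reason[!keep], stringsAsFactors = FALSE)
  structure(list(triads = triads, exclusions = exclusions, params = params),
            class = "cerna_result")
}

#' @export
print.cerna_result <- function(x, ...) {
  cat(sprintf("cerna_result: %d surviving triads, %d excluded candidates\n",
              nrow(x$triads), nrow(x$exclusions)))
  if (nrow(x$exclusions) > 0) {
    tab <- sort(table(x$exclusions$reason), decreasing = TRUE)
    cat("  exclusions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Merge surviving triads into a ceRNA network
#'
#' Nodes are the union of triad members (annotated with layer, direction and,
#' when DE results are supplied, consensus log2FC); edges are the union of
#' lncRNA->miRNA and miRNA->mRNA edges, deduplicated across triads.
#'
#' @param triads the `triads` data frame of a `cerna_result` (or the object
#'   itself).
#' @param de optional named list of `de_result` objects used to attach
#'   `consensus_log2fc` to nodes.
#' @return A [cerna_network()].
#' @export
build_network <- function(triads, de = NULL) {
  if (inherits(triads, "cerna_result")) triads <- triads$triads
  if (nrow(triads) == 0)
    return(cerna_network(
      nodes = data.frame(id = character(0), layer = character(0),
                         direction = character(0), consensus_log2fc = numeric(0),
                         stringsAsFactors = FALSE),
      edges = data.frame(source = character(0), target = character(0),
                         edge_type = character(0), mre_count = integer(0),
                         stringsAsFactors = FALSE)))
  nodes <- rbind(
    data.frame(id = triads$lncRNA_id, layer = "lncRNA",
               direction = triads$lnc_direction, stringsAsFactors = FALSE),
    data.frame(id = triads$miRNA_id, layer = "miRNA",
               direction = triads$mi_direction, stringsAsFactors = FALSE),
    data.frame(id = triads$mRNA_id, layer = "mRNA",
               direction = triads$m_direction, stringsAsFactors = FALSE))
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  nodes <- nodes[order(match(nodes$layer, c("lncRNA", "miRNA", "mRNA")), nodes$id), ]
  lfc <- rep(NA_real_, nrow(nodes))
  if (!is.null(de)) {
    all_tab <- do.call(rbind, lapply(de, function(x) x$table))
    lfc <- all_tab$consensus_log2fc[match(nodes$id, all_tab$feature_id)]
  }
  nodes$consensus_log2fc <- lfc
  edges <- rbind(
    data.frame(source = triads$lncRNA_id, target = triads$miRNA_id,
               edge_type = "lnc_mi", mre_count = triads$mre_lnc_mi,
               stringsAsFactors = FALSE),
    data.frame(source = triads$miRNA_id, target = triads$mRNA_id,
               edge_type = "mi_m", mre_count = triads$mre_mi_m,
               stringsAsFactors = FALSE))
  edges <- edges[!duplicated(paste(edges$source, edges$target, edges$edge_type)), ]
  edges <- edges[order(edges$edge_type, edges$source, edges$target), ]
  rownames(nodes) <- rownames(edges) <- NULL
  cerna_network(nodes, edges)
}
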