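#' Parameters for paired differential expression
#'
#' The study design compares one tumour against one paired normal sample, so no
#' dispersion can be estimated from the data; a fixed negative-binomial
#' dispersion (default 0.16, i.e. a biological coefficient of variation of 0.4,
#' the conventional value for human tissue without replicates) is assumed by
#' the per-pair exact test. Cut-offs follow the usual paired screen: raw
#' p <= 0.05 and |log2 fold change| > 1 in the pairs required by `consensus`.
#'
#' @param p_cutoff per-pair p-value cut-off (default 0.05). p-values are raw by
#'   default; set `adjust = TRUE` for Benjamini-Hochberg adjustment across
#'   features within each pair.
#' @param lfc_cutoff per-pair |log2FC| cut-off (default 1).
#' @param dispersion fixed NB dispersion phi (default 0.16; phi = BCV^2).
#' @param pseudo_count prior count on the CPM scale added to both sides of the
#'   fold change so that zeros give finite log-ratios (default 0.5).
#' @param trim_m,trim_a TMM trim fractions for the log-ratios (M, default 0.30)
#'   and average log-intensities (A, default 0.05).
#' @param consensus how per-pair calls are combined into one call per feature:
#'   `"all"` (cut-offs met in every pair with one consistent sign — the strict
#'   reading of "differential in all groups"), `"majority"` (met in more than
#'   half of the pairs, with one consistent sign among the passing pairs), or
#'   `"any"`.
#' @param adjust apply BH adjustment to each pair's p-values before
#'   thresholding (default `FALSE`, matching the use of raw p-values).
#' @return A list of class `de_params`.
#' @export
de_params <- function(p_cutoff = 0.05, lfc_cutoff = 1, dispersion = 0.16,
                      pseudo_count = 0.5, trim_m = 0.30, trim_a = 0.05,
                      consensus = c("all", "majority", "any"), adjust = FALSE) {
  consensus <- match.arg(consensus)
  stopifnot(p_cutoff > 0, lfc_cutoff > 0, dispersion >= 0, pseudo_count >= 0,
            trim_m >= 0, trim_m < 0.5, trim_a >= 0, trim_a < 0.5)
  structure(list(p_cutoff = p_cutoff, lfc_cutoff = lfc_cutoff,
                 dispersion = dispersion, pseudo_count = pseudo_count,
                 trim_m = trim_m, trim_a = trim_a, consensus = consensus,
                 adjust = adjust),
            class = "de_params")
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Between-sample scaling factors for count data, computed from trimmed,
#' precision-weighted log-ratios against a reference sample. The reference is
#' the sample whose 75th-percentile count fraction is closest to the mean of
#' those fractions. For each sample s versus the reference r, over features
#' with non-zero counts in both, M = log2((y_s/N_s)/(y_r/N_r)) and
#' A = 0.5*log2((y_s/N_s)*(y_r/N_r)); the most extreme `trim_m` of features at
#' each end by M and `trim_a` at each end by A are dropped, and the factor is
#' 2^(weighted mean of the remaining M) with inverse approximate-binomial
#' variance weights 1/((N_s-y_s)/(N_s*y_s) + (N_r-y_r)/(N_r*y_r)). Factors are
#' rescaled to have geometric mean 1, so that effective library sizes
#' N_s * f_s preserve the overall count scale.
#'
#' @param em an [expression_matrix()] or a plain counts matrix.
#' @param trim_m,trim_a trim fractions (defaults 0.30 and 0.05).
#' @return Data frame of class `norm_factors` with columns `sample_id`,
#'   `lib_size`, `norm_factor`.
#' @export
tmm_factors <- function(em, trim_m = 0.30, trim_a = 0.05) {
  counts <- if (inherits(em, "expr_matrix")) em$counts else as.matrix(em)
  if (ncol(counts) < 2L) stop_named("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop_named("sample with all-zero counts: ", colnames(counts)[lib == 0][1])
  f75 <- apply(counts, 2L, function(x) stats::quantile(x, 0.75, names = FALSE)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(s) {
    .tmm_one(counts[, s], counts[, ref], lib[s], lib[ref], trim_m, trim_a)
  }, 0)
  f <- f / geomean(f)
  structure(data.frame(sample_id = colnames(counts), lib_size = lib,
                       norm_factor = f, row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("norm_factors", "data.frame"))
}

# Single-sample TMM factor against a reference library.
.tmm_one <- function(y, yr, n, nr, trim_m, trim_a) {
  keep <- y > 0 & yr > 0
  y <- y[keep]; yr <- yr[keep]
  if (length(y) == 0) {
    warning("no features shared with the reference sample; factor set to 1",
            call. = FALSE)
    return(1)
  }
  m <- log2((y / n) / (yr / nr))
  a <- 0.5 * log2((y / n) * (yr / nr))
  w <- 1 / ((n - y) / (n * y) + (nr - yr) / (nr * yr))
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (length(m) == 0 || max(abs(m)) < 1e-6) return(1)
  k <- length(m)
  lo_m <- floor(k * trim_m) + 1
  hi_m <- k + 1 - lo_m
  lo_a <- floor(k * trim_a) + 1
  hi_a <- k + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) return(1)
  2^(sum(w[keep2] * m[keep2]) / sum(w[keep2]))
}

#' Conditional negative-binomial exact test for one tumour/normal pair
#'
#' Tests whether a feature's two counts (one tumour, one paired normal
#' observation) are consistent with a common expression level, assuming each is
#' negative-binomial with the same mean and a fixed dispersion `phi`. Counts
#' are first rescaled to the common effective library size S (the geometric
#' mean of the two effective library sizes) and rounded; conditional on the
#' rescaled total T, the tumour count follows a symmetric beta-binomial
#' BB(T, 1/phi, 1/phi), and the two-sided p-value is the probability of
#' outcomes whose conditional probability is at most that of the observed
#' split. With `phi = 0` this reduces to the conditional binomial(T, 1/2)
#' test. A total of zero gives p = 1 by convention.
#'
#' @param count_t,count_n non-negative counts (vectors of equal length are
#'   accepted and tested feature-wise).
#' @param efflib_t,efflib_n effective library sizes (> 0): library size times
#'   TMM factor.
#' @param dispersion NB dispersion phi >= 0.
#' @return Vector of two-sided p-values.
#' @export
pair_exact_test <- function(count_t, count_n, efflib_t, efflib_n,
                            dispersion = 0.16) {
  stopifnot(length(count_t) == length(count_n),
            efflib_t > 0, efflib_n > 0, dispersion >= 0,
            all(count_t >= 0), all(count_n >= 0))
  s <- geomean(c(efflib_t, efflib_n))
  yt <- round(count_t * s / efflib_t)
  yn <- round(count_n * s / efflib_n)
  vapply(seq_along(yt), function(i) .cond_pvalue(yt[i], yn[i], dispersion), 0)
}

# Two-sided conditional p-value for one rescaled (tumour, normal) count pair.
# Exploits the symmetry and unimodality (r >= 1) of the conditional law:
# p = P(X <= m) + P(X >= T - m) with m = min(yt, yn).
.cond_pvalue <- function(yt, yn, phi) {
  tt <- yt + yn
  if (tt == 0) return(1)
  m <- min(yt, yn)
  if (m >= tt - m) return(1)
  if (phi == 0) {
    p <- stats::pbinom(m, tt, 0.5) +
      stats::pbinom(tt - m - 1, tt, 0.5, lower.tail = FALSE)
    return(min(1, p))
  }
  r <- 1 / phi
  k <- 0:m
  lp <- lchoose(k + r - 1, k) + lchoose(tt - k + r - 1, tt - k) -
    lchoose(tt + 2 * r - 1, tt)
  min(1, 2 * sum(exp(lp)))
}

#' Counts per million, optionally TMM-normalized and log-transformed
#'
#' @param em an [expression_matrix()].
#' @param factors optional [tmm_factors()] result; when supplied, effective
#'   library sizes `lib_size * norm_factor` are used.
#' @param log return `log2(CPM + 1)` (the scale used for the ceRNA correlation
#'   filter) instead of raw CPM.
#' @return Numeric matrix, features x samples.
#' @export
cpm_matrix <- function(em, factors = NULL, log = FALSE) {
  counts <- if (inherits(em, "expr_matrix")) em$counts else as.matrix(em)
  lib <- colSums(counts)
  if (!is.null(factors)) {
    idx <- match(colnames(counts), factors$sample_id)
    if (anyNA(idx)) stop_named("normalization factors missing for sample ",
                               colnames(counts)[is.na(idx)][1])
    lib <- lib * factors$norm_factor[idx]
  }
  out <- sweep(counts, 2L, lib, "/") * 1e6
  if (log) log2(out + 1) else out
}

#' Per-pair differential expression with a cross-pair consensus rule
#'
#' For every feature and every tumour/normal pair: the log2 fold change is
#' computed on the TMM-normalized CPM scale with a pseudo-count
#' (`log2((cpm_t + c)/(cpm_n + c))`), and a p-value from
#' [pair_exact_test()]. A feature is called differential according to
#' `params$consensus` (default: cut-offs met in every pair with one consistent
#' sign). The consensus log2FC is the arithmetic mean of the per-pair values.
#'
#' @param em an [expression_matrix()].
#' @param design a [paired_design()]; every referenced sample must exist in
#'   `em`.
#' @param params a [de_params()] object.
#' @return An object of class `de_result`: list with `table` (data frame
#'   `feature_id`, `layer`, `consensus_log2fc`, `direction`, `is_de`),
#'   `log2fc` and `p` (features x pairs matrices, columns named by patient),
#'   and the `params` used.
#' @export
call_de <- function(em, design, params = de_params()) {
  stopifnot(inherits(em, "expr_matrix"), inherits(design, "paired_design"),
            inherits(params, "de_params"))
  check_design(design, em)
  counts <- em$counts
  nf <- tmm_factors(em, params$trim_m, params$trim_a)
  efflib <- stats::setNames(nf$lib_size * nf$norm_factor, nf$sample_id)
  npair <- nrow(design)
  lfc <- p <- matrix(NA_real_, nrow(counts), npair,
                     dimnames = list(rownames(counts), design$patient_id))
  for (j in seq_len(npair)) {
    st <- design$tumor[j]; sn <- design$normal[j]
    cpm_t <- counts[, st] / efflib[st] * 1e6
    cpm_n <- counts[, sn] / efflib[sn] * 1e6
    lfc[, j] <- log2((cpm_t + params$pseudo_count) / (cpm_n + params$pseudo_count))
    p[, j] <- pair_exact_test(counts[, st], counts[, sn],
                              efflib[st], efflib[sn], params$dispersion)
  }
  p_eff <- if (params$adjust) apply(p, 2L, stats::p.adjust, method = "BH") else p
  pass <- p_eff <= params$p_cutoff & abs(lfc) > params$lfc_cutoff
  sgn <- sign(lfc)
  n_up <- rowSums(pass & sgn > 0)
  n_dn <- rowSums(pass & sgn < 0)
  is_de <- switch(params$consensus,
                  all = (n_up == npair) | (n_dn == npair),
                  majority = pmax(n_up, n_dn) > npair / 2 & pmin(n_up, n_dn) == 0,
                  any = (n_up + n_dn) >= 1L)
  consensus <- rowMeans(lfc)
  direction <- ifelse(!is_de, "none", ifelse(consensus > 0, "up", "down"))
  # a consensus lfc of exactly zero cannot support a call
  is_de <- is_de & direction != "none" & consensus != 0
  structure(list(
    table = data.frame(feature_id = rownames(counts), layer = em$layer,
                       consensus_log2fc = consensus, direction = direction,
                       is_de = is_de, row.names = NULL, stringsAsFactors = FALSE),
    log2fc = lfc, p = p, factors = nf, params = params),
    class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  tab <- x$table
  cat(sprintf("de_result [%s]: %d features, %d DE (%d up / %d down), %d pairs\n",
              tab$layer[1], nrow(tab), sum(tab$is_de),
              sum(tab$direction == "up"), sum(tab$direction == "down"),
              ncol(x$log2fc)))
  invisible(x)
}

#' Flatten a DE result to a TSV-ready data frame
#'
#' @param de a `de_result`.
#' @return Data frame with the summary columns plus per-pair
#'   `log2fc.<patient>` and `p.<patient>` columns.
#' @export
de_table <- function(de) {
  stopifnot(inherits(de, "de_result"))
  lfc <- de$log2fc; colnames(lfc) <- paste0("log2fc.", colnames(lfc))
  p <- de$p; colnames(p) <- paste0("p.", colnames(p))
  cbind(de$table, as.data.frame(lfc, optional = TRUE),
        as.data.frame(p, optional = TRUE), row.names = NULL)
}
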