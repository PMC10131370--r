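#' Relative quantification by the 2^(-ddCt) method
#'
#' For each sample, delta-Ct is the target gene's Ct minus the reference
#' gene's Ct; for each patient, delta-delta-Ct is the tumour delta-Ct minus
#' the paired normal delta-Ct, and the per-pair fold change is 2^(-ddCt).
#' Per-pair folds are aggregated with a geometric mean by default (the
#' arithmetic mean is available, but folds are ratios and the geometric mean
#' is the unbiased summary on the log scale).
#'
#' @param ct a [ct_table()].
#' @param gene target gene id to quantify.
#' @param aggregate `"geometric"` (default) or `"arithmetic"` mean of the
#'   per-pair folds.
#' @return List with `gene`, `per_pair` (data frame `patient_id`, `ddct`,
#'   `fold`) and `mean_fold`.
#' @export
ddct_fold_change <- function(ct, gene, aggregate = c("geometric", "arithmetic")) {
  aggregate <- match.arg(aggregate)
  ct <- ct_table(ct)
  rows <- ct[ct$gene_id == gene, , drop = FALSE]
  if (nrow(rows) == 0) stop_named("no Ct rows for gene ", gene)
  dct <- rows$ct_target - rows$ct_reference
  patients <- unique(rows$patient_id)
  ddct <- vapply(patients, function(p) {
    it <- which(rows$patient_id == p & rows$group == "tumor")
    in_ <- which(rows$patient_id == p & rows$group == "normal")
    if (length(it) != 1L || length(in_) != 1L)
      stop_named("pair ", p, " for gene ", gene,
                 " lacks a matched tumor/normal Ct measurement")
    dct[it] - dct[in_]
  }, 0)
  fold <- 2^(-ddct)
  mean_fold <- if (aggregate == "geometric") geomean(fold) else mean(fold)
  list(gene = gene,
       per_pair = data.frame(patient_id = patients, ddct = unname(ddct),
                             fold = unname(fold), stringsAsFactors = FALSE),
       mean_fold = mean_fold)
}

# Logistic regression of label on a single predictor by iteratively
# reweighted least squares with an (optional) ridge penalty on the slope.
# Used as the stabilized fall-back when a training fold is perfectly
# separated and the unpenalized ML estimate diverges.
.ridge_logit <- function(x, y, lambda = 0, maxit = 100L, tol = 1e-10) {
  X <- cbind(1, x)
  beta <- c(stats::qlogis(max(min(mean(y), 0.99), 0.01)), 0)
  pen <- diag(c(0, lambda))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(X, y - mu)) - pen %*% beta
    hess <- crossprod(X * w, X) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Leave-one-out cross-validated tumour probabilities
#'
#' Each sample is scored by a binomial generalized linear model (logit link,
#' one predictor) trained on all remaining samples; the returned vector holds
#' the held-out tumour probabilities. When a training fold is perfectly
#' separated, the maximum-likelihood fit diverges and a ridge-stabilized fit
#' (penalty 1e-4 on the slope) is substituted; the affected folds are
#' recorded in the `ridge_folds` attribute and reported via a message.
#'
#' @param values numeric predictor, one value per sample (conventionally the
#'   log2 relative expression, `-dCt`).
#' @param labels `"tumor"` / `"normal"` per sample (tumour is the positive
#'   class); at least two samples per class.
#' @param ridge penalty used by the stabilized fall-back fit.
#' @return Numeric vector of held-out tumour probabilities, with attribute
#'   `ridge_folds`.
#' @export
loocv_scores <- function(values, labels, ridge = 1e-4) {
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels),
            all(labels %in% c("tumor", "normal")))
  y <- as.integer(labels == "tumor")
  if (sum(y) < 2L || sum(1 - y) < 2L)
    stop_named("need at least 2 samples per class for LOOCV")
  n <- length(y)
  probs <- numeric(n)
  ridge_folds <- integer(0)
  for (i in seq_len(n)) {
    xi <- values[-i]; yi <- y[-i]
    if (stats::sd(xi) == 0) {
      # constant predictor: intercept-only model, probability = prevalence
      probs[i] <- mean(yi)
      next
    }
    separated <- FALSE
    fit <- withCallingHandlers(
      stats::glm(yi ~ xi, family = stats::binomial()),
      warning = function(w) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (separated || !fit$converged) {
      beta <- .ridge_logit(xi, yi, lambda = ridge)
      ridge_folds <- c(ridge_folds, i)
      probs[i] <- stats::plogis(beta[1] + beta[2] * values[i])
    } else {
      probs[i] <- unname(stats::predict(fit,
                                        newdata = data.frame(xi = values[i]),
                                        type = "response"))
    }
  }
  if (length(ridge_folds) > 0)
    message("LOOCV: ridge-stabilized fit used in ", length(ridge_folds),
            " fold(s) (perfect separation)")
  attr(probs, "ridge_folds") <- ridge_folds
  probs
}

#' ROC curve and AUC
#'
#' The ROC curve is traced over all distinct score thresholds; the AUC is the
#' Mann-Whitney pair statistic (the probability that a random tumour sample
#' outranks a random normal sample, ties counted 1/2), computed from average
#' ranks — which equals the trapezoidal area under the tied ROC curve.
#'
#' @param scores numeric scores, larger meaning more tumour-like.
#' @param labels `"tumor"` / `"normal"` per sample; both classes must be
#'   present.
#' @return Object of class `roc_result`: list with `scores`, `labels`, `fpr`,
#'   `tpr` (monotone from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c("tumor", "normal")))
  pos <- labels == "tumor"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop_named("both classes must be present to compute a ROC curve")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores[pos] >= t), 0)
  fp <- vapply(thr, function(t) sum(scores[!pos] >= t), 0)
  structure(list(scores = scores, labels = labels,
                 fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos), auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d tumor vs %d normal)\n",
              x$auc, sum(x$labels == "tumor"), sum(x$labels == "normal")))
  invisible(x)
}

#' Single-gene diagnostic evaluation from a Ct table
#'
#' Convenience wrapper running the full diagnostic path for one gene: the
#' per-sample log2 relative expression (-dCt) is the predictor, held-out
#' tumour probabilities come from [loocv_scores()], and the ROC/AUC is
#' computed on those probabilities (set `score = "expression"` to rank by raw
#' relative expression instead).
#'
#' @param ct a [ct_table()].
#' @param gene target gene id.
#' @param score `"loocv"` (default) or `"expression"`.
#' @return A `roc_result`, with the fitted probabilities in `$scores`.
#' @export
diagnostic_roc <- function(ct, gene, score = c("loocv", "expression")) {
  score <- match.arg(score)
  ct <- ct_table(ct)
  rows <- ct[ct$gene_id == gene, , drop = FALSE]
  if (nrow(rows) == 0) stop_named("no Ct rows for gene ", gene)
  rel <- -(rows$ct_target - rows$ct_reference)  # log2 of 2^(-dCt)
  s <- if (score == "loocv") loocv_scores(rel, rows$group) else rel
  roc_auc(as.numeric(s), rows$group)
}
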