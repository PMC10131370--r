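# Independent oracles, deliberately coded on different paths from the
# package implementation: full enumeration, sorting instead of ranking,
# explicit pair counting. They are slow and only used on small inputs.

# Conditional two-count exact test by full enumeration of the conditional
# distribution: product of two NB (or Poisson) pmfs normalized over all
# splits of the total; p = mass of outcomes no more probable than observed.
oracle_exact_p <- function(yt, yn, phi, mu = NULL) {
  tot <- yt + yn
  if (tot == 0) return(1)
  k <- 0:tot
  if (phi == 0) {
    if (is.null(mu)) mu <- tot / 2
    lp <- stats::dpois(k, mu, log = TRUE) + stats::dpois(tot - k, mu, log = TRUE)
  } else {
    if (is.null(mu)) mu <- tot / 2
    lp <- stats::dnbinom(k, size = 1 / phi, mu = mu, log = TRUE) +
      stats::dnbinom(tot - k, size = 1 / phi, mu = mu, log = TRUE)
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[yt + 1] * (1 + 1e-9)])
}

# Step-by-step TMM oracle: sorting-based trimming rather than rank windows.
oracle_tmm <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(counts)
  f75 <- vapply(seq_len(ncol(counts)), function(s)
    stats::quantile(counts[, s], 0.75, names = FALSE) / lib[s], 0)
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    ok <- counts[, s] > 0 & counts[, ref] > 0
    ys <- counts[ok, s]; yr <- counts[ok, ref]
    m <- log2((ys / lib[s]) / (yr / lib[ref]))
    a <- 0.5 * log2((ys / lib[s]) * (yr / lib[ref]))
    w <- 1 / ((lib[s] - ys) / (lib[s] * ys) + (lib[ref] - yr) / (lib[ref] * yr))
    if (length(m) == 0 || max(abs(m)) < 1e-6) { fac[s] <- 1; next }
    n <- length(m)
    dm <- floor(n * trim_m); da <- floor(n * trim_a)
    keep_m <- logical(n); keep_m[order(m)[(dm + 1):(n - dm)]] <- TRUE
    keep_a <- logical(n); keep_a[order(a)[(da + 1):(n - da)]] <- TRUE
    keep <- keep_m & keep_a
    fac[s] <- 2^(sum(w[keep] * m[keep]) / sum(w[keep]))
  }
  fac / exp(mean(log(fac)))
}

# Hypergeometric upper tail P(X >= k) by enumerating every possible draw of
# n from N (first K elements of the background are "in the term").
oracle_hyper_p <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# AUC by explicit counting over all positive x negative pairs, ties 1/2.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == "tumor"]
  sn <- scores[labels == "normal"]
  tot <- 0
  for (p in sp) for (n in sn)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(sp) * length(sn))
}

# Unpenalized logistic regression by plain Newton iteration (per-fold oracle
# for the LOOCV scores).
oracle_logit <- function(x, y, maxit = 200L) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(maxit)) {
    mu <- stats::plogis(drop(X %*% beta))
    w <- pmax(mu * (1 - mu), 1e-12)
    step <- solve(crossprod(X * w, X), crossprod(X, y - mu))
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  beta
}

# Trapezoidal area under an (fpr, tpr) polygon.
oracle_trapezoid <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
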