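mk_ct <- function(folds, n = 4, noise = 0, patient_sd = 0, seed = 5) {
  cfg <- sim_config(ct_pairs = n, ct_noise_sd = noise, ct_patient_sd = patient_sd,
                    seed = seed)
  simulate_ct_table(cfg, folds = data.frame(gene_id = names(folds),
                                            fold = unname(folds)))
}

test_that("2^(-ddCt) recovers the constructed fold changes", {
  ct <- mk_ct(c(gA = 1, gB = 2, gC = 346))
  expect_equal(ddct_fold_change(ct, "gA")$per_pair$ddct, rep(0, 4))
  expect_equal(ddct_fold_change(ct, "gA")$mean_fold, 1)
  expect_equal(ddct_fold_change(ct, "gB")$mean_fold, 2)      # ddCt = -1
  expect_equal(ddct_fold_change(ct, "gC")$mean_fold, 346, tolerance = 1e-12)
  # patient baseline shifts cancel within pairs
  ct2 <- mk_ct(c(gC = 346), patient_sd = 1.5)
  expect_equal(ddct_fold_change(ct2, "gC")$mean_fold, 346, tolerance = 1e-12)
})

test_that("a missing partner sample is reported with the pair's name", {
  ct <- mk_ct(c(gA = 4))
  broken <- ct[!(ct$patient_id == "ctP02" & ct$group == "normal"), ]
  expect_error(ddct_fold_change(broken, "gA"), "ctP02")
  expect_error(ddct_fold_change(ct, "nope"), "no Ct rows")
})

test_that("LOOCV probabilities preserve the predictor order under separation", {
  x <- c(1, 2, 3, 10, 11, 12)
  labels <- rep(c("normal", "tumor"), each = 3)
  p <- suppressMessages(loocv_scores(x, labels))
  expect_identical(order(p), order(x))
  expect_true(all(p[4:6] > p[1:3]))
})

test_that("a constant predictor yields the training-fold prevalence", {
  x <- rep(2.5, 6)
  labels <- c("tumor", "tumor", "tumor", "normal", "normal", "normal")
  p <- loocv_scores(x, labels)
  # held-out tumour: 2 of 5 remaining are tumour, etc.
  expect_equal(p, c(2, 2, 2, 3, 3, 3) / 5, ignore_attr = TRUE)
})

test_that("LOOCV probabilities equal per-fold refits on a toy set", {
  # two crossing pairs keep every training fold non-separated
  x <- c(0.2, 1.5, 2.2, 0.8, 1.0, 1.8, 2.5, 2.9)
  labels <- c("normal", "normal", "normal", "normal",
              "tumor", "tumor", "tumor", "tumor")
  p <- loocv_scores(x, labels)
  y <- as.integer(labels == "tumor")
  for (i in seq_along(x)) {
    beta <- oracle_logit(x[-i], y[-i])
    expect_equal(p[i], unname(stats::plogis(beta[1] + beta[2] * x[i])),
                 tolerance = 1e-6, info = paste("fold", i))
  }
})

test_that("AUC equals brute-force pair counting, including ties", {
  scores <- c(3, 1, 4, 1, 5, 2, 2, 6)
  labels <- c("tumor", "normal", "tumor", "tumor",
              "tumor", "normal", "normal", "normal")
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  expect_error(roc_auc(1:3, rep("tumor", 3)), "both classes")
})

test_that("ROC curve is monotone from (0,0) to (1,1) and integrates to AUC", {
  set.seed(19)
  scores <- round(rnorm(40), 1)          # rounding forces ties
  labels <- ifelse(rbinom(40, 1, plogis(scores)) == 1, "tumor", "normal")
  r <- roc_auc(scores, labels)
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
  expect_false(is.unsorted(r$fpr))
  expect_false(is.unsorted(r$tpr))
  expect_equal(oracle_trapezoid(r$fpr, r$tpr), r$auc, tolerance = 1e-10)
})

test_that("AUC is invariant to monotone transforms and flips under negation", {
  set.seed(23)
  scores <- rnorm(30)
  labels <- sample(c("tumor", "normal"), 30, replace = TRUE, prob = c(0.4, 0.6))
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a, tolerance = 1e-12)
  expect_equal(roc_auc(-scores, labels)$auc + a, 1, tolerance = 1e-10)
})

test_that("AUC agrees with pROC on random data", {
  set.seed(29)
  for (i in 1:5) {
    scores <- sample(1:10, 25, replace = TRUE)
    labels <- sample(c("tumor", "normal"), 25, replace = TRUE)
    if (length(unique(labels)) < 2) next
    mine <- roc_auc(scores, labels)$auc
    theirs <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("normal", "tumor"),
      direction = "<", quiet = TRUE)))
    expect_equal(mine, theirs, tolerance = 1e-10)
  }
})

test_that("diagnostic_roc separates tumour from normal at a planted fold", {
  ct <- mk_ct(c(gA = 8), n = 16, noise = 0.2, patient_sd = 0.5, seed = 7)
  r <- diagnostic_roc(ct, "gA")
  expect_gt(r$auc, 0.95)
})
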