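test_that("TMM factors are 1 for identical and for rescaled samples", {
  set.seed(3)
  base <- rpois(60, rlnorm(60, log(60), 1))
  m <- cbind(s1 = base, s2 = base)
  rownames(m) <- sprintf("g%02d", seq_len(60))
  f <- tmm_factors(m)
  expect_equal(f$norm_factor, c(1, 1), tolerance = 1e-12)
  # doubling every count only changes the library size, not the factor
  m2 <- cbind(s1 = base, s2 = base * 2L)
  expect_equal(tmm_factors(m2)$norm_factor, c(1, 1), tolerance = 1e-12)
})

test_that("TMM errors on an all-zero sample, naming it", {
  m <- cbind(s1 = c(5, 2, 9), s2 = c(0, 0, 0))
  rownames(m) <- c("a", "b", "c")
  expect_error(tmm_factors(m), "all-zero counts: s2")
})

test_that("TMM agrees with the independent step-by-step oracle and edgeR", {
  set.seed(11)
  for (i in 1:3) {
    m <- matrix(rpois(80 * 5, rlnorm(80, log(70), 1.2)), 80, 5,
                dimnames = list(sprintf("g%02d", 1:80), sprintf("s%d", 1:5)))
    mine <- tmm_factors(m)$norm_factor
    expect_equal(mine, oracle_tmm(m), tolerance = 1e-10)
    ed <- edgeR::calcNormFactors(edgeR::DGEList(counts = m), method = "TMM")
    expect_equal(mine, ed$samples$norm.factors, tolerance = 1e-8)
  }
})

test_that("exact test handles the closed-form and degenerate cases", {
  # symmetric split is the conditional mode: p = 1
  expect_equal(pair_exact_test(7, 7, 1e6, 1e6, 0.16), 1)
  expect_equal(pair_exact_test(0, 0, 1e6, 1e6, 0.16), 1)
  # Poisson limit, 10 vs 0: two-sided binomial(10, 1/2) tail
  expect_equal(pair_exact_test(10, 0, 1e6, 1e6, 0), 2 * 0.5^10, tolerance = 1e-12)
  # vectorized over features
  p <- pair_exact_test(c(5, 50), c(5, 10), 1e6, 1e6, 0.16)
  expect_length(p, 2L)
  expect_lt(p[2], p[1])
})

test_that("exact test matches enumeration for sampled totals and dispersions", {
  set.seed(5)
  for (phi in c(0, 0.16, 0.4)) {
    for (tot in sample(1:150, 10)) {
      yt <- sample(0:tot, 1)
      expect_equal(pair_exact_test(yt, tot - yt, 1e6, 1e6, phi),
                   oracle_exact_p(yt, tot - yt, phi), tolerance = 1e-10,
                   info = sprintf("phi=%g yt=%d tot=%d", phi, yt, tot))
    }
  }
})

test_that("a feature equal in all samples is never called differential", {
  cfg <- small_cfg(seed = 2)
  ds <- simulate_dataset(cfg)
  em <- ds$matrices$mRNA
  em$counts[1, ] <- 123
  de <- call_de(em, ds$design)
  expect_false(de$table$is_de[1])
  expect_equal(de$table$direction[1], "none")
})

test_that("the all-pairs consensus requires every pair to pass", {
  # feature engineered to pass strongly in 5 of 6 pairs and fail in one
  set.seed(8)
  n_pairs <- 6
  design <- paired_design(sprintf("P%d", 1:n_pairs),
                          sprintf("T%d", 1:n_pairs), sprintf("N%d", 1:n_pairs))
  base <- matrix(rpois(200 * 12, rlnorm(200, log(120), 0.8)), 200, 12,
                 dimnames = list(sprintf("g%03d", 1:200),
                                 c(design$tumor, design$normal)))
  up <- base["g001", design$normal] * 16
  up[6] <- base["g001", design$normal[6]]      # pair 6 shows no change
  base["g001", design$tumor] <- up
  em <- expression_matrix(base, "mRNA")
  de_all <- call_de(em, design, de_params(consensus = "all"))
  de_maj <- call_de(em, design, de_params(consensus = "majority"))
  expect_false(de_all$table[de_all$table$feature_id == "g001", "is_de"])
  expect_true(de_maj$table[de_maj$table$feature_id == "g001", "is_de"])
})

test_that("tightening cut-offs never adds DE calls", {
  ds <- simulate_dataset(small_cfg(seed = 4))
  em <- ds$matrices$lncRNA
  loose <- call_de(em, ds$design, de_params(p_cutoff = 0.05, lfc_cutoff = 1))
  tight_p <- call_de(em, ds$design, de_params(p_cutoff = 0.01, lfc_cutoff = 1))
  tight_f <- call_de(em, ds$design, de_params(p_cutoff = 0.05, lfc_cutoff = 2))
  de_set <- function(x) x$table$feature_id[x$table$is_de]
  expect_true(all(de_set(tight_p) %in% de_set(loose)))
  expect_true(all(de_set(tight_f) %in% de_set(loose)))
})

test_that("DE calls are invariant to rescaling one sample's counts", {
  ds <- simulate_dataset(small_cfg(seed = 6))
  em <- ds$matrices$mRNA
  em2 <- em
  em2$counts[, ds$design$tumor[1]] <- em2$counts[, ds$design$tumor[1]] * 3L
  de1 <- call_de(em, ds$design)
  de2 <- call_de(em2, ds$design)
  keep <- rowMeans(em$counts) >= 20
  expect_identical(de1$table$is_de[keep], de2$table$is_de[keep])
  expect_identical(de1$table$direction[keep], de2$table$direction[keep])
})

test_that("planted features are recovered with the planted direction", {
  ds <- simulate_dataset(small_cfg(seed = 9))
  de <- lapply(ds$matrices, call_de, design = ds$design)
  rec <- evaluate_de_recovery(de, ds$truth)
  expect_gte(rec$sensitivity, 0.85)
  expect_lte(rec$fdp, 0.1)
})
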