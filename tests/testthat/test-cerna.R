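test_that("target-database intersection keeps shared pairs with the min MRE", {
  rec <- interaction_records(data.frame(
    source = c("miR1", "miR1", "miR2"),
    target = c("mA", "mA", "mB"),
    edge_type = "mi_m",
    mre_count = c(5L, 4L, 6L),
    database = c("miranda_like", "targetscan_like", "miranda_like")))
  out <- intersect_target_dbs(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(out$mre_count, 4L)          # min across the two databases
  expect_equal(out$source, "miR1")
  expect_equal(nrow(intersect_target_dbs(rec[0, ])), 0L)
  rec$database[3] <- "mystery_db"
  expect_error(intersect_target_dbs(rec), "mystery_db.*miranda_like")
})

test_that("pairwise_pearson matches the textbook computation", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  expect_equal(pairwise_pearson(x, 2 * x + 1), 1)
  expect_equal(pairwise_pearson(x, -x), -1)
  set.seed(21)
  y <- x + rnorm(12, 0, 3)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pairwise_pearson(x, y), manual, tolerance = 1e-12)
  expect_true(is.na(pairwise_pearson(rep(1, 5), 1:5)))
  expect_true(is.na(pairwise_pearson(1:2, 2:1)))
})

test_that("planted triads survive and every decoy fails its designated filter", {
  ds <- simulate_dataset(small_cfg(seed = 31))
  de <- lapply(ds$matrices, call_de, design = ds$design)
  res <- assemble_triads(de, ds$interactions, ds$matrices, ds$design)
  ev <- evaluate_network_recovery(res, ds$truth)
  expect_equal(ev$n_recovered, ev$n_planted)
  expect_equal(ev$n_decoys_surviving, 0L)
  expect_equal(ev$n_reason_mismatch, 0L)
  # every surviving triad re-checks all four predicates independently
  logcpm_l <- cpm_matrix(ds$matrices$lncRNA, tmm_factors(ds$matrices$lncRNA), log = TRUE)
  logcpm_m <- cpm_matrix(ds$matrices$mRNA, tmm_factors(ds$matrices$mRNA), log = TRUE)
  samples <- c(ds$design$tumor, ds$design$normal)
  for (i in seq_len(nrow(res$triads))) {
    tr <- res$triads[i, ]
    expect_true(tr$mre_lnc_mi >= 3 && tr$mre_mi_m >= 3)
    expect_identical(tr$lnc_direction, tr$m_direction)
    expect_false(tr$mi_direction == tr$lnc_direction)
    r <- stats::cor(logcpm_l[tr$lncRNA_id, samples], logcpm_m[tr$mRNA_id, samples])
    expect_equal(tr$pearson_r, r, tolerance = 1e-12)
    expect_gt(r, 0.8)
  }
})

test_that("triad assembly is invariant to input record order", {
  ds <- simulate_dataset(small_cfg(seed = 32))
  de <- lapply(ds$matrices, call_de, design = ds$design)
  res1 <- assemble_triads(de, ds$interactions, ds$matrices, ds$design)
  set.seed(1)
  shuffled <- ds$interactions[sample(nrow(ds$interactions)), ]
  res2 <- assemble_triads(de, shuffled, ds$matrices, ds$design)
  expect_setequal(triad_key(res1$triads), triad_key(res2$triads))
  expect_setequal(paste(triad_key(res1$exclusions), res1$exclusions$reason),
                  paste(triad_key(res2$exclusions), res2$exclusions$reason))
})

test_that("raising thresholds only shrinks the surviving set", {
  ds <- simulate_dataset(small_cfg(seed = 33))
  de <- lapply(ds$matrices, call_de, design = ds$design)
  base <- assemble_triads(de, ds$interactions, ds$matrices, ds$design,
                          cerna_params(min_pearson_r = 0.8))
  strict <- assemble_triads(de, ds$interactions, ds$matrices, ds$design,
                            cerna_params(min_pearson_r = 0.95))
  expect_true(all(triad_key(strict$triads) %in% triad_key(base$triads)))
})

test_that("networks merge triads with deduplicated nodes and edges", {
  triads <- data.frame(
    lncRNA_id = c("lncA", "lncB"), miRNA_id = c("miR1", "miR1"),
    mRNA_id = c("mA", "mA"), mre_lnc_mi = c(4L, 5L), mre_mi_m = c(3L, 3L),
    pearson_r = c(0.9, 0.92), lnc_direction = "up", mi_direction = "down",
    m_direction = "up", stringsAsFactors = FALSE)
  net <- build_network(triads)
  # independent recount: unique members and unique directed edges
  expect_equal(nrow(net$nodes),
               length(unique(c(triads$lncRNA_id, triads$miRNA_id, triads$mRNA_id))))
  edges_expected <- unique(rbind(cbind(triads$lncRNA_id, triads$miRNA_id),
                                 cbind(triads$miRNA_id, triads$mRNA_id)))
  expect_equal(nrow(net$edges), nrow(edges_expected))
  expect_equal(nrow(net$nodes), 4L)
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(c(net$edges$source, net$edges$target) %in% net$nodes$id))
  empty <- build_network(triads[0, ])
  expect_equal(nrow(empty$nodes), 0L)
  expect_equal(nrow(empty$edges), 0L)
})

test_that("with decoys only, no triad survives the filters", {
  ds <- simulate_dataset(small_cfg(seed = 34, n_triads = 0,
                                   n_validation = c(lncRNA = 0, mRNA = 0)))
  de <- lapply(ds$matrices, call_de, design = ds$design)
  res <- assemble_triads(de, ds$interactions, ds$matrices, ds$design)
  expect_equal(nrow(res$triads), 0L)
})
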