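test_that("the generator is bit-identical under a fixed seed", {
  a <- simulate_dataset(small_cfg(seed = 41))
  b <- simulate_dataset(small_cfg(seed = 41))
  c <- simulate_dataset(small_cfg(seed = 42))
  expect_identical(a$matrices$mRNA$counts, b$matrices$mRNA$counts)
  expect_identical(a$interactions, b$interactions)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$matrices$mRNA$counts, c$matrices$mRNA$counts))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_features = c(lncRNA = 10, miRNA = 300, mRNA = 5000)),
               "infeasible")
  expect_error(sim_config(de_lfc_range = c(0.5, 2)))
})

test_that("planted per-pair fold changes carry the planted sign in every pair", {
  # spec'd detectability contract: |lfc| >= 1.5 and mean count >= 50
  n_feat <- 0L; n_good <- 0L
  for (seed in 51:53) {
    ds <- simulate_dataset(sim_config(seed = seed))
    for (layer in c("lncRNA", "miRNA", "mRNA")) {
      em <- ds$matrices[[layer]]
      truth <- ds$truth$de[ds$truth$de$layer == layer, ]
      truth <- truth[abs(truth$log2fc) >= 1.5, ]
      keep <- rowMeans(em$counts[truth$feature_id, , drop = FALSE]) >= 50
      truth <- truth[keep, ]
      cpm <- cpm_matrix(em)
      ratio <- log2((cpm[truth$feature_id, ds$design$tumor] + 0.5) /
                      (cpm[truth$feature_id, ds$design$normal] + 0.5))
      signs_ok <- rowSums(sign(ratio) == sign(truth$log2fc)) == ncol(ratio)
      n_feat <- n_feat + nrow(truth)
      n_good <- n_good + sum(signs_ok)
    }
  }
  expect_gte(n_good / n_feat, 0.99)
})

test_that("latent coupling raises planted-triad correlations above the no-coupling null", {
  r_coupled <- r_null <- numeric(0)
  for (seed in 61:75) {
    for (coup in c(0.35, 0)) {
      ds <- simulate_dataset(small_cfg(seed = seed, coupling_sd = coup))
      lc <- cpm_matrix(ds$matrices$lncRNA, tmm_factors(ds$matrices$lncRNA), log = TRUE)
      mc <- cpm_matrix(ds$matrices$mRNA, tmm_factors(ds$matrices$mRNA), log = TRUE)
      r <- mapply(function(l, m) stats::cor(lc[l, ], mc[m, ]),
                  ds$truth$triads$lncRNA_id, ds$truth$triads$mRNA_id)
      if (coup > 0) r_coupled <- c(r_coupled, r) else r_null <- c(r_null, r)
    }
  }
  # planted separation alone already couples the profiles; the latent factor
  # adds shared tumour-side variation on top
  expect_gt(mean(r_coupled), mean(r_null))
  expect_gte(mean(r_coupled > 0.8), 0.95)
})

test_that("interaction tables give true edges >=3 MREs in both target databases", {
  ds <- simulate_dataset(small_cfg(seed = 44))
  rec <- ds$interactions
  for (i in seq_len(nrow(ds$truth$triads))) {
    tr <- ds$truth$triads[i, ]
    lm <- rec[rec$source == tr$lncRNA_id & rec$target == tr$miRNA_id, ]
    mm <- rec[rec$source == tr$miRNA_id & rec$target == tr$mRNA_id, ]
    expect_gte(min(lm$mre_count), 3)
    expect_setequal(mm$database, c("miranda_like", "targetscan_like"))
    expect_gte(min(mm$mre_count), 3)
  }
})

test_that("truth and dataset serialize to plain text and read back", {
  ds <- simulate_dataset(small_cfg(seed = 45))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  em <- read_expression_matrix(file.path(dir, "counts_miRNA.tsv"), "miRNA")
  expect_identical(em$counts, ds$matrices$miRNA$counts)
  expect_identical(read_interactions(file.path(dir, "interactions.tsv"))$mre_count,
                   ds$interactions$mre_count)
  truth <- read_truth(dir)
  expect_identical(truth$triads$lncRNA_id, ds$truth$triads$lncRNA_id)
  expect_identical(truth$decoys$category, ds$truth$decoys$category)
  expect_equal(truth$validation$fold, ds$truth$validation$fold, tolerance = 1e-6)
  gmt <- read_gmt(file.path(dir, "pathway.gmt"), "pathway")
  expect_equal(length(gmt$term_id), 12L)
})

test_that("Ct simulation inverts exactly at zero noise, including fold 346", {
  cfg <- sim_config(ct_pairs = 16, ct_noise_sd = 0, seed = 3)
  ct <- simulate_ct_table(cfg, folds = data.frame(gene_id = "lncX", fold = 346))
  expect_equal(ddct_fold_change(ct, "lncX")$mean_fold, 346, tolerance = 1e-12)
  ds <- simulate_dataset(small_cfg(seed = 46, ct_noise_sd = 0))
  ct2 <- simulate_ct_table(ds$config, ds$truth, noise_sd = 0)
  for (i in seq_len(nrow(ds$truth$validation)))
    expect_equal(ddct_fold_change(ct2, ds$truth$validation$gene_id[i])$mean_fold,
                 ds$truth$validation$fold[i], tolerance = 1e-9)
})
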