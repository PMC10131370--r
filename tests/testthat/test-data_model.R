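test_that("count matrices round-trip losslessly through TSV", {
  em <- toy_matrix(5, 4, "lncRNA")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(em, path)
  back <- read_expression_matrix(path, "lncRNA")
  expect_identical(back$counts, em$counts)
  expect_identical(back$layer, "lncRNA")
})

test_that("count parsers reject invariant violations and name the offender", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), path)
  expect_error(read_expression_matrix(path, "mRNA"), "gA")
  m <- matrix(c(1, -2, 3, 4), 2, 2,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  expect_error(expression_matrix(m, "mRNA"), "negative count.*gB")
  m2 <- matrix(c(1, 2.5, 3, 4), 2, 2,
               dimnames = list(c("gA", "gB"), c("s1", "s2")))
  expect_error(expression_matrix(m2, "mRNA"), "non-integer count.*gB")
  expect_error(expression_matrix(matrix(1:3, 3, 1,
                                        dimnames = list(letters[1:3], "s1")),
                                 "mRNA"), "at least 2 samples")
})

test_that("paired design enforces unique samples and matrix membership", {
  expect_error(paired_design(c("p1", "p2"), c("t1", "t2"), c("n1", "t1")),
               "two pairs")
  d <- paired_design("p1", "t1", "n1")
  em <- toy_matrix()
  expect_error(call_de(em, d), "missing from")
})

test_that("interaction tables validate and keep per-database duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tedge_type\tmre_count\tdatabase",
               "lncA\tmiR1\tlnc_mi\t4\tmircode_like",
               "miR1\tmA\tmi_m\t5\tmiranda_like",
               "miR1\tmA\tmi_m\t3\ttargetscan_like"), path)
  rec <- read_interactions(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(sum(rec$source == "miR1" & rec$target == "mA"), 2L)

  writeLines(c("source\ttarget\tedge_type\tmre_count\tdatabase",
               "lncA\tmiR1\tlnc_mi\t-1\tmircode_like"), path)
  expect_error(read_interactions(path), "mre_count")
  writeLines(c("source\ttarget\tedge_type\tmre_count\tdatabase",
               "lncA\tmiR1\tweird\t2\tmircode_like"), path)
  expect_error(read_interactions(path), "edge_type")
})

test_that("GMT and Ct tables round-trip", {
  ann <- annotation_set(c("P1", "P2"), c("term one", "term two"), "pathway",
                        list(c("a", "b", "c"), c("b", "d")))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(ann, path)
  back <- read_gmt(path, "pathway")
  expect_identical(back$term_id, ann$term_id)
  expect_identical(back$members, ann$members)

  ct <- ct_table(data.frame(sample_id = c("s1", "s2"), patient_id = "p1",
                            group = c("tumor", "normal"), gene_id = "g",
                            ct_target = c(20.5, 22.1), ct_reference = 16))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_ct_table(ct, p2)
  expect_equal(read_ct_table(p2)$ct_target, ct$ct_target)
  expect_error(ct_table(transform(ct, ct_target = c(-1, 22))), "finite and > 0")
})

test_that("network export writes SIF + attributes and round-trips edges", {
  triads <- data.frame(lncRNA_id = "lncA", miRNA_id = "miR1", mRNA_id = "mA",
                       mre_lnc_mi = 4L, mre_mi_m = 3L, pearson_r = 0.95,
                       lnc_direction = "up", mi_direction = "down",
                       m_direction = "up", stringsAsFactors = FALSE)
  net <- build_network(triads)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)
  prefix <- file.path(withr::local_tempdir(), "net")
  write_network(net, prefix)
  sif <- read_sif(paste0(prefix, ".sif"))
  expect_setequal(paste(sif$source, sif$target),
                  paste(net$edges$source, net$edges$target))
  nodes <- utils::read.delim(paste0(prefix, ".nodes.tsv"))
  expect_equal(nrow(nodes), 3L)

  empty <- build_network(triads[0, , drop = FALSE])
  eprefix <- file.path(withr::local_tempdir(), "e")
  expect_warning(write_network(empty, eprefix), "empty")
  expect_equal(nrow(read_sif(paste0(eprefix, ".sif"))), 0L)
  expect_equal(nrow(utils::read.delim(paste0(eprefix, ".nodes.tsv"))), 0L)
})
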