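# Shared fixtures built in code.

# A reduced simulation configuration for unit tests: same structure as the
# default study conditions, smaller layers so a full pipeline run takes well
# under a second.
small_cfg <- function(seed = 1, ...) {
  args <- list(n_features = c(lncRNA = 150, miRNA = 100, mRNA = 300),
               n_triads = 4, n_decoys_per_filter = 2,
               n_extra_de = c(lncRNA = 5, miRNA = 5, mRNA = 10),
               n_background_edges = 30,
               n_terms = c(pathway = 12, GO_BP = 6, GO_MF = 6, GO_CC = 6),
               term_size_range = c(5, 40),
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# A tiny deterministic expression matrix.
toy_matrix <- function(n_feat = 3, n_samp = 4, layer = "mRNA", seed = 99) {
  set.seed(seed)
  m <- matrix(rpois(n_feat * n_samp, 40), n_feat, n_samp,
              dimnames = list(sprintf("g%02d", seq_len(n_feat)),
                              sprintf("s%02d", seq_len(n_samp))))
  expression_matrix(m, layer)
}

triad_key <- function(df) paste(df$lncRNA_id, df$miRNA_id, df$mRNA_id)
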