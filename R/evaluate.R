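# Recovery metrics against planted truth. These are the acceptance oracles
# for the synthetic-data contract: they only compare identifiers and
# directions, and never look inside the generator.

#' Differential-expression recovery against planted truth
#'
#' A planted feature counts as recovered when it is called differential with
#' the planted direction; any called feature not planted (or called with the
#' wrong direction) is a false discovery.
#'
#' @param de named list of `de_result` objects per layer.
#' @param truth_de the `de` component of a dataset truth (or a truth list).
#' @return List with `sensitivity`, `fdp`, `n_truth`, `n_called`,
#'   `n_recovered`.
#' @export
evaluate_de_recovery <- function(de, truth_de) {
  if (is.list(truth_de) && !is.data.frame(truth_de)) truth_de <- truth_de$de
  called <- do.call(rbind, lapply(de, function(x)
    x$table[x$table$is_de, c("feature_id", "layer", "direction")]))
  key <- function(df) paste(df$feature_id, df$layer, df$direction)
  truth_key <- key(truth_de)
  called_key <- if (nrow(called) > 0) key(called) else character(0)
  n_rec <- sum(truth_key %in% called_key)
  n_called <- length(called_key)
  list(sensitivity = if (nrow(truth_de) > 0) n_rec / nrow(truth_de) else NA_real_,
       fdp = if (n_called > 0) sum(!called_key %in% truth_key) / n_called else 0,
       n_truth = nrow(truth_de), n_called = n_called, n_recovered = n_rec)
}

#' ceRNA network recovery against planted truth
#'
#' Checks that planted triads survive the filters, that planted decoys do
#' not, and that each excluded decoy's recorded exclusion reason equals the
#' filter it was constructed to violate.
#'
#' @param result a `cerna_result` from [assemble_triads()].
#' @param truth a dataset truth (with `triads` and `decoys`).
#' @return List with `n_planted`, `n_recovered`, `triad_recovery`,
#'   `n_decoys`, `n_decoys_surviving`, `n_reason_mismatch`, and a per-decoy
#'   data frame `decoy_audit` (`decoy_id`, `category`, `status`, `reason`).
#' @export
evaluate_network_recovery <- function(result, truth) {
  tkey <- function(df) paste(df$lncRNA_id, df$miRNA_id, df$mRNA_id)
  planted <- tkey(truth$triads)
  surviving <- tkey(result$triads)
  excl_key <- tkey(result$exclusions)
  decoy_key <- tkey(truth$decoys)
  status <- ifelse(decoy_key %in% surviving, "survived",
                   ifelse(decoy_key %in% excl_key, "excluded", "absent"))
  reason <- result$exclusions$reason[match(decoy_key, excl_key)]
  audit <- data.frame(decoy_id = truth$decoys$decoy_id,
                      category = truth$decoys$category,
                      status = status, reason = reason,
                      stringsAsFactors = FALSE)
  list(n_planted = length(planted),
       n_recovered = sum(planted %in% surviving),
       triad_recovery = if (length(planted) > 0)
         mean(planted %in% surviving) else NA_real_,
       n_decoys = length(decoy_key),
       n_decoys_surviving = sum(status == "survived"),
       n_reason_mismatch = sum(status != "excluded" |
                                 is.na(reason) | reason != audit$category),
       decoy_audit = audit)
}
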