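#' Domain containers for the ceRNA workflow
#'
#' The pipeline works on three RNA layers measured on the same patients:
#' lncRNA, miRNA and mRNA raw count matrices with a paired tumour/normal
#' design. These light S3 constructors validate the invariants every stage
#' relies on (unique identifiers, non-negative integer counts, consistent
#' pairing) and fail early with a message naming the offending record.
#'
#' @param counts numeric matrix of raw counts, features in rows and samples in
#'   columns; `dimnames` must carry feature and sample identifiers.
#' @param layer one of `"lncRNA"`, `"miRNA"`, `"mRNA"`.
#' @return An object of class `expr_matrix`: a list with elements `layer` and
#'   `counts` (integer matrix with feature/sample dimnames).
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expression_matrix(m, "mRNA")
#' @export
expression_matrix <- function(counts, layer = c("lncRNA", "miRNA", "mRNA")) {
  layer <- match.arg(layer)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_named("expression matrix needs feature ids (rownames) and sample ids (colnames)")
  if (ncol(counts) < 2L)
    stop_named("expression matrix needs at least 2 samples, got ", ncol(counts))
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup) > 0)
    stop_named("duplicate feature id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  dup <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup) > 0)
    stop_named("duplicate sample id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts) || any(!is.finite(counts)))
    stop_named("counts must be finite numbers; missing values are not permitted")
  if (any(counts < 0))
    stop_named("negative count for feature ",
               rownames(counts)[which(counts < 0, arr.ind = TRUE)[1, 1]])
  if (any(counts != round(counts)))
    stop_named("non-integer count for feature ",
               rownames(counts)[which(counts != round(counts), arr.ind = TRUE)[1, 1]])
  storage.mode(counts) <- "double"
  structure(list(layer = layer, counts = counts), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d features x %d samples\n",
              x$layer, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

feature_ids <- function(em) rownames(em$counts)
sample_ids <- function(em) colnames(em$counts)

#' Paired tumour/normal design
#'
#' @param patient_id,tumor,normal character vectors of equal length; one row
#'   per patient with the identifiers of that patient's tumour and adjacent
#'   normal sample.
#' @return A `paired_design` data frame with columns `patient_id`, `tumor`,
#'   `normal`.
#' @export
paired_design <- function(patient_id, tumor, normal) {
  df <- data.frame(patient_id = as.character(patient_id),
                   tumor = as.character(tumor),
                   normal = as.character(normal),
                   stringsAsFactors = FALSE)
  if (nrow(df) < 1L) stop_named("design needs at least one pair")
  if (anyDuplicated(df$patient_id))
    stop_named("duplicate patient id in design: ",
               df$patient_id[duplicated(df$patient_id)][1])
  all_samples <- c(df$tumor, df$normal)
  if (anyDuplicated(all_samples))
    stop_named("sample appears in two pairs: ",
               all_samples[duplicated(all_samples)][1])
  class(df) <- c("paired_design", "data.frame")
  df
}

check_design <- function(design, em) {
  missing <- setdiff(c(design$tumor, design$normal), sample_ids(em))
  if (length(missing) > 0)
    stop_named("design sample(s) missing from ", em$layer, " matrix: ",
               paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Validate a table of putative RNA-RNA interaction records
#'
#' Interaction records stand in for entries retrieved from miRNA-target
#' databases: lncRNA-miRNA pairings (edge type `lnc_mi`, miRcode-style) and
#' miRNA-mRNA pairings (edge type `mi_m`, miRanda/TargetScan-style), each with
#' the number of miRNA response elements (MREs) supporting the pair and a tag
#' naming the source database. The same pair may appear once per database.
#'
#' @param df data frame with columns `source`, `target`, `edge_type`,
#'   `mre_count`, `database`.
#' @return The validated data frame with class `interaction_records`.
#' @export
interaction_records <- function(df) {
  required <- c("source", "target", "edge_type", "mre_count", "database")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_named("interaction table missing column(s): ", paste(missing, collapse = ", "))
  df <- df[required]
  for (col in c("source", "target", "edge_type", "database"))
    df[[col]] <- as.character(df[[col]])
  bad <- !df$edge_type %in% c("lnc_mi", "mi_m")
  if (any(bad))
    stop_named("unknown edge_type '", df$edge_type[bad][1], "' for pair ",
               df$source[bad][1], " - ", df$target[bad][1],
               " (expected lnc_mi or mi_m)")
  mre <- df$mre_count
  if (!is.numeric(mre) || anyNA(mre) || any(mre != round(mre)) || any(mre < 0)) {
    bad <- which(is.na(suppressWarnings(as.numeric(mre))) |
                   suppressWarnings(as.numeric(mre)) < 0 |
                   suppressWarnings(as.numeric(mre)) != round(suppressWarnings(as.numeric(mre))))
    stop_named("mre_count must be a non-negative integer; offending pair: ",
               df$source[bad[1]], " - ", df$target[bad[1]],
               " (mre_count = ", mre[bad[1]], ")")
  }
  df$mre_count <- as.integer(mre)
  class(df) <- c("interaction_records", "data.frame")
  df
}

#' Validate a qPCR Ct table
#'
#' One row per (sample, gene) with the threshold cycle of the target gene and
#' of the reference gene (beta-actin style) measured in the same sample.
#' `patient_id` links each tumour row to its paired normal row.
#'
#' @param df data frame with columns `sample_id`, `patient_id`, `group`
#'   (`tumor`/`normal`), `gene_id`, `ct_target`, `ct_reference`.
#' @return The validated data frame with class `ct_table`.
#' @export
ct_table <- function(df) {
  required <- c("sample_id", "patient_id", "group", "gene_id",
                "ct_target", "ct_reference")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_named("Ct table missing column(s): ", paste(missing, collapse = ", "))
  df <- df[required]
  if (!all(df$group %in% c("tumor", "normal")))
    stop_named("Ct table group must be 'tumor' or 'normal'")
  ct <- c(df$ct_target, df$ct_reference)
  if (!is.numeric(df$ct_target) || !is.numeric(df$ct_reference) ||
      anyNA(ct) || any(!is.finite(ct)) || any(ct <= 0))
    stop_named("Ct values must be finite and > 0")
  class(df) <- c("ct_table", "data.frame")
  df
}

#' ceRNA network container
#'
#' @param nodes data frame with columns `id`, `layer`, `direction`,
#'   `consensus_log2fc`.
#' @param edges data frame with columns `source`, `target`, `edge_type`,
#'   `mre_count`.
#' @return A `cerna_network` object (list with `nodes` and `edges`).
#' @export
cerna_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "layer", "direction", "consensus_log2fc") %in% names(nodes)),
            all(c("source", "target", "edge_type", "mre_count") %in% names(edges)))
  if (nrow(edges) > 0) {
    loose <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
    if (length(loose) > 0)
      stop_named("edge endpoint(s) not present as nodes: ",
                 paste(utils::head(loose, 5), collapse = ", "))
  }
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  tab <- table(factor(x$nodes$layer, levels = c("lncRNA", "miRNA", "mRNA")))
  cat(sprintf("cerna_network: %d nodes (%d lncRNA, %d miRNA, %d mRNA), %d edges\n",
              nrow(x$nodes), tab["lncRNA"], tab["miRNA"], tab["mRNA"], nrow(x$edges)))
  invisible(x)
}
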