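# Readers and writers for the plain-text formats the pipeline touches.
# All tables are tab-separated UTF-8 with a header row; feature ids are opaque
# strings. Count matrices admit no missing values.

#' Read a feature-by-sample count matrix
#'
#' Expects a tab-separated file whose first column holds feature identifiers
#' and whose header row holds sample identifiers.
#'
#' @param path path to a TSV file.
#' @param layer RNA layer tag, one of `"lncRNA"`, `"miRNA"`, `"mRNA"`.
#' @return An [expression_matrix()] object.
#' @export
read_expression_matrix <- function(path, layer = c("lncRNA", "miRNA", "mRNA")) {
  layer <- match.arg(layer)
  if (!file.exists(path)) stop_named("count file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop_named("count file needs a feature column and >=2 samples: ", path)
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop_named("duplicate feature id(s) in ", path, ": ",
               paste(utils::head(dup, 5), collapse = ", "))
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat))
    stop_named("non-numeric counts in ", path)
  rownames(mat) <- ids
  expression_matrix(mat, layer)
}

#' Write a count matrix to TSV
#'
#' @param em an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  df <- data.frame(feature_id = feature_ids(em),
                   em$counts, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a paired tumour/normal design table
#'
#' @param path TSV with columns `patient_id`, `tumor`, `normal`.
#' @return A [paired_design()] data frame.
#' @export
read_design <- function(path) {
  df <- read_tsv_strict(path, c("patient_id", "tumor", "normal"), "design")
  paired_design(df$patient_id, df$tumor, df$normal)
}

#' @rdname read_design
#' @param design a [paired_design()].
#' @export
write_design <- function(design, path) write_tsv(design, path)

#' Read an interaction table
#'
#' @param path TSV with columns `source`, `target`, `edge_type`, `mre_count`,
#'   `database`.
#' @return An [interaction_records()] data frame.
#' @export
read_interactions <- function(path) {
  df <- read_tsv_strict(path, c("source", "target", "edge_type", "mre_count", "database"),
                        "interaction")
  interaction_records(df)
}

#' @rdname read_interactions
#' @param records an [interaction_records()] data frame.
#' @export
write_interactions <- function(records, path) write_tsv(records, path)

#' Read a GMT-style annotation file
#'
#' One term per line: `term_id <TAB> term_name <TAB> member genes...`.
#'
#' @param path GMT file.
#' @param category annotation category tag: `"GO_BP"`, `"GO_MF"`, `"GO_CC"` or
#'   `"pathway"`.
#' @return An `annotation_set`: list with vectors `term_id`, `term_name`,
#'   `category` and list `members`.
#' @export
read_gmt <- function(path, category = c("pathway", "GO_BP", "GO_MF", "GO_CC")) {
  category <- match.arg(category)
  if (!file.exists(path)) stop_named("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3L
  if (any(short))
    stop_named("GMT line without members (need id, name, >=1 gene): line ",
               which(short)[1], " of ", path)
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop_named("duplicate term id in ", path, ": ", ids[duplicated(ids)][1])
  annotation_set(term_id = ids,
                 term_name = vapply(parts, `[[`, "", 2L),
                 category = category,
                 members = lapply(parts, function(p) unique(p[-(1:2)])))
}

#' Construct an annotation set
#'
#' @param term_id,term_name character vectors.
#' @param category scalar or vector of categories.
#' @param members list of character vectors of member gene ids.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(term_id, term_name, category, members) {
  n <- length(term_id)
  category <- rep_len(as.character(category), n)
  stopifnot(length(term_name) == n, length(members) == n,
            all(category %in% c("pathway", "GO_BP", "GO_MF", "GO_CC")))
  if (any(vapply(members, length, 1L) == 0L))
    stop_named("annotation term with empty member set: ",
               term_id[vapply(members, length, 1L) == 0L][1])
  for (cat in unique(category)) {
    ids <- term_id[category == cat]
    if (anyDuplicated(ids))
      stop_named("duplicate term id within category ", cat, ": ",
                 ids[duplicated(ids)][1])
  }
  structure(list(term_id = as.character(term_id),
                 term_name = as.character(term_name),
                 category = category,
                 members = members),
            class = "annotation_set")
}

#' @rdname read_gmt
#' @param anns an `annotation_set` (single category).
#' @export
write_gmt <- function(anns, path) {
  lines <- mapply(function(id, nm, mem) paste(c(id, nm, mem), collapse = "\t"),
                  anns$term_id, anns$term_name, anns$members)
  writeLines(lines, path)
  invisible(path)
}

#' Combine annotation sets across categories
#' @param ... `annotation_set` objects.
#' @return A single `annotation_set`.
#' @export
c_annotation_sets <- function(...) {
  sets <- list(...)
  annotation_set(term_id = unlist(lapply(sets, `[[`, "term_id")),
                 term_name = unlist(lapply(sets, `[[`, "term_name")),
                 category = unlist(lapply(sets, `[[`, "category")),
                 members = do.call(c, lapply(sets, `[[`, "members")))
}

#' Read / write a qPCR Ct table
#'
#' @param path TSV with the [ct_table()] columns.
#' @return A [ct_table()] data frame.
#' @export
read_ct_table <- function(path) {
  df <- read_tsv_strict(path, c("sample_id", "patient_id", "group", "gene_id",
                                "ct_target", "ct_reference"), "Ct")
  ct_table(df)
}

#' @rdname read_ct_table
#' @param ct a [ct_table()].
#' @export
write_ct_table <- function(ct, path) write_tsv(ct, path)

#' Export a ceRNA network for graph-visualization tools
#'
#' Writes three files: `<prefix>.sif` (simple interaction format,
#' `source TAB targets TAB target` — SIF has no attribute slots, so the
#' interaction label is always `targets`), `<prefix>.nodes.tsv` (id, layer,
#' direction, consensus_log2fc) and `<prefix>.edges.tsv` (source, target,
#' edge_type, mre_count).
#'
#' @param network a [cerna_network()].
#' @param prefix output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_network <- function(network, prefix) {
  stopifnot(inherits(network, "cerna_network"))
  sif <- paste0(prefix, ".sif")
  if (nrow(network$edges) == 0) {
    warning("writing an empty ceRNA network", call. = FALSE)
    writeLines(character(0), sif)
  } else {
    writeLines(paste(network$edges$source, "targets", network$edges$target,
                     sep = "\t"), sif)
  }
  nodes_path <- paste0(prefix, ".nodes.tsv")
  edges_path <- paste0(prefix, ".edges.tsv")
  write_tsv(network$nodes, nodes_path)
  write_tsv(network$edges, edges_path)
  invisible(c(sif, nodes_path, edges_path))
}

#' Read back a SIF edge file
#'
#' @param path a `.sif` file written by [write_network()].
#' @return Data frame with columns `source`, `interaction`, `target`.
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) stop_named("SIF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(source = character(0), interaction = character(0),
                      target = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) stop_named("malformed SIF line ", which(bad)[1], " in ", path)
  data.frame(source = vapply(parts, `[[`, "", 1L),
             interaction = vapply(parts, `[[`, "", 2L),
             target = vapply(parts, `[[`, "", 3L),
             stringsAsFactors = FALSE)
}
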