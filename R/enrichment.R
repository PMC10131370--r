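#' Hypergeometric over-representation analysis
#'
#' Standard one-sided over-representation test of a query gene set (here: the
#' mRNAs of the ceRNA network) against term-membership annotations. For a term
#' containing K of the N background genes, with n query genes of which k fall
#' in the term, the p-value is the hypergeometric upper tail
#' \deqn{p = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' p-values are Benjamini-Hochberg adjusted within each annotation category,
#' and rows are returned sorted by category and ascending p.
#'
#' @param query character vector of query gene ids; every query gene must be
#'   in the background (absent genes raise an error rather than being dropped
#'   silently).
#' @param annotations an [annotation_set()] (may span several categories).
#' @param background optional character vector of background gene ids; by
#'   default, all genes carrying at least one annotation in the term's
#'   category. Term memberships are intersected with the background.
#' @return Data frame with columns `term_id`, `term_name`, `category`, `k`,
#'   `K`, `n`, `N`, `p`, `p_adj`.
#' @export
hypergeom_enrich <- function(query, annotations, background = NULL) {
  stopifnot(inherits(annotations, "annotation_set"))
  query <- unique(as.character(query))
  if (length(annotations$term_id) == 0) stop_named("annotations are empty")
  out <- lapply(unique(annotations$category), function(cat) {
    sel <- annotations$category == cat
    members <- annotations$members[sel]
    bg <- if (is.null(background)) unique(unlist(members)) else unique(as.character(background))
    missing <- setdiff(query, bg)
    if (length(missing) > 0)
      stop_named("query gene(s) absent from the ", cat, " background: ",
                 paste(utils::head(missing, 5), collapse = ", "))
    members <- lapply(members, intersect, bg)
    kk <- vapply(members, function(m) length(intersect(m, query)), 1L)
    bigk <- vapply(members, length, 1L)
    n <- length(query)
    bign <- length(bg)
    keep <- bigk > 0
    p <- stats::phyper(kk[keep] - 1L, bigk[keep], bign - bigk[keep], n,
                       lower.tail = FALSE)
    df <- data.frame(term_id = annotations$term_id[sel][keep],
                     term_name = annotations$term_name[sel][keep],
                     category = cat, k = kk[keep], K = bigk[keep],
                     n = n, N = bign, p = p,
                     p_adj = stats::p.adjust(p, method = "BH"),
                     stringsAsFactors = FALSE)
    df[order(df$p, -df$k, df$term_id), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Top enriched terms of a category
#'
#' Returns the most significant terms of one category, with ties on p broken
#' by larger overlap k and then lexicographic term id. Default limits follow
#' the usual reporting convention: 20 for pathways, 10 per GO category.
#'
#' @param rows result of [hypergeom_enrich()].
#' @param category one of `"pathway"`, `"GO_BP"`, `"GO_MF"`, `"GO_CC"`.
#' @param limit maximum number of rows (default 20 for pathway, 10 otherwise).
#' @return The selected rows of `rows`.
#' @export
top_terms <- function(rows, category, limit = NULL) {
  stopifnot(category %in% c("pathway", "GO_BP", "GO_MF", "GO_CC"))
  if (is.null(limit)) limit <- if (category == "pathway") 20L else 10L
  sel <- rows[rows$category == category, , drop = FALSE]
  sel <- sel[order(sel$p, -sel$k, sel$term_id), , drop = FALSE]
  out <- utils::head(sel, limit)
  rownames(out) <- NULL
  out
}
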