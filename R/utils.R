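# Internal helpers shared across modules.

geomean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a pinned, restored RNG state
#'
#' The generator contracts require bit-identical output for a given seed across
#' platforms, so the RNG algorithm is pinned (Mersenne-Twister / Inversion /
#' Rejection) and the caller's RNG state is restored afterwards.
#' @noRd
with_pinned_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  old_kind <- RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_named <- function(...) stop(..., call. = FALSE)

read_tsv_strict <- function(path, required, what) {
  if (!file.exists(path)) stop_named(what, " file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_named(what, " file ", path, " is missing column(s): ",
               paste(missing, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
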