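# Internal helpers: classed conditions, RNG scoping, TSV round-trips.

coex_param_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("coex_param_error", "coex_error")))
}

coex_data_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("coex_data_error", "coex_error")))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    coex_param_error("'seed' must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Write a matrix as TSV with an id column
#'
#' First column holds row names (default \code{gene_id}), remaining columns
#' are the matrix columns. Used for expression matrices, correlation/TOM
#' matrices and trend tables.
#'
#' @param x numeric matrix with row and column names.
#' @param path output file path.
#' @param id_col name for the first column.
#' @export
write_tsv_matrix <- function(x, path, id_col = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by \code{write_tsv_matrix}
#'
#' @param path TSV file whose first column holds row identifiers.
#' @return numeric matrix with row names from the first column.
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

write_tsv_df <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_df <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
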