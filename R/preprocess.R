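# Log2 transformation, replicate averaging and the coefficient-of-variation
# filter applied to treatment-averaged expression profiles.

#' Log2-transform an expression matrix
#'
#' @param exprs numeric gene x sample matrix of expression indices.
#' @param offset nonnegative constant added before taking logs.
#' @return matrix of \code{log2(exprs + offset)}, same shape.
#' @export
log_transform <- function(exprs, offset = 0) {
  if (offset < 0) coex_param_error("'offset' must be nonnegative")
  bad <- which(exprs + offset <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    g <- rownames(exprs)[bad[1, 1]] %||% bad[1, 1]
    s <- colnames(exprs)[bad[1, 2]] %||% bad[1, 2]
    coex_data_error("nonpositive expression value at gene ", g,
                    ", sample ", s, " (offset ", offset, ")")
  }
  log2(exprs + offset)
}

#' Average replicate arrays within each treatment
#'
#' Biological and technical replicates are treated identically. Treatment
#' order in the output follows first appearance in the sample sheet.
#'
#' @param exprs gene x sample matrix (log2 scale).
#' @param samples sample sheet data frame with columns \code{sample_id} and
#'   \code{treatment}; every matrix column must be listed.
#' @return gene x treatment matrix of per-treatment means.
#' @export
average_replicates <- function(exprs, samples) {
  missing <- setdiff(colnames(exprs), samples$sample_id)
  if (length(missing) > 0) {
    coex_data_error("expression columns absent from the sample sheet: ",
                    paste(missing, collapse = ", "))
  }
  sheet <- samples[samples$sample_id %in% colnames(exprs), , drop = FALSE]
  treatments <- unique(sheet$treatment)
  out <- vapply(treatments, function(tr) {
    cols <- sheet$sample_id[sheet$treatment == tr]
    rowMeans(exprs[, cols, drop = FALSE])
  }, numeric(nrow(exprs)))
  out <- matrix(out, nrow = nrow(exprs),
                dimnames = list(rownames(exprs), treatments))
  out
}

#' Filter genes by coefficient of variation
#'
#' For each gene the CV is the ratio of the standard deviation (n-1
#' denominator) to the mean of its treatment-averaged log2 values; genes are
#' kept when CV >= cutoff (boundary inclusive). Genes with nonpositive mean
#' have an undefined CV and are dropped with a flag. \code{invert = TRUE}
#' applies the reciprocal convention (mean/sd, keep when <= cutoff) instead.
#'
#' @param treatment_matrix gene x treatment matrix from
#'   \code{\link{average_replicates}}.
#' @param cutoff positive CV cutoff.
#' @param invert use the mean/sd orientation with a keep-if-<= rule.
#' @return list with \code{kept} and \code{dropped} gene id vectors,
#'   \code{table} (gene_id, mu, sigma, cv, kept, flagged) and \code{matrix},
#'   the kept submatrix.
#' @export
cv_filter <- function(treatment_matrix, cutoff, invert = FALSE) {
  if (nrow(treatment_matrix) == 0) coex_data_error("empty treatment matrix")
  if (cutoff <= 0) coex_param_error("'cutoff' must be > 0")
  mu <- rowMeans(treatment_matrix)
  sigma <- apply(treatment_matrix, 1, stats::sd)
  cv <- ifelse(mu > 0, sigma / mu, NA_real_)
  if (invert) {
    stat <- ifelse(mu > 0 & sigma > 0, mu / sigma, NA_real_)
    kept <- !is.na(stat) & stat <= cutoff
  } else {
    kept <- !is.na(cv) & cv >= cutoff
  }
  tab <- data.frame(gene_id = rownames(treatment_matrix), mu = mu,
                    sigma = sigma, cv = cv, kept = kept,
                    flagged = is.na(cv), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(kept = tab$gene_id[kept], dropped = tab$gene_id[!kept], table = tab,
       matrix = treatment_matrix[kept, , drop = FALSE])
}
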