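# Cross-experiment comparison of module memberships, and comparison of
# condition-dependent against condition-independent analyses.

#' Build membership profiles across analyses
#'
#' @param partitions named list of labeled \code{module_partition} objects,
#'   one per experiment; names are experiment ids.
#' @return list with \code{assignments} (data frame: gene_id, experiment_id,
#'   module), \code{analyzed} (named list of analyzed-gene vectors) and
#'   \code{assigned} (named list of assigned-gene vectors).
#' @export
membership_profiles <- function(partitions) {
  if (length(partitions) == 0) coex_param_error("no partitions supplied")
  if (is.null(names(partitions))) {
    coex_param_error("'partitions' must be named by experiment id")
  }
  rows <- lapply(names(partitions), function(ex) {
    p <- partitions[[ex]]
    asg <- p$colors[p$colors != "unassigned"]
    if (length(asg) == 0) return(NULL)
    data.frame(gene_id = names(asg), experiment_id = ex, module = unname(asg),
               stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  if (is.null(assignments)) {
    assignments <- data.frame(gene_id = character(0),
                              experiment_id = character(0),
                              module = character(0))
  }
  list(assignments = assignments,
       analyzed = lapply(partitions, function(p) names(p$colors)),
       assigned = lapply(partitions, function(p)
         names(p$colors)[p$colors != "unassigned"]))
}

#' Distribution of per-gene module membership across experiments
#'
#' Counts, for each number of experiments, how many genes were assigned to a
#' module in exactly that many experiments. Genes never assigned anywhere are
#' excluded.
#'
#' @param profiles list from \code{\link{membership_profiles}}.
#' @return data frame (n_experiments, n_genes); the counts sum to the number
#'   of distinct genes assigned anywhere.
#' @export
membership_distribution <- function(profiles) {
  a <- profiles$assignments
  if (nrow(a) == 0) {
    return(data.frame(n_experiments = integer(0), n_genes = integer(0)))
  }
  per_gene <- tapply(a$experiment_id, a$gene_id,
                     function(x) length(unique(x)))
  tab <- table(per_gene)
  data.frame(n_experiments = as.integer(names(tab)),
             n_genes = as.integer(tab))
}

#' Four-way assignment counts over the common analyzed genes
#'
#' Over genes analyzed under both strategies: assigned in both, in the
#' condition-dependent analysis only, in the condition-independent analysis
#' only, or in neither. Genes analyzed under only one strategy are reported
#' as margins.
#'
#' @param dep list with \code{analyzed} and \code{assigned} gene vectors for
#'   the condition-dependent side (unions across its experiments).
#' @param indep same for the condition-independent side.
#' @return one-row data frame with the four counts, the common-gene count and
#'   the strategy-specific analyzed-only margins.
#' @export
venn_counts <- function(dep, indep) {
  common <- intersect(dep$analyzed, indep$analyzed)
  da <- intersect(dep$assigned, common)
  ia <- intersect(indep$assigned, common)
  both <- length(intersect(da, ia))
  dep_only <- length(setdiff(da, ia))
  indep_only <- length(setdiff(ia, da))
  neither <- length(common) - both - dep_only - indep_only
  data.frame(common_analyzed = length(common), both = both,
             dep_only = dep_only, indep_only = indep_only, neither = neither,
             dep_analyzed_only = length(setdiff(dep$analyzed, indep$analyzed)),
             indep_analyzed_only = length(setdiff(indep$analyzed, dep$analyzed)))
}

#' Overlap matrix between condition-dependent and -independent modules
#'
#' Rows are condition-dependent modules (one per experiment, labeled
#' \code{experiment-color}); columns are condition-independent modules plus
#' explicit \code{unassigned} and \code{not_analyzed} columns, so row sums
#' equal module sizes exactly.
#'
#' @param dep_partitions named list of labeled partitions (condition-dependent).
#' @param indep_partition labeled partition of the combined analysis.
#' @return integer matrix of gene counts.
#' @export
module_overlap_matrix <- function(dep_partitions, indep_partition) {
  indep_cols <- c(setdiff(unique(indep_partition$colors), "unassigned"),
                  "unassigned", "not_analyzed")
  rows <- list()
  for (ex in names(dep_partitions)) {
    p <- dep_partitions[[ex]]
    for (mod in setdiff(unique(p$colors), "unassigned")) {
      genes <- module_genes(p, mod)
      status <- ifelse(genes %in% names(indep_partition$colors),
                       indep_partition$colors[genes], "not_analyzed")
      rows[[paste0(ex, "-", mod)]] <-
        vapply(indep_cols, function(cc) sum(status == cc), integer(1))
    }
  }
  if (length(rows) == 0) {
    return(matrix(integer(0), nrow = 0, ncol = length(indep_cols),
                  dimnames = list(NULL, indep_cols)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- names(rows)
  out
}
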