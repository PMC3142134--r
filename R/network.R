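# Unsigned weighted coexpression network: Pearson correlation, soft-power
# adjacency a = |r|^beta, topological overlap, average-linkage clustering of
# the 1 - TOM dissimilarity, static tree cut, color labels, eigengenes and
# Z-score trend summaries.

#' Network analysis parameters
#'
#' @param beta soft-thresholding power (>= 1). Published analyses of the rice
#'   compendium used values between 4 and 30 per experiment.
#' @param tree_cut dendrogram cut height in (0, 1]; larger values assign more
#'   genes to more modules.
#' @param min_module_size smallest gene count reported as a module.
#' @param rsq_cut scale-free fit index required before a candidate beta is
#'   recommended.
#' @return list of class \code{network_params}.
#' @export
network_params <- function(beta = 6, tree_cut = 0.95, min_module_size = 30,
                           rsq_cut = 0.85) {
  if (beta < 1) coex_param_error("'beta' must be >= 1")
  if (tree_cut <= 0 || tree_cut > 1) {
    coex_param_error("'tree_cut' must be in (0, 1]")
  }
  if (min_module_size < 2) coex_param_error("'min_module_size' must be >= 2")
  if (rsq_cut <= 0 || rsq_cut > 1) coex_param_error("'rsq_cut' must be in (0, 1]")
  structure(list(beta = beta, tree_cut = tree_cut,
                 min_module_size = as.integer(min_module_size),
                 rsq_cut = rsq_cut),
            class = "network_params")
}

#' Pearson correlation matrix over treatment profiles
#'
#' @param treatment_matrix gene x treatment matrix (>= 3 treatments); genes
#'   with zero variance must already have been removed (the CV filter
#'   guarantees this).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(treatment_matrix) {
  if (ncol(treatment_matrix) < 3) {
    coex_param_error("at least 3 treatments are required")
  }
  sds <- apply(treatment_matrix, 1, stats::sd)
  if (any(sds == 0)) {
    coex_data_error("zero-variance gene(s): ",
                    paste(utils::head(rownames(treatment_matrix)[sds == 0], 5),
                          collapse = ", "))
  }
  r <- stats::cor(t(treatment_matrix))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Soft-thresholded unsigned adjacency
#'
#' @param corr correlation matrix.
#' @param beta soft power; \code{a_ij = |r_ij|^beta}. Unsigned adjacency lets
#'   positively and negatively correlated genes share a module.
#' @return adjacency matrix in [0, 1] with unit diagonal.
#' @export
soft_adjacency <- function(corr, beta) {
  if (beta < 1) coex_param_error("'beta' must be >= 1")
  a <- abs(corr)^beta
  diag(a) <- 1
  a
}

#' Whole-network connectivity
#'
#' @param adjacency adjacency matrix with unit diagonal.
#' @return per-gene connectivity \code{k_i}, the sum of off-diagonal
#'   adjacencies.
#' @export
connectivity <- function(adjacency) {
  rowSums(adjacency) - diag(adjacency)
}

#' Signed scale-free topology fit index
#'
#' Bins connectivities into \code{n_bins} equal-width bins, regresses
#' log10(bin frequency) on log10(bin mean connectivity) over nonempty bins and
#' returns \code{-sign(slope) * R^2}, so 1 means a perfect decreasing
#' power-law fit.
#'
#' @param adjacency adjacency matrix.
#' @param n_bins number of connectivity bins.
#' @return fit index in [-1, 1], or NA (with a warning and an
#'   \code{explanation} attribute) when all connectivities coincide.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  k <- connectivity(adjacency)
  if (sum(k > 0) < n_bins) {
    coex_data_error("need at least ", n_bins, " genes with positive connectivity")
  }
  if (max(k) - min(k) < .Machine$double.eps^0.5) {
    warning("all connectivities identical; scale-free fit index undefined")
    return(structure(NA_real_,
                     explanation = "all connectivities identical"))
  }
  bins <- cut(k, breaks = seq(min(k), max(k), length.out = n_bins + 1),
              include.lowest = TRUE)
  freq <- as.numeric(table(bins)) / length(k)
  kmean <- tapply(k, bins, mean)
  ok <- freq > 0 & !is.na(kmean) & kmean > 0
  y <- log10(freq[ok])
  fit <- stats::lm(y ~ log10(as.numeric(kmean[ok])))
  slope <- stats::coef(fit)[2L]
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  as.numeric(-sign(slope) * r2)
}

#' Recommend a soft power
#'
#' Returns the smallest candidate whose scale-free fit index reaches
#' \code{rsq_cut}, or the candidate with the best index when none does. An
#' explicitly chosen beta always takes precedence in the pipeline; the
#' recommendation is advisory, mirroring how the published analyses treated
#' it.
#'
#' @param corr correlation matrix.
#' @param candidates candidate powers.
#' @param rsq_cut required fit index.
#' @param n_bins bins for \code{\link{scale_free_fit}}.
#' @return list with \code{beta} and \code{table} (beta, fit_index, mean_k,
#'   max_k).
#' @export
pick_beta <- function(corr, candidates = c(1:10, seq(12, 20, 2), seq(24, 30, 3)),
                      rsq_cut = 0.85, n_bins = 10) {
  if (length(candidates) == 0) coex_param_error("'candidates' must be nonempty")
  rows <- lapply(candidates, function(b) {
    a <- soft_adjacency(corr, b)
    idx <- suppressWarnings(tryCatch(scale_free_fit(a, n_bins),
                                     coex_data_error = function(e) NA_real_))
    k <- connectivity(a)
    data.frame(beta = b, fit_index = as.numeric(idx), mean_k = mean(k),
               max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  hit <- which(!is.na(tab$fit_index) & tab$fit_index >= rsq_cut)
  beta <- if (length(hit) > 0) {
    tab$beta[hit[1L]]
  } else if (all(is.na(tab$fit_index))) {
    tab$beta[1L]
  } else {
    tab$beta[which.max(tab$fit_index)]
  }
  list(beta = beta, table = tab)
}

#' Topological overlap matrix
#'
#' \deqn{\omega_{ij} = (l_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})}
#' with \eqn{l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}}; the diagonal is 1. Two
#' genes overlap strongly when they are directly connected and share strongly
#' connected neighbors.
#'
#' @param adjacency adjacency matrix in [0, 1] with unit diagonal.
#' @return symmetric TOM with entries in [0, 1].
#' @export
topological_overlap <- function(adjacency) {
  a0 <- adjacency
  diag(a0) <- 0
  l <- a0 %*% a0
  k <- rowSums(a0)
  denom <- outer(k, k, pmin) + 1 - a0
  omega <- (l + a0) / denom
  diag(omega) <- 1
  omega
}

#' Cluster genes on topological-overlap dissimilarity
#'
#' Average-linkage agglomeration of \code{d = 1 - TOM}.
#'
#' @param tom topological overlap matrix.
#' @return an \code{\link[stats]{hclust}} tree.
#' @export
cluster_genes <- function(tom) {
  if (nrow(tom) < 2) coex_param_error("at least 2 genes are required")
  stats::hclust(stats::as.dist(1 - tom), method = "average")
}

# Static cut: maximal subtrees whose internal merge heights are all <= cut
# (inclusive). Average linkage has monotone heights, so walking the merge list
# in order and finalizing children of any too-high merge is exact.
static_cut <- function(tree, cut_height) {
  n <- length(tree$order)
  members <- vector("list", n - 1L)
  clusters <- list()
  get_members <- function(x) if (x < 0) -x else members[[x]]
  finalize <- function(x) {
    mm <- get_members(x)
    if (length(mm) > 0) clusters[[length(clusters) + 1L]] <<- mm
  }
  for (i in seq_len(n - 1L)) {
    a <- tree$merge[i, 1L]; b <- tree$merge[i, 2L]
    if (tree$height[i] <= cut_height) {
      members[[i]] <- c(get_members(a), get_members(b))
    } else {
      finalize(a); finalize(b)
      members[[i]] <- integer(0)
    }
  }
  finalize(n - 1L)
  # singletons cut away below the root appear through their parent merges;
  # anything never finalized is a singleton leaf under a too-high merge
  seen <- unlist(clusters, use.names = FALSE)
  clusters <- c(clusters, as.list(setdiff(seq_len(n), seen)))
  clusters
}

#' Detect modules by a static tree cut
#'
#' Every maximal subtree merging entirely at or below \code{tree_cut} is a
#' candidate cluster; candidates reaching \code{min_module_size} become
#' modules and all remaining genes are unassigned. The assigned-gene count is
#' non-decreasing in \code{tree_cut}.
#'
#' @param dendro tree from \code{\link{cluster_genes}}.
#' @param params a \code{\link{network_params}} object (or a list with
#'   \code{tree_cut} and \code{min_module_size}).
#' @return object of class \code{module_partition}: list with \code{labels}
#'   (named integer vector, 0 = unassigned, modules numbered by decreasing
#'   size), \code{sizes}, and \code{params}.
#' @export
cut_modules <- function(dendro, params) {
  tree_cut <- params$tree_cut
  min_size <- params$min_module_size
  if (tree_cut <= 0 || tree_cut > 1) {
    coex_param_error("'tree_cut' must be in (0, 1]")
  }
  genes <- dendro$labels
  n <- length(genes)
  if (min_size > n) {
    warning("min_module_size exceeds the gene count; all genes unassigned")
  }
  clusters <- static_cut(dendro, tree_cut)
  keep <- clusters[vapply(clusters, length, integer(1)) >= min_size]
  # order modules by decreasing size, ties by smallest first-gene index
  if (length(keep) > 0) {
    ord <- order(-vapply(keep, length, integer(1)),
                 vapply(keep, min, integer(1)))
    keep <- keep[ord]
  }
  labels <- stats::setNames(integer(n), genes)
  for (i in seq_along(keep)) labels[keep[[i]]] <- i
  sizes <- vapply(keep, length, integer(1))
  structure(list(labels = labels, sizes = sizes, params = params),
            class = "module_partition")
}

#' Standard module color sequence
#'
#' The conventional color ordering used to name coexpression modules by
#' decreasing size; the fifteenth color is midnightblue.
#'
#' @return character vector of color names.
#' @export
standard_module_colors <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")
}

#' Label modules with the standard color sequence
#'
#' Modules sorted by decreasing size (ties by smallest first-gene index)
#' receive turquoise, blue, brown, ... in order; beyond the named sequence,
#' numbered \code{moduleNN} labels are used. Unassigned genes keep the
#' reserved label \code{"unassigned"}.
#'
#' @param partition a \code{module_partition} from \code{\link{cut_modules}}.
#' @return the partition with added \code{colors} (named character vector per
#'   gene) and \code{module_colors} (color per module index).
#' @export
label_module_colors <- function(partition) {
  n_mod <- length(partition$sizes)
  pal <- standard_module_colors()
  cols <- if (n_mod <= length(pal)) pal[seq_len(n_mod)] else {
    c(pal, sprintf("module%02d", seq.int(length(pal) + 1L, n_mod)))[seq_len(n_mod)]
  }
  gene_colors <- rep("unassigned", length(partition$labels))
  assigned <- partition$labels > 0
  gene_colors[assigned] <- cols[partition$labels[assigned]]
  names(gene_colors) <- names(partition$labels)
  partition$colors <- gene_colors
  partition$module_colors <- cols
  partition
}

#' Genes belonging to one module
#'
#' @param partition a labeled \code{module_partition}.
#' @param module module color (or index).
#' @return character vector of gene ids.
#' @export
module_genes <- function(partition, module) {
  if (is.numeric(module)) {
    names(partition$labels)[partition$labels == module]
  } else {
    names(partition$colors)[partition$colors == module]
  }
}

row_zscore <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  (m - mu) / sd
}

#' Module eigengene and anti-correlation sign groups
#'
#' The eigengene is the first principal component of the module's z-scored
#' gene x treatment submatrix, oriented to correlate non-negatively with the
#' module's mean z profile. Each gene's sign group is the sign of its
#' correlation with the eigengene (zero counts as positive); genes in the
#' negative group are the module's anti-correlated members.
#'
#' @param treatment_matrix gene x treatment matrix.
#' @param partition labeled \code{module_partition}.
#' @param module module color or index.
#' @return list with \code{eigengene} (named by treatment), \code{signs}
#'   (+1/-1 per gene), and \code{var_explained}.
#' @export
module_eigengene <- function(treatment_matrix, partition, module) {
  genes <- module_genes(partition, module)
  if (length(genes) < 2) coex_param_error("module must have >= 2 genes")
  sub <- treatment_matrix[genes, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) coex_data_error("constant gene(s) in module submatrix")
  z <- row_zscore(sub)
  sv <- svd(z)
  eig <- sv$v[, 1L]
  ref <- colMeans(z)
  if (stats::sd(ref) > 0 && stats::cor(eig, ref) < 0) eig <- -eig
  signs <- vapply(seq_len(nrow(z)), function(i) {
    r <- stats::cor(z[i, ], eig)
    if (is.na(r) || r >= 0) 1 else -1
  }, numeric(1))
  names(signs) <- genes
  names(eig) <- colnames(treatment_matrix)
  list(eigengene = eig,
       signs = signs,
       var_explained = sv$d[1L]^2 / sum(sv$d^2))
}

#' Z-score trend summaries per module and sign group
#'
#' Each gene's profile is standardized across treatments; module trends are
#' the mean z per treatment within each sign group. Unassigned genes receive
#' singleton trends (their own z profile), returned separately.
#'
#' @param treatment_matrix gene x treatment matrix.
#' @param partition labeled \code{module_partition}.
#' @return list with \code{z} (all-gene z matrix), \code{module_trends}
#'   (long data frame: module, sign_group, treatment, mean_z, n_genes) and
#'   \code{unassigned_z} (z matrix of unassigned genes).
#' @export
trend_summary <- function(treatment_matrix, partition) {
  genes <- names(partition$colors)
  m <- treatment_matrix[genes, , drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warning("excluding constant gene(s) from trend summary: ",
            paste(utils::head(genes[sds == 0], 5), collapse = ", "))
    genes <- genes[sds > 0]
    m <- m[genes, , drop = FALSE]
  }
  z <- row_zscore(m)
  treatments <- colnames(treatment_matrix)
  rows <- list()
  for (col in unique(partition$colors[genes])) {
    if (col == "unassigned") next
    eg <- module_eigengene(treatment_matrix, partition, col)
    for (sg in c(1, -1)) {
      gg <- intersect(names(eg$signs)[eg$signs == sg], genes)
      if (length(gg) == 0) next
      mz <- colMeans(z[gg, , drop = FALSE])
      rows[[paste(col, sg)]] <- data.frame(
        module = col, sign_group = if (sg > 0) "+" else "-",
        treatment = treatments, mean_z = as.numeric(mz),
        n_genes = length(gg), stringsAsFactors = FALSE)
    }
  }
  trends <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(0), sign_group = character(0),
               treatment = character(0), mean_z = numeric(0),
               n_genes = integer(0))
  rownames(trends) <- NULL
  un <- intersect(names(partition$colors)[partition$colors == "unassigned"],
                  genes)
  list(z = z, module_trends = trends,
       unassigned_z = z[un, , drop = FALSE])
}
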