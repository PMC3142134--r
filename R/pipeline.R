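# Orchestration: per-experiment (condition-dependent) and pooled
# (condition-independent) analyses from a single configuration.

#' Build an analysis configuration
#'
#' @param experiments list of per-experiment blocks; each a list with
#'   \code{id}, \code{exprs} (matrix or TSV path), \code{samples} (data frame
#'   or TSV path), \code{cv_cutoff}, \code{params}
#'   (\code{\link{network_params}}), and optional \code{exclude_samples} /
#'   \code{exclude_treatments} (explicit, config-driven exclusions; chip-level
#'   quality screening is deliberately not automated).
#' @param annotations optional annotation data frame or TSV path
#'   (gene_id, domain_id).
#' @param combined list with \code{cv_cutoff} and \code{params} for the
#'   pooled, condition-independent analysis. The published combined analysis
#'   of the rice compendium used CV 0.9, beta 4 and tree cut 0.95.
#' @param values_are_log2 set TRUE when input matrices are already on the
#'   log2 scale (synthetic data is generated in log2 units); otherwise a log2
#'   transform is applied first.
#' @param out_dir directory for reports.
#' @param seed integer recorded in run logs.
#' @return list of class \code{analysis_config}.
#' @export
analysis_config <- function(experiments, annotations = NULL,
                            combined = list(cv_cutoff = 0.9,
                                            params = network_params(beta = 4,
                                                                    tree_cut = 0.95)),
                            values_are_log2 = FALSE, out_dir = NULL,
                            seed = 1L) {
  ids <- vapply(experiments, function(e) e$id, character(1))
  if (anyDuplicated(ids)) coex_param_error("experiment ids must be unique")
  structure(list(experiments = experiments, annotations = annotations,
                 combined = combined, values_are_log2 = values_are_log2,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Structured key-value mirror of \code{\link{analysis_config}}: top-level
#' keys \code{experiments} (list of blocks with \code{id}, \code{exprs},
#' \code{samples}, \code{cv_cutoff}, \code{beta}, \code{tree_cut},
#' \code{min_module_size}, optional exclusions), \code{annotations},
#' \code{combined}, \code{values_are_log2}, \code{out_dir}, \code{seed}.
#'
#' @param path YAML file path; relative data paths are resolved against its
#'   directory.
#' @return an \code{analysis_config}.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(base, p)
  }
  block_params <- function(b) {
    network_params(beta = b$beta %||% 6, tree_cut = b$tree_cut %||% 0.95,
                   min_module_size = b$min_module_size %||% 30)
  }
  experiments <- lapply(y$experiments, function(b) {
    list(id = b$id, exprs = resolve(b$exprs), samples = resolve(b$samples),
         cv_cutoff = b$cv_cutoff %||% 0.6, params = block_params(b),
         exclude_samples = as.character(b$exclude_samples %||% character(0)),
         exclude_treatments = as.character(b$exclude_treatments %||% character(0)))
  })
  combined <- list(
    cv_cutoff = y$combined$cv_cutoff %||% 0.9,
    params = network_params(beta = y$combined$beta %||% 4,
                            tree_cut = y$combined$tree_cut %||% 0.95,
                            min_module_size = y$combined$min_module_size %||% 30))
  analysis_config(experiments = experiments,
                  annotations = resolve(y$annotations),
                  combined = combined,
                  values_are_log2 = isTRUE(y$values_are_log2),
                  out_dir = y$out_dir, seed = y$seed %||% 1L)
}

load_experiment_data <- function(block) {
  exprs <- block$exprs
  if (is.character(exprs)) exprs <- read_tsv_matrix(exprs)
  samples <- block$samples
  if (is.character(samples)) samples <- read_tsv_df(samples)
  drop <- samples$sample_id %in% (block$exclude_samples %||% character(0)) |
    samples$treatment %in% (block$exclude_treatments %||% character(0))
  samples <- samples[!drop, , drop = FALSE]
  exprs <- exprs[, samples$sample_id, drop = FALSE]
  list(exprs = exprs, samples = samples)
}

load_annotations <- function(ann) {
  if (is.null(ann)) return(NULL)
  if (is.character(ann)) read_tsv_df(ann) else ann
}

#' Run the full module-detection chain on one expression data set
#'
#' log2 transform (unless already applied), replicate averaging, CV filter,
#' correlation, soft adjacency, topological overlap, average-linkage
#' clustering, static tree cut, color labeling, eigengene/sign groups, trend
#' summary and (when annotations are given) domain enrichment.
#'
#' @param exprs gene x sample matrix.
#' @param samples sample sheet.
#' @param cv_cutoff CV filter cutoff.
#' @param params \code{\link{network_params}}.
#' @param experiment_id label used in outputs.
#' @param annotations optional (gene_id, domain_id) data frame.
#' @param values_are_log2 TRUE if \code{exprs} is already log2.
#' @param alpha enrichment significance level.
#' @return result bundle: list with the partition, trends, eigengenes,
#'   enrichment records, CV report, analyzed matrix and a one-row manifest of
#'   gene counts at each stage.
#' @export
run_experiment_pipeline <- function(exprs, samples, cv_cutoff, params,
                                    experiment_id = "EXP1",
                                    annotations = NULL,
                                    values_are_log2 = FALSE, alpha = 0.01) {
  lg <- if (values_are_log2) exprs else log_transform(exprs)
  tmat <- average_replicates(lg, samples)
  cv <- cv_filter(tmat, cv_cutoff)
  manifest_base <- data.frame(experiment_id = experiment_id,
                              n_genes_input = nrow(exprs),
                              n_treatments = ncol(tmat),
                              cv_cutoff = cv_cutoff, beta = params$beta,
                              tree_cut = params$tree_cut,
                              min_module_size = params$min_module_size,
                              n_analyzed = length(cv$kept),
                              stringsAsFactors = FALSE)
  if (length(cv$kept) < 2) {
    warning("experiment ", experiment_id,
            ": fewer than 2 genes passed the CV filter; no modules detected")
    empty <- structure(list(labels = stats::setNames(integer(0), character(0)),
                            sizes = integer(0), params = params),
                       class = "module_partition")
    empty <- label_module_colors(empty)
    manifest <- cbind(manifest_base,
                      data.frame(n_assigned = 0L, n_unassigned = 0L,
                                 n_modules = 0L))
    return(list(experiment_id = experiment_id, params = params, cv = cv,
                treatment_matrix = cv$matrix, partition = empty,
                eigengenes = list(), trends = NULL, enrichment = NULL,
                manifest = manifest))
  }
  corr <- correlation_matrix(cv$matrix)
  adj <- soft_adjacency(corr, params$beta)
  tom <- topological_overlap(adj)
  tree <- cluster_genes(tom)
  partition <- label_module_colors(cut_modules(tree, params))
  eigengenes <- lapply(stats::setNames(nm = setdiff(unique(partition$colors),
                                                    "unassigned")),
                       function(mod) module_eigengene(cv$matrix, partition, mod))
  trends <- trend_summary(cv$matrix, partition)
  enr <- if (!is.null(annotations)) {
    enrich_modules(partition, annotations, background = cv$kept, alpha = alpha)
  }
  manifest <- cbind(manifest_base, data.frame(
    n_assigned = sum(partition$colors != "unassigned"),
    n_unassigned = sum(partition$colors == "unassigned"),
    n_modules = length(partition$sizes)))
  list(experiment_id = experiment_id, params = params, cv = cv,
       treatment_matrix = cv$matrix, partition = partition,
       eigengenes = eigengenes, trends = trends, enrichment = enr,
       manifest = manifest, correlation = corr, dendrogram = tree)
}

#' Condition-dependent analysis: one network per experiment
#'
#' @param config an \code{\link{analysis_config}}.
#' @return named list of per-experiment result bundles (see
#'   \code{\link{run_experiment_pipeline}}); experiments whose analysis fails
#'   are dropped with a warning while the others proceed.
#' @export
run_condition_dependent <- function(config) {
  ann <- load_annotations(config$annotations)
  bundles <- list()
  for (block in config$experiments) {
    res <- tryCatch({
      dat <- load_experiment_data(block)
      run_experiment_pipeline(dat$exprs, dat$samples,
                              cv_cutoff = block$cv_cutoff,
                              params = block$params,
                              experiment_id = block$id, annotations = ann,
                              values_are_log2 = config$values_are_log2)
    }, error = function(e) {
      warning("experiment ", block$id, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) bundles[[block$id]] <- res
  }
  bundles
}

#' Condition-independent analysis: one network from the pooled data
#'
#' Pools all experiments (gene intersection, sample union), applies the CV
#' filter across all combined treatments and runs the same network chain with
#' the combined parameters. When the per-experiment bundles are supplied, the
#' comparison outputs (membership distribution, four-way assignment counts
#' and the module overlap matrix) are attached.
#'
#' @param config an \code{\link{analysis_config}} with >= 2 experiments.
#' @param dep_bundles optional result of \code{\link{run_condition_dependent}}.
#' @return result bundle with element \code{comparison} when
#'   \code{dep_bundles} is given.
#' @export
run_condition_independent <- function(config, dep_bundles = NULL) {
  if (length(config$experiments) < 2) {
    coex_param_error("condition-independent analysis needs >= 2 experiments")
  }
  ann <- load_annotations(config$annotations)
  datasets <- lapply(config$experiments, function(block) {
    dat <- load_experiment_data(block)
    if (!config$values_are_log2) dat$exprs <- log_transform(dat$exprs)
    list(exprs = dat$exprs,
         samples = dat$samples)
  })
  pooled <- combine_experiments(datasets)
  bundle <- run_experiment_pipeline(
    pooled$exprs, pooled$samples, cv_cutoff = config$combined$cv_cutoff,
    params = config$combined$params, experiment_id = "combined",
    annotations = ann, values_are_log2 = TRUE)
  if (!is.null(dep_bundles) && length(dep_bundles) > 0) {
    dep_parts <- lapply(dep_bundles, `[[`, "partition")
    profiles <- membership_profiles(dep_parts)
    dep_side <- list(
      analyzed = unique(unlist(profiles$analyzed, use.names = FALSE)),
      assigned = unique(unlist(profiles$assigned, use.names = FALSE)))
    indep_side <- list(
      analyzed = names(bundle$partition$colors),
      assigned = names(bundle$partition$colors)[
        bundle$partition$colors != "unassigned"])
    bundle$comparison <- list(
      profiles = profiles,
      membership = membership_distribution(profiles),
      venn = venn_counts(dep_side, indep_side),
      overlap = module_overlap_matrix(dep_parts, bundle$partition))
  }
  bundle
}
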