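# Report writer: gene lists per module, CV reports, trend tables and plots,
# enrichment tables, summary tables and comparison outputs.

plot_module_trend <- function(trends, module, path) {
  tr <- trends$module_trends
  tr <- tr[tr$module == module, , drop = FALSE]
  if (nrow(tr) == 0) return(invisible(NULL))
  treatments <- unique(tr$treatment)
  grDevices::png(path, width = 800, height = 500)
  on.exit(grDevices::dev.off())
  graphics::plot(NA, xlim = c(1, length(treatments)),
                 ylim = range(tr$mean_z) + c(-0.2, 0.2),
                 xaxt = "n", xlab = "treatment", ylab = "mean Z-score",
                 main = paste0("module ", module))
  graphics::axis(1, at = seq_along(treatments), labels = treatments, las = 2)
  for (sg in unique(tr$sign_group)) {
    sub <- tr[tr$sign_group == sg, , drop = FALSE]
    graphics::lines(match(sub$treatment, treatments), sub$mean_z,
                    col = if (sg == "+") "firebrick" else "steelblue", lwd = 2)
  }
  graphics::abline(h = 0, lty = 3)
  invisible(path)
}

write_bundle_reports <- function(bundle, out_dir, plots) {
  ex <- bundle$experiment_id
  p <- bundle$partition
  files <- character(0)
  for (mod in setdiff(unique(p$colors), "unassigned")) {
    genes <- module_genes(p, mod)
    sg <- bundle$eigengenes[[mod]]$signs[genes]
    df <- data.frame(gene_id = genes, experiment_id = ex, module_color = mod,
                     sign_group = ifelse(sg > 0, "+", "-"),
                     stringsAsFactors = FALSE)
    files <- c(files, write_tsv_df(df, file.path(out_dir,
                                                 paste0(ex, "-", mod, ".tsv"))))
    if (plots) {
      files <- c(files, plot_module_trend(bundle$trends, mod,
                                          file.path(out_dir,
                                                    paste0(ex, "-", mod, ".png"))))
    }
  }
  un <- names(p$colors)[p$colors == "unassigned"]
  files <- c(files, write_tsv_df(
    data.frame(gene_id = un, experiment_id = rep(ex, length(un)),
               stringsAsFactors = FALSE),
    file.path(out_dir, paste0(ex, "-unassigned.tsv"))))
  files <- c(files, write_tsv_df(bundle$cv$table,
                                 file.path(out_dir, paste0(ex, "-cv.tsv"))))
  if (!is.null(bundle$trends)) {
    files <- c(files, write_tsv_df(bundle$trends$module_trends,
                                   file.path(out_dir, paste0(ex, "-trends.tsv"))))
  }
  if (!is.null(bundle$enrichment)) {
    files <- c(files, write_tsv_df(bundle$enrichment,
                                   file.path(out_dir,
                                             paste0(ex, "-enrichment.tsv"))))
  }
  if (!is.null(bundle$correlation)) {
    files <- c(files, write_tsv_matrix(bundle$correlation,
                                       file.path(out_dir,
                                                 paste0(ex, "-correlation.tsv"))))
  }
  files
}

#' Write the complete report set for an analysis
#'
#' Per experiment: one gene-list TSV per module (named
#' \code{<experiment>-<color>}), an unassigned-gene list, the CV report,
#' trend tables (plus PNG trend plots unless disabled), enrichment records
#' and the full correlation matrix. Across experiments: a gene-count summary
#' table, the enrichment summary, the membership distribution, four-way
#' assignment counts and the module overlap matrix when a
#' condition-independent bundle with comparisons is supplied, and a run log.
#'
#' @param dep_bundles named list from \code{\link{run_condition_dependent}}.
#' @param out_dir output directory, created if needed.
#' @param indep_bundle optional bundle from
#'   \code{\link{run_condition_independent}}.
#' @param plots write PNG trend plots.
#' @param seed seed recorded in the run log.
#' @return invisibly, the files written.
#' @export
write_reports <- function(dep_bundles, out_dir, indep_bundle = NULL,
                          plots = TRUE, seed = NA) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (bundle in dep_bundles) {
    files <- c(files, write_bundle_reports(bundle, out_dir, plots))
  }
  manifests <- do.call(rbind, lapply(dep_bundles, `[[`, "manifest"))
  if (!is.null(indep_bundle)) {
    files <- c(files, write_bundle_reports(indep_bundle, out_dir, plots))
    manifests <- rbind(manifests, indep_bundle$manifest)
  }
  files <- c(files, write_tsv_df(manifests, file.path(out_dir, "summary.tsv")))
  enr <- lapply(c(dep_bundles, list(indep_bundle)), function(b) {
    if (is.null(b) || is.null(b$enrichment)) return(NULL)
    cbind(experiment_id = b$experiment_id, enrichment_summary(b$enrichment))
  })
  enr <- do.call(rbind, enr)
  if (!is.null(enr)) {
    files <- c(files, write_tsv_df(enr, file.path(out_dir,
                                                  "enrichment_summary.tsv")))
  }
  if (!is.null(indep_bundle$comparison)) {
    cmp <- indep_bundle$comparison
    files <- c(files,
               write_tsv_df(cmp$membership,
                            file.path(out_dir, "membership_distribution.tsv")),
               write_tsv_df(cmp$venn, file.path(out_dir, "venn_counts.tsv")),
               write_tsv_matrix(cmp$overlap,
                                file.path(out_dir, "module_overlap.tsv"),
                                id_col = "dep_module"))
    a <- cmp$profiles$assignments
    tp <- tapply(a$experiment_id, a$gene_id, function(x) length(unique(x)))
    per_gene <- data.frame(gene_id = names(tp),
                           n_experiments = as.integer(tp),
                           stringsAsFactors = FALSE)
    files <- c(files, write_tsv_df(per_gene,
                                   file.path(out_dir, "membership_per_gene.tsv")))
  }
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(paste0("coexmod ", as.character(utils::packageVersion("coexmod"))),
               paste0("R ", getRversion()),
               paste0("seed ", seed),
               paste0("date ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               paste0("experiments ", paste(names(dep_bundles), collapse = ", "))),
             log_path)
  invisible(c(files, log_path))
}
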