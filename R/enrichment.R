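# Hypergeometric domain enrichment per module with Bonferroni control.

#' Upper-tail hypergeometric probability
#'
#' Probability of observing \code{k} or more annotated genes in a module of
#' size \code{n} drawn from a background of \code{N} genes of which \code{K}
#' carry the domain:
#' \deqn{p = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}}
#' evaluated in log space via \code{\link[stats]{phyper}}.
#'
#' @param N background size.
#' @param K background genes carrying the domain.
#' @param n module size.
#' @param k module genes carrying the domain.
#' @return the upper-tail probability \eqn{P(X \ge k)}.
#' @export
hypergeometric_upper_tail <- function(N, K, n, k) {
  if (K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(K, n)) {
    coex_param_error("invalid hypergeometric parameters (N=", N, ", K=", K,
                     ", n=", n, ", k=", k, ")")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Test modules for domain over-representation
#'
#' One test per (module, domain) pair where the domain occurs in at least one
#' module gene; the Bonferroni family size \code{m} is the number of such
#' tests in the analysis. The background universe defaults to the genes
#' analyzed in the experiment (those passing the CV filter), the pool the
#' modules were drawn from. Unassigned genes are never tested as a module.
#'
#' @param partition labeled \code{module_partition}.
#' @param annotations data frame (gene_id, domain_id).
#' @param background character vector of background gene ids; every module
#'   gene must be included.
#' @param alpha family-wise significance level.
#' @return data frame (module, domain, N, K, n, k, p, p_bonferroni,
#'   significant) with attributes \code{m} and \code{alpha}.
#' @export
enrich_modules <- function(partition, annotations, background, alpha = 0.01) {
  if (length(background) == 0) coex_param_error("empty background gene set")
  background <- unique(background)
  mods <- setdiff(unique(partition$colors), "unassigned")
  all_mod_genes <- names(partition$colors)[partition$colors != "unassigned"]
  if (!all(all_mod_genes %in% background)) {
    coex_param_error("every module gene must be in the background universe")
  }
  ann <- unique(annotations[annotations$gene_id %in% background, , drop = FALSE])
  N <- length(background)
  K_by_domain <- table(ann$domain_id)
  rows <- list()
  for (mod in mods) {
    genes <- module_genes(partition, mod)
    n <- length(genes)
    mod_ann <- ann[ann$gene_id %in% genes, , drop = FALSE]
    if (nrow(mod_ann) == 0) next
    k_by_domain <- table(mod_ann$domain_id)
    for (d in names(k_by_domain)) {
      K <- as.integer(K_by_domain[[d]])
      k <- as.integer(k_by_domain[[d]])
      rows[[paste(mod, d)]] <- data.frame(
        module = mod, domain = d, N = N, K = K, n = n, k = k,
        p = hypergeometric_upper_tail(N, K, n, k), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(0), domain = character(0), N = integer(0),
               K = integer(0), n = integer(0), k = integer(0), p = numeric(0))
  m <- nrow(out)
  out$p_bonferroni <- pmin(1, out$p * m)
  out$significant <- out$p <= alpha / max(m, 1L)
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  out
}

#' Per-analysis enrichment summary
#'
#' @param records data frame from \code{\link{enrich_modules}}.
#' @return one-row data frame: number of modules tested, modules with at
#'   least one significantly enriched domain, and unique enriched domains.
#' @export
enrichment_summary <- function(records) {
  sig <- records[records$significant, , drop = FALSE]
  data.frame(n_modules_tested = length(unique(records$module)),
             n_modules_enriched = length(unique(sig$module)),
             n_domains_enriched = length(unique(sig$domain)),
             n_tests = nrow(records))
}
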