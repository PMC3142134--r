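# Independent oracles and shared fixtures for the test suite. Oracles are
# deliberately naive (literal formulas, loops, exhaustive enumeration) and
# share no code with the implementation they check.

# Literal triple-loop topological overlap: for every pair (i, j), sum the
# common-neighbor products over u != i, j and apply the overlap formula.
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, -i])
  w <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      w[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  w
}

# Exhaustive hypergeometric upper tail: enumerate every size-n draw from N
# genes of which the first K carry the domain, and count draws with >= k hits.
hyper_oracle <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k == 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Naive O(n^3) average-linkage agglomeration; returns merge heights in order.
avg_linkage_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq.int(i + 1, length(clusters))) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Two-pass textbook Pearson correlation from centered sums of products.
cor_oracle <- function(m) {
  n <- nrow(m)
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      xi <- m[i, ] - mean(m[i, ]); xj <- m[j, ] - mean(m[j, ])
      out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  out
}

# Least-squares line via closed-form normal equations (independent of lm).
ols_oracle <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  pred <- ic + sl * x
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  list(slope = sl, r2 = r2)
}

# Random symmetric "correlation-like" matrix with unit diagonal.
random_corr <- function(n, seed) {
  set.seed(seed)
  r <- matrix(stats::runif(n * n, -1, 1), n)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

# Block-diagonal union of cliques: `sizes` repeated `counts` times; members
# of an s-clique all have connectivity s - 1.
clique_adjacency <- function(sizes, counts) {
  blocks <- rep(sizes, counts)
  n <- sum(blocks)
  a <- matrix(0, n, n)
  at <- 0
  for (s in blocks) {
    idx <- at + seq_len(s)
    a[idx, idx] <- 1
    at <- at + s
  }
  dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
  a
}

ari <- function(x, y) mclust::adjustedRandIndex(x, y)

reference_params <- function() {
  network_params(beta = 6, tree_cut = 0.95, min_module_size = 30)
}

# Run the reference recovery benchmark for one seed; returns the planted and
# recovered labels plus sign-group agreement for anti-correlated genes.
run_reference_seed <- function(seed) {
  spec <- reference_synthetic_spec(seed = seed)
  d <- generate_experiment(spec)
  b <- run_experiment_pipeline(d$exprs, d$samples, cv_cutoff = 0.6,
                               params = reference_params(),
                               values_are_log2 = TRUE)
  colors <- b$partition$colors
  planted <- d$truth$label[match(names(colors), d$truth$gene_id)]
  truth_sign <- d$truth$sign[match(names(colors), d$truth$gene_id)]
  assigned <- colors != "unassigned"
  non_bg <- !(planted %in% c("background", "housekeeping"))
  ari_val <- ari(planted[assigned & non_bg], colors[assigned & non_bg])

  # for each planted module, the recovered color of its positive majority
  neg_total <- 0L; neg_ok <- 0L
  for (mod in unique(planted[non_bg])) {
    pos <- names(colors)[planted == mod & truth_sign == 1]
    neg <- names(colors)[planted == mod & truth_sign == -1]
    if (length(neg) == 0) next
    host <- names(sort(table(colors[pos][colors[pos] != "unassigned"]),
                       decreasing = TRUE))[1]
    eg_signs <- if (!is.null(host) && host %in% names(b$eigengenes)) {
      b$eigengenes[[host]]$signs
    } else numeric(0)
    neg_total <- neg_total + length(neg)
    neg_ok <- neg_ok + sum(colors[neg] == host &
                             names(colors[neg]) %in% names(eg_signs)[eg_signs < 0])
  }
  list(ari = ari_val, sign_rate = neg_ok / max(neg_total, 1L),
       bundle = b, truth = d$truth)
}

# Memoized 20-seed reference runs shared by several acceptance checks.
reference_runs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- lapply(1:20, run_reference_seed)
    cache
  }
})

# Obscuring benchmark for one seed: recovery ARI over planted-module genes
# (unassigned kept as its own label) for the condition-dependent run on
# experiment 1 versus the pooled condition-independent run.
run_obscuring_seed <- function(seed) {
  bm <- obscuring_benchmark(seed = seed)
  truth <- bm$truth
  planted_genes <- truth$gene_id[!(truth$label %in%
                                     c("background", "housekeeping"))]
  score <- function(colors) {
    genes <- intersect(planted_genes, names(colors))
    ari(truth$label[match(genes, truth$gene_id)], colors[genes])
  }
  d1 <- bm$experiments[[1]]
  dep <- run_experiment_pipeline(d1$exprs, d1$samples, cv_cutoff = 0.6,
                                 params = reference_params(),
                                 values_are_log2 = TRUE)
  pooled <- combine_experiments(bm$experiments)
  indep <- run_experiment_pipeline(pooled$exprs, pooled$samples,
                                   cv_cutoff = 0.6,
                                   params = reference_params(),
                                   values_are_log2 = TRUE)
  list(dep = score(dep$partition$colors), indep = score(indep$partition$colors),
       dep_bundle = dep, indep_bundle = indep, benchmark = bm)
}
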