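# Correlation, soft adjacency, scale-free fit, topological overlap,
# clustering, static tree cut, color labels, eigengenes and trends.

test_that("Pearson correlations match a two-pass textbook computation", {
  set.seed(21)
  tm <- matrix(rnorm(60), nrow = 10,
               dimnames = list(paste0("g", 1:10), paste0("T", 1:6)))
  r <- correlation_matrix(tm)
  expect_lt(max(abs(r - cor_oracle(tm))), 1e-12)
  expect_equal(diag(r), setNames(rep(1, 10), rownames(tm)))
  expect_equal(r["g1", "g2"], r["g2", "g1"])

  tm2 <- rbind(tm, copy = tm["g1", ], neg = 2 * mean(tm["g1", ]) - tm["g1", ])
  r2 <- correlation_matrix(tm2)
  expect_equal(r2["g1", "copy"], 1)
  expect_equal(r2["g1", "neg"], -1)

  expect_error(correlation_matrix(tm[, 1:2]), class = "coex_param_error")
  tm3 <- rbind(tm, flat = rep(3, 6))
  expect_error(correlation_matrix(tm3), "flat", class = "coex_data_error")
})

test_that("soft adjacency is |r|^beta and shrinks as beta grows", {
  r <- matrix(c(1, -0.8, -0.8, 1), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(soft_adjacency(r, 2)["a", "b"], 0.64)
  rr <- random_corr(15, seed = 22)
  expect_equal(soft_adjacency(rr, 1), abs(rr))
  a6 <- soft_adjacency(rr, 6); a12 <- soft_adjacency(rr, 12)
  off <- upper.tri(rr)
  expect_true(all(a12[off] <= a6[off]))
  expect_error(soft_adjacency(rr, 0.5), class = "coex_param_error")
})

test_that("scale-free fit index is the signed R^2 of the log-log regression", {
  # cliques with k in {1, 2, 4} and member counts 60/30/15 (frequency ~ 1/k):
  # log10(freq) is exactly linear in log10(k) with negative slope
  a <- clique_adjacency(c(2, 3, 5), c(30, 10, 3))
  expect_equal(scale_free_fit(a, n_bins = 10), 1)
  # counts increasing with k give a positive slope and a negative index
  a_pos <- clique_adjacency(c(2, 4), c(2, 3))
  expect_lte(scale_free_fit(a_pos, n_bins = 5), 0)
  # random adjacency agrees with a closed-form least-squares oracle
  rr <- abs(random_corr(80, seed = 23))^3
  diag(rr) <- 1
  idx <- scale_free_fit(rr, n_bins = 8)
  k <- rowSums(rr) - 1
  bins <- cut(k, seq(min(k), max(k), length.out = 9), include.lowest = TRUE)
  freq <- as.numeric(table(bins)) / length(k)
  km <- tapply(k, bins, mean)
  ok <- freq > 0 & !is.na(km)
  o <- ols_oracle(log10(as.numeric(km[ok])), log10(freq[ok]))
  expect_lt(abs(idx - (-sign(o$slope) * o$r2)), 1e-10)
  # identical connectivities: undefined, NA with explanation
  expect_warning(res <- scale_free_fit(clique_adjacency(4, 5), n_bins = 5))
  expect_true(is.na(res))
})

test_that("pick_beta recommends the smallest candidate reaching the fit cut", {
  one <- pick_beta(random_corr(30, seed = 24), candidates = 1)
  expect_equal(one$beta, 1)
  expect_equal(nrow(one$table), 1L)
  # disjoint perfect cliques: adjacency (hence the index) is beta-invariant,
  # so with a passing index the smallest candidate must win
  a <- clique_adjacency(c(2, 3, 5), c(30, 10, 3))
  res <- pick_beta(a, candidates = c(2, 4, 8), rsq_cut = 0.95)
  expect_equal(res$beta, 2)
  expect_equal(res$table$fit_index, rep(1, 3))
  expect_error(pick_beta(a, candidates = numeric(0)),
               class = "coex_param_error")
})

test_that("fit index grows then saturates with beta on modular networks", {
  # moderate-noise modules, where soft thresholding actually has work to do:
  # the index should climb from its low point and level off near its maximum
  passes <- 0L
  for (s in 1:20) {
    trends <- orthogonal_trends(10, 5, seed = 400 + s)
    mods <- lapply(1:5, function(i)
      planted_module(paste0("M", i), 20, trend = trends[, i],
                     loading_range = c(1, 2)))
    spec <- synthetic_spec(10, 3, mods, n_background = 100, noise_sd = 1.5,
                           seed = 500 + s)
    d <- generate_experiment(spec)
    tm <- average_replicates(d$exprs, d$samples)
    corr <- correlation_matrix(tm)
    fits <- pick_beta(corr, candidates = c(1, 2, 4, 6, 8, 10))$table$fit_index
    rise <- fits[which.min(fits):length(fits)]
    ok <- all(diff(rise) > -0.1) && fits[length(fits)] >= max(fits) - 0.15
    passes <- passes + ok
  }
  expect_gte(passes, 16L)
})

test_that("topological overlap matches its closed limits and the triple-loop oracle", {
  full <- matrix(1, 3, 3)
  expect_equal(topological_overlap(full), matrix(1, 3, 3))
  empty <- diag(3)
  expect_equal(topological_overlap(empty), diag(3))
  for (s in 1:3) {
    a <- abs(random_corr(20, seed = 30 + s))
    diag(a) <- 1
    expect_lt(max(abs(topological_overlap(a) - tom_oracle(a))), 1e-12)
  }
  w <- topological_overlap(abs(random_corr(25, seed = 34))^2)
  expect_true(all(w >= -1e-12 & w <= 1 + 1e-12))
  expect_equal(w, t(w))
})

test_that("average-linkage clustering reproduces hand and oracle merge heights", {
  tom <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tree <- cluster_genes(tom)
  expect_equal(tree$height, 0)

  d3 <- matrix(c(0, 0.1, 0.9,
                 0.1, 0, 0.9,
                 0.9, 0.9, 0), 3, dimnames = list(letters[1:3], letters[1:3]))
  tree3 <- cluster_genes(1 - d3)
  expect_equal(tree3$height, c(0.1, 0.9))

  set.seed(35)
  d <- as.matrix(dist(matrix(rnorm(30), 15)))
  d <- d / max(d)
  dimnames(d) <- list(paste0("g", 1:15), paste0("g", 1:15))
  tree15 <- cluster_genes(1 - d)
  expect_equal(tree15$height, avg_linkage_heights(d), tolerance = 1e-12)
})

# two flat clusters of 40 and 30 genes joining at height 0.9
two_cluster_tree <- function() {
  n <- 70
  d <- matrix(0.9, n, n)
  d[1:40, 1:40] <- 0.2
  d[41:70, 41:70] <- 0.3
  diag(d) <- 0
  dimnames(d) <- list(paste0("g", 1:n), paste0("g", 1:n))
  cluster_genes(1 - d)
}

test_that("the static cut respects height, minimum size and monotonicity", {
  tree <- two_cluster_tree()
  p <- cut_modules(tree, network_params(tree_cut = 0.8, min_module_size = 25))
  expect_equal(sort(p$sizes, decreasing = TRUE), c(40L, 30L))
  expect_equal(sum(p$labels == 0), 0L)

  p35 <- cut_modules(tree, network_params(tree_cut = 0.8, min_module_size = 35))
  expect_equal(p35$sizes, 40L)
  expect_equal(sum(p35$labels == 0), 30L)

  p95 <- cut_modules(tree, network_params(tree_cut = 0.95, min_module_size = 25))
  expect_equal(p95$sizes, 70L)
  expect_gte(sum(p95$labels > 0), sum(p$labels > 0))

  expect_warning(
    pbig <- cut_modules(tree, network_params(tree_cut = 0.8,
                                             min_module_size = 100)),
    "unassigned")
  expect_equal(sum(pbig$labels == 0), 70L)

  # assigned-gene count is non-decreasing in the cut height on random trees
  set.seed(36)
  d <- as.matrix(dist(matrix(rnorm(80), 40)))
  d <- d / max(d)
  dimnames(d) <- list(paste0("g", 1:40), paste0("g", 1:40))
  tr <- cluster_genes(1 - d)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9, 1), function(h) {
    sum(cut_modules(tr, network_params(tree_cut = h,
                                       min_module_size = 5))$labels > 0)
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("modules take the standard color sequence by decreasing size", {
  fake_partition <- function(sizes) {
    labels <- rep(seq_along(sizes), sizes)
    names(labels) <- paste0("g", seq_along(labels))
    structure(list(labels = labels, sizes = as.integer(sizes),
                   params = network_params()), class = "module_partition")
  }
  p <- label_module_colors(fake_partition(c(120, 80, 45)))
  expect_equal(p$module_colors, c("turquoise", "blue", "brown"))
  p15 <- label_module_colors(fake_partition(seq(150, 10, by = -10)))
  expect_equal(p15$module_colors[15], "midnightblue")
  p40 <- label_module_colors(fake_partition(rep(2, 40)))
  expect_equal(p40$module_colors[31:40], sprintf("module%02d", 31:40))
})

test_that("size ties give the earlier color to the earlier first gene", {
  n <- 40
  d <- matrix(0.9, n, n)
  d[1:20, 1:20] <- 0.1
  d[21:40, 21:40] <- 0.1
  diag(d) <- 0
  dimnames(d) <- list(paste0("g", 1:n), paste0("g", 1:n))
  p <- label_module_colors(
    cut_modules(cluster_genes(1 - d),
                network_params(tree_cut = 0.5, min_module_size = 10)))
  expect_equal(unname(p$colors["g1"]), "turquoise")
  expect_equal(unname(p$colors["g21"]), "blue")
})

test_that("eigengenes recover planted trends and split sign groups", {
  # identical genes: eigengene equals the shared z-profile, all signs +
  prof <- c(1, 3, 5, 4, 2)
  tm <- matrix(rep(prof, each = 4), nrow = 4,
               dimnames = list(paste0("g", 1:4), paste0("T", 1:5)))
  tm <- tm + matrix(rnorm(20, sd = 1e-9), 4)
  part <- structure(list(labels = setNames(rep(1L, 4), rownames(tm)),
                         sizes = 4L, params = network_params()),
                    class = "module_partition")
  part <- label_module_colors(part)
  eg <- module_eigengene(tm, part, "turquoise")
  zprof <- as.numeric(scale(prof))
  expect_equal(unname(eg$eigengene) / max(abs(eg$eigengene)),
               zprof / max(abs(zprof)), tolerance = 1e-6)
  expect_equal(unname(eg$signs), rep(1, 4))

  # half the genes exactly negated: signs split along the planted labels
  m <- planted_module("M1", size = 10, trend = c(0, 2, -1, 1, -2),
                      anti_fraction = 0.5)
  spec <- synthetic_spec(5, 2, list(m), noise_sd = 1e-9, seed = 41)
  d <- generate_experiment(spec)
  tm2 <- average_replicates(d$exprs, d$samples)
  part2 <- structure(list(labels = setNames(rep(1L, 10), rownames(tm2)),
                          sizes = 10L, params = network_params()),
                     class = "module_partition")
  part2 <- label_module_colors(part2)
  eg2 <- module_eigengene(tm2, part2, "turquoise")
  # with an exact 50/50 split the eigengene orientation is arbitrary, but the
  # two sign groups must coincide with the planted labels
  expect_true(all(eg2$signs == d$truth$sign) ||
                all(eg2$signs == -d$truth$sign))

  expect_error(module_eigengene(tm, part, "missing"),
               class = "coex_param_error")
})

test_that("noisy planted modules still correlate >= 0.9 with the eigengene trend", {
  hits <- 0L
  for (s in 1:20) {
    trend <- random_trend(8, seed = 600 + s)
    m <- planted_module("M1", size = 30, trend = trend,
                        loading_range = c(8, 12), anti_fraction = 0.3)
    spec <- synthetic_spec(8, 2, list(m), noise_sd = 0.25 * 10, seed = 700 + s)
    d <- generate_experiment(spec)
    tm <- average_replicates(d$exprs, d$samples)
    part <- label_module_colors(structure(
      list(labels = setNames(rep(1L, 30), rownames(tm)), sizes = 30L,
           params = network_params()), class = "module_partition"))
    eg <- module_eigengene(tm, part, "turquoise")
    hits <- hits + (abs(cor(eg$eigengene, as.numeric(scale(trend)))) >= 0.9)
  }
  expect_gte(hits, 18L)
})

test_that("trend summaries are unit z-scores averaged by sign group", {
  tm <- rbind(g1 = c(2, 4, 6), g2 = c(2, 4, 6), g3 = c(6, 4, 2),
              g4 = c(1, 5, 3))
  colnames(tm) <- paste0("T", 1:3)
  part <- label_module_colors(structure(
    list(labels = setNames(c(1L, 1L, 1L, 0L), rownames(tm)), sizes = 3L,
         params = network_params()), class = "module_partition"))
  ts <- trend_summary(tm, part)
  # n-1 denominator: sd(c(2,4,6)) = 2, so z = (-1, 0, 1)
  expect_equal(unname(ts$z["g1", ]), c(-1, 0, 1))
  expect_true(all(abs(rowMeans(ts$z)) < 1e-12))
  expect_equal(unname(apply(ts$z, 1, sd)), rep(1, 4))
  tr <- ts$module_trends
  plus <- tr[tr$sign_group == "+", ]
  expect_equal(plus$mean_z, c(-1, 0, 1))
  expect_equal(unique(plus$n_genes), 2L)
  minus <- tr[tr$sign_group == "-", ]
  expect_equal(minus$mean_z, c(1, 0, -1))
  # unassigned genes get their own singleton trends
  expect_equal(rownames(ts$unassigned_z), "g4")
})
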