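# Synthetic-data generator: planted structure, determinism, probe layer and
# annotation fixtures.

near_zero_noise_spec <- function(modules, ...) {
  synthetic_spec(n_treatments = 4, n_replicates = 2, modules = modules,
                 noise_sd = 1e-9, seed = 7L, ...)
}

test_that("planted module genes are perfectly correlated in the zero-noise limit", {
  m <- planted_module("M1", size = 3, trend = c(0, 1, 0.5, -1))
  d <- generate_experiment(near_zero_noise_spec(list(m)))
  r <- cor(t(d$exprs))
  expect_equal(unname(r[upper.tri(r)]), rep(1, 3), tolerance = 1e-6)
})

test_that("anti-correlated members split into perfect +/- correlation groups", {
  m <- planted_module("M1", size = 6, trend = c(0, 1, 0.5, -1),
                      anti_fraction = 0.5)
  d <- generate_experiment(near_zero_noise_spec(list(m)))
  s <- d$truth$sign
  r <- cor(t(d$exprs))
  same <- outer(s, s) > 0
  diag(same) <- NA
  expect_equal(unname(r[which(same)]), rep(1, sum(same, na.rm = TRUE)),
               tolerance = 1e-6)
  expect_equal(unname(r[which(!same)]), rep(-1, sum(!same, na.rm = TRUE)),
               tolerance = 1e-6)
  expect_equal(sum(s == -1), 3)
})

test_that("identical spec and seed reproduce every output exactly", {
  spec <- reference_synthetic_spec(seed = 3)
  d1 <- generate_experiment(spec)
  d2 <- generate_experiment(spec)
  expect_identical(d1, d2)
  p1 <- generate_probe_layer(d1$truth[1:20, ], n_degenerate_sets = 2,
                             n_multimap_sets = 2, seed = 5)
  p2 <- generate_probe_layer(d1$truth[1:20, ], n_degenerate_sets = 2,
                             n_multimap_sets = 2, seed = 5)
  expect_identical(p1, p2)
  a1 <- generate_annotations(d1$truth, n_domains = 10, background_rate = 0.1,
                             seed = 11)
  a2 <- generate_annotations(d1$truth, n_domains = 10, background_rate = 0.1,
                             seed = 11)
  expect_identical(a1, a2)
})

test_that("invalid specs raise parameter errors naming the field", {
  expect_error(planted_module("M", size = 1, trend = c(0, 1)),
               "size", class = "coex_param_error")
  expect_error(planted_module("M", size = 3, trend = c(1, 1, 1)),
               "trend", class = "coex_param_error")
  expect_error(planted_module("M", size = 3, trend = c(0, 1), anti_fraction = 2),
               "anti_fraction", class = "coex_param_error")
  m <- planted_module("M", size = 2, trend = c(0, 1))
  expect_error(synthetic_spec(2, 2, list(m), noise_sd = 0),
               "noise_sd", class = "coex_param_error")
  expect_error(synthetic_spec(3, 2, list(m)), "trend length",
               class = "coex_param_error")
  expect_error(synthetic_spec(2, 2, list(m), n_background = -1),
               "n_background", class = "coex_param_error")
})

test_that("housekeeping genes vary less than background noise genes", {
  m <- planted_module("M1", size = 2, trend = c(0, 1, -1))
  spec <- synthetic_spec(3, 3, list(m), n_background = 150,
                         n_housekeeping = 150, noise_sd = 0.5, seed = 2)
  d <- generate_experiment(spec)
  sds <- apply(d$exprs, 1, sd)
  lab <- d$truth$label
  expect_lt(mean(sds[lab == "housekeeping"]), mean(sds[lab == "background"]))
})

test_that("probe layer states assigned/unassigned/discarded outcomes as planted", {
  spec <- reference_synthetic_spec(seed = 2)
  truth <- generate_experiment(spec)$truth[1:15, ]
  clean <- generate_probe_layer(truth, seed = 3)
  expect_true(all(clean$expected$expected_status == "assigned"))
  expect_equal(clean$expected$expected_gene, truth$gene_id)

  layered <- generate_probe_layer(truth, n_degenerate_sets = 3,
                                  n_multimap_sets = 2, seed = 4)
  tab <- table(layered$expected$expected_status)
  expect_equal(as.integer(tab[c("assigned", "unassigned", "discarded")]),
               c(15L, 3L, 2L))
  # degenerate sets carry exactly 8 probes that are substrings of a transcript
  dps <- layered$probes[startsWith(names(layered$probes), "dps_001")]
  hits <- vapply(dps, function(p) any(grepl(p, layered$transcripts,
                                            fixed = TRUE)), logical(1))
  expect_equal(sum(hits), 8L)
  # multimap probes sit in two transcripts
  mps <- layered$probes[startsWith(names(layered$probes), "mps_001")]
  n_tx <- vapply(mps, function(p) sum(vapply(layered$transcripts, grepl,
                                             logical(1), pattern = p,
                                             fixed = TRUE)), integer(1))
  expect_true(all(n_tx == 2L))
  expect_error(generate_probe_layer(truth, probe_len = 500, seed = 1),
               class = "coex_param_error")
})

test_that("annotation generation follows planted enrichment semantics", {
  m1 <- planted_module("M1", size = 20, trend = c(0, 1, -1),
                       enriched_domain = "PF_X", enrichment_fold = Inf)
  m2 <- planted_module("M2", size = 20, trend = c(1, 0, -1))
  spec <- synthetic_spec(3, 2, list(m1, m2), n_background = 20, seed = 5)
  truth <- generate_experiment(spec)$truth

  only <- generate_annotations(truth, n_domains = 3, background_rate = 0,
                               seed = 6)
  expect_true(all(only$domain_id == "PF_X"))
  expect_setequal(only$gene_id, truth$gene_id[truth$label == "M1"])

  all_ann <- generate_annotations(truth, n_domains = 3, background_rate = 1,
                                  seed = 6)
  expect_equal(nrow(all_ann), nrow(truth) * 4)  # 3 background domains + PF_X
  expect_error(generate_annotations(truth, 3, background_rate = 1.5),
               class = "coex_param_error")
})

test_that("combining experiments takes the sample union over the gene intersection", {
  m <- planted_module("M1", size = 5, trend = c(0, 1, -1))
  spec <- synthetic_spec(3, 2, list(m), n_background = 5, seed = 8)
  d <- generate_experiment(spec, experiment_id = "A")
  d2 <- d
  d2$samples$experiment_id <- "B"
  pooled <- combine_experiments(list(d, d2))
  expect_equal(nrow(pooled$exprs), nrow(d$exprs))
  expect_equal(ncol(pooled$exprs), 2 * ncol(d$exprs))
  expect_equal(pooled$samples$experiment_id,
               rep(c("A", "B"), each = ncol(d$exprs)))

  # disjoint universes fail; partial overlap keeps the shared genes
  d3 <- d
  rownames(d3$exprs) <- paste0("other_", rownames(d3$exprs))
  d3$samples$experiment_id <- "C"
  expect_error(combine_experiments(list(d, d3)), class = "coex_data_error")
  d4 <- d
  rownames(d4$exprs)[1:5] <- paste0("other_", 1:5)
  d4$samples$experiment_id <- "D"
  expect_equal(nrow(combine_experiments(list(d, d4))$exprs), nrow(d$exprs) - 5)
})

test_that("written synthetic datasets round-trip through TSV/FASTA", {
  spec <- reference_synthetic_spec(seed = 4)
  d <- generate_experiment(spec)
  d$probe_layer <- generate_probe_layer(d$truth[1:5, ], seed = 2)
  d$annotations <- generate_annotations(d$truth, 5, 0.1, seed = 2)
  out <- withr::local_tempdir()
  write_synthetic_dataset(d, out)
  expect_equal(read_tsv_matrix(file.path(out, "expression.tsv")), d$exprs)
  expect_equal(read_tsv_df(file.path(out, "samples.tsv")), d$samples)
  tx <- Biostrings::readDNAStringSet(file.path(out, "transcripts.fasta"))
  expect_equal(as.character(tx), d$probe_layer$transcripts)
})
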