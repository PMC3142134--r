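# Synthetic multi-treatment expression data with planted coexpression modules.
#
# The generator works directly on the log2 scale: each planted-module gene g is
#   x_{g,s} = b_g + s_g * lambda_g * trend_{m(g)}(treatment(s)) + eps,
# with eps ~ N(0, noise_sd^2), baseline b_g ~ U(baseline_range), loading
# lambda_g ~ U(loading_range) and sign s_g in {+1, -1} (a planted fraction of
# members is anti-correlated). Housekeeping genes are b_g + eps with sd
# noise_sd/10; background genes are b_g + eps with sd noise_sd.

#' Describe one planted coexpression module
#'
#' @param module_id label for the module.
#' @param size number of member genes (>= 2).
#' @param trend numeric vector of latent expression values, one per treatment;
#'   must have nonzero variance. It is the shared driver all member genes
#'   follow (up to sign, loading and noise).
#' @param loading_range interval of positive loading magnitudes
#'   \eqn{\lambda_g}; per-gene loadings are drawn uniformly from it. The
#'   default, with unit-variance trends, gives planted genes log2 swings large
#'   enough to pass coefficient-of-variation cutoffs in the 0.6-0.9 range.
#' @param anti_fraction proportion in [0,1] of member genes with negative sign
#'   (anti-correlated with the trend).
#' @param enriched_domain optional domain label planted on this module's genes.
#' @param enrichment_fold fold over the annotation background rate at which
#'   member genes carry \code{enriched_domain}.
#' @return an object of class \code{planted_module}.
#' @export
planted_module <- function(module_id, size, trend,
                           loading_range = c(8, 12),
                           anti_fraction = 0,
                           enriched_domain = NULL,
                           enrichment_fold = 1) {
  if (!is.character(module_id) || length(module_id) != 1L) {
    coex_param_error("'module_id' must be a single label")
  }
  if (length(size) != 1L || size < 2) {
    coex_param_error("'size' must be >= 2 in module ", module_id)
  }
  if (!is.numeric(trend) || length(trend) < 2L || stats::var(trend) == 0) {
    coex_param_error("'trend' must have nonzero variance in module ", module_id)
  }
  if (length(loading_range) != 2L || any(loading_range <= 0) ||
      loading_range[1] > loading_range[2]) {
    coex_param_error("'loading_range' must be a positive interval in module ",
                     module_id)
  }
  if (anti_fraction < 0 || anti_fraction > 1) {
    coex_param_error("'anti_fraction' must be in [0,1] in module ", module_id)
  }
  if (enrichment_fold < 0) {
    coex_param_error("'enrichment_fold' must be >= 0 in module ", module_id)
  }
  structure(list(module_id = module_id, size = as.integer(size),
                 trend = as.numeric(trend), loading_range = loading_range,
                 anti_fraction = anti_fraction,
                 enriched_domain = enriched_domain,
                 enrichment_fold = enrichment_fold),
            class = "planted_module")
}

#' Specify a synthetic multi-treatment experiment
#'
#' @param n_treatments number of treatments (conditions).
#' @param n_replicates replicate arrays per treatment.
#' @param modules list of \code{\link{planted_module}} objects; each trend must
#'   have length \code{n_treatments}.
#' @param n_background number of pure-noise genes.
#' @param n_housekeeping number of near-constant genes (noise sd is
#'   \code{noise_sd / 10}).
#' @param noise_sd residual standard deviation on the log2 scale; defaults to
#'   0.25 times the mean planted loading.
#' @param baseline_range interval (log2 units) for per-gene baselines,
#'   mimicking the intensity spread of expressed genes.
#' @param seed integer driving all random draws.
#' @return an object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_treatments, n_replicates, modules,
                           n_background = 0, n_housekeeping = 0,
                           noise_sd = NULL, baseline_range = c(4, 12),
                           seed = 1L) {
  if (n_treatments < 1 || n_replicates < 1) {
    coex_param_error("'n_treatments' and 'n_replicates' must be >= 1")
  }
  if (n_background < 0) coex_param_error("'n_background' must be >= 0")
  if (n_housekeeping < 0) coex_param_error("'n_housekeeping' must be >= 0")
  if (!is.list(modules) || !all(vapply(modules, inherits, logical(1),
                                       "planted_module"))) {
    coex_param_error("'modules' must be a list of planted_module objects")
  }
  for (m in modules) {
    if (length(m$trend) != n_treatments) {
      coex_param_error("trend length of module ", m$module_id,
                       " does not equal 'n_treatments'")
    }
  }
  ids <- vapply(modules, `[[`, character(1), "module_id")
  if (anyDuplicated(ids)) coex_param_error("module ids must be unique")
  if (is.null(noise_sd)) {
    mean_loading <- if (length(modules)) {
      mean(vapply(modules, function(m) mean(m$loading_range), numeric(1)))
    } else 1
    noise_sd <- 0.25 * mean_loading
  }
  if (noise_sd <= 0) coex_param_error("'noise_sd' must be > 0")
  if (length(baseline_range) != 2L || baseline_range[1] > baseline_range[2]) {
    coex_param_error("'baseline_range' must be an interval")
  }
  structure(list(n_treatments = as.integer(n_treatments),
                 n_replicates = as.integer(n_replicates),
                 modules = modules,
                 n_background = as.integer(n_background),
                 n_housekeeping = as.integer(n_housekeeping),
                 noise_sd = noise_sd, baseline_range = baseline_range,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' A unit-variance latent trend
#'
#' Draws standard-normal latent values for each treatment and standardizes
#' them to mean 0 and (n-1 denominator) standard deviation 1, so planted
#' expression swings are controlled entirely by the loadings.
#'
#' @param n_treatments number of treatments.
#' @param seed integer seed.
#' @return numeric vector of length \code{n_treatments}.
#' @export
random_trend <- function(n_treatments, seed) {
  with_seed(seed, {
    z <- stats::rnorm(n_treatments)
    while (stats::sd(z) == 0) z <- stats::rnorm(n_treatments)
    as.numeric(scale(z))
  })
}

#' Pairwise-uncorrelated latent trends
#'
#' Draws standard-normal treatment profiles, centers them, orthogonalizes
#' via QR and standardizes each to unit variance, so distinct planted modules
#' follow exactly uncorrelated expression programs and the planted partition
#' is identifiable from coexpression alone.
#'
#' @param n_treatments number of treatments.
#' @param n_trends number of trends (must be < \code{n_treatments}).
#' @param seed integer seed.
#' @return matrix with one column per trend, each mean 0 and sd 1.
#' @export
orthogonal_trends <- function(n_treatments, n_trends, seed) {
  if (n_trends >= n_treatments) {
    coex_param_error("'n_trends' must be smaller than 'n_treatments'")
  }
  with_seed(seed, {
    x <- matrix(stats::rnorm(n_treatments * n_trends), n_treatments, n_trends)
    x <- scale(x, center = TRUE, scale = FALSE)
    q <- qr.Q(qr(x))[, seq_len(n_trends), drop = FALSE]
    apply(q, 2, function(col) as.numeric(scale(col)))
  })
}

#' Reference synthetic study conditions
#'
#' The benchmark configuration used throughout the package's validation: five
#' planted modules of sizes 40, 60, 80, 100 and 120 with a 30\% anti-correlated
#' fraction, 12 treatments with 3 replicate arrays each, 500 pure-noise
#' background genes, 100 housekeeping genes, and residual noise equal to a
#' quarter of the mean loading. The first module carries a planted domain
#' (\code{"PF_M1"}) for enrichment validation.
#'
#' @param seed integer seed; also used (offset) to draw the latent trends.
#' @return a \code{\link{synthetic_spec}}.
#' @export
reference_synthetic_spec <- function(seed = 1L) {
  sizes <- c(40, 60, 80, 100, 120)
  trends <- orthogonal_trends(12, length(sizes), seed = seed * 131L)
  modules <- lapply(seq_along(sizes), function(i) {
    planted_module(module_id = paste0("M", i), size = sizes[i],
                   trend = trends[, i],
                   anti_fraction = 0.3,
                   enriched_domain = if (i == 1L) "PF_M1" else NULL,
                   enrichment_fold = if (i == 1L) 20 else 1)
  })
  synthetic_spec(n_treatments = 12, n_replicates = 3, modules = modules,
                 n_background = 500, n_housekeeping = 100, seed = seed)
}

#' Generate one synthetic experiment
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param experiment_id label recorded in the sample sheet.
#' @return list with components \code{exprs} (gene x sample log2 matrix),
#'   \code{samples} (sample sheet data frame with columns sample_id,
#'   experiment_id, treatment, replicate) and \code{truth} (data frame with
#'   gene_id, label, sign, loading, baseline, enriched_domain,
#'   enrichment_fold).
#' @export
generate_experiment <- function(spec, experiment_id = "EXP1") {
  if (!inherits(spec, "synthetic_spec")) {
    coex_param_error("'spec' must be a synthetic_spec")
  }
  nt <- spec$n_treatments; nr <- spec$n_replicates
  treatments <- sprintf("T%02d", seq_len(nt))
  samples <- data.frame(
    sample_id = paste0(rep(treatments, each = nr), "_r", rep(seq_len(nr), nt)),
    experiment_id = experiment_id,
    treatment = rep(treatments, each = nr),
    replicate = rep(seq_len(nr), nt),
    stringsAsFactors = FALSE)

  with_seed(spec$seed, {
    rows <- list(); truth <- list()
    for (m in spec$modules) {
      n_neg <- round(m$anti_fraction * m$size)
      s <- sample(c(rep(-1, n_neg), rep(1, m$size - n_neg)))
      b <- stats::runif(m$size, spec$baseline_range[1], spec$baseline_range[2])
      lam <- stats::runif(m$size, m$loading_range[1], m$loading_range[2])
      gid <- sprintf("%s_g%03d", m$module_id, seq_len(m$size))
      tr_per_sample <- m$trend[match(samples$treatment, treatments)]
      x <- matrix(0, nrow = m$size, ncol = nrow(samples))
      for (i in seq_len(m$size)) {
        x[i, ] <- b[i] + s[i] * lam[i] * tr_per_sample +
          stats::rnorm(nrow(samples), sd = spec$noise_sd)
      }
      rownames(x) <- gid
      rows[[m$module_id]] <- x
      truth[[m$module_id]] <- data.frame(
        gene_id = gid, label = m$module_id, sign = s, loading = lam,
        baseline = b,
        enriched_domain = if (is.null(m$enriched_domain)) NA_character_ else
          m$enriched_domain,
        enrichment_fold = m$enrichment_fold, stringsAsFactors = FALSE)
    }
    extra <- function(n, prefix, sd) {
      if (n == 0L) return(NULL)
      b <- stats::runif(n, spec$baseline_range[1], spec$baseline_range[2])
      x <- matrix(stats::rnorm(n * nrow(samples), sd = sd),
                  nrow = n, ncol = nrow(samples)) + b
      gid <- sprintf("%s_g%03d", prefix, seq_len(n))
      rownames(x) <- gid
      list(x = x, truth = data.frame(
        gene_id = gid, label = prefix, sign = 1, loading = 0, baseline = b,
        enriched_domain = NA_character_, enrichment_fold = 1,
        stringsAsFactors = FALSE))
    }
    bg <- extra(spec$n_background, "background", spec$noise_sd)
    hk <- extra(spec$n_housekeeping, "housekeeping", spec$noise_sd / 10)
    exprs <- do.call(rbind, c(rows, list(bg$x, hk$x)))
    colnames(exprs) <- samples$sample_id
    truth_df <- do.call(rbind, c(truth, list(bg$truth, hk$truth)))
    rownames(truth_df) <- NULL
    stopifnot(!anyDuplicated(truth_df$gene_id))
    list(exprs = exprs, samples = samples, truth = truth_df)
  })
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_base <- function(probe, pos) {
  base <- substr(probe, pos, pos)
  repl <- setdiff(c("A", "C", "G", "T"), base)[1L]
  substr(probe, pos, pos) <- repl
  probe
}

#' Generate a probe-set layer over synthetic genes
#'
#' Each gene receives one transcript (uniform-random nucleotides) and one
#' normal probe set whose probes are exact substrings of that transcript.
#' Degenerate sets (expected downstream outcome: unassigned) carry only 8
#' exact-match probes, the rest mutated; multi-mapping sets (expected outcome:
#' discarded) match two transcripts, via a shared cassette appended to both.
#'
#' @param truth truth data frame from \code{\link{generate_experiment}}.
#' @param probes_per_set probes per set (the Rice GeneChip uses 11).
#' @param probe_len probe length in bases (25 on the Rice GeneChip).
#' @param n_degenerate_sets number of extra sets with only 8 perfect matches.
#' @param n_multimap_sets number of extra sets matching two transcripts.
#' @param transcript_len length of each generated transcript.
#' @param seed integer seed.
#' @return list with \code{transcripts} and \code{probes} (named character
#'   vectors, probe names \code{probeset#index}) and \code{expected}, a data
#'   frame (probeset_id, expected_status, expected_gene) stating the correct
#'   downstream assignment for every set.
#' @export
generate_probe_layer <- function(truth, probes_per_set = 11, probe_len = 25,
                                 n_degenerate_sets = 0, n_multimap_sets = 0,
                                 transcript_len = 300, seed = 1L) {
  if (probe_len < 1) coex_param_error("'probe_len' must be >= 1")
  if (probes_per_set < 9) {
    coex_param_error("'probes_per_set' must be >= 9 for assignable sets")
  }
  if (n_degenerate_sets < 0 || n_multimap_sets < 0) {
    coex_param_error("degenerate/multimap set counts must be >= 0")
  }
  if (probe_len > transcript_len) {
    coex_param_error("'probe_len' exceeds the generated transcript length")
  }
  genes <- truth$gene_id
  if (n_multimap_sets > 0 && length(genes) < 2L) {
    coex_param_error("multimap sets need at least two genes")
  }
  with_seed(seed, {
    transcripts <- random_dna(length(genes), transcript_len)
    names(transcripts) <- genes
    draw_probes <- function(seq, n) {
      starts <- sample(seq_len(nchar(seq) - probe_len + 1L), n, replace = TRUE)
      substring(seq, starts, starts + probe_len - 1L)
    }
    probes <- character(0); expected <- list()
    add_set <- function(ps_id, pr, status, gene) {
      names(pr) <- paste0(ps_id, "#", seq_along(pr))
      probes <<- c(probes, pr)
      expected[[ps_id]] <<- data.frame(
        probeset_id = ps_id, expected_status = status,
        expected_gene = gene, stringsAsFactors = FALSE)
    }
    for (g in genes) {
      add_set(paste0("ps_", g), draw_probes(transcripts[[g]], probes_per_set),
              "assigned", g)
    }
    if (n_degenerate_sets > 0) {
      tg <- genes[((seq_len(n_degenerate_sets) - 1L) %% length(genes)) + 1L]
      for (i in seq_len(n_degenerate_sets)) {
        pr <- draw_probes(transcripts[[tg[i]]], probes_per_set)
        for (j in 9:probes_per_set) {
          pr[j] <- mutate_base(pr[j], sample.int(probe_len, 1L))
          # a point mutation could still match elsewhere by chance only at
          # ~len/4^25; treated as impossible
        }
        add_set(sprintf("dps_%03d", i), pr, "unassigned", NA_character_)
      }
    }
    if (n_multimap_sets > 0) {
      for (i in seq_len(n_multimap_sets)) {
        pair <- genes[(((2L * i - 2L):(2L * i - 1L)) %% length(genes)) + 1L]
        cassette <- random_dna(1L, probes_per_set * probe_len)
        transcripts[pair] <- paste0(transcripts[pair], cassette)
        add_set(sprintf("mps_%03d", i), draw_probes(cassette, probes_per_set),
                "discarded", NA_character_)
      }
    }
    expected <- do.call(rbind, expected)
    rownames(expected) <- NULL
    list(transcripts = transcripts, probes = probes, expected = expected)
  })
}

#' Generate a gene-to-domain annotation table
#'
#' Every gene carries each background domain independently at
#' \code{background_rate}; members of a module with a planted
#' \code{enriched_domain} carry that domain at \code{fold * background_rate}
#' (capped at 1).
#'
#' @param truth truth data frame from \code{\link{generate_experiment}}.
#' @param n_domains number of background domain labels (\code{PF0001}, ...).
#' @param background_rate per-(gene, domain) carriage probability.
#' @param seed integer seed.
#' @return data frame (gene_id, domain_id) with unique pairs.
#' @export
generate_annotations <- function(truth, n_domains, background_rate,
                                 seed = 1L) {
  if (background_rate < 0 || background_rate > 1) {
    coex_param_error("'background_rate' must be in [0,1]")
  }
  if (any(truth$enrichment_fold < 0, na.rm = TRUE)) {
    coex_param_error("'enrichment_fold' must be >= 0")
  }
  domains <- sprintf("PF%04d", seq_len(n_domains))
  planted <- unique(stats::na.omit(truth$enriched_domain))
  domains <- union(domains, planted)
  with_seed(seed, {
    out <- list()
    for (d in domains) {
      p <- rep(background_rate, nrow(truth))
      hit <- !is.na(truth$enriched_domain) & truth$enriched_domain == d
      # fold = Inf plants the domain with certainty even at background rate 0
      p[hit] <- ifelse(is.infinite(truth$enrichment_fold[hit]), 1,
                       pmin(1, truth$enrichment_fold[hit] * background_rate))
      carry <- stats::runif(nrow(truth)) < p
      if (any(carry)) {
        out[[d]] <- data.frame(gene_id = truth$gene_id[carry], domain_id = d,
                               stringsAsFactors = FALSE)
      }
    }
    ann <- if (length(out)) do.call(rbind, out) else
      data.frame(gene_id = character(0), domain_id = character(0))
    rownames(ann) <- NULL
    ann[order(ann$gene_id, ann$domain_id), , drop = FALSE]
  })
}

#' Benchmark for the module-obscuring effect of pooled analyses
#'
#' Generates \code{n_experiments} experiments over one gene universe. Two
#' shared modules are planted in every experiment (with independent trends,
#' loadings and signs per experiment, as unrelated studies re-activate a
#' shared program differently), while module \code{M} is planted only in the
#' first experiment: in all others its genes are pure background noise.
#' Comparing planted-module recovery between the first experiment's own
#' (condition-dependent) analysis and the pooled (condition-independent)
#' analysis quantifies how pooling unrelated conditions can obscure
#' condition-specific coexpression.
#'
#' @param seed integer seed.
#' @param n_experiments number of experiments (>= 2).
#' @param shared_sizes sizes of the modules planted in every experiment.
#' @param specific_size size of the experiment-1-specific module \code{M}.
#' @param n_background pure-noise genes per experiment (in experiments 2..n,
#'   \code{specific_size} further noise genes carry module M's gene ids).
#' @param n_housekeeping near-constant genes per experiment.
#' @param n_treatments,n_replicates design of each experiment.
#' @return list with \code{experiments} (list of generate_experiment outputs,
#'   identical gene universes), \code{truth} (experiment 1's truth table) and
#'   \code{specific_module}, the id of the experiment-specific module.
#' @export
obscuring_benchmark <- function(seed = 1L, n_experiments = 3,
                                shared_sizes = c(50, 60), specific_size = 40,
                                n_background = 150, n_housekeeping = 30,
                                n_treatments = 12, n_replicates = 3) {
  if (n_experiments < 2) coex_param_error("'n_experiments' must be >= 2")
  n_shared <- length(shared_sizes)
  make_spec <- function(exp_idx, with_specific) {
    trends <- orthogonal_trends(n_treatments, n_shared + 1L,
                                seed = seed * 977L + exp_idx)
    mods <- lapply(seq_len(n_shared), function(i) {
      planted_module(paste0("S", i), shared_sizes[i], trend = trends[, i],
                     anti_fraction = 0.3)
    })
    if (with_specific) {
      mods <- c(mods, list(planted_module("M", specific_size,
                                          trend = trends[, n_shared + 1L],
                                          anti_fraction = 0.3)))
    }
    synthetic_spec(n_treatments = n_treatments, n_replicates = n_replicates,
                   modules = mods,
                   n_background = if (with_specific) n_background else
                     n_background + specific_size,
                   n_housekeeping = n_housekeeping,
                   seed = seed * 7919L + exp_idx)
  }
  first <- generate_experiment(make_spec(1L, TRUE), experiment_id = "EXP1")
  experiments <- list(EXP1 = first)
  m_ids <- first$truth$gene_id[first$truth$label == "M"]
  for (e in seq.int(2L, n_experiments)) {
    ex_id <- paste0("EXP", e)
    d <- generate_experiment(make_spec(e, FALSE), experiment_id = ex_id)
    # the last `specific_size` background genes stand in for module M's genes
    bg <- d$truth$gene_id[d$truth$label == "background"]
    stopifnot(length(bg) >= specific_size)
    ren <- stats::setNames(m_ids, utils::tail(bg, specific_size))
    idx <- match(names(ren), rownames(d$exprs))
    rownames(d$exprs)[idx] <- unname(ren)
    d$truth$gene_id[match(names(ren), d$truth$gene_id)] <- unname(ren)
    experiments[[ex_id]] <- d
  }
  list(experiments = experiments, truth = first$truth, specific_module = "M")
}

#' Pool experiments into a condition-independent data set
#'
#' Columns are the union of all samples (sample ids prefixed with their
#' experiment id); rows are the genes present in every experiment.
#'
#' @param experiments list of lists with components \code{exprs} and
#'   \code{samples} as returned by \code{\link{generate_experiment}}.
#' @return list with pooled \code{exprs} and \code{samples}.
#' @export
combine_experiments <- function(experiments) {
  if (length(experiments) < 1L) coex_param_error("no experiments supplied")
  genes <- Reduce(intersect, lapply(experiments, function(e) rownames(e$exprs)))
  if (length(genes) == 0L) {
    coex_data_error("no genes are shared by all experiments")
  }
  mats <- list(); sheets <- list()
  for (e in experiments) {
    sh <- e$samples
    new_ids <- paste0(sh$experiment_id, ".", sh$sample_id)
    m <- e$exprs[genes, sh$sample_id, drop = FALSE]
    colnames(m) <- new_ids
    sh$sample_id <- new_ids
    sh$treatment <- paste0(sh$experiment_id, ".", sh$treatment)
    mats[[length(mats) + 1L]] <- m
    sheets[[length(sheets) + 1L]] <- sh
  }
  samples <- do.call(rbind, sheets)
  if (anyDuplicated(samples$sample_id)) {
    coex_data_error("sample ids are not unique after experiment prefixing")
  }
  rownames(samples) <- NULL
  list(exprs = do.call(cbind, mats), samples = samples)
}

#' Write a synthetic data set to disk
#'
#' Emits the expression matrix, sample sheet, truth table and (if present)
#' probe-layer FASTA files and annotation TSV under \code{dir}.
#'
#' @param dataset list from \code{\link{generate_experiment}}, optionally with
#'   \code{probe_layer} and \code{annotations} elements attached.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    write_tsv_matrix(dataset$exprs, file.path(dir, "expression.tsv")),
    write_tsv_df(dataset$samples, file.path(dir, "samples.tsv")),
    write_tsv_df(dataset$truth, file.path(dir, "truth.tsv")))
  if (!is.null(dataset$probe_layer)) {
    pl <- dataset$probe_layer
    tf <- file.path(dir, "transcripts.fasta")
    pf <- file.path(dir, "probes.fasta")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(pl$transcripts), tf)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(pl$probes), pf)
    files <- c(files, tf, pf,
               write_tsv_df(pl$expected, file.path(dir, "expected_assignments.tsv")))
  }
  if (!is.null(dataset$annotations)) {
    files <- c(files,
               write_tsv_df(dataset$annotations, file.path(dir, "annotations.tsv")))
  }
  invisible(files)
}
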