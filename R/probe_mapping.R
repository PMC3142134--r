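# Probe-set to gene assignment by exact probe matching.
#
# A probe set is assigned to a gene when nine or more of its probes match a
# single transcript perfectly (full length, ungapped, either strand by
# default); sets reaching nine matches on two or more transcripts are
# discarded, and sets reaching nine on none are left unassigned.

#' Build an exact-match transcript index
#'
#' Wraps the transcript set for exact substring queries of a fixed probe
#' length, optionally matching the reverse complement of the query as well
#' (GeneChip probes are antisense to the mRNA, and strand handling of the
#' original alignment is not standardized, so both strands are searched by
#' default).
#'
#' @param transcripts named character vector, \code{Biostrings::DNAStringSet},
#'   or path to a FASTA file.
#' @param probe_len probe length every query must have.
#' @param revcomp also match the reverse complement of each query.
#' @return object of class \code{transcript_index}.
#' @export
index_transcripts <- function(transcripts, probe_len = 25, revcomp = TRUE) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts)) {
    transcripts <- Biostrings::readDNAStringSet(transcripts)
  }
  if (!methods::is(transcripts, "DNAStringSet")) {
    transcripts <- Biostrings::DNAStringSet(transcripts)
  }
  if (length(transcripts) == 0L) coex_data_error("no transcripts supplied")
  if (is.null(names(transcripts)) || anyDuplicated(names(transcripts))) {
    coex_data_error("transcripts must carry unique names")
  }
  if (any(Biostrings::width(transcripts) < probe_len)) {
    coex_data_error("all transcripts must be at least 'probe_len' long")
  }
  structure(list(transcripts = transcripts, probe_len = as.integer(probe_len),
                 revcomp = revcomp),
            class = "transcript_index")
}

#' Query a transcript index with one probe
#'
#' @param index a \code{\link{index_transcripts}} object.
#' @param probe nucleotide string of the index's probe length. Probes
#'   containing N never match.
#' @return character vector of transcript names containing the probe (or,
#'   when enabled, its reverse complement) as an exact substring.
#' @export
query_index <- function(index, probe) {
  if (!inherits(index, "transcript_index")) {
    coex_param_error("'index' must come from index_transcripts()")
  }
  if (nchar(probe) != index$probe_len) {
    coex_param_error("probe length ", nchar(probe),
                     " does not match index probe length ", index$probe_len)
  }
  if (grepl("N", probe, fixed = TRUE)) return(character(0))
  pat <- Biostrings::DNAString(probe)
  hits <- Biostrings::vcountPattern(pat, index$transcripts, fixed = TRUE) > 0
  if (index$revcomp) {
    rc <- Biostrings::reverseComplement(pat)
    hits <- hits |
      Biostrings::vcountPattern(rc, index$transcripts, fixed = TRUE) > 0
  }
  names(index$transcripts)[hits]
}

#' Group probe FASTA records into probe sets
#'
#' Probe names are expected as \code{<probeset_id><delim><index>}.
#'
#' @param probes named character vector or path to a probe FASTA file.
#' @param delim delimiter separating probe-set id from probe index.
#' @return named list of character vectors, one per probe set.
#' @export
probe_sets_from_fasta <- function(probes, delim = "#") {
  if (is.character(probes) && length(probes) == 1L && file.exists(probes)) {
    ss <- Biostrings::readDNAStringSet(probes)
    probes <- stats::setNames(as.character(ss), names(ss))
  }
  ids <- sub(paste0(delim, "[^", delim, "]*$"), "", names(probes))
  split(unname(probes), factor(ids, levels = unique(ids)))
}

#' Assign probe sets to genes
#'
#' A set is \code{assigned} to the unique transcript matched perfectly by at
#' least \code{min_probes} of its probes, \code{discarded} if two or more
#' transcripts reach that count, and \code{unassigned} otherwise.
#'
#' @param probe_sets named list of probe character vectors (see
#'   \code{\link{probe_sets_from_fasta}}).
#' @param index a \code{\link{index_transcripts}} object built with the same
#'   probe length.
#' @param min_probes minimum perfectly matching probes for assignment
#'   (default 9 of the Rice GeneChip's 11).
#' @return data frame (probeset_id, status, gene_id, n_matches) with the full
#'   per-gene match counts attached as attribute \code{match_counts}.
#' @export
assign_probe_sets <- function(probe_sets, index, min_probes = 9) {
  if (!inherits(index, "transcript_index")) {
    coex_param_error("'index' must come from index_transcripts()")
  }
  lens <- unique(nchar(unlist(probe_sets, use.names = FALSE)))
  if (length(lens) > 0 && any(lens != index$probe_len)) {
    coex_param_error("probe length does not match the index probe length")
  }
  counts_per_set <- lapply(probe_sets, function(pr) {
    hits <- unlist(lapply(pr, query_index, index = index), use.names = FALSE)
    if (length(hits) == 0L) integer(0) else table(hits)
  })
  rows <- lapply(names(probe_sets), function(ps) {
    ct <- counts_per_set[[ps]]
    top <- names(ct)[ct >= min_probes]
    if (length(top) == 1L) {
      data.frame(probeset_id = ps, status = "assigned", gene_id = top,
                 n_matches = as.integer(ct[[top]]), stringsAsFactors = FALSE)
    } else if (length(top) >= 2L) {
      data.frame(probeset_id = ps, status = "discarded",
                 gene_id = NA_character_, n_matches = NA_integer_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(probeset_id = ps, status = "unassigned",
                 gene_id = NA_character_, n_matches = NA_integer_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "match_counts") <- counts_per_set
  out
}

#' Collapse probe-set signals to gene-level expression
#'
#' Genes measured by several assigned probe sets receive the arithmetic mean
#' of those sets' signals per sample, on the linear (pre-log2) scale;
#' unassigned and discarded sets contribute nothing.
#'
#' @param assignments data frame from \code{\link{assign_probe_sets}}.
#' @param probeset_matrix probeset x sample expression matrix (linear scale).
#' @return gene x sample matrix with one row per assigned gene.
#' @export
summarize_gene_expression <- function(assignments, probeset_matrix) {
  asg <- assignments[assignments$status == "assigned", , drop = FALSE]
  missing <- setdiff(asg$probeset_id, rownames(probeset_matrix))
  if (length(missing) > 0) {
    coex_data_error("assigned probe sets missing from the expression matrix: ",
                    paste(missing, collapse = ", "))
  }
  genes <- unique(asg$gene_id)
  out <- t(vapply(genes, function(g) {
    sets <- asg$probeset_id[asg$gene_id == g]
    colMeans(probeset_matrix[sets, , drop = FALSE])
  }, numeric(ncol(probeset_matrix))))
  rownames(out) <- genes
  colnames(out) <- colnames(probeset_matrix)
  out
}
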