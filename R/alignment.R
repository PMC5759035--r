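## Pairwise identity machinery shared by clustering, reliability filtering
## and cross-referencing. The optimal alignments themselves come from
## Biostrings::pairwiseAlignment (Needleman-Wunsch with affine gaps);
## identity bookkeeping follows the USEARCH-like "internal" convention:
## matching columns / alignment columns after stripping terminal-gap
## columns. The pipeline's thresholds (0.97 OTU radius, 0.75 reference
## screen) are all compared inclusively (>=).

default_scoring <- function() {
  list(match = 1, mismatch = -2, gap_open = 10, gap_extend = 1)
}

## Vectorised core: align many patterns against one subject.
## type "global" or "global-local" (query global, free subject ends).
align_set <- function(patterns, subject, type = "global",
                      scoring = default_scoring()) {
  m <- .align_many_cpp(as.character(patterns), subject,
                       scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend,
                       identical(type, "global-local"))
  lapply(seq_len(nrow(m)), function(i) {
    cols <- unname(m[i, "columns"])
    structure(list(
      identity = if (cols > 0) unname(m[i, "matches"]) / cols else 0,
      aligned_columns = as.integer(cols),
      matches = as.integer(m[i, "matches"]),
      query_coverage = unname(m[i, "query_cols"]) / nchar(patterns[i]),
      score = unname(m[i, "score"])), class = "cbc_alignment")
  })
}

#' Global pairwise identity
#'
#' Optimal global (Needleman-Wunsch) alignment with affine gap costs;
#' identity is matching columns over alignment columns after terminal-gap
#' columns are stripped.
#'
#' @param a,b DNA strings (non-empty)
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (positive gap costs); defaults +1/-2/10/1
#' @return a `cbc_alignment` list: `identity`, `aligned_columns`,
#'   `matches`, `query_coverage`, `score`
#' @export
global_identity <- function(a, b, scoring = default_scoring()) {
  if (!nzchar(a) || !nzchar(b)) stop_cbc("empty sequence in global_identity")
  align_set(a, b, type = "global", scoring = scoring)[[1]]
}

#' Semiglobal (glocal) identity of a query inside a longer target
#'
#' The query is aligned end-to-end; gaps at the target's ends are free.
#' Used to match short mOTU representatives against full-length consensus
#' reads. Identity is computed over the query's aligned span.
#'
#' @param query,target DNA strings; a warning is raised when the query is
#'   longer than the target
#' @inheritParams global_identity
#' @return a `cbc_alignment` list
#' @export
semiglobal_identity <- function(query, target, scoring = default_scoring()) {
  if (!nzchar(query) || !nzchar(target))
    stop_cbc("empty sequence in semiglobal_identity")
  if (nchar(query) > nchar(target))
    warning("semiglobal_identity: query longer than target", call. = FALSE)
  align_set(query, target, type = "global-local", scoring = scoring)[[1]]
}

kmer_vector <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

#' k-mer prefilter for alignment candidates
#'
#' Returns the indices of candidates sharing at least `min_shared` distinct
#' k-mers with the query. A performance guard only: alignment-based
#' decisions downstream remain authoritative.
#'
#' @param query DNA string
#' @param candidates character vector of DNA strings
#' @param k k-mer size (>= 4)
#' @param min_shared minimum number of shared distinct k-mers (0 keeps all)
#' @return integer indices into `candidates`
#' @export
kmer_prefilter <- function(query, candidates, k = 8, min_shared = 1) {
  if (k < 4) stop_cbc("kmer_prefilter requires k >= 4")
  if (!length(candidates)) return(integer(0))
  if (min_shared <= 0) return(seq_along(candidates))
  qk <- unique(kmer_vector(query, k))
  shared <- vapply(candidates, function(s) {
    sum(unique(kmer_vector(s, k)) %in% qk)
  }, numeric(1), USE.NAMES = FALSE)
  which(shared >= min_shared)
}

## Conservative lower bound on shared k-mers for a candidate at >= `threshold`
## identity to a query of length L: each of the <= ceil((1-t)L) differing
## columns (substitution or indel) can destroy at most k k-mers.
## Extra slack of one error is subtracted to stay superset-safe.
kmer_screen_bound <- function(query_length, threshold, k = 8) {
  e <- ceiling((1 - threshold) * query_length) + 1
  max(1, (query_length - k + 1) - k * e)
}

## Shared-kmer counts of a query against precomputed candidate k-mer sets.
shared_kmer_counts <- function(query, kmer_sets, k = 8) {
  qk <- unique(kmer_vector(query, k))
  vapply(kmer_sets, function(s) sum(s %in% qk), numeric(1))
}
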