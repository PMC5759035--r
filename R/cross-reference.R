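## Linking the culture-dependent collection (cOTUs, via their consensus
## reads) with the culture-independent microbiome profile (mOTUs), and
## estimating how much of each habitat's core-microbiome relative
## abundance the collection recovered.

#' Screen mOTUs against a curated reference database
#'
#' Retains mOTUs whose best global identity against the curated set
#' reaches `min_identity` (default 0.75, inclusive); the rest are
#' reported as discards.
#'
#' @param motus data frame with columns `motu_id`, `sequence`
#' @param curated_db `cbc_seqs` or data frame with a `sequence` column
#' @param min_identity identity floor (default 0.75)
#' @param scoring alignment scoring
#' @return list: `retained` (motus rows), `discarded` (motu ids)
#' @export
filter_motus <- function(motus, curated_db, min_identity = 0.75,
                         scoring = default_scoring()) {
  if (!nrow(curated_db)) stop_cbc("curated_db must be non-empty")
  keep <- vapply(motus$sequence, function(q) {
    for (s in curated_db$sequence) {
      r <- semiglobal_identity(q, s, scoring = scoring)
      if (r$identity >= min_identity) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
  list(retained = motus[keep, , drop = FALSE],
       discarded = motus$motu_id[!keep])
}

#' Match mOTU representatives against consensus reads
#'
#' Semiglobal alignment of each (short) mOTU representative against
#' k-mer-prescreened consensus reads; pairs at `>= min_identity` with
#' query coverage `>= min_query_coverage` are emitted.
#'
#' @param motus data frame `motu_id`, `sequence`
#' @param ccs `cbc_seqs` of consensus reads
#' @param min_identity identity floor (default 0.97)
#' @param min_query_coverage minimum fraction of the mOTU aligned
#'   (default 0.90)
#' @param scoring alignment scoring
#' @param k k-mer size of the candidate screen
#' @return data frame: `motu_id`, `ccs_id`, `identity`
#' @export
match_motus <- function(motus, ccs, min_identity = 0.97,
                        min_query_coverage = 0.90,
                        scoring = default_scoring(), k = 8) {
  if (!nrow(motus) || !nrow(ccs))
    stop_cbc("match_motus needs non-empty mOTU and consensus sets")
  ccs_kmers <- lapply(ccs$sequence, function(s) unique(kmer_vector(s, k)))
  out <- list()
  for (i in seq_len(nrow(motus))) {
    q <- motus$sequence[i]
    shared <- shared_kmer_counts(q, ccs_kmers, k = k)
    bound <- kmer_screen_bound(nchar(q), min_identity, k = k)
    cand <- which(shared >= bound)
    for (j in cand) {
      r <- semiglobal_identity(q, ccs$sequence[j], scoring = scoring)
      if (r$identity >= min_identity &&
          r$query_coverage >= min_query_coverage) {
        out[[length(out) + 1L]] <- data.frame(
          motu_id = motus$motu_id[i], ccs_id = ccs$id[j],
          identity = r$identity, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(motu_id = character(0), ccs_id = character(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Aggregate mOTU-consensus matches into mOTU-cOTU links
#'
#' @param pairs data frame from [match_motus()]
#' @param ccs_to_cotu named character vector: ccs_id -> cotu_id; pairs
#'   whose read is absent from the mapping are dropped with a warning
#' @return data frame: `motu_id`, `cotu_id`, `n_supporting_ccs`,
#'   `best_identity` (one row per link, many-to-many preserved)
#' @export
link_to_cotus <- function(pairs, ccs_to_cotu) {
  known <- pairs$ccs_id %in% names(ccs_to_cotu)
  if (any(!known))
    warning(sprintf("%d match(es) dropped: consensus read not in mapping",
                    sum(!known)), call. = FALSE)
  pairs <- pairs[known, , drop = FALSE]
  if (!nrow(pairs))
    return(data.frame(motu_id = character(0), cotu_id = character(0),
                      n_supporting_ccs = integer(0),
                      best_identity = numeric(0), stringsAsFactors = FALSE))
  pairs$cotu_id <- unname(ccs_to_cotu[pairs$ccs_id])
  agg <- split(pairs, paste(pairs$motu_id, pairs$cotu_id, sep = "\r"))
  out <- do.call(rbind, lapply(agg, function(g) {
    data.frame(motu_id = g$motu_id[1], cotu_id = g$cotu_id[1],
               n_supporting_ccs = nrow(g),
               best_identity = max(g$identity), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$motu_id, out$cotu_id), , drop = FALSE]
}

#' Flag the core mOTUs of a habitat
#'
#' mOTUs are ranked by descending abundance; the minimal prefix whose
#' cumulative abundance reaches `cumulative_cutoff` is the core. Ties at
#' the boundary abundance are all included.
#'
#' @param abundance named numeric vector: mOTU -> relative abundance in
#'   the habitat
#' @param cumulative_cutoff cumulative abundance cutoff (default 0.90)
#' @return logical vector named by mOTU id
#' @export
define_core <- function(abundance, cumulative_cutoff = 0.90) {
  o <- order(-abundance)
  cum <- cumsum(abundance[o])
  n_core <- which(cum >= cumulative_cutoff - 1e-12)[1]
  if (is.na(n_core)) n_core <- length(abundance)  # cutoff unreachable
  boundary <- abundance[o][n_core]
  core_ids <- names(abundance)[o][seq_len(n_core)]
  tied <- names(abundance)[abundance >= boundary - 1e-12 & abundance > 0]
  core <- names(abundance) %in% union(core_ids, tied) & abundance > 0
  names(core) <- names(abundance)
  core
}

#' Core-microbiome recovery estimate for one habitat
#'
#' The recovered fraction is the summed abundance of *linked* core mOTUs
#' over the summed abundance of all core mOTUs, as a percentage.
#'
#' @param links data frame from [link_to_cotus()]
#' @param abundance named numeric vector of mOTU abundances in the habitat
#' @param core logical vector from [define_core()] (recomputed when
#'   `NULL`)
#' @param habitat habitat name carried into the report
#' @param core_only use the core subset as denominator (default TRUE);
#'   `FALSE` computes whole-community recovery
#' @return list of class `cbc_recovery`: `habitat`, `n_matched_cotus`,
#'   `n_matched_motus`, `recovered_core_abundance` (percent)
#' @export
recovery_estimate <- function(links, abundance, core = NULL,
                              habitat = "habitat", core_only = TRUE) {
  if (is.null(core)) core <- define_core(abundance)
  denom_ids <- if (core_only) names(abundance)[core] else
    names(abundance)[abundance > 0]
  denom <- sum(abundance[denom_ids])
  if (denom <= 0) stop_cbc("habitat %s has zero core abundance", habitat)
  linked <- intersect(denom_ids, unique(links$motu_id))
  structure(list(
    habitat = habitat,
    n_matched_cotus = length(unique(links$cotu_id[links$motu_id %in%
                                                    denom_ids])),
    n_matched_motus = length(linked),
    recovered_core_abundance = 100 * sum(abundance[linked]) / denom),
    class = "cbc_recovery")
}

#' @export
print.cbc_recovery <- function(x, ...) {
  cat(sprintf("%s: %.1f%% of core abundance recovered (%d cOTUs ~ %d mOTUs)\n",
              x$habitat, x$recovered_core_abundance, x$n_matched_cotus,
              x$n_matched_motus))
  invisible(x)
}
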