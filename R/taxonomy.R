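## k-mer bootstrap taxonomy: a single naive-Bayes-free classifier in the
## RDP/SINTAX family. Each bootstrap draws a subsample of the query's
## 8-mers, scores every reference by shared-k-mer count and votes with the
## top reference's lineage; per-rank confidence is the fraction of
## bootstraps agreeing with the modal label. Ranks below the confidence
## cutoff are collapsed to "unknown", displayed with the "u_" prefix of
## the deepest known label.

#' Classify a sequence against a labelled reference set
#'
#' @param seq query DNA string (length >= k)
#' @param reference data frame with columns `sequence` and the lineage
#'   ranks `phylum` ... `genus` (complete labels)
#' @param k k-mer size (default 8)
#' @param subsample k-mers drawn per bootstrap (default 32)
#' @param bootstraps number of bootstrap votes (default 100)
#' @param cutoff per-rank confidence cutoff below which a rank is unknown
#'   (default 0.9)
#' @param seed integer seed
#' @return list of class `cbc_lineage`: per-rank `labels` (NA when
#'   unknown), `confidence`, and `display_label`
#' @export
classify_taxonomy <- function(seq, reference, k = 8, subsample = 32,
                              bootstraps = 100, cutoff = 0.9, seed = 1) {
  if (!nrow(reference)) stop_cbc("empty reference set")
  if (nchar(seq) < k) stop_cbc("query shorter than k = %d", k)
  if (anyNA(reference[, LINEAGE_RANKS]))
    stop_cbc("reference lineages must be complete")
  set.seed(seed)
  qk <- kmer_vector(seq, k)
  uq <- unique(qk)
  ## membership matrix: references x unique query k-mers
  member <- vapply(reference$sequence, function(s) {
    uq %in% unique(kmer_vector(s, k))
  }, logical(length(uq)))
  member <- matrix(member, nrow = length(uq))
  votes <- integer(bootstraps)
  for (b in seq_len(bootstraps)) {
    idx <- match(sample(qk, subsample, replace = TRUE), uq)
    score <- colSums(member[idx, , drop = FALSE])
    votes[b] <- which.max(score)  # ties -> first reference
  }
  labels <- rep(NA_character_, length(LINEAGE_RANKS))
  confidence <- numeric(length(LINEAGE_RANKS))
  names(labels) <- names(confidence) <- LINEAGE_RANKS
  for (r in LINEAGE_RANKS) {
    vote_labels <- reference[[r]][votes]
    tab <- sort(table(vote_labels), decreasing = TRUE)
    modal <- names(tab)[1]
    confidence[r] <- tab[[1]] / bootstraps
    labels[r] <- modal
  }
  ## apply cutoff with downward monotonicity: once unknown, stay unknown
  known <- confidence >= cutoff
  if (any(!known)) {
    first_unknown <- which(!known)[1]
    labels[first_unknown:length(labels)] <- NA_character_
  }
  structure(list(labels = labels, confidence = confidence,
                 display_label = collapse_unknown(labels)),
            class = "cbc_lineage")
}

#' Collapse unknown ranks to a display label
#'
#' The label is the deepest known rank's name; when the genus is unknown
#' the `u_` prefix marks the label as an unknown member of that deepest
#' known group (e.g. `u_Rhizobiaceae`); with all ranks unknown the label
#' is `u_Bacteria`.
#'
#' @param labels named character vector over ranks phylum..genus, `NA`
#'   where unknown (a `cbc_lineage` is also accepted)
#' @return display label string
#' @export
collapse_unknown <- function(labels) {
  if (inherits(labels, "cbc_lineage")) labels <- labels$labels
  known <- !is.na(labels)
  if (!any(known)) return("u_Bacteria")
  deepest <- max(which(known))
  lab <- labels[[deepest]]
  if (LINEAGE_RANKS[deepest] == "genus") lab else paste0("u_", lab)
}

#' Classify a set of centroids and return a lineage table
#'
#' @param centroids named character vector of sequences
#' @param reference labelled reference data frame, see
#'   [classify_taxonomy()]
#' @param seed integer seed (one child seed per centroid)
#' @param ... passed to [classify_taxonomy()]
#' @return data frame: `id`, ranks, per-rank confidences, `display_label`
#' @export
classify_set <- function(centroids, reference, seed = 1, ...) {
  out <- lapply(seq_along(centroids), function(i) {
    ln <- classify_taxonomy(centroids[[i]], reference,
                            seed = derive_seed(seed, names(centroids)[i]),
                            ...)
    df <- data.frame(id = names(centroids)[i], stringsAsFactors = FALSE)
    for (r in LINEAGE_RANKS) {
      df[[r]] <- ln$labels[[r]]
      df[[paste0("conf_", r)]] <- ln$confidence[[r]]
    }
    df$display_label <- ln$display_label
    df
  })
  do.call(rbind, out)
}
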