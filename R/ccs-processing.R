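## Demultiplexing of long consensus reads to plate wells and the two
## read-level filters applied before deconvolution: coverage (pass count
## >= 2) and reliability (similarity to a curated reference database
## and/or to a consensus read from another well). Unassigned or unreliable
## reads are returned, never silently dropped.

#' Demultiplex consensus reads to wells by barcode prefix
#'
#' The barcode is read from the first `nchar(barcode)` bases of each
#' sequence and matched against the map by Hamming distance. A read is
#' assigned only when exactly matched within `max_mismatch`; the barcode
#' prefix is stripped from assigned reads.
#'
#' @param reads `cbc_seqs` record set
#' @param barcode_map named character vector: barcode -> well_id;
#'   barcodes must be equal length and pairwise separated by more than
#'   `2 * max_mismatch` mismatches
#' @param max_mismatch maximum Hamming distance for an assignment
#' @return list: `assigned` (`cbc_seqs` with `well` annotation set and
#'   barcode stripped), `unassigned` (`cbc_seqs`)
#' @export
demultiplex <- function(reads, barcode_map, max_mismatch = 1) {
  barcodes <- names(barcode_map)
  blen <- unique(nchar(barcodes))
  if (length(blen) != 1L) stop_cbc("barcodes must be equal length")
  if (max_mismatch >= blen / 2)
    stop_cbc("max_mismatch must be below half the barcode length")
  bmat <- do.call(rbind, strsplit(barcodes, "", fixed = TRUE))
  if (length(barcodes) > 1) {
    ## ambiguity guard: all pairs must differ in > 2*max_mismatch positions
    for (i in seq_len(length(barcodes) - 1)) {
      d <- rowSums(bmat[(i + 1):length(barcodes), , drop = FALSE] !=
                     matrix(bmat[i, ], length(barcodes) - i, blen,
                            byrow = TRUE))
      if (any(d <= 2 * max_mismatch))
        stop_cbc("ambiguous barcode map: pair within %d mismatches",
                 2 * max_mismatch)
    }
  }
  prefix <- substr(reads$sequence, 1, blen)
  pmat <- do.call(rbind, strsplit(prefix, "", fixed = TRUE))
  well <- rep(NA_character_, nrow(reads))
  for (i in seq_len(nrow(reads))) {
    d <- rowSums(bmat != matrix(pmat[i, ], nrow(bmat), blen, byrow = TRUE))
    hit <- which(d <= max_mismatch)
    if (length(hit) == 1L) well[i] <- barcode_map[[hit]]
  }
  assigned <- reads[!is.na(well), , drop = FALSE]
  if (nrow(assigned)) {
    assigned$sequence <- substring(assigned$sequence, blen + 1)
    assigned <- set_seq_annot(assigned, "well", well[!is.na(well)])
  }
  list(assigned = assigned,
       unassigned = reads[is.na(well), , drop = FALSE])
}

#' Coverage filter on consensus pass counts
#'
#' Retains reads whose `passes` annotation is at least `min_passes`
#' (default 2, i.e. the ">= 2x coverage" rule, boundary inclusive).
#'
#' @param ccs `cbc_seqs` with a `passes` annotation on every record
#' @param min_passes minimum pass count (default 2)
#' @return list: `retained`, `dropped` (`cbc_seqs`)
#' @export
filter_by_coverage <- function(ccs, min_passes = 2) {
  passes <- suppressWarnings(as.integer(seq_annot(ccs, "passes")))
  if (any(is.na(passes)))
    stop_cbc("missing or non-integer 'passes' annotation on %d read(s)",
             sum(is.na(passes)))
  keep <- passes >= min_passes
  list(retained = ccs[keep, , drop = FALSE],
       dropped = ccs[!keep, , drop = FALSE])
}

#' Reliability filter against a curated database and collection peers
#'
#' A consensus read is reliable when its best global identity to a curated
#' reference sequence reaches `db_min_identity`, or its best identity to a
#' consensus read from a *different* well reaches `peer_min_identity`
#' (within-well reads cannot self-validate). The decision and its reason
#' (`db_hit`, `peer_hit`, `both`, `none`) are annotated on every read.
#'
#' @param ccs `cbc_seqs` with `well` annotations
#' @param curated_db `cbc_seqs` of curated reference sequences
#' @param db_min_identity identity floor against the database (default
#'   0.80)
#' @param peer_min_identity identity floor against other-well peers
#'   (default 0.97)
#' @param scoring alignment scoring
#' @param k k-mer size of the candidate screen
#' @return list: `retained`, `dropped`, and `report` (data frame `id`,
#'   `well`, `reliable`, `reason`)
#' @export
reliability_filter <- function(ccs, curated_db, db_min_identity = 0.80,
                               peer_min_identity = 0.97,
                               scoring = default_scoring(), k = 8) {
  if (!nrow(curated_db)) stop_cbc("curated_db must be non-empty")
  wells <- seq_annot(ccs, "well")
  db_kmers <- lapply(curated_db$sequence,
                     function(s) unique(kmer_vector(s, k)))
  ccs_kmers <- lapply(ccs$sequence, function(s) unique(kmer_vector(s, k)))

  best_identity <- function(seq_i, pool_seqs, pool_kmers, floor_id) {
    shared <- vapply(pool_kmers, function(s) {
      sum(s %in% unique(kmer_vector(seq_i, k)))
    }, numeric(1))
    bound <- kmer_screen_bound(nchar(seq_i), floor_id, k = k)
    cand <- which(shared >= bound)
    cand <- cand[order(-shared[cand])]
    for (j in cand) {
      if (global_identity(seq_i, pool_seqs[j],
                          scoring = scoring)$identity >= floor_id)
        return(TRUE)
    }
    FALSE
  }

  db_hit <- logical(nrow(ccs)); peer_hit <- logical(nrow(ccs))
  for (i in seq_len(nrow(ccs))) {
    db_hit[i] <- best_identity(ccs$sequence[i], curated_db$sequence,
                               db_kmers, db_min_identity)
    if (!db_hit[i]) {  # db hit already suffices; peer check only if needed
      other <- which(wells != wells[i])
      peer_hit[i] <- best_identity(ccs$sequence[i], ccs$sequence[other],
                                   ccs_kmers[other], peer_min_identity)
    }
  }
  reliable <- db_hit | peer_hit
  reason <- ifelse(db_hit & peer_hit, "both",
                   ifelse(db_hit, "db_hit",
                          ifelse(peer_hit, "peer_hit", "none")))
  out <- set_seq_annot(ccs, "reliable", ifelse(reliable, "yes", "no"))
  out <- set_seq_annot(out, "reason", reason)
  list(retained = out[reliable, , drop = FALSE],
       dropped = out[!reliable, , drop = FALSE],
       report = data.frame(id = ccs$id, well = wells, reliable = reliable,
                           reason = reason, stringsAsFactors = FALSE))
}
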