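## Short-read 16S profiling: expected-error filter, length window, k-mer
## plastid screen, exact dereplication, UPARSE-style OTU calling (size
## order, singletons excluded as seeds, chimera check on) and mapping of
## all retained reads back to per-sample counts. Filters are applied in a
## fixed order (EE -> length -> plastid) and the QC ledger is conserving:
## every input read ends in exactly one bin.

#' Expected number of errors of a read
#'
#' `EE = sum(10^(-Q/10))` over the per-base Phred scores.
#'
#' @param quality integer vector of Phred scores
#' @return numeric expected error
#' @export
expected_error <- function(quality) {
  if (is.null(quality)) stop_cbc("expected_error: missing quality scores")
  sum(10^(-quality / 10))
}

#' Maximum expected-error filter
#'
#' Retains reads with `EE <= max_ee` (inclusive; default 0.25).
#'
#' @param reads `cbc_seqs` with qualities
#' @param max_ee expected-error cap
#' @return list: `retained`, `dropped`
#' @export
ee_filter <- function(reads, max_ee = 0.25) {
  ee <- vapply(reads$quality, expected_error, numeric(1))
  keep <- ee <= max_ee
  list(retained = reads[keep, , drop = FALSE],
       dropped = reads[!keep, , drop = FALSE])
}

#' Length window filter
#'
#' Retains reads with `min <= length <= max` (both inclusive; defaults
#' 230 and 270).
#'
#' @param reads `cbc_seqs`
#' @param min,max length bounds in bases
#' @return list: `retained`, `dropped`
#' @export
length_filter <- function(reads, min = 230, max = 270) {
  len <- nchar(reads$sequence)
  keep <- len >= min & len <= max
  list(retained = reads[keep, , drop = FALSE],
       dropped = reads[!keep, , drop = FALSE])
}

#' k-mer plastid screen
#'
#' A read is flagged as plastid when the fraction of its k-mers found in
#' the plastid reference k-mer set reaches `max_shared_fraction`. Reads
#' shorter than `k` cannot be screened and pass.
#'
#' @param reads `cbc_seqs`
#' @param plastid_refs character vector of plastid reference sequences
#' @param k k-mer size (default 21)
#' @param max_shared_fraction flagging threshold (default 0.05)
#' @return list: `retained`, `flagged`
#' @export
plastid_screen <- function(reads, plastid_refs, k = 21,
                           max_shared_fraction = 0.05) {
  if (!length(plastid_refs)) stop_cbc("plastid_refs must be non-empty")
  ref_kmers <- unique(unlist(lapply(plastid_refs, kmer_vector, k = k)))
  frac <- vapply(reads$sequence, function(s) {
    km <- kmer_vector(s, k)
    if (!length(km)) return(0)
    mean(km %in% ref_kmers)
  }, numeric(1), USE.NAMES = FALSE)
  flag <- frac >= max_shared_fraction
  list(retained = reads[!flag, , drop = FALSE],
       flagged = reads[flag, , drop = FALSE])
}

#' Exact dereplication
#'
#' @param reads `cbc_seqs`
#' @return data frame `id` (of the first occurrence), `sequence`, `size`,
#'   sorted by decreasing size; sizes sum to the input read count
#' @export
dereplicate <- function(reads) {
  if (!nrow(reads))
    return(data.frame(id = character(0), sequence = character(0),
                      size = integer(0), stringsAsFactors = FALSE))
  first <- !duplicated(reads$sequence)
  size <- as.integer(table(factor(reads$sequence,
                                  levels = reads$sequence[first])))
  out <- data.frame(id = reads$id[first],
                    sequence = reads$sequence[first],
                    size = size, stringsAsFactors = FALSE)
  out[order(-out$size, out$id), , drop = FALSE]
}

#' Build an OTU profile from per-sample short reads
#'
#' Applies the QC chain per sample (EE, length, plastid), pools the
#' retained reads, dereplicates, clusters the non-singleton unique
#' sequences at `threshold` with a chimera check on new seeds, then maps
#' *all* retained reads (singletons included) back per sample.
#'
#' @param reads `cbc_seqs` with a `sample=` annotation and qualities
#' @param plastid_refs plastid reference sequences
#' @param max_ee expected-error cap (default 0.25)
#' @param length_range `c(min, max)` length window (default 230-270)
#' @param plastid_k,plastid_fraction plastid screen parameters
#' @param threshold OTU radius (default 0.97)
#' @param chimera_check run [flag_chimera()] on candidate seeds (default
#'   TRUE)
#' @param min_seed_size minimum dereplicated size to seed an OTU
#'   (default 2: singletons never seed)
#' @param scoring alignment scoring
#' @return list: `table` (samples x OTUs), `centroids` (named character),
#'   `qc` (data frame per sample: `n_input`, `n_fail_ee`,
#'   `n_fail_length`, `n_plastid`, `n_retained`), `n_unmapped`
#' @export
build_profile <- function(reads, plastid_refs, max_ee = 0.25,
                          length_range = c(230, 270), plastid_k = 21,
                          plastid_fraction = 0.05, threshold = 0.97,
                          chimera_check = TRUE, min_seed_size = 2,
                          scoring = default_scoring()) {
  samples <- seq_annot(reads, "sample", default = "sample1")
  qc <- list(); retained <- list()
  for (s in unique(samples)) {
    r0 <- reads[samples == s, , drop = FALSE]
    f1 <- ee_filter(r0, max_ee = max_ee)
    f2 <- length_filter(f1$retained, min = length_range[1],
                        max = length_range[2])
    f3 <- plastid_screen(f2$retained, plastid_refs, k = plastid_k,
                         max_shared_fraction = plastid_fraction)
    if (!nrow(f3$retained))
      warning(sprintf("sample %s: no reads retained", s), call. = FALSE)
    qc[[s]] <- data.frame(
      sample = s, n_input = nrow(r0), n_fail_ee = nrow(f1$dropped),
      n_fail_length = nrow(f2$dropped), n_plastid = nrow(f3$flagged),
      n_retained = nrow(f3$retained), stringsAsFactors = FALSE)
    retained[[s]] <- f3$retained
  }
  pooled <- do.call(rbind, retained)
  class(pooled) <- c("cbc_seqs", "data.frame")
  derep <- dereplicate(pooled)
  seeds <- derep[derep$size >= min_seed_size, , drop = FALSE]
  if (!nrow(seeds)) stop_cbc("no non-singleton sequences to seed OTUs")
  clusters <- greedy_cluster(seeds$id, seeds$sequence, sizes = seeds$size,
                             threshold = threshold, order = "size_desc",
                             scoring = scoring)
  centroids <- vapply(clusters, `[[`, character(1), "centroid_sequence")
  names(centroids) <- sprintf("OTU_%03d", seq_along(centroids))
  if (chimera_check && length(centroids) >= 3) {
    drop <- vapply(seq_along(centroids), function(i) {
      flag_chimera(centroids[[i]], centroids[-i], scoring = scoring)
    }, logical(1))
    centroids <- centroids[!drop]
  }
  mapped <- map_reads_to_otus(pooled, centroids, min_identity = threshold,
                              scoring = scoring)
  qc <- do.call(rbind, qc)
  rownames(qc) <- NULL
  list(table = mapped$table, centroids = centroids, qc = qc,
       n_unmapped = mapped$n_unmapped)
}
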