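## Greedy centroid clustering at an identity threshold, UPARSE-style.
## Used at three levels: consensus reads within a well (wOTUs), wOTU
## centroids across the collection (cOTUs), and short-read OTU calling.
## Differences from strict UCLUST first-hit behaviour are deliberate and
## documented: each sequence joins the BEST-identity qualifying centroid,
## which makes the partition robust to input order among centroids.

#' Greedy centroid clustering
#'
#' Sequences are processed in decreasing size (or length) order; each
#' either joins the existing centroid of highest identity `>= threshold`
#' (ties broken toward the earliest-created centroid) or founds a new
#' cluster. Centroids are therefore pairwise below the threshold.
#'
#' @param ids character vector of sequence ids
#' @param sequences DNA strings
#' @param sizes integer weights (e.g. dereplication sizes); default 1
#' @param threshold identity threshold in (0.5, 1], default 0.97
#' @param order processing order: `"size_desc"` (dereplicated reads,
#'   UPARSE convention) or `"length_desc"` (long consensus reads); ties
#'   broken by length descending then id
#' @param scoring alignment scoring, see [global_identity()]
#' @param k k-mer size of the candidate screen
#' @return list of clusters, each with `centroid_id`, `centroid_sequence`,
#'   `member_ids`, `member_identities`, `size`
#' @export
greedy_cluster <- function(ids, sequences, sizes = NULL, threshold = 0.97,
                           order = c("size_desc", "length_desc"),
                           scoring = default_scoring(), k = 8) {
  order <- match.arg(order)
  if (!length(ids)) return(list())
  if (threshold <= 0.5 || threshold > 1)
    stop_cbc("clustering threshold must lie in (0.5, 1]")
  if (is.null(sizes)) sizes <- rep(1L, length(ids))
  stopifnot(length(sequences) == length(ids), length(sizes) == length(ids))

  len <- nchar(sequences)
  o <- if (order == "size_desc") {
    order(-sizes, -len, ids)
  } else {
    order(-len, ids)
  }
  ids <- ids[o]; sequences <- sequences[o]; sizes <- sizes[o]

  centroids <- list()        # per-centroid state
  centroid_kmers <- list()
  for (i in seq_along(ids)) {
    seq_i <- sequences[i]
    best <- 0; best_j <- 0L
    if (length(centroids)) {
      shared <- shared_kmer_counts(seq_i, centroid_kmers, k = k)
      bound <- kmer_screen_bound(nchar(seq_i), threshold, k = k)
      # creation order so identity ties resolve toward the earliest centroid
      cand <- which(shared >= bound)
      for (j in cand) {
        res <- global_identity(seq_i, centroids[[j]]$centroid_sequence,
                               scoring = scoring)
        if (res$identity >= threshold && res$identity > best) {
          best <- res$identity; best_j <- j
        }
      }
    }
    if (best_j > 0L) {
      cl <- centroids[[best_j]]
      cl$member_ids <- c(cl$member_ids, ids[i])
      cl$member_identities <- c(cl$member_identities, best)
      cl$size <- cl$size + sizes[i]
      centroids[[best_j]] <- cl
    } else {
      centroids[[length(centroids) + 1L]] <- list(
        centroid_id = ids[i], centroid_sequence = seq_i,
        member_ids = ids[i], member_identities = 1,
        size = sizes[i])
      centroid_kmers[[length(centroids)]] <-
        unique(kmer_vector(seq_i, k))
    }
  }
  centroids
}

#' Cluster the reliable consensus reads of one well into wOTUs
#'
#' @param ccs a `cbc_seqs` record set of reliable consensus reads from a
#'   single well
#' @param threshold identity threshold (default 0.97)
#' @param scoring alignment scoring
#' @return list with `wotus` (clusters, ids prefixed by the well id),
#'   `n_wotus`, and `composition` ("single" or "multiple")
#' @export
cluster_well <- function(ccs, threshold = 0.97, scoring = default_scoring()) {
  if (!nrow(ccs)) stop_cbc("cluster_well: no reliable consensus reads")
  cl <- greedy_cluster(ccs$id, ccs$sequence, threshold = threshold,
                       order = "length_desc", scoring = scoring)
  list(wotus = cl, n_wotus = length(cl),
       composition = if (length(cl) == 1L) "single" else "multiple")
}

#' Recluster wOTU centroids into collection-level cOTUs
#'
#' @param wotu_table data frame with columns `well_id`, `wotu_id`,
#'   `centroid_sequence` and optionally `medium`
#' @param threshold identity threshold (default 0.97)
#' @param scoring alignment scoring
#' @return list with `cotus` (one element per cOTU: `cotu_id`,
#'   `centroid_sequence`, `member_wotus`, `wells`, `media`, `size`) and
#'   `mapping` (data frame `wotu_id` -> `cotu_id`)
#' @export
cluster_collection <- function(wotu_table, threshold = 0.97,
                               scoring = default_scoring()) {
  stopifnot(all(c("well_id", "wotu_id", "centroid_sequence") %in%
                  names(wotu_table)))
  cl <- greedy_cluster(wotu_table$wotu_id, wotu_table$centroid_sequence,
                       threshold = threshold, order = "length_desc",
                       scoring = scoring)
  cotus <- lapply(seq_along(cl), function(i) {
    members <- cl[[i]]$member_ids
    rows <- match(members, wotu_table$wotu_id)
    wells <- unique(wotu_table$well_id[rows])
    media <- if ("medium" %in% names(wotu_table)) {
      sort(unique(wotu_table$medium[rows]))
    } else character(0)
    list(cotu_id = sprintf("cOTU_%03d", i),
         centroid_sequence = cl[[i]]$centroid_sequence,
         member_wotus = data.frame(well_id = wotu_table$well_id[rows],
                                   wotu_id = members,
                                   stringsAsFactors = FALSE),
         wells = wells, media = media, size = length(members))
  })
  mapping <- do.call(rbind, lapply(cotus, function(co) {
    data.frame(wotu_id = co$member_wotus$wotu_id, cotu_id = co$cotu_id,
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(mapping$wotu_id))
    stop_cbc("internal error: wOTU mapped to more than one cOTU")
  list(cotus = cotus, mapping = mapping)
}

#' Map reads to OTU centroids and build a count table
#'
#' Each read is counted toward its best-identity centroid at
#' `>= min_identity`, otherwise discarded.
#'
#' @param reads `cbc_seqs` record set; the `sample` annotation names the
#'   sample of each read (single sample assumed when absent)
#' @param centroids named character vector of centroid sequences
#' @param min_identity identity threshold (default 0.97)
#' @param scoring alignment scoring
#' @param k k-mer size of the candidate screen
#' @return list with `table` (samples x OTUs integer matrix) and
#'   `n_unmapped` per sample
#' @export
map_reads_to_otus <- function(reads, centroids, min_identity = 0.97,
                              scoring = default_scoring(), k = 8) {
  if (!length(centroids)) stop_cbc("map_reads_to_otus: no centroids")
  samples <- seq_annot(reads, "sample", default = "sample1")
  otu_ids <- names(centroids)
  kmer_sets <- lapply(centroids, function(s) unique(kmer_vector(s, k)))
  n_reads <- nrow(reads)
  ## candidate centroids per read, then one vectorised alignment call
  ## per centroid over the reads that shortlisted it
  cand_by_centroid <- vector("list", length(centroids))
  for (i in seq_len(n_reads)) {
    shared <- shared_kmer_counts(reads$sequence[i], kmer_sets, k = k)
    bound <- kmer_screen_bound(nchar(reads$sequence[i]), min_identity,
                               k = k)
    for (j in which(shared >= bound))
      cand_by_centroid[[j]] <- c(cand_by_centroid[[j]], i)
  }
  best <- numeric(n_reads); best_j <- integer(n_reads)
  for (j in seq_along(centroids)) {
    idx <- cand_by_centroid[[j]]
    if (!length(idx)) next
    res <- align_set(reads$sequence[idx], centroids[[j]],
                     type = "global", scoring = scoring)
    ident <- vapply(res, `[[`, numeric(1), "identity")
    better <- ident >= min_identity & ident > best[idx]
    best[idx[better]] <- ident[better]
    best_j[idx[better]] <- j
  }
  assign_id <- ifelse(best_j > 0L, otu_ids[pmax(best_j, 1L)],
                      NA_character_)
  sample_levels <- unique(samples)
  tab <- matrix(0L, nrow = length(sample_levels), ncol = length(otu_ids),
                dimnames = list(sample_levels, otu_ids))
  keep <- !is.na(assign_id)
  if (any(keep)) {
    counts <- table(factor(samples[keep], levels = sample_levels),
                    factor(assign_id[keep], levels = otu_ids))
    tab[] <- as.integer(counts)
  }
  unmapped <- tapply(!keep, factor(samples, levels = sample_levels), sum)
  list(table = tab, n_unmapped = as.integer(unmapped))
}

#' Flag a candidate sequence as a two-parent chimera
#'
#' A candidate is chimeric when some single crossover between two parents
#' explains it markedly better than any single parent: both segments align
#' at `>= min_segment_identity` while the best whole-sequence identity to
#' any one parent is at least `min_improvement` below the crossover model's
#' identity.
#'
#' @param candidate DNA string
#' @param parents character vector of candidate parent sequences (>= 2)
#' @param min_segment_identity per-segment identity floor (default 0.97)
#' @param min_improvement required identity gain of the crossover model
#'   over the best single parent (default 0.02)
#' @param n_breakpoints number of evenly spaced crossover points tried
#' @param scoring alignment scoring
#' @return logical
#' @export
flag_chimera <- function(candidate, parents, min_segment_identity = 0.97,
                         min_improvement = 0.02, n_breakpoints = 7,
                         scoring = default_scoring()) {
  if (length(parents) < 2) stop_cbc("flag_chimera needs >= 2 parents")
  L <- nchar(candidate)
  single <- vapply(parents, function(p) {
    global_identity(candidate, p, scoring = scoring)$identity
  }, numeric(1))
  best_single <- max(single)
  if (best_single >= 1) return(FALSE)
  cuts <- round(seq_len(n_breakpoints) * L / (n_breakpoints + 1))
  cuts <- unique(cuts[cuts >= 20 & cuts <= L - 20])
  top2 <- order(-single)[1:2]
  for (cut in cuts) {
    left <- substr(candidate, 1, cut)
    right <- substr(candidate, cut + 1, L)
    for (a in top2) for (b in top2) {
      if (a == b) next
      ia <- semiglobal_identity(left, parents[a], scoring = scoring)
      ib <- semiglobal_identity(right, parents[b], scoring = scoring)
      if (ia$identity >= min_segment_identity &&
          ib$identity >= min_segment_identity) {
        cross <- (ia$identity * cut + ib$identity * (L - cut)) / L
        if (best_single <= cross - min_improvement) return(TRUE)
      }
    }
  }
  FALSE
}
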