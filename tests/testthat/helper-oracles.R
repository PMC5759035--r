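# Independent oracles and fixture builders shared across the test files.

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Substitution-mutate `n_sub` distinct positions of a sequence.
mutate_subs <- function(seq, n_sub) {
  bases <- strsplit(seq, "")[[1]]
  pos <- sample(length(bases), n_sub)
  for (p in pos) bases[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                            bases[p]), 1)
  paste(bases, collapse = "")
}

# Brute-force affine-gap global alignment score by explicit enumeration of
# every alignment (gap of length L costs open + L * ext). Exponential:
# keep sequences short.
brute_force_score <- function(a, b, match = 1, mismatch = -2,
                              open = 10, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- -Inf
  score_cols <- function(cols) {
    s <- 0; i <- 0; j <- 0; run <- ""
    for (c in cols) {
      if (c == "M") {
        i <- i + 1; j <- j + 1
        s <- s + if (av[i] == bv[j]) match else mismatch
        run <- ""
      } else {
        i <- i + (c == "X"); j <- j + (c == "Y")
        s <- s - ext - if (run == c) 0 else open
        run <- c
      }
    }
    s
  }
  rec <- function(i, j, cols) {
    if (i == length(av) && j == length(bv)) {
      best <<- max(best, score_cols(cols)); return(invisible())
    }
    if (i < length(av) && j < length(bv)) rec(i + 1, j + 1, c(cols, "M"))
    if (i < length(av)) rec(i + 1, j, c(cols, "X"))
    if (j < length(bv)) rec(i, j + 1, c(cols, "Y"))
  }
  rec(0, 0, character(0))
  best
}

# Exhaustive same-order greedy clustering oracle: no k-mer screening or
# shortcuts, every input aligned against every existing centroid.
oracle_greedy_cluster <- function(ids, sequences, sizes = NULL,
                                  threshold = 0.97,
                                  order = "length_desc") {
  if (is.null(sizes)) sizes <- rep(1L, length(ids))
  len <- nchar(sequences)
  o <- if (order == "size_desc") order(-sizes, -len, ids) else
    order(-len, ids)
  ids <- ids[o]; sequences <- sequences[o]
  assignment <- integer(length(ids))
  centroid_seqs <- character(0)
  for (i in seq_along(ids)) {
    best <- 0; best_j <- 0L
    for (j in seq_along(centroid_seqs)) {
      idy <- global_identity(sequences[i], centroid_seqs[j])$identity
      if (idy >= threshold && idy > best) { best <- idy; best_j <- j }
    }
    if (best_j == 0L) {
      centroid_seqs <- c(centroid_seqs, sequences[i])
      best_j <- length(centroid_seqs)
    }
    assignment[i] <- best_j
  }
  split(ids, assignment)
}

# Partition of a greedy_cluster() result as a canonical sorted list.
cluster_partition <- function(clusters) {
  parts <- lapply(clusters, function(cl) sort(cl$member_ids))
  parts[order(vapply(parts, `[`, character(1), 1))]
}

# Small labelled reference set with two clades sharing a phylum but
# differing at genus; used by taxonomy tests.
toy_reference <- function(len = 400, seed = 11) {
  set.seed(seed)
  root <- random_seq(len)
  g1 <- mutate_subs(root, round(0.15 * len))
  g2 <- mutate_subs(root, round(0.15 * len))
  data.frame(
    taxon_id = c("refA", "refB"),
    sequence = c(g1, g2),
    phylum = "Phylum_1", class = "Class_1", order = "Order_1",
    family = c("Family_1", "Family_2"),
    genus = c("Genus_1", "Genus_2"),
    stringsAsFactors = FALSE)
}

mutate_sequence_for_test <- function(seq, rate) {
  cbcsyncom:::mutate_sequence(seq, rate)
}

# Reads with constant quality for filter tests.
reads_with_quality <- function(seqs, q) {
  seq_records(sprintf("r%03d", seq_along(seqs)), seqs,
              quality = lapply(nchar(seqs), function(n) rep(q, n)))
}
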