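test_that("greedy clustering handles duplicates, separated pairs and order", {
  cl <- greedy_cluster(c("a", "b"), c("ACGTACGTAC", "ACGTACGTAC"))
  expect_length(cl, 1)
  expect_equal(sort(cl[[1]]$member_ids), c("a", "b"))
  expect_equal(cl[[1]]$size, 2)

  set.seed(81)
  s1 <- random_seq(200); s2 <- mutate_subs(s1, 100)  # ~50% identity
  cl2 <- greedy_cluster(c("x", "y"), c(s1, s2), threshold = 0.97)
  expect_length(cl2, 2)
  expect_length(greedy_cluster(character(0), character(0)), 0)
  expect_error(greedy_cluster("a", "ACGT", threshold = 0.3), "threshold")
})

test_that("greedy clustering equals the exhaustive oracle on random instances", {
  set.seed(83)
  for (rep in 1:30) {
    n_seeds <- sample(2:4, 1)
    seeds <- vapply(seq_len(n_seeds), function(i) random_seq(120), "")
    n <- sample(6:12, 1)
    seqs <- vapply(seq_len(n), function(i) {
      mutate_subs(seeds[sample(n_seeds, 1)], sample(0:8, 1))
    }, "")
    ids <- sprintf("s%02d", seq_len(n))
    thr <- sample(c(0.90, 0.95, 0.97), 1)
    mine <- cluster_partition(greedy_cluster(ids, seqs, threshold = thr,
                                             order = "length_desc"))
    oracle <- oracle_greedy_cluster(ids, seqs, threshold = thr)
    oracle <- lapply(oracle, sort)
    oracle <- oracle[order(vapply(oracle, `[`, "", 1))]
    expect_equal(mine, unname(oracle), info = paste("instance", rep))
  }
})

test_that("clustering output is a partition with separated centroids", {
  set.seed(85)
  seeds <- vapply(1:3, function(i) random_seq(150), "")
  seqs <- unlist(lapply(seeds, function(s)
    vapply(1:5, function(i) mutate_subs(s, sample(0:2, 1)), "")))
  ids <- sprintf("q%02d", seq_along(seqs))
  cl <- greedy_cluster(ids, seqs, threshold = 0.95)
  members <- unlist(lapply(cl, `[[`, "member_ids"))
  expect_setequal(members, ids)
  expect_equal(anyDuplicated(members), 0L)
  cents <- vapply(cl, `[[`, "", "centroid_sequence")
  if (length(cents) > 1) {
    for (i in 1:(length(cents) - 1)) for (j in (i + 1):length(cents))
      expect_lt(global_identity(cents[i], cents[j])$identity, 0.95)
  }
  # determinism
  expect_identical(cl, greedy_cluster(ids, seqs, threshold = 0.95))
})

test_that("well clustering counts members and collection clustering maps all wOTUs", {
  taxa <- generate_reference_taxa(6, seq_length = 400, n_clades = 6,
                                  seed = 87)
  # two-member well with ~25%-divergent taxa -> 2 wOTUs
  reads <- seq_records(
    sprintf("r%d", 1:6),
    c(replicate(3, mutate_sequence_for_test(taxa$sequence[1], 0.005)),
      replicate(3, mutate_sequence_for_test(taxa$sequence[2], 0.005))))
  wc <- cluster_well(reads)
  expect_equal(wc$n_wotus, 2)
  expect_equal(wc$composition, "multiple")
  single <- cluster_well(reads[1:3, , drop = FALSE])
  expect_equal(single$composition, "single")
  expect_error(cluster_well(reads[0, , drop = FALSE]), "no reliable")

  wotu_table <- data.frame(
    well_id = c("P01-A01", "P01-A01", "P01-A02", "P01-A03"),
    wotu_id = c("w1", "w2", "w3", "w4"),
    centroid_sequence = c(taxa$sequence[1], taxa$sequence[2],
                          taxa$sequence[1], taxa$sequence[2]),
    medium = c("LB8", "LB8", "YPD", "LB35"), stringsAsFactors = FALSE)
  coll <- cluster_collection(wotu_table)
  expect_length(coll$cotus, 2)
  expect_setequal(coll$mapping$wotu_id, wotu_table$wotu_id)
  expect_equal(anyDuplicated(coll$mapping$wotu_id), 0L)
  by_id <- coll$cotus[[which(vapply(coll$cotus, function(co)
    "w1" %in% co$member_wotus$wotu_id, TRUE))]]
  expect_setequal(by_id$wells, c("P01-A01", "P01-A02"))
  expect_setequal(by_id$media, c("LB8", "YPD"))
})

test_that("read mapping counts reads at the identity floor and discards the rest", {
  set.seed(91)
  c1 <- random_seq(250); c2 <- mutate_subs(c1, 60)
  centroids <- c(OTU_1 = c1, OTU_2 = c2)
  reads <- seq_records(
    c("m1", "m2", "m3"),
    c(c1, mutate_subs(c2, 2), mutate_subs(c1, 30)),  # exact, 99%, 88%
    annotations = list(c(sample = "s1"), c(sample = "s1"),
                       c(sample = "s2")))
  m <- map_reads_to_otus(reads, centroids, min_identity = 0.97)
  expect_equal(m$table["s1", "OTU_1"], 1L)
  expect_equal(m$table["s1", "OTU_2"], 1L)
  expect_equal(sum(m$table["s2", ]), 0L)
  expect_equal(m$n_unmapped, c(0L, 1L))
})

test_that("chimera flagging detects crossovers but spares parents and noise", {
  set.seed(93)
  p1 <- random_seq(300); p2 <- mutate_subs(p1, 90)  # ~30% divergent
  chimera <- paste0(substr(p1, 1, 150), substr(p2, 151, 300))
  expect_true(flag_chimera(chimera, c(p1, p2)))
  expect_false(flag_chimera(p1, c(p1, p2)))
  expect_false(flag_chimera(random_seq(300), c(p1, p2)))
})
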