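test_that("expected error follows the Phred definition", {
  expect_equal(expected_error(20L), 0.01)
  expect_equal(expected_error(rep(30L, 250)), 0.25)
  expect_error(expected_error(NULL), "missing quality")

  reads <- rbind(reads_with_quality(list(random_seq(250))[[1]], 30),
                 reads_with_quality(random_seq(250), 20))
  reads$id <- c("q30", "q20")
  class(reads) <- c("cbc_seqs", "data.frame")
  f <- ee_filter(reads, max_ee = 0.25)
  expect_equal(f$retained$id, "q30")  # EE 0.25 kept (inclusive)
  expect_equal(f$dropped$id, "q20")   # EE 2.5 dropped
})

test_that("length filter bounds are inclusive at 230 and 270", {
  reads <- seq_records(c("a", "b", "c", "d"),
                       vapply(c(229, 230, 270, 271), random_seq, ""))
  f <- length_filter(reads)
  expect_equal(f$retained$id, c("b", "c"))
  expect_equal(f$dropped$id, c("a", "d"))
})

test_that("plastid screen flags plastid copies and spares 16S-like reads", {
  set.seed(131)
  plastids <- vapply(1:2, function(i) random_seq(300), "")
  copy <- substr(plastids[1], 26, 275)
  foreign <- mutate_subs(random_seq(250), 0)
  reads <- seq_records(c("copy", "foreign"), c(copy, foreign))
  s <- plastid_screen(reads, plastids)
  expect_equal(s$flagged$id, "copy")
  expect_equal(s$retained$id, "foreign")
  short <- seq_records("tiny", "ACGTACGT")
  expect_equal(nrow(plastid_screen(short, plastids)$retained), 1)

  # reads 20% divergent from the plastid set are almost always retained
  div <- seq_records(sprintf("d%02d", 1:30), vapply(1:30, function(i)
    mutate_subs(substr(plastids[1], 26, 275), 50), ""))
  sd_ <- plastid_screen(div, plastids)
  expect_gte(nrow(sd_$retained) / 30, 0.9)
})

test_that("flagged plastid fraction tracks the generator setting", {
  taxa <- generate_reference_taxa(5, seq_length = 400, n_clades = 5,
                                  seed = 133)
  prof <- generate_habitat_profiles(taxa$taxon_id, "h", seed = 133)
  sv <- simulate_survey(taxa, prof, region = c(51, 300),
                        n_reads_per_habitat = 2000, per_base_error = 0.01,
                        plastid_fraction = 0.1, seed = 134)
  s <- plastid_screen(sv$reads, sv$plastid_refs)
  frac <- nrow(s$flagged) / nrow(sv$reads)
  expect_lt(abs(frac - 0.1), 0.02)
  # and the screen recovers the generator's origin annotation
  expect_true(all(seq_annot(s$flagged, "origin") == "plastid"))
})

test_that("dereplication conserves sizes and sorts by abundance", {
  reads <- seq_records(sprintf("r%d", 1:5),
                       c("ACGTACGT", "ACGTACGT", "ACGTACGT",
                         "TTTTCCCC", "GGGGAAAA"))
  d <- dereplicate(reads)
  expect_equal(d$size, c(3L, 1L, 1L))
  expect_equal(d$sequence[1], "ACGTACGT")
  expect_equal(sum(d$size), 5)
  set.seed(135)
  many <- seq_records(sprintf("m%03d", 1:60),
                      sample(vapply(1:10, function(i) random_seq(40), ""),
                             60, replace = TRUE))
  expect_equal(sum(dereplicate(many)$size), 60)
})

test_that("profiles from clean reads recover single taxa and keep the QC ledger", {
  taxa <- generate_reference_taxa(4, seq_length = 400, n_clades = 4,
                                  seed = 137)
  prof <- generate_habitat_profiles(taxa$taxon_id,
                                    c("s1", "s2"), lognormal_sigma = 1,
                                    seed = 138)
  sv <- simulate_survey(taxa, prof, region = c(76, 325),
                        n_reads_per_habitat = 400, per_base_error = 0.01,
                        plastid_fraction = 0.05, seed = 139)
  bp <- build_profile(sv$reads, sv$plastid_refs)
  # ledger conservation per sample
  expect_equal(bp$qc$n_input,
               bp$qc$n_fail_ee + bp$qc$n_fail_length + bp$qc$n_plastid +
                 bp$qc$n_retained)
  expect_equal(sum(bp$qc$n_input), nrow(sv$reads))
  # mapped counts never exceed retained reads
  expect_true(all(rowSums(bp$table) + bp$n_unmapped ==
                    bp$qc$n_retained[match(rownames(bp$table),
                                           bp$qc$sample)]))
  # abundances correlate with the truth
  rel <- bp$table / rowSums(bp$table)
  truth_rel <- sv$counts / rowSums(sv$counts)
  r <- vapply(rownames(rel), function(s) {
    est <- vapply(seq_len(nrow(taxa)), function(i) {
      hits <- vapply(names(bp$centroids), function(cid)
        global_identity(bp$centroids[[cid]],
                        substr(taxa$sequence[i], 76, 325))$identity >= 0.97,
        logical(1))
      sum(rel[s, hits])
    }, numeric(1))
    stats::cor(est, as.numeric(truth_rel[s, ]))
  }, numeric(1))
  expect_true(all(r >= 0.95))

  # a single-taxon error-free sample collapses to one OTU
  one <- simulate_survey(taxa[1, ], prof[, 1, drop = FALSE] * 0 + 1,
                         region = c(76, 325), n_reads_per_habitat = 50,
                         per_base_error = 0, plastid_fraction = 0,
                         seed = 140)
  bp1 <- build_profile(one$reads, sv$plastid_refs, chimera_check = FALSE)
  expect_equal(ncol(bp1$table), 1)
  expect_equal(sum(bp1$n_unmapped), 0L)
  expect_equal(sum(bp1$table), sum(bp1$qc$n_retained))
})
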