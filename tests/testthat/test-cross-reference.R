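test_that("mOTU database screen keeps hits and discards noise, boundary inclusive", {
  set.seed(101)
  db_seq <- random_seq(600)
  db <- seq_records("db1", db_seq)
  motus <- data.frame(
    motu_id = c("m1", "m2"),
    sequence = c(substr(db_seq, 101, 350), random_seq(250)),
    stringsAsFactors = FALSE)
  f <- filter_motus(motus, db, min_identity = 0.75)
  expect_equal(f$retained$motu_id, "m1")
  expect_equal(f$discarded, "m2")

  # random non-biological 250-mers essentially never reach the 0.75 floor
  junk <- data.frame(motu_id = sprintf("j%02d", 1:50),
                     sequence = vapply(1:50, function(i) random_seq(250), ""),
                     stringsAsFactors = FALSE)
  fj <- filter_motus(junk, db)
  expect_lte(nrow(fj$retained), 1)

  # a sequence at exactly the threshold is retained (inclusive >=)
  exact <- substr(db_seq, 1, 100)
  exact <- mutate_subs(exact, 25)  # 75/100 matching columns
  idy <- semiglobal_identity(exact, db_seq)$identity
  if (idy == 0.75) {
    fe <- filter_motus(data.frame(motu_id = "e", sequence = exact), db)
    expect_equal(fe$retained$motu_id, "e")
  }
})

test_that("mOTU-consensus matching finds cultured taxa and skips uncultured", {
  set.seed(103)
  taxa <- generate_reference_taxa(6, seq_length = 500, n_clades = 6,
                                  seed = 104)
  ccs <- seq_records(sprintf("ccs_%d", 1:4),
                     vapply(1:4, function(i)
                       mutate_sequence_for_test(taxa$sequence[i], 0.005), ""))
  motus <- data.frame(motu_id = sprintf("m%d", 1:6),
                      sequence = substr(taxa$sequence, 101, 350),
                      stringsAsFactors = FALSE)
  pairs <- match_motus(motus, ccs, min_identity = 0.97,
                       min_query_coverage = 0.9)
  matched <- sort(unique(pairs$motu_id))
  expect_setequal(matched, c("m1", "m2", "m3", "m4"))  # m5/m6 uncultured
  expect_true(all(pairs$identity >= 0.97))

  # verbatim cut matches at identity 1
  cut <- data.frame(motu_id = "cut", sequence = substr(ccs$sequence[1],
                                                       51, 300))
  pc <- match_motus(cut, ccs)
  expect_true(any(pc$identity == 1 & pc$ccs_id == "ccs_1"))
})

test_that("links aggregate supports and preserve many-to-many structure", {
  pairs <- data.frame(
    motu_id = c("m1", "m1", "m2", "m2", "gone"),
    ccs_id = c("c1", "c2", "c1", "c3", "c9"),
    identity = c(1, 0.99, 0.98, 0.985, 1), stringsAsFactors = FALSE)
  mapping <- c(c1 = "cotu1", c2 = "cotu1", c3 = "cotu2")
  expect_warning(links <- link_to_cotus(pairs, mapping), "dropped")
  expect_equal(nrow(links), 3)
  l11 <- links[links$motu_id == "m1" & links$cotu_id == "cotu1", ]
  expect_equal(l11$n_supporting_ccs, 2L)
  expect_equal(l11$best_identity, 1)
  # one mOTU linked to two cOTUs stays two links
  expect_equal(sum(links$motu_id == "m2"), 2)
})

test_that("core flags take the minimal prefix reaching the cutoff", {
  ab <- c(m1 = 0.5, m2 = 0.3, m3 = 0.15, m4 = 0.05)
  core <- define_core(ab, cumulative_cutoff = 0.9)
  expect_equal(unname(core), c(TRUE, TRUE, TRUE, FALSE))
  expect_true(define_core(c(only = 1))[["only"]])
  expect_equal(sum(define_core(ab, cumulative_cutoff = 1)), 4)
  # ties at the boundary are all included
  tied <- c(a = 0.4, b = 0.3, c = 0.3)
  expect_equal(sum(define_core(tied, 0.7)), 3)
})

test_that("recovery is the linked share of core abundance", {
  ab <- c(m1 = 0.5, m2 = 0.3, m3 = 0.2)
  links <- data.frame(motu_id = c("m1", "m3"), cotu_id = c("c1", "c2"),
                      stringsAsFactors = FALSE)
  rec <- recovery_estimate(links, ab, core = c(m1 = TRUE, m2 = TRUE,
                                               m3 = TRUE))
  expect_equal(rec$recovered_core_abundance, 70)
  expect_equal(rec$n_matched_motus, 2)
  expect_equal(rec$n_matched_cotus, 2)

  all_linked <- data.frame(motu_id = names(ab), cotu_id = "c1")
  expect_equal(recovery_estimate(all_linked, ab)$recovered_core_abundance,
               100)
  none <- links[0, ]
  expect_equal(recovery_estimate(none, ab)$recovered_core_abundance, 0)
  expect_error(recovery_estimate(links, c(m1 = 0), core = c(m1 = FALSE)),
               "zero core")
})

test_that("adding a link never decreases recovery", {
  set.seed(107)
  ab <- stats::setNames(as.numeric(rmultinom(1, 1000, rep(1, 12)) / 1000),
                        sprintf("m%02d", 1:12))
  core <- define_core(ab)
  ids <- names(ab)
  links <- data.frame(motu_id = character(0), cotu_id = character(0))
  last <- 0
  for (i in seq_along(ids)) {
    links <- rbind(links, data.frame(motu_id = ids[i],
                                     cotu_id = sprintf("c%d", i)))
    now <- recovery_estimate(links, ab, core = core)$recovered_core_abundance
    expect_gte(now, last)
    last <- now
  }
  expect_equal(last, 100)
})
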