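test_that("reference taxa have clade structure and are deterministic", {
  t1 <- generate_reference_taxa(20, seq_length = 300, n_clades = 4,
                                within_clade_divergence = 0.01,
                                between_clade_divergence = 0.20, seed = 5)
  t2 <- generate_reference_taxa(20, seq_length = 300, n_clades = 4,
                                within_clade_divergence = 0.01,
                                between_clade_divergence = 0.20, seed = 5)
  expect_identical(t1, t2)
  expect_error(generate_reference_taxa(3, n_clades = 5), "exceed")

  # single taxon equals its clade ancestor (no within mutation applied)
  single <- generate_reference_taxa(1, seq_length = 200, n_clades = 1,
                                    seed = 2)
  expect_equal(nchar(single$sequence), 200)

  # mean within-clade identity exceeds mean between-clade identity
  pairs_id <- function(rows) {
    mean(apply(rows, 1, function(p)
      global_identity(t1$sequence[p[1]], t1$sequence[p[2]])$identity))
  }
  same <- which(outer(t1$clade, t1$clade, "==") & upper.tri(diag(20)),
                arr.ind = TRUE)
  diff <- which(outer(t1$clade, t1$clade, "!=") & upper.tri(diag(20)),
                arr.ind = TRUE)
  set.seed(1)
  diff <- diff[sample(nrow(diff), 30), ]
  expect_gt(pairs_id(same), pairs_id(diff))
})

test_that("habitat profiles are normalised and skewed like a core microbiome", {
  p <- generate_habitat_profiles(sprintf("t%03d", 1:100),
                                 c("rhizosphere", "endophytic_root"),
                                 seed = 3)
  expect_equal(unname(rowSums(p)), c(1, 1))
  # sigma = 0 -> uniform
  u <- generate_habitat_profiles(c("a", "b", "c"), "h",
                                 lognormal_sigma = 0, seed = 1)
  expect_equal(unname(u[1, ]), rep(1 / 3, 3))
  expect_equal(unname(generate_habitat_profiles("a", "h", seed = 1)[1, 1]),
               1)
  # at the default sigma the top 20% of taxa hold >= 80% of abundance
  # in >= 95% of draws
  hits <- vapply(1:200, function(i) {
    x <- generate_habitat_profiles(sprintf("t%03d", 1:100), "h",
                                   seed = 1000 + i)
    sum(sort(x[1, ], decreasing = TRUE)[1:20]) >= 0.80
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("collection wells follow the multi-member mixing probability", {
  taxa <- generate_reference_taxa(12, seq_length = 300, n_clades = 12,
                                  seed = 8)
  prof <- generate_habitat_profiles(
    taxa$taxon_id, c("rhizosphere", "endophytic_root", "endophytic_stalk"),
    lognormal_sigma = 1, seed = 8)

  # multi_member_prob = 0, error = 0: every read equals a reference taxon
  coll0 <- simulate_collection(taxa, prof, n_wells = 30,
                               multi_member_prob = 0, per_base_error = 0,
                               barcode_length = 10, seed = 9)
  expect_true(all(vapply(coll0$well_truth, nrow, 1L) == 1))
  bl <- 10
  amplicons <- substring(coll0$reads$sequence, bl + 1)
  expect_true(all(amplicons %in% taxa$sequence))

  # multi_member_prob = 1: every well is multi-member
  coll1 <- simulate_collection(taxa, prof, n_wells = 30,
                               multi_member_prob = 1, members_max = 2,
                               medium_growth_prob = 1, seed = 10)
  expect_true(all(vapply(coll1$well_truth, nrow, 1L) == 2))

  # near-even split at p = 0.5 over many wells
  coll <- simulate_collection(taxa, prof, n_wells = 500,
                              multi_member_prob = 0.5, seed = 11)
  frac_multi <- mean(vapply(coll$well_truth, nrow, 1L) > 1)
  expect_lt(abs(frac_multi - 0.5), 0.05)

  # determinism
  collb <- simulate_collection(taxa, prof, n_wells = 500,
                               multi_member_prob = 0.5, seed = 11)
  expect_identical(coll$reads, collb$reads)

  # read headers carry the well / passes / medium annotations
  expect_false(anyNA(seq_annot(coll$reads, "well")))
  expect_false(anyNA(seq_annot(coll$reads, "passes")))
  expect_true(all(seq_annot(coll$reads, "medium") %in%
                    c("LB8", "LB35", "YPD")))
})

test_that("survey reads follow habitat abundances and the quality model", {
  taxa <- generate_reference_taxa(5, seq_length = 500, n_clades = 5,
                                  seed = 21)
  prof <- generate_habitat_profiles(taxa$taxon_id, "rhizosphere",
                                    lognormal_sigma = 0, seed = 1)
  prof[1, ] <- c(0.30, 0.30, 0.20, 0.10, 0.10)
  sv <- simulate_survey(taxa, prof, region = c(101, 350),
                        n_reads_per_habitat = 10000, per_base_error = 0,
                        plastid_fraction = 0, seed = 22)
  share <- mean(seq_annot(sv$reads, "origin") == taxa$taxon_id[1])
  expect_lt(abs(share - 0.30), 0.02)
  expect_equal(nchar(sv$motus$sequence[1]), 250)
  expect_error(simulate_survey(taxa, prof, region = c(400, 600)),
               "region")

  # constant Q40 passes the default expected-error cap at any length here
  svq <- simulate_survey(taxa, prof, region = c(101, 350),
                         n_reads_per_habitat = 50, quality_range = c(40, 40),
                         seed = 23)
  ee <- vapply(svq$reads$quality, expected_error, numeric(1))
  expect_true(all(ee <= 0.25))
})

test_that("inoculation tables separate groups only when enriched", {
  prof <- generate_habitat_profiles(sprintf("t%02d", 1:10),
                                    c("exophytic_root", "endophytic_root"),
                                    lognormal_sigma = 1, seed = 31)
  members <- c("t01", "t02")
  inoc <- simulate_inoculation(prof, members, enrichment = 50,
                               n_replicates = 5, depth = 50000, seed = 32)
  expect_equal(nrow(inoc$table), 20)  # 2 habitats x 2 groups x 5
  rel <- inoc$table / rowSums(inoc$table)
  sums <- rowSums(rel[, members])
  trt <- inoc$metadata$treatment
  for (h in c("exophytic_root", "endophytic_root")) {
    hsel <- startsWith(rownames(inoc$table), h)
    expect_true(min(sums[hsel & trt == "inoculated"]) >
                  max(sums[hsel & trt == "uninoculated"]))
  }
  expect_error(simulate_inoculation(prof, "nope", seed = 1), "absent")
  degen <- suppressWarnings(
    simulate_inoculation(prof, members, depth = 0, seed = 1))
  expect_true(all(degen$table == 0))
  expect_true(isTRUE(attr(degen, "degenerate")))
})

test_that("the assembled world validates and is reproducible", {
  cfg <- cbc_config(generator = list(n_taxa = 8, n_clades = 8, n_wells = 20,
                                     survey_reads_per_habitat = 100))
  w1 <- simulate_cbc_world(cfg, seed = 41)
  w2 <- simulate_cbc_world(cfg, seed = 41)
  expect_identical(w1$collection$reads, w2$collection$reads)
  expect_identical(w1$survey$reads, w2$survey$reads)
  expect_silent(validate_truth(w1))
  bad <- w1
  bad$habitat_profiles[1, ] <- bad$habitat_profiles[1, ] * 2
  expect_error(validate_truth(bad), "sum to 1")
})
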