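test_that("relative abundance normalises rows and rejects empty samples", {
  tab <- matrix(c(2, 2, 0, 5), nrow = 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("o1", "o2")))
  rel <- relative_abundance(tab)
  expect_equal(unname(rel["s1", ]), c(0.5, 0.5))
  expect_equal(unname(rel["s2", ]), c(0, 1))
  tab[1, ] <- 0
  expect_error(relative_abundance(tab), "s1")
})

test_that("Bray-Curtis matches the hand formula and its axioms", {
  x <- c(2, 1, 0) / 3; y <- c(1, 1, 1) / 3
  d <- bray_curtis(rbind(a = x, b = y))
  expect_equal(d["a", "b"], 1 / 3)
  # identical samples -> 0; disjoint supports -> 1
  d2 <- bray_curtis(rbind(p = c(0.5, 0.5, 0), q = c(0.5, 0.5, 0),
                          r = c(0, 0, 1)))
  expect_equal(d2["p", "q"], 0)
  expect_equal(d2["p", "r"], 1)
  set.seed(141)
  m <- matrix(runif(60), nrow = 6)
  m <- m / rowSums(m)
  dm <- bray_curtis(m)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  expect_true(all(dm >= 0 & dm <= 1))
})

test_that("PCoA reconstructs planted Euclidean configurations exactly", {
  set.seed(143)
  pts <- cbind(runif(8, -2, 2), runif(8, -2, 2))
  d <- as.matrix(dist(pts))
  ord <- pcoa_ordination(d)
  rec <- as.matrix(dist(ord$coordinates[, 1:2]))
  expect_lt(max(abs(rec - d)), 1e-8)
  expect_equal(sum(ord$proportion_explained), 1)
  expect_error(pcoa_ordination(d[1:2, 1:2]), "at least 3")
})

test_that("ANOSIM is maximal for perfectly separated toy groups", {
  rel <- rbind(a1 = c(1, 0, 0, 0), a2 = c(0.9, 0.1, 0, 0),
               a3 = c(0.95, 0.05, 0, 0), a4 = c(0.85, 0.15, 0, 0),
               b1 = c(0, 0, 1, 0), b2 = c(0, 0, 0.9, 0.1),
               b3 = c(0, 0, 0.85, 0.15), b4 = c(0, 0, 0.8, 0.2))
  d <- bray_curtis(rel)
  res <- anosim_test(d, rep(c("A", "B"), each = 4), n_perm = 199, seed = 3)
  expect_equal(res$statistic, 1)
  expect_lte(res$p_value, 0.1)
  expect_gte(res$p_value, 1 / 200)
  expect_error(anosim_test(d, c("A", rep("B", 7))), "ANOSIM needs")
  # determinism under seed
  res2 <- anosim_test(d, rep(c("A", "B"), each = 4), n_perm = 199, seed = 3)
  expect_identical(res$p_value, res2$p_value)
})

test_that("Kruskal-Wallis reproduces the hand-ranked example", {
  res <- kruskal_wallis(c(1, 2, 3, 4), c("g1", "g1", "g2", "g2"))
  expect_equal(res$statistic, 2.4)
  expect_equal(res$df, 1)
  same <- kruskal_wallis(rep(2, 6), rep(c("a", "b"), 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("per-OTU screens call significance at unadjusted p < alpha", {
  set.seed(145)
  tab <- matrix(runif(80), nrow = 8)
  colnames(tab) <- sprintf("o%02d", 1:10)
  rownames(tab) <- sprintf("s%d", 1:8)
  tab[1:4, 1] <- tab[1:4, 1] + 5  # strong group effect in o01
  rel <- tab / rowSums(tab)
  kw <- per_otu_kw(rel, rep(c("in", "un"), each = 4))
  expect_true("o01" %in% kw$significant)
  expect_equal(kw$results$significant, kw$results$p_value < 0.05)
  kw_adj <- per_otu_kw(rel, rep(c("in", "un"), each = 4), adjust = TRUE)
  expect_lte(length(kw_adj$significant), length(kw$significant))
})

test_that("displacement sums syncom abundance per habitat and group", {
  rel <- rbind(
    r_in_1 = c(0.6, 0.3, 0.1), r_in_2 = c(0.7, 0.2, 0.1),
    r_un_1 = c(0.05, 0.15, 0.8), r_un_2 = c(0.1, 0.1, 0.8))
  colnames(rel) <- c("o1", "o2", "o3")
  groups <- c("inoculated", "inoculated", "uninoculated", "uninoculated")
  habitats <- rep("root", 4)
  disp <- displacement_summary(rel, c("o1", "o2"), groups, habitats)
  s <- disp$summary
  expect_equal(s$syncom_abundance_pct[s$group == "inoculated"], 90)
  expect_equal(s$syncom_abundance_pct[s$group == "uninoculated"], 20)
  expect_true(all(disp$per_sample <= 1))
  expect_lte(length(disp$colonizers), 2)
  expect_warning(
    displacement_summary(rel, "absent", groups, habitats), "no synthetic")
})

test_that("growth response reports the fold change of the group means", {
  w <- data.frame(
    treatment = rep(c("inoculated", "uninoculated"), each = 5),
    weight = c(7.82 + c(-0.2, -0.1, 0, 0.1, 0.2),
               2.31 + c(-0.1, -0.05, 0, 0.05, 0.1)))
  g <- growth_response(w)
  expect_equal(g$mean_inoculated, 7.82)
  expect_equal(g$mean_uninoculated, 2.31)
  expect_equal(g$fold_change, 3.4)
  expect_lt(g$p_value, 0.001)
  dry <- data.frame(
    treatment = rep(c("inoculated", "uninoculated"), each = 3),
    weight = c(0.7, 0.7, 0.7, 0.23, 0.23, 0.23))
  expect_equal(growth_response(dry)$fold_change, 3.0)
  eq <- data.frame(treatment = rep(c("inoculated", "uninoculated"), 3),
                   weight = rep(1, 6))
  expect_equal(growth_response(eq)$fold_change, 1.0)
})
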