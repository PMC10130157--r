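test_that("design df reconstruction matches the factorial layouts", {
  meta <- make_design(3, 7, c(6, 24), 2)
  cult <- meta[meta$role == "culture", ]
  df <- design_df(cult, c("donor", "medium", "time_h", "replicate"))
  expect_identical(df, c(donor = 2L, medium = 6L, time_h = 1L,
                         replicate = 1L, Residuals = 73L, Total = 83L))

  meta2 <- make_design(10, 3, 24, 1)
  cult2 <- meta2[meta2$role == "culture", ]
  df2 <- design_df(cult2, c("donor", "medium"))
  expect_identical(df2, c(donor = 9L, medium = 2L, Residuals = 18L,
                          Total = 29L))

  meta3 <- meta_for_groups(c("a", "a", "b", "b"))
  expect_identical(design_df(meta3, "donor"),
                   c(donor = 1L, Residuals = 2L, Total = 3L))
  expect_error(design_df(meta3, "nope"), "not in metadata")
})

test_that("a perfectly separating factor explains all the variance", {
  d <- block_distance(c("a", "a", "b", "b"))
  meta <- meta_for_groups(c("a", "a", "b", "b"))
  pm <- suppressMessages(permanova(d, meta, "donor", n_perm = 999, seed = 1))
  expect_equal(pm["donor", "R2"], 1.0)
  expect_equal(pm["Residuals", "SumsOfSqs"], 0, tolerance = 1e-12)
  # 4 samples: permutations enumerated exhaustively; 8 of 24 orderings
  # preserve the two-block partition
  expect_equal(pm["donor", "Pr(>F)"], 1 / 3)
})

test_that("anova accounting enforces SS additivity and R2 normalisation", {
  tab <- permanova_accounting(c(f1 = 3, f2 = 1), c(2L, 1L), 4, 10L)
  expect_equal(tab["Total", "SumsOfSqs"], 8)
  expect_equal(sum(tab[c("f1", "f2", "Residuals"), "R2"]), 1)
  expect_equal(tab["f1", "MeanSqs"], 1.5)
  expect_equal(tab["f1", "F.Models"], 1.5 / 0.4)
})

test_that("sequential SS agree with vegan::adonis2 (by = 'terms')", {
  skip_if_not_installed("vegan")
  sim <- simulate_experiment(community_sim_spec(
    n_donors = 3, n_media = 3, time_points_h = c(6, 24), n_replicates = 2,
    n_taxa = 40, seed = 11))
  meta <- sim$metadata
  cult <- meta$sample_id[meta$role == "culture"]
  rel <- to_relative(unclass(sim$table)[cult, ])
  d <- distance_matrix(rel, "braycurtis")
  pm <- permanova(d, meta, c("donor", "medium", "time_h"), n_perm = 0)
  md <- as.data.frame(meta[match(cult, meta$sample_id), ])
  md$time_h <- factor(md$time_h)
  av <- vegan::adonis2(stats::as.dist(d) ~ donor + medium + time_h,
                       data = md, permutations = 2, by = "terms")
  expect_equal(pm[c("donor", "medium", "time_h"), "SumsOfSqs"],
               av$SumOfSqs[1:3], tolerance = 1e-10)
  expect_equal(pm[c("donor", "medium", "time_h"), "R2"],
               av$R2[1:3], tolerance = 1e-10)
  expect_equal(pm[c("donor", "medium", "time_h"), "F.Models"],
               av$F[1:3], tolerance = 1e-10)
  expect_equal(pm["Residuals", "SumsOfSqs"], av$SumOfSqs[4], tolerance = 1e-10)
})

test_that("single-factor sequential SS equal the classical one-way decomposition", {
  set.seed(12)
  groups <- rep(c("a", "b", "c"), times = c(3, 2, 3))
  profiles <- t(replicate(8, random_profile(12)))
  rownames(profiles) <- sprintf("S%d", 1:8)
  d <- distance_matrix(profiles, "braycurtis")
  meta <- meta_for_groups(groups)
  pm <- permanova(d, meta, "donor", n_perm = 0)
  oracle <- oneway_ss_oracle(d, groups)
  expect_equal(pm["donor", "SumsOfSqs"], oracle$factor, tolerance = 1e-10)
  expect_equal(pm["Residuals", "SumsOfSqs"], oracle$residual, tolerance = 1e-10)
  expect_equal(pm["Total", "SumsOfSqs"], oracle$total, tolerance = 1e-10)
})

test_that("permutation p matches the exhaustive oracle on small designs", {
  d <- block_distance(c("a", "a", "b", "b"))
  meta <- meta_for_groups(c("a", "a", "b", "b"))
  expect_equal(exhaustive_permutation_p(d, meta, "donor"), 1 / 3)

  # noisy 6-sample design: permanova enumerates all 720 row permutations,
  # the oracle the 20 distinct labelings; tail probabilities must agree
  set.seed(13)
  profiles <- t(replicate(6, random_profile(10)))
  rownames(profiles) <- sprintf("S%d", 1:6)
  d2 <- distance_matrix(profiles, "braycurtis")
  meta2 <- meta_for_groups(rep(c("a", "b"), each = 3))
  pm <- suppressMessages(permanova(d2, meta2, "donor", n_perm = 999, seed = 1))
  expect_equal(pm["donor", "Pr(>F)"],
               exhaustive_permutation_p(d2, meta2, "donor"))

  # constant distances: nothing to test, p = 1
  dc <- block_distance(rep("x", 4)); dc[] <- 0
  expect_equal(exhaustive_permutation_p(dc, meta, "donor"), 1)
  pmc <- permanova(dc, meta, "donor", n_perm = 99, seed = 1)
  expect_equal(pmc["donor", "Pr(>F)"], 1)
})

test_that("aliased designs and missing factor levels are rejected", {
  d <- block_distance(c("a", "a", "b", "b"))
  meta <- meta_for_groups(c("a", "a", "b", "b"))
  meta$copy <- meta$donor
  expect_error(permanova(d, meta, c("donor", "copy"), n_perm = 0),
               "aliased")
  meta2 <- meta_for_groups(c("a", "a", "b", "b"))
  meta2$donor[2] <- NA
  expect_error(permanova(d, meta2, "donor", n_perm = 0), "missing levels")
})

test_that("permutation p-values are reproducible given a seed", {
  set.seed(14)
  profiles <- t(replicate(12, random_profile(15)))
  rownames(profiles) <- sprintf("S%d", 1:12)
  d <- distance_matrix(profiles, "braycurtis")
  meta <- meta_for_groups(rep(c("a", "b", "c"), each = 4))
  p1 <- permanova(d, meta, "donor", n_perm = 199, seed = 42)
  p2 <- permanova(d, meta, "donor", n_perm = 199, seed = 42)
  expect_identical(p1["donor", "Pr(>F)"], p2["donor", "Pr(>F)"])
})

test_that("donor R2 grows with donor effect size on synthetic data", {
  r2_at <- function(sd, seed) {
    sim <- simulate_experiment(community_sim_spec(
      n_donors = 3, n_media = 3, time_points_h = 6, n_replicates = 2,
      n_taxa = 40, donor_effect_sd = sd, medium_effect_sd = 0.5,
      time_effect_sd = 0, depth = 5000, seed = seed))
    meta <- sim$metadata
    cult <- meta$sample_id[meta$role == "culture"]
    rel <- to_relative(unclass(sim$table)[cult, ])
    d <- distance_matrix(rel, "braycurtis")
    permanova(d, meta, c("donor", "medium"), n_perm = 0)["donor", "R2"]
  }
  seeds <- 1:5
  low <- vapply(seeds, function(s) r2_at(0.2, s), numeric(1))
  high <- vapply(seeds, function(s) r2_at(2.0, s), numeric(1))
  expect_gt(mean(high), mean(low))
})
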