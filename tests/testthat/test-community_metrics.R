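test_that("to_relative normalises rows and rejects empty samples", {
  tab <- make_table(rbind(c(5, 5, 10), c(7, 0, 0)))
  rel <- to_relative(tab)
  expect_equal(rel["S1", ], c(ASV1 = 0.25, ASV2 = 0.25, ASV3 = 0.5))
  expect_equal(unname(rowSums(rel)), c(1, 1))
  expect_equal(unname(to_relative(make_table(matrix(7, 1, 1)))[1, ]), 1)
  m <- rbind(c(1, 1), c(0, 0))
  rownames(m) <- c("ok", "empty"); colnames(m) <- c("a", "b")
  expect_error(to_relative(m), "empty")
})

test_that("aggregation conserves totals, buckets unassigned taxa, is idempotent", {
  tab <- make_table(rbind(c(3, 4, 2), c(1, 0, 5)), taxa = c("a", "b", "c"))
  tx <- taxonomy(data.frame(taxon_id = c("a", "b", "c"),
                            family = c("F", "F", NA)))
  fam <- aggregate_taxa(tab, tx, "family")
  expect_equal(fam[, "F"], c(S1 = 7, S2 = 1))
  expect_equal(fam[, "unclassified_family"], c(S1 = 2, S2 = 5))
  expect_identical(rowSums(fam), rowSums(unclass(tab)))   # exact conservation

  tx2 <- taxonomy(data.frame(taxon_id = colnames(fam),
                             family = colnames(fam)))
  expect_equal(unclass(aggregate_taxa(fam, tx2, "family")), unclass(fam))
  expect_error(aggregate_taxa(tab, tx, "species"), "unsupported rank")
})

test_that("Shannon index matches base-2 closed forms", {
  expect_equal(shannon(c(0.5, 0.5)), 1.0)
  expect_equal(shannon(1.0), 0.0)
  expect_equal(shannon(rep(1 / 8, 8)), 3.0)
  for (n in c(2, 5, 16)) expect_equal(shannon(rep(1 / n, n)), log2(n))
  expect_equal(shannon(rep(1 / 8, 8), base = exp(1)), log(8))
  # uniform maximises H: any perturbation decreases it
  set.seed(1)
  for (i in 1:20) {
    p <- random_profile(6)
    expect_lte(shannon(p), log2(6) + 1e-12)
  }
})

test_that("Gini-Simpson index matches closed forms and ignores taxon order", {
  expect_equal(simpson(1.0), 0.0)
  expect_equal(simpson(c(0.5, 0.5)), 0.5)
  for (n in c(2, 7, 30)) expect_equal(simpson(rep(1 / n, n)), 1 - 1 / n)
  set.seed(2)
  p <- random_profile(10)
  expect_equal(simpson(p), simpson(sample(p)))
})

test_that("Jensen-Shannon divergence is symmetric, bounded, zero iff equal", {
  expect_equal(jsd(c(0.3, 0.7), c(0.3, 0.7)), 0.0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1.0)
  # frozen oracle: direct evaluation of the two KL sums in base 2
  expect_equal(jsd(c(0.5, 0.5), c(1, 0)), 0.311278, tolerance = 1e-6)
  set.seed(3)
  for (i in 1:25) {
    p <- random_profile(8); q <- random_profile(8)
    v <- jsd(p, q)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, jsd(q, p))
    if (v < 1e-12) expect_equal(p, q)
  }
})

test_that("Euclidean distance on proportions satisfies the triangle inequality", {
  expect_equal(euclidean(c(0.2, 0.8), c(0.2, 0.8)), 0.0)
  expect_equal(euclidean(c(1, 0), c(0, 1)), sqrt(2))
  set.seed(4)
  for (i in 1:25) {
    p <- random_profile(6); q <- random_profile(6); r <- random_profile(6)
    expect_lte(euclidean(p, r), euclidean(p, q) + euclidean(q, r) + 1e-12)
  }
})

test_that("Bray-Curtis is bounded in [0, 1] with the expected extremes", {
  expect_equal(braycurtis(c(0.4, 0.6), c(0.4, 0.6)), 0.0)
  expect_equal(braycurtis(c(1, 0), c(0, 1)), 1.0)
  set.seed(5)
  for (i in 1:25) {
    v <- braycurtis(random_profile(7), random_profile(7))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("distance_matrix agrees with the pairwise functions", {
  set.seed(6)
  profiles <- t(replicate(4, random_profile(5)))
  rownames(profiles) <- paste0("S", 1:4)
  for (metric in c("jsd", "euclidean", "braycurtis")) {
    d <- distance_matrix(profiles, metric)
    f <- get(metric)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 4))
    for (i in 1:3) for (j in (i + 1):4)
      expect_equal(d[i, j], f(profiles[i, ], profiles[j, ]))
  }
})

test_that("divergence_from_source scores cultures against the matched feces", {
  set.seed(7)
  source <- random_profile(10)
  cultures <- rbind(identical_culture = source,
                    near = 0.9 * source + 0.1 * rep(0.1, 10),
                    far = rev(source))
  out_jsd <- divergence_from_source(cultures, source, "jsd")
  out_euc <- divergence_from_source(cultures, source, "euclidean")
  expect_equal(unname(out_jsd["identical_culture"]), 0)
  expect_equal(unname(out_euc["identical_culture"]), 0)
  expect_lt(out_jsd["near"], out_jsd["far"])
  expect_lt(out_euc["near"], out_euc["far"])

  # 15 cultures (5 media x 3 times) -> 15 values ready for ranking
  many <- t(replicate(15, random_profile(10)))
  rownames(many) <- sprintf("M%d_T%d", rep(1:5, each = 3), rep(c(6, 12, 24), 5))
  vals <- divergence_from_source(many, source, "jsd")
  expect_length(vals, 15)
  expect_true(all(vals >= 0 & vals <= 1))

  expect_error(divergence_from_source(cultures, source, "jsd",
                                      culture_donor = rep("D1", 3),
                                      source_donor = "D2"),
               "donor mismatch")
})
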