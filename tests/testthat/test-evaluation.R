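ranked <- score_table(stats::setNames(10:1, sprintf("P%02d", 1:10)), "toy")
ess_front <- sprintf("P%02d", 1:3)

test_that("top_k counts essentials among the k highest-ranked proteins", {
  res <- top_k(ranked, ess_front, 3)
  expect_equal(res$true_positive_count, 3L)
  expect_equal(res$precision, 1)
  res2 <- top_k(ranked, c("NOT", "HERE"), 5)
  expect_equal(res2$true_positive_count, 0L)
  res3 <- top_k(ranked, ess_front, 10)
  expect_equal(res3$precision, 0.3)
  expect_error(top_k(ranked, ess_front, 0), "out of range")
  expect_error(top_k(ranked, ess_front, 11), "out of range")
})

test_that("jackknife cumulative counts and trapezoidal AUC match hand results", {
  tab <- score_table(c(E1 = 4, N1 = 3, E2 = 2, N2 = 1), "x")
  jk <- jackknife(tab, c("E1", "E2"), 4)
  expect_equal(jk$cumulative, c(1, 1, 2, 2))
  expect_equal(jk$auc, 4.5)
  # all essentials first
  jk2 <- jackknife(ranked, ess_front, 3)
  expect_equal(jk2$cumulative, 1:3)
  # none found in prefix -> zero area
  jk3 <- jackknife(ranked, "P10", 5)
  expect_equal(jk3$auc, 0)
})

test_that("jackknife at depth k agrees with top_k and increments are 0/1", {
  set.seed(2)
  vals <- stats::setNames(stats::rnorm(50), sprintf("G%02d", 1:50))
  tab <- score_table(vals, "rnd")
  ess <- sample(names(vals), 17)
  jk <- jackknife(tab, ess, 50)
  expect_equal(jk$cumulative[50], top_k(tab, ess, 50)$true_positive_count)
  expect_true(all(diff(jk$cumulative) %in% c(0L, 1L)))
  expect_true(all(diff(jk$cumulative) >= 0))
})

test_that("promoting an essential protein never decreases the AUC", {
  ids <- sprintf("P%02d", 1:12)
  ess <- c("P09", "P11")
  base <- score_table(stats::setNames(12:1, ids), "a")
  for (boost in c(11.5, 12.5)) {
    vals <- stats::setNames(12:1, ids)
    vals["P11"] <- boost   # move an essential protein up the ranking
    up <- score_table(vals, "b")
    expect_gte(jackknife(up, ess, 12)$auc, jackknife(base, ess, 12)$auc)
  }
})

test_that("random baselines are seeded, reproducible and correctly sized", {
  ids <- sprintf("P%02d", 1:30)
  a <- random_baseline(ids, ids[1:10], max_rank = 20, n_shuffles = 10, seed = 4)
  b <- random_baseline(ids, ids[1:10], max_rank = 20, n_shuffles = 10, seed = 4)
  expect_length(a, 10)
  expect_identical(lapply(a, `[[`, "cumulative"), lapply(b, `[[`, "cumulative"))
  c2 <- random_baseline(ids, ids[1:10], max_rank = 20, n_shuffles = 3, seed = 5)
  expect_false(identical(a[[1]]$cumulative, c2[[1]]$cumulative))
})

test_that("overlap analysis does set algebra and essential fractions", {
  a <- score_table(c(p1 = 3, p2 = 2, p3 = 1, p4 = 0), "A")
  b <- score_table(c(p2 = 3, p3 = 2, p4 = 1, p1 = 0), "B")
  ov <- overlap_analysis(a, b, essential = "p1", k = 3)
  expect_equal(ov$common_count, 2L)
  expect_identical(ov$only_a, "p1")
  expect_identical(ov$only_b, "p4")
  expect_equal(ov$essential_fraction_only_a, 1)
  expect_equal(ov$essential_fraction_only_b, 0)
  expect_equal(ov$common_count + length(ov$only_a), 3L)
  # identical rankings: full overlap, empty differences
  ov2 <- overlap_analysis(a, a, "p1", 3)
  expect_equal(ov2$common_count, 3L)
  expect_length(ov2$only_a, 0)
  expect_true(is.nan(ov2$essential_fraction_only_a))
  # symmetry under swapping the tables
  ov3 <- overlap_analysis(b, a, "p1", 3)
  expect_identical(ov3$only_a, ov$only_b)
  expect_identical(ov3$only_b, ov$only_a)
  expect_equal(ov3$common_count, ov$common_count)
})

test_that("reference_value returns the score at a rank, ties passed through", {
  tab <- score_table(c(a = 5, b = 4, c = 4, d = 1), "x")
  expect_equal(reference_value(tab, 1), 5)
  expect_equal(reference_value(tab, 3), 4)
  expect_equal(reference_value(tab, 4), 1)
  expect_error(reference_value(tab, 5), "out of range")
})
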