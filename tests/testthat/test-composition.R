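test_that("per-position counting is correct, order-invariant and grouped", {
  rec <- make_records(c(paste0("AC", strrep("G", 18)),
                        paste0("AC", strrep("T", 18)),
                        paste0("TT", strrep("G", 18))),
                      outcome = c("positive", "positive", "negative"))
  tab <- count_nucleotides(rec, "positive")
  expect_equal(tab$group_size, 2L)
  expect_equal(tab$counts[1, "A"], 2L)
  expect_equal(tab$counts[2, "C"], 2L)
  expect_equal(unname(rowSums(tab$counts)), rep(2L, 21))
  shuffled <- count_nucleotides(rec[c(3, 1, 2), ], "positive")
  expect_equal(shuffled, tab)
  expect_error(count_nucleotides(rec, "unknown"), "empty group")
})

test_that("the packaged occurrence fixture matches the published counts", {
  fx <- load_table1_fixture()
  expect_equal(fx$positive$group_size, 129L)
  expect_equal(fx$negative$group_size, 89L)
  expect_equal(unname(rowSums(fx$positive$counts)), rep(129L, 21))
  expect_equal(unname(rowSums(fx$negative$counts)), rep(89L, 21))
  expect_equal(unname(fx$positive$counts[20, "C"]), 63L)
  expect_equal(unname(fx$positive$counts[3, "T"]), 51L)
  expect_equal(unname(fx$negative$counts[21, "C"]), 4L)
})

test_that("frequency deltas are group proportion differences summing to 0", {
  fx <- load_table1_fixture()
  d <- frequency_delta(fx$positive, fx$negative)
  expect_equal(unname(d[20, "C"]), 63 / 129 - 29 / 89, tolerance = 1e-12)
  expect_equal(unname(rowSums(d)), rep(0, 21), tolerance = 1e-12)
  expect_true(all(d >= -1 & d <= 1))
  same <- frequency_delta(fx$positive, fx$positive)
  expect_equal(unname(same), matrix(0, 21, 4))
})

test_that("position chi-square is Pearson without continuity correction", {
  r3 <- chisq_position(c(33, 21, 24, 51), c(22, 20, 27, 20))
  expect_equal(r3$df, 3L)
  expect_equal(r3$p, 0.0307, tolerance = 2e-3)
  r20 <- chisq_position(c(13, 63, 26, 27), c(21, 29, 20, 19))
  expect_equal(r20$p, 0.0222, tolerance = 2e-3)
  # cross-check the statistic against the hand formula on one table
  tab <- rbind(c(33, 21, 24, 51), c(22, 20, 27, 20))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(r3$chi2, sum((tab - e)^2 / e), tolerance = 1e-12)
})

test_that("homogeneous tables give chi2 = 0 and absent bases reduce df", {
  h <- chisq_position(c(10, 10, 10, 10), c(7, 7, 7, 7))
  expect_equal(h$chi2, 0)
  expect_equal(h$p, 1)
  dropped <- chisq_position(c(10, 0, 5, 5), c(7, 0, 9, 2))
  expect_equal(dropped$df, 2L)
  expect_equal(dropped$dropped, "C")
})

test_that("minP Monte Carlo matches exhaustive label enumeration on a toy", {
  m <- matrix(c("A", "A", "A", "C", "C", "G",
                "T", "G", "T", "G", "T", "T"), ncol = 2)
  labels <- c(1, 1, 1, 0, 0, 0)
  ex <- minp_exhaustive(m, 3)
  mc <- minp_permutation(m, labels, n_perm = 10000, seed = 5,
                         add_one = FALSE)
  expect_equal(mc$p_raw, ex$p_raw, tolerance = 1e-10)
  se <- sqrt(ex$p_exact * (1 - ex$p_exact) / 10000)
  expect_true(all(abs(mc$p_perm - ex$p_exact) <= 3 * se + 1e-12))
})

test_that("minP adjustment is conservative and deterministic under a seed", {
  set.seed(21)
  rec <- make_records(random_guides(40),
                      outcome = rep(c("positive", "negative"), each = 20))
  a <- minp_permutation(rec, n_perm = 400, seed = 99)
  b <- minp_permutation(rec, n_perm = 400, seed = 99)
  expect_identical(a, b)
  expect_true(all(a$p_perm >= a$p_raw - 3 * sqrt(0.25 / 400)))
  expect_true(all(a$p_perm > 0 & a$p_perm <= 1))
  expect_error(minp_permutation(rec, n_perm = 0, seed = 1), "n_perm")
})

test_that("raw p-values agree between the test table and permutation paths", {
  set.seed(31)
  rec <- make_records(random_guides(30),
                      outcome = rep(c("positive", "negative"), c(18, 12)))
  tests <- composition_tests(count_nucleotides(rec, "positive"),
                             count_nucleotides(rec, "negative"))
  perm <- minp_permutation(rec, n_perm = 1, seed = 1)
  expect_equal(perm$p_raw, tests$p_raw, tolerance = 1e-10)
})

test_that("composition summary reports counts, percentages and p-values", {
  set.seed(41)
  rec <- make_records(random_guides(30),
                      outcome = rep(c("positive", "negative"), c(16, 14)))
  s <- composition_summary(rec, n_perm = 50, seed = 3)
  expect_equal(nrow(s), 21)
  expect_equal(s$pos_A + s$pos_C + s$pos_G + s$pos_T, rep(16, 21))
  expect_equal(s$pos_A_pct, round(100 * s$pos_A / 16, 1))
  expect_true(all(c("p_raw", "p_perm") %in% names(s)))
})
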