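test_that("false-match probability agrees with exhaustive enumeration", {
  cases <- expand.grid(n = c(6L, 9L, 12L), a = c(2L, 4L),
                       s = c(3L, 5L), theta = c(1L, 2L, 3L))
  cases <- cases[cases$s <= cases$n & cases$a <= cases$n &
                   cases$theta <= cases$s, ]
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], expect_equal(
      false_match_probability(n, a, s, theta),
      oracle_false_match(n, a, s, theta),
      tolerance = 1e-12,
      label = sprintf("n=%d a=%d s=%d theta=%d", n, a, s, theta)))
  }
})

test_that("false-match probability matches the hypergeometric tail route", {
  # independent cross-check: P(X >= theta), X ~ Hyper(s special of n, a drawn)
  cases <- list(c(200000, 2000, 10, 10), c(200000, 2000, 20, 10),
                c(1024, 20, 15, 8), c(5000, 100, 30, 12))
  for (cs in cases) {
    ref <- stats::phyper(cs[4] - 1, cs[3], cs[1] - cs[3], cs[2],
                         lower.tail = FALSE)
    expect_equal(false_match_probability(cs[1], cs[2], cs[3], cs[4]) / ref,
                 1, tolerance = 1e-9)
  }
})

test_that("false-match probability handles degenerate regimes", {
  expect_identical(false_match_probability(100, 5, 20, 6), 0)  # theta > a
  expect_identical(false_match_probability(50, 10, 50, 8), 1)  # s = n
  expect_identical(false_match_probability(100, 0, 10, 1), 0)  # nothing active
  expect_error(false_match_probability(10, 20, 5, 2), "`a`")
  expect_error(false_match_probability(10, 5, 20, 2), "`s`")
  expect_error(false_match_probability(10, 5, 5, 0), "theta")
})

test_that("false-match probability is monotone in theta, s, and a", {
  n <- 10000; a <- 300
  p_theta <- vapply(4:12, function(th)
    false_match_probability(n, a, 12, th), numeric(1))
  expect_true(all(diff(p_theta) <= 0))
  p_s <- vapply(8:20, function(s)
    false_match_probability(n, a, s, 8), numeric(1))
  expect_true(all(diff(p_s) >= 0))
  p_a <- vapply(seq(100, 1000, by = 100), function(aa)
    false_match_probability(n, aa, 12, 8), numeric(1))
  expect_true(all(diff(p_a) >= 0))
  expect_true(all(c(p_theta, p_s, p_a) >= 0 & c(p_theta, p_s, p_a) <= 1))
})

test_that("noise tolerance is the oversampling slack fraction", {
  expect_equal(noise_tolerance(20, 10), 0.5)
  expect_equal(noise_tolerance(16, 8), 0.5)
  expect_equal(noise_tolerance(7, 7), 0)
  expect_error(noise_tolerance(5, 9), "theta")
})

test_that("pattern and capacity counts follow the budget arithmetic", {
  expect_identical(patterns_per_neuron(6000, 20), 300)
  expect_identical(patterns_per_neuron(20, 20), 1)
  expect_identical(patterns_per_neuron(6000, 40), 150)
  expect_error(patterns_per_neuron(6000, 0), "synapses_per_pattern")

  expect_equal(transition_capacity(32, 0.02, 200), 320000)
  expect_equal(transition_capacity(1, 1.0, 1), 1)
  # linear in patterns_per_cell
  expect_equal(transition_capacity(32, 0.02, 400),
               2 * transition_capacity(32, 0.02, 200))
  expect_error(transition_capacity(32, 0, 200), "column_sparsity")
  expect_error(transition_capacity(32, 1.5, 200), "column_sparsity")
})

test_that("representation counts are exact big integers", {
  expect_identical(representation_count(2, 3), "9")
  expect_identical(representation_count(7, 1), "1")
  expect_identical(representation_count(10, 2), "1024")
  # value frozen from an independent big-integer computation of 32^40
  expect_identical(
    representation_count(40, 32),
    "1606938044258990275541962092341162602522202993782792835301376")
  # agrees with double arithmetic where doubles are exact
  expect_identical(representation_count(5, 13),
                   format(13^5, scientific = FALSE))
})

test_that("shared-segment Monte Carlo is consistent and degenerates to Eq. 1", {
  # parameters chosen so the single-set probability is measurable
  r1 <- shared_segment_false_match(1000, 100, 20, 4, stored_sets = 1L,
                                   trials = 40000L, seed = 11L)
  p1 <- false_match_probability(1000, 100, 20, 4)
  expect_lt(abs(r1$estimate - p1), 3 * max(r1$stderr, 1e-4))
  # for a single stored set the conditional probability is the same for
  # every draw (symmetry), so independent seeds must agree within joint
  # Monte-Carlo error
  r2 <- shared_segment_false_match(1000, 100, 20, 4, stored_sets = 1L,
                                   trials = 40000L, seed = 21L)
  expect_lt(abs(r1$estimate - r2$estimate),
            3 * sqrt(r1$stderr^2 + r2$stderr^2) + 1e-4)
  # mixing several sets on one segment can only add error
  r3 <- shared_segment_false_match(1000, 100, 20, 4, stored_sets = 3L,
                                   trials = 40000L, seed = 31L)
  expect_gte(r3$estimate + 3 * r3$stderr, p1)
  expect_identical(
    shared_segment_false_match(1000, 3, 20, 5, trials = 10L)$estimate, 0)
  expect_error(shared_segment_false_match(1000, 100, 20, 4, trials = 0))
})

test_that("error tables cover the grid and serialize to CSV", {
  tab <- error_table(n = c(200000, 10000), a = c(2000, 200),
                     s = c(10, 20), theta = c(10, 10))
  expect_equal(nrow(tab), 4L)
  expect_named(tab, c("n", "a", "s", "theta", "p_false"))
  hit <- tab[tab$n == 200000 & tab$s == 10, "p_false"]
  expect_equal(hit / 9.8e-21, 1, tolerance = 0.01)
  path <- withr::local_tempfile(fileext = ".csv")
  write_error_table(tab, path)
  back <- utils::read.csv(path)
  expect_equal(back$p_false, tab$p_false, tolerance = 1e-12)
  expect_error(error_table(numeric(0), numeric(0), 1, 1), "non-empty")
})

test_that("error tables are monotone along the theta axis", {
  tab <- error_table(n = 2048, a = 40, s = rep(20L, 10), theta = 3:12)
  tab <- tab[order(tab$theta), ]
  expect_true(all(diff(tab$p_false) <= 0))
})
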