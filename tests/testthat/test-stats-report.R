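make_forces <- function(...) {
  groups <- list(...)
  do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    data.frame(case_id = g$case %||% "1", pattern_id = g$pattern,
               level = "T5", side = "left", diameter = 5,
               fx = g$mags, fy = 0, fz = 0, magnitude = g$mags)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pattern comparisons behave on degenerate and shifted samples", {
  # identical samples: zero statistic, p = 1
  f <- make_forces(list(pattern = 1, mags = c(30, 40, 50)),
                   list(pattern = 2, mags = c(30, 40, 50)))
  cmp <- compare_patterns(f)
  expect_equal(cmp$diff_means, 0)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_welch, 1)

  # clearly shifted distributions: tiny p
  set.seed(8)
  a <- rnorm(50, 100, 5); b <- rnorm(50, 120, 5)
  f2 <- make_forces(list(pattern = 1, mags = a), list(pattern = 2, mags = b))
  cmp2 <- compare_patterns(f2)
  expect_lt(cmp2$p_welch, 0.001)
  expect_equal(cmp2$diff_means, mean(a) - mean(b), tolerance = 1e-12)

  # p-values invariant under sample order permutation
  f3 <- make_forces(list(pattern = 1, mags = sample(a)),
                    list(pattern = 2, mags = sample(b)))
  expect_equal(compare_patterns(f3)$p_welch, cmp2$p_welch, tolerance = 1e-12)
})

test_that("grouped alternate-vs-periapical comparison is included", {
  set.seed(9)
  f <- make_forces(list(pattern = 1, mags = rnorm(20, 80, 10)),
                   list(pattern = 2, mags = rnorm(20, 95, 10)),
                   list(pattern = 3, mags = rnorm(20, 92, 10)),
                   list(pattern = 4, mags = rnorm(20, 85, 10)),
                   list(pattern = 5, mags = rnorm(20, 82, 10)))
  cmp <- compare_patterns(f)
  expect_true("alternate_vs_periapical" %in% cmp$comparison)
  expect_equal(nrow(cmp), choose(5, 2) + 1)
  expect_true(all(cmp$p_welch >= 0 & cmp$p_welch <= 1))
  expect_true(all(cmp$p_holm >= cmp$p_welch - 1e-12))
})

test_that("cohort summary statistics agree with a brute-force pass", {
  sm <- cohort_run()
  forces <- sm$forces
  for (k in unique(forces$pattern_id)) {
    mags <- forces$magnitude[forces$pattern_id == k]
    row <- sm$pooled_forces[sm$pooled_forces$pattern_id == k, ]
    expect_equal(row$mean, sum(mags) / length(mags), tolerance = 1e-12)
    expect_equal(row$min, min(mags), tolerance = 1e-12)
    expect_equal(row$max, max(mags), tolerance = 1e-12)
    expect_equal(row$n_screws, length(mags))
    expect_true(row$min <= row$mean && row$mean <= row$max)
    expect_gte(row$sd, 0)
  }
  # complete grid: every case has an entry for every pattern
  counts <- table(sm$indices$case_id[sm$indices$pattern_id > 0])
  expect_true(all(counts == 5))
})
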