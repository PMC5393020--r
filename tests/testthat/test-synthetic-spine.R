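test_that("vertebral dimensions scale anatomically and with stature", {
  lv <- vertebral_levels()
  for (field in c("width", "depth", "height")) {
    vals <- vapply(lv, function(l) vertebral_dimensions(l, 170)[[field]],
                   numeric(1))
    expect_true(all(diff(vals) >= 0))
  }
  d_t6_small <- vertebral_dimensions("T6", 153)
  d_t6_tall <- vertebral_dimensions("T6", 170)
  expect_equal(unname(d_t6_tall / d_t6_small), rep(170 / 153, 4),
               tolerance = 1e-12)
  # within 20% of the shipped reference table at near-reference stature
  tab <- vertebral_dimension_table()
  ref <- unlist(tab[tab$level == "T6", c("width", "depth", "height")])
  got <- vertebral_dimensions("T6", 165)[c("width", "depth", "height")]
  expect_true(all(abs(got - ref) / ref < 0.2))
  expect_error(vertebral_dimensions("C3", 170), "unknown vertebral level")
  expect_error(vertebral_dimensions("T6", 100), "height")
})

test_that("generated geometry reproduces the requested clinical indices", {
  cases <- bundled_cases()
  for (i in c(1, 4)) {
    ci <- cases[[i]]
    g <- generate_spine(ci, seed = 7)
    r <- index_report(g, ci)
    expect_lt(abs(r$mt_cobb - ci$mt_cobb), 1)
    expect_lt(abs(r$pt_cobb - ci$pt_cobb), 1)
    expect_lt(abs(r$tll_cobb - ci$tll_cobb), 1)
    expect_lt(abs(r$kyphosis - ci$kyphosis), 1)
    expect_lt(abs(r$lordosis - ci$lordosis), 1)
    expect_lt(abs(r$mt_avr - ci$mt_avr), 2)
    expect_lt(abs(r$tll_avr - ci$tll_avr), 2)
    validate_spine_geometry(g)
  }
})

test_that("round-trip holds over randomized valid indices", {
  set.seed(11)
  base <- straight_indices()
  for (rep in 1:5) {
    ci <- base
    ci$pt_cobb <- runif(1, 5, 45)
    ci$mt_cobb <- runif(1, 30, 70)
    ci$tll_cobb <- runif(1, 10, 45)
    ci$kyphosis <- runif(1, 5, 40)
    ci$lordosis <- runif(1, 15, 50)
    ci$mt_avr <- runif(1, 5, 22)
    ci$tll_avr <- runif(1, 0, 12)
    g <- generate_spine(ci, seed = 100 + rep)
    r <- index_report(g, ci)
    expect_lt(abs(r$mt_cobb - ci$mt_cobb), 1)
    expect_lt(abs(r$kyphosis - ci$kyphosis), 1)
    expect_lt(abs(r$mt_avr - ci$mt_avr), 2)
  }
})

test_that("all angles zero produces a straight spine", {
  g <- generate_spine(straight_indices(), seed = 3, jitter_sd = 0)
  r <- index_report(g, straight_indices())
  expect_lt(r$mt_cobb, 0.5)
  expect_lt(abs(r$kyphosis), 0.5)
  expect_lt(r$mt_avr, 1)
})

test_that("generation is deterministic and mirror-equivariant", {
  ci <- bundled_cases()[[2]]
  g1 <- generate_spine(ci, seed = 5)
  g2 <- generate_spine(ci, seed = 5)
  expect_identical(g1$vertebrae, g2$vertebrae)
  g3 <- generate_spine(ci, seed = 6)
  expect_false(identical(g1$vertebrae[["T8"]]$landmarks,
                         g3$vertebrae[["T8"]]$landmarks))

  # negating all coronal convexities mirrors the geometry across the
  # sagittal plane
  gm <- generate_spine(ci, seed = 5, convexity = c(pt = -1, mt = 1, tll = -1))
  Mir <- diag(c(1, -1, 1))
  for (lv in names(g1$vertebrae)) {
    expect_lt(max(abs(as.numeric(Mir %*% g1$vertebrae[[lv]]$center) -
                        gm$vertebrae[[lv]]$center)), 1e-9)
    p1 <- as.numeric(g1$vertebrae[[lv]]$center +
                       g1$vertebrae[[lv]]$R %*%
                       g1$vertebrae[[lv]]$landmarks$pedicle_left)
    p2 <- as.numeric(gm$vertebrae[[lv]]$center +
                       gm$vertebrae[[lv]]$R %*%
                       gm$vertebrae[[lv]]$landmarks$pedicle_right)
    expect_lt(max(abs(as.numeric(Mir %*% p1) - p2)), 1e-9)
  }
})

test_that("infeasible index combinations are rejected with the constraint named", {
  ci <- straight_indices()
  ci$mt_apex <- "T5"            # apex cephalad of the superior end vertebra
  expect_error(validate_clinical_indices(ci), "apex")
  ci2 <- straight_indices()
  ci2$uiv <- "L3"; ci2$liv <- "T10"
  expect_error(validate_clinical_indices(ci2), "UIV")
})

test_that("cohort generation is deterministic and content-keyed", {
  cases <- bundled_cases()[c(1, 1, 3)]      # duplicated first row
  cohort <- cohort_from_table(cases, base_seed = 2)
  expect_length(cohort, 3)
  expect_identical(cohort[[1]]$geometry$vertebrae,
                   cohort[[2]]$geometry$vertebrae)
  expect_false(identical(cohort[[1]]$geometry$vertebrae,
                         cohort[[3]]$geometry$vertebrae))
  expect_length(cohort_from_table(list(), base_seed = 1), 0)
})

test_that("geometry exports write valid files", {
  g <- generate_spine(straight_indices(), seed = 1)
  tf <- tempfile(fileext = ".json")
  write_spine_json(g, tf)
  parsed <- jsonlite::read_json(tf)
  expect_named(parsed$vertebrae$T6, c("level", "center", "rotation", "dims",
                                      "landmarks"))
  to <- tempfile(fileext = ".obj")
  write_spine_obj(g, to)
  expect_gt(length(readLines(to)), 17 * 15)
})
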