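test_that("screw patterns follow the dropout rules", {
  fused <- level_range("T4", "L2")          # case-1 style, 11 levels
  p1 <- make_pattern(fused, "T9", "right", 1)
  expect_equal(nrow(p1$screws), 22)
  expect_equal(nrow(p1$dropped), 0)

  p2 <- make_pattern(fused, "T9", "right", 2)
  expect_equal(nrow(p2$dropped), 5)
  expect_equal(nrow(p2$screws), 17)
  expect_true(all(p2$dropped$side == "right"))   # convex side
  expect_equal(p2$dropped$level, c("T5", "T7", "T9", "T11", "L1"))
  expect_equal(100 * nrow(p2$dropped) / p2$n_reference, 22.7, tolerance = 0.01)

  p3 <- make_pattern(fused, "T9", "right", 3)
  expect_true(all(p3$dropped$side == "left"))    # concave side
  expect_equal(p3$dropped$level, p2$dropped$level)

  # periapical: same dropout count, consecutive levels centered on apex
  p4 <- make_pattern(fused, "T9", "right", 4)
  expect_equal(nrow(p4$dropped), 5)
  expect_equal(p4$dropped$level, c("T7", "T8", "T9", "T10", "T11"))
  expect_true(all(p4$dropped$side == "right"))
  p5 <- make_pattern(fused, "T9", "right", 5)
  expect_true(all(p5$dropped$side == "left"))

  # UIV and LIV stay bilateral in every pattern
  for (p in list(p2, p3, p4, p5)) {
    expect_equal(sum(p$screws$level == "T4"), 2)
    expect_equal(sum(p$screws$level == "L2"), 2)
  }

  # 4-level toy fusion: a single alternate dropout at the second level
  pt <- make_pattern(level_range("T5", "T8"), "T6", "right", 2)
  expect_equal(nrow(pt$dropped), 1)
  expect_equal(pt$dropped$level, "T6")

  # screw diameters respect the thoracic / lumbar envelopes
  th <- p1$screws$diameter[is_thoracic(p1$screws$level)]
  lu <- p1$screws$diameter[!is_thoracic(p1$screws$level)]
  expect_true(all(th >= 4.5 & th <= 5.5))
  expect_true(all(lu >= 5.5 & lu <= 6.0))

  expect_error(make_pattern(fused, "T4", "right", 4), "interior")
  expect_error(make_pattern(level_range("T4", "T6"), "T5", "right", 1),
               "4 fused levels")
})

test_that("cohort screw reductions match the study envelope", {
  pats <- list()
  for (ci in bundled_cases()) {
    for (k in 1:5) {
      pats[[length(pats) + 1]] <- make_pattern(level_range(ci$uiv, ci$liv),
                                               ci$mt_apex, "right", k)
    }
  }
  rs <- reduction_stats(pats)
  ref <- rs$per_construct[rs$per_construct$pattern_id == 1, ]
  expect_true(all(ref$reduction_pct == 0))
  expect_true(all(ref$density == 2))
  alt <- rs$per_construct[rs$per_construct$pattern_id >= 2, ]
  expect_equal(nrow(alt), 40)
  expect_true(all(alt$reduction_pct >= 21 & alt$reduction_pct <= 25))
  expect_equal(round(mean(alt$reduction_pct)), 23)
})

test_that("all-dropout arithmetic matches the closed form", {
  # hypothetical: unilateral at every interior level of an n-level fusion
  for (n in c(6, 9, 12)) {
    fused <- level_label(seq(4, 3 + n))
    expect_equal(100 * (n - 2) / (2 * n),
                 (n - 2) / (2 * n) * 100)   # arithmetic identity
    p <- make_pattern(fused, fused[ceiling(n / 2)], "right", 2)
    expect_lte(nrow(p$dropped), n - 2)
  }
})

test_that("rod contouring produces the requested sagittal geometry", {
  g <- generate_spine(bundled_cases()[[1]], seed = 1)
  fused <- level_range("T4", "L2")
  r0 <- contour_rod("left", g, fused, contour_angle = 0, lumbar_angle = 0)
  expect_lt(scolisim:::rod_bow_depth(r0), 1e-6)
  r25 <- contour_rod("right", g, fused, 25)
  expect_equal(unname(r25$measured_contour), 25, tolerance = 0.1)
  r35 <- contour_rod("left", g, fused, 35)
  expect_gt(scolisim:::rod_bow_depth(r35), scolisim:::rod_bow_depth(r25))
  # arc length covers the instrumented segment
  expect_equal(r25$node_levels, fused)
})

test_that("a straight spine already matching the rods needs no force", {
  p <- calibrated_params()
  g <- generate_spine(straight_indices(), seed = 1, jitter_sd = 0)
  ci <- straight_indices()
  fused <- level_range(ci$uiv, ci$liv)
  m <- apply_surgical_release(assemble_model(g, p), fused)
  rods <- list(left = contour_rod("left", g, fused, 0, lumbar_angle = 0),
               right = contour_rod("right", g, fused, 0, lumbar_angle = 0))
  pat <- make_pattern(fused, ci$mt_apex, "right", 1)
  res <- simulate_segmental_translation(m, g, pat, rods, nsteps = 5)
  expect_true(res$converged)
  expect_lt(max(res$screw_forces$magnitude), 1)
})

test_that("bone-screw force summaries pool correctly", {
  fake <- function(mags, pid = 1) {
    structure(list(pattern_id = pid,
                   screw_forces = data.frame(level = "T5", side = "left",
                                             diameter = 5, fx = mags,
                                             fy = 0, fz = 0,
                                             magnitude = mags)),
              class = "simulation_result")
  }
  one <- bone_screw_forces(fake(c(30, 50)))
  expect_equal(unname(one$summary[c("mean", "min", "max")]), c(40, 30, 50))
  pooled <- bone_screw_forces(list(fake(c(30, 50)), fake(40)))
  expect_equal(unname(pooled$summary[["mean"]]), 40)
  expect_equal(unname(pooled$summary[["n"]]), 3)
  zero <- bone_screw_forces(fake(c(0, 0)))
  expect_equal(unname(zero$summary[c("mean", "sd", "min", "max")]),
               c(0, 0, 0, 0))
})

test_that("instrumented equilibrium balances globally and cables never push", {
  # use the cached cohort's first case, reference pattern
  runs <- attr(cohort_run(), "runs")
  res <- runs[[1]]$results[["1"]]
  st <- res$configuration$state
  mm <- res$model
  # re-evaluated residual below tolerance on free DOFs
  Fg <- residual(mm, st)
  Fg[mm$fixed] <- 0
  expect_lt(max(abs(Fg[, 1:3])), 0.5 + 1e-9)
  expect_lt(max(abs(Fg[, 4:6])), 50 + 1e-6)
  # global equilibrium: boundary reactions plus the rod grounding
  # forces balance the construct
  tot <- colSums(residual(mm, st)[, 1:3])
  ground_sum <- c(0, 0, 0)
  for (el in mm$elements) {
    if (el$type != "ground") next
    fe <- element_forces(el, st$x, st$R)
    ground_sum <- ground_sum + fe$i[1:3]
  }
  expect_lt(max(abs(tot - ground_sum)), 1e-3)
  # tension-only ligaments: no negative tensions anywhere
  for (el in mm$elements) {
    if (el$type != "cable") next
    pi_ <- st$x[el$body_i, ] + st$R[[el$body_i]] %*% el$a_i
    pj_ <- st$x[el$body_j, ] + st$R[[el$body_j]] %*% el$a_j
    expect_gte(cable_force(el, max(vnorm(pj_ - pi_), 1e-9)), 0)
  }
})
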