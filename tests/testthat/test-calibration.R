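test_that("FSU calibration reproduces the load-displacement targets", {
  p <- calibrate_fsu(default_stiffness_params(), "thoracic")
  fit <- attr(p, "fsu_fit")$thoracic
  tgt <- p$fsu_targets$thoracic[names(fit)]
  expect_true(all(abs(fit - tgt) / tgt < 0.02))

  # doubling all targets doubles the achieved assembled stiffness within
  # 2% (the primary diagonal itself more than doubles: the ligament-cable
  # contributions do not scale with the targets)
  p2 <- default_stiffness_params()
  p2$fsu_targets$thoracic <- p2$fsu_targets$thoracic * 2
  p2 <- calibrate_fsu(p2, "thoracic")
  fit2 <- attr(p2, "fsu_fit")$thoracic
  expect_true(all(abs(fit2 / fit - 2) < 0.04))
  expect_true(all(p2$primary_diag$thoracic >= p$primary_diag$thoracic))

  # identity: re-calibrating already-calibrated params changes nothing
  p3 <- calibrate_fsu(p, "thoracic")
  expect_equal(p3$primary_diag$thoracic, p$primary_diag$thoracic,
               tolerance = 0.02)
})

test_that("release partition achieves the printed stiffness reductions", {
  p <- calibrated_params()
  for (region in c("thoracic", "lumbar")) {
    geom <- fsu_geometry(scolisim:::ref_levels_for(region))
    fsu <- paste(scolisim:::ref_levels_for(region), collapse = "-")
    intact <- assemble_model(geom, p, ribcage = FALSE)
    released <- apply_surgical_release(intact, fsu)
    ratio <- function(mode) fsu_stiffness(released, fsu, mode) /
      fsu_stiffness(intact, fsu, mode)
    expect_equal(ratio("axial_rotation"), 0.830, tolerance = 0.005)
    expect_equal(ratio("flexion"), 0.850, tolerance = 0.005)
    expect_equal(ratio("lateral_bending"), 0.962, tolerance = 0.005)
    expect_equal(ratio("axial_compression"), 0.860, tolerance = 0.005)
  }
})

test_that("zero reduction targets are reported as an infeasible partition", {
  # the interspinous cable contributes flexion stiffness that removal
  # cannot avoid, so demanding a 0% flexion reduction is infeasible and
  # must be reported naming the mode
  p0 <- default_stiffness_params()
  p0$release_reduction[] <- 0
  expect_error(calibrate_release_partition(p0), "infeasible.*flexion")

  # modes without an unavoidable removed-element share do go to zero:
  # with tiny reduction targets the facet stiffness nearly vanishes and
  # the release barely changes coronal bending and axial compression
  p1 <- default_stiffness_params()
  p1$release_reduction <- c(axial_rotation = 0.02, flexion = 0.10,
                            coronal_bending = 0.005,
                            axial_compression = 0.005)
  p1 <- calibrate_release_partition(p1)
  geom <- fsu_geometry(c("T6", "T7"))
  intact <- assemble_model(geom, p1, ribcage = FALSE)
  released <- apply_surgical_release(intact, "T6-T7")
  for (mode in c("lateral_bending", "axial_compression")) {
    expect_equal(fsu_stiffness(released, "T6-T7", mode) /
                   fsu_stiffness(intact, "T6-T7", mode), 0.995,
                 tolerance = 0.005)
  }
})

test_that("calibrated stiffness matrices stay symmetric positive semidefinite", {
  p <- calibrated_params()
  g <- generate_spine(bundled_cases()[[1]], seed = 1)
  m <- assemble_model(g, p)
  for (el in m$elements) {
    if (el$type != "spring6") next
    expect_lt(max(abs(el$K - t(el$K))), 1e-9)
    expect_gte(min(eigen(el$K, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-9)
  }
})

test_that("side bending behaves physically", {
  p <- calibrated_params()
  g <- generate_spine(straight_indices(), seed = 3, jitter_sd = 0)
  m <- assemble_model(g, p)
  ci <- straight_indices()

  # zero load leaves the geometry unchanged
  bent0 <- simulate_side_bending(m, g, "left", bending_load(0, 0))
  expect_lt(max(abs(attr(bent0, "configuration")$displacement)), 1e-6)

  # straight symmetric spine: left and right bending mirror each other
  bl <- simulate_side_bending(m, g, "left")
  br <- simulate_side_bending(m, g, "right")
  expect_lt(abs(cobb_angle(bl, "T6", "T12") - cobb_angle(br, "T6", "T12")),
            0.1)

  # doubling stiffness roughly halves the deflection (near-linear regime)
  soft <- simulate_side_bending(m, g, "left", bending_load(1000, 60))
  m2 <- apply_patient_calibration(m, ci, scale = c(pt = 2, mt = 2, tll = 2))
  stiff <- simulate_side_bending(m2, g, "left", bending_load(1000, 60))
  d_soft <- cobb_angle(soft, "T6", "T12")
  d_stiff <- cobb_angle(stiff, "T6", "T12")
  expect_equal(d_soft / d_stiff, 2, tolerance = 0.1)
})

test_that("increasing a region's stiffness decreases its bending response", {
  p <- calibrated_params()
  ci <- bundled_cases()[[1]]
  g <- generate_spine(ci, seed = 1)
  m <- assemble_model(g, p)
  bend_mt <- function(s_mt) {
    m2 <- apply_patient_calibration(m, ci, scale = c(pt = 1, mt = s_mt,
                                                     tll = 1))
    bent <- simulate_side_bending(m2, g, "right")
    ci$mt_cobb - cobb_angle(bent, ci$mt_sup_end, ci$mt_inf_end)
  }
  expect_gt(bend_mt(0.7), bend_mt(1.4))
})

test_that("patient calibration recovers known regional factors", {
  p <- calibrated_params()
  ci <- bundled_cases()[[1]]
  g <- generate_spine(ci, seed = 1)
  base <- assemble_model(g, p)
  truth <- c(pt = 0.7, mt = 1.3, tll = 0.9)
  m_true <- apply_patient_calibration(base, ci, scale = truth)
  synth <- ci
  for (dir in c("left", "right")) {
    bent <- simulate_side_bending(m_true, g, dir)
    cb <- scolisim:::regional_cobbs(bent, ci)
    synth[[paste0("pt_bend_", dir)]] <- cb[["pt"]]
    synth[[paste0("mt_bend_", dir)]] <- cb[["mt"]]
    synth[[paste0("tll_bend_", dir)]] <- cb[["tll"]]
  }
  pc <- calibrate_patient(g, synth, p)
  expect_true(pc$converged)
  expect_lt(max(abs(pc$achieved - pc$targets)), 2)
  expect_true(all(abs(pc$scale - truth) / truth < 0.10))
  expect_true(all(pc$asym < 1.25))   # no synthetic asymmetry to recover
})

test_that("parameter recovery holds across randomized synthetic cases", {
  # scaled-down version of the recovery experiment: randomized factor
  # triplets on one geometry, median relative error < 10%
  p <- calibrated_params()
  ci <- bundled_cases()[[4]]
  g <- generate_spine(ci, seed = 2)
  base <- assemble_model(g, p)
  set.seed(14)
  errs <- c()
  for (rep in 1:3) {
    truth <- c(pt = runif(1, 0.6, 1.6), mt = runif(1, 0.6, 1.6),
               tll = runif(1, 0.6, 1.6))
    m_true <- apply_patient_calibration(base, ci, scale = truth)
    synth <- ci
    for (dir in c("left", "right")) {
      bent <- simulate_side_bending(m_true, g, dir)
      cb <- scolisim:::regional_cobbs(bent, ci)
      synth[[paste0("pt_bend_", dir)]] <- cb[["pt"]]
      synth[[paste0("mt_bend_", dir)]] <- cb[["mt"]]
      synth[[paste0("tll_bend_", dir)]] <- cb[["tll"]]
    }
    pc <- calibrate_patient(g, synth, p)
    errs <- c(errs, abs(pc$scale - truth) / truth)
  }
  expect_lt(median(errs), 0.10)
})

test_that("calibration on a case's own output is a fixed point", {
  p <- calibrated_params()
  ci <- bundled_cases()[[1]]
  g <- generate_spine(ci, seed = 1)
  base <- assemble_model(g, p)
  synth <- ci
  for (dir in c("left", "right")) {
    bent <- simulate_side_bending(base, g, dir)
    cb <- scolisim:::regional_cobbs(bent, ci)
    synth[[paste0("pt_bend_", dir)]] <- cb[["pt"]]
    synth[[paste0("mt_bend_", dir)]] <- cb[["mt"]]
    synth[[paste0("tll_bend_", dir)]] <- cb[["tll"]]
  }
  pc <- calibrate_patient(g, synth, p)
  expect_true(all(abs(pc$scale - 1) < 0.1))
  expect_true(all(abs(pc$asym - 1) < 0.1))
})
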