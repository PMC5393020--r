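test_that("default stiffness parameters carry the reference cable values", {
  p <- default_stiffness_params()
  expect_equal(unname(p$cable_ref[c("ALL", "PLL", "LF", "ITL", "ISL_SSL")]),
               c(23.6, 24.9, 32.6, 12.9, 32.1))
  expect_equal(unname(p$ribcage), c(1.40, 1.35, 1.31))
  expect_equal(unname(p$release_reduction), c(0.17, 0.15, 0.038, 0.14))
})

test_that("cable force law is tension-only and linear in elongation", {
  cbl <- list(k = 23.6, L0 = 30)
  expect_equal(cable_force(cbl, 31), 23.6)
  expect_equal(cable_force(cbl, 28), 0)
  expect_equal(cable_force(cbl, 30), 0)
  expect_error(cable_force(cbl, -1), "positive")
})

test_that("assembled models have the full element set per FSU", {
  p <- calibrated_params()
  ci <- bundled_cases()[[1]]
  g <- generate_spine(ci, seed = 1)
  m <- assemble_model(g, p)
  expect_equal(nrow(m$meta$fsu), 17)          # T1-T2 ... L5-pelvis
  for (fsu in m$meta$fsu$name) {
    els <- m$elements[fsu_elements(m, fsu)]
    nms <- vapply(els, `[[`, "", "name")
    expect_setequal(nms, c("ALL", "PLL", "LF", "ITL_left", "ITL_right",
                           "ISL_SSL", "primary_disc", "facet_left",
                           "facet_right"))
  }
  # assembled at rest: zero residual
  expect_lt(max(abs(residual(m))), 1e-8)
})

test_that("surgical release removes exactly the resected elements", {
  p <- calibrated_params()
  g <- generate_spine(bundled_cases()[[1]], seed = 1)
  m <- assemble_model(g, p)
  m0 <- apply_surgical_release(m, character(0))
  expect_identical(length(m0$elements), length(m$elements))

  m1 <- apply_surgical_release(m, "T6-T7")
  els <- m1$elements[fsu_elements(m1, "T6-T7")]
  nms <- vapply(els, `[[`, "", "name")
  expect_setequal(nms, c("ALL", "PLL", "LF", "ITL_left", "ITL_right",
                         "primary_disc"))
  # other FSUs untouched
  expect_length(fsu_elements(m1, "T8-T9"), 9)

  ci <- bundled_cases()[[1]]
  m2 <- apply_surgical_release(m, level_range(ci$uiv, ci$liv))
  expect_length(m2$meta$released, 10)         # T4..L2: 10 FSUs
  expect_error(apply_surgical_release(m, "T90-T91"), "unknown FSU")
})

test_that("FSU probe recovers a single spring's stiffness analytically", {
  k <- 137
  m <- toy_cable_model(k = k, L0 = 20)
  # probe in axial tension: displace the upper body +z and read the
  # restoring force (brute-force residual oracle)
  st <- model_state(m)
  st$x[1, 3] <- st$x[1, 3] + 0.5
  Fg <- residual(m, st)
  expect_equal(-Fg[1, 3] / 0.5, k, tolerance = 1e-3)
})

test_that("FSU stiffness matches the analytic assembled projection on toys", {
  # two parallel vertical cables at +/- 10 mm lateral offset, both taut
  # under axial tension: axial stiffness 2k, coronal rotation stiffness
  # 2 k d^2 (about the midline), computed by the constrained-mode probe
  k <- 50; d <- 10; L0 <- 20
  bodies <- list(list(name = "T6", X0 = c(0, 0, L0), R0 = diag(3)),
                 list(name = "T7", X0 = c(0, 0, 0), R0 = diag(3)))
  fixed <- matrix(FALSE, 2, 6, dimnames = list(c("T6", "T7"), NULL))
  fixed[2, ] <- TRUE
  elements <- list(
    new_cable("left", 1L, 2L, c(0, d, 0), c(0, d, 0), k, L0, fsu = "T6-T7"),
    new_cable("right", 1L, 2L, c(0, -d, 0), c(0, -d, 0), k, L0, fsu = "T6-T7"))
  m <- list(bodies = bodies, body_index = list(T6 = 1L, T7 = 2L),
            fixed = fixed, elements = elements,
            meta = list(fsu = data.frame(name = "T6-T7", upper = "T6",
                                         lower = "T7", region = "thoracic",
                                         body_i = 1L, body_j = 2L,
                                         cx = 0, cy = 0, cz = L0 / 2),
                        released = character(0)))
  class(m) <- "multibody_model"
  # lateral-bending probe about the disc center: only the rising-side
  # cable is taut, its elongation rate is theta*d, so the analytic
  # rotational stiffness is k*d^2 (the probe magnitude keeps the
  # elongation on the linear branch of the smoothed law)
  probe <- fsu_stiffness(m, "T6-T7", "lateral_bending", delta = 0.5)
  analytic <- k * d^2 * pi / 180                   # N.mm per degree
  # within 1%: the finite-angle probe includes second-order chord-tilt
  # coupling absent from the small-angle closed form
  expect_equal(probe, analytic, tolerance = 0.01)
})

test_that("rib-cage weighting raises thoracic FSU stiffness by the stated factors", {
  p <- calibrated_params()
  g <- fsu_geometry(c("T6", "T7"))
  m1 <- assemble_model(g, p, ribcage = TRUE)
  m0 <- assemble_model(g, p, ribcage = FALSE)
  ratio <- function(mode) fsu_stiffness(m1, "T6-T7", mode) /
    fsu_stiffness(m0, "T6-T7", mode)
  expect_equal(ratio("flexion"), 1.40, tolerance = 0.005)
  expect_equal(ratio("lateral_bending"), 1.35, tolerance = 0.005)
  expect_equal(ratio("axial_rotation"), 1.31, tolerance = 0.005)
  # lumbar FSUs carry no rib-cage weighting
  gl <- fsu_geometry(c("L2", "L3"))
  ml1 <- assemble_model(gl, p, ribcage = TRUE)
  ml0 <- assemble_model(gl, p, ribcage = FALSE)
  expect_equal(fsu_stiffness(ml1, "L2-L3", "flexion") /
                 fsu_stiffness(ml0, "L2-L3", "flexion"), 1,
               tolerance = 1e-9)
})

test_that("element forces obey Newton's third law", {
  set.seed(21)
  p <- calibrated_params()
  g <- generate_spine(bundled_cases()[[2]], seed = 9)
  m <- assemble_model(g, p)
  st <- model_state(m)
  for (b in seq_len(17)) {
    st$x[b, ] <- st$x[b, ] + rnorm(3, 0, 1.5)
    st$R[[b]] <- rotvec_to_matrix(rnorm(3, 0, 0.04)) %*% st$R[[b]]
  }
  for (el in m$elements[sample(length(m$elements), 30)]) {
    fe <- element_forces(el, st$x, st$R)
    if (is.null(fe) || is.null(fe$j)) next
    expect_lt(max(abs(fe$i[1:3] + fe$j[1:3])), 1e-9)
    # net moment about the origin vanishes
    mi <- fe$i[4:6] + cross_prod(st$x[el$body_i, ], fe$i[1:3])
    mj <- fe$j[4:6] + cross_prod(st$x[el$body_j, ], fe$j[1:3])
    expect_lt(max(abs(mi + mj)), 1e-6 * (1 + max(abs(mi))))
  }
  # whole-model: with no loads and no grounds, total wrench is zero
  Fg <- residual(m, st)
  expect_lt(max(abs(colSums(Fg[, 1:3]))), 1e-6)
  mom <- rowSums(vapply(seq_len(nrow(Fg)), function(b)
    Fg[b, 4:6] + cross_prod(st$x[b, ], Fg[b, 1:3]), numeric(3)))
  expect_lt(max(abs(mom)), 1e-4)
})

test_that("compiled kernels agree with the reference element implementation", {
  set.seed(33)
  p <- calibrated_params()
  g <- generate_spine(bundled_cases()[[1]], seed = 1)
  m <- assemble_model(g, p)
  m <- apply_patient_calibration(m, bundled_cases()[[1]],
                                 scale = c(pt = 0.8, mt = 1.4, tll = 0.6),
                                 asym = c(pt = 1.5, mt = 2, tll = 1.2))
  st <- model_state(m)
  for (b in seq_len(17)) {
    st$x[b, ] <- st$x[b, ] + rnorm(3, 0, 2)
    st$R[[b]] <- rotvec_to_matrix(rnorm(3, 0, 0.05)) %*% st$R[[b]]
  }
  op <- options(scolisim.use_compiled = TRUE)
  Fc <- residual(m, st)
  options(scolisim.use_compiled = FALSE)
  Fr <- residual(m, st)
  options(op)
  expect_lt(max(abs(Fc - Fr)), 1e-8 * (1 + max(abs(Fr))))
  Jc <- scolisim:::tangent_packed(scolisim:::pack_model(m), st, 1)
  Jr <- scolisim:::assemble_tangent(m, st)
  expect_lt(max(abs(Jc - Jr)), 1e-8 * (1 + max(abs(Jr))))
})

test_that("stiffness parameters round-trip through the config file", {
  p <- default_stiffness_params()
  p$cable_ref[["ALL"]] <- 29.9
  p$fsu_targets$lumbar[["flexion"]] <- 2600
  tf <- tempfile(fileext = ".yml")
  write_stiffness_config(p, tf)
  q <- read_stiffness_config(tf)
  expect_equal(q$cable_ref[["ALL"]], 29.9)
  expect_equal(q$fsu_targets$lumbar[["flexion"]], 2600)
  expect_equal(q$ribcage, p$ribcage)
})
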