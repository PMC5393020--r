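test_that("Cobb angle matches analytic endplate tilts", {
  # straight column: zero everywhere
  g0 <- tilted_geometry(c("T6", "T7", "T8"), c(0, 0, 0))
  expect_equal(cobb_angle(g0, "T6", "T8"), 0, tolerance = 1e-9)

  # coronal tilts +10 and -15 deg -> Cobb 25
  g <- tilted_geometry(c("T6", "T7", "T8"), c(0, 0, 0),
                       cor_tilt_deg = c(10, 0, -15))
  expect_equal(cobb_angle(g, "T6", "T8"), 25, tolerance = 1e-6)
  expect_error(cobb_angle(g, "T8", "T6"), "cephalad")
})

test_that("sagittal angle matches an analytic arc", {
  # linear sagittal tilt profile subtending 30 degrees (upper vertebrae
  # flexed forward, lower extended: a kyphotic arc)
  g <- tilted_geometry(paste0("T", 2:12), seq(15, -15, length.out = 11))
  expect_equal(sagittal_angle(g, "T2", "T12", positive = "kyphosis"), 30,
               tolerance = 1e-6)
  # lordosis convention flips the sign
  expect_equal(sagittal_angle(g, "T2", "T12", positive = "lordosis"), -30,
               tolerance = 1e-6)
})

test_that("apical rotation reads back the constructed axial rotation", {
  g <- fsu_geometry(c("T8", "T9"))
  expect_equal(apical_rotation(g, "T9"), 0, tolerance = 1e-9)
  g$vertebrae[["T9"]]$R <- rot_z(deg2rad(19))
  expect_equal(apical_rotation(g, "T9"), 19, tolerance = 1e-6)
  g$vertebrae[["T9"]]$R <- rot_z(deg2rad(-19))
  expect_equal(apical_rotation(g, "T9"), 19, tolerance = 1e-6)
})

test_that("indices are invariant under global rigid motion", {
  ci <- bundled_cases()[[1]]
  g <- generate_spine(ci, seed = 2)
  r0 <- index_report(g, ci)
  shift <- c(12.3, -45.6, 78.9)
  g2 <- g
  for (lv in names(g2$vertebrae)) {
    g2$vertebrae[[lv]]$center <- g2$vertebrae[[lv]]$center + shift
  }
  g2$pelvis$center <- g2$pelvis$center + shift
  r1 <- index_report(g2, ci)
  for (f in c("pt_cobb", "mt_cobb", "tll_cobb", "kyphosis", "lordosis",
              "mt_avr", "tll_avr")) {
    expect_lt(abs(r1[[f]] - r0[[f]]), 1e-9)
  }
})

test_that("mirrored geometry yields identical unsigned Cobb", {
  ci <- bundled_cases()[[3]]
  g <- generate_spine(ci, seed = 4)
  gm <- generate_spine(ci, seed = 4, convexity = c(pt = -1, mt = 1, tll = -1))
  expect_equal(cobb_angle(g, ci$mt_sup_end, ci$mt_inf_end),
               cobb_angle(gm, ci$mt_sup_end, ci$mt_inf_end),
               tolerance = 1e-9)
})

test_that("index report serializes to a one-row data frame", {
  ci <- bundled_cases()[[1]]
  g <- generate_spine(ci, seed = 1)
  df <- as.data.frame(index_report(g, ci))
  expect_equal(nrow(df), 1)
  expect_true(all(c("mt_cobb", "kyphosis", "mt_avr") %in% names(df)))
})
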