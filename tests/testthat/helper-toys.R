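# Shared fixtures: small analytic models, geometry builders, and the
# memoised cohort run used by the acceptance tests.

# two rigid bodies connected by a single vertical cable; lower body fixed
toy_cable_model <- function(k = 100, L0 = 20) {
  bodies <- list(
    list(name = "upper", X0 = c(0, 0, L0), R0 = diag(3)),
    list(name = "lower", X0 = c(0, 0, 0), R0 = diag(3))
  )
  fixed <- matrix(FALSE, 2, 6, dimnames = list(c("upper", "lower"), NULL))
  fixed[2, ] <- TRUE
  fixed[1, 4:6] <- TRUE       # keep the toy translational
  elements <- list(new_cable("axial", 1L, 2L, a_i = c(0, 0, 0),
                             a_j = c(0, 0, 0), k = k, L0 = L0))
  m <- list(bodies = bodies,
            body_index = list(upper = 1L, lower = 2L),
            fixed = fixed, elements = elements,
            meta = list(fsu = data.frame(), released = character(0)))
  class(m) <- "multibody_model"
  m
}

# straight vertical mini spine geometry with explicit sagittal tilts
# applied per vertebra (deg, rotation about +Y)
tilted_geometry <- function(levels, sag_tilt_deg, cor_tilt_deg = NULL,
                            height = 170) {
  g <- fsu_geometry(levels, height = height)
  for (i in seq_along(levels)) {
    R <- rot_y(deg2rad(sag_tilt_deg[i]))
    if (!is.null(cor_tilt_deg)) R <- R %*% rot_x(deg2rad(cor_tilt_deg[i]))
    g$vertebrae[[i]]$R <- R
  }
  g
}

# a clinical_indices row with every angle zero (straight spine)
straight_indices <- function() {
  clinical_indices(case_id = "straight", sex = "F", age = 15, height = 160,
                   weight = 50, lenke = "1A",
                   pt_sup_end = "T2", mt_sup_end = "T6", mt_apex = "T9",
                   mt_inf_end = "T12",
                   pt_cobb = 0, mt_cobb = 0, tll_cobb = 0,
                   pt_bend_left = 0, pt_bend_right = 0,
                   mt_bend_left = 0, mt_bend_right = 0,
                   tll_bend_left = 0, tll_bend_right = 0,
                   mt_avr = 0, tll_avr = 0, kyphosis = 0, lordosis = 0,
                   uiv = "T4", liv = "L2")
}

# memoised full-cohort pipeline run shared by the acceptance tests
.test_cache <- new.env(parent = emptyenv())
cohort_run <- function() {
  if (is.null(.test_cache$cohort)) {
    cfg <- run_config(verbose = FALSE)
    .test_cache$cohort <- run_pipeline(cfg)
  }
  .test_cache$cohort
}

cross_prod <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
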