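#' Generate a 3D scoliotic spine geometry matching clinical indices
#'
#' Stands in for a biplanar-radiograph 3D reconstruction: vertebral body
#' frames are placed along a composite space curve — one coronal circular-
#' arc-like bump per curve region (PT, MT, TL/L), sagittal kyphosis and
#' lordosis arcs, and an axial-rotation bump peaking at each curve apex —
#' and the bump amplitudes are solved so that measuring the generated
#' geometry with [index_report()] reproduces the requested indices
#' (coronal Cobb and sagittal angles within 1 degree, apical rotations
#' within 2 degrees). Mirror-symmetric landmark jitter emulates
#' reconstruction error without breaking the left/right landmark symmetry
#' of each vertebra.
#'
#' @param indices A `clinical_indices`.
#' @param seed Integer seed; identical `(indices, seed)` give identical
#'   geometry.
#' @param convexity Named numeric signs (`pt`, `mt`, `tll`), +1 = convex
#'   toward the patient's left, -1 = convex right. Default: right-convex
#'   main thoracic, left-convex proximal thoracic and thoracolumbar/lumbar.
#' @param jitter_sd Landmark jitter standard deviation, mm.
#' @param tol Fit tolerance on the coronal/sagittal angles, degrees.
#' @param max_iter Maximum amplitude-fit sweeps.
#' @return A `spine_geometry` with the fitted profile amplitudes attached
#'   as attribute `"fit"`.
#' @export
#' @examples
#' g <- generate_spine(bundled_cases()[[1]], seed = 1)
#' cobb_angle(g, "T6", "T12")  # ~55
generate_spine <- function(indices, seed,
                           convexity = c(pt = 1, mt = -1, tll = 1),
                           jitter_sd = 0.8, tol = 0.25, max_iter = 60) {
  validate_clinical_indices(indices)
  stopifnot(all(c("pt", "mt", "tll") %in% names(convexity)))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)

  lv <- vertebral_levels()
  dims <- lapply(lv, vertebral_dimensions, height = indices$height)
  names(dims) <- lv
  jitter <- lapply(lv, function(l) draw_landmark_jitter(jitter_sd))
  names(jitter) <- lv

  # cumulative axial stations of the vertebral centers (mm from T1 center)
  h <- numeric(length(lv))
  for (i in seq_along(lv)[-1]) {
    h[i] <- h[i - 1] + dims[[i - 1]][["height"]] / 2 + dims[[i - 1]][["disc"]] +
      dims[[i]][["height"]] / 2
  }
  names(h) <- lv
  h_pelvis <- h[["L5"]] + dims[["L5"]][["height"]] / 2 +
    dims[["L5"]][["disc"]] + 35

  station <- function(level) if (level == "pelvis") h_pelvis else h[[level]]

  # region spans (stations): coronal bumps and axial-rotation bumps
  pt_a <- station(indices$pt_sup_end); pt_b <- station(indices$mt_sup_end)
  pt_span <- c(a = pt_a, m = (pt_a + pt_b) / 2, b = pt_b)
  mt_span <- c(a = station(indices$mt_sup_end), m = station(indices$mt_apex),
               b = station(indices$mt_inf_end))
  tll_span <- c(a = station(indices$mt_inf_end),
                m = station(tll_apex_level(indices)),
                b = station(indices$tll_inf_end))
  kyp_span <- c(a = station("T1"), m = station("T7"), b = station("L1"))
  lor_span <- c(a = station("T12"), m = station("L3"), b = h_pelvis + 20)

  # sine-quarter-wave bump: 0 at a and b, 1 at m, maximal slope at the ends
  bump <- function(hh, span) {
    out <- numeric(length(hh))
    up <- hh >= span["a"] & hh <= span["m"]
    dn <- hh > span["m"] & hh <= span["b"]
    out[up] <- sin(pi / 2 * (hh[up] - span["a"]) / (span["m"] - span["a"]))
    out[dn] <- cos(pi / 2 * (hh[dn] - span["m"]) / (span["b"] - span["m"]))
    out
  }

  # approximate dCobb/dA (rad per mm of amplitude) for the Newton updates
  cobb_slope <- function(span) {
    (pi / 2) * (1 / (span["m"] - span["a"]) + 1 / (span["b"] - span["m"]))
  }

  targets <- c(pt = indices$pt_cobb, mt = indices$mt_cobb,
               tll = indices$tll_cobb, kyp = indices$kyphosis,
               lor = indices$lordosis)
  spans <- list(pt = pt_span, mt = mt_span, tll = tll_span,
                kyp = kyp_span, lor = lor_span)
  amp <- vapply(names(targets), function(k) {
    if (targets[[k]] == 0) 0 else deg2rad(targets[[k]]) / cobb_slope(spans[[k]])
  }, numeric(1))
  names(amp) <- names(targets)
  rot_amp <- c(mt = indices$mt_avr, tll = indices$tll_avr)

  sgn <- c(pt = unname(convexity[["pt"]]), mt = unname(convexity[["mt"]]),
           tll = unname(convexity[["tll"]]))

  build <- function(amp, rot_amp) {
    ypr <- function(hh) {
      sgn[["pt"]] * amp[["pt"]] * bump(hh, pt_span) +
        sgn[["mt"]] * amp[["mt"]] * bump(hh, mt_span) +
        sgn[["tll"]] * amp[["tll"]] * bump(hh, tll_span)
    }
    xpr <- function(hh) {
      -amp[["kyp"]] * bump(hh, kyp_span) + amp[["lor"]] * bump(hh, lor_span)
    }
    phi <- function(hh) {
      deg2rad(sgn[["mt"]] * rot_amp[["mt"]] * bump(hh, mt_span) +
                sgn[["tll"]] * rot_amp[["tll"]] * bump(hh, tll_span))
    }
    z_top <- h_pelvis + 60
    frame_at <- function(hh, twist) {
      p <- c(xpr(hh), ypr(hh), z_top - hh)
      dh <- 1
      pm <- c(xpr(hh - dh), ypr(hh - dh), z_top - (hh - dh))
      pp <- c(xpr(hh + dh), ypr(hh + dh), z_top - (hh + dh))
      zl <- normalize(pm - pp)                 # cephalad tangent
      xl <- normalize(c(1, 0, 0) - sum(c(1, 0, 0) * zl) * zl)
      yl <- c(zl[2] * xl[3] - zl[3] * xl[2],
              zl[3] * xl[1] - zl[1] * xl[3],
              zl[1] * xl[2] - zl[2] * xl[1])
      R <- cbind(xl, yl, zl) %*% rot_z(twist)
      list(center = p, R = R)
    }
    verts <- vector("list", length(lv))
    names(verts) <- lv
    for (i in seq_along(lv)) {
      fr <- frame_at(h[i], phi(h[i]))
      lm <- vertebra_landmarks(dims[[i]])
      for (nm in names(lm)) lm[[nm]] <- lm[[nm]] + jitter[[i]][[nm]]
      verts[[i]] <- list(level = lv[i], center = fr$center, R = fr$R,
                         dims = dims[[i]], landmarks = lm)
    }
    pel <- frame_at(h_pelvis, 0)
    g <- list(vertebrae = verts,
              pelvis = list(center = pel$center, R = pel$R),
              height_cm = indices$height)
    class(g) <- "spine_geometry"
    g
  }

  measured <- function(g) {
    r <- index_report(g, indices)
    list(ang = c(pt = r$pt_cobb, mt = r$mt_cobb, tll = r$tll_cobb,
                 kyp = r$kyphosis, lor = r$lordosis),
         rot = c(mt = r$mt_avr, tll = r$tll_avr))
  }

  g <- build(amp, rot_amp)
  for (it in seq_len(max_iter)) {
    m <- measured(g)
    err_ang <- targets - m$ang
    err_rot <- c(mt = indices$mt_avr, tll = indices$tll_avr) - m$rot
    if (all(abs(err_ang) < tol) && all(abs(err_rot) < 2 * tol)) break
    for (k in names(targets)) {
      if (targets[[k]] == 0 && amp[[k]] == 0) next
      amp[[k]] <- amp[[k]] + deg2rad(err_ang[[k]]) / cobb_slope(spans[[k]])
    }
    for (k in c("mt", "tll")) {
      tgt <- if (k == "mt") indices$mt_avr else indices$tll_avr
      if (tgt == 0 && rot_amp[[k]] == 0) next
      rot_amp[[k]] <- rot_amp[[k]] + err_rot[[k]]
    }
    g <- build(amp, rot_amp)
  }
  validate_spine_geometry(g)
  attr(g, "fit") <- list(amplitudes = amp, rotation_amplitudes = rot_amp,
                         convexity = sgn, iterations = it, seed = seed,
                         errors = c(targets - measured(g)$ang))
  attr(g, "indices") <- indices
  g
}

# Deterministic per-case seed derived from the case content, so duplicated
# rows map to identical geometry.
case_seed <- function(indices, base_seed) {
  s <- paste(unlist(indices[case_table_columns()]), collapse = "|")
  v <- utf8ToInt(s)
  hash <- 0
  for (x in v) hash <- (hash * 31 + x) %% 2^28
  (as.integer(base_seed) %% 2^20) * 2048 + (hash %% 2048)
}

#' Generate geometry for a whole cohort
#'
#' One geometry per case, each with a deterministic seed derived from the
#' base seed and the case content (duplicated rows therefore yield
#' identical geometry).
#'
#' @param cases A list of `clinical_indices`, or a path to a case-table
#'   CSV (see [read_case_table()]).
#' @param base_seed Integer root seed.
#' @param ... Passed to [generate_spine()].
#' @return A list of `list(indices, geometry)` pairs, one per case.
#' @export
cohort_from_table <- function(cases, base_seed = 1, ...) {
  if (is.character(cases)) cases <- read_case_table(cases)
  lapply(cases, function(ci) {
    list(indices = ci,
         geometry = generate_spine(ci, seed = case_seed(ci, base_seed), ...))
  })
}
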