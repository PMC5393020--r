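#' Simulate simultaneous two-rod segmental translation
#'
#' The correction maneuver: both pre-contoured rods are presented along
#' the pedicle columns and every pedicle screw is drawn toward its rod
#' seating point gradually and simultaneously, with equilibrium
#' re-established at every increment. During translation the polyaxial
#' head and dorsal height adjustability are free: the screw-rod link is a
#' tension-only pull of the pedicle entry point toward the rod axis line
#' (free sliding along the rod, free azimuth), whose rest distance ramps
#' linearly down to the head standoff over the schedule, plus a seating
#' spring that progressively transmits orientation. At
#' the end of the schedule the construct is rigidly locked — every
#' screw-rod junction becomes a stiff 6-D spring assembled force-free at
#' the reached relative pose — and a final equilibrium (the springback
#' onto the locked construct) is solved. The bone-screw force is the
#' reaction transmitted at each anchor in that final locked state.
#'
#' Boundary conditions: pelvis fixed, T1 transverse-plane translations
#' constrained. Rod bodies are stabilized by very weak grounding springs
#' until the screws engage.
#'
#' @param model Released (and patient-calibrated) spine
#'   `multibody_model`.
#' @param geometry Preoperative `spine_geometry`.
#' @param pattern A `screw_pattern`.
#' @param rods Named list of `rod_def` (`left`, `right`).
#' @param nsteps Translation increments (default 20).
#' @param k_attach Pull-in penalty stiffness, N/mm.
#' @param k_lock_t,k_lock_r Locked-junction stiffness (N/mm, N.mm/rad).
#' @param standoff Dorsal offset of the rod seating line from the
#'   pedicle column, mm (nominal screw head height); sets where the rods
#'   are presented.
#' @param seat_slop Residual pedicle-to-seating-line distance at full
#'   seating, mm (polyaxial angulation slack).
#' @param k_seat_tilt,k_seat_sag,k_seat_twist Rotational stiffness of
#'   the progressive head-rod seating about the coronal, sagittal and
#'   axial axes (N.mm/rad). The sagittal component carries part of the
#'   rod-contour kyphosis restoration (the polyaxial swivel is not
#'   fully free once the head engages the rod under load).
#' @param ftol,ttol Solver residual tolerances (N, N.mm).
#' @param gap_tol Maximum allowed residual screw-rod gap before locking,
#'   mm.
#' @return A `simulation_result`: final configuration, per-screw force
#'   vectors and magnitudes, corrected-geometry `index_report` (when the
#'   case's indices are attached to the geometry), per-step trace,
#'   convergence flags.
#' @export
simulate_segmental_translation <- function(model, geometry, pattern, rods,
                                           nsteps = 20, k_attach = 4000,
                                           k_lock_t = 20000, k_lock_r = 1e6,
                                           standoff = 8, seat_slop = 8,
                                           k_seat_tilt = 5e4,
                                           k_seat_sag = 3e4,
                                           k_seat_twist = 4e3, ftol = 0.5,
                                           ttol = 50, gap_tol = 0.1) {
  stopifnot(inherits(pattern, "screw_pattern"))
  for (lv in pattern$fused) {
    if (!lv %in% names(geometry$vertebrae))
      stop("fused level ", lv, " not present in the geometry", call. = FALSE)
  }
  for (s in c("left", "right")) {
    if (!all(pattern$fused %in% rods[[s]]$node_levels))
      stop("rod (", s, " side) too short: uncovered level(s) ",
           paste(setdiff(pattern$fused, rods[[s]]$node_levels),
                 collapse = ", "), call. = FALSE)
  }

  m <- model
  n0 <- length(m$bodies)
  m$fixed["T1", 1:2] <- TRUE

  # append rod node bodies + beam + grounding elements
  node_body <- list(left = integer(0), right = integer(0))
  for (s in c("left", "right")) {
    rod <- rods[[s]]
    nn <- nrow(rod$nodes)
    idx <- integer(nn)
    for (i in seq_len(nn)) {
      # node frame: local z cephalad along the rod polyline
      t_dir <- if (i < nn) rod$nodes[i, ] - rod$nodes[i + 1, ] else
        rod$nodes[i - 1, ] - rod$nodes[i, ]
      zl <- normalize(t_dir)
      xl <- normalize(c(1, 0, 0) - sum(c(1, 0, 0) * zl) * zl)
      yl <- c(zl[2] * xl[3] - zl[3] * xl[2],
              zl[3] * xl[1] - zl[1] * xl[3],
              zl[1] * xl[2] - zl[2] * xl[1])
      b <- list(name = paste0("rod_", s, "_", rod$node_levels[i]),
                X0 = as.numeric(rod$nodes[i, ]), R0 = cbind(xl, yl, zl))
      m$bodies[[length(m$bodies) + 1]] <- b
      idx[i] <- length(m$bodies)
      m$body_index[[b$name]] <- idx[i]
    }
    node_body[[s]] <- idx
    m$fixed <- rbind(m$fixed, matrix(FALSE, nn, 6))
    rownames(m$fixed) <- vapply(m$bodies, `[[`, "", "name")
    for (i in seq_len(nn)) {
      m$elements[[length(m$elements) + 1]] <- new_ground(
        name = paste0("rod_ground_", s, "_", i), body_i = idx[i],
        k_t = 0.02, k_r = 200, X0 = m$bodies[[idx[i]]]$X0,
        R0 = m$bodies[[idx[i]]]$R0)
    }
    for (i in seq_len(nn - 1)) {
      bi <- idx[i]; bj <- idx[i + 1]
      seg <- m$bodies[[bj]]$X0 - m$bodies[[bi]]$X0
      zl <- normalize(-seg)                     # cephalad
      xl <- normalize(c(1, 0, 0) - sum(c(1, 0, 0) * zl) * zl)
      yl <- c(zl[2] * xl[3] - zl[3] * xl[2],
              zl[3] * xl[1] - zl[1] * xl[3],
              zl[1] * xl[2] - zl[2] * xl[1])
      A0 <- cbind(xl, yl, zl)
      mid <- (m$bodies[[bi]]$X0 + m$bodies[[bj]]$X0) / 2
      bm <- rod$beams[[i]]
      K <- diag(c(bm[["shear"]], bm[["shear"]], bm[["axial"]],
                  bm[["bend"]], bm[["bend"]], bm[["torsion"]]))
      m$elements[[length(m$elements) + 1]] <- new_spring6(
        name = paste0("rod_beam_", s, "_", i), body_i = bi, body_j = bj,
        a_i = as.numeric(t(m$bodies[[bi]]$R0) %*% (mid - m$bodies[[bi]]$X0)),
        a_j = as.numeric(t(m$bodies[[bj]]$R0) %*% (mid - m$bodies[[bj]]$X0)),
        B_i = t(m$bodies[[bi]]$R0) %*% A0, B_j = t(m$bodies[[bj]]$R0) %*% A0,
        K = K)   # both attachments at the segment midpoint: rest dt0 = 0
    }
  }

  # pull-in elements and seating springs, one pair per screw
  pull_ids <- integer(0)
  seat_ids <- integer(0)
  screw_meta <- list()
  for (r in seq_len(nrow(pattern$screws))) {
    lv <- pattern$screws$level[r]; sd <- pattern$screws$side[r]
    vb <- m$body_index[[lv]]
    node <- node_body[[sd]][match(lv, rods[[sd]]$node_levels)]
    a_i <- geometry$vertebrae[[lv]]$landmarks[[paste0("pedicle_", sd)]]
    dir_i <- c(-1, 0, 0)            # screw axis: posterior, vertebra frame
    # tension-only pull of the pedicle entry toward the rod axis line,
    # with the along-rod position free (the rod slides in the saddles)
    # and the rest distance ramping down to the seating slop
    el0 <- new_rodline(
      name = paste0("screw_", lv, "_", sd), body_i = vb, body_j = node,
      a_i = a_i, dir_i = dir_i, k = k_attach, L0 = 1, L0_end = seat_slop,
      s_max = 0)
    st0 <- model_state(m)
    gm0 <- .rodline_geom(el0, st0$x, st0$R, ramp_s = 0)
    el0$L0 <- if (is.null(gm0)) 1 else max(gm0$L, seat_slop)
    m$elements[[length(m$elements) + 1]] <- el0
    pull_ids <- c(pull_ids, length(m$elements))
    # progressive seating of the head on the rod: transmits coronal tilt
    # strongly (the rod sits in the saddle groove) and axial twist weakly
    # (friction only until locking); sagittal pitch stays polyaxially free
    Kseat <- matrix(0, 6, 6)
    Kseat[4, 4] <- k_seat_tilt
    Kseat[5, 5] <- k_seat_sag
    Kseat[6, 6] <- k_seat_twist
    D0_start <- t(geometry$vertebrae[[lv]]$R) %*% m$bodies[[node]]$R0
    m$elements[[length(m$elements) + 1]] <- new_spring6(
      name = paste0("seat_", lv, "_", sd), body_i = vb, body_j = node,
      a_i = c(0, 0, 0), a_j = c(0, 0, 0), B_i = diag(3), B_j = diag(3),
      K = Kseat, D0 = D0_start,
      D0_ramp = matrix_to_rotvec(t(D0_start)))
    seat_ids <- c(seat_ids, length(m$elements))
    screw_meta[[length(screw_meta) + 1]] <-
      list(level = lv, side = sd, body = vb, node = node, a_i = a_i,
           diameter = pattern$screws$diameter[r])
  }

  cfg <- solve_equilibrium(m, loads = list(), nsteps = nsteps,
                           ftol = ftol, ttol = ttol,
                           ftol_path = 4 * ftol, ttol_path = 4 * ttol)
  st <- cfg$state

  gaps <- vapply(seq_along(screw_meta), function(i) {
    el <- m$elements[[pull_ids[i]]]
    el$L0 <- 0; el$L0_end <- 0
    gm <- .rodline_geom(el, st$x, st$R, ramp_s = 1)
    if (is.null(gm)) 0 else max(0, gm$L - seat_slop)
  }, numeric(1))
  gaps_ok <- all(gaps <= gap_tol)

  # lock the construct: replace pull-in cables by stiff 6-D junctions
  # assembled force-free at the reached pose, then solve the springback
  m_lock <- m
  m_lock$elements <- m_lock$elements[-c(pull_ids, seat_ids)]
  K_lock <- diag(c(rep(k_lock_t, 3), rep(k_lock_r, 3)))
  lock_ids <- integer(0)
  for (sm in screw_meta) {
    A0 <- st$R[[sm$node]]                       # lock frame = rod node frame
    p_anchor <- as.numeric(st$x[sm$body, ] + st$R[[sm$body]] %*% sm$a_i)
    m_lock$elements[[length(m_lock$elements) + 1]] <- new_spring6(
      name = paste0("lock_", sm$level, "_", sm$side),
      body_i = sm$body, body_j = sm$node,
      a_i = sm$a_i, a_j = c(0, 0, 0),
      B_i = t(st$R[[sm$body]]) %*% A0, B_j = t(st$R[[sm$node]]) %*% A0,
      K = K_lock,
      dt0 = as.numeric(t(A0) %*% (st$x[sm$node, ] - p_anchor)),
      D0 = diag(3))
    lock_ids <- c(lock_ids, length(m_lock$elements))
  }
  cfg2 <- solve_equilibrium(m_lock, loads = list(), nsteps = 1,
                            ftol = ftol, ttol = ttol, state0 = st)
  st2 <- cfg2$state

  forces <- do.call(rbind, lapply(seq_along(screw_meta), function(i) {
    sm <- screw_meta[[i]]
    fe <- element_forces(m_lock$elements[[lock_ids[i]]], st2$x, st2$R)
    f <- fe$i[1:3]                              # force on the vertebra
    data.frame(level = sm$level, side = sm$side, diameter = sm$diameter,
               fx = f[1], fy = f[2], fz = f[3], magnitude = vnorm(f))
  }))

  corrected <- apply_configuration(geometry, m_lock, cfg2)
  indices <- attr(geometry, "indices")
  report <- if (!is.null(indices)) index_report(corrected, indices) else NULL

  out <- list(pattern_id = pattern$pattern_id, pattern = pattern,
              configuration = cfg2, translation_log = cfg$log,
              lock_log = cfg2$log,
              screw_forces = forces, gaps = gaps, gaps_ok = gaps_ok,
              corrected_geometry = corrected, report = report,
              converged = cfg$converged && cfg2$converged,
              model = m_lock)
  class(out) <- "simulation_result"
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> pattern %d, %d screws, %s\n",
              x$pattern_id, nrow(x$screw_forces),
              if (x$converged) "converged" else "NOT converged"))
  s <- bone_screw_forces(x)$summary
  cat(sprintf("  bone-screw force %.1f +/- %.1f N (%.1f-%.1f)\n",
              s[["mean"]], s[["sd"]], s[["min"]], s[["max"]]))
  if (!is.null(x$report))
    cat(sprintf("  corrected MT Cobb %.1f deg, kyphosis %.1f deg, MT AVR %.1f deg\n",
                x$report$mt_cobb, x$report$kyphosis, x$report$mt_avr))
  cat(sprintf("  max residual screw-rod gap %.3f mm\n", max(x$gaps)))
  invisible(x)
}

#' Bone-screw force magnitudes and summary
#'
#' @param result A `simulation_result`, or a list of them (cohort pooling:
#'   all screws of all cases).
#' @return List with `per_screw` (data frame) and `summary`
#'   (mean, sd, min, max, n).
#' @export
bone_screw_forces <- function(result) {
  if (inherits(result, "simulation_result")) result <- list(result)
  per <- do.call(rbind, lapply(result, function(r) r$screw_forces))
  mg <- per$magnitude
  list(per_screw = per,
       summary = c(mean = mean(mg), sd = if (length(mg) > 1) stats::sd(mg) else 0,
                   min = min(mg), max = max(mg), n = length(mg)))
}
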