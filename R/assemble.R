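#' Assemble the flexible multibody spine model
#'
#' Builds rigid bodies for every vertebra in the geometry (plus the pelvis
#' when present) and connects each functional spinal unit (FSU) with the
#' full element set: six tension-only ligament cables (ALL, PLL, LF, left
#' and right ITL, combined ISL+SSL), two facet-capsule 6-D springs, and
#' the primary 6-D intervertebral spring carrying the calibrated disc
#' stiffness with rib-cage weighting on the thoracic rotational terms.
#' All elements are assembled force-free in the input configuration (the
#' preoperative geometry is the rest state). By default the most caudal
#' body (the pelvis in a full model) is fixed.
#'
#' @param geometry A `spine_geometry` (full spine, or any consecutive
#'   subset of vertebrae as produced by [fsu_geometry()]).
#' @param params A `stiffness_params`, normally from [calibrated_params()].
#'   Uncalibrated params fall back to target-valued primary diagonals and
#'   zero facet springs.
#' @param ribcage Apply the thoracic rib-cage weighting factors.
#' @return A `multibody_model`.
#' @export
assemble_model <- function(geometry, params = calibrated_params(),
                           ribcage = TRUE) {
  lv <- names(geometry$vertebrae)
  has_pelvis <- !is.null(geometry$pelvis)
  body_names <- c(lv, if (has_pelvis) "pelvis")
  n <- length(body_names)
  bodies <- vector("list", n)
  for (i in seq_along(lv)) {
    v <- geometry$vertebrae[[i]]
    bodies[[i]] <- list(name = v$level, X0 = v$center, R0 = v$R)
  }
  if (has_pelvis) {
    bodies[[n]] <- list(name = "pelvis", X0 = geometry$pelvis$center,
                        R0 = geometry$pelvis$R)
  }
  body_index <- stats::setNames(as.list(seq_len(n)), body_names)
  fixed <- matrix(FALSE, n, 6, dimnames = list(body_names, NULL))
  fixed[n, ] <- TRUE   # caudal boundary body

  lw <- function(level, name) landmark_world(geometry, level, name)
  to_local <- function(b, w) as.numeric(t(bodies[[b]]$R0) %*% (w - bodies[[b]]$X0))

  elements <- list()
  fsu_rows <- list()
  for (k in seq_len(n - 1)) {
    u <- body_names[k]; l <- body_names[k + 1]
    fsu_name <- paste0(u, "-", l)
    vu <- geometry$vertebrae[[u]]
    Du <- vu$dims[["depth"]]; Hu <- vu$dims[["height"]]
    disc_u <- vu$dims[["disc"]]
    z_u <- as.numeric(vu$R %*% c(0, 0, 1))
    lower_is_vert <- l != "pelvis"
    region <- if (lower_is_vert && is_thoracic(l)) "thoracic" else "lumbar"
    scale_cab <- fsu_depth_scale(geometry, u, l, ref = c("T6", "T7"))
    ref_pair <- if (region == "thoracic") c("T6", "T7") else c("L2", "L3")
    scale_fsu <- fsu_depth_scale(geometry, u, l, ref = ref_pair)

    # paired attachment world points (upper inferior side / lower superior)
    proj <- function(w_up) w_up - disc_u * z_u
    pair <- function(w_up, w_lo_fun) {
      list(up = w_up, lo = if (lower_is_vert) w_lo_fun() else proj(w_up))
    }
    mid2 <- function(a, b) (a + b) / 2
    at <- list(
      ALL = pair(mid2(lw(u, "inf_ant_left"), lw(u, "inf_ant_right")),
                 function() mid2(lw(l, "sup_ant_left"), lw(l, "sup_ant_right"))),
      PLL = pair(mid2(lw(u, "inf_post_left"), lw(u, "inf_post_right")),
                 function() mid2(lw(l, "sup_post_left"), lw(l, "sup_post_right"))),
      LF = pair(vu$center + vu$R %*% c(-0.95 * Du, 0, -Hu / 2),
                function() {
                  vl <- geometry$vertebrae[[l]]
                  as.numeric(vl$center + vl$R %*%
                               c(-0.95 * vl$dims[["depth"]], 0,
                                 vl$dims[["height"]] / 2))
                }),
      ITL_left = pair(lw(u, "transverse_left"),
                      function() lw(l, "transverse_left")),
      ITL_right = pair(lw(u, "transverse_right"),
                       function() lw(l, "transverse_right")),
      ISL_SSL = pair(vu$center + vu$R %*%
                       (params$isl_attach_frac * vu$landmarks[["spinous"]]),
                     function() {
                       vl <- geometry$vertebrae[[l]]
                       as.numeric(vl$center + vl$R %*%
                                    (params$isl_attach_frac *
                                       vl$landmarks[["spinous"]]))
                     })
    )
    cable_k <- params$cable_ref
    if (!is.null(params$cable_table)) {
      row <- params$cable_table[params$cable_table$fsu == fsu_name, ]
      if (nrow(row) == 1) {
        for (nm in names(cable_k))
          if (nm %in% names(row)) cable_k[[nm]] <- row[[nm]]
        scale_cab <- 1
      }
    }
    for (nm in names(at)) {
      ref_nm <- if (nm %in% c("ITL_left", "ITL_right")) "ITL" else nm
      w_up <- as.numeric(at[[nm]]$up); w_lo <- as.numeric(at[[nm]]$lo)
      L0 <- max(vnorm(w_lo - w_up), 0.5)
      elements[[length(elements) + 1]] <- new_cable(
        name = nm, body_i = k, body_j = k + 1,
        a_i = to_local(k, w_up), a_j = to_local(k + 1, w_lo),
        k = cable_k[[ref_nm]] * scale_cab, L0 = L0, fsu = fsu_name)
    }

    # disc center and FSU mid-frame
    c_lo <- if (lower_is_vert) lw(l, "sup_center") else proj(lw(u, "inf_center"))
    cc <- (lw(u, "inf_center") + c_lo) / 2
    R_u <- bodies[[k]]$R0; R_l <- bodies[[k + 1]]$R0
    R_mid <- R_u %*% rotvec_to_matrix(0.5 * matrix_to_rotvec(t(R_u) %*% R_l))

    diag6 <- function(v) diag(c(v[1:3], v[4:6] * 180 / pi))  # deg -> rad units
    tgt <- params$fsu_targets[[region]]
    tgt_diag <- c(tgt[["shear_ap"]], tgt[["shear_lat"]],
                  tgt[["axial_compression"]], tgt[["lateral_bending"]],
                  tgt[["flexion"]], tgt[["axial_rotation"]])
    prim <- if (!is.null(params$primary_diag))
      params$primary_diag[[region]] else tgt_diag
    prim <- prim * scale_fsu
    if (ribcage && region == "thoracic") {
      w <- params$ribcage
      add <- c(0, 0, 0,
               (w[["lateral_bending"]] - 1) * tgt_diag[4],
               (w[["flexion_extension"]] - 1) * tgt_diag[5],
               (w[["axial_rotation"]] - 1) * tgt_diag[6]) * scale_fsu
      prim <- prim + add
    }
    a_i <- to_local(k, cc); a_j <- to_local(k + 1, cc)
    B_i <- t(R_u) %*% R_mid; B_j <- t(R_l) %*% R_mid
    elements[[length(elements) + 1]] <- new_spring6(
      name = "primary_disc", body_i = k, body_j = k + 1,
      a_i = a_i, a_j = a_j, B_i = B_i, B_j = B_j,
      K = diag6(prim), fsu = fsu_name)
    fac <- if (!is.null(params$facet_diag))
      params$facet_diag[[region]] * scale_fsu else rep(0, 6)
    for (side in c("facet_left", "facet_right")) {
      elements[[length(elements) + 1]] <- new_spring6(
        name = side, body_i = k, body_j = k + 1,
        a_i = a_i, a_j = a_j, B_i = B_i, B_j = B_j,
        K = diag6(fac / 2), fsu = fsu_name)
    }
    fsu_rows[[k]] <- data.frame(name = fsu_name, upper = u, lower = l,
                                region = region, body_i = k, body_j = k + 1,
                                cx = cc[1], cy = cc[2], cz = cc[3],
                                stringsAsFactors = FALSE)
  }

  model <- list(bodies = bodies, body_index = body_index, fixed = fixed,
                elements = elements,
                meta = list(fsu = do.call(rbind, fsu_rows),
                            released = character(0),
                            ribcage = ribcage))
  class(model) <- "multibody_model"
  model
}

#' @export
print.multibody_model <- function(x, ...) {
  cat("<multibody_model>", length(x$bodies), "bodies,",
      length(x$elements), "elements,", nrow(x$meta$fsu), "FSUs\n")
  if (length(x$meta$released))
    cat("  released:", paste(x$meta$released, collapse = ", "), "\n")
  cat("  fixed bodies:",
      paste(rownames(x$fixed)[rowSums(x$fixed) == 6], collapse = ", "), "\n")
  invisible(x)
}

# elements of one FSU, optionally filtered by name
fsu_elements <- function(model, fsu_name, names = NULL) {
  which(vapply(model$elements, function(el) {
    !is.na(el$fsu) && el$fsu == fsu_name &&
      (is.null(names) || el$name %in% names)
  }, logical(1)))
}

#' Apply the pedicle-screw placement surgical release
#'
#' Removes, at every released FSU, the two facet-capsule springs and the
#' combined interspinous/supraspinous cable — the elements resected during
#' pedicle-screw placement. All other elements are untouched.
#'
#' @param model A `multibody_model`.
#' @param levels FSU names (`"T6-T7"`) or a set of vertebra labels, in
#'   which case every FSU with both bodies in the set is released (so the
#'   instrumented levels UIV..LIV release all their intermediate FSUs).
#' @return The released model.
#' @export
apply_surgical_release <- function(model, levels) {
  if (length(levels) == 0) return(model)
  if (all(grepl("-", levels, fixed = TRUE))) {
    sel <- levels
  } else {
    f <- model$meta$fsu
    sel <- f$name[f$upper %in% levels & f$lower %in% levels]
  }
  bad <- setdiff(sel, model$meta$fsu$name)
  if (length(bad)) stop("unknown FSU(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  drop <- vapply(model$elements, function(el) {
    !is.na(el$fsu) && el$fsu %in% sel &&
      el$name %in% c("facet_left", "facet_right", "ISL_SSL")
  }, logical(1))
  model$elements <- model$elements[!drop]
  model$meta$released <- union(model$meta$released, sel)
  model
}

#' Build a straight reference FSU (or longer segment) geometry
#'
#' Vertically stacked, jitter-free vertebrae of the requested consecutive
#' levels (no pelvis) — the harness for FSU-level calibration and probing.
#'
#' @param levels Character vector of consecutive level labels, cephalad
#'   first (e.g. `c("T6","T7")`).
#' @param height Patient height, cm (scales dimensions).
#' @return A `spine_geometry` without a pelvis.
#' @export
fsu_geometry <- function(levels = c("T6", "T7"), height = 170) {
  idx <- level_index(levels)
  if (any(diff(idx) != 1)) stop("levels must be consecutive", call. = FALSE)
  dims <- lapply(levels, vertebral_dimensions, height = height)
  z <- 0
  verts <- vector("list", length(levels))
  names(verts) <- levels
  for (i in seq_along(levels)) {
    if (i > 1) {
      z <- z - dims[[i - 1]][["height"]] / 2 - dims[[i - 1]][["disc"]] -
        dims[[i]][["height"]] / 2
    }
    verts[[i]] <- list(level = levels[i], center = c(0, 0, z), R = diag(3),
                       dims = dims[[i]], landmarks = vertebra_landmarks(dims[[i]]))
  }
  g <- list(vertebrae = verts, pelvis = NULL, height_cm = height)
  class(g) <- "spine_geometry"
  g
}

# Probe displacement definitions: mode -> rotation axis or translation dir
.probe_modes <- list(
  flexion = list(kind = "rot", axis = c(0, 1, 0)),
  extension = list(kind = "rot", axis = c(0, -1, 0)),
  lateral_bending = list(kind = "rot", axis = c(1, 0, 0)),
  axial_rotation = list(kind = "rot", axis = c(0, 0, 1)),
  axial_compression = list(kind = "trans", dir = c(0, 0, -1)),
  shear_ap = list(kind = "trans", dir = c(1, 0, 0)),
  shear_lat = list(kind = "trans", dir = c(0, 1, 0))
)

#' Secant stiffness of a functional spinal unit
#'
#' Small-displacement constrained probe: the whole body chain cephalad of
#' the FSU is displaced rigidly in the requested mode about the disc
#' center (rotations) or along the mode direction (translations), and the
#' conjugate restoring force of the model residual is read back.
#'
#' @param model A `multibody_model` whose bodies form a cephalocaudal
#'   chain (spine-only models).
#' @param level Upper vertebra label of the FSU, or the FSU name
#'   ("T6-T7").
#' @param mode One of `"flexion"`, `"extension"`, `"lateral_bending"`,
#'   `"axial_rotation"`, `"axial_compression"`, `"shear_ap"`,
#'   `"shear_lat"`.
#' @param delta Probe magnitude: degrees for rotations, mm for
#'   translations (default 0.5).
#' @return Secant stiffness: N.mm/deg for rotational modes, N/mm for
#'   translational modes.
#' @export
fsu_stiffness <- function(model, level, mode, delta = 0.5) {
  f <- model$meta$fsu
  row <- if (grepl("-", level, fixed = TRUE)) f[f$name == level, ] else
    f[f$upper == level, ]
  if (nrow(row) != 1) stop("unknown FSU '", level, "'", call. = FALSE)
  pm <- .probe_modes[[mode]]
  if (is.null(pm)) stop("unknown probe mode '", mode, "'", call. = FALSE)
  cc <- c(row$cx, row$cy, row$cz)
  group <- seq_len(row$body_i)
  state <- model_state(model)
  if (pm$kind == "rot") {
    th <- deg2rad(delta)
    Rot <- rotvec_to_matrix(th * pm$axis)
    for (b in group) {
      state$x[b, ] <- cc + Rot %*% (state$x[b, ] - cc)
      state$R[[b]] <- Rot %*% state$R[[b]]
    }
    Fg <- residual(model, state)
    m_tot <- c(0, 0, 0)
    for (b in group) {
      m_tot <- m_tot + Fg[b, 4:6] +
        c((state$x[b, 2] - cc[2]) * Fg[b, 3] - (state$x[b, 3] - cc[3]) * Fg[b, 2],
          (state$x[b, 3] - cc[3]) * Fg[b, 1] - (state$x[b, 1] - cc[1]) * Fg[b, 3],
          (state$x[b, 1] - cc[1]) * Fg[b, 2] - (state$x[b, 2] - cc[2]) * Fg[b, 1])
    }
    -sum(m_tot * pm$axis) / delta          # N.mm per degree
  } else {
    for (b in group) state$x[b, ] <- state$x[b, ] + delta * pm$dir
    Fg <- residual(model, state)
    f_tot <- colSums(Fg[group, 1:3, drop = FALSE])
    -sum(f_tot * pm$dir) / delta           # N per mm
  }
}
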