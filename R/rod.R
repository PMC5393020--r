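#' Build a contoured spinal rod
#'
#' The rod is a planar sagittal curve discretized into one node per
#' instrumented level (nodes are the screw-head seating points). Its
#' sagittal shape is a thoracic arc whose end tangents subtend the
#' contouring angle, blended with a lumbar lordotic arc when the
#' construct extends into the lumbar spine; in the coronal plane the rod
#' is a straight line between its end-level seating positions — the
#' geometric driver of coronal correction under segmental translation.
#'
#' Mechanically the rod is a chain of rigid nodes linked by 6-D beam
#' springs with slender-beam stiffness for a solid circular section
#' (default 5.5 mm cobalt-chrome, E = 230 GPa).
#'
#' @param side `"left"` or `"right"` (which pedicle column it seats on).
#' @param geometry Preoperative `spine_geometry`.
#' @param fused Instrumented levels UIV..LIV.
#' @param contour_angle Thoracic contouring angle, degrees (tangent
#'   subtension over the thoracic instrumented segment).
#' @param lumbar_angle Lumbar contouring angle, degrees.
#' @param diameter Rod diameter, mm.
#' @param E Elastic modulus, N/mm^2.
#' @param posterior_offset Seating offset posterior to the pedicle entry
#'   points, mm.
#' @param stiffness_scale Multiplier on all beam stiffnesses (large
#'   values emulate a rigid rod).
#' @return A `rod_def`: node positions/levels, beam stiffnesses, measured
#'   contour angle.
#' @export
contour_rod <- function(side = c("left", "right"), geometry, fused,
                        contour_angle = 25, lumbar_angle = 30,
                        diameter = 5.5, E = 230000, posterior_offset = 8,
                        stiffness_scale = 1) {
  side <- match.arg(side)
  ped <- paste0("pedicle_", side)
  anchors <- t(vapply(fused, function(lv) landmark_world(geometry, lv, ped),
                      numeric(3)))
  z <- anchors[, 3]
  thor <- is_thoracic(fused)
  n <- length(fused)

  # sagittal tangent-angle profile phi(z): linear sweep of the contour
  # angle over the thoracic segment, plus the opposite lumbar sweep
  z_top <- z[1]; z_bot <- z[n]
  z_jn <- if (any(!thor)) (min(z[thor]) + max(z[!thor])) / 2 else z_bot
  phi_at <- function(zz) {
    out <- numeric(length(zz))
    span_t <- z_top - z_jn
    if (span_t > 0) {
      tt <- pmin(pmax((z_top - zz) / span_t, 0), 1)
      out <- deg2rad(contour_angle) * (0.5 - tt)     # +A/2 at top -> -A/2
    }
    if (any(!thor)) {
      span_l <- z_jn - z_bot
      tl <- pmin(pmax((z_jn - zz) / span_l, 0), 1)
      out <- out + deg2rad(lumbar_angle) * tl        # lordotic sweep back
    }
    out
  }
  # integrate dx/dz = tan(phi) from the top node down
  xs <- numeric(n)
  grid_x <- function() {
    for (i in 2:n) {
      zz <- seq(z[i - 1], z[i], length.out = 9)
      dz <- diff(zz)
      ph <- phi_at((zz[-1] + zz[-9]) / 2)
      xs[i] <<- xs[i - 1] + sum(dz * tan(ph))
    }
  }
  if (n > 1) grid_x()
  # anchor the sagittal shape posterior to the pedicle column
  x_nodes <- xs + mean(anchors[c(1, n), 1] - xs[c(1, n)]) - posterior_offset
  # coronal line between the end seating points
  y_nodes <- anchors[1, 2] + (anchors[n, 2] - anchors[1, 2]) *
    (z_top - z) / max(z_top - z_bot, 1e-9)
  nodes <- cbind(x = x_nodes, y = y_nodes, z = z)

  # measured thoracic tangent subtension (for verification)
  thor_idx <- which(thor)
  measured <- if (length(thor_idx) >= 2) {
    rad2deg(phi_at(z[thor_idx[1]]) - phi_at(z[max(thor_idx)]))
  } else 0

  # slender-beam lumped stiffness per segment
  r <- diameter / 2
  A <- pi * r^2
  I <- pi * r^4 / 4
  G <- E / 2.6
  J <- 2 * I
  seg_len <- if (n > 1) sqrt(rowSums((nodes[-1, , drop = FALSE] -
                                        nodes[-n, , drop = FALSE])^2)) else numeric(0)
  beams <- lapply(seg_len, function(h) {
    c(shear = 12 * E * I / h^3, axial = E * A / h,
      bend = E * I / h, torsion = G * J / h) * stiffness_scale
  })
  out <- list(side = side, fused = fused, nodes = nodes,
              node_levels = fused, diameter = diameter, E = E,
              contour_angle = contour_angle, lumbar_angle = lumbar_angle,
              measured_contour = measured, beams = beams,
              stiffness_scale = stiffness_scale)
  class(out) <- "rod_def"
  out
}

#' @export
print.rod_def <- function(x, ...) {
  cat(sprintf("<rod_def> %s side, %d nodes (%s-%s), %.1f mm, contour %.1f deg (measured %.2f)\n",
              x$side, nrow(x$nodes), x$fused[1], x$fused[length(x$fused)],
              x$diameter, x$contour_angle, x$measured_contour))
  invisible(x)
}

# sagittal bow depth (max perpendicular deviation from the end chord)
rod_bow_depth <- function(rod) {
  nd <- rod$nodes
  n <- nrow(nd)
  chord <- nd[n, c(1, 3)] - nd[1, c(1, 3)]
  chord <- chord / vnorm(chord)
  rel <- sweep(nd[, c(1, 3)], 2, nd[1, c(1, 3)])
  max(abs(rel[, 1] * chord[2] - rel[, 2] * chord[1]))
}
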