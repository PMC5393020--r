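#' @title Spine geometry containers
#' @description
#' A `spine_geometry` holds, for each vertebra T1..L5, a rigid-body frame
#' (center position in mm plus a 3x3 rotation matrix, global frame) and a
#' set of named anatomical landmarks in the local frame: superior/inferior
#' endplate centers and corners, left/right pedicle entry points,
#' left/right transverse process tips, and the spinous process tip.
#' The pelvis is carried as a single additional rigid frame used as the
#' caudal boundary body.
#' @name spine_geometry
NULL

# Local landmark set of one vertebral body. Left/right pairs mirror across
# the local sagittal (XZ) plane before any jitter is applied; jitter is
# drawn mirror-symmetrically so the pairs remain exact mirror images.
vertebra_landmarks <- function(dims) {
  W <- dims[["width"]]; D <- dims[["depth"]]; H <- dims[["height"]]
  list(
    sup_center     = c(0, 0, H / 2),
    inf_center     = c(0, 0, -H / 2),
    sup_ant_left   = c(D / 2, W / 2, H / 2),
    sup_ant_right  = c(D / 2, -W / 2, H / 2),
    sup_post_left  = c(-D / 2, W / 2, H / 2),
    sup_post_right = c(-D / 2, -W / 2, H / 2),
    inf_ant_left   = c(D / 2, W / 2, -H / 2),
    inf_ant_right  = c(D / 2, -W / 2, -H / 2),
    inf_post_left  = c(-D / 2, W / 2, -H / 2),
    inf_post_right = c(-D / 2, -W / 2, -H / 2),
    pedicle_left   = c(-0.7 * D, 0.45 * W, 0.15 * H),
    pedicle_right  = c(-0.7 * D, -0.45 * W, 0.15 * H),
    transverse_left  = c(-0.35 * D, 0.95 * W, 0),
    transverse_right = c(-0.35 * D, -0.95 * W, 0),
    spinous        = c(-1.5 * D, 0, -0.2 * H)
  )
}

# Landmarks that sit on the local sagittal midline (jitter keeps y = 0)
# and the left-side landmarks whose jitter is mirrored onto the right.
.midline_landmarks <- c("sup_center", "inf_center", "spinous")
.left_landmarks <- c("sup_ant_left", "sup_post_left", "inf_ant_left",
                     "inf_post_left", "pedicle_left", "transverse_left")

mirror_name <- function(nm) sub("_left$", "_right", nm)

# Draw a mirror-symmetric landmark jitter set for one vertebra.
draw_landmark_jitter <- function(sd) {
  j <- list()
  for (nm in .midline_landmarks) {
    v <- stats::rnorm(2, 0, sd)
    j[[nm]] <- c(v[1], 0, v[2])
  }
  for (nm in .left_landmarks) {
    v <- stats::rnorm(3, 0, sd)
    j[[nm]] <- v
    j[[mirror_name(nm)]] <- c(v[1], -v[2], v[3])
  }
  j
}

#' World coordinates of a named landmark
#'
#' @param geometry A `spine_geometry`.
#' @param level Vertebral level label.
#' @param name Landmark name (see [spine_geometry]).
#' @return Numeric length-3 world position, mm.
#' @export
landmark_world <- function(geometry, level, name) {
  v <- geometry$vertebrae[[level]]
  if (is.null(v)) stop("no vertebra '", level, "' in geometry", call. = FALSE)
  p <- v$landmarks[[name]]
  if (is.null(p)) stop("vertebra ", level, " is missing landmark '", name,
                       "'", call. = FALSE)
  as.numeric(v$center + v$R %*% p)
}

# World endpoints of the coronal endplate line (midpoints of the left and
# right corner pairs) of the superior or inferior endplate.
endplate_line <- function(geometry, level, which = c("sup", "inf")) {
  which <- match.arg(which)
  l <- (landmark_world(geometry, level, paste0(which, "_ant_left")) +
          landmark_world(geometry, level, paste0(which, "_post_left"))) / 2
  r <- (landmark_world(geometry, level, paste0(which, "_ant_right")) +
          landmark_world(geometry, level, paste0(which, "_post_right"))) / 2
  list(left = l, right = r)
}

# Sagittal endplate direction (anterior->posterior midline of the plate).
endplate_sagittal_dir <- function(geometry, level, which = c("sup", "inf")) {
  which <- match.arg(which)
  if (level == "pelvis") {
    # S1 proxy: the pelvis frame's transverse plane, anterior direction
    return(as.numeric(geometry$pelvis$R %*% c(1, 0, 0)))
  }
  a <- (landmark_world(geometry, level, paste0(which, "_ant_left")) +
          landmark_world(geometry, level, paste0(which, "_ant_right"))) / 2
  p <- (landmark_world(geometry, level, paste0(which, "_post_left")) +
          landmark_world(geometry, level, paste0(which, "_post_right"))) / 2
  a - p
}

#' Validate a spine geometry
#'
#' Checks cephalocaudal ordering of the vertebral centers and that no two
#' adjacent vertebral bodies interpenetrate (center spacing at least 90%
#' of the sum of the half-heights).
#'
#' @param geometry A `spine_geometry`.
#' @return `geometry`, invisibly; errors name the violated constraint.
#' @export
validate_spine_geometry <- function(geometry) {
  stopifnot(inherits(geometry, "spine_geometry"))
  lv <- names(geometry$vertebrae)
  z <- vapply(geometry$vertebrae, function(v) v$center[3], numeric(1))
  if (any(diff(z) >= 0))
    stop("vertebral centers are not strictly ordered cephalad to caudad",
         call. = FALSE)
  for (i in seq_len(length(lv) - 1)) {
    a <- geometry$vertebrae[[i]]; b <- geometry$vertebrae[[i + 1]]
    gap <- vnorm(a$center - b$center)
    min_gap <- 0.9 * (a$dims[["height"]] + b$dims[["height"]]) / 2
    if (gap < min_gap)
      stop("vertebral bodies ", lv[i], " and ", lv[i + 1],
           " interpenetrate (spacing ", round(gap, 2), " mm < ",
           round(min_gap, 2), " mm)", call. = FALSE)
  }
  invisible(geometry)
}

#' @export
print.spine_geometry <- function(x, ...) {
  cat("<spine_geometry>", length(x$vertebrae), "vertebrae + pelvis\n")
  t1 <- x$vertebrae[[1]]$center; l5 <- x$vertebrae[[length(x$vertebrae)]]$center
  cat(sprintf("  T1 center  (%.1f, %.1f, %.1f) mm\n", t1[1], t1[2], t1[3]))
  cat(sprintf("  L5 center  (%.1f, %.1f, %.1f) mm\n", l5[1], l5[2], l5[3]))
  invisible(x)
}

#' Export a spine geometry as JSON
#'
#' Writes per-vertebra frames (center, rotation matrix rows) and local
#' landmark coordinates under documented key names
#' (`vertebrae/<level>/{center,rotation,landmarks}` and
#' `pelvis/{center,rotation}`).
#'
#' @param geometry A `spine_geometry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spine_json <- function(geometry, path) {
  obj <- list(
    coordinate_frame = "right-handed; X anterior, Y patient-left, Z cephalad; mm",
    vertebrae = lapply(geometry$vertebrae, function(v) {
      list(level = v$level, center = v$center,
           rotation = lapply(1:3, function(i) v$R[i, ]),
           dims = as.list(v$dims), landmarks = v$landmarks)
    }),
    pelvis = list(center = geometry$pelvis$center,
                  rotation = lapply(1:3, function(i) geometry$pelvis$R[i, ]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export landmark point cloud as Wavefront OBJ
#'
#' Convenience visualization export: every landmark of every vertebra as an
#' OBJ vertex.
#'
#' @param geometry A `spine_geometry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spine_obj <- function(geometry, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# scolisim landmark point cloud (mm)", con)
  for (v in geometry$vertebrae) {
    for (nm in names(v$landmarks)) {
      p <- as.numeric(v$center + v$R %*% v$landmarks[[nm]])
      writeLines(sprintf("v %.4f %.4f %.4f", p[1], p[2], p[3]), con)
    }
  }
  invisible(path)
}
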