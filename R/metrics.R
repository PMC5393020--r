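#' Coronal Cobb angle between two end vertebrae
#'
#' The classic radiographic measure: the angle between the coronal-plane
#' (YZ) projections of the upper end vertebra's superior endplate line and
#' the lower end vertebra's inferior endplate line, each line taken through
#' the left/right endplate corner landmarks.
#'
#' @param geometry A `spine_geometry`.
#' @param upper_end,lower_end Level labels; `upper_end` cephalad of
#'   `lower_end`.
#' @return Angle in degrees, in `[0, 180)`.
#' @export
#' @examples
#' g <- generate_spine(bundled_cases()[[1]], seed = 1)
#' cobb_angle(g, "T6", "T12")
cobb_angle <- function(geometry, upper_end, lower_end) {
  if (level_index(upper_end) >= level_index(lower_end))
    stop("invalid level pair: '", upper_end, "' must be cephalad of '",
         lower_end, "'", call. = FALSE)
  u <- endplate_line(geometry, upper_end, "sup")
  l <- endplate_line(geometry, lower_end, "inf")
  du <- (u$left - u$right)[c(2, 3)]   # coronal (YZ) projection
  dl <- (l$left - l$right)[c(2, 3)]
  tilt <- function(d) atan2(d[2], d[1])          # tilt vs the Y axis
  a <- rad2deg(abs(tilt(du) - tilt(dl)))
  a <- a %% 180
  a
}

#' Sagittal Cobb angle (kyphosis / lordosis)
#'
#' Signed angle between the sagittal-plane (XZ) projections of the upper
#' superior and lower inferior endplate directions. With
#' `positive = "kyphosis"` a posteriorly convex (thoracic) curve is
#' positive; with `positive = "lordosis"` an anteriorly convex (lumbar)
#' curve is positive. `lower_end = "pelvis"` uses the pelvis frame's
#' transverse plane as the S1 endplate proxy.
#'
#' @param geometry A `spine_geometry`.
#' @param upper_end Level label.
#' @param lower_end Level label or "pelvis".
#' @param positive Sign convention, `"kyphosis"` or `"lordosis"`.
#' @return Signed angle in degrees.
#' @export
sagittal_angle <- function(geometry, upper_end, lower_end,
                           positive = c("kyphosis", "lordosis")) {
  positive <- match.arg(positive)
  if (lower_end != "pelvis" && level_index(upper_end) >= level_index(lower_end))
    stop("invalid level pair: '", upper_end, "' must be cephalad of '",
         lower_end, "'", call. = FALSE)
  du <- endplate_sagittal_dir(geometry, upper_end, "sup")[c(1, 3)]
  dl <- endplate_sagittal_dir(geometry, lower_end, "inf")[c(1, 3)]
  tilt <- function(d) atan2(d[2], d[1])          # tilt vs the X axis
  a <- rad2deg(tilt(dl) - tilt(du))
  a <- ((a + 180) %% 360) - 180
  if (positive == "lordosis") a <- -a
  a
}

#' Apical vertebral rotation
#'
#' Transverse-plane (XY) angle between the apical vertebra's local sagittal
#' (anterior) axis and the global sagittal plane — a projection-type axial
#' rotation measure.
#'
#' @param geometry A `spine_geometry`.
#' @param apex Level label of the apical vertebra.
#' @return Angle in degrees, in `[0, 90]`.
#' @export
apical_rotation <- function(geometry, apex) {
  v <- geometry$vertebrae[[apex]]
  if (is.null(v)) stop("no vertebra '", apex, "' in geometry", call. = FALSE)
  ax <- as.numeric(v$R %*% c(1, 0, 0))   # local anterior axis, world frame
  a <- rad2deg(abs(atan2(ax[2], ax[1])))
  if (a > 90) a <- 180 - a
  a
}

#' Measure the full set of clinical indices on a geometry
#'
#' Computes the regional coronal Cobb angles, thoracic kyphosis (T2-T12),
#' lumbar lordosis (L1-pelvis), and apical vertebral rotations, using the
#' end/apex levels recorded in `indices`.
#'
#' @param geometry A `spine_geometry`.
#' @param indices The `clinical_indices` whose curve levels define the
#'   measurement frames.
#' @param kyphosis_levels,lordosis_levels Measurement levels, overridable;
#'   defaults are the common radiographic conventions T2-T12 and
#'   L1-pelvis (S1 proxy).
#' @return An `index_report`: named list of angles (degrees) plus the
#'   levels used.
#' @export
index_report <- function(geometry, indices,
                         kyphosis_levels = c("T2", "T12"),
                         lordosis_levels = c("L1", "pelvis")) {
  tll_apex <- tll_apex_level(indices)
  rep <- list(
    pt_cobb = cobb_angle(geometry, indices$pt_sup_end, indices$mt_sup_end),
    mt_cobb = cobb_angle(geometry, indices$mt_sup_end, indices$mt_inf_end),
    tll_cobb = cobb_angle(geometry, indices$mt_inf_end, indices$tll_inf_end),
    kyphosis = sagittal_angle(geometry, kyphosis_levels[1], kyphosis_levels[2],
                              positive = "kyphosis"),
    lordosis = sagittal_angle(geometry, lordosis_levels[1], lordosis_levels[2],
                              positive = "lordosis"),
    mt_avr = apical_rotation(geometry, indices$mt_apex),
    tll_avr = apical_rotation(geometry, tll_apex),
    levels = list(pt = c(indices$pt_sup_end, indices$mt_sup_end),
                  mt = c(indices$mt_sup_end, indices$mt_apex, indices$mt_inf_end),
                  tll = c(indices$mt_inf_end, tll_apex, indices$tll_inf_end),
                  kyphosis = kyphosis_levels, lordosis = lordosis_levels)
  )
  class(rep) <- "index_report"
  rep
}

# TL/L apical vertebra: midpoint of the TL/L curve span (not printed in
# standard case tables).
tll_apex_level <- function(indices) {
  a <- level_index(indices$mt_inf_end); b <- level_index(indices$tll_inf_end)
  level_label(floor((a + b) / 2))
}

#' @export
print.index_report <- function(x, ...) {
  cat("<index_report>\n")
  cat(sprintf("  Cobb  PT %.1f  MT %.1f  TL/L %.1f deg\n",
              x$pt_cobb, x$mt_cobb, x$tll_cobb))
  cat(sprintf("  kyphosis %.1f  lordosis %.1f deg\n", x$kyphosis, x$lordosis))
  cat(sprintf("  AVR  MT %.1f  TL/L %.1f deg\n", x$mt_avr, x$tll_avr))
  invisible(x)
}

#' One-row data-frame form of an index report
#' @param x An `index_report`.
#' @param ... Unused.
#' @return A one-row data frame of the angle fields.
#' @export
as.data.frame.index_report <- function(x, ...) {
  data.frame(pt_cobb = x$pt_cobb, mt_cobb = x$mt_cobb, tll_cobb = x$tll_cobb,
             kyphosis = x$kyphosis, lordosis = x$lordosis,
             mt_avr = x$mt_avr, tll_avr = x$tll_avr)
}
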