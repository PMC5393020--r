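#' Default stiffness parameters
#'
#' Bundles every stiffness quantity of the intervertebral connection:
#'
#' * Reference tension stiffnesses of the six ligament cables for the
#'   T6-T7 functional spinal unit (N/mm): 23.6 (anterior longitudinal
#'   ligament), 24.9 (posterior longitudinal ligament), 32.6 (ligamentum
#'   flavum), 12.9 (each intertransverse ligament), 32.1 (interspinous
#'   combined with supraspinous ligament). Other levels are scaled by the
#'   vertebral-body depth ratio (a cross-section proxy), overridable via
#'   `cable_table`.
#' * Load-displacement targets of the reference intact FSU per probe mode
#'   (rotations N.mm/deg, translations N/mm) for a thoracic (T6-T7) and a
#'   lumbar (L2-L3) reference unit. These targets are a documented modeling
#'   assumption representative of published cadaveric FSU data; the primary
#'   disc spring is calibrated against them.
#' * Rib-cage weighting factors applied to the thoracic primary-spring
#'   rotational stiffness: +40% flexion/extension, +35% lateral bending,
#'   +31% axial rotation.
#' * Stiffness reductions from the pedicle-screw placement surgical release
#'   (facetectomy + interspinous resection): 17% axial rotation, 15%
#'   flexion, 3.8% coronal-plane bending, 14% axial compression. The
#'   calibration module partitions the removed-element stiffness so the
#'   released FSU reproduces these.
#'
#' The primary-spring and facet-spring diagonals are calibration outputs
#' (`NULL` until [calibrate_fsu()] / [calibrate_release_partition()] run;
#' see [calibrated_params()] for the one-call version).
#'
#' @return A `stiffness_params` object.
#' @export
#' @examples
#' p <- default_stiffness_params()
#' p$cable_ref[["ALL"]]   # 23.6 N/mm
default_stiffness_params <- function() {
  p <- list(
    cable_ref = c(ALL = 23.6, PLL = 24.9, LF = 32.6, ITL = 12.9,
                  ISL_SSL = 32.1),
    cable_table = NULL,
    fsu_targets = list(
      thoracic = c(shear_ap = 250, shear_lat = 250, axial_compression = 1200,
                   lateral_bending = 2000, flexion = 2000,
                   axial_rotation = 2000),
      lumbar = c(shear_ap = 350, shear_lat = 350, axial_compression = 1700,
                 lateral_bending = 2600, flexion = 2400,
                 axial_rotation = 3600)
    ),
    ribcage = c(flexion_extension = 1.40, lateral_bending = 1.35,
                axial_rotation = 1.31),
    release_reduction = c(axial_rotation = 0.17, flexion = 0.15,
                          coronal_bending = 0.038, axial_compression = 0.14),
    # fraction of the spinous-process offset at which the combined
    # interspinous/supraspinous cable attaches (moment-arm control)
    isl_attach_frac = 0.35,
    primary_diag = NULL,   # list(thoracic=, lumbar=) c(kx,ky,kz,krx,kry,krz)
    facet_diag = NULL      # same layout; per FSU, split over left/right
  )
  class(p) <- "stiffness_params"
  p
}

#' @export
print.stiffness_params <- function(x, ...) {
  cat("<stiffness_params>\n  cables (T6-T7, N/mm):",
      paste(names(x$cable_ref), x$cable_ref, sep = "=", collapse = " "), "\n")
  cat("  ribcage weighting:",
      paste(names(x$ribcage), x$ribcage, sep = "=", collapse = " "), "\n")
  cat("  release reductions:",
      paste(names(x$release_reduction), x$release_reduction, sep = "=",
            collapse = " "), "\n")
  cat("  calibrated:", !is.null(x$primary_diag) && !is.null(x$facet_diag), "\n")
  invisible(x)
}

# Flatten to / restore from a human-editable flat key-value config.
# Units are carried in the key names.

#' Write stiffness parameters to a flat YAML config file
#' @param params A `stiffness_params`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stiffness_config <- function(params, path) {
  flat <- list()
  for (nm in names(params$cable_ref))
    flat[[paste0("cable_", nm, "_N_per_mm")]] <- params$cable_ref[[nm]]
  for (reg in names(params$fsu_targets))
    for (nm in names(params$fsu_targets[[reg]]))
      flat[[paste0("fsu_", reg, "_", nm, "_target")]] <-
        params$fsu_targets[[reg]][[nm]]
  for (nm in names(params$ribcage))
    flat[[paste0("ribcage_", nm, "_factor")]] <- params$ribcage[[nm]]
  for (nm in names(params$release_reduction))
    flat[[paste0("release_", nm, "_fraction")]] <- params$release_reduction[[nm]]
  flat[["isl_attach_frac"]] <- params$isl_attach_frac
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Read stiffness parameters back from a flat YAML config file
#' @param path Config path written by [write_stiffness_config()].
#' @return A `stiffness_params` (uncalibrated).
#' @export
read_stiffness_config <- function(path) {
  flat <- yaml::read_yaml(path)
  p <- default_stiffness_params()
  for (nm in names(p$cable_ref)) {
    key <- paste0("cable_", nm, "_N_per_mm")
    if (!is.null(flat[[key]])) p$cable_ref[[nm]] <- flat[[key]]
  }
  for (reg in names(p$fsu_targets))
    for (nm in names(p$fsu_targets[[reg]])) {
      key <- paste0("fsu_", reg, "_", nm, "_target")
      if (!is.null(flat[[key]])) p$fsu_targets[[reg]][[nm]] <- flat[[key]]
    }
  for (nm in names(p$ribcage)) {
    key <- paste0("ribcage_", nm, "_factor")
    if (!is.null(flat[[key]])) p$ribcage[[nm]] <- flat[[key]]
  }
  for (nm in names(p$release_reduction)) {
    key <- paste0("release_", nm, "_fraction")
    if (!is.null(flat[[key]])) p$release_reduction[[nm]] <- flat[[key]]
  }
  if (!is.null(flat[["isl_attach_frac"]]))
    p$isl_attach_frac <- flat[["isl_attach_frac"]]
  p
}

# depth-ratio stiffness scale of an FSU relative to a reference level pair
fsu_depth_scale <- function(geometry, upper, lower, ref = c("T6", "T7")) {
  dep <- function(lv) {
    if (lv == "pelvis") lv <- "L5"
    v <- geometry$vertebrae[[lv]]
    if (!is.null(v)) return(v$dims[["depth"]])
    tab <- vertebral_dimension_table()
    tab$depth[match(lv, tab$level)] * geometry$height_cm / 170
  }
  tab <- vertebral_dimension_table()
  ref_d <- mean(tab$depth[match(ref, tab$level)]) * geometry$height_cm / 170
  (dep(upper) + dep(lower)) / 2 / ref_d
}
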