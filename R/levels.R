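#' Vertebral level labels
#'
#' The modeled column runs from T1 down to L5; the pelvis is appended as the
#' caudal boundary body. Levels are addressed by their clinical labels
#' ("T1".."T12", "L1".."L5") and internally by an index increasing in the
#' caudal direction (T1 = 1, ..., L5 = 17).
#'
#' @return Character vector of the 17 vertebral level labels, cephalad first.
#' @export
#' @examples
#' vertebral_levels()
vertebral_levels <- function() {
  c(paste0("T", 1:12), paste0("L", 1:5))
}

#' Convert a level label to its cephalocaudal index
#'
#' @param level Character vector of level labels (e.g. "T6", "L2"). "pelvis"
#'   maps to 18, directly caudal to L5.
#' @return Integer index (T1 = 1 ... L5 = 17, pelvis = 18).
#' @export
level_index <- function(level) {
  lv <- c(vertebral_levels(), "pelvis")
  idx <- match(level, lv)
  if (anyNA(idx)) {
    stop("unknown vertebral level label: ",
         paste(unique(level[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}

#' Convert a cephalocaudal index back to its level label
#' @param idx Integer index in 1..18.
#' @return Level label ("T1".."L5", "pelvis").
#' @export
level_label <- function(idx) {
  lv <- c(vertebral_levels(), "pelvis")
  if (any(idx < 1L | idx > length(lv))) {
    stop("level index out of range 1..18", call. = FALSE)
  }
  lv[idx]
}

#' Enumerate the levels spanned by an inclusive cephalad..caudad range
#' @param upper,lower Level labels; `upper` must be cephalad of `lower`.
#' @return Character vector of labels from `upper` to `lower`.
#' @export
level_range <- function(upper, lower) {
  i <- level_index(upper); j <- level_index(lower)
  if (i >= j) stop("'", upper, "' is not cephalad of '", lower, "'", call. = FALSE)
  level_label(seq(i, j))
}

is_thoracic <- function(level) startsWith(level, "T")
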