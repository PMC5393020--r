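#' Default vertebral body dimension table
#'
#' Anthropometric reference dimensions (mm) of the T1..L5 vertebral bodies
#' for a 170 cm adolescent: transverse endplate width, anteroposterior
#' depth, body height, and the height of the subjacent intervertebral disc.
#' Values increase monotonically from the upper thoracic to the lower
#' lumbar spine, consistent with published morphometric series.
#'
#' @return Data frame with columns `level`, `width`, `depth`, `height`,
#'   `disc` (all mm, reference height 170 cm).
#' @export
vertebral_dimension_table <- function() {
  lv <- vertebral_levels()
  n <- length(lv)
  t <- (seq_len(n) - 1) / (n - 1)            # 0 at T1, 1 at L5
  data.frame(
    level  = lv,
    width  = round(26 + 24 * t, 2),          # 26 -> 50 mm
    depth  = round(17 + 18 * t, 2),          # 17 -> 35 mm
    height = round(16 + 12 * t, 2),          # 16 -> 28 mm
    disc   = round(4 + 7 * t, 2),            # 4  -> 11 mm
    stringsAsFactors = FALSE
  )
}

#' Vertebral body dimensions scaled to patient height
#'
#' Scales the reference dimension table linearly by standing height about
#' the 170 cm reference, so all dimensions are proportional to patient
#' height and nondecreasing from T1 to L5.
#'
#' @param level Vertebral level label ("T1".."L5").
#' @param height Patient standing height, cm (120..200).
#' @return Named numeric vector `c(width, depth, height, disc)` in mm.
#' @export
#' @examples
#' vertebral_dimensions("T6", 170)
vertebral_dimensions <- function(level, height) {
  if (!is.numeric(height) || height < 120 || height > 200)
    stop("patient height must lie in 120..200 cm", call. = FALSE)
  tab <- vertebral_dimension_table()
  i <- match(level, tab$level)
  if (is.na(i)) stop("unknown vertebral level label: ", level, call. = FALSE)
  s <- height / 170
  c(width = tab$width[i] * s, depth = tab$depth[i] * s,
    height = tab$height[i] * s, disc = tab$disc[i] * s)
}
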