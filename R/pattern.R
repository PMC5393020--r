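#' Build a pedicle-screw pattern
#'
#' Pattern 1 is the maximal-density reference: bilateral polyaxial screws
#' with dorsal height adjustability at every level fused. The four
#' alternative patterns drop screws on one side while always keeping UIV
#' and LIV bilateral:
#'
#' * pattern 2 / 3 — convex / concave *alternate* dropouts: every other
#'   interior level starting one level caudal to UIV. For constructs of
#'   eight or more levels with an even level count, strict alternation
#'   strands two adjacent bilateral levels above LIV; the level adjacent
#'   to LIV is then also dropped, which keeps the per-construct screw
#'   reduction in the 21-25% envelope of the study's constructs.
#' * pattern 4 / 5 — convex / concave *periapical* dropouts: the same
#'   number of dropouts as the alternate patterns for the same construct,
#'   at consecutive interior levels centered on the apical vertebra
#'   (clamped inside the interior).
#'
#' Screw diameters: 5.0 mm thoracic, 6.0 mm lumbar (within the 4.5-5.5 /
#' 5.5-6.0 mm envelopes).
#'
#' @param fused Contiguous fused levels, cephalad first (UIV..LIV), at
#'   least 4 levels.
#' @param apex Apical vertebra (must be interior to `fused`).
#' @param convex_side `"left"` or `"right"` — side of the main curve
#'   convexity.
#' @param pattern_id 1..5.
#' @return A `screw_pattern`: screw table (level, side, diameter), dropped
#'   screws, fused levels and bookkeeping.
#' @export
#' @examples
#' p2 <- make_pattern(level_range("T4", "L2"), "T9", "right", 2)
#' nrow(p2$screws)   # 17 = 22 - 5 dropouts
make_pattern <- function(fused, apex, convex_side = c("right", "left"),
                         pattern_id) {
  convex_side <- match.arg(convex_side)
  stopifnot(pattern_id %in% 1:5)
  n <- length(fused)
  if (n < 4) stop("at least 4 fused levels are required", call. = FALSE)
  idx <- level_index(fused)
  if (any(diff(idx) != 1)) stop("fused levels must be contiguous", call. = FALSE)
  apos <- match(apex, fused)
  if (is.na(apos) || apos == 1 || apos == n)
    stop("apex '", apex, "' must be an interior fused level", call. = FALSE)
  concave_side <- if (convex_side == "left") "right" else "left"

  alternate_positions <- function(n) {
    pos <- seq(2, n - 1, by = 2)
    if (n >= 8 && n %% 2 == 0) pos <- union(pos, n - 1)
    pos
  }
  drop_pos <- integer(0)
  drop_side <- character(0)
  if (pattern_id >= 2) {
    alt <- alternate_positions(n)
    d <- length(alt)
    side <- if (pattern_id %in% c(2, 4)) convex_side else concave_side
    if (pattern_id %in% c(2, 3)) {
      drop_pos <- alt
    } else {
      start <- apos - floor((d - 1) / 2)
      start <- max(2, min(start, n - d))
      drop_pos <- seq(start, length.out = d)
    }
    drop_side <- rep(side, length(drop_pos))
  }

  diam <- ifelse(is_thoracic(fused), 5.0, 6.0)
  screws <- data.frame(level = rep(fused, each = 2),
                       side = rep(c("left", "right"), n),
                       diameter = rep(diam, each = 2),
                       stringsAsFactors = FALSE)
  dropped <- data.frame(level = fused[drop_pos], side = drop_side,
                        stringsAsFactors = FALSE)
  if (nrow(dropped)) {
    keep <- !(paste(screws$level, screws$side) %in%
                paste(dropped$level, dropped$side))
    screws <- screws[keep, ]
  }
  out <- list(pattern_id = pattern_id, fused = fused, apex = apex,
              convex_side = convex_side, screws = screws, dropped = dropped,
              n_reference = 2L * n)
  class(out) <- "screw_pattern"
  out
}

#' @export
print.screw_pattern <- function(x, ...) {
  cat(sprintf("<screw_pattern> #%d: %d screws over %d levels (%s-%s), %d dropped\n",
              x$pattern_id, nrow(x$screws), length(x$fused), x$fused[1],
              x$fused[length(x$fused)], nrow(x$dropped)))
  if (nrow(x$dropped))
    cat("  dropouts:", paste(x$dropped$level, x$dropped$side, collapse = ", "),
        "\n")
  invisible(x)
}

#' Screw-count reduction and density statistics
#'
#' For a collection of screw patterns (typically all five patterns over a
#' cohort): per-construct reduction percentage relative to the bilateral
#' reference, screw density (screws per level fused), and per-pattern
#' aggregates.
#'
#' @param patterns List of `screw_pattern` objects.
#' @return List with `per_construct` and `per_pattern` data frames and
#'   `overall_alternative_mean`, the mean reduction over all alternative
#'   (pattern 2-5) constructs.
#' @export
reduction_stats <- function(patterns) {
  per <- do.call(rbind, lapply(seq_along(patterns), function(i) {
    p <- patterns[[i]]
    data.frame(construct = i, pattern_id = p$pattern_id,
               n_levels = length(p$fused), n_screws = nrow(p$screws),
               n_dropped = nrow(p$dropped),
               density = nrow(p$screws) / length(p$fused),
               reduction_pct = 100 * nrow(p$dropped) / p$n_reference)
  }))
  agg <- do.call(rbind, lapply(split(per, per$pattern_id), function(d) {
    data.frame(pattern_id = d$pattern_id[1], n_constructs = nrow(d),
               mean_reduction_pct = mean(d$reduction_pct),
               min_reduction_pct = min(d$reduction_pct),
               max_reduction_pct = max(d$reduction_pct),
               mean_density = mean(d$density))
  }))
  alt <- per$reduction_pct[per$pattern_id >= 2]
  list(per_construct = per, per_pattern = agg,
       overall_alternative_mean = if (length(alt)) mean(alt) else NA_real_)
}
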