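#' Summarize a cohort of instrumentation simulations
#'
#' Collects, over all cases and screw patterns: the corrected geometric
#' indices (main thoracic Cobb, thoracic kyphosis, apical vertebral
#' rotation, plus the other measured indices), pooled bone-screw force
#' statistics per pattern (all screws of all cases), screw-count
#' reduction statistics, and per-case deviations of every alternative
#' pattern from the reference pattern.
#'
#' @param runs A list with one entry per case, each
#'   `list(indices =, results = list of simulation_result keyed by
#'   pattern id)` — the structure produced by [run_pipeline()].
#' @return A `cohort_summary`.
#' @export
summarize_cohort <- function(runs) {
  idx_rows <- list(); force_rows <- list(); pat_list <- list()
  for (run in runs) {
    ci <- run$indices
    pre <- index_report(run$geometry, ci)
    idx_rows[[length(idx_rows) + 1]] <- data.frame(
      case_id = ci$case_id, pattern_id = 0L,
      mt_cobb = pre$mt_cobb, kyphosis = pre$kyphosis, mt_avr = pre$mt_avr,
      pt_cobb = pre$pt_cobb, tll_cobb = pre$tll_cobb,
      lordosis = pre$lordosis, tll_avr = pre$tll_avr,
      converged = NA, stringsAsFactors = FALSE)
    for (res in run$results) {
      if (is.null(res)) next
      r <- res$report
      idx_rows[[length(idx_rows) + 1]] <- data.frame(
        case_id = ci$case_id, pattern_id = res$pattern_id,
        mt_cobb = r$mt_cobb, kyphosis = r$kyphosis, mt_avr = r$mt_avr,
        pt_cobb = r$pt_cobb, tll_cobb = r$tll_cobb,
        lordosis = r$lordosis, tll_avr = r$tll_avr,
        converged = res$converged, stringsAsFactors = FALSE)
      sf <- res$screw_forces
      sf$case_id <- ci$case_id
      sf$pattern_id <- res$pattern_id
      force_rows[[length(force_rows) + 1]] <- sf
      pat_list[[length(pat_list) + 1]] <- res$pattern
    }
  }
  indices <- do.call(rbind, idx_rows)
  forces <- do.call(rbind, force_rows)
  pooled <- do.call(rbind, lapply(split(forces, forces$pattern_id), function(d)
    data.frame(pattern_id = d$pattern_id[1], n_screws = nrow(d),
               mean = mean(d$magnitude), sd = stats::sd(d$magnitude),
               min = min(d$magnitude), max = max(d$magnitude))))
  rownames(pooled) <- NULL

  # per-case deviation of each alternative pattern from the reference
  dev_rows <- list()
  ref <- indices[indices$pattern_id == 1, ]
  for (k in setdiff(unique(indices$pattern_id), c(0L, 1L))) {
    alt <- indices[indices$pattern_id == k, ]
    mref <- ref[match(alt$case_id, ref$case_id), ]
    dev_rows[[length(dev_rows) + 1]] <- data.frame(
      case_id = alt$case_id, pattern_id = k,
      d_mt_cobb = alt$mt_cobb - mref$mt_cobb,
      d_kyphosis = alt$kyphosis - mref$kyphosis,
      d_mt_avr = alt$mt_avr - mref$mt_avr)
  }
  deviations <- if (length(dev_rows)) do.call(rbind, dev_rows) else NULL

  out <- list(indices = indices, forces = forces, pooled_forces = pooled,
              deviations = deviations,
              reductions = reduction_stats(pat_list))
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>", length(unique(x$indices$case_id)), "cases,",
      length(setdiff(unique(x$indices$pattern_id), 0)), "patterns\n")
  cat("  pooled bone-screw forces (N):\n")
  print(x$pooled_forces, row.names = FALSE, digits = 3)
  if (!is.null(x$deviations)) {
    cat(sprintf("  max |MT Cobb deviation| from reference: %.1f deg\n",
                max(abs(x$deviations$d_mt_cobb))))
    cat(sprintf("  max |kyphosis/AVR deviation|: %.1f / %.1f deg\n",
                max(abs(x$deviations$d_kyphosis)),
                max(abs(x$deviations$d_mt_avr))))
  }
  invisible(x)
}

#' Pairwise statistical comparison of bone-screw forces between patterns
#'
#' Primary test: Welch two-sample t on the pooled per-screw force
#' magnitudes of each pattern pair. Sensitivity output: paired t on
#' per-case mean forces. Also reports the grouped comparison of the
#' alternate-dropout patterns (2, 3) versus the periapical patterns
#' (4, 5). Raw and Holm-adjusted p-values are both reported.
#'
#' @param summary A `cohort_summary` (or the `forces` data frame).
#' @return Data frame with one row per comparison: difference of means,
#'   test statistic, raw and Holm-adjusted two-sided p for the pooled
#'   Welch test, and the paired-t p where both patterns cover the same
#'   cases.
#' @export
compare_patterns <- function(summary) {
  forces <- if (inherits(summary, "cohort_summary")) summary$forces else summary
  pats <- sort(unique(forces$pattern_id))
  if (length(pats) < 2) {
    return(data.frame(comparison = character(), mean_a = numeric(),
                      mean_b = numeric(), diff_means = numeric(),
                      statistic = numeric(), p_welch = numeric(),
                      p_paired = numeric(), p_holm = numeric()))
  }
  combos <- utils::combn(pats, 2, simplify = FALSE)
  rows <- list()
  grab <- function(ids) forces$magnitude[forces$pattern_id %in% ids]
  per_case_mean <- function(ids) {
    d <- forces[forces$pattern_id %in% ids, ]
    tapply(d$magnitude, d$case_id, mean)
  }
  run_test <- function(label, ids_a, ids_b) {
    a <- grab(ids_a); b <- grab(ids_b)
    identical_samples <- length(a) == length(b) && all(sort(a) == sort(b))
    if (identical_samples) {
      wt <- list(statistic = 0, p.value = 1)
    } else {
      wt <- stats::t.test(a, b)
    }
    ma <- per_case_mean(ids_a); mb <- per_case_mean(ids_b)
    common <- intersect(names(ma), names(mb))
    pt <- if (length(common) >= 3 && !identical_samples &&
              stats::sd(ma[common] - mb[common]) > 0) {
      stats::t.test(ma[common], mb[common], paired = TRUE)$p.value
    } else NA_real_
    data.frame(comparison = label,
               mean_a = mean(a), mean_b = mean(b),
               diff_means = mean(a) - mean(b),
               statistic = unname(wt$statistic), p_welch = wt$p.value,
               p_paired = pt, stringsAsFactors = FALSE)
  }
  for (cb in combos) {
    rows[[length(rows) + 1]] <- run_test(paste0("pattern", cb[1], "_vs_",
                                                cb[2]), cb[1], cb[2])
  }
  if (all(c(2, 3, 4, 5) %in% pats)) {
    rows[[length(rows) + 1]] <- run_test("alternate_vs_periapical",
                                         c(2, 3), c(4, 5))
  }
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_welch, method = "holm")
  out
}
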