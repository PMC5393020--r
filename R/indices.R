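#' Clinical indices of one scoliosis case
#'
#' Bundles the radiographic measurements that drive the patient-specific
#' model: regional coronal Cobb angles (proximal thoracic PT, main thoracic
#' MT, thoracolumbar/lumbar TL/L) with their side-bending values, apical
#' vertebral rotations, sagittal kyphosis and lordosis, the curve landmark
#' levels, and the instrumented segment (UIV to LIV).
#'
#' All angles are in degrees and non-negative; side-bending values are the
#' Cobb angles re-measured on voluntary left/right bending radiographs.
#'
#' @param case_id Case label.
#' @param sex "F" or "M".
#' @param age Years.
#' @param height Standing height, cm (must lie in 120..200).
#' @param weight Body mass, kg.
#' @param lenke Lenke classification label (e.g. "1A").
#' @param pt_sup_end,mt_sup_end,mt_apex,mt_inf_end Curve landmark levels.
#'   The PT curve spans `pt_sup_end` to `mt_sup_end`; the MT curve spans
#'   `mt_sup_end` to `mt_inf_end` with apex `mt_apex`.
#' @param pt_cobb,mt_cobb,tll_cobb Preoperative coronal Cobb angles, deg.
#' @param pt_bend_left,pt_bend_right,mt_bend_left,mt_bend_right,tll_bend_left,tll_bend_right
#'   Side-bending Cobb angles, deg.
#' @param mt_avr,tll_avr Apical vertebral rotations, deg.
#' @param kyphosis,lordosis Sagittal angles, deg.
#' @param uiv,liv Upper and lower instrumented vertebrae.
#' @param tll_inf_end Inferior end vertebra of the TL/L curve. Not part of
#'   the standard case-table schema; defaults to "L4".
#' @return An object of class `clinical_indices` (a named list).
#' @export
#' @examples
#' ci <- bundled_cases()[[1]]
#' ci$mt_cobb
clinical_indices <- function(case_id, sex, age, height, weight, lenke,
                             pt_sup_end, mt_sup_end, mt_apex, mt_inf_end,
                             pt_cobb, mt_cobb, tll_cobb,
                             pt_bend_left, pt_bend_right,
                             mt_bend_left, mt_bend_right,
                             tll_bend_left, tll_bend_right,
                             mt_avr, tll_avr, kyphosis, lordosis,
                             uiv, liv, tll_inf_end = "L4") {
  x <- list(case_id = as.character(case_id), sex = as.character(sex),
            age = as.numeric(age), height = as.numeric(height),
            weight = as.numeric(weight), lenke = as.character(lenke),
            pt_sup_end = pt_sup_end, mt_sup_end = mt_sup_end,
            mt_apex = mt_apex, mt_inf_end = mt_inf_end,
            pt_cobb = as.numeric(pt_cobb), mt_cobb = as.numeric(mt_cobb),
            tll_cobb = as.numeric(tll_cobb),
            pt_bend_left = as.numeric(pt_bend_left),
            pt_bend_right = as.numeric(pt_bend_right),
            mt_bend_left = as.numeric(mt_bend_left),
            mt_bend_right = as.numeric(mt_bend_right),
            tll_bend_left = as.numeric(tll_bend_left),
            tll_bend_right = as.numeric(tll_bend_right),
            mt_avr = as.numeric(mt_avr), tll_avr = as.numeric(tll_avr),
            kyphosis = as.numeric(kyphosis), lordosis = as.numeric(lordosis),
            uiv = uiv, liv = liv, tll_inf_end = tll_inf_end)
  class(x) <- "clinical_indices"
  validate_clinical_indices(x)
  x
}

#' Validate a `clinical_indices` object
#'
#' Checks the structural invariants: non-negative angles, valid level
#' labels, the MT apex strictly between its end vertebrae, the TL/L curve
#' caudal to the MT inferior end, and UIV cephalad of LIV. Violations are
#' reported with the constraint named.
#'
#' @param x A `clinical_indices` object.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_clinical_indices <- function(x) {
  stopifnot(inherits(x, "clinical_indices"))
  ang <- c("pt_cobb", "mt_cobb", "tll_cobb", "pt_bend_left", "pt_bend_right",
           "mt_bend_left", "mt_bend_right", "tll_bend_left", "tll_bend_right",
           "mt_avr", "tll_avr", "kyphosis", "lordosis")
  for (a in ang) {
    v <- x[[a]]
    if (!is.finite(v)) stop("case ", x$case_id, ": angle '", a, "' is not finite", call. = FALSE)
    if (v < 0) stop("case ", x$case_id, ": angle '", a, "' violates Cobb >= 0", call. = FALSE)
  }
  if (!x$sex %in% c("F", "M"))
    stop("case ", x$case_id, ": sex must be 'F' or 'M'", call. = FALSE)
  if (!is.finite(x$height) || x$height < 120 || x$height > 200)
    stop("case ", x$case_id, ": height must lie in 120..200 cm", call. = FALSE)
  lev <- c("pt_sup_end", "mt_sup_end", "mt_apex", "mt_inf_end", "uiv", "liv",
           "tll_inf_end")
  idx <- lapply(lev, function(f) level_index(x[[f]]))
  names(idx) <- lev
  if (!(idx$mt_sup_end < idx$mt_apex && idx$mt_apex < idx$mt_inf_end))
    stop("case ", x$case_id,
         ": violated constraint: MT apex must lie strictly between the ",
         "superior and inferior end vertebrae", call. = FALSE)
  if (!(idx$pt_sup_end < idx$mt_sup_end))
    stop("case ", x$case_id,
         ": violated constraint: PT superior end must be cephalad of the ",
         "MT superior end", call. = FALSE)
  if (!(idx$mt_inf_end < idx$tll_inf_end))
    stop("case ", x$case_id,
         ": violated constraint: TL/L inferior end must be caudal of the ",
         "MT inferior end", call. = FALSE)
  if (!(idx$uiv < idx$liv))
    stop("case ", x$case_id,
         ": violated constraint: UIV must be cephalad of LIV", call. = FALSE)
  invisible(x)
}

#' @export
print.clinical_indices <- function(x, ...) {
  cat("<clinical_indices> case", x$case_id,
      sprintf("(%s, %g y, %g cm, Lenke %s)\n", x$sex, x$age, x$height, x$lenke))
  cat(sprintf("  PT  %s-%s  Cobb %g (bend L %g / R %g)\n", x$pt_sup_end,
              x$mt_sup_end, x$pt_cobb, x$pt_bend_left, x$pt_bend_right))
  cat(sprintf("  MT  %s-%s-%s  Cobb %g (bend L %g / R %g)  AVR %g\n",
              x$mt_sup_end, x$mt_apex, x$mt_inf_end, x$mt_cobb,
              x$mt_bend_left, x$mt_bend_right, x$mt_avr))
  cat(sprintf("  TL/L %s-%s  Cobb %g (bend L %g / R %g)  AVR %g\n",
              x$mt_inf_end, x$tll_inf_end, x$tll_cobb, x$tll_bend_left,
              x$tll_bend_right, x$tll_avr))
  cat(sprintf("  kyphosis %g  lordosis %g  fusion %s-%s\n", x$kyphosis,
              x$lordosis, x$uiv, x$liv))
  invisible(x)
}

case_table_columns <- function() {
  c("case_id", "sex", "age", "height", "weight", "lenke",
    "pt_sup_end", "mt_sup_end", "mt_apex", "mt_inf_end",
    "pt_cobb", "mt_cobb", "tll_cobb",
    "pt_bend_left", "pt_bend_right", "mt_bend_left", "mt_bend_right",
    "tll_bend_left", "tll_bend_right", "mt_avr", "tll_avr",
    "kyphosis", "lordosis", "uiv", "liv")
}

#' Read a case table
#'
#' Parses a CSV file with one row per case and the exact
#' `clinical_indices` field names as columns (angles as plain numbers in
#' degrees). A transcription of the study cohort ships with the package;
#' see [bundled_cases()].
#'
#' @param path Path to the CSV file.
#' @return A list of validated `clinical_indices`, one per row (empty list
#'   for an empty table).
#' @export
read_case_table <- function(path) {
  if (!file.exists(path)) stop("case table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("case table '", path, "' contains no rows", call. = FALSE)
    return(list())
  }
  missing_cols <- setdiff(case_table_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("case table schema violation: missing column(s) ",
         paste0("'", missing_cols, "'", collapse = ", "), call. = FALSE)
  }
  num_cols <- c("age", "height", "weight", "pt_cobb", "mt_cobb", "tll_cobb",
                "pt_bend_left", "pt_bend_right", "mt_bend_left",
                "mt_bend_right", "tll_bend_left", "tll_bend_right",
                "mt_avr", "tll_avr", "kyphosis", "lordosis")
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    for (cc in num_cols) {
      v <- suppressWarnings(as.numeric(row[[cc]]))
      if (is.na(v)) {
        stop("case table row ", i, ", column '", cc,
             "': non-numeric angle value '", row[[cc]], "'", call. = FALSE)
      }
      row[[cc]] <- v
    }
    args <- as.list(row)[case_table_columns()]
    if ("tll_inf_end" %in% names(df)) args$tll_inf_end <- row[["tll_inf_end"]]
    out[[i]] <- tryCatch(do.call(clinical_indices, args),
                         error = function(e) {
                           stop("case table row ", i, ": ", conditionMessage(e),
                                call. = FALSE)
                         })
  }
  out
}

#' The bundled ten-case cohort
#'
#' Clinical indices of the ten adolescent idiopathic scoliosis cases the
#' package ships as its reference cohort, read from the bundled case table
#' (`inst/extdata/bundled_cases.csv`). The PT superior end vertebra is not
#' part of the published indices and is set to T2 for all cases; the TL/L
#' inferior end defaults to L4.
#'
#' @return List of 10 `clinical_indices`.
#' @export
bundled_cases <- function() {
  read_case_table(system.file("extdata", "bundled_cases.csv",
                              package = "scolisim", mustWork = TRUE))
}
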