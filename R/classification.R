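#' Exclude subjects with diabetes at screening
#'
#' Subjects with fasting plasma glucose >= 7.0 mmol/L, or on glucose-lowering
#' medication when a `diabetes_medication` column is present, are excluded
#' before any index analysis. Subjects with no recorded fasting glucose are
#' excluded with reason "missing". The operation is idempotent.
#'
#' @param cohort cohort data frame with a `glucose_0` column.
#' @param threshold fasting glucose exclusion bound, mmol/L (default 7.0,
#'   subjects at or above are excluded).
#' @return list with `cohort` (retained rows) and `exclusions` (data frame of
#'   `subject_id`, `reason`).
#' @export
exclude_diabetes <- function(cohort, threshold = 7.0) {
  if (!"glucose_0" %in% names(cohort)) stop("cohort lacks a glucose_0 column")
  g0 <- cohort$glucose_0
  reason <- rep(NA_character_, nrow(cohort))
  reason[is.na(g0)] <- "missing fasting glucose"
  reason[!is.na(g0) & g0 >= threshold] <-
    sprintf("fasting glucose >= %.1f mmol/L", threshold)
  if ("diabetes_medication" %in% names(cohort)) {
    med <- isTRUE_vec(cohort$diabetes_medication)
    reason[med & is.na(reason)] <- "diabetes medication"
  }
  keep <- is.na(reason)
  list(
    cohort = cohort[keep, , drop = FALSE],
    exclusions = data.frame(
      subject_id = cohort$subject_id[!keep],
      reason = reason[!keep],
      stringsAsFactors = FALSE
    )
  )
}

# Internal: lenient logical coercion (TRUE/FALSE, 0/1, yes/no).
isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  if (is.numeric(x)) return(!is.na(x) & x != 0)
  s <- tolower(as.character(x))
  !is.na(s) & s %in% c("true", "t", "yes", "y", "1")
}

#' Weight class from BMI
#'
#' Three categories: normal weight (BMI < 25), overweight (25 <= BMI < 30)
#' and obesity (BMI >= 30 kg/m2). No underweight category is used.
#'
#' @param bmi body mass index, kg/m2.
#' @return factor with levels "normal weight", "overweight", "obesity".
#' @export
weight_class <- function(bmi) {
  if (any(!is.na(bmi) & bmi <= 0)) stop("bmi must be positive")
  cut(bmi, breaks = c(0, 25, 30, Inf), right = FALSE,
      labels = c("normal weight", "overweight", "obesity"))
}

#' Abdominal obesity from waist circumference
#'
#' WHO/IDF thresholds for European and Middle Eastern populations:
#' waist >= 94 cm in men, >= 80 cm in women.
#'
#' @param waist waist circumference, cm.
#' @param sex "male" or "female" (recycled if scalar).
#' @param cut_male,cut_female thresholds in cm.
#' @return logical vector.
#' @export
abdominal_obesity <- function(waist, sex, cut_male = 94, cut_female = 80) {
  if (any(!is.na(waist) & waist <= 0)) stop("waist must be positive")
  sex <- normalize_sex(sex)
  if (any(is.na(sex))) stop("sex must be known for every subject")
  waist >= ifelse(sex == "male", cut_male, cut_female)
}

#' Tertile boundaries of the reference population's ISI
#'
#' The reference group's ISI distribution is split into three equally large
#' groups. Boundaries are the 1/3 and 2/3 quantiles computed by linear
#' interpolation between order statistics at positions p(n-1)+1 (R's type-7
#' rule); a nearest-rank alternative (type 1) is available.
#'
#' @param isi numeric vector of reference-group ISI values.
#' @param type quantile type, 7 (default, interpolating) or 1 (nearest rank).
#' @return object of class `tertile_reference` with elements `cut_lo`,
#'   `cut_hi`, `labels`, `n_reference`.
#' @export
tertile_reference <- function(isi, type = 7) {
  isi <- isi[is.finite(isi)]
  if (length(isi) < 3) stop("degenerate reference: fewer than 3 finite values")
  if (diff(range(isi)) == 0) stop("degenerate reference: all values equal")
  q <- stats::quantile(isi, probs = c(1, 2) / 3, type = type, names = FALSE)
  new_tertile_reference(q[1], q[2], n_reference = length(isi))
}

#' Construct a tertile reference from known boundaries
#'
#' @param cut_lo,cut_hi lower and upper ISI boundaries (cut_lo < cut_hi).
#' @param n_reference optional size of the reference sample.
#' @return object of class `tertile_reference`.
#' @export
new_tertile_reference <- function(cut_lo, cut_hi, n_reference = NA_integer_) {
  if (!(cut_lo < cut_hi)) stop("cut_lo must be below cut_hi")
  structure(
    list(cut_lo = cut_lo, cut_hi = cut_hi,
         labels = c("insulin resistant", "intermediate", "insulin sensitive"),
         n_reference = n_reference),
    class = "tertile_reference"
  )
}

#' @export
print.tertile_reference <- function(x, ...) {
  cat("ISI tertile reference (n =", x$n_reference, ")\n")
  cat(sprintf("  %s: ISI < %.1f\n", x$labels[1], x$cut_lo))
  cat(sprintf("  %s: %.1f <= ISI < %.1f\n", x$labels[2], x$cut_lo, x$cut_hi))
  cat(sprintf("  %s: ISI >= %.1f\n", x$labels[3], x$cut_hi))
  invisible(x)
}

#' Classify subjects against an ISI tertile reference
#'
#' Boundary rules follow the reference definitions exactly: ISI < cut_lo is
#' "insulin resistant"; cut_lo <= ISI < cut_hi is "intermediate"; ISI >=
#' cut_hi is "insulin sensitive". Ties at a boundary are assigned by these
#' inequalities, never split.
#'
#' @param isi numeric vector.
#' @param ref a [tertile_reference()] object.
#' @return ordered factor with the reference labels; `NA` for missing ISI.
#' @export
classify_isi <- function(isi, ref) {
  stopifnot(inherits(ref, "tertile_reference"))
  cat_idx <- ifelse(is.na(isi), NA_integer_,
                    ifelse(isi < ref$cut_lo, 1L,
                           ifelse(isi < ref$cut_hi, 2L, 3L)))
  factor(ref$labels[cat_idx], levels = ref$labels, ordered = TRUE)
}

#' Prevalence cross-tabulation of ISI categories by adiposity stratum
#'
#' Counts and percentages of each ISI category within strata defined by
#' group, sex and an adiposity classification (weight class from BMI, or
#' abdominal obesity from waist circumference).
#'
#' @param cohort cohort data frame (`subject_id`, `group`, `sex`, `bmi`,
#'   `waist`).
#' @param indices per-subject index table from [ogtt_indices()], or a data
#'   frame with `subject_id` and `isi`.
#' @param ref a [tertile_reference()].
#' @param adiposity "weight_class" or "abdominal_obesity".
#' @param by stratification columns besides adiposity, default group and sex.
#' @return tidy data frame: stratification columns, `category`, `n`, `pct`
#'   (half-up, one decimal) and `stratum_n`. Empty strata keep `n = 0` and
#'   `pct = NA`.
#' @export
prevalence_crosstab <- function(cohort, indices, ref,
                                adiposity = c("weight_class",
                                              "abdominal_obesity"),
                                by = c("group", "sex")) {
  adiposity <- match.arg(adiposity)
  d <- merge(cohort, indices[, c("subject_id", "isi")], by = "subject_id")
  d$category <- classify_isi(d$isi, ref)
  d$adiposity <- switch(adiposity,
    weight_class = weight_class(d$bmi),
    abdominal_obesity = factor(
      ifelse(abdominal_obesity(d$waist, d$sex),
             "abdominal obesity", "normal waist"),
      levels = c("normal waist", "abdominal obesity"))
  )
  d <- d[!is.na(d$category) & !is.na(d$adiposity), , drop = FALSE]
  strata <- c(by, "adiposity")
  tab <- as.data.frame(table(d[c(strata, "category")]),
                       responseName = "n", stringsAsFactors = FALSE)
  key <- do.call(paste, c(tab[strata], sep = "\r"))
  stratum_n <- stats::ave(tab$n, key, FUN = sum)
  tab$pct <- ifelse(stratum_n > 0, proportion_pct(tab$n, pmax(stratum_n, 1)),
                    NA_real_)
  tab$pct[stratum_n == 0] <- NA_real_
  tab$stratum_n <- stratum_n
  tab <- tab[do.call(order, tab[strata]), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
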