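#' Mean concentration over the four informative OGTT timepoints
#'
#' Mean glucose and mean insulin are defined as the unweighted arithmetic mean
#' of the fasting, 30-, 60- and 120-minute samples. A 90-minute sample, when
#' drawn, is ignored: it enters neither the mean nor any downstream index.
#'
#' @param values named numeric vector of timed concentrations; names are
#'   minutes since the glucose load ("0", "30", "60", "120", optionally "90").
#' @param subject_id optional identifier used in error messages.
#' @return the arithmetic mean of the 0/30/60/120-minute values.
#' @export
#' @examples
#' mean_level(c("0" = 4, "30" = 8, "60" = 6, "120" = 6)) # 6
mean_level <- function(values, subject_id = NULL) {
  required <- c("0", "30", "60", "120")
  who <- if (is.null(subject_id)) "" else paste0(" for subject ", subject_id)
  missing_tp <- required[!required %in% names(values)]
  v <- values[required]
  missing_tp <- union(missing_tp, required[is.na(v)])
  if (length(missing_tp) > 0) {
    stop("missing OGTT timepoint(s) ", paste(missing_tp, collapse = ", "),
         " min", who)
  }
  if (any(v <= 0)) {
    stop("non-positive concentration", who)
  }
  mean(unname(v))
}

#' Matsuda composite insulin sensitivity index
#'
#' \deqn{ISI = 10000 / \sqrt{G_0 \cdot I_0 \cdot \bar G \cdot \bar I}}
#' with glucose in mmol/L and insulin in mIE/L. This unit convention puts the
#' index on the scale on which reference-population tertile boundaries of
#' roughly 78 and 133 arise; data recorded with glucose in mg/dL can be
#' converted via `glucose_units = "mg/dL"` (1 mmol/L = 18.0182 mg/dL).
#'
#' @param g0 fasting glucose, mmol/L.
#' @param gmean mean glucose over 0/30/60/120 min, mmol/L.
#' @param i0 fasting insulin, mIE/L.
#' @param imean mean insulin over 0/30/60/120 min, mIE/L.
#' @param glucose_units "mmol/L" (default) or "mg/dL".
#' @param constant numerator constant, default 10000.
#' @return the insulin sensitivity index (dimensionless); vectorized.
#' @export
#' @examples
#' matsuda_isi(4, 4, 25, 25) # 100
matsuda_isi <- function(g0, gmean, i0, imean,
                        glucose_units = c("mmol/L", "mg/dL"),
                        constant = 10000) {
  glucose_units <- match.arg(glucose_units)
  if (glucose_units == "mg/dL") {
    g0 <- g0 / 18.0182
    gmean <- gmean / 18.0182
  }
  ok <- stats::complete.cases(g0, gmean, i0, imean)
  if (any(c(g0, gmean, i0, imean)[!is.na(c(g0, gmean, i0, imean))] <= 0)) {
    stop("all glucose and insulin values must be strictly positive")
  }
  out <- rep(NA_real_, length(g0))
  out[ok] <- constant / sqrt(g0[ok] * i0[ok] * gmean[ok] * imean[ok])
  out
}

#' Corrected insulin response (CIR)
#'
#' Early-phase beta-cell response from the 30-minute OGTT sample:
#' \deqn{CIR = 100 \cdot I_{30} / (G_{30} (G_{30} - 3.89))}
#' with glucose in mmol/L. The index is undefined when the 30-minute glucose
#' does not exceed the offset (3.89 mmol/L = 70 mg/dL); such subjects get
#' `NA` and are flagged rather than assigned a negative index.
#'
#' @param g30 30-minute glucose, mmol/L.
#' @param i30 30-minute insulin, mIE/L.
#' @param offset glucose offset in mmol/L, default 3.89.
#' @return CIR, or `NA` where undefined; vectorized.
#' @export
#' @examples
#' corrected_insulin_response(7.89, 60) # 6000 / (7.89 * 4)
corrected_insulin_response <- function(g30, i30, offset = 3.89) {
  if (any(!is.na(i30) & i30 <= 0)) stop("30-min insulin must be positive")
  out <- rep(NA_real_, length(g30))
  ok <- !is.na(g30) & !is.na(i30) & g30 > offset
  out[ok] <- 100 * i30[ok] / (g30[ok] * (g30[ok] - offset))
  out
}

#' Oral disposition index (DIo)
#'
#' Beta-cell function adjusted for insulin sensitivity: the exact product
#' CIR x ISI. Undefined whenever either factor is undefined.
#'
#' @param cir corrected insulin response.
#' @param isi Matsuda insulin sensitivity index.
#' @return DIo; vectorized, `NA` propagates.
#' @export
disposition_index <- function(cir, isi) {
  if (any(!is.na(cir) & cir < 0) || any(!is.na(isi) & isi < 0)) {
    stop("CIR and ISI must be non-negative")
  }
  cir * isi
}

#' Compute per-subject OGTT indices for a cohort
#'
#' Vectorizes [mean_level()], [matsuda_isi()], [corrected_insulin_response()]
#' and [disposition_index()] over a cohort table. Missingness is handled
#' complete-case per derived quantity: a subject missing the 30-minute insulin
#' loses CIR and DIo but keeps ISI only if all ISI inputs are present; a
#' subject missing any of the four informative glucose or insulin samples is
#' flagged and loses the indices that depend on it, without affecting other
#' subjects.
#'
#' @param cohort data frame with columns `subject_id`, `glucose_0`,
#'   `glucose_30`, `glucose_60`, `glucose_120`, `insulin_0`, `insulin_30`,
#'   `insulin_60`, `insulin_120` (90-minute columns, if present, are ignored).
#' @param glucose_units passed to [matsuda_isi()].
#' @param cir_offset passed to [corrected_insulin_response()].
#' @return data frame with one row per subject: `subject_id`, `mean_glucose`,
#'   `mean_insulin`, `isi`, `cir`, `dio`, logical `cir_undefined`, and a
#'   `missing` column naming absent inputs ("" when complete).
#' @export
ogtt_indices <- function(cohort, glucose_units = "mmol/L", cir_offset = 3.89) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stop("cohort must be a non-empty data frame")
  }
  times <- c(0, 30, 60, 120)
  gcols <- paste0("glucose_", times)
  icols <- paste0("insulin_", times)
  need <- c("subject_id", gcols, icols)
  absent <- setdiff(need, names(cohort))
  if (length(absent) > 0) {
    stop("cohort is missing column(s): ", paste(absent, collapse = ", "))
  }
  g <- as.matrix(cohort[gcols])
  i <- as.matrix(cohort[icols])
  if (any(g[!is.na(g)] <= 0) || any(i[!is.na(i)] <= 0)) {
    stop("all recorded concentrations must be strictly positive")
  }

  g_ok <- stats::complete.cases(g)
  i_ok <- stats::complete.cases(i)
  mean_glucose <- ifelse(g_ok, rowMeans(g), NA_real_)
  mean_insulin <- ifelse(i_ok, rowMeans(i), NA_real_)

  isi <- rep(NA_real_, nrow(cohort))
  isi_in <- g_ok & i_ok
  isi[isi_in] <- matsuda_isi(g[isi_in, 1], mean_glucose[isi_in],
                             i[isi_in, 1], mean_insulin[isi_in],
                             glucose_units = glucose_units)

  cir <- corrected_insulin_response(g[, 2], i[, 2], offset = cir_offset)
  cir_undefined <- !is.na(g[, 2]) & !is.na(i[, 2]) & g[, 2] <= cir_offset
  dio <- disposition_index(cir, isi)

  miss <- apply(cbind(g, i), 1, function(r) {
    paste(c(gcols, icols)[is.na(r)], collapse = ";")
  })

  data.frame(
    subject_id = cohort$subject_id,
    mean_glucose = mean_glucose,
    mean_insulin = mean_insulin,
    isi = isi,
    cir = cir,
    dio = dio,
    cir_undefined = cir_undefined,
    missing = miss,
    stringsAsFactors = FALSE
  )
}
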