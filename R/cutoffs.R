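#' Age-adjust a positive index on the log10 scale
#'
#' Because ISI and DIo are right-skewed, analyses work on log10 values.
#' Adjustment residualizes log10 values on age by least squares, pooled
#' across groups within sex, and adds back the pooled mean, so the adjusted
#' values are uncorrelated with age and preserve the pooled mean. With a
#' single pooled age slope per sex, the adjustment shifts groups coherently
#' and cancels from any between-group level comparison at a common age.
#'
#' @param values strictly positive index values (ISI or DIo).
#' @param age ages in years.
#' @param sex optional sex labels; when given, the regression is run within
#'   each sex separately.
#' @param group optional group labels, used only when `per_group = TRUE`.
#' @param per_group adjust within each group x sex cell instead of pooling
#'   across groups (non-default).
#' @return adjusted log10 values, same length as `values`; `NA` inputs stay
#'   `NA`.
#' @export
age_adjust_outcome <- function(values, age, sex = NULL, group = NULL,
                               per_group = FALSE) {
  if (any(!is.na(values) & values <= 0)) {
    stop("index values must be strictly positive for log10 adjustment")
  }
  y <- log10(values)
  cell <- if (is.null(sex)) rep("all", length(y)) else normalize_sex(sex)
  if (per_group) {
    if (is.null(group)) stop("per_group adjustment needs group labels")
    cell <- paste(cell, group, sep = "\r")
  }
  out <- rep(NA_real_, length(y))
  for (cl in unique(cell)) {
    idx <- which(cell == cl & !is.na(y) & !is.na(age))
    if (length(idx) == 0) next
    yy <- y[idx]
    aa <- age[idx]
    if (length(idx) < 3 || stats::var(aa) == 0) {
      warning("zero age variance; returning unadjusted log10 values")
      out[idx] <- yy
      next
    }
    fit <- stats::lm.fit(cbind(1, aa), yy)
    out[idx] <- mean(yy) + fit$residuals
  }
  out
}

#' Fit the within-group line of adjusted outcome on an anthropometric measure
#'
#' Ordinary least squares of age-adjusted log10 outcome on BMI or waist
#' circumference within one group x sex stratum. The fitted line is the
#' object the equivalence construction intersects.
#'
#' @param x anthropometric measure (BMI kg/m2 or waist cm).
#' @param y age-adjusted log10 outcome.
#' @param group,sex,measure,outcome metadata labels carried along for
#'   compatibility checks.
#' @return object of class `group_line`: `intercept`, `slope`, `n`,
#'   `residual_sd`, `range` (observed measure range), and the labels.
#' @export
fit_group_line <- function(x, y, group = NA, sex = NA,
                           measure = NA, outcome = NA) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (stats::var(x) == 0) stop("measure has zero variance")
  fit <- stats::lm.fit(cbind(1, x), y)
  rsd <- if (n > 2) sqrt(sum(fit$residuals^2) / (n - 2)) else NA_real_
  structure(
    list(intercept = unname(fit$coefficients[1]),
         slope = unname(fit$coefficients[2]),
         n = n, residual_sd = rsd, range = range(x),
         group = group, sex = sex, measure = measure, outcome = outcome),
    class = "group_line"
  )
}

#' @export
coef.group_line <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.group_line <- function(object, newdata, ...) {
  object$intercept + object$slope * newdata
}

#' @export
print.group_line <- function(x, ...) {
  cat(sprintf("group line [%s, %s] %s ~ %s: intercept %.4f, slope %.5f (n = %d)\n",
              x$group, x$sex, x$outcome, x$measure, x$intercept, x$slope, x$n))
  invisible(x)
}

#' Equivalence cut-off between two group lines
#'
#' Solves for the comparison-group measure value at which the comparison
#' line attains the reference line's level at the reference threshold:
#' \deqn{x_{cmp} = (a_{ref} + b_{ref} x_{ref} - a_{cmp}) / b_{cmp}.}
#' The raw solution is reported together with a value snapped to the
#' reporting grid (0.5 kg/m2 for BMI, 1 cm for waist).
#'
#' @param fit_ref,fit_cmp [fit_group_line()] objects for the reference and
#'   comparison groups; must agree on sex, measure and outcome when labelled.
#' @param x_ref reference threshold on the measure scale.
#' @param grid rounding grid; default 0.5 for BMI, 1.0 for waist, else no
#'   rounding.
#' @param slope_tol smallest comparison slope magnitude considered
#'   identifiable.
#' @param warn_extrapolation warn when the cut-off falls outside the
#'   comparison group's observed measure range.
#' @return object of class `equivalence_cutoff`: `cutoff` (raw),
#'   `cutoff_rounded`, `reference_threshold`, `reference_level`,
#'   `extrapolated`, plus the metadata labels.
#' @export
equivalence_cutoff <- function(fit_ref, fit_cmp, x_ref, grid = NULL,
                               slope_tol = 1e-8, warn_extrapolation = TRUE) {
  stopifnot(inherits(fit_ref, "group_line"), inherits(fit_cmp, "group_line"))
  for (f in c("sex", "measure", "outcome")) {
    if (!is.na(fit_ref[[f]]) && !is.na(fit_cmp[[f]]) &&
        fit_ref[[f]] != fit_cmp[[f]]) {
      stop("fits disagree on ", f)
    }
  }
  if (!is.finite(fit_cmp$slope) || abs(fit_cmp$slope) < slope_tol) {
    stop("non-identifiable cut-off: comparison slope is (near) zero")
  }
  level <- fit_ref$intercept + fit_ref$slope * x_ref
  x_cmp <- (level - fit_cmp$intercept) / fit_cmp$slope
  extrapolated <- x_cmp < fit_cmp$range[1] || x_cmp > fit_cmp$range[2]
  if (extrapolated && warn_extrapolation) {
    warning(sprintf(
      "cut-off %.2f lies outside the comparison group's observed range [%.1f, %.1f]",
      x_cmp, fit_cmp$range[1], fit_cmp$range[2]))
  }
  if (is.null(grid)) {
    grid <- switch(as.character(fit_cmp$measure),
                   bmi = 0.5, waist = 1.0, NA_real_)
  }
  rounded <- if (is.na(grid)) x_cmp else round_half_up(x_cmp / grid) * grid
  structure(
    list(sex = fit_cmp$sex, measure = fit_cmp$measure,
         outcome = fit_cmp$outcome, group = fit_cmp$group,
         reference_threshold = x_ref, reference_level = level,
         cutoff = x_cmp, cutoff_rounded = rounded,
         extrapolated = extrapolated,
         fit_ref = fit_ref, fit_cmp = fit_cmp),
    class = "equivalence_cutoff"
  )
}

#' @export
print.equivalence_cutoff <- function(x, ...) {
  cat(sprintf(
    "%s %s equivalence cut-off (%s): %.2f (reported %.1f) at reference threshold %.1f\n",
    x$sex, x$measure, x$outcome, x$cutoff, x$cutoff_rounded,
    x$reference_threshold))
  invisible(x)
}

default_thresholds <- function() {
  list(bmi = c(25, 30), waist = c(male = 94, female = 80))
}

#' Fit the full equivalence cut-off model for a cohort
#'
#' The central estimator: for each sex, outcome (log10 ISI, log10 DIo) and
#' anthropometric measure (BMI, waist circumference), the outcome is
#' age-adjusted on the log10 scale (pooled across groups within sex), a
#' straight line is fitted within each group, and for every reference
#' threshold the comparison-group measure value with the same adjusted
#' outcome level is solved for. An optional subject-level percentile
#' bootstrap (resampling within group x sex) provides confidence intervals.
#'
#' @param cohort cohort data frame (`subject_id`, `group`, `sex`, `age`,
#'   `bmi`, `waist`, OGTT columns if `indices` is not supplied).
#' @param reference_group label of the reference group in `cohort$group`.
#' @param indices optional precomputed [ogtt_indices()] table.
#' @param measures subset of `c("bmi", "waist")`.
#' @param outcomes subset of `c("isi", "dio")`.
#' @param thresholds list with elements `bmi` (vector of BMI thresholds) and
#'   `waist` (named vector, thresholds per sex).
#' @param per_group_adjust use per-group instead of pooled age adjustment.
#' @param min_n strata smaller than this are flagged unreliable (default 30).
#' @param n_boot bootstrap resamples (0 = no bootstrap).
#' @param conf bootstrap confidence level.
#' @param seed seed for the bootstrap; mandatory when `n_boot > 0`.
#' @return object of class `cutoff_model` with a tidy `results` data frame,
#'   the per-stratum `fits`, and the analysis data. Methods: `print`,
#'   `summary`, `coef`, `predict`, `plot`.
#' @export
cutoff_model <- function(cohort, reference_group, indices = NULL,
                         measures = c("bmi", "waist"),
                         outcomes = c("isi", "dio"),
                         thresholds = default_thresholds(),
                         per_group_adjust = FALSE, min_n = 30,
                         n_boot = 0, conf = 0.95, seed = NULL) {
  measures <- match.arg(measures, several.ok = TRUE)
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  if (n_boot > 0 && is.null(seed)) {
    stop("a seed is mandatory when bootstrapping")
  }
  if (!reference_group %in% cohort$group) {
    stop("reference group '", reference_group, "' not present in cohort")
  }
  if (is.null(indices)) indices <- ogtt_indices(cohort)
  d <- merge(cohort[c("subject_id", "group", "sex", "age", "bmi", "waist")],
             indices[c("subject_id", "isi", "dio")], by = "subject_id")
  d$sex <- normalize_sex(d$sex)
  comparisons <- setdiff(unique(d$group), reference_group)

  adjusted <- list()
  for (oc in outcomes) {
    ok <- !is.na(d[[oc]]) & d[[oc]] > 0
    adj <- rep(NA_real_, nrow(d))
    adj[ok] <- age_adjust_outcome(d[[oc]][ok], d$age[ok], sex = d$sex[ok],
                                  group = d$group[ok],
                                  per_group = per_group_adjust)
    adjusted[[oc]] <- adj
  }

  solve_all <- function(dat, adj_list, warn = FALSE) {
    rows <- list()
    fits <- list()
    for (sx in sort(unique(dat$sex))) {
      for (oc in outcomes) {
        for (ms in measures) {
          sel_ref <- dat$sex == sx & dat$group == reference_group
          f_ref <- try(fit_group_line(
            dat[[ms]][sel_ref], adj_list[[oc]][sel_ref],
            group = reference_group, sex = sx, measure = ms,
            outcome = paste0("log10_", oc)), silent = TRUE)
          if (inherits(f_ref, "try-error")) next
          thr <- if (ms == "waist") thresholds$waist[[sx]] else thresholds[[ms]]
          for (cg in comparisons) {
            sel_cmp <- dat$sex == sx & dat$group == cg
            f_cmp <- try(fit_group_line(
              dat[[ms]][sel_cmp], adj_list[[oc]][sel_cmp],
              group = cg, sex = sx, measure = ms,
              outcome = paste0("log10_", oc)), silent = TRUE)
            if (inherits(f_cmp, "try-error")) next
            fits[[paste(sx, oc, ms, cg, sep = ".")]] <- list(
              reference = f_ref, comparison = f_cmp)
            for (x_ref in thr) {
              ec <- try(equivalence_cutoff(f_ref, f_cmp, x_ref,
                                           warn_extrapolation = warn),
                        silent = TRUE)
              if (inherits(ec, "try-error")) {
                rows[[length(rows) + 1]] <- data.frame(
                  sex = sx, outcome = oc, measure = ms, group = cg,
                  reference_threshold = x_ref, reference_level = NA_real_,
                  cutoff = NA_real_, cutoff_rounded = NA_real_,
                  extrapolated = NA, n_ref = f_ref$n, n_cmp = f_cmp$n,
                  unreliable = TRUE, stringsAsFactors = FALSE)
                next
              }
              rows[[length(rows) + 1]] <- data.frame(
                sex = sx, outcome = oc, measure = ms, group = cg,
                reference_threshold = x_ref,
                reference_level = ec$reference_level,
                cutoff = ec$cutoff, cutoff_rounded = ec$cutoff_rounded,
                extrapolated = ec$extrapolated,
                n_ref = f_ref$n, n_cmp = f_cmp$n,
                unreliable = f_ref$n < min_n || f_cmp$n < min_n,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
    list(results = do.call(rbind, rows), fits = fits)
  }

  base <- solve_all(d, adjusted)
  results <- base$results
  if (is.null(results)) stop("no estimable stratum in the cohort")

  if (n_boot > 0) {
    set.seed(as.integer(seed))
    cells <- split(seq_len(nrow(d)), paste(d$group, d$sex, sep = "\r"))
    kcol <- paste(results$sex, results$outcome, results$measure,
                  results$group, results$reference_threshold)
    boot_mat <- matrix(NA_real_, nrow = nrow(results), ncol = n_boot)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(cells, function(ii) {
        ii[sample.int(length(ii), replace = TRUE)]
      }), use.names = FALSE)
      db <- d[idx, , drop = FALSE]
      adjb <- list()
      for (oc in outcomes) {
        ok <- !is.na(db[[oc]]) & db[[oc]] > 0
        adj <- rep(NA_real_, nrow(db))
        adj[ok] <- suppressWarnings(
          age_adjust_outcome(db[[oc]][ok], db$age[ok], sex = db$sex[ok],
                             group = db$group[ok],
                             per_group = per_group_adjust))
        adjb[[oc]] <- adj
      }
      rb <- solve_all(db, adjb)$results
      if (is.null(rb)) next
      kb <- paste(rb$sex, rb$outcome, rb$measure, rb$group,
                  rb$reference_threshold)
      boot_mat[match(kb, kcol), b] <- rb$cutoff
    }
    alpha <- (1 - conf) / 2
    qs <- t(apply(boot_mat, 1, function(v) {
      v <- v[is.finite(v)]
      if (length(v) < 2) c(NA_real_, NA_real_)
      else stats::quantile(v, c(alpha, 1 - alpha), names = FALSE)
    }))
    results$ci_lo <- qs[, 1]
    results$ci_hi <- qs[, 2]
  } else {
    results$ci_lo <- NA_real_
    results$ci_hi <- NA_real_
  }

  structure(
    list(results = results, fits = base$fits,
         reference_group = reference_group, thresholds = thresholds,
         data = cbind(d, as.data.frame(
           stats::setNames(adjusted, paste0("adj_log10_", names(adjusted))))),
         n_boot = n_boot, conf = conf, min_n = min_n,
         call = match.call()),
    class = "cutoff_model"
  )
}

#' @export
print.cutoff_model <- function(x, digits = 2, ...) {
  cat("Anthropometric equivalence cut-off model\n")
  cat("  reference group:", x$reference_group, "\n")
  r <- x$results
  out <- data.frame(
    sex = r$sex, outcome = paste0("log10_", r$outcome), measure = r$measure,
    group = r$group, at = r$reference_threshold,
    cutoff = round(r$cutoff, digits), reported = r$cutoff_rounded,
    flag = ifelse(r$unreliable, "unreliable",
                  ifelse(!is.na(r$extrapolated) & r$extrapolated,
                         "extrapolated", ""))
  )
  if (x$n_boot > 0) {
    out$ci <- sprintf("[%.*f, %.*f]", digits, r$ci_lo, digits, r$ci_hi)
  }
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cutoff_model <- function(object, ...) {
  structure(list(model = object), class = "summary.cutoff_model")
}

#' @export
print.summary.cutoff_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nGroup lines (age-adjusted log10 outcome ~ measure):\n")
  for (nm in names(m$fits)) {
    print(m$fits[[nm]]$reference)
    print(m$fits[[nm]]$comparison)
  }
  if (m$n_boot > 0) {
    cat(sprintf("\nBootstrap: %d resamples, %.0f%% percentile intervals\n",
                m$n_boot, 100 * m$conf))
  }
  invisible(x)
}

#' @export
coef.cutoff_model <- function(object, ...) {
  r <- object$results
  stats::setNames(r$cutoff, paste(r$group, r$sex, r$measure, r$outcome,
                                  r$reference_threshold, sep = "."))
}

#' Evaluate a fitted group line of a cutoff model
#'
#' @param object a [cutoff_model()].
#' @param group,sex,measure,outcome stratum selectors.
#' @param x measure values at which to evaluate.
#' @param ... unused.
#' @return predicted age-adjusted log10 outcome values.
#' @export
predict.cutoff_model <- function(object, group, sex, measure, outcome = "isi",
                                 x, ...) {
  sex <- normalize_sex(sex)
  key <- grep(paste(sex, outcome, measure, sep = "."), names(object$fits),
              fixed = TRUE, value = TRUE)
  if (length(key) == 0) stop("no fitted stratum matches the selectors")
  pair <- object$fits[[key[1]]]
  line <- if (group == object$reference_group) pair$reference else {
    key2 <- paste(sex, outcome, measure, group, sep = ".")
    if (!key2 %in% names(object$fits)) stop("group not fitted: ", group)
    object$fits[[key2]]$comparison
  }
  predict(line, x)
}

#' Plot the group lines and derived cut-offs
#'
#' One panel per sex x measure for the chosen outcome: subject-level adjusted
#' values (thinned scatter), fitted group lines, reference thresholds
#' (vertical dashed) and derived cut-offs (vertical dotted).
#'
#' @param x a [cutoff_model()].
#' @param outcome "isi" or "dio".
#' @param max_points at most this many points plotted per group.
#' @param ... passed to [plot()].
#' @export
plot.cutoff_model <- function(x, outcome = "isi", max_points = 400, ...) {
  d <- x$data
  ycol <- paste0("adj_log10_", outcome)
  sexes <- sort(unique(d$sex))
  measures <- unique(x$results$measure)
  op <- graphics::par(mfrow = c(length(sexes), length(measures)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  groups <- unique(d$group)
  cols <- stats::setNames(grDevices::hcl.colors(max(2, length(groups)),
                                                "Dark 2")[seq_along(groups)],
                          groups)
  for (sx in sexes) {
    for (ms in measures) {
      sel <- d$sex == sx & !is.na(d[[ycol]]) & !is.na(d[[ms]])
      dd <- d[sel, , drop = FALSE]
      graphics::plot(dd[[ms]], dd[[ycol]], type = "n",
                     xlab = ms, ylab = paste0("age-adjusted log10 ", outcome),
                     main = paste(sx, "-", ms), ...)
      for (g in groups) {
        dg <- dd[dd$group == g, , drop = FALSE]
        if (nrow(dg) > max_points) {
          dg <- dg[seq(1, nrow(dg), length.out = max_points), , drop = FALSE]
        }
        graphics::points(dg[[ms]], dg[[ycol]], col = cols[[g]], pch = 16,
                         cex = 0.4)
      }
      for (nm in names(x$fits)) {
        if (!startsWith(nm, paste(sx, outcome, ms, sep = "."))) next
        pr <- x$fits[[nm]]$reference
        pc <- x$fits[[nm]]$comparison
        graphics::abline(pr$intercept, pr$slope, col = cols[[pr$group]], lwd = 2)
        graphics::abline(pc$intercept, pc$slope, col = cols[[pc$group]], lwd = 2)
      }
      rr <- x$results[x$results$sex == sx & x$results$measure == ms &
                        x$results$outcome == outcome, , drop = FALSE]
      graphics::abline(v = unique(rr$reference_threshold), lty = 2)
      graphics::abline(v = rr$cutoff, lty = 3,
                       col = cols[rr$group])
      graphics::legend("topright", legend = groups, col = cols[groups],
                       pch = 16, bty = "n", cex = 0.8)
    }
  }
  invisible(x)
}
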