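#' Scale a variable to unit sample variance
#'
#' Divides by the sample standard deviation (denominator n - 1) without
#' centering, so a regression coefficient on the scaled variable is the
#' effect per one SD of the original variable. Binary indicators should not
#' be standardized.
#'
#' @param x numeric vector with positive variance.
#' @return `x / sd(x)`, with the SD stored in attribute `"scaled:sd"`.
#' @export
standardize <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    stop("cannot standardize '", deparse(substitute(x)), "': zero variance")
  }
  structure(x / s, "scaled:sd" = s)
}

# Internal: is a column a binary indicator (two distinct non-missing values
# coded 0/1 or logical/factor with two levels)?
is_binary <- function(x) {
  if (is.logical(x) || is.factor(x) || is.character(x)) return(TRUE)
  u <- sort(unique(x[!is.na(x)]))
  length(u) <= 2 && all(u %in% c(0, 1))
}

#' Log10-transform skewed variables in a table
#'
#' Applies log10 to the configured list of right-skewed variables before
#' analysis; the applied transformations are recorded in the
#' `"log10_transformed"` attribute for provenance.
#'
#' @param data data frame.
#' @param vars character vector of column names to transform (default: the
#'   customary skewed variables `isi`, `dio`, `triglycerides`), intersected
#'   with the columns actually present.
#' @return the data frame with transformed columns.
#' @export
log10_transform <- function(data, vars = c("isi", "dio", "triglycerides")) {
  vars <- intersect(vars, names(data))
  for (v in vars) {
    bad <- which(!is.na(data[[v]]) & data[[v]] <= 0)
    if (length(bad) > 0) {
      id <- if ("subject_id" %in% names(data)) {
        data$subject_id[bad[1]]
      } else {
        paste("row", bad[1])
      }
      stop("non-positive value of '", v, "' (first at ", id,
           ") cannot be log10-transformed")
    }
    data[[v]] <- log10(data[[v]])
  }
  attr(data, "log10_transformed") <- vars
  data
}

#' Variance inflation factors
#'
#' VIF of predictor j is 1 / (1 - R2_j) where R2_j comes from regressing
#' predictor j on the remaining predictors. A warning is emitted when any
#' VIF reaches 3.5, the customary screening bound for these models; a
#' perfectly collinear predictor yields an infinite VIF.
#'
#' @param x data frame or numeric matrix of predictors (at least 2 columns).
#' @param warn_at warning threshold (default 3.5).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(x, warn_at = 3.5) {
  x <- as.matrix(as.data.frame(x))
  if (ncol(x) < 2) stop("VIF needs at least 2 predictors")
  out <- stats::setNames(numeric(ncol(x)), colnames(x))
  for (j in seq_len(ncol(x))) {
    yj <- x[, j]
    xj <- cbind(1, x[, -j, drop = FALSE])
    ok <- stats::complete.cases(yj, xj)
    fit <- stats::lm.fit(xj[ok, , drop = FALSE], yj[ok])
    tss <- sum((yj[ok] - mean(yj[ok]))^2)
    r2 <- 1 - sum(fit$residuals^2) / tss
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  if (any(!is.finite(out))) {
    warning("perfect collinearity: infinite VIF for ",
            paste(names(out)[!is.finite(out)], collapse = ", "))
  } else if (any(out >= warn_at)) {
    warning("VIF at or above ", warn_at, " for ",
            paste(names(out)[out >= warn_at], collapse = ", "))
  }
  out
}

#' Multivariate linear regression with standardized coefficients
#'
#' Fits an ordinary least-squares regression of a (typically log10 ISI)
#' outcome on a declared term list. Continuous predictors are standardized
#' to unit variance so their coefficients are per 1 SD; binary indicators are
#' left on their natural scale. Inference uses classical standard errors
#' with normal-approximation confidence intervals by default (t-based by
#' option). Complete cases only; the n actually used is reported.
#'
#' @param formula model formula, e.g. `log10(isi) ~ bmi + triglycerides +
#'   smoker`.
#' @param data data frame.
#' @param standardize_terms standardize continuous predictors (default TRUE).
#' @param conf confidence level (default 0.95).
#' @param ci_type "normal" (default) or "t".
#' @param backward drop the least significant term with p >= `alpha` one at a
#'   time until all remaining terms are significant (default FALSE).
#' @param alpha significance threshold used by `backward` and by
#'   [interaction_scan()] gating.
#' @return object of class `isi_regression` with components `beta`, `se`,
#'   `ci`, `p`, `r2`, `n`, `vif`, `sd_terms`, `dropped`, and the underlying
#'   `lm` fit.
#' @export
isi_regression <- function(formula, data, standardize_terms = TRUE,
                           conf = 0.95, ci_type = c("normal", "t"),
                           backward = FALSE, alpha = 0.05) {
  ci_type <- match.arg(ci_type)
  mf_all <- stats::model.frame(formula, data = data,
                               na.action = stats::na.pass)
  cc <- stats::complete.cases(mf_all)
  work <- data[cc, , drop = FALSE]
  vars <- attr(stats::terms(mf_all), "term.labels")
  n <- nrow(work)
  if (n < length(vars) + 2) stop("too few complete cases for the term list")

  sd_terms <- stats::setNames(rep(1, length(vars)), vars)
  if (standardize_terms) {
    for (v in vars) {
      if (v %in% names(work) && is.numeric(work[[v]]) &&
          !is_binary(work[[v]])) {
        s <- stats::sd(work[[v]])
        if (s == 0) stop("zero variance in term '", v, "'")
        work[[v]] <- work[[v]] / s
        sd_terms[v] <- s
      }
    }
  }

  fit_once <- function(fml, dat) {
    fit <- stats::lm(fml, data = dat)
    mm <- stats::model.matrix(fit)
    if (fit$rank < ncol(mm)) {
      aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("rank-deficient design; collinear term(s): ",
           paste(aliased, collapse = ", "))
    }
    fit
  }

  fit <- fit_once(formula, work)
  dropped <- character(0)

  term_p <- function(fit) {
    sm <- summary(fit)
    b <- sm$coefficients[, 1]
    se <- sm$coefficients[, 2]
    if (ci_type == "normal") 2 * stats::pnorm(-abs(b / se))
    else 2 * stats::pt(-abs(b / se), df = fit$df.residual)
  }

  if (backward) {
    repeat {
      p <- term_p(fit)
      tl <- attr(stats::terms(fit), "term.labels")
      # map coefficient p-values back to terms (factors expand to dummies)
      asg <- attr(stats::model.matrix(fit), "assign")
      pt_term <- vapply(seq_along(tl), function(k) min(p[asg == k]), 0)
      worst <- which.max(pt_term)
      if (length(tl) <= 1 || pt_term[worst] < alpha) break
      dropped <- c(dropped, tl[worst])
      fml <- stats::update(stats::formula(fit),
                           paste(". ~ . -", tl[worst]))
      fit <- fit_once(fml, work)
    }
  }

  sm <- summary(fit)
  b <- sm$coefficients[, 1]
  se <- sm$coefficients[, 2]
  z <- if (ci_type == "normal") stats::qnorm(1 - (1 - conf) / 2)
       else stats::qt(1 - (1 - conf) / 2, df = fit$df.residual)
  ci <- cbind(lo = b - z * se, hi = b + z * se)
  p <- term_p(fit)

  mm <- stats::model.matrix(fit)
  cont <- setdiff(colnames(mm), "(Intercept)")
  cont <- cont[vapply(cont, function(cn) length(unique(mm[, cn])) > 2, TRUE)]
  v <- if (length(cont) >= 2) {
    suppressWarnings(vif(mm[, cont, drop = FALSE]))
  } else {
    NULL
  }

  structure(
    list(beta = b, se = se, ci = ci, p = p, r2 = sm$r.squared,
         n = n, vif = v, sd_terms = sd_terms, dropped = dropped,
         conf = conf, ci_type = ci_type, alpha = alpha,
         formula = stats::formula(fit), data = work, fit = fit,
         call = match.call()),
    class = "isi_regression"
  )
}

#' @export
coef.isi_regression <- function(object, ...) object$beta

#' @export
print.isi_regression <- function(x, digits = 3, ...) {
  cat("Standardized-coefficient regression (n =", x$n,
      ", R2 =", round(x$r2, 3), ")\n")
  tab <- data.frame(
    beta = round(x$beta, digits),
    ci_lo = round(x$ci[, 1], digits),
    ci_hi = round(x$ci[, 2], digits),
    p = signif(x$p, 2)
  )
  print(tab)
  if (!is.null(x$vif)) {
    cat("VIF:", paste(sprintf("%s=%.2f", names(x$vif), x$vif),
                      collapse = ", "), "\n")
  }
  if (length(x$dropped) > 0) {
    cat("dropped by backward elimination:",
        paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.isi_regression <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Gated interaction scan against a moderator
#'
#' To limit the multiple-testing burden, interactions are considered only for
#' terms whose marginal effect is significant: for every term of a fitted
#' model with marginal p below `alpha`, the model is refitted with a
#' term-by-moderator product, and the product term's p-value is reported;
#' all other terms are reported as gated (skipped).
#'
#' @param object a fitted [isi_regression()].
#' @param moderator name of the moderating column (e.g. group or sex); must
#'   vary and must be present in the model data.
#' @param alpha gate threshold (default: the model's alpha, 0.05).
#' @return data frame with `term`, `marginal_p`, `interaction_p`, `status`
#'   ("tested" or "skipped (gated)").
#' @export
interaction_scan <- function(object, moderator, alpha = object$alpha) {
  stopifnot(inherits(object, "isi_regression"))
  dat <- object$data
  if (!moderator %in% names(dat)) {
    stop("moderator '", moderator, "' is not in the model data")
  }
  if (length(unique(dat[[moderator]][!is.na(dat[[moderator]])])) < 2) {
    stop("moderator '", moderator, "' is constant")
  }
  tl <- setdiff(attr(stats::terms(object$fit), "term.labels"), moderator)
  asg <- attr(stats::model.matrix(object$fit), "assign")
  tl_all <- attr(stats::terms(object$fit), "term.labels")
  rows <- lapply(tl, function(tm) {
    k <- match(tm, tl_all)
    mp <- min(object$p[asg == k])
    if (is.na(mp) || mp >= alpha) {
      return(data.frame(term = tm, marginal_p = mp,
                        interaction_p = NA_real_,
                        status = "skipped (gated)",
                        stringsAsFactors = FALSE))
    }
    fml <- stats::update(object$formula,
                         paste(". ~ . +", moderator, "+", tm, ":", moderator))
    fit2 <- stats::lm(fml, data = dat)
    sm <- summary(fit2)$coefficients
    inter <- grep(":", rownames(sm), fixed = TRUE, value = TRUE)
    inter <- inter[grepl(tm, inter, fixed = TRUE)]
    bp <- if (object$ci_type == "normal") {
      2 * stats::pnorm(-abs(sm[inter, 1] / sm[inter, 2]))
    } else {
      2 * stats::pt(-abs(sm[inter, 1] / sm[inter, 2]),
                    df = fit2$df.residual)
    }
    data.frame(term = tm, marginal_p = mp, interaction_p = min(bp),
               status = "tested", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Age-adjusted comparison of two groups
#'
#' Differences in means are examined by linear regression adjusting for age;
#' differences in proportions by logistic regression (iteratively reweighted
#' least squares) on group and age.
#'
#' @param y outcome: continuous, or binary (0/1 or logical) for
#'   `type = "proportion"`.
#' @param group two-level group labels; the second sorted level is contrasted
#'   against the first.
#' @param age ages in years.
#' @param type "continuous" or "proportion".
#' @param conf confidence level.
#' @return list with `estimate` (adjusted mean difference, or odds ratio),
#'   `ci`, `p`, `type`, `n`.
#' @export
age_adjusted_comparison <- function(y, group, age,
                                    type = c("continuous", "proportion"),
                                    conf = 0.95) {
  type <- match.arg(type)
  g <- factor(group)
  if (nlevels(g) != 2) stop("exactly two groups are required")
  ok <- stats::complete.cases(y, g, age)
  d <- data.frame(y = y[ok], g = g[ok], age = age[ok])
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (type == "continuous") {
    fit <- stats::lm(y ~ g + age, data = d)
    sm <- summary(fit)$coefficients
    est <- sm[2, 1]
    se <- sm[2, 2]
    list(estimate = est, ci = c(est - z * se, est + z * se),
         p = 2 * stats::pnorm(-abs(est / se)), type = type, n = nrow(d))
  } else {
    if (!all(d$y %in% c(0, 1))) stop("proportion outcome must be binary")
    fit <- stats::glm(y ~ g + age, data = d, family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-8,
                                                   maxit = 50))
    mu <- stats::fitted(fit)
    if (!fit$converged || any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
      stop("logistic fit did not converge (possible complete separation; ",
           "fitted probabilities reach 0/1)")
    }
    sm <- summary(fit)$coefficients
    est <- sm[2, 1]
    se <- sm[2, 2]
    list(estimate = exp(est),
         ci = exp(c(est - z * se, est + z * se)),
         p = 2 * stats::pnorm(-abs(est / se)), type = type, n = nrow(d))
  }
}
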