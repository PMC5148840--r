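test_that("age adjustment removes the age trend and preserves the mean", {
  set.seed(1)
  n <- 400
  age <- runif(n, 30, 75)
  sex <- rep(c("male", "female"), n / 2)
  # planted linear age slope on the log10 scale
  y <- 10^(2 - 0.004 * (age - 50) + rnorm(n, 0, 0.15))
  adj <- age_adjust_outcome(y, age, sex = sex)
  for (sx in c("male", "female")) {
    i <- sex == sx
    expect_lt(abs(cor(adj[i], age[i])), 1e-10)
    expect_equal(mean(adj[i]), mean(log10(y[i])), tolerance = 1e-12)
  }
})

test_that("age adjustment is a no-op when there is no age effect", {
  set.seed(2)
  age <- runif(300, 30, 75)
  y <- 10^rnorm(300, 2, 0.2)
  adj <- age_adjust_outcome(y, age)
  fit <- lm(log10(y) ~ age)
  expect_equal(adj, mean(log10(y)) + unname(resid(fit)), tolerance = 1e-12)
  # slope is tiny, so adjusted ~= raw log10 values
  expect_equal(adj, log10(y), tolerance = 0.05)
})

test_that("zero age variance falls back to unadjusted log10 with a warning", {
  y <- c(80, 100, 120, 140)
  expect_warning(adj <- age_adjust_outcome(y, rep(50, 4)), "zero age variance")
  expect_equal(adj, log10(y))
})

test_that("group line fit recovers exact coefficients and matches the normal equations", {
  # exactly collinear points
  x <- c(20, 25, 30)
  y <- 2.5 - 0.02 * x
  f <- fit_group_line(x, y)
  expect_equal(f$intercept, 2.5, tolerance = 1e-12)
  expect_equal(f$slope, -0.02, tolerance = 1e-12)
  expect_equal(f$residual_sd, 0, tolerance = 1e-10)

  # 5-point fixture against the closed-form oracle
  x5 <- c(21, 24, 26, 29, 33)
  y5 <- c(2.31, 2.22, 2.19, 2.05, 1.98)
  f5 <- fit_group_line(x5, y5)
  beta <- normal_equations(cbind(1, x5), y5)
  expect_equal(unname(coef(f5)), unname(beta), tolerance = 1e-10)

  # affine equivariance: shifting outcomes shifts only the intercept
  f5c <- fit_group_line(x5, y5 + 0.37)
  expect_equal(f5c$slope, f5$slope, tolerance = 1e-12)
  expect_equal(f5c$intercept, f5$intercept + 0.37, tolerance = 1e-12)

  expect_error(fit_group_line(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_group_line(rep(5, 4), 1:4), "zero variance")
})

test_that("equivalence cut-off solves the level-matching equation", {
  mk <- function(a, b) {
    structure(list(intercept = a, slope = b, n = 100, residual_sd = 0.1,
                   range = c(18, 40), group = "g", sex = "male",
                   measure = "bmi", outcome = "log10_isi"),
              class = "group_line")
  }
  # identical fits: cutoff equals the threshold
  f <- mk(2.6, -0.02)
  expect_equal(equivalence_cutoff(f, f, 30)$cutoff, 30, tolerance = 1e-12)
  # pure horizontal shift: parallel lines, intercept lower by 2|b|
  f2 <- mk(2.6 - 2 * 0.02, -0.02)
  expect_equal(equivalence_cutoff(f, f2, 30)$cutoff, 28, tolerance = 1e-12)
  # hand-solved example: ref level at 30 is 2.0; (2.0 - 2.5)/(-0.02) = 25
  ec <- equivalence_cutoff(mk(2.6, -0.02), mk(2.5, -0.02), 30)
  expect_equal(ec$reference_level, 2.0, tolerance = 1e-12)
  expect_equal(ec$cutoff, 25, tolerance = 1e-12)
  expect_equal(ec$cutoff_rounded, 25)
  # zero comparison slope is not identifiable
  expect_error(equivalence_cutoff(f, mk(2.5, 0), 30), "non-identifiable")
  # solutions outside the observed range warn
  expect_warning(equivalence_cutoff(mk(3.4, -0.02), mk(2.0, -0.02), 30),
                 "outside")
})

test_that("round-trip: the comparison line reproduces the reference level at the cut-off", {
  set.seed(3)
  for (rep in 1:10) {
    a1 <- runif(1, 2, 3); b1 <- runif(1, -0.05, -0.005)
    a2 <- runif(1, 2, 3); b2 <- runif(1, -0.05, -0.005)
    f1 <- structure(list(intercept = a1, slope = b1, n = 50,
                         residual_sd = 0.1, range = c(0, 100), group = "r",
                         sex = NA, measure = "bmi", outcome = NA),
                    class = "group_line")
    f2 <- structure(list(intercept = a2, slope = b2, n = 50,
                         residual_sd = 0.1, range = c(0, 100), group = "c",
                         sex = NA, measure = "bmi", outcome = NA),
                    class = "group_line")
    ec <- suppressWarnings(equivalence_cutoff(f1, f2, 30))
    expect_equal(predict(f2, ec$cutoff), predict(f1, 30), tolerance = 1e-10)
  }
})

test_that("adding a constant to every subject's outcome leaves cut-offs unchanged", {
  co <- generate_cohort(default_params("planted_shift", delta = 2, n = 300,
                                       seed = 9))
  idx <- ogtt_indices(co)
  m1 <- suppressWarnings(cutoff_model(co, "reference", indices = idx,
                                      measures = "bmi", outcomes = "isi"))
  idx2 <- idx
  idx2$isi <- idx2$isi * 10  # +1 on the log10 scale
  m2 <- suppressWarnings(cutoff_model(co, "reference", indices = idx2,
                                      measures = "bmi", outcomes = "isi"))
  expect_equal(coef(m1), coef(m2), tolerance = 1e-10)
})

test_that("reference compared with itself returns the thresholds exactly", {
  co <- generate_cohort(default_params("null", n = 200, seed = 21))
  idx <- ogtt_indices(co)
  co$group <- "reference"
  co2 <- co
  co2$group <- "mirror"
  co2$subject_id <- paste0("M", co2$subject_id)
  idx2 <- idx
  idx2$subject_id <- paste0("M", idx2$subject_id)
  both <- rbind(co, co2)
  idx_both <- rbind(idx, idx2)
  m <- suppressWarnings(cutoff_model(both, "reference", indices = idx_both,
                                     measures = "bmi", outcomes = "isi"))
  expect_equal(m$results$cutoff, m$results$reference_threshold,
               tolerance = 1e-9)
})

test_that("planted horizontal shifts are recovered across seeds", {
  # 2000 subjects per group (1000 per stratum), shifts 1/2/4 kg/m2
  errs <- c()
  for (delta in c(1, 2, 4)) {
    for (seed in 1:5) {
      co <- generate_cohort(default_params("planted_shift", delta = delta,
                                           n = 1000, seed = 100 + seed))
      m <- suppressWarnings(
        cutoff_model(co, "reference", measures = "bmi", outcomes = "isi"))
      r <- m$results[m$results$reference_threshold == 30, ]
      errs <- c(errs, abs(r$cutoff - (30 - delta)))
    }
  }
  expect_lt(mean(errs), 0.2)
})

test_that("a comparison group with zero planted slope is flagged", {
  p <- default_params("null", n = 200, seed = 4)
  for (k in seq_along(p$strata)) {
    if (p$strata[[k]]$group == "comparison") {
      p$strata[[k]]$isi_slope_bmi <- 0
      p$strata[[k]]$isi_slope_age <- 0
      p$strata[[k]]$isi_sd <- 0
    }
  }
  co <- generate_cohort(p)
  # per-group adjustment keeps the comparison outcome exactly constant, so
  # the fitted comparison slope is exactly zero
  m <- suppressWarnings(cutoff_model(co, "reference", measures = "bmi",
                                     outcomes = "isi",
                                     per_group_adjust = TRUE))
  expect_true(all(is.na(m$results$cutoff)))
  expect_true(all(m$results$unreliable))
})

test_that("small strata are marked unreliable", {
  co <- generate_cohort(default_params("null", n = 20, seed = 5))
  m <- suppressWarnings(cutoff_model(co, "reference", measures = "bmi",
                                     outcomes = "isi", min_n = 30))
  expect_true(all(m$results$unreliable))
})

test_that("bootstrap intervals cover the planted cut-off", {
  # 95% percentile bootstrap should cover the truth in >= 90% of replicates
  delta <- 2
  hits <- 0
  n_seeds <- 50
  for (seed in seq_len(n_seeds)) {
    co <- generate_cohort(default_params("planted_shift", delta = delta,
                                         n = 400, seed = 7000 + seed))
    co <- co[co$sex == "male", ]
    m <- suppressWarnings(
      cutoff_model(co, "reference", measures = "bmi", outcomes = "isi",
                   n_boot = 200, seed = seed))
    r <- m$results[m$results$reference_threshold == 30, ]
    if (!is.na(r$ci_lo) && r$ci_lo <= 30 - delta && 30 - delta <= r$ci_hi) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / n_seeds, 0.90)
})

test_that("bootstrap requires a seed", {
  co <- generate_cohort(default_params("null", n = 100, seed = 1))
  expect_error(cutoff_model(co, "reference", n_boot = 10), "seed")
})

test_that("cutoff model methods work", {
  co <- generate_cohort(default_params("planted_shift", delta = 2, n = 300,
                                       seed = 31))
  m <- suppressWarnings(cutoff_model(co, "reference"))
  expect_s3_class(m, "cutoff_model")
  expect_output(print(m), "equivalence cut-off")
  expect_output(print(summary(m)), "Group lines")
  expect_true(all(is.finite(coef(m)) | is.na(coef(m))))
  # predict evaluates the stored line
  pair <- m$fits[["male.isi.bmi.comparison"]]
  expect_equal(predict(m, "comparison", "male", "bmi", "isi", x = 27),
               predict(pair$comparison, 27))
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf, width = 800, height = 600)
  expect_silent(plot(m, outcome = "isi"))
  grDevices::dev.off()
  unlink(tf)
})
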