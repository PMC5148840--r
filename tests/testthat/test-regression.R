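test_that("standardize divides by the n-1 sample SD and is idempotent at unit SD", {
  z <- standardize(c(-1, 1))
  expect_equal(as.numeric(z), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(attr(z, "scaled:sd"), sqrt(2))
  u <- c(-1, 0, 1) / sd(c(-1, 0, 1))
  expect_equal(as.numeric(standardize(u)), u, tolerance = 1e-12)
  expect_error(standardize(rep(3, 5)), "zero variance")
})

test_that("log10 transform applies to configured variables only", {
  d <- data.frame(subject_id = c("a", "b", "c"),
                  isi = c(1, 10, 100), other = c(1, 10, 100))
  out <- log10_transform(d, "isi")
  expect_equal(out$isi, c(0, 1, 2))
  expect_equal(out$other, c(1, 10, 100))
  expect_identical(log10_transform(d, character(0)), {
    d2 <- d
    attr(d2, "log10_transformed") <- character(0)
    d2
  })
  d$isi[2] <- -5
  expect_error(log10_transform(d, "isi"), "b")
})

test_that("ols fit matches the closed-form normal equations", {
  # 4-point single-predictor fixture
  d <- data.frame(y = c(1.2, 0.8, 0.5, 0.1), x = c(1, 2, 3, 4))
  fit <- isi_regression(y ~ x, d, standardize_terms = FALSE)
  beta <- normal_equations(cbind(1, d$x), d$y)
  expect_equal(unname(coef(fit)), unname(beta), tolerance = 1e-10)

  # random small instances, multiple predictors
  set.seed(10)
  for (rep in 1:100) {
    n <- sample(8:20, 1)
    k <- sample(1:4, 1)
    X <- matrix(rnorm(n * k), n, k)
    y <- rnorm(n)
    d <- as.data.frame(X)
    names(d) <- paste0("x", seq_len(k))
    d$y <- y
    fml <- as.formula(paste("y ~", paste(names(d)[1:k], collapse = "+")))
    fit <- isi_regression(fml, d, standardize_terms = FALSE)
    oracle <- normal_equations(cbind(1, X), y)
    expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-8)
  }
})

test_that("intercept-only model returns the sample mean", {
  d <- data.frame(y = c(3, 5, 7, 9))
  fit <- isi_regression(y ~ 1, d)
  expect_equal(unname(coef(fit)), mean(d$y))
})

test_that("standardized beta equals unstandardized beta times the term SD", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 50
    d <- data.frame(x1 = rnorm(n, 0, 3), x2 = runif(n, 10, 40))
    d$y <- 0.2 * d$x1 - 0.05 * d$x2 + rnorm(n)
    raw <- isi_regression(y ~ x1 + x2, d, standardize_terms = FALSE)
    std <- isi_regression(y ~ x1 + x2, d, standardize_terms = TRUE)
    expect_equal(std$beta[["x1"]], raw$beta[["x1"]] * sd(d$x1),
                 tolerance = 1e-10)
    expect_equal(std$beta[["x2"]], raw$beta[["x2"]] * sd(d$x2),
                 tolerance = 1e-10)
  }
})

test_that("binary indicators are not standardized", {
  set.seed(12)
  d <- data.frame(x = rnorm(100), b = rbinom(100, 1, 0.4))
  d$y <- d$x + 0.5 * d$b + rnorm(100)
  fit <- isi_regression(y ~ x + b, d)
  expect_equal(fit$sd_terms[["b"]], 1)
  expect_false(fit$sd_terms[["x"]] == 1)
})

test_that("rank-deficient designs error with the collinear term named", {
  d <- data.frame(x = rnorm(30))
  d$dup <- d$x
  d$y <- d$x + rnorm(30)
  expect_error(isi_regression(y ~ x + dup, d), "dup")
})

test_that("VIF matches its closed form", {
  # orthogonal predictors have VIF exactly 1
  X <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(unname(vif(X)), c(1, 1))

  # two predictors with sample correlation exactly 0.6
  set.seed(13)
  x1 <- as.numeric(scale(rnorm(200)))
  z <- residuals(lm(rnorm(200) ~ x1))
  z <- z / sd(z) * sd(x1)
  x2 <- 0.6 * x1 + sqrt(1 - 0.36) * z
  expect_equal(cor(x1, x2), 0.6, tolerance = 1e-12)
  v <- vif(cbind(x1 = x1, x2 = x2))
  expect_equal(unname(v), c(1.5625, 1.5625), tolerance = 1e-10)

  # duplicated predictor: infinite VIF with a warning
  expect_warning(vd <- vif(cbind(p = x1, q = x1)), "collinearity")
  expect_true(all(!is.finite(vd)))
  # high-but-finite collinearity warns at the 3.5 screening bound
  x3 <- 0.95 * x1 + sqrt(1 - 0.95^2) * z
  expect_warning(vif(cbind(x1, x3)), "3.5")
})

test_that("VIF agrees with the standard car implementation", {
  skip_if_not_installed("car")
  set.seed(14)
  d <- data.frame(a = rnorm(80), b = rnorm(80), c = rnorm(80))
  d$b <- d$b + 0.7 * d$a
  d$y <- d$a - d$b + d$c + rnorm(80)
  ours <- vif(d[c("a", "b", "c")])
  theirs <- car::vif(lm(y ~ a + b + c, d))
  expect_equal(unname(ours), unname(theirs[c("a", "b", "c")]),
               tolerance = 1e-8)
})

test_that("interaction scan gates on marginal significance", {
  set.seed(15)
  n <- 300
  d <- data.frame(x = rnorm(n), noise = rnorm(n),
                  g = rep(c("a", "b"), n / 2))
  d$y <- 0.8 * d$x + rnorm(n)  # noise has no marginal effect
  fit <- isi_regression(y ~ x + noise, d)
  scan <- interaction_scan(fit, "g")
  expect_equal(scan$status[scan$term == "x"], "tested")
  expect_equal(scan$status[scan$term == "noise"], "skipped (gated)")
  expect_true(is.na(scan$interaction_p[scan$term == "noise"]))
  expect_error(interaction_scan(fit, "missing_col"), "not in the model data")
  d$const <- "a"
  fit2 <- isi_regression(y ~ x, d)
  expect_error(interaction_scan(fit2, "const"), "constant")
})

test_that("interaction scan type-I error is calibrated near 5%", {
  # null simulation: marginal effect present, no interaction
  n_seeds <- 500
  n <- 800
  rejections <- 0
  for (s in seq_len(n_seeds)) {
    set.seed(20000 + s)
    d <- data.frame(x = rnorm(n), g = rep(c("a", "b"), n / 2))
    d$y <- 0.3 * d$x + rnorm(n)
    fit <- isi_regression(y ~ x, d, standardize_terms = FALSE)
    scan <- interaction_scan(fit, "g")
    p <- scan$interaction_p[scan$term == "x"]
    if (!is.na(p) && p < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_seeds
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("interaction scan detects a planted standardized interaction of 0.1", {
  n_seeds <- 50
  n <- 1500
  detected <- 0
  for (s in seq_len(n_seeds)) {
    set.seed(30000 + s)
    # effect-coded moderator: the product x*g has unit variance, so the
    # planted coefficient 0.1 is the standardized interaction effect
    d <- data.frame(x = rnorm(n), g = rep(c(-1, 1), n / 2))
    d$y <- 0.3 * d$x + 0.1 * d$x * d$g + rnorm(n)
    fit <- isi_regression(y ~ x, d, standardize_terms = FALSE)
    scan <- interaction_scan(fit, "g")
    p <- scan$interaction_p[scan$term == "x"]
    if (!is.na(p) && p < 0.05) detected <- detected + 1
  }
  expect_gte(detected / n_seeds, 0.8)
})

test_that("age-adjusted comparison of means removes the age confounding", {
  set.seed(16)
  n <- 2000
  g <- rep(c("ref", "cmp"), n / 2)
  age <- ifelse(g == "cmp", rnorm(n, 45, 8), rnorm(n, 50, 8))
  y <- 2 - 0.01 * age + ifelse(g == "cmp", -0.1, 0) + rnorm(n, 0, 0.2)
  res <- age_adjusted_comparison(y, g, age, type = "continuous")
  # factor levels sort cmp < ref: coefficient is ref - cmp = +0.1
  expect_equal(res$estimate, 0.1, tolerance = 0.03)
  expect_lt(res$p, 0.05)

  # no-confounding limit: zero age coefficient, estimate = raw difference
  y0 <- ifelse(g == "cmp", 1, 0) + rnorm(n, 0, 0.1)
  res0 <- age_adjusted_comparison(y0, g, age, type = "continuous")
  raw <- mean(y0[g == "ref"]) - mean(y0[g == "cmp"])
  expect_equal(res0$estimate, raw, tolerance = 0.01)
})

test_that("age-adjusted odds ratios recover a planted effect", {
  hits <- 0
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    set.seed(40000 + s)
    n <- 4000
    g <- rep(c(0, 1), n / 2)
    age <- rnorm(n, 48, 10)
    eta <- -1 + log(2) * g + 0.01 * (age - 48)
    y <- rbinom(n, 1, plogis(eta))
    res <- age_adjusted_comparison(y, g, age, type = "proportion")
    if (res$estimate >= 1.7 && res$estimate <= 2.4) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("complete separation in the logistic fit is diagnosed", {
  d <- data.frame(y = rep(c(0, 1), each = 20),
                  g = rep(c("a", "b"), each = 20),
                  age = rnorm(40, 50, 5))
  expect_error(age_adjusted_comparison(d$y, d$g, d$age, type = "proportion"),
               "separation")
})

test_that("backward elimination drops non-significant terms one at a time", {
  set.seed(17)
  n <- 500
  d <- data.frame(x = rnorm(n), junk1 = rnorm(n), junk2 = rnorm(n))
  d$y <- 0.5 * d$x + rnorm(n)
  fit <- isi_regression(y ~ x + junk1 + junk2, d, backward = TRUE)
  expect_true("x" %in% names(coef(fit)) ||
                any(grepl("x", names(coef(fit)))))
  expect_true(all(c("junk1", "junk2") %in% fit$dropped))
})
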