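# Tiny in-code fixtures shared across test files.

# A minimal hand-written cohort: constant trajectories so every index has a
# closed form. glucose constant 4 mmol/L, insulin constant 25 mIE/L gives
# ISI = 10000 / sqrt(4 * 25 * 4 * 25) = 100 and CIR = 2500/(4 * 0.11).
constant_cohort <- function(n = 3, glucose = 4, insulin = 25) {
  data.frame(
    subject_id = sprintf("C%02d", seq_len(n)),
    group = rep(c("reference", "comparison"), length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    age = seq(35, 65, length.out = n),
    bmi = seq(22, 32, length.out = n),
    waist = seq(80, 100, length.out = n),
    glucose_0 = glucose, glucose_30 = glucose, glucose_60 = glucose,
    glucose_90 = glucose, glucose_120 = glucose,
    insulin_0 = insulin, insulin_30 = insulin, insulin_60 = insulin,
    insulin_90 = insulin, insulin_120 = insulin,
    stringsAsFactors = FALSE
  )
}

# Closed-form OLS oracle: solve the normal equations directly.
normal_equations <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
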