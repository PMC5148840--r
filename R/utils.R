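#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for reported percentages and for
#' snapping cut-offs to their reporting grid. Base [round()] rounds half to
#' even, which does not match the usual epidemiological reporting style.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.25, 1) # 0.3, where round(0.25, 1) gives 0.2
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentage of a count, rounded to reporting precision
#'
#' @param count number of subjects in the cell.
#' @param n stratum size.
#' @param digits decimal places (default 1, the usual reporting precision).
#' @return percentage on the 0-100 scale.
#' @export
#' @examples
#' proportion_pct(71, 326) # 21.8
proportion_pct <- function(count, n, digits = 1) {
  if (any(n <= 0)) stop("stratum size must be positive")
  if (any(count < 0) || any(count > n)) stop("count must be in [0, n]")
  round_half_up(100 * count / n, digits)
}

# Derive a reproducible sub-seed from a master seed and a step label, so each
# pipeline stage consumes an independent stream. Kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 131) %% 2147483647L)
}

# Internal: consistent sex labels.
normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("m", "man", "men")] <- "male"
  s[s %in% c("f", "woman", "women")] <- "female"
  bad <- !is.na(s) & !s %in% c("male", "female")
  if (any(bad)) {
    stop("unknown sex label(s): ", paste(unique(s[bad]), collapse = ", "))
  }
  s
}
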