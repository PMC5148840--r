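#' Cohort table schema
#'
#' Column names, semantic types and units of the delimited cohort format.
#' Concentrations are mmol/L (glucose, triglycerides, HDL) and mIE/L
#' (insulin); the decimal separator is "." and empty strings are missing
#' values.
#'
#' @return list with `required`, `optional` and `numeric` column names and a
#'   `version` tag.
#' @export
cohort_schema <- function() {
  list(
    required = c("subject_id", "group", "sex", "age", "bmi", "waist",
                 "glucose_0", "glucose_30", "glucose_60", "glucose_120",
                 "insulin_0", "insulin_30", "insulin_60", "insulin_120"),
    optional = c("glucose_90", "insulin_90", "triglycerides", "hdl",
                 "smoker", "physical_activity", "family_history",
                 "diabetes_medication", "latent_isi", "latent_dio"),
    numeric = c("age", "bmi", "waist",
                "glucose_0", "glucose_30", "glucose_60", "glucose_90",
                "glucose_120", "insulin_0", "insulin_30", "insulin_60",
                "insulin_90", "insulin_120", "triglycerides", "hdl",
                "physical_activity", "latent_isi", "latent_dio"),
    logical = c("smoker", "family_history", "diabetes_medication"),
    version = "1"
  )
}

#' Read a cohort table from CSV
#'
#' Comma-separated, UTF-8, mandatory header row, "." decimal separator,
#' empty string = missing. Required columns must be present; rows whose
#' numeric fields fail to parse are dropped with a per-row message, the
#' remaining rows are loaded.
#'
#' @param path file path.
#' @param schema schema list, default [cohort_schema()].
#' @return validated cohort data frame; any dropped rows are recorded in the
#'   `"row_errors"` attribute (line numbers are 1-based data rows).
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0) stop("empty cohort file: ", path)
  absent <- setdiff(schema$required, names(raw))
  if (length(absent) > 0) {
    stop("cohort file is missing required column(s): ",
         paste(absent, collapse = ", "))
  }
  raw[raw == ""] <- NA

  row_errors <- data.frame(row = integer(0), column = character(0),
                           value = character(0), stringsAsFactors = FALSE)
  for (col in intersect(schema$numeric, names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad) > 0) {
      row_errors <- rbind(row_errors, data.frame(
        row = bad, column = col, value = raw[[col]][bad],
        stringsAsFactors = FALSE))
    }
    raw[[col]] <- v
  }
  if (nrow(row_errors) > 0) {
    drop <- unique(row_errors$row)
    message(length(drop), " row(s) dropped due to malformed numeric values ",
            "(rows ", paste(utils::head(drop, 5), collapse = ", "),
            if (length(drop) > 5) ", ..." else "", ")")
    raw <- raw[-drop, , drop = FALSE]
  }
  for (col in intersect(schema$logical, names(raw))) {
    raw[[col]] <- ifelse(is.na(raw[[col]]), NA, isTRUE_vec(raw[[col]]))
  }
  raw$sex <- normalize_sex(raw$sex)
  attr(raw, "row_errors") <- row_errors
  rownames(raw) <- NULL
  raw
}

#' Write a cohort (or any result table) to CSV at full precision
#'
#' Numeric columns are serialized with 17 significant digits so that a write
#' followed by [read_cohort()] reproduces every double bit-for-bit.
#'
#' @param x data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  y <- x
  for (col in names(y)) {
    if (is.numeric(y[[col]])) {
      y[[col]] <- ifelse(is.na(y[[col]]), "",
                         sprintf("%.17g", y[[col]]))
    }
  }
  utils::write.csv(y, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

report_defaults <- function() {
  list(
    scenario = "planted_shift", delta = 2, n = 1000,
    reference_group = "reference",
    thresholds = default_thresholds(),
    log10_vars = c("isi", "dio", "triglycerides"),
    model_terms = c("bmi", "waist", "triglycerides", "hdl", "smoker",
                    "physical_activity", "family_history"),
    moderator = "group",
    n_boot = 1000, bootstrap = FALSE, conf = 0.95,
    min_n = 30
  )
}

#' One-shot analysis report
#'
#' Chains the whole pipeline: simulate (or read) a cohort, apply the diabetes
#' exclusion, compute OGTT indices, derive the reference ISI tertiles,
#' cross-tabulate insulin-resistance prevalence, fit the equivalence cut-off
#' model, and fit the standardized risk-factor regression with a gated
#' interaction scan. All outputs are deterministic given the seed; a
#' structured log records exclusions, gating decisions and warnings together
#' with a hash of the effective configuration.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer master seed; mandatory (every stochastic stage draws
#'   from a sub-seed derived from it).
#' @param config named list overriding the defaults (see
#'   `isiequiv:::report_defaults()`), or a path to a YAML/JSON file with the
#'   same fields. Set `cohort_file` to analyse an existing cohort CSV
#'   instead of simulating.
#' @return invisibly, a list with the result tables and output file paths
#'   (`indices.csv`, `prevalence.csv`, `cutoffs.csv`, `fits.json`,
#'   `provenance.json`, `report.log`).
#' @export
run_report <- function(out_dir, seed, config = list()) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory for run_report")
  }
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg <- utils::modifyList(report_defaults(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop("output dir not writable: ", out_dir)

  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, pretty = TRUE)
  note("config hash: ", unname(tools::md5sum(cfg_file)))
  note("seed: ", seed)

  if (!is.null(cfg$cohort_file)) {
    cohort <- read_cohort(cfg$cohort_file)
    note("cohort read from ", cfg$cohort_file, " (n = ", nrow(cohort), ")")
  } else {
    params <- default_params(cfg$scenario, delta = cfg$delta, n = cfg$n,
                             seed = derive_seed(seed, "simulate"))
    cohort <- generate_cohort(params)
    note("cohort simulated: scenario ", cfg$scenario, ", n = ", nrow(cohort))
  }

  ex <- exclude_diabetes(cohort)
  cohort <- ex$cohort
  for (k in seq_len(nrow(ex$exclusions))) {
    note("excluded ", ex$exclusions$subject_id[k], ": ",
         ex$exclusions$reason[k])
  }
  note(nrow(ex$exclusions), " subject(s) excluded, ", nrow(cohort),
       " retained")

  indices <- ogtt_indices(cohort)
  note(sum(indices$cir_undefined), " subject(s) with undefined CIR")
  f_indices <- file.path(out_dir, "indices.csv")
  write_cohort(indices, f_indices)

  ref_isi <- indices$isi[cohort$group == cfg$reference_group &
                           !is.na(indices$isi)]
  ref <- tertile_reference(ref_isi)
  note(sprintf("reference ISI tertile boundaries: %.1f / %.1f (n = %d)",
               ref$cut_lo, ref$cut_hi, ref$n_reference))

  prev <- rbind(
    prevalence_crosstab(cohort, indices, ref, adiposity = "weight_class"),
    prevalence_crosstab(cohort, indices, ref, adiposity = "abdominal_obesity")
  )
  f_prev <- file.path(out_dir, "prevalence.csv")
  write_cohort(prev, f_prev)

  model <- withCallingHandlers(
    cutoff_model(cohort, reference_group = cfg$reference_group,
                 indices = indices, thresholds = cfg$thresholds,
                 min_n = cfg$min_n,
                 n_boot = if (isTRUE(cfg$bootstrap)) cfg$n_boot else 0,
                 conf = cfg$conf, seed = derive_seed(seed, "bootstrap")),
    warning = function(w) {
      note("warning (cutoffs): ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  f_cut <- file.path(out_dir, "cutoffs.csv")
  write_cohort(model$results, f_cut)

  prov <- list(
    package_version = as.character(utils::packageVersion("isiequiv")),
    reference_group = cfg$reference_group,
    thresholds = cfg$thresholds,
    tertiles = list(cut_lo = ref$cut_lo, cut_hi = ref$cut_hi,
                    n = ref$n_reference),
    fits = lapply(model$fits, function(pair) {
      lapply(pair, function(f) {
        f[c("group", "sex", "measure", "outcome", "intercept", "slope",
            "n", "residual_sd")]
      })
    })
  )
  f_prov <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, f_prov, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  ana <- merge(cohort, indices[c("subject_id", "isi", "dio")],
               by = "subject_id")
  ana <- log10_transform(ana, cfg$log10_vars)
  terms_present <- intersect(cfg$model_terms, names(ana))
  fml <- stats::as.formula(paste("isi ~", paste(terms_present,
                                                collapse = " + ")))
  fits <- list()
  for (sx in sort(unique(ana$sex))) {
    dat <- ana[ana$sex == sx, , drop = FALSE]
    reg <- withCallingHandlers(
      isi_regression(fml, dat),
      warning = function(w) {
        note("warning (regression, ", sx, "): ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    scan <- interaction_scan(reg, cfg$moderator)
    for (k in seq_len(nrow(scan))) {
      note("interaction scan (", sx, ") term ", scan$term[k], ": ",
           scan$status[k])
    }
    fits[[sx]] <- list(
      outcome = "log10_isi", n = reg$n, r2 = reg$r2,
      beta = as.list(reg$beta),
      ci_lo = as.list(reg$ci[, 1]), ci_hi = as.list(reg$ci[, 2]),
      p = as.list(reg$p),
      vif = if (is.null(reg$vif)) NULL else as.list(reg$vif),
      interactions = scan
    )
  }
  f_fits <- file.path(out_dir, "fits.json")
  jsonlite::write_json(fits, f_fits, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  f_log <- file.path(out_dir, "report.log")
  writeLines(log_lines, f_log)

  invisible(list(
    cohort = cohort, indices = indices, tertiles = ref, prevalence = prev,
    cutoffs = model, fits = fits,
    files = c(indices = f_indices, prevalence = f_prev, cutoffs = f_cut,
              fits = f_fits, provenance = f_prov, log = f_log,
              config = cfg_file)
  ))
}
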