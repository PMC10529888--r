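cohort_required_cols <- c(
  "id", "t1_plain", "t1_hbp", "lv_ml", "resected_ml",
  "pdr_pre", "r15_pre", "pdr_post", "r15_post",
  "bili_preop", paste0("bili_pod", 3:7),
  "inr_preop", paste0("inr_pod", 3:7),
  "time_days", "event"
)

#' Read / write a cohort CSV
#'
#' One row per patient. Mandatory columns: `id`, the T1 pair
#' (`t1_plain`, `t1_hbp`, ms), volumes (`lv_ml`, `resected_ml`), pre-
#' and postoperative ICG results (`pdr_pre`, `r15_pre`, `pdr_post`,
#' `r15_post`), the lab course in wide form (`bili_preop`,
#' `bili_pod3`..`bili_pod7` in mg/dL; `inr_preop`, `inr_pod3`..`inr_pod7`),
#' and survival (`time_days`, logical `event`). Extra columns (e.g.
#' `surgery_type` or the generator's latent fields) round-trip
#' unchanged; missing values are empty fields. Numeric fields
#' round-trip bit-identically.
#'
#' @param path CSV file path.
#' @return `read_cohort()` returns the cohort tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("No cohort file at `%s`.", path))
  raw <- suppressWarnings(readr::read_csv(
    path, col_types = readr::cols(.default = readr::col_character()),
    comment = "#"))
  missing <- setdiff(cohort_required_cols, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Cohort file is missing mandatory columns: ",
                 paste(missing, collapse = ", "), "."))
  }
  # numeric conversion through base strtod (correctly rounded, so the
  # 17-digit serialisation round-trips bit-identically)
  char_cols <- c("id", "surgery_type")
  logical_cols <- c("event", "ldf_latent")
  bad <- character(0)
  cohort <- raw
  for (col in setdiff(names(raw), char_cols)) {
    v <- raw[[col]]
    filled <- !is.na(v) & v != ""
    if (col %in% logical_cols) {
      parsed <- as.logical(toupper(v))
    } else {
      parsed <- suppressWarnings(as.numeric(v))
    }
    broken <- which(filled & is.na(parsed))
    if (length(broken) > 0) {
      if (col %in% cohort_required_cols) {
        bad <- c(bad, sprintf("row %d, column `%s`: `%s`",
                              broken + 1, col, v[broken]))
      }
      next  # undeclared extra column stays character
    }
    cohort[[col]] <- parsed
  }
  if (length(bad) > 0) {
    abort(paste0("Malformed cells in `", path, "`:\n  ",
                 paste(utils::head(bad, 10), collapse = "\n  ")))
  }
  if (anyDuplicated(cohort$id)) abort("Patient identifiers must be unique.")
  cohort
}

#' @rdname read_cohort
#' @param cohort Cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  missing <- setdiff(cohort_required_cols, names(cohort))
  if (length(missing) > 0) {
    abort(paste0("Cohort is missing mandatory columns: ",
                 paste(missing, collapse = ", "), "."))
  }
  # doubles serialised at 17 significant digits so write/read is the
  # identity on every numeric field
  out <- dplyr::mutate(tibble::as_tibble(cohort), dplyr::across(
    dplyr::where(is.double),
    function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' Bundles every tunable of the analysis: generator parameters (used
#' when no cohort file is supplied), model coefficients, classification
#' cut-offs and outcome thresholds, plus the seed. Configurations
#' round-trip losslessly through a flat `key = value` text file.
#'
#' @param params A [generator_params()].
#' @param coefficients A [model_coefficients()].
#' @param class_rule An [icg_class_rule()].
#' @param outcome A [outcome_rule()].
#' @param cohort_path Optional path to an observed-cohort CSV; when set,
#'   the generator is bypassed.
#' @param output_dir Optional directory for CSV outputs.
#' @param seed Integer seed applied to the generator.
#' @return A `run_config` list.
#' @export
run_config <- function(params = generator_params(n = 71),
                       coefficients = model_coefficients(),
                       class_rule = icg_class_rule(),
                       outcome = outcome_rule(),
                       cohort_path = NULL, output_dir = NULL, seed = 1) {
  check_number(seed, "seed")
  structure(
    list(params = params, coefficients = coefficients,
         class_rule = class_rule, outcome = outcome,
         cohort_path = cohort_path, output_dir = output_dir,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

fmt_val <- function(x) {
  if (is.character(x)) paste(x, collapse = ",")
  else if (is.logical(x)) paste(ifelse(x, "true", "false"), collapse = ",")
  else paste(sprintf("%.17g", x), collapse = ",")
}

#' Write / read a run configuration as a flat key=value file
#'
#' Numeric values are serialised with 17 significant digits, so the
#' round trip is lossless.
#'
#' @param config A [run_config()].
#' @param path Destination file.
#' @return `read_run_config()` returns the [run_config()];
#'   `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config.")
  p <- config$params
  rf <- p$resection_fractions
  lines <- c(
    "# erlf run configuration (flat key=value)",
    sprintf("seed=%d", config$seed),
    if (!is.null(config$cohort_path)) sprintf("cohort_path=%s", config$cohort_path),
    if (!is.null(config$output_dir)) sprintf("output_dir=%s", config$output_dir),
    unlist(lapply(setdiff(names(p), c("resection_fractions", "seed")),
                  function(k) sprintf("generator.%s=%s", k, fmt_val(p[[k]])))),
    if (!is.null(p$seed)) sprintf("generator.seed=%d", p$seed),
    sprintf("generator.resection_types=%s", fmt_val(rf$type)),
    sprintf("generator.resection_fraction_values=%s", fmt_val(rf$fraction)),
    sprintf("generator.resection_weights=%s", fmt_val(rf$weight)),
    unlist(lapply(names(config$coefficients),
                  function(k) sprintf("coefficients.%s=%s", k, fmt_val(config$coefficients[[k]])))),
    unlist(lapply(names(config$class_rule),
                  function(k) sprintf("class_rule.%s=%s", k, fmt_val(config$class_rule[[k]])))),
    unlist(lapply(names(config$outcome),
                  function(k) sprintf("outcome.%s=%s", k, fmt_val(config$outcome[[k]]))))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No config file at `%s`.", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  get_val <- function(key, default = NULL) {
    if (!key %in% keys) return(default)
    vals[match(key, keys)]
  }
  num <- function(key, default = NULL) {
    v <- get_val(key)
    if (is.null(v)) return(default)
    as.numeric(strsplit(v, ",", fixed = TRUE)[[1]])
  }
  section <- function(prefix, skip = character()) {
    sel <- startsWith(keys, paste0(prefix, "."))
    nms <- sub(paste0("^", prefix, "\\."), "", keys[sel])
    keep <- !nms %in% skip
    setNames(lapply(vals[sel][keep], function(v) {
      as.numeric(strsplit(v, ",", fixed = TRUE)[[1]])
    }), nms[keep])
  }
  rf_skip <- c("resection_types", "resection_fraction_values", "resection_weights")
  gen_args <- section("generator", skip = rf_skip)
  gen_args$resection_fractions <- tibble::tibble(
    type = strsplit(get_val("generator.resection_types"), ",")[[1]],
    fraction = num("generator.resection_fraction_values"),
    weight = num("generator.resection_weights")
  )
  run_config(
    params = do.call(generator_params, gen_args),
    coefficients = do.call(model_coefficients, section("coefficients")),
    class_rule = do.call(icg_class_rule, section("class_rule")),
    outcome = do.call(outcome_rule, section("outcome")),
    cohort_path = get_val("cohort_path"),
    output_dir = get_val("output_dir"),
    seed = num("seed")
  )
}

#' Run the full remnant-function analysis pipeline
#'
#' Loads (or generates) a cohort, derives per-patient scores (RR, eLF,
#' rLV, erLF) and classifications, then evaluates two predictors of the
#' postoperative reference (ICG-PDR < 10 %/min): the preoperative ICG
#' classification (LDF) and the erLF classification (predicted PLDF).
#' For each, it reports the confusion matrix, the five diagnostic
#' metrics, and the ROC-AUC of the underlying continuous score
#' (preoperative PDR, erLF; both oriented lower-is-positive). Clinical
#' outcome flags, Kaplan-Meier coordinates per erLF class and the
#' univariable Cox fit of overall survival on erLF complete the report.
#' Every threshold applied is echoed in the run log.
#'
#' @param config A [run_config()].
#' @return An `erlf_report` list with elements `cohort` (scored tibble
#'   including outcome flags), `metrics` (one row per model),
#'   `confusions`, `cox`, `km`, and `log`. When `config$output_dir` is
#'   set, `cohort_scored.csv`, `metrics.csv`, `km.csv`, `cox.csv` and
#'   `run_log.txt` are written there.
#' @examples
#' report <- run_pipeline(run_config(params = generator_params(n = 71, seed = 42)))
#' report$metrics
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config.")
  co <- config$coefficients
  rule <- config$class_rule
  pretty <- function(x) format(x, digits = 15, trim = TRUE)
  log <- c(
    "erlf pipeline run",
    sprintf("model: %s * exp(%s * RR) * exp(%s * volume / %s mL)",
            pretty(co$scale), pretty(co$rr_coeff), pretty(co$vol_coeff),
            pretty(co$vol_unit_ml)),
    paste0("note: the volume coefficient is applied per ", pretty(co$vol_unit_ml),
           " mL; a literal per-mL exponent would leave the published",
           " coefficients dimensionally inconsistent with PDR-scale scores"),
    sprintf("cut-offs: preop PDR < %s or R15 > %s -> LDF; postop/erLF < %s -> PLDF, > %s -> PNLF",
            pretty(rule$preop_pdr_cutoff), pretty(rule$preop_r15_cutoff),
            pretty(rule$postop_lower), pretty(rule$postop_upper)),
    sprintf("outcome: bili > %s mg/dL or INR > %s (and above baseline), days %s-%s; severe: 50/50 (bili > %s umol/L = %s mg/dL and INR > %s) or bili > %s mg/dL",
            pretty(config$outcome$bili_dysfunction_mg_dl),
            pretty(config$outcome$inr_dysfunction),
            min(config$outcome$window_days), max(config$outcome$window_days),
            pretty(config$outcome$fifty_fifty_bili_umol_l),
            pretty(round_half_up(convert_bilirubin(
              config$outcome$fifty_fifty_bili_umol_l, config$outcome), 2)),
            pretty(config$outcome$fifty_fifty_inr),
            pretty(config$outcome$severe_bili_mg_dl))
  )

  stage <- "load_cohort"
  result <- tryCatch({
    if (!is.null(config$cohort_path)) {
      cohort <- read_cohort(config$cohort_path)
      log <- c(log, sprintf("cohort: %d records read from %s",
                            nrow(cohort), config$cohort_path))
    } else {
      p <- config$params
      if (is.null(p$seed)) {
        p$seed <- config$seed
      }
      cohort <- generate_cohort(p)
      log <- c(log, sprintf("cohort: %d records generated (seed %d)",
                            nrow(cohort), p$seed))
    }

    stage <- "score"
    cohort <- score_cohort(cohort, coefficients = co, rule = rule)

    stage <- "clinical_outcome"
    flags <- purrr::map_dfr(
      seq_len(nrow(cohort)),
      function(i) {
        row <- cohort[i, ]
        clinical_outcome(
          preop_bili = row$bili_preop,
          bili_series = data.frame(pod = 3:7,
                                   value = as.numeric(row[paste0("bili_pod", 3:7)])),
          preop_inr = row$inr_preop,
          inr_series = data.frame(pod = 3:7,
                                  value = as.numeric(row[paste0("inr_pod", 3:7)])),
          rule = config$outcome
        )
      })
    cohort <- dplyr::bind_cols(cohort, flags)

    stage <- "evaluate"
    reference <- cohort$postop_class == "PLDF"
    log <- c(log, sprintf("reference: postoperative PDR < %s %%/min (%d of %d positive)",
                          format(rule$postop_lower), sum(reference), nrow(cohort)))
    cms <- list(
      preop_icg = confusion(cohort$preop_class == "LDF", reference),
      erlf = confusion(cohort$erlf_class == "PLDF", reference)
    )
    aucs <- c(
      preop_icg = roc_auc(cohort$pdr_pre, reference, "lower_is_positive"),
      erlf = roc_auc(cohort$erlf, reference, "lower_is_positive")
    )
    metrics <- dplyr::bind_rows(lapply(names(cms), function(m) {
      dplyr::bind_cols(tibble::tibble(model = m), diagnostic_metrics(cms[[m]]),
                       tibble::tibble(auc = unname(aucs[m])))
    }))

    stage <- "survival"
    cox <- cox_univariable(cohort, "erlf")
    km <- km_by_class(cohort)
    log <- c(log, sprintf("cox: HR %.4f per erLF unit (95%% CI %.4f; %.4f), %d events",
                          cox$hr, cox$ci_low, cox$ci_high, cox$n_events))

    list(cohort = cohort, metrics = metrics, confusions = cms,
         cox = cox, km = km, log = log)
  }, error = function(e) {
    abort(sprintf("Pipeline failed at stage `%s`: %s", stage, conditionMessage(e)))
  })

  report <- structure(result, class = "erlf_report")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(report$cohort, file.path(config$output_dir, "cohort_scored.csv"))
    readr::write_csv(report$metrics, file.path(config$output_dir, "metrics.csv"))
    readr::write_csv(report$km, file.path(config$output_dir, "km.csv"))
    readr::write_csv(tidy(report$cox), file.path(config$output_dir, "cox.csv"))
    writeLines(report$log, file.path(config$output_dir, "run_log.txt"))
  }
  report
}

#' @export
print.erlf_report <- function(x, ...) {
  cat("erlf pipeline report\n")
  cat(sprintf("  %d patients; %d reference PLDF\n", nrow(x$cohort),
              sum(x$cohort$postop_class == "PLDF")))
  print(x$metrics)
  print(x$cox)
  invisible(x)
}
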