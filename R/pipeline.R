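# Pipeline orchestration: CSV schema I/O, per-subject fitting, group
# summaries, agreement statistics, and report serialisation.

SERIES_CSV_COLUMNS <- c("subject_id", "group", "matrix", "time_min",
                        "concentration", "unit", "censor_flag")

#' Read the pipeline series CSV
#'
#' Strict typed parsing of the schema
#' `subject_id, group, matrix, time_min, concentration, unit, censor_flag`
#' (censor_flag may be empty on input, meaning `"observed"`). Duplicate
#' `(subject, matrix, time)` rows, non-monotone times, negative observed
#' concentrations and unknown units/matrices are schema errors naming the
#' offending rows; a gas-phase unit on plasma rows (or vice versa) logs a
#' unit-mismatch warning.
#'
#' @param path CSV file path.
#' @return A named list of subject records, each a list with `subject_id`,
#'   `group`, and `breath`/`plasma` [concentration_series()] (possibly
#'   absent).
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) {
    b2p_stop("b2p_schema_error", sprintf("input file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(SERIES_CSV_COLUMNS, names(df))
  if (length(missing)) {
    b2p_stop("b2p_schema_error", sprintf(
      "missing column(s): %s", paste(missing, collapse = ", ")))
  }
  df$subject_id <- as.character(df$subject_id)
  if (!is.numeric(df$time_min) || !is.numeric(df$concentration)) {
    b2p_stop("b2p_schema_error", "time_min and concentration must be numeric")
  }
  df$censor_flag[is.na(df$censor_flag) | df$censor_flag == ""] <- "observed"
  bad_flag <- which(!df$censor_flag %in% CENSOR_FLAGS)
  if (length(bad_flag)) {
    b2p_stop("b2p_schema_error", sprintf(
      "invalid censor_flag at row(s) %s", paste(utils::head(bad_flag, 5), collapse = ", ")))
  }
  bad_matrix <- which(!df$matrix %in% c("breath", "plasma"))
  if (length(bad_matrix)) {
    b2p_stop("b2p_schema_error", sprintf(
      "invalid matrix at row(s) %s", paste(utils::head(bad_matrix, 5), collapse = ", ")))
  }
  bad_unit <- which(!df$unit %in% SERIES_UNITS)
  if (length(bad_unit)) {
    b2p_stop("b2p_schema_error", sprintf(
      "invalid unit at row(s) %s", paste(utils::head(bad_unit, 5), collapse = ", ")))
  }
  neg <- which(df$concentration < 0 & df$censor_flag == "observed")
  if (length(neg)) {
    b2p_stop("b2p_schema_error", sprintf(
      "negative concentration at row(s) %s", paste(utils::head(neg, 5), collapse = ", ")))
  }
  key <- paste(df$subject_id, df$matrix, df$time_min)
  if (anyDuplicated(key)) {
    b2p_stop("b2p_schema_error", sprintf(
      "duplicated (subject, matrix, time) at row(s) %s",
      paste(utils::head(which(duplicated(key)), 5), collapse = ", ")))
  }
  gas_on_plasma <- df$matrix == "plasma" & df$unit %in% c("ppbv", "pptv")
  liq_on_breath <- df$matrix == "breath" & df$unit %in% c("ug/mL", "ng/mL")
  if (any(gas_on_plasma | liq_on_breath)) {
    b2p_warn("b2p_unit_mismatch", sprintf(
      "unit/matrix mismatch at row(s) %s",
      paste(utils::head(which(gas_on_plasma | liq_on_breath), 5), collapse = ", ")))
  }
  records <- list()
  for (sid in unique(df$subject_id)) {
    rec <- list(subject_id = sid,
                group = df$group[df$subject_id == sid][1])
    for (mx in c("breath", "plasma")) {
      sub <- df[df$subject_id == sid & df$matrix == mx, , drop = FALSE]
      if (nrow(sub) == 0L) next
      if (is.unsorted(sub$time_min, strictly = TRUE)) {
        # rows may arrive time-sorted or not; re-sorting is safe because
        # duplicates were already rejected
        sub <- sub[order(sub$time_min), , drop = FALSE]
      }
      unit <- unique(sub$unit)
      if (length(unit) != 1L) {
        b2p_stop("b2p_schema_error", sprintf(
          "mixed units within subject %s %s series", sid, mx))
      }
      rec[[mx]] <- concentration_series(
        sid, mx, sub$time_min, sub$concentration, unit,
        censored = sub$censor_flag, group = rec$group)
    }
    records[[sid]] <- rec
  }
  records
}

#' Write subject records (or a cohort) to the pipeline series CSV
#'
#' Numbers are written with `%.6g`, making a read-write cycle byte-stable
#' modulo that documented formatting.
#'
#' @param x a `"cohort"` from [generate_cohort()] or a record list as
#'   returned by [read_series_csv()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path) {
  records <- if (inherits(x, "cohort")) x$subjects else x
  rows <- list()
  for (rec in records) {
    for (mx in c("breath", "plasma")) {
      s <- rec[[mx]]
      if (is.null(s)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s$subject_id,
        group = if (!is.null(rec$group)) rec$group else s$group,
        matrix = mx,
        time_min = fmt_num(s$times),
        concentration = fmt_num(s$values),
        unit = s$unit,
        censor_flag = s$censored)
    }
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param input path to a series CSV, a `"cohort"` object, or `NULL` to
#'   simulate a default cohort from `seed`.
#' @param doses data.frame (`subject_id`, `dose_mg`) or path to such a
#'   CSV; taken from the cohort when simulating.
#' @param calibration optional [calibration_curve()], path to a curve
#'   JSON, or path to a standards CSV (fitted on the fly).
#' @param lod breath detection limit override, ppbv.
#' @param model_selection `"fixed2"` (report the two-compartment fit, the
#'   study's reporting convention) or `"aic"` (report the lowest-AIC
#'   structure). All three structures are fitted and logged either way,
#'   unless `fit_structures = "two-only"`.
#' @param fit_structures `"all"` (default: fit 1-, 2- and 3-compartment
#'   structures so the AIC table is complete) or `"two-only"` (fit only
#'   the two-compartment model; roughly 5x faster, intended for large
#'   simulation sweeps where only the reported fit is consumed). Requires
#'   `model_selection = "fixed2"`.
#' @param regression_scope `"pooled"` or `"per-group"` (per-group also
#'   emits the pooled model).
#' @param icc_log_scale compute Bland-Altman on the log scale.
#' @param pair_tolerance pairing window, minutes.
#' @param seed integer seed (used only when simulating).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, doses = NULL, calibration = NULL,
                            lod = 0.04,
                            model_selection = c("fixed2", "aic"),
                            fit_structures = c("all", "two-only"),
                            regression_scope = c("pooled", "per-group"),
                            icc_log_scale = FALSE,
                            pair_tolerance = 1 / 6,
                            seed = 20250212) {
  model_selection <- match.arg(model_selection)
  fit_structures <- match.arg(fit_structures)
  regression_scope <- match.arg(regression_scope)
  if (fit_structures == "two-only" && model_selection != "fixed2") {
    b2p_stop("b2p_invalid_argument",
             "fit_structures = 'two-only' requires model_selection = 'fixed2'")
  }
  if (is.character(input) && !file.exists(input)) {
    b2p_stop("b2p_invalid_argument", sprintf("input path does not exist: %s", input))
  }
  structure(
    list(input = input, doses = doses, calibration = calibration,
         lod = lod, model_selection = model_selection,
         fit_structures = fit_structures,
         regression_scope = regression_scope,
         icc_log_scale = icc_log_scale,
         pair_tolerance = pair_tolerance, seed = as.integer(seed)),
    class = "pipeline_config")
}

resolve_doses <- function(config, cohort) {
  if (!is.null(cohort)) {
    return(data.frame(
      subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
      dose_mg = vapply(cohort$subjects, function(s) s$dose$amount, 1)))
  }
  d <- config$doses
  if (is.character(d)) d <- utils::read.csv(d, stringsAsFactors = FALSE,
                                            colClasses = c(subject_id = "character"))
  if (is.null(d) || !all(c("subject_id", "dose_mg") %in% names(d))) {
    b2p_stop("b2p_schema_error",
             "doses must provide columns subject_id, dose_mg")
  }
  d
}

fit_one <- function(series, dose, config) {
  if (identical(config$fit_structures, "two-only")) {
    f2 <- fit_compartment_model(series, dose, 2L)
    return(list(primary = f2, selected = f2,
                aic_table = data.frame(n_compartments = 2L, aic = f2$aic,
                                       ssr = f2$ssr, status = "ok")))
  }
  sel <- select_model(series, dose)
  primary <- if (config$model_selection == "fixed2" && !is.null(sel$fit2)) {
    sel$fit2
  } else {
    sel
  }
  list(primary = primary, selected = sel, aic_table = sel$aic_table)
}

fit_row <- function(fit, rec, mx) {
  d <- fit$derived
  data.frame(
    group = rec$group, subject_id = rec$subject_id, matrix = mx,
    n_compartments = fit$n_compartments,
    V1 = fit$micro$V1, K10 = fit$micro$K10,
    K12 = if (is.null(fit$micro$K12)) NA_real_ else fit$micro$K12,
    K21 = if (is.null(fit$micro$K21)) NA_real_ else fit$micro$K21,
    T_half_alpha = d$t_half_alpha, T_half_beta = d$t_half_beta,
    CL = d$cl, AUC_0_120 = d$auc_0_T, SSR = fit$ssr, AIC = fit$aic)
}

#' Run the full breath-to-plasma analysis pipeline
#'
#' Orchestrates: (optional) simulation or CSV ingestion, censoring,
#' per-subject compartmental fits for both matrices (all three structures
#' fitted, AICs logged), a parameter-table-style group summary with
#' breath-vs-plasma t-tests, observed Cmax/Tmax with dose-group ANOVA,
#' breath-plasma pairing, Spearman correlation, log-log regression
#' (pooled and optionally per group), breath-based plasma prediction, and
#' per-group ICC / Bland-Altman agreement of predicted vs measured plasma.
#'
#' @param config a [pipeline_config()].
#' @return A report bundle (list of class `"b2p_report"`) with elements
#'   `fits`, `fit_failures`, `aic_tables`, `group_summary`, `observed`,
#'   `anova_cmax`, `pairs`, `spearman`, `regression`, `predictions`,
#'   `agreement`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- NULL
  if (is.null(config$input)) {
    cohort <- generate_cohort(cohort_config(seed = config$seed))
    records <- lapply(cohort$subjects, function(s) {
      list(subject_id = s$subject_id, group = s$group,
           breath = s$breath, plasma = s$plasma)
    })
    names(records) <- vapply(records, `[[`, "", "subject_id")
  } else if (inherits(config$input, "cohort")) {
    cohort <- config$input
    records <- lapply(cohort$subjects, function(s) {
      list(subject_id = s$subject_id, group = s$group,
           breath = s$breath, plasma = s$plasma)
    })
    names(records) <- vapply(records, `[[`, "", "subject_id")
  } else {
    records <- read_series_csv(config$input)
  }
  doses <- resolve_doses(config, cohort)

  calib <- config$calibration
  if (is.character(calib)) {
    calib <- if (grepl("\\.json$", calib)) {
      read_calibration_json(calib)
    } else {
      fit_calibration(utils::read.csv(calib))
    }
  }

  fit_rows <- list(); aic_tables <- list(); failures <- list()
  obs_rows <- list()
  pair_rows <- list()
  for (rec in records) {
    dose_mg <- doses$dose_mg[match(rec$subject_id, doses$subject_id)]
    if (is.na(dose_mg)) {
      b2p_stop("b2p_schema_error", sprintf("no dose for subject %s", rec$subject_id))
    }
    dose <- dose_event(dose_mg)
    for (mx in c("breath", "plasma")) {
      s <- rec[[mx]]
      if (is.null(s)) next
      if (mx == "breath") s <- censor_series(s, config$lod)
      rec[[mx]] <- s
      res <- tryCatch(fit_one(s, dose, config), b2p_error = function(e) e)
      key <- paste(rec$subject_id, mx, sep = ":")
      if (inherits(res, "condition")) {
        failures[[key]] <- conditionMessage(res)
        next
      }
      fit_rows[[key]] <- fit_row(res$primary, rec, mx)
      aic_tables[[key]] <- res$aic_table
      om <- tryCatch(observed_metrics(s), b2p_error = function(e) NULL)
      if (!is.null(om)) {
        obs_rows[[key]] <- data.frame(
          group = rec$group, subject_id = rec$subject_id, matrix = mx,
          c_max = om$c_max, t_max = om$t_max, unit = s$unit)
      }
    }
    if (!is.null(rec$breath) && !is.null(rec$plasma)) {
      pr <- tryCatch(
        pair_matrices(rec$breath, rec$plasma, config$pair_tolerance),
        b2p_error = function(e) NULL)
      if (!is.null(pr)) {
        pr$subject_id <- rec$subject_id
        pr$group <- rec$group
        pair_rows[[rec$subject_id]] <- pr
      }
    }
  }
  if (length(fit_rows) == 0L) {
    b2p_stop("b2p_fit_failure", "all subject fits failed")
  }
  fits <- do.call(rbind, fit_rows); rownames(fits) <- NULL
  observed <- do.call(rbind, obs_rows); rownames(observed) <- NULL
  pairs <- do.call(rbind, pair_rows); rownames(pairs) <- NULL

  group_summary <- summarise_groups(fits)

  anova_cmax <- lapply(c("breath", "plasma"), function(mx) {
    sub <- observed[observed$matrix == mx, , drop = FALSE]
    gs <- split(sub$c_max, sub$group)
    if (length(gs) >= 2L && all(lengths(gs) >= 2L)) {
      res <- one_way_anova(gs)
      data.frame(matrix = mx, F = res$statistic, df1 = res$df[1],
                 df2 = res$df[2], p = res$p_value)
    }
  })
  anova_cmax <- do.call(rbind, anova_cmax)

  spearman <- regression <- agreement <- NULL
  predictions <- NULL
  if (!is.null(pairs) && nrow(pairs) >= 3L) {
    spearman_all <- spearman_correlation(pairs)
    spearman <- data.frame(scope = "ALL", r = spearman_all$r,
                           p = spearman_all$p_value, n = spearman_all$n)
    pooled <- fit_loglog(pairs)
    regression <- data.frame(
      scope = "ALL", slope = pooled$slope, intercept = pooled$intercept,
      r_squared = pooled$r_squared, n_pairs = pooled$n_pairs)
    if (config$regression_scope == "per-group") {
      for (g in unique(pairs$group)) {
        sub <- pairs[pairs$group == g, , drop = FALSE]
        if (nrow(sub) >= 3L) {
          m <- fit_loglog(sub)
          sp <- spearman_correlation(sub)
          regression <- rbind(regression, data.frame(
            scope = g, slope = m$slope, intercept = m$intercept,
            r_squared = m$r_squared, n_pairs = m$n_pairs))
          spearman <- rbind(spearman, data.frame(
            scope = g, r = sp$r, p = sp$p_value, n = sp$n))
        }
      }
    }
    predictions <- pairs
    predictions$cp_predicted <- predict_plasma(pooled, predictions$ce)
    agr_rows <- list()
    agr_rows[["ALL"]] <- c(scope = "ALL",
                           icc_agreement(predictions$cp, predictions$cp_predicted,
                                         log_scale = config$icc_log_scale))
    for (g in unique(predictions$group)) {
      sub <- predictions[predictions$group == g, , drop = FALSE]
      if (nrow(sub) >= 3L) {
        agr_rows[[g]] <- c(scope = g,
                           icc_agreement(sub$cp, sub$cp_predicted,
                                         log_scale = config$icc_log_scale))
      }
    }
    agreement <- do.call(rbind, lapply(agr_rows, function(a) data.frame(
      scope = a$scope, icc = a$icc, icc_ci_low = a$icc_ci[1],
      icc_ci_high = a$icc_ci[2], p = a$p_value, bias = a$bias,
      loa_low = a$loa_low, loa_high = a$loa_high, n = a$n)))
    rownames(agreement) <- NULL
  }

  structure(
    list(fits = fits, fit_failures = failures, aic_tables = aic_tables,
         group_summary = group_summary, observed = observed,
         anova_cmax = anova_cmax, pairs = pairs, spearman = spearman,
         regression = regression, predictions = predictions,
         agreement = agreement,
         calibration = calib,
         log = list(seed = config$seed,
                    model_selection = config$model_selection,
                    regression_scope = config$regression_scope,
                    lod = config$lod,
                    package_version = as.character(utils::packageVersion("breath2plasma")),
                    r_version = paste(R.version$major, R.version$minor, sep = "."))),
    class = "b2p_report")
}

# Table-1-style group summary: mean (SD) per parameter, matrix and group,
# with breath-vs-plasma t-tests for the commensurable parameters only.
summarise_groups <- function(fits) {
  params <- c("V1", "CL", "AUC_0_120", "T_half_alpha", "T_half_beta",
              "K10", "K12", "K21")
  rows <- list()
  for (g in unique(fits$group)) {
    for (p in params) {
      ce <- fits[fits$group == g & fits$matrix == "breath", p]
      cp <- fits[fits$group == g & fits$matrix == "plasma", p]
      pval <- NA_real_
      if (!p %in% INCOMMENSURABLE_PARAMS &&
          length(ce) == length(cp) && length(ce) >= 2L &&
          !anyNA(ce) && !anyNA(cp)) {
        pval <- tryCatch(compare_parameters(ce, cp, p)$p_value,
                         b2p_error = function(e) NA_real_)
      }
      rows[[paste(g, p)]] <- data.frame(
        group = g, parameter = p,
        ce_mean = mean(ce), ce_sd = stats::sd(ce),
        cp_mean = mean(cp), cp_sd = stats::sd(cp),
        ce_label = sprintf("%.2f (%.2f)", mean(ce), stats::sd(ce)),
        cp_label = sprintf("%.2f (%.2f)", mean(cp), stats::sd(cp)),
        p = pval)
    }
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

#' Write a report bundle to disk
#'
#' Emits `report.json` (the full bundle, numbers at full precision) plus
#' flat CSV tables: `fits.csv`, `group_summary.csv`, `observed.csv`,
#' `pairs.csv`, `predictions.csv` and `statistics.csv` (one row per
#' statistic: name, group, estimate, ci_low, ci_high, p).
#'
#' @param bundle a `"b2p_report"` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "b2p_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ser <- bundle
  ser$calibration <- if (!is.null(bundle$calibration)) {
    unclass(bundle$calibration)
  }
  jsonlite::write_json(
    lapply(ser, function(x) if (inherits(x, "condition")) conditionMessage(x) else x),
    file.path(dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null")
  for (tab in c("fits", "group_summary", "observed", "pairs", "predictions")) {
    if (!is.null(bundle[[tab]])) {
      utils::write.csv(bundle[[tab]], file.path(dir, paste0(tab, ".csv")),
                       row.names = FALSE)
    }
  }
  stats_rows <- list()
  add <- function(name, group, estimate, ci_low = NA, ci_high = NA, p = NA) {
    stats_rows[[length(stats_rows) + 1L]] <<- data.frame(
      name = name, group = group, estimate = estimate,
      ci_low = ci_low, ci_high = ci_high, p = round(p, 3))
  }
  if (!is.null(bundle$spearman)) {
    for (i in seq_len(nrow(bundle$spearman))) {
      r <- bundle$spearman[i, ]
      add("spearman_r", r$scope, r$r, p = r$p)
    }
  }
  if (!is.null(bundle$regression)) {
    for (i in seq_len(nrow(bundle$regression))) {
      r <- bundle$regression[i, ]
      add("loglog_slope", r$scope, r$slope)
      add("loglog_intercept", r$scope, r$intercept)
      add("loglog_r_squared", r$scope, r$r_squared)
    }
  }
  if (!is.null(bundle$agreement)) {
    for (i in seq_len(nrow(bundle$agreement))) {
      r <- bundle$agreement[i, ]
      add("icc", r$scope, r$icc, r$icc_ci_low, r$icc_ci_high, r$p)
      add("bland_altman_bias", r$scope, r$bias, r$loa_low, r$loa_high)
    }
  }
  if (!is.null(bundle$anova_cmax)) {
    for (i in seq_len(nrow(bundle$anova_cmax))) {
      r <- bundle$anova_cmax[i, ]
      add("anova_cmax_F", r$matrix, r$F, p = r$p)
    }
  }
  if (length(stats_rows)) {
    utils::write.csv(do.call(rbind, stats_rows),
                     file.path(dir, "statistics.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.b2p_report <- function(x, ...) {
  cat(sprintf("<b2p_report> %d fits (%d failures), %s pairs\n",
              nrow(x$fits), length(x$fit_failures),
              if (is.null(x$pairs)) 0 else nrow(x$pairs)))
  if (!is.null(x$regression)) {
    r <- x$regression[x$regression$scope == "ALL", ]
    cat(sprintf("  pooled link: LN(cp) = %.4g LN(ce) %+.4g (R^2 %.3f, n %d)\n",
                r$slope, r$intercept, r$r_squared, r$n_pairs))
  }
  if (!is.null(x$agreement)) {
    for (i in seq_len(nrow(x$agreement))) {
      a <- x$agreement[i, ]
      cat(sprintf("  ICC[%s] = %.3f (%.3f, %.3f)\n",
                  a$scope, a$icc, a$icc_ci_low, a$icc_ci_high))
    }
  }
  invisible(x)
}
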