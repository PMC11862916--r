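# Synthetic cohort generator: emulates a three-group (1/2/4 x ED50)
# rat bolus design with breath sampled every 20 s and plasma at nine
# post-dose draws, so the whole pipeline is testable without animal data.
#
# Plasma kinetics are simulated mechanistically (two-compartment bolus,
# group means set to the plasma columns of the study's parameter table);
# breath is derived from plasma through the empirical log-log link rather
# than a lung compartment, which guarantees the agreement stage has an
# exactly known truth.

#' Default per-group plasma micro-parameters
#'
#' Group means used by [cohort_config()]: central volume and rate
#' constants of the two-compartment plasma model for the low (6 mg/kg),
#' medium (12 mg/kg) and high (24 mg/kg) dose groups.
#' @return A named list of [micro_params()].
#' @export
default_pk_population <- function() {
  list(
    BL = micro_params(V1 = 0.25, K10 = 0.23, K12 = 0.16, K21 = 0.05),
    BM = micro_params(V1 = 0.21, K10 = 0.25, K12 = 0.13, K21 = 0.03),
    BH = micro_params(V1 = 0.19, K10 = 0.19, K12 = 0.12, K21 = 0.08)
  )
}

#' Configuration of a synthetic cohort
#'
#' @param groups data.frame with columns `name`, `dose_per_kg` (mg/kg),
#'   `n_subjects`. Default: BL/BM/BH at 6/12/24 mg/kg, 6 rats each
#'   (1, 2 and 4 times the righting-reflex ED50).
#' @param body_mass_mean,body_mass_sd body mass distribution, grams.
#' @param pk_population named list of group-mean [micro_params()] for
#'   plasma; names must match `groups$name`.
#' @param iiv_cv inter-individual lognormal coefficient of variation
#'   applied independently to each micro parameter (0.25 approximates the
#'   SD/mean ratios of the study's parameter table).
#' @param link_slope,link_intercept log-log breath-plasma link on the
#'   (pptv, ng/mL) convention; inverted to generate breath from plasma.
#' @param noise_cv multiplicative lognormal measurement noise.
#' @param lod_ppbv breath detection limit, ppbv.
#' @param breath_interval breath sampling interval, minutes (20 s).
#' @param plasma_times blood-draw schedule, minutes post-dose.
#' @param duration monitoring duration, minutes.
#' @param seed integer RNG seed; same config + seed gives identical output.
#' @param formulation_mg_ml propofol formulation strength used only to
#'   derive the infusion-duration metadata (0.4 mL per 30 s pump rate).
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(groups = data.frame(
                            name = c("BL", "BM", "BH"),
                            dose_per_kg = c(6, 12, 24),
                            n_subjects = c(6L, 6L, 6L)),
                          body_mass_mean = 330, body_mass_sd = 25,
                          pk_population = default_pk_population(),
                          iiv_cv = 0.25,
                          link_slope = 1.42, link_intercept = -1.70,
                          noise_cv = 0.05,
                          lod_ppbv = 0.04,
                          breath_interval = 1 / 3,
                          plasma_times = c(1, 3, 5, 10, 20, 30, 60, 90, 120),
                          duration = 120,
                          seed = 20250212,
                          formulation_mg_ml = 10) {
  groups <- as.data.frame(groups)
  if (!all(c("name", "dose_per_kg", "n_subjects") %in% names(groups))) {
    b2p_stop("b2p_invalid_argument",
             "groups needs columns name, dose_per_kg, n_subjects")
  }
  if (any(groups$n_subjects < 1L) || any(groups$dose_per_kg <= 0)) {
    b2p_stop("b2p_invalid_argument", "doses must be positive, n_subjects >= 1")
  }
  if (!all(groups$name %in% names(pk_population))) {
    b2p_stop("b2p_invalid_argument", "pk_population must name every group")
  }
  stopifnot_number(body_mass_mean, "body_mass_mean", positive = TRUE)
  stopifnot_number(body_mass_sd, "body_mass_sd", nonneg = TRUE)
  stopifnot_number(iiv_cv, "iiv_cv", nonneg = TRUE)
  stopifnot_number(noise_cv, "noise_cv", nonneg = TRUE)
  stopifnot_number(lod_ppbv, "lod_ppbv", positive = TRUE)
  stopifnot_number(breath_interval, "breath_interval", positive = TRUE)
  stopifnot_number(duration, "duration", positive = TRUE)
  if (any(plasma_times <= 0) || is.unsorted(plasma_times, strictly = TRUE)) {
    b2p_stop("b2p_invalid_argument", "plasma_times must be positive and increasing")
  }
  structure(
    list(groups = groups, body_mass_mean = body_mass_mean,
         body_mass_sd = body_mass_sd, pk_population = pk_population,
         iiv_cv = iiv_cv, link_slope = link_slope,
         link_intercept = link_intercept, noise_cv = noise_cv,
         lod_ppbv = lod_ppbv, breath_interval = breath_interval,
         plasma_times = plasma_times, duration = duration,
         seed = as.integer(seed), formulation_mg_ml = formulation_mg_ml),
    class = "cohort_config")
}

# lognormal multiplier with coefficient of variation cv (median 1)
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2))))
}

sample_micro <- function(mean_mp, cv) {
  m <- rlnorm_cv(4, cv)
  micro_params(V1 = mean_mp$V1 * m[1], K10 = mean_mp$K10 * m[2],
               K12 = mean_mp$K12 * m[3], K21 = mean_mp$K21 * m[4])
}

#' Generate a complete synthetic cohort
#'
#' Per subject: body mass is drawn from a truncated normal, the dose is
#' `dose_per_kg * mass / 1000`, individual micro parameters are sampled
#' lognormally around the group means, plasma is simulated by the
#' closed-form bolus model at the blood-draw schedule with multiplicative
#' noise, and breath is derived on the 20-s grid by inverting the log-log
#' link (`ce_pptv = exp((ln(cp_ngml) - intercept) / slope)`) with
#' independent noise, converted to ppbv and LOD-censored. Pre-dose
#' baseline rows (t = 0, value 0) are emitted with the zeroed flag.
#'
#' @param config a [cohort_config()].
#' @return A list of class `"cohort"`: `subjects` (list of records, each
#'   with `subject_id`, `group`, `body_mass_g`, `dose` ([dose_event()]),
#'   `infusion_duration_min`, `true_params`, `breath`, `plasma`), `truth`
#'   (data.frame of generating parameters), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    breath_times <- seq(config$breath_interval, config$duration,
                        by = config$breath_interval)
    subjects <- list()
    truth_rows <- list()
    sid <- 0L
    for (gi in seq_len(nrow(config$groups))) {
      g <- config$groups[gi, ]
      mean_mp <- config$pk_population[[g$name]]
      for (si in seq_len(g$n_subjects)) {
        sid <- sid + 1L
        subject_id <- sprintf("%s-%02d", g$name, si)
        mass <- 0
        while (mass <= 0) {
          mass <- stats::rnorm(1, config$body_mass_mean, config$body_mass_sd)
        }
        dose_mg <- g$dose_per_kg * mass / 1000
        dose <- dose_event(dose_mg)
        infusion_min <- (dose_mg / config$formulation_mg_ml) / 0.4 * 0.5
        mp <- sample_micro(mean_mp, config$iiv_cv)
        mac <- micro_to_macro(mp, dose)

        cp_true <- predict_concentration(mac, dose, config$plasma_times)
        cp_obs <- cp_true * rlnorm_cv(length(cp_true), config$noise_cv)
        plasma <- concentration_series(
          subject_id, "plasma",
          times = c(0, config$plasma_times),
          values = c(0, cp_obs), unit = "ug/mL",
          censored = c("below_lod_zeroed",
                       rep("observed", length(cp_obs))),
          group = g$name)

        cp_grid <- predict_concentration(mac, dose, breath_times)  # ug/mL
        cp_ngml <- convert_units(cp_grid, "ug/mL", "ng/mL")
        ce_pptv <- exp((log(cp_ngml) - config$link_intercept) / config$link_slope)
        ce_pptv <- ce_pptv * rlnorm_cv(length(ce_pptv), config$noise_cv)
        ce_ppbv <- convert_units(ce_pptv, "pptv", "ppbv")
        breath <- concentration_series(
          subject_id, "breath",
          times = c(0, breath_times),
          values = c(0, ce_ppbv), unit = "ppbv",
          censored = c("below_lod_zeroed",
                       rep("observed", length(ce_ppbv))),
          group = g$name)
        breath <- censor_series(breath, config$lod_ppbv)

        subjects[[sid]] <- list(
          subject_id = subject_id, group = g$name,
          body_mass_g = mass, dose = dose,
          infusion_duration_min = infusion_min,
          true_params = mp, breath = breath, plasma = plasma)
        truth_rows[[sid]] <- data.frame(
          subject_id = subject_id, group = g$name,
          body_mass_g = mass, dose_mg = dose_mg,
          V1 = mp$V1, K10 = mp$K10, K12 = mp$K12, K21 = mp$K21,
          link_slope = config$link_slope,
          link_intercept = config$link_intercept)
      }
    }
    structure(list(subjects = subjects,
                   truth = do.call(rbind, truth_rows),
                   config = config),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects in %d groups (seed %d)\n",
              length(x$subjects), nrow(x$config$groups), x$config$seed))
  invisible(x)
}

#' Generate synthetic calibration standards
#'
#' Forward-evaluates a known calibration curve at the requested
#' concentrations and perturbs the signals with multiplicative lognormal
#' noise, yielding a standards table ready for [fit_calibration()].
#'
#' @param curve a [calibration_curve()] used as ground truth.
#' @param concentrations ppbv levels; must lie within the curve's range.
#' @param noise_cv multiplicative noise CV (0 = exact).
#' @param seed optional RNG seed for reproducible noise.
#' @return data.frame with columns `concentration_ppbv`, `signal_intensity`.
#' @export
generate_calibration_standards <- function(curve, concentrations,
                                           noise_cv = 0, seed = NULL) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (length(concentrations) == 0L) {
    return(data.frame(concentration_ppbv = numeric(0),
                      signal_intensity = numeric(0)))
  }
  if (any(concentrations < curve$valid_range[1] - 1e-12) ||
      any(concentrations > curve$valid_range[2] + 1e-12)) {
    b2p_stop("b2p_out_of_range", "standard levels outside the stated range")
  }
  gen <- function() {
    sig <- concentration_to_signal(curve, concentrations) *
      rlnorm_cv(length(concentrations), noise_cv)
    data.frame(concentration_ppbv = concentrations, signal_intensity = sig)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
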