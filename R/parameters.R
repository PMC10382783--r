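#' Point estimate with optional uncertainty metadata
#'
#' A point estimate is the atom of the model configuration: a mean plus
#' whatever uncertainty information the evidence synthesis produced for it
#' (a standard deviation, a 95\% confidence interval, a sample size). Units
#' are contextual (EUR, probability, or QALY change).
#'
#' @param mean Numeric scalar, the point estimate.
#' @param sd Optional non-negative standard deviation. For bootstrap-derived
#'   costs this is the standard deviation of the replicate means.
#' @param ci Optional length-2 numeric `c(low, high)` 95\% confidence
#'   interval; must bracket `mean`.
#' @param n Optional positive integer, the sample size behind the estimate
#'   (number of patients, error cases, or bootstrap replicates depending on
#'   the parameter).
#' @return An object of class `"point_estimate"`: a list with elements
#'   `mean`, `sd`, `ci_low`, `ci_high`, `n` (missing ones are `NULL`).
#' @examples
#' point_estimate(1091.12, sd = 220.92, ci = c(702.51, 1551))
#' @export
point_estimate <- function(mean, sd = NULL, ci = NULL, n = NULL) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    stop("point_estimate: 'mean' must be a finite numeric scalar", call. = FALSE)
  if (!is.null(sd)) {
    if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
      stop("point_estimate: 'sd' must be a single non-negative number", call. = FALSE)
  }
  ci_low <- ci_high <- NULL
  if (!is.null(ci)) {
    if (!is.numeric(ci) || length(ci) != 2L || any(!is.finite(ci)))
      stop("point_estimate: 'ci' must be numeric c(low, high)", call. = FALSE)
    if (ci[1] > mean || mean > ci[2])
      stop(sprintf(
        "point_estimate: interval [%g, %g] does not bracket mean %g",
        ci[1], ci[2], mean), call. = FALSE)
    ci_low <- ci[1]; ci_high <- ci[2]
  }
  if (!is.null(n)) {
    if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
      stop("point_estimate: 'n' must be a positive integer", call. = FALSE)
    n <- as.integer(n)
  }
  structure(list(mean = mean, sd = sd, ci_low = ci_low, ci_high = ci_high,
                 n = n),
            class = "point_estimate")
}

#' Per-arm model parameters
#'
#' Bundles the four inputs the decision tree needs for one arm: the
#' probability of discharge medication error, the mean cost of an error's
#' consequences, the per-patient pharmacist labour cost, and the utility
#' decrement (QALY change, non-positive) attached to an error.
#'
#' @param arm_label `"reference"` or `"intervention"`.
#' @param p_error [point_estimate] with mean in \[0, 1\].
#' @param error_cost [point_estimate], EUR, mean >= 0.
#' @param labour_cost [point_estimate], EUR, mean >= 0.
#' @param utility_decrement [point_estimate], QALY change, mean <= 0.
#' @param display Display name; defaults to `"SC"` for the reference arm and
#'   `"PACT"` for the intervention arm.
#' @return An object of class `"arm_parameters"`.
#' @export
arm_parameters <- function(arm_label = c("reference", "intervention"),
                           p_error, error_cost, labour_cost,
                           utility_decrement, display = NULL) {
  arm_label <- match.arg(arm_label)
  for (nm in c("p_error", "error_cost", "labour_cost", "utility_decrement")) {
    pe <- get(nm)
    if (!inherits(pe, "point_estimate"))
      stop(sprintf("arm_parameters: '%s' must be a point_estimate", nm),
           call. = FALSE)
  }
  if (p_error$mean < 0 || p_error$mean > 1)
    stop(sprintf("arm_parameters (%s): p_error mean %g outside [0, 1]",
                 arm_label, p_error$mean), call. = FALSE)
  if (error_cost$mean < 0)
    stop(sprintf("arm_parameters (%s): error_cost mean must be >= 0",
                 arm_label), call. = FALSE)
  if (labour_cost$mean < 0)
    stop(sprintf("arm_parameters (%s): labour_cost mean must be >= 0",
                 arm_label), call. = FALSE)
  if (utility_decrement$mean > 0)
    stop(sprintf("arm_parameters (%s): utility_decrement mean must be <= 0",
                 arm_label), call. = FALSE)
  if (is.null(display))
    display <- if (arm_label == "reference") "SC" else "PACT"
  structure(list(arm_label = arm_label, display = display,
                 p_error = p_error, error_cost = error_cost,
                 labour_cost = labour_cost,
                 utility_decrement = utility_decrement),
            class = "arm_parameters")
}

#' Deterministic sensitivity analysis settings
#'
#' @param relative_variation Fraction in (0, 1) applied as mean * (1 +/- r)
#'   to parameters without a 95\% CI (probabilities, utility decrements).
#'   Default 0.20.
#' @param bounds Optional named list of explicit `c(low, high)` overrides
#'   keyed by parameter id (e.g. `"reference.p_error"`).
#' @return A list of class `"dsa_settings"`.
#' @export
dsa_settings <- function(relative_variation = 0.20, bounds = list()) {
  if (!is.numeric(relative_variation) || length(relative_variation) != 1L ||
      relative_variation <= 0 || relative_variation >= 1)
    stop("dsa_settings: relative_variation must be in (0, 1)", call. = FALSE)
  if (!is.list(bounds))
    stop("dsa_settings: bounds must be a named list", call. = FALSE)
  structure(list(relative_variation = relative_variation, bounds = bounds),
            class = "dsa_settings")
}

#' Probabilistic sensitivity analysis settings
#'
#' @param iterations Number of Monte-Carlo iterations (default 1000).
#' @param seed Optional integer seed recorded with draws.
#' @param probability_sd Standard deviation assumed for probability
#'   parameters when no other information is available (default 0.2); the
#'   standard error used in method-of-moments fitting is
#'   `probability_sd / sqrt(n)`.
#' @param bootstrap_reps Number of bootstrap replications behind
#'   bootstrap-derived cost estimates; their standard error is taken as
#'   `sd / sqrt(bootstrap_reps)` (default 1000).
#' @param overrides Named list of explicit distribution specifications keyed
#'   by parameter id, each `list(family =, alpha =, beta =)` with family one
#'   of `"beta"`, `"gamma"`, `"one_minus_gamma"`. Used verbatim in
#'   reproduction mode.
#' @return A list of class `"psa_settings"`.
#' @export
psa_settings <- function(iterations = 1000, seed = NULL,
                         probability_sd = 0.2, bootstrap_reps = 1000,
                         overrides = list()) {
  if (!is.numeric(iterations) || length(iterations) != 1L || iterations < 1)
    stop("psa_settings: iterations must be >= 1", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  if (!is.numeric(probability_sd) || probability_sd <= 0)
    stop("psa_settings: probability_sd must be > 0", call. = FALSE)
  if (!is.numeric(bootstrap_reps) || bootstrap_reps < 1)
    stop("psa_settings: bootstrap_reps must be >= 1", call. = FALSE)
  if (!is.list(overrides))
    stop("psa_settings: overrides must be a named list", call. = FALSE)
  for (id in names(overrides)) {
    ov <- overrides[[id]]
    if (!all(c("family", "alpha", "beta") %in% names(ov)))
      stop(sprintf("psa_settings: override '%s' needs family, alpha, beta", id),
           call. = FALSE)
    if (!ov$family %in% c("beta", "gamma", "one_minus_gamma"))
      stop(sprintf("psa_settings: override '%s' has unknown family '%s'",
                   id, ov$family), call. = FALSE)
    if (ov$alpha <= 0 || ov$beta <= 0)
      stop(sprintf("psa_settings: override '%s' hyperparameters must be > 0",
                   id), call. = FALSE)
  }
  structure(list(iterations = as.integer(iterations), seed = seed,
                 probability_sd = probability_sd,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 overrides = overrides),
            class = "psa_settings")
}

#' Assemble a model configuration
#'
#' The configuration is the single object every stage of the analysis reads:
#' the two arms' parameters, the DSA and PSA settings, the willingness-to-pay
#' grid, and optionally the labour-costing and synthetic-cohort blocks.
#'
#' @param reference,intervention [arm_parameters] for the two arms.
#' @param dsa A [dsa_settings] object.
#' @param psa A [psa_settings] object.
#' @param wtp Strictly increasing non-negative willingness-to-pay grid
#'   (EUR/QALY). Default `seq(0, 50000, by = 1000)`.
#' @param labour Optional labour-costing block: a list with elements
#'   `calendar` ([work_calendar]) and per-arm lists `reference`/`intervention`
#'   each holding a [salary_inputs] object and `mean_minutes`.
#' @param cohort Optional named list of [cohort_spec] objects
#'   (`reference`, `intervention`) for the synthetic-data stage.
#' @param cost_year Free-text annotation of the cost year(s) of the inputs.
#' @return An object of class `"cua_config"`.
#' @seealso [base_case_config()], [load_config()], [write_config()]
#' @export
model_config <- function(reference, intervention,
                         dsa = dsa_settings(), psa = psa_settings(),
                         wtp = seq(0, 50000, by = 1000),
                         labour = NULL, cohort = NULL, cost_year = NULL) {
  if (!inherits(reference, "arm_parameters") ||
      reference$arm_label != "reference")
    stop("model_config: 'reference' must be arm_parameters with label 'reference'",
         call. = FALSE)
  if (!inherits(intervention, "arm_parameters") ||
      intervention$arm_label != "intervention")
    stop("model_config: 'intervention' must be arm_parameters with label 'intervention'",
         call. = FALSE)
  if (!inherits(dsa, "dsa_settings")) dsa <- do.call(dsa_settings, dsa)
  if (!inherits(psa, "psa_settings")) psa <- do.call(psa_settings, psa)
  if (!is.numeric(wtp) || length(wtp) < 1L || any(wtp < 0))
    stop("model_config: wtp grid must be non-negative numeric", call. = FALSE)
  if (length(wtp) > 1L && any(diff(wtp) <= 0))
    stop("model_config: wtp grid must be strictly increasing", call. = FALSE)
  structure(list(reference = reference, intervention = intervention,
                 dsa = dsa, psa = psa, wtp = as.numeric(wtp),
                 labour = labour, cohort = cohort, cost_year = cost_year),
            class = "cua_config")
}

# Identifiers of the eight stochastic base parameters, in reporting order.
param_ids <- function() {
  as.vector(outer(c("reference", "intervention"),
                  c("p_error", "error_cost", "labour_cost",
                    "utility_decrement"),
                  paste, sep = "."))
}

# Fetch a point_estimate by "arm.param" id.
get_param <- function(cfg, id) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("reference", "intervention"))
    stop(sprintf("unknown parameter id '%s'", id), call. = FALSE)
  pe <- cfg[[parts[1]]][[parts[2]]]
  if (is.null(pe)) stop(sprintf("unknown parameter id '%s'", id), call. = FALSE)
  pe
}

# Return a config with the mean of one parameter replaced.
set_param_mean <- function(cfg, id, value) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  cfg[[parts[1]]][[parts[2]]]$mean <- value
  cfg
}

#' Packaged base-case configuration
#'
#' The full base case of the published evaluation: error probabilities 0.653
#' (SC) and 0.139 (PACT); bootstrap mean error costs 1091.12 and 638.73 EUR
#' (replicate-mean SDs 220.92 / 205.76, percentile CIs 702.51-1551 and
#' 248.41-1074.17); per-patient pharmacist labour costs 37.21 and 86.70 EUR
#' (bootstrap CIs 29.18-47.39 and 58.84-119.77); utility decrements
#' -0.02906349626 and -0.023469269 QALY (elicitation SDs 0.072 / 0.075). The
#' decrements are carried at full precision rather than the 3-decimal
#' rounding used in summary tables, because only the full-precision values
#' reproduce the published expected effects.
#'
#' PSA distribution overrides are the published hyperparameters (reproduction
#' mode): Beta(372.96, 198.19) and Beta(44.78, 277.36) for the error
#' probabilities; Gamma(24393.59, 0.04473), Gamma(9636.58, 0.06628),
#' Gamma(59903.58, 0.00062), Gamma(30197.42, 0.00287) shape/scale for the
#' costs; 1-Gamma(13279.82, 0.00008) and 1-Gamma(2828.56, 0.00036) for the
#' decrements.
#'
#' The labour block carries the salary mid-points (48,960 and 64,489.5 EUR),
#' the statutory on-cost rates (employer PRSI 10.75\%, imputed pension
#' 13.10\%, overheads 40\%), the working calendar (37 h week, 24 leave days,
#' 9 public holidays, 1 h daily break), and the observed mean contact minutes
#' (40.6 SC, 72.8 PACT). The cohort block carries the synthetic-data
#' generator's defaults matched to the study's summary statistics.
#'
#' @return A validated [model_config] object.
#' @examples
#' cfg <- base_case_config()
#' cfg$reference$p_error$mean
#' @export
base_case_config <- function() {
  # n behind the error probabilities, reconstructed from the error-case
  # counts (66 SC, 15 PACT) at the observed prevalences
  n_sc <- as.integer(round(66 / 0.653))   # 101
  n_pact <- as.integer(round(15 / 0.139)) # 108
  reference <- arm_parameters(
    "reference",
    p_error = point_estimate(0.653, sd = 0.2, n = n_sc),
    error_cost = point_estimate(1091.12, sd = 220.92, ci = c(702.51, 1551),
                                n = 1000L),
    labour_cost = point_estimate(37.21, ci = c(29.18, 47.39)),
    utility_decrement = point_estimate(-0.02906349626, sd = 0.072, n = 66L))
  intervention <- arm_parameters(
    "intervention",
    p_error = point_estimate(0.139, sd = 0.2, n = n_pact),
    error_cost = point_estimate(638.73, sd = 205.76, ci = c(248.41, 1074.17),
                                n = 1000L),
    labour_cost = point_estimate(86.70, ci = c(58.84, 119.77)),
    utility_decrement = point_estimate(-0.023469269, sd = 0.075, n = 15L))
  overrides <- list(
    reference.p_error = list(family = "beta", alpha = 372.96, beta = 198.19),
    intervention.p_error = list(family = "beta", alpha = 44.78, beta = 277.36),
    reference.error_cost = list(family = "gamma", alpha = 24393.59,
                                beta = 0.04473),
    intervention.error_cost = list(family = "gamma", alpha = 9636.58,
                                   beta = 0.06628),
    reference.labour_cost = list(family = "gamma", alpha = 59903.58,
                                 beta = 0.00062),
    intervention.labour_cost = list(family = "gamma", alpha = 30197.42,
                                    beta = 0.00287),
    reference.utility_decrement = list(family = "one_minus_gamma",
                                       alpha = 13279.82, beta = 0.00008),
    intervention.utility_decrement = list(family = "one_minus_gamma",
                                          alpha = 2828.56, beta = 0.00036))
  labour <- list(
    calendar = work_calendar(),
    reference = list(salary = salary_inputs(48960), mean_minutes = 40.6),
    intervention = list(salary = salary_inputs(64489.5), mean_minutes = 72.8))
  cohort <- list(
    reference = cohort_spec("reference", n_patients = n_sc, p_error = 0.653,
                            time_mean = 40.6, time_sd = 29.17,
                            cost_mean = 1091.12, cost_sd = 1091.12,
                            decrement_mean = -0.02906349626,
                            decrement_sd = 0.072),
    intervention = cohort_spec("intervention", n_patients = n_pact,
                               p_error = 0.139,
                               time_mean = 72.8, time_sd = 52.47,
                               cost_mean = 638.73, cost_sd = 638.73,
                               decrement_mean = -0.023469269,
                               decrement_sd = 0.075))
  model_config(
    reference = reference, intervention = intervention,
    dsa = dsa_settings(relative_variation = 0.20),
    psa = psa_settings(iterations = 1000, probability_sd = 0.2,
                       bootstrap_reps = 1000, overrides = overrides),
    wtp = seq(0, 50000, by = 1000),
    labour = labour, cohort = cohort,
    cost_year = "2013 hospital tariffs; salary-scale year as published")
}

# ---- serialisation ---------------------------------------------------------

pe_to_list <- function(pe) {
  out <- list(mean = pe$mean)
  if (!is.null(pe$sd)) out$sd <- pe$sd
  if (!is.null(pe$ci_low)) out$ci <- c(pe$ci_low, pe$ci_high)
  if (!is.null(pe$n)) out$n <- pe$n
  out
}

pe_from_list <- function(x, field) {
  allowed <- c("mean", "sd", "ci", "n")
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("config: unknown key(s) %s in '%s'",
                 paste(sQuote(bad), collapse = ", "), field), call. = FALSE)
  if (is.null(x$mean))
    stop(sprintf("config: '%s' is missing 'mean'", field), call. = FALSE)
  ci <- if (!is.null(x$ci)) as.numeric(unlist(x$ci)) else NULL
  tryCatch(point_estimate(x$mean, sd = x$sd, ci = ci, n = x$n),
           error = function(e)
             stop(sprintf("config: invalid '%s': %s", field,
                          conditionMessage(e)), call. = FALSE))
}

arm_to_list <- function(arm) {
  list(display = arm$display,
       p_error = pe_to_list(arm$p_error),
       error_cost = pe_to_list(arm$error_cost),
       labour_cost = pe_to_list(arm$labour_cost),
       utility_decrement = pe_to_list(arm$utility_decrement))
}

arm_from_list <- function(x, arm_label) {
  allowed <- c("display", "p_error", "error_cost", "labour_cost",
               "utility_decrement")
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("config: unknown key(s) %s in arm '%s'",
                 paste(sQuote(bad), collapse = ", "), arm_label),
         call. = FALSE)
  for (nm in setdiff(allowed, "display"))
    if (is.null(x[[nm]]))
      stop(sprintf("config: arm '%s' is missing '%s'", arm_label, nm),
           call. = FALSE)
  arm_parameters(
    arm_label,
    p_error = pe_from_list(x$p_error, paste0(arm_label, ".p_error")),
    error_cost = pe_from_list(x$error_cost, paste0(arm_label, ".error_cost")),
    labour_cost = pe_from_list(x$labour_cost,
                               paste0(arm_label, ".labour_cost")),
    utility_decrement = pe_from_list(
      x$utility_decrement, paste0(arm_label, ".utility_decrement")),
    display = x$display)
}

config_to_list <- function(cfg) {
  out <- list(
    cost_year = cfg$cost_year,
    reference = arm_to_list(cfg$reference),
    intervention = arm_to_list(cfg$intervention),
    dsa = list(relative_variation = cfg$dsa$relative_variation),
    psa = list(iterations = cfg$psa$iterations,
               probability_sd = cfg$psa$probability_sd,
               bootstrap_reps = cfg$psa$bootstrap_reps),
    wtp = list(from = cfg$wtp[1],
               to = cfg$wtp[length(cfg$wtp)],
               by = if (length(cfg$wtp) > 1) cfg$wtp[2] - cfg$wtp[1] else NA))
  if (length(cfg$wtp) > 1 &&
      !isTRUE(all.equal(cfg$wtp,
                        seq(out$wtp$from, out$wtp$to, by = out$wtp$by))))
    out$wtp <- cfg$wtp   # irregular grid: store verbatim
  if (length(cfg$dsa$bounds)) out$dsa$bounds <- cfg$dsa$bounds
  if (!is.null(cfg$psa$seed)) out$psa$seed <- cfg$psa$seed
  if (length(cfg$psa$overrides)) out$psa$overrides <- cfg$psa$overrides
  if (!is.null(cfg$labour)) {
    lb <- cfg$labour
    out$labour <- list(
      calendar = unclass(lb$calendar),
      reference = list(salary = unclass(lb$reference$salary),
                       mean_minutes = lb$reference$mean_minutes),
      intervention = list(salary = unclass(lb$intervention$salary),
                          mean_minutes = lb$intervention$mean_minutes))
  }
  if (!is.null(cfg$cohort))
    out$cohort <- lapply(cfg$cohort, unclass)
  out[!vapply(out, is.null, logical(1))]
}

config_from_list <- function(x) {
  allowed <- c("cost_year", "reference", "intervention", "dsa", "psa", "wtp",
               "labour", "cohort")
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("config: unknown top-level key(s) %s",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  for (nm in c("reference", "intervention"))
    if (is.null(x[[nm]]))
      stop(sprintf("config: missing required block '%s'", nm), call. = FALSE)

  dsa <- x$dsa
  if (!is.null(dsa)) {
    bad <- setdiff(names(dsa), c("relative_variation", "bounds"))
    if (length(bad))
      stop(sprintf("config: unknown key(s) %s in 'dsa'",
                   paste(sQuote(bad), collapse = ", ")), call. = FALSE)
    dsa <- dsa_settings(
      relative_variation = if (is.null(dsa$relative_variation)) 0.20
                           else dsa$relative_variation,
      bounds = if (is.null(dsa$bounds)) list()
               else lapply(dsa$bounds, function(b) as.numeric(unlist(b))))
  } else dsa <- dsa_settings()

  psa <- x$psa
  if (!is.null(psa)) {
    bad <- setdiff(names(psa), c("iterations", "seed", "probability_sd",
                                 "bootstrap_reps", "overrides"))
    if (length(bad))
      stop(sprintf("config: unknown key(s) %s in 'psa'",
                   paste(sQuote(bad), collapse = ", ")), call. = FALSE)
    psa <- psa_settings(
      iterations = if (is.null(psa$iterations)) 1000 else psa$iterations,
      seed = psa$seed,
      probability_sd = if (is.null(psa$probability_sd)) 0.2
                       else psa$probability_sd,
      bootstrap_reps = if (is.null(psa$bootstrap_reps)) 1000
                       else psa$bootstrap_reps,
      overrides = if (is.null(psa$overrides)) list() else psa$overrides)
  } else psa <- psa_settings()

  wtp <- x$wtp
  if (is.null(wtp)) {
    wtp <- seq(0, 50000, by = 1000)
  } else if (is.list(wtp) && !is.null(wtp$from)) {
    wtp <- seq(wtp$from, wtp$to, by = wtp$by)
  } else {
    wtp <- as.numeric(unlist(wtp))
  }

  labour <- NULL
  if (!is.null(x$labour)) {
    lb <- x$labour
    cal <- do.call(work_calendar, if (is.null(lb$calendar)) list()
                                  else lb$calendar)
    mk_arm <- function(a, nm) {
      if (is.null(a)) stop(sprintf("config: labour block missing '%s'", nm),
                           call. = FALSE)
      list(salary = do.call(salary_inputs, a$salary),
           mean_minutes = a$mean_minutes)
    }
    labour <- list(calendar = cal,
                   reference = mk_arm(lb$reference, "reference"),
                   intervention = mk_arm(lb$intervention, "intervention"))
  }

  cohort <- NULL
  if (!is.null(x$cohort))
    cohort <- lapply(x$cohort, function(cs) do.call(cohort_spec, cs))

  model_config(reference = arm_from_list(x$reference, "reference"),
               intervention = arm_from_list(x$intervention, "intervention"),
               dsa = dsa, psa = psa, wtp = wtp,
               labour = labour, cohort = cohort, cost_year = x$cost_year)
}

#' Read a model configuration from YAML or JSON
#'
#' The file must follow the documented schema: top-level keys `reference`,
#' `intervention`, `dsa`, `psa`, `wtp` plus the optional `labour`, `cohort`
#' and `cost_year` blocks; each arm parameter is a mapping
#' `{mean, sd?, ci? [low, high], n?}`. Unknown keys are rejected and every
#' structural invariant (probability bounds, strictly increasing WTP grid,
#' positive hyperparameters) is enforced at load time.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [model_config] object.
#' @examples
#' cfg <- load_config(system.file("extdata", "base_case.yaml",
#'                                package = "cuatree"))
#' cfg$intervention$labour_cost$mean
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  config_from_list(raw)
}

#' Write a model configuration to YAML or JSON
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))`
#' returns a configuration equal to `cfg` field by field.
#'
#' @param cfg A [model_config] object.
#' @param path Output path; format chosen by extension (`.json` for JSON,
#'   YAML otherwise).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cua_config"))
  x <- config_to_list(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}
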