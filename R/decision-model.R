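#' Expected cost and effect of one arm
#'
#' Evaluates the two-branch decision tree for one arm. Every patient accrues
#' the labour cost; patients on the error branch (probability `p_error`)
#' additionally accrue the error cost and the utility decrement, while
#' patients without a discharge medication error have no change in
#' health-related quality of life. Hence
#' `expected_cost = p * error_cost + labour_cost` and
#' `expected_effect = p * utility_decrement` (a non-positive QALY change
#' relative to the no-error baseline).
#'
#' @param arm An [arm_parameters] object, or a plain list with numeric
#'   `p_error`, `error_cost`, `labour_cost`, `utility_decrement` (means).
#' @return A list of class `"arm_outcome"`: `expected_cost` (EUR),
#'   `expected_effect` (QALY change), `arm_label`, `display`.
#' @examples
#' expected_outcome(base_case_config()$reference) # cost 749.71, effect -0.0190
#' @export
expected_outcome <- function(arm) {
  g <- function(nm) {
    v <- arm[[nm]]
    if (inherits(v, "point_estimate")) v$mean else as.numeric(v)
  }
  structure(list(
    expected_cost = g("p_error") * g("error_cost") + g("labour_cost"),
    expected_effect = g("p_error") * g("utility_decrement"),
    arm_label = if (!is.null(arm$arm_label)) arm$arm_label else NA_character_,
    display = if (!is.null(arm$display)) arm$display else NA_character_),
    class = "arm_outcome")
}

# Quadrant-based dominance classification. Dominance is decided by the signs
# of (delta_cost, delta_effect), never by the sign of the ICER: both a
# dominant and a dominated pair yield a negative ratio. Boundary cases with
# exactly one zero component are grouped with the adjacent trade-off
# quadrant (by the sign of delta_effect, then delta_cost).
dominance_label <- function(delta_cost, delta_effect) {
  if (delta_cost == 0 && delta_effect == 0) return("equivalent")
  if (delta_cost < 0 && delta_effect > 0) return("intervention_dominant")
  if (delta_cost > 0 && delta_effect < 0) return("reference_dominant")
  if (delta_effect > 0 || (delta_effect == 0 && delta_cost > 0))
    "trade_off_ne"
  else
    "trade_off_sw"
}

#' Incremental analysis of two arm outcomes
#'
#' Computes the incremental cost and effect of the intervention relative to
#' the reference, the incremental cost-effectiveness ratio (ICER) when the
#' incremental effect is nonzero, and the dominance quadrant. A negative
#' ICER alone never labels dominance; the quadrant does.
#'
#' @param intervention,reference [expected_outcome()] results (or lists with
#'   `expected_cost` and `expected_effect`).
#' @return A list of class `"incremental_result"`: `delta_cost` (EUR),
#'   `delta_effect` (QALY), `icer` (EUR/QALY, `NA` when undefined),
#'   `icer_defined` (logical), `dominance` (one of `intervention_dominant`,
#'   `reference_dominant`, `trade_off_ne`, `trade_off_sw`, `equivalent`).
#' @export
incremental <- function(intervention, reference) {
  dc <- intervention$expected_cost - reference$expected_cost
  de <- intervention$expected_effect - reference$expected_effect
  if (!is.finite(dc) || !is.finite(de))
    stop("incremental: outcomes must be finite", call. = FALSE)
  defined <- de != 0
  structure(list(delta_cost = dc, delta_effect = de,
                 icer = if (defined) dc / de else NA_real_,
                 icer_defined = defined,
                 dominance = dominance_label(dc, de)),
            class = "incremental_result")
}

#' Net monetary benefit
#'
#' `NMB(lambda) = lambda * delta_effect - delta_cost`, where `lambda` is the
#' willingness-to-pay per QALY. Vectorised over any argument.
#'
#' @param delta_cost Incremental cost, EUR.
#' @param delta_effect Incremental effect, QALY.
#' @param lambda Willingness-to-pay, EUR/QALY, >= 0.
#' @return NMB in EUR.
#' @examples
#' nmb(-574.23, 0.0157, lambda = c(0, 45000))
#' @export
nmb <- function(delta_cost, delta_effect, lambda) {
  if (any(lambda < 0)) stop("nmb: lambda must be >= 0", call. = FALSE)
  lambda * delta_effect - delta_cost
}

#' Fit the two-arm decision-tree cost-utility model
#'
#' The central constructor: evaluates the decision tree at the configured
#' point estimates and performs the incremental analysis. The returned
#' object is the entry point for everything downstream — [summary()] prints
#' the base-case table, [one_way_dsa()] runs deterministic sensitivity
#' analysis, [simulate()] runs the probabilistic sensitivity analysis, and
#' [ceac()] turns PSA draws into an acceptability curve.
#'
#' @param config A [model_config], or a path to a configuration file (passed
#'   to [load_config()]). Defaults to the packaged base case.
#' @return An object of class `"cua"`: list with `outcomes` (per-arm
#'   data.frame), `incremental` ([incremental()] result), `config`.
#' @examples
#' fit <- cua()
#' summary(fit)
#' coef(fit)
#' @export
cua <- function(config = base_case_config()) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "cua_config"))
  ref <- expected_outcome(config$reference)
  int <- expected_outcome(config$intervention)
  inc <- incremental(int, ref)
  outcomes <- data.frame(
    arm = c("reference", "intervention"),
    strategy = c(config$reference$display, config$intervention$display),
    expected_cost = c(ref$expected_cost, int$expected_cost),
    expected_effect = c(ref$expected_effect, int$expected_effect),
    stringsAsFactors = FALSE)
  structure(list(outcomes = outcomes, incremental = inc, config = config),
            class = "cua")
}

#' Base-case results table
#'
#' One row per strategy with expected cost and effect; the intervention row
#' carries the incremental columns and the ICER/dominance pair. Monetary
#' values are rounded to cents and effects to 9 decimals at report time.
#'
#' @param fit A `"cua"` object from [cua()].
#' @return data.frame with columns `strategy`, `cost`, `incremental_cost`,
#'   `effect`, `incremental_effect`, `icer`, `dominance`.
#' @export
base_case_table <- function(fit) {
  stopifnot(inherits(fit, "cua"))
  o <- fit$outcomes; inc <- fit$incremental
  data.frame(
    strategy = o$strategy,
    cost = round(o$expected_cost, 2),
    incremental_cost = c(NA_real_, round(inc$delta_cost, 2)),
    effect = round(o$expected_effect, 9),
    incremental_effect = c(NA_real_, round(inc$delta_effect, 9)),
    icer = c(NA_real_, round(inc$icer, 2)),
    dominance = c(NA_character_, inc$dominance),
    stringsAsFactors = FALSE)
}

#' @export
print.cua <- function(x, ...) {
  inc <- x$incremental
  cat("Two-arm decision-tree cost-utility model\n")
  cat(sprintf("  %s vs %s: ICER %s EUR/QALY (%s)\n",
              x$config$intervention$display, x$config$reference$display,
              if (inc$icer_defined) formatC(inc$icer, format = "f", digits = 2,
                                            big.mark = ",") else "undefined",
              inc$dominance))
  invisible(x)
}

#' Summarise a fitted cost-utility model
#'
#' @param object A `"cua"` object.
#' @param lambda Willingness-to-pay values at which to report the net
#'   monetary benefit (default 0 and 45,000 EUR/QALY).
#' @param ... Unused.
#' @return Invisibly, a list with the base-case table and the NMB values.
#' @export
summary.cua <- function(object, lambda = c(0, 45000), ...) {
  tab <- base_case_table(object)
  inc <- object$incremental
  nmb_vals <- nmb(inc$delta_cost, inc$delta_effect, lambda)
  cat("Base case\n")
  print(tab, row.names = FALSE)
  cat("\nNet monetary benefit:\n")
  for (i in seq_along(lambda))
    cat(sprintf("  lambda = %s EUR/QALY: NMB = %s EUR\n",
                formatC(lambda[i], format = "d", big.mark = ","),
                formatC(nmb_vals[i], format = "f", digits = 2,
                        big.mark = ",")))
  invisible(list(table = tab, lambda = lambda, nmb = nmb_vals))
}

#' Model coefficients: the eight base parameter means
#'
#' @param object A `"cua"` object.
#' @param ... Unused.
#' @return Named numeric vector keyed by parameter id
#'   (`"reference.p_error"`, ...).
#' @export
coef.cua <- function(object, ...) {
  ids <- param_ids()
  stats::setNames(vapply(ids,
                         function(id) get_param(object$config, id)$mean,
                         numeric(1)),
                  ids)
}
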