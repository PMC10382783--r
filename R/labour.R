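#' Pharmacist salary inputs
#'
#' Annual gross salary (mid-point of the relevant pay scale) plus the three
#' flat on-cost rates applied to gross salary: employer PRSI (Pay Related
#' Social Insurance), imputed pension, and overheads.
#'
#' @param annual_gross Annual gross salary, EUR, > 0.
#' @param prsi_rate Employer PRSI rate (default 0.1075).
#' @param pension_rate Imputed pension rate (default 0.1310).
#' @param overhead_rate Overheads rate (default 0.40).
#' @return An object of class `"salary_inputs"`.
#' @export
salary_inputs <- function(annual_gross, prsi_rate = 0.1075,
                          pension_rate = 0.1310, overhead_rate = 0.40) {
  if (!is.numeric(annual_gross) || length(annual_gross) != 1L ||
      annual_gross <= 0)
    stop("salary_inputs: annual_gross must be a single positive number",
         call. = FALSE)
  for (nm in c("prsi_rate", "pension_rate", "overhead_rate")) {
    r <- get(nm)
    if (!is.numeric(r) || length(r) != 1L || r < 0 || r >= 1)
      stop(sprintf("salary_inputs: %s must be in [0, 1)", nm), call. = FALSE)
  }
  structure(list(annual_gross = annual_gross, prsi_rate = prsi_rate,
                 pension_rate = pension_rate, overhead_rate = overhead_rate),
            class = "salary_inputs")
}

#' Working calendar
#'
#' Describes the productive working year: a 365.25-day year with a 5/7
#' working-day fraction, contractual weekly hours, annual leave, public
#' holidays and a daily unpaid break. These defaults reproduce the published
#' per-hour and per-minute labour costs.
#'
#' @param hours_per_week Contracted hours per week (default 37).
#' @param leave_days Annual leave days (default 24).
#' @param public_holidays Public holidays per year (default 9).
#' @param break_hours_per_day Daily break, hours (default 1).
#' @param days_per_year Calendar days per year (default 365.25).
#' @return An object of class `"work_calendar"`.
#' @export
work_calendar <- function(hours_per_week = 37, leave_days = 24,
                          public_holidays = 9, break_hours_per_day = 1,
                          days_per_year = 365.25) {
  vals <- c(hours_per_week = hours_per_week, leave_days = leave_days,
            public_holidays = public_holidays,
            break_hours_per_day = break_hours_per_day,
            days_per_year = days_per_year)
  if (any(!is.finite(vals)) || any(vals[c(1, 5)] <= 0) || any(vals < 0))
    stop("work_calendar: inputs must be non-negative (hours_per_week and days_per_year positive)",
         call. = FALSE)
  structure(as.list(vals), class = "work_calendar")
}

#' Total annual employment cost
#'
#' Gross salary plus employer PRSI, imputed pension and overheads, each a
#' flat fraction of gross: `annual_gross * (1 + prsi + pension + overheads)`.
#'
#' @param s A [salary_inputs] object.
#' @return Annual employment cost, EUR.
#' @examples
#' annual_employment_cost(salary_inputs(48960)) # 80220.96
#' @export
annual_employment_cost <- function(s) {
  stopifnot(inherits(s, "salary_inputs"))
  s$annual_gross * (1 + s$prsi_rate + s$pension_rate + s$overhead_rate)
}

#' Productive hours per year
#'
#' Working days are `days_per_year * 5/7` minus leave and public holidays;
#' each working day contributes `hours_per_week / 5` contracted hours less
#' the daily break.
#'
#' @param cal A [work_calendar] object.
#' @return Productive hours per year (about 1458.5 under the defaults).
#' @export
productive_hours_per_year <- function(cal) {
  stopifnot(inherits(cal, "work_calendar"))
  workdays <- cal$days_per_year * 5 / 7 - cal$leave_days - cal$public_holidays
  hours <- workdays * (cal$hours_per_week / 5 - cal$break_hours_per_day)
  if (!is.finite(hours) || hours <= 0)
    stop("productive_hours_per_year: calendar yields non-positive productive hours",
         call. = FALSE)
  hours
}

#' Labour cost per minute of work
#'
#' @param s A [salary_inputs] object.
#' @param cal A [work_calendar] object.
#' @return EUR per minute: annual employment cost / productive hours / 60.
#' @examples
#' cost_per_minute(salary_inputs(48960), work_calendar()) # ~0.9166972
#' @export
cost_per_minute <- function(s, cal = work_calendar()) {
  annual_employment_cost(s) / productive_hours_per_year(cal) / 60
}

#' Per-patient labour cost
#'
#' Contact minutes times the per-minute labour rate, reported to cents.
#' Intermediate computation is full precision; rounding happens only here,
#' at report time.
#'
#' @param minutes Observed contact minutes, >= 0.
#' @param rate EUR per minute (see [cost_per_minute()]).
#' @return EUR, rounded to cents.
#' @examples
#' per_patient_labour_cost(40.6, cost_per_minute(salary_inputs(48960))) # 37.22
#' @export
per_patient_labour_cost <- function(minutes, rate) {
  if (any(!is.finite(minutes)) || any(minutes < 0))
    stop("per_patient_labour_cost: minutes must be non-negative", call. = FALSE)
  round(minutes * rate, 2)
}

#' Labour-costing table
#'
#' Itemised per-arm labour costing: gross salary (A), employer PRSI (B),
#' imputed pension (C), overheads (D), total annual employment cost, cost
#' per hour, cost per minute, and — when mean contact minutes are supplied —
#' the per-patient labour cost.
#'
#' @param labour A labour block as held in a [model_config]: list with
#'   `calendar` and per-arm `reference`/`intervention` lists of
#'   `salary` ([salary_inputs]) and `mean_minutes`.
#' @return A data.frame with one column per arm, row names the line items.
#' @examples
#' labour_cost_table(base_case_config()$labour)
#' @export
labour_cost_table <- function(labour) {
  cal <- labour$calendar
  cols <- lapply(labour[c("reference", "intervention")], function(a) {
    s <- a$salary
    total <- annual_employment_cost(s)
    cpm <- cost_per_minute(s, cal)
    c(annual_gross = s$annual_gross,
      employer_prsi = s$annual_gross * s$prsi_rate,
      imputed_pension = s$annual_gross * s$pension_rate,
      overheads = s$annual_gross * s$overhead_rate,
      total_per_annum = total,
      cost_per_hour = cpm * 60,
      cost_per_minute = cpm,
      mean_minutes = if (is.null(a$mean_minutes)) NA_real_ else a$mean_minutes,
      per_patient_cost = if (is.null(a$mean_minutes)) NA_real_
                         else per_patient_labour_cost(a$mean_minutes, cpm))
  })
  as.data.frame(cols)
}
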