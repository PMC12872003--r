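# Labour-cost economics: wage derivation, per-operation cost margin of the
# drone-assisted method, and drone-procurement break-even analysis.

#' Derive the daily wage from a base salary and annual adjustments
#'
#' Compounds a base net monthly salary through an ordered list of annual
#' fractional adjustments, then divides by the number of working days per
#' month. The default arguments reproduce the Ghana public-sector chain:
#' GHS 2,594/month compounded by +30% and +23% gives GHS 4,147.8, and over
#' 20 working days a daily wage of GHS 207.4.
#'
#' @param base_monthly_salary Positive base salary (currency units/month).
#' @param annual_adjustments Numeric vector of fractional adjustments
#'   (e.g. `c(0.30, 0.23)`); each must exceed -1. Order is immaterial.
#' @param working_days_per_month Positive integer, default 20.
#' @return Daily wage at full precision.
#' @export
#' @examples
#' derive_daily_wage(2594, c(0.30, 0.23), 20) # 207.39
derive_daily_wage <- function(base_monthly_salary = 2594,
                              annual_adjustments = c(0.30, 0.23),
                              working_days_per_month = 20) {
  stopifnot(base_monthly_salary > 0, working_days_per_month >= 1)
  if (any(annual_adjustments <= -1)) {
    stop("each annual adjustment must be > -1", call. = FALSE)
  }
  base_monthly_salary * prod(1 + annual_adjustments) / working_days_per_month
}

#' Worker-cost margin per operation
#'
#' The labour cost saved by running one operation with the proposed method
#' instead of the conventional one over the same area:
#' \deqn{M = R \cdot S \cdot (E_c - E_p)}
#' where `R` is the daily wage, `S` the operation area (km\eqn{^2}), and
#' `Ec`, `Ep` the conventional and proposed labour intensities in
#' person-days per km\eqn{^2} (typically the arm-mean TPDUAs). Negative when
#' the proposed method is less efficient.
#'
#' @param daily_wage Positive wage R (currency/day).
#' @param area_km2 Positive operation area S.
#' @param tpdua_conventional,tpdua_proposed Labour intensities Ec and Ep.
#' @return Margin M in currency units per operation.
#' @export
#' @examples
#' worker_cost_margin(207.4, 10, 8.03, 4.00) # 8358.22
worker_cost_margin <- function(daily_wage, area_km2, tpdua_conventional,
                               tpdua_proposed) {
  stopifnot(daily_wage > 0, area_km2 >= 0)
  daily_wage * area_km2 * (tpdua_conventional - tpdua_proposed)
}

#' Operations needed to recover a drone purchase
#'
#' Given a positive per-operation margin `M`, the drone cost is recovered
#' after `drone_cost / M` operations (continuous) or after the smallest
#' whole number of operations `n` with `n * M >= drone_cost`. Both values
#' are reported; neither is rounded toward the other.
#'
#' @param drone_cost Positive procurement cost.
#' @param margin Positive per-operation margin from [worker_cost_margin()].
#' @return A list with `continuous` and `whole_operations`.
#' @export
#' @examples
#' m <- worker_cost_margin(207.4, 10, 8.03, 4.00)
#' break_even_operations(75000, m) # continuous 8.97, whole 9
break_even_operations <- function(drone_cost, margin) {
  stopifnot(drone_cost > 0)
  if (margin <= 0) {
    stop("margin must be positive: the investment is never recovered",
         call. = FALSE)
  }
  cont <- drone_cost / margin
  whole <- ceiling(cont)
  # guard against ceiling() landing one short of n*M >= cost at FP boundaries
  if (whole * margin < drone_cost) whole <- whole + 1
  list(continuous = cont, whole_operations = as.integer(whole))
}

#' Margin as a function of operation area
#'
#' Evaluates the worker-cost margin over a vector of operation areas;
#' strictly increasing in area whenever `Ec > Ep`.
#'
#' @inheritParams worker_cost_margin
#' @param areas Numeric vector of non-negative areas (km\eqn{^2}).
#' @return A data.frame with columns `area_km2`, `margin`.
#' @export
margin_curve <- function(daily_wage, areas, tpdua_conventional,
                         tpdua_proposed) {
  if (length(areas) == 0) stop("areas must be non-empty", call. = FALSE)
  data.frame(
    area_km2 = areas,
    margin = vapply(areas, function(a) {
      worker_cost_margin(daily_wage, a, tpdua_conventional, tpdua_proposed)
    }, numeric(1))
  )
}
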