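# Operational-efficiency indicators: labour intensity per unit area,
# larvicide-use efficiency, detection ratios and arm-level summaries.

#' Round half away from zero
#'
#' Display rounding used throughout the reports: ties round away from zero
#' (2.905 -> 2.91), unlike [base::round()]'s banker's rounding. Computation
#' always carries full precision; this is applied only when a value is
#' compared with or printed like a published table cell.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Total person-days for one sub-district
#'
#' Sums workers times workdays over the field phases of a single
#' sub-district. An empty phase table contributes 0 person-days so that
#' partially logged districts aggregate safely.
#'
#' @param phases A data.frame of work-phase records (`workers`, `days`),
#'   all for one sub-district.
#' @return Non-negative integer person-day total.
#' @export
#' @examples
#' ph <- data.frame(workers = c(2, 3), days = c(1, 1))
#' total_person_days(ph) # 5
total_person_days <- function(phases) {
  if (is.null(phases) || nrow(phases) == 0) return(0L)
  if ("sub_district" %in% names(phases) &&
      length(unique(phases$sub_district)) > 1) {
    stop("phases must all belong to one sub-district", call. = FALSE)
  }
  as.integer(sum(phases$workers * phases$days))
}

#' Total person-days per unit area (TPDUA)
#'
#' The labour-intensity indicator: person-days of fieldwork summed over all
#' phases, divided by the operation area in km\eqn{^2}. Returned at full
#' precision; use [round_half_away()] for table-style display.
#'
#' @inheritParams total_person_days
#' @param area_km2 Positive operation area in km\eqn{^2}.
#' @return Person-days per km\eqn{^2}.
#' @export
#' @examples
#' compute_tpdua(data.frame(workers = c(2, 3), days = c(1, 1)), 0.94) # 5.319
compute_tpdua <- function(phases, area_km2) {
  if (!is.numeric(area_km2) || length(area_km2) != 1 || is.na(area_km2) ||
      area_km2 <= 0) {
    stop("area_km2 must be a single positive number", call. = FALSE)
  }
  total_person_days(phases) / area_km2
}

#' Waterbodies treated per larvicide pack
#'
#' @param sprayed_sites Non-negative count of treated waterbodies.
#' @param packs_per_month Positive larvicide pack units applied.
#' @return Sites per pack unit.
#' @export
sites_per_pack <- function(sprayed_sites, packs_per_month) {
  stopifnot(length(sprayed_sites) == length(packs_per_month))
  if (any(packs_per_month <= 0)) {
    stop("packs_per_month must be > 0", call. = FALSE)
  }
  sprayed_sites / packs_per_month
}

#' Drone-to-manual detection ratio
#'
#' @param sites_drone Waterbody count found by drone mapping.
#' @param sites_manual Waterbody count found by manual scouting; must be > 0
#'   (the ratio is undefined otherwise).
#' @return `sites_drone / sites_manual`.
#' @export
detection_ratio <- function(sites_drone, sites_manual) {
  if (any(sites_manual == 0)) {
    stop("detection ratio undefined when sites_manual == 0", call. = FALSE)
  }
  sites_drone / sites_manual
}

#' High-risk classification ratio
#'
#' Fraction of detected waterbodies classified high-risk (and hence
#' sprayed) in a district. In the control arm every found site is sprayed,
#' so the ratio is 1 by construction.
#'
#' @param sprayed_sites,found_sites Non-negative counts; `found_sites` > 0.
#' @return Value in \[0, 1\].
#' @export
high_risk_ratio <- function(sprayed_sites, found_sites) {
  if (any(found_sites == 0)) {
    stop("high-risk ratio undefined when found_sites == 0", call. = FALSE)
  }
  sprayed_sites / found_sites
}

#' Arm-level summary with Tukey-hinge quartiles
#'
#' Mean, median and hinge quartiles of an indicator within one study arm.
#' Quartiles are Tukey hinges — medians of the lower and upper half-samples,
#' with the halves including the middle value when n is odd; at n = 4 each
#' hinge is the midpoint of a pair. Hinges (not interpolation quantiles) are
#' used because they are the convention the published interquartile ranges
#' follow at these tiny group sizes.
#'
#' @param values Numeric vector, length >= 1.
#' @param arm Label for the group (e.g. `"intervention"`).
#' @return A one-row data.frame with `arm`, `mean`, `median`, `q1`, `q3`, `n`.
#' @export
#' @examples
#' group_summary(c(5.32, 4.85, 2.82, 2.99), "intervention")
group_summary <- function(values, arm = NA_character_) {
  if (length(values) == 0 || any(is.na(values))) {
    stop("values must be a non-empty numeric vector without NAs",
         call. = FALSE)
  }
  s <- sort(values)
  n <- length(s)
  med <- stats::median(s)
  half <- floor((n + 1) / 2) # lower/upper halves include the middle if n odd
  q1 <- stats::median(s[seq_len(half)])
  q3 <- stats::median(s[seq(n - half + 1, n)])
  data.frame(arm = arm, mean = mean(s), median = med, q1 = q1, q3 = q3, n = n,
             stringsAsFactors = FALSE)
}

#' Population-adjusted case rate
#'
#' Monthly confirmed-case counts divided by the resident population, giving
#' cases per person per month.
#'
#' @param cases Non-negative case count.
#' @param population Positive resident population.
#' @return `cases / population`.
#' @export
population_adjusted_rate <- function(cases, population) {
  if (any(population <= 0)) stop("population must be > 0", call. = FALSE)
  if (any(cases < 0)) stop("cases must be >= 0", call. = FALSE)
  cases / population
}

#' Per-district efficiency report
#'
#' Joins the sub-district, work-phase, spray-log and detection tables into
#' one row per district: total person-days, TPDUA, sites treated per pack,
#' drone/manual detection ratio (NA where no detection comparison was run)
#' and high-risk ratio.
#'
#' @param subdistricts,workphases,spray_logs,detections Data frames in the
#'   package's schemas (see [read_lsm_table()]); `detections` may be `NULL`.
#' @return A data.frame with one row per sub-district plus the arm label.
#' @export
efficiency_report <- function(subdistricts, workphases, spray_logs,
                              detections = NULL) {
  out <- lapply(seq_len(nrow(subdistricts)), function(i) {
    d <- subdistricts[i, ]
    ph <- workphases[workphases$sub_district == d$name, , drop = FALSE]
    sl <- spray_logs[spray_logs$sub_district == d$name, , drop = FALSE]
    det <- if (!is.null(detections)) {
      detections[detections$sub_district == d$name, , drop = FALSE]
    }
    pd <- total_person_days(ph)
    data.frame(
      sub_district = d$name, arm = d$arm,
      total_person_days = pd,
      tpdua = pd / d$area_km2,
      sites_per_pack = if (nrow(sl)) {
        sites_per_pack(sl$sprayed_sites, sl$packs_per_month)
      } else NA_real_,
      detection_ratio = if (!is.null(det) && nrow(det)) {
        detection_ratio(det$sites_drone, det$sites_manual)
      } else NA_real_,
      high_risk_ratio = if (nrow(sl)) {
        high_risk_ratio(sl$sprayed_sites, sl$found_sites)
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
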