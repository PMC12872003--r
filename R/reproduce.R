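# One-shot harness: recompute every desk-reproducible published statistic
# from the packaged fixtures and report computed vs printed side by side.

#' Recompute the published operational statistics from the fixtures
#'
#' Runs the whole desk-reproducible analysis from the packaged tables: the
#' eight TPDUA cells and arm means, hinge medians/IQRs, the exact
#' Mann-Whitney tests on TPDUA and sites-per-pack, the eight sites-per-pack
#' cells and arm means, the per-treated-site larvicide reduction, detection
#' ratios, the wage chain and cost-margin/break-even figures, genus and sex
#' composition, and the genus-by-site chi-square. Each check compares the
#' recomputed value with the printed one at the printed precision.
#'
#' Checks carrying a `note` refer to documented print inconsistencies (see
#' [fixture_notes()]): there the printed value itself is inconsistent with
#' the printed inputs and the comparison tolerance is widened to one unit
#' in the last printed digit.
#'
#' @param fixtures Fixture bundle, by default [load_paper_fixtures()];
#'   inject a modified copy to probe the harness's sensitivity.
#' @return A data.frame with columns `check`, `computed`, `printed`,
#'   `tolerance`, `pass`, `note`; all checks pass on the shipped fixtures.
#' @export
#' @examples
#' rep <- reproduce_paper()
#' all(rep$pass)
reproduce_paper <- function(fixtures = load_paper_fixtures()) {
  fx <- fixtures
  rows <- list()
  add <- function(check, computed, printed, tolerance = NULL, note = "") {
    tol <- tolerance %||% 5e-3 # half a unit in the 2nd decimal by default
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, computed = computed, printed = printed,
      tolerance = tol, pass = is.finite(computed) &&
        abs(computed - printed) <= tol + 1e-12,
      note = note, stringsAsFactors = FALSE)
  }

  ## labour intensity -------------------------------------------------------
  eff <- efficiency_report(fx$subdistricts, fx$workphases, fx$spray_logs)
  printed_tpdua <- c(Nkwantanang = 5.32, Abaam = 4.85, Takyiman = 2.82,
                     Asuom = 2.99, Abodom = 12.24, Subi = 5.41,
                     Pramkese = 7.74, Kade = 6.72)
  for (d in names(printed_tpdua)) {
    add(paste0("tpdua_", d), eff$tpdua[eff$sub_district == d],
        printed_tpdua[[d]])
  }
  tp_i <- eff$tpdua[eff$arm == "intervention"]
  tp_c <- eff$tpdua[eff$arm == "control"]
  add("tpdua_mean_intervention", mean(tp_i), 4.00)
  add("tpdua_mean_control", mean(tp_c), 8.03)
  # the printed IQRs are hinges of the 2-decimal table values
  gi <- group_summary(round_half_away(tp_i), "intervention")
  gc_ <- group_summary(round_half_away(tp_c), "control")
  add("tpdua_median_intervention", gi$median, 3.92)
  add("tpdua_q1_intervention", gi$q1, 2.91)
  add("tpdua_q3_intervention", gi$q3, 5.09)
  add("tpdua_median_control", gc_$median, 7.23)
  add("tpdua_q1_control", gc_$q1, 6.07)
  add("tpdua_q3_control", gc_$q3, 9.99)
  mw <- mann_whitney_exact(tp_i, tp_c)
  add("tpdua_mw_u", mw$u_statistic, 0, tolerance = 0)
  add("tpdua_mw_p", mw$p_two_sided, 0.029, tolerance = 5e-4)

  ## larvicide efficiency ---------------------------------------------------
  printed_spp <- c(Nkwantanang = 146, Abaam = 182, Takyiman = 178,
                   Asuom = 170, Abodom = 36, Subi = 50, Pramkese = 48,
                   Kade = 105)
  for (d in names(printed_spp)) {
    add(paste0("sites_per_pack_", d),
        eff$sites_per_pack[eff$sub_district == d], printed_spp[[d]],
        tolerance = 0.5)
  }
  spp_i <- eff$sites_per_pack[eff$arm == "intervention"]
  spp_c <- eff$sites_per_pack[eff$arm == "control"]
  add("sites_per_pack_mean_intervention", mean(spp_i), 169, tolerance = 0.5)
  add("sites_per_pack_mean_control", mean(spp_c), 60, tolerance = 0.5)
  si <- group_summary(spp_i, "intervention")
  sc <- group_summary(spp_c, "control")
  add("sites_per_pack_median_intervention", si$median, 174.0, tolerance = 0.05)
  add("sites_per_pack_q1_intervention", si$q1, 158.0, tolerance = 0.05)
  add("sites_per_pack_q3_intervention", si$q3, 180.0, tolerance = 0.05)
  add("sites_per_pack_median_control", sc$median, 49.0, tolerance = 0.05)
  add("sites_per_pack_q1_control", sc$q1, 42.0, tolerance = 0.05)
  add("sites_per_pack_q3_control", sc$q3, 77.5, tolerance = 0.05)
  mw2 <- mann_whitney_exact(spp_c, spp_i)
  add("sites_per_pack_mw_u", mw2$u_statistic, 0, tolerance = 0)
  add("sites_per_pack_mw_p", mw2$p_two_sided, 0.029, tolerance = 5e-4)
  add("larvicide_reduction_per_site",
      1 - round_half_away(mean(spp_c), 0) / round_half_away(mean(spp_i), 0),
      0.645)

  ## high-risk ratios -------------------------------------------------------
  printed_hr <- c(Nkwantanang = 0.557, Abaam = 0.592, Takyiman = 0.747,
                  Asuom = 0.585)
  for (d in names(printed_hr)) {
    tol <- if (d == "Nkwantanang") 5e-4 else 2e-3
    note <- if (d == "Nkwantanang") "" else "high-risk-ratio-rounding"
    add(paste0("high_risk_ratio_", d),
        eff$high_risk_ratio[eff$sub_district == d], printed_hr[[d]],
        tolerance = tol, note = note)
  }

  ## detection --------------------------------------------------------------
  det <- fx$detections
  printed_dr <- c(Nkwantanan = 4.53, Abaam = 4.23, Takyiman = 1.83,
                  Asuom = 4.68)
  for (d in names(printed_dr)) {
    add(paste0("detection_ratio_", d),
        detection_ratio(det$sites_drone[det$sub_district == d],
                        det$sites_manual[det$sub_district == d]),
        printed_dr[[d]])
  }
  add("detection_ratio_total",
      detection_ratio(sum(det$sites_drone), sum(det$sites_manual)), 3.61)

  ## economics --------------------------------------------------------------
  monthly <- 2594 * prod(1 + c(0.30, 0.23))
  add("adjusted_monthly_salary", monthly, 4148, tolerance = 0.5)
  wage <- derive_daily_wage(2594, c(0.30, 0.23), 20)
  add("daily_wage", wage, 207.4, tolerance = 0.05)
  margin <- worker_cost_margin(wage, 10, mean(tp_c), mean(tp_i))
  be <- break_even_operations(75000, margin)
  # the source prose says "approximately ten"; both values are reported and
  # the qualitative check accepts the 8-12 neighbourhood of ten
  add("break_even_whole_operations_near_ten", be$whole_operations, 10,
      tolerance = 2, note = "qualitative: source prose 'approximately ten'")

  ## entomology -------------------------------------------------------------
  cs <- summarize_catches(fx$trap_catches)
  add("total_insects", cs$total_insects, 964, tolerance = 0)
  add("total_mosquitoes", cs$total_mosquitoes, 783, tolerance = 0)
  add("mosquito_share_pct", 100 * cs$mosquito_share, 81.2, tolerance = 0.05)
  add("culex_share_pct", 100 * cs$genus_props[["Culex"]], 90.8,
      tolerance = 0.05)
  add("aedes_share_pct", 100 * cs$genus_props[["Aedes"]], 4.73)
  add("anopheles_share_pct", 100 * cs$genus_props[["Anopheles"]], 4.34)
  add("mansonia_share_pct", 100 * cs$genus_props[["Mansonia"]], 0.13)
  sx <- fx$sex_counts
  add("male_share_pct",
      100 * sx$count[sx$sex == "male"] / sum(sx$count), 24.5,
      tolerance = 0.05)
  add("female_share_pct",
      100 * sx$count[sx$sex == "female"] / sum(sx$count), 75.5,
      tolerance = 0.05)
  ct <- build_contingency(fx$trap_catches, c("Abaam", "Pramkese"),
                          min_genus_total = 2)
  chi <- chi_square_test(ct$table)
  add("chi_square_statistic", chi$statistic, 33.63)
  add("chi_square_df", chi$df, 2, tolerance = 0)
  add("chi_square_p_below_0.001", as.numeric(chi$p_value < 0.001), 1,
      tolerance = 0)

  do.call(rbind, rows)
}
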