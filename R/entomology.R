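# CDC light-trap catch aggregation: genus/sex composition, weekly series
# and the genus-by-site contingency table with a minimum-count exclusion.

mosquito_genera <- function() setdiff(LSM_GENERA, "non_target")

#' Summarise trap catches
#'
#' Aggregates light-trap records into overall composition summaries. Genus
#' and sex proportions are fractions of the mosquito total (non-target
#' insects are excluded from that denominator); the mosquito share itself is
#' a fraction of all insects captured, matching each published percentage's
#' implied base.
#'
#' @param records A data.frame of trap-catch records (`site`, `week_index`,
#'   `genus`, `sex`, `count`).
#' @return A list: `total_insects`, `total_mosquitoes`, `genus_counts`,
#'   `genus_props`, `sex_counts`, `sex_props`, `site_totals` (mosquitoes per
#'   site), `mosquito_share`.
#' @export
summarize_catches <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no trap-catch records to summarise", call. = FALSE)
  }
  total_insects <- sum(records$count)
  mosq <- records[records$genus %in% mosquito_genera(), , drop = FALSE]
  total_mosquitoes <- sum(mosq$count)
  gc <- tapply(mosq$count, factor(mosq$genus, mosquito_genera()), sum)
  gc[is.na(gc)] <- 0
  sc <- tapply(mosq$count, factor(mosq$sex, LSM_SEXES), sum)
  sc[is.na(sc)] <- 0
  st <- tapply(mosq$count, mosq$site, sum)
  list(
    total_insects = total_insects,
    total_mosquitoes = total_mosquitoes,
    genus_counts = gc,
    genus_props = if (total_mosquitoes > 0) gc / total_mosquitoes else gc * NA,
    sex_counts = sc,
    sex_props = if (total_mosquitoes > 0) sc / total_mosquitoes else sc * NA,
    site_totals = st,
    mosquito_share = total_mosquitoes / total_insects
  )
}

#' Weekly mosquito catch series for one site
#'
#' Totals mosquito counts per week at a site, reporting every week from 1
#' to the last observed week (or `through_week`) with zeros where nothing
#' was caught — trap weeks with no captures are data, not gaps.
#'
#' @param records Trap-catch records.
#' @param site Site name; must occur in `records`.
#' @param through_week Optional last week to report; defaults to the
#'   largest `week_index` at the site.
#' @param mosquitoes_only Drop non-target insects first (default TRUE).
#' @return A data.frame `week_index`, `count`, weeks ascending.
#' @export
weekly_series <- function(records, site, through_week = NULL,
                          mosquitoes_only = TRUE) {
  if (!site %in% records$site) {
    stop("unknown site: ", site, call. = FALSE)
  }
  r <- records[records$site == site, , drop = FALSE]
  if (mosquitoes_only) {
    r <- r[r$genus %in% mosquito_genera(), , drop = FALSE]
  }
  last <- through_week %||% if (nrow(r)) max(r$week_index) else 0L
  if (last < 1) return(data.frame(week_index = integer(), count = integer()))
  weeks <- seq_len(last)
  tot <- tapply(r$count, factor(r$week_index, weeks), sum)
  tot[is.na(tot)] <- 0
  data.frame(week_index = weeks, count = as.integer(tot))
}

#' Genus-by-site contingency table with rare-genus exclusion
#'
#' Builds the mosquito genus-by-site count matrix for a pair of sites,
#' excluding any genus whose total across both sites falls below
#' `min_genus_total`. The default threshold of 2 excludes singleton genera
#' (a single specimen cannot inform a distribution comparison) while
#' remaining a general rule rather than a hard-coded taxon.
#'
#' @param records Trap-catch records (non-target insects are ignored).
#' @param sites Character vector of exactly two site names, column order.
#' @param min_genus_total Minimum combined count for a genus to be kept.
#' @return A list: `table` (matrix genera x 2 sites), `excluded`
#'   (data.frame of dropped genera with their totals and reason).
#' @export
#' @examples
#' fx <- load_paper_fixtures()
#' ct <- build_contingency(fx$trap_catches, c("Abaam", "Pramkese"))
#' chi_square_test(ct$table)$statistic # 33.63
build_contingency <- function(records, sites, min_genus_total = 2) {
  if (length(sites) != 2) stop("exactly two sites required", call. = FALSE)
  missing <- setdiff(sites, unique(records$site))
  if (length(missing)) {
    stop("site(s) absent from records: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  r <- records[records$site %in% sites &
                 records$genus %in% mosquito_genera(), , drop = FALSE]
  m <- tapply(r$count, list(factor(r$genus, mosquito_genera()),
                            factor(r$site, sites)), sum)
  m[is.na(m)] <- 0
  m <- m[rowSums(m) > 0, , drop = FALSE]
  totals <- rowSums(m)
  drop <- totals < min_genus_total
  excluded <- data.frame(
    genus = rownames(m)[drop],
    total = unname(totals[drop]),
    reason = sprintf("total %d below minimum %d", unname(totals[drop]),
                     min_genus_total),
    stringsAsFactors = FALSE
  )
  list(table = m[!drop, , drop = FALSE], excluded = excluded)
}
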