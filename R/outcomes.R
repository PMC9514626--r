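# Per-patient aggregation of healthcare resource utilization (HRU) counts
# and costs over the pre-index and post-index 365-day windows.

#' Names of the HRU count outcomes
#'
#' The 21 count outcomes of the outcome grid: psychiatric hospitalizations,
#' bed days (each overall / acute / elective), ED, outpatient and home
#' visits, private psychiatrist and psychologist visits; the somatic
#' counterparts (hospitalizations and bed days with acute/elective splits,
#' ED, outpatient); GP visits; other healthcare specialist visits.
#'
#' @return character vector of outcome names.
#' @export
hru_count_outcomes <- function() {
  c("psych_hospitalization", "psych_hospitalization_acute",
    "psych_hospitalization_elective",
    "psych_bed_days", "psych_bed_days_acute", "psych_bed_days_elective",
    "psych_ed", "psych_outpatient", "psych_home_visit",
    "private_psychiatrist", "private_psychologist",
    "somatic_hospitalization", "somatic_hospitalization_acute",
    "somatic_hospitalization_elective",
    "somatic_bed_days", "somatic_bed_days_acute", "somatic_bed_days_elective",
    "somatic_ed", "somatic_outpatient",
    "gp", "other_specialist")
}

#' Names of the cost outcomes
#'
#' The 9 cost categories (EUR): totals excluding and including medicine,
#' psychiatric services (hospital psychiatric services, private
#' psychiatrist, private psychologist and psychiatric home visits), somatic
#' services, GP, other private specialists, and the three medicine groups
#' (other / other psychiatric N05A+N05B / antidepressant N06A).
#'
#' @return character vector of outcome names.
#' @export
hru_cost_outcomes <- function() {
  c("cost_total_excl_medicine", "cost_total_incl_medicine",
    "cost_psychiatric", "cost_somatic", "cost_gp", "cost_other_specialist",
    "cost_medicine_other", "cost_medicine_other_psychiatric",
    "cost_medicine_antidepressant")
}

#' Observation window around an index date
#'
#' The pre-index window is the 365 days ending the day before the index
#' date; the post-index window is the 365 days starting the day after. The
#' index day itself belongs to neither window (the TRD-defining redemption
#' is itself a cost event and would otherwise contaminate the post-year);
#' `config$include_index_day_in_post = TRUE` extends the post window to
#' start on the index day.
#'
#' @param index_date the index date.
#' @param which `"pre"` or `"post"`.
#' @param config a [default_code_config()].
#' @return list with `start` and `end` dates (inclusive).
#' @export
#' @examples
#' window_bounds(as.Date("2010-06-01"), "post")
window_bounds <- function(index_date, which = c("post", "pre"),
                          config = default_code_config()) {
  which <- match.arg(which)
  d <- as.IDate(index_date)
  w <- config$window_days
  if (which == "pre") {
    list(start = d - w, end = d - 1L)
  } else if (isTRUE(config$include_index_day_in_post)) {
    list(start = d, end = d + w)
  } else {
    list(start = d + 1L, end = d + w)
  }
}

# nights of a stay that fall inside [w_start, w_end]; completed same-day
# inpatient stays inside the window count as one bed day
clipped_nights <- function(start, end, w_start, w_end) {
  nights <- pmax(pmin(as.integer(end), as.integer(w_end)) -
                   pmax(as.integer(start), as.integer(w_start)), 0L)
  same_day <- start == end & start >= w_start & start <= w_end
  nights[same_day] <- 1L
  nights
}

contact_outcome <- function(sector, contact_type) {
  fcase(
    sector == "psychiatric" & contact_type == "hospitalization", "psych_hospitalization",
    sector == "psychiatric" & contact_type == "ed", "psych_ed",
    sector == "psychiatric" & contact_type == "outpatient", "psych_outpatient",
    sector == "psychiatric" & contact_type == "home_visit", "psych_home_visit",
    contact_type == "private_psychiatrist", "private_psychiatrist",
    contact_type == "private_psychologist", "private_psychologist",
    sector == "somatic" & contact_type == "hospitalization", "somatic_hospitalization",
    sector == "somatic" & contact_type == "ed", "somatic_ed",
    sector == "somatic" & contact_type == "outpatient", "somatic_outpatient",
    contact_type == "gp", "gp",
    contact_type == "other_specialist", "other_specialist"
  )
}

#' HRU counts for one person and window
#'
#' Hospitalizations (and every visit-type contact) are counted at their
#' start date inside the window; bed days are the nights of the stay
#' falling inside the window (clipped at the window bounds, with completed
#' same-day inpatient stays counting as one bed day); the acute/elective
#' split follows the admission mode.
#'
#' @param contacts contact rows of one person.
#' @param window list with `start`/`end` from [window_bounds()].
#' @param config a [default_code_config()].
#' @return named numeric vector over [hru_count_outcomes()].
#' @export
count_hru <- function(contacts, window, config = default_code_config()) {
  out <- setNames(numeric(length(hru_count_outcomes())), hru_count_outcomes())
  ct <- as.data.table(contacts)
  if (nrow(ct) == 0L) return(out)
  base <- contact_outcome(ct$sector, ct$contact_type)
  in_win <- ct$start_date >= window$start & ct$start_date <= window$end
  cnt <- table(base[in_win])
  out[names(cnt)] <- out[names(cnt)] + as.numeric(cnt)
  hosp <- ct$contact_type == "hospitalization" & in_win
  for (mode in c("acute", "elective")) {
    cnt <- table(paste0(base, "_", mode)[hosp & ct$admission_mode == mode])
    out[names(cnt)] <- out[names(cnt)] + as.numeric(cnt)
  }
  # bed days: any stay overlapping the window contributes clipped nights
  hs <- ct[contact_type == "hospitalization" &
             start_date <= window$end & end_date >= window$start]
  if (nrow(hs)) {
    nights <- clipped_nights(hs$start_date, hs$end_date, window$start, window$end)
    sec <- ifelse(hs$sector == "psychiatric", "psych_bed_days", "somatic_bed_days")
    agg <- tapply(nights, sec, sum)
    out[names(agg)] <- out[names(agg)] + as.numeric(agg)
    agg <- tapply(nights, paste0(sec, "_", hs$admission_mode), sum)
    out[names(agg)] <- out[names(agg)] + as.numeric(agg)
  }
  out
}

#' HRU costs for one person and window
#'
#' In `config$cost_mode = "recorded"` (default) the per-event `cost_eur`
#' fields are summed; in `"fixed"` mode each counted contact is priced from
#' the configured fixed-price table (hospitalizations per clipped bed day,
#' other contacts per event). Medicine costs are split by ATC prefix into
#' antidepressant (N06A), other psychiatric (N05A, N05B) and other
#' medicine. Psychiatric cost comprises hospital psychiatric services,
#' psychiatric home visits, private psychiatrist and private psychologist
#' services.
#'
#' @param contacts contact rows of one person.
#' @param prescriptions prescription rows of one person.
#' @param window list with `start`/`end` from [window_bounds()].
#' @param config a [default_code_config()].
#' @return named numeric vector over [hru_cost_outcomes()].
#' @export
cost_hru <- function(contacts, prescriptions, window,
                     config = default_code_config()) {
  out <- setNames(numeric(length(hru_cost_outcomes())), hru_cost_outcomes())
  ct <- as.data.table(contacts)
  if (nrow(ct)) {
    in_win <- ct$start_date >= window$start & ct$start_date <= window$end
    ct <- ct[in_win]
  }
  if (nrow(ct)) {
    cost <- contact_cost(ct, window, config)
    grp <- cost_category(ct$sector, ct$contact_type)
    agg <- tapply(cost, grp, sum)
    out[names(agg)] <- out[names(agg)] + as.numeric(agg)
  }
  rx <- as.data.table(prescriptions)
  if (nrow(rx)) {
    rx <- rx[redemption_date >= window$start & redemption_date <= window$end]
  }
  if (nrow(rx)) {
    grp <- medicine_group(rx$atc_code, config)
    agg <- tapply(rx$cost_eur, grp, sum)
    out[names(agg)] <- out[names(agg)] + as.numeric(agg)
  }
  out["cost_total_excl_medicine"] <- out["cost_psychiatric"] +
    out["cost_somatic"] + out["cost_gp"] + out["cost_other_specialist"]
  out["cost_total_incl_medicine"] <- out["cost_total_excl_medicine"] +
    out["cost_medicine_other"] + out["cost_medicine_other_psychiatric"] +
    out["cost_medicine_antidepressant"]
  out
}

contact_cost <- function(ct, window, config) {
  if (config$cost_mode == "recorded") return(ct$cost_eur)
  pt <- as.data.table(config$fixed_price_table)
  priced <- pt[ct, on = c("sector", "contact_type", "admission_mode")]
  if (anyNA(priced$price_eur)) {
    miss <- priced[is.na(price_eur)][1]
    stop(sprintf("fixed_price_table has no entry for %s/%s/%s",
                 miss$sector, miss$contact_type, miss$admission_mode))
  }
  mult <- rep(1L, nrow(priced))
  hosp <- priced$contact_type == "hospitalization"
  mult[hosp] <- clipped_nights(priced$start_date[hosp], priced$end_date[hosp],
                               window$start, window$end)
  mult[hosp] <- pmax(mult[hosp], 1L)
  priced$price_eur * mult
}

cost_category <- function(sector, contact_type) {
  fcase(
    sector == "psychiatric", "cost_psychiatric",
    contact_type %in% c("private_psychiatrist", "private_psychologist"), "cost_psychiatric",
    sector == "somatic", "cost_somatic",
    contact_type == "gp", "cost_gp",
    contact_type == "other_specialist", "cost_other_specialist"
  )
}

medicine_group <- function(atc_code, config) {
  up <- toupper(atc_code)
  ad <- config$medicine_cost_groups$antidepressant
  op <- config$medicine_cost_groups$other_psychiatric
  hit_ad <- Reduce(`|`, lapply(ad, startsWith, x = up))
  hit_op <- Reduce(`|`, lapply(op, startsWith, x = up))
  ifelse(hit_ad, "cost_medicine_antidepressant",
         ifelse(hit_op, "cost_medicine_other_psychiatric", "cost_medicine_other"))
}

#' Per-patient HRU summaries for a matched population
#'
#' Computes, for every member of the matched population and for both the
#' pre-index and post-index year, the full count and cost outcome grid.
#' Returned in long form, one row per person x window x outcome.
#'
#' @param bundle a `registry_bundle`.
#' @param matched `matched` table (from [condition_followup()]).
#' @param config a [default_code_config()].
#' @param windows which windows to compute (default both).
#' @param outcomes restrict to these outcome names (default: all; cost
#'   totals always pull in their component categories internally).
#' @return data.table: `person_id`, `group` ("TRD"/"nonTRD"), `set_id`,
#'   stratum variables, `window`, `outcome`, `value`.
#' @export
compute_hru_summaries <- function(bundle, matched,
                                  config = default_code_config(),
                                  windows = c("pre", "post"),
                                  outcomes = NULL) {
  m <- as.data.table(matched)
  if (nrow(m) == 0L) stop("matched population is empty")
  all_out <- c(hru_count_outcomes(), hru_cost_outcomes())
  requested <- if (is.null(outcomes)) all_out else intersect(all_out, outcomes)
  sel <- requested
  if (any(c("cost_total_excl_medicine", "cost_total_incl_medicine") %in% sel)) {
    sel <- union(sel, hru_cost_outcomes())
  }
  ct <- as.data.table(bundle$contacts)[person_id %in% m$person_id]
  rx <- as.data.table(bundle$prescriptions)[person_id %in% m$person_id]
  pieces <- vector("list", 0L)
  for (wname in windows) {
    wb <- window_bounds(m$index_date, wname, config)
    win <- m[, .(person_id, w_start = wb$start, w_end = wb$end)]

    counts <- window_counts(ct, win)
    costs <- window_costs(ct, rx, win, config)
    long <- rbind(counts, costs)
    long[, window := wname]
    pieces[[length(pieces) + 1L]] <- long
  }
  long <- rbindlist(pieces)[outcome %in% sel]
  # dense grid: every person x outcome x window, zero-filled
  full <- CJ(person_id = m$person_id, outcome = sel, window = windows,
             unique = TRUE)
  long <- long[full, on = c("person_id", "outcome", "window")]
  long[is.na(value), value := 0]
  meta <- m[, .(person_id, group = ifelse(role == "case", "TRD", "nonTRD"),
                set_id, age_group, sex, year_group, severity)]
  long <- meta[long, on = "person_id"]
  if ("cost_total_excl_medicine" %in% sel) {
    # assemble cost totals after zero-filling so additivity holds exactly
    tot <- long[outcome %in% c("cost_psychiatric", "cost_somatic", "cost_gp",
                               "cost_other_specialist")]
    tot <- tot[, .(value = sum(value)), by = .(person_id, window)]
    long[tot, on = c("person_id", "window"),
         value := ifelse(outcome == "cost_total_excl_medicine", i.value, value)]
    med <- long[outcome %in% c("cost_medicine_other",
                               "cost_medicine_other_psychiatric",
                               "cost_medicine_antidepressant")]
    med <- med[, .(value = sum(value)), by = .(person_id, window)]
    tot2 <- merge(tot, med, by = c("person_id", "window"))
    tot2[, value := value.x + value.y]
    long[tot2, on = c("person_id", "window"),
         value := ifelse(outcome == "cost_total_incl_medicine", i.value, value)]
  }
  long[outcome %in% requested]
}

# long counts for all persons at once (vectorized over the matched table)
window_counts <- function(ct, win) {
  empty <- data.table(person_id = character(0), outcome = character(0),
                      value = numeric(0))
  if (nrow(ct) == 0L) return(empty)
  ev <- win[ct, on = "person_id", nomatch = 0L, allow.cartesian = TRUE]
  pieces <- list(empty)
  vis <- ev[start_date >= w_start & start_date <= w_end]
  if (nrow(vis)) {
    vis[, outcome := contact_outcome(sector, contact_type)]
    pieces <- c(pieces, list(vis[, .(value = as.numeric(.N)),
                                 by = .(person_id, outcome)]))
    hosp <- vis[contact_type == "hospitalization"]
    if (nrow(hosp)) {
      hosp[, outcome := paste0(outcome, "_", admission_mode)]
      pieces <- c(pieces, list(hosp[, .(value = as.numeric(.N)),
                                    by = .(person_id, outcome)]))
    }
  }
  stays <- ev[contact_type == "hospitalization" &
                start_date <= w_end & end_date >= w_start]
  if (nrow(stays)) {
    stays[, nights := clipped_nights(start_date, end_date, w_start, w_end)]
    stays[, outcome := ifelse(sector == "psychiatric",
                              "psych_bed_days", "somatic_bed_days")]
    bd <- stays[, .(value = as.numeric(sum(nights))), by = .(person_id, outcome)]
    stays[, outcome := paste0(outcome, "_", admission_mode)]
    bd2 <- stays[, .(value = as.numeric(sum(nights))), by = .(person_id, outcome)]
    pieces <- c(pieces, list(bd, bd2))
  }
  rbindlist(pieces)
}

window_costs <- function(ct, rx, win, config) {
  pieces <- list(data.table(person_id = character(0), outcome = character(0),
                            value = numeric(0)))
  if (nrow(ct)) {
    ev <- win[ct, on = "person_id", nomatch = 0L, allow.cartesian = TRUE]
    ev <- ev[start_date >= w_start & start_date <= w_end]
    if (nrow(ev)) {
      if (config$cost_mode == "recorded") {
        ev[, value := cost_eur]
      } else {
        pt <- as.data.table(config$fixed_price_table)
        ev <- pt[ev, on = c("sector", "contact_type", "admission_mode")]
        if (anyNA(ev$price_eur)) {
          miss <- ev[is.na(price_eur)][1]
          stop(sprintf("fixed_price_table has no entry for %s/%s/%s",
                       miss$sector, miss$contact_type, miss$admission_mode))
        }
        ev[, value := price_eur]
        hosp <- ev$contact_type == "hospitalization"
        if (any(hosp)) {
          n <- pmax(clipped_nights(ev$start_date[hosp], ev$end_date[hosp],
                                   ev$w_start[hosp], ev$w_end[hosp]), 1L)
          ev[hosp, value := price_eur * n]
        }
      }
      ev[, outcome := cost_category(sector, contact_type)]
      pieces <- c(pieces, list(ev[, .(value = sum(value)),
                                  by = .(person_id, outcome)]))
    }
  }
  if (nrow(rx)) {
    rv <- win[rx, on = "person_id", nomatch = 0L, allow.cartesian = TRUE]
    rv <- rv[redemption_date >= w_start & redemption_date <= w_end]
    if (nrow(rv)) {
      rv[, outcome := medicine_group(atc_code, config)]
      pieces <- c(pieces, list(rv[, .(value = sum(cost_eur)),
                                  by = .(person_id, outcome)]))
    }
  }
  rbindlist(pieces)
}

#' Descriptive mean (sd) per outcome, group and window
#'
#' @param summaries output of [compute_hru_summaries()].
#' @return data.table: `outcome`, `window`, `group`, `n`, `mean`, `sd`
#'   (0 with `sd_undefined = TRUE` for single-observation cells).
#' @export
summarize_by_group <- function(summaries) {
  s <- as.data.table(summaries)
  out <- s[, .(n = .N, mean = mean(value),
               sd = if (.N < 2L) 0 else sd(value),
               sd_undefined = .N < 2L),
           by = .(outcome, window, group)]
  setorder(out, window, outcome, group)
  out[]
}

utils::globalVariables(c("i.value", "value.x", "value.y", "sd_undefined"))
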