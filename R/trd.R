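# Treatment-shift detection and TRD classification.
#
# A treatment shift is a change in antidepressant drug (a new chemical
# substance at ATC level 5 among SSRI/SNRI/TCA/MAOI), the add-on of another
# antidepressant to ongoing therapy, or the initiation of ECT. TRD is
# defined at the second shift occurring within one year prior to one year
# after the MDD diagnosis; that second shift's date is the index date.

#' Antidepressant class of an ATC code
#'
#' Classifies level-5 ATC codes into SSRI / SNRI / TCA / MAOI by the longest
#' matching configured prefix, or `"none"` when no prefix matches.
#'
#' @param atc_code character vector of 7-character ATC codes.
#' @param config a [default_code_config()].
#' @return character vector over `{SSRI, SNRI, TCA, MAOI, none}`.
#' @export
#' @examples
#' substance_class(c("N06AB06", "N06AF03", "N05AH04"))
substance_class <- function(atc_code, config = default_code_config()) {
  out <- rep("none", length(atc_code))
  best <- rep(0L, length(atc_code))
  for (cls in names(config$antidepressant_class_prefixes)) {
    for (p in config$antidepressant_class_prefixes[[cls]]) {
      hit <- startsWith(toupper(atc_code), p) & nchar(p) > best
      out[hit] <- cls
      best[hit] <- nchar(p)
    }
  }
  out
}

# in-window event list (date, id) for one person; id is the full ATC level-5
# code, or "ECT" for procedure events
shift_events <- function(prescriptions, procedures, mdd_date, config) {
  dates <- integer(0); ids <- character(0)
  if (!is.null(prescriptions) && nrow(prescriptions) > 0L) {
    keep <- substance_class(prescriptions$atc_code, config) != "none"
    dates <- c(dates, as.integer(as.IDate(prescriptions$redemption_date[keep])))
    ids <- c(ids, toupper(prescriptions$atc_code[keep]))
  }
  if (!is.null(procedures) && nrow(procedures) > 0L) {
    keep <- toupper(procedures$sks_code) %in% toupper(config$ect_codes)
    dates <- c(dates, as.integer(as.IDate(procedures$date[keep])))
    ids <- c(ids, rep("ECT", sum(keep)))
  }
  m <- as.integer(as.IDate(mdd_date))
  w <- config$window_days
  keep <- dates >= m - w & dates <= m + w
  ord <- order(dates[keep], ids[keep])
  list(date = dates[keep][ord], id = ids[keep][ord])
}

#' Detect treatment shifts for one person
#'
#' Considers, in chronological order, the first in-window occurrence of each
#' distinct antidepressant substance and of ECT. The earliest such event is
#' treatment initiation (not a shift); every later distinct new-treatment
#' event is one shift. Same-day distinct new substances each count once,
#' ordered lexicographically. Shift kind is `ect` for ECT, `add_on` when any
#' other substance was redeemed within the preceding
#' `activity_window_days` (default 90, a labelling convention only), else
#' `switch`.
#'
#' With `config$re_initiation_counts = TRUE` the semantics change from
#' "new substance" to "change from the previous treatment": returning to an
#' earlier substance counts again. With `config$ect_always_shift = TRUE` the
#' first occurrence of ECT counts as a shift even when it is the first
#' treatment event. `config$min_days_between_shifts` discards shifts closer
#' than that many days to the previously counted treatment event.
#'
#' @param prescriptions single-person prescription rows (`redemption_date`,
#'   `atc_code`).
#' @param procedures single-person procedure rows (`date`, `sks_code`).
#' @param mdd_date the person's MDD diagnosis date.
#' @param config a [default_code_config()].
#' @return data.frame with one row per shift: `date`, `kind`,
#'   `new_treatment`, `prior_active` (comma-collapsed substances active at
#'   the shift date).
#' @export
detect_shifts <- function(prescriptions, procedures, mdd_date,
                          config = default_code_config()) {
  ev <- shift_events(prescriptions, procedures, mdd_date, config)
  empty <- data.frame(date = as.Date(character(0)), kind = character(0),
                      new_treatment = character(0), prior_active = character(0),
                      stringsAsFactors = FALSE)
  if (length(ev$date) == 0L) return(empty)

  if (isTRUE(config$re_initiation_counts)) {
    # change-from-previous: collapse consecutive duplicates of the ordered
    # full event sequence
    keep <- c(TRUE, ev$id[-1] != ev$id[-length(ev$id)])
    cand_date <- ev$date[keep]
    cand_id <- ev$id[keep]
  } else {
    # new-treatment semantics: first occurrence of each distinct treatment
    keep <- !duplicated(ev$id)
    cand_date <- ev$date[keep]
    cand_id <- ev$id[keep]
  }

  is_shift <- rep(TRUE, length(cand_id))
  if (isTRUE(config$ect_always_shift)) {
    first_non_ect <- which(cand_id != "ECT")[1]
    if (!is.na(first_non_ect)) is_shift[first_non_ect] <- FALSE
  } else {
    is_shift[1] <- FALSE
  }

  # minimum spacing from the previously counted treatment event
  min_gap <- config$min_days_between_shifts %||% 0L
  if (min_gap > 0L) {
    last_date <- cand_date[1]
    for (i in seq_along(cand_id)[-1]) {
      if (is_shift[i] && cand_date[i] - last_date < min_gap) {
        is_shift[i] <- FALSE
      } else {
        last_date <- cand_date[i]
      }
    }
  }

  sd_ <- cand_date[is_shift]
  si <- cand_id[is_shift]
  if (length(sd_) == 0L) return(empty)

  aw <- config$activity_window_days
  rx_dates <- ev$date[ev$id != "ECT"]
  rx_ids <- ev$id[ev$id != "ECT"]
  prior_active <- vapply(seq_along(sd_), function(i) {
    act <- unique(rx_ids[rx_dates >= sd_[i] - aw & rx_dates <= sd_[i] &
                           rx_ids != si[i]])
    paste(sort(act), collapse = ",")
  }, character(1))
  kind <- ifelse(si == "ECT", "ect",
                 ifelse(nzchar(prior_active), "add_on", "switch"))
  data.frame(date = as.Date(sd_, origin = "1970-01-01"), kind = kind,
             new_treatment = si, prior_active = prior_active,
             stringsAsFactors = FALSE)
}

#' Classify treatment resistance from a shift sequence
#'
#' @param entry one cohort entry (needs `person_id`, `mdd_date`).
#' @param shifts output of [detect_shifts()] for the person.
#' @return one-row data.frame: `person_id`, `is_trd`, `index_date` (date of
#'   the second shift when TRD, else `NA` until matching assigns one),
#'   `n_shifts_in_window`, `prevalent_trd` (second shift on or before the
#'   MDD date; such persons are excluded from the cohort).
#' @export
classify_trd <- function(entry, shifts) {
  n <- nrow(shifts)
  is_trd <- n >= 2L
  index_date <- if (is_trd) as.Date(shifts$date[2]) else as.Date(NA)
  data.frame(person_id = entry$person_id, is_trd = is_trd,
             index_date = index_date, n_shifts_in_window = n,
             prevalent_trd = is_trd && index_date <= as.Date(entry$mdd_date),
             stringsAsFactors = FALSE)
}

#' Classify treatment resistance for a whole cohort
#'
#' Vectorized equivalent of [detect_shifts()] + [classify_trd()] applied to
#' every candidate. Under the default semantics (new-treatment shifts, no
#' minimum spacing) the computation is a grouped first-occurrence scan; any
#' non-default switch falls back to the per-person path, which is slower but
#' identical in result.
#'
#' @param bundle a `registry_bundle`.
#' @param candidates data.table with `person_id` and `mdd_date`.
#' @param config a [default_code_config()].
#' @return data.table: `person_id`, `is_trd`, `index_date`,
#'   `n_shifts_in_window`, `prevalent_trd`.
#' @export
classify_trd_cohort <- function(bundle, candidates,
                                config = default_code_config()) {
  cand <- as.data.table(candidates)[, .(person_id, mdd_date)]
  default_path <- !isTRUE(config$re_initiation_counts) &&
    !isTRUE(config$ect_always_shift) &&
    (config$min_days_between_shifts %||% 0L) == 0L

  if (!default_path) {
    rx_s <- split(as.data.frame(bundle$prescriptions),
                  bundle$prescriptions$person_id)
    pr_s <- split(as.data.frame(bundle$procedures),
                  bundle$procedures$person_id)
    out <- lapply(seq_len(nrow(cand)), function(i) {
      pid <- cand$person_id[i]
      sh <- detect_shifts(rx_s[[pid]], pr_s[[pid]], cand$mdd_date[i], config)
      classify_trd(cand[i], sh)
    })
    return(as.data.table(rbindlist(out)))
  }

  rx <- as.data.table(bundle$prescriptions)
  rx <- rx[substance_class(atc_code, config) != "none",
           .(person_id, date = redemption_date, id = toupper(atc_code))]
  ect <- as.data.table(bundle$procedures)
  ect <- ect[toupper(sks_code) %in% toupper(config$ect_codes),
             .(person_id, date, id = "ECT")]
  ev <- rbind(rx, ect)
  ev <- ev[cand, on = "person_id", nomatch = 0L]
  w <- config$window_days
  ev <- ev[date >= mdd_date - w & date <= mdd_date + w]
  status <- cand[, .(person_id, mdd_date)]
  if (nrow(ev) == 0L) {
    status[, `:=`(is_trd = FALSE, index_date = as.IDate(NA),
                  n_shifts_in_window = 0L, prevalent_trd = FALSE)]
    return(status[, .(person_id, is_trd, index_date, n_shifts_in_window,
                      prevalent_trd)])
  }
  firsts <- ev[, .(date = min(date)), by = .(person_id, id)]
  setorder(firsts, person_id, date, id)
  agg <- firsts[, .(n_events = .N, second_shift_date = date[3]), by = person_id]
  status <- agg[status, on = "person_id"]
  status[is.na(n_events), n_events := 1L]  # 1 => zero shifts sentinel
  status[, n_shifts_in_window := pmax(n_events - 1L, 0L)]
  status[, is_trd := n_shifts_in_window >= 2L]
  status[, index_date := as.IDate(ifelse(is_trd, second_shift_date, NA))]
  status[, prevalent_trd := is_trd & index_date <= mdd_date]
  status[, .(person_id, is_trd, index_date, n_shifts_in_window, prevalent_trd)]
}

#' Brute-force shift oracle
#'
#' Independent re-derivation of the shift-date sequence by an explicit
#' day-by-day state machine over the calendar span of the events: it walks
#' every day in order, maintains the set of treatments seen so far (or the
#' previous day's treatment under re-initiation semantics), and records a
#' shift whenever the day introduces a countable treatment change. Used only
#' to verify [detect_shifts()] on small instances.
#'
#' @inheritParams detect_shifts
#' @return vector of shift dates (class `Date`).
#' @export
shift_oracle <- function(prescriptions, procedures, mdd_date,
                         config = default_code_config()) {
  ev <- shift_events(prescriptions, procedures, mdd_date, config)
  if (length(ev$date) == 0L) return(as.Date(character(0)))
  re_init <- isTRUE(config$re_initiation_counts)
  ect_first <- isTRUE(config$ect_always_shift)
  min_gap <- config$min_days_between_shifts %||% 0L

  seen <- character(0)
  prev_id <- NULL
  initiated <- FALSE
  last_counted <- NA_integer_
  shift_dates <- integer(0)

  for (day in sort(unique(ev$date))) {
    todays <- unique(ev$id[ev$date == day])
    for (id in sort(todays)) {           # lexicographic within day
      countable <- if (re_init) {
        is.null(prev_id) || id != prev_id
      } else {
        !(id %in% seen)
      }
      if (!countable) next
      seen <- union(seen, id)
      takes_initiation <- if (ect_first) id != "ECT" && !initiated else !initiated
      if (takes_initiation) {
        initiated <- TRUE
        prev_id <- id
        last_counted <- day
        next
      }
      prev_id <- id  # the regimen changes even when the shift is not counted
      if (min_gap > 0L && !is.na(last_counted) && day - last_counted < min_gap) {
        next
      }
      shift_dates <- c(shift_dates, day)
      last_counted <- day
    }
  }
  as.Date(shift_dates, origin = "1970-01-01")
}

utils::globalVariables(c("id", "i.person_id"))
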