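# 1:2 exact matching of TRD cases to non-TRD MDD controls on
# (age group, sex, diagnosis-year group, severity), index-date assignment
# for controls (same diagnosis-to-index offset as the case), and
# complete-follow-up conditioning.

STRATUM_VARS <- c("age_group", "sex", "year_group", "severity")

#' Match TRD cases to non-TRD controls 1:2 within exact strata
#'
#' Cases are processed in a seeded random order; each case receives two
#' controls sampled uniformly without replacement from the unused pool of
#' non-TRD cohort members sharing the exact stratum (implemented as
#' sequential allocation from a pre-shuffled pool, which is the same
#' distribution). When only one control remains a 1-control set is formed
#' if `config$allow_partial` (default), otherwise the case is left
#' unmatched; cases with an empty pool are unmatched and logged. Controls
#' are non-TRD for the whole study, and each control's index date is its
#' own MDD date plus the case's diagnosis-to-index offset in days.
#'
#' @param cases cohort entries of TRD persons joined with their `index_date`.
#' @param controls cohort entries of non-TRD persons.
#' @param seed integer seed controlling processing order and sampling; a
#'   fixed seed makes the matched cohort byte-identical across runs.
#' @param config a [default_code_config()].
#' @return list with `matched` (one row per person: `set_id`, `role`
#'   ("case"/"control"), `person_id`, `case_person_id`, stratum variables,
#'   `mdd_date`, `case_offset_days`, `index_date`) and `attrition`
#'   (matching log).
#' @export
match_cohort <- function(cases, controls, seed = 20150101L,
                         config = default_code_config()) {
  ca <- as.data.table(cases)
  co <- as.data.table(controls)
  need <- c("person_id", "mdd_date", "index_date", STRATUM_VARS)
  stopifnot(all(need %in% names(ca)))
  ca <- copy(ca)[, case_offset_days := as.integer(index_date) - as.integer(mdd_date)]
  n_cases <- nrow(ca)
  if (nrow(co) == 0L) {
    warning("control pool is empty; no sets formed")
    return(list(matched = empty_matched(), attrition = match_log(n_cases, 0L, 0L, n_cases)))
  }

  set.seed(seed)
  ca <- ca[sample.int(nrow(ca))]          # randomized case processing order
  ca[, case_rk := seq_len(.N)]
  co <- co[sample.int(nrow(co))]          # pre-shuffled pools: sequential
  co[, pool_rk := seq_len(.N)]            # draws are uniform w/o replacement

  ca[, stratum := do.call(paste, c(.SD, sep = "|")), .SDcols = STRATUM_VARS]
  co[, stratum := do.call(paste, c(.SD, sep = "|")), .SDcols = STRATUM_VARS]
  # split preserves the shuffled order within each stratum
  ca_idx <- split(seq_len(nrow(ca)), ca$stratum)
  co_idx <- split(seq_len(nrow(co)), co$stratum)

  keep_cols <- c("person_id", "mdd_date", STRATUM_VARS)
  pieces <- vector("list", 0L)
  unmatched <- 0L; partial <- 0L
  for (s in names(ca_idx)) {
    cs <- ca[ca_idx[[s]]]
    pool <- co[co_idx[[s]] %||% integer(0)]
    n_c <- nrow(cs); n_p <- nrow(pool)
    n2 <- min(n_c, n_p %/% 2L)                       # cases with 2 controls
    extra <- as.integer(isTRUE(config$allow_partial) && n_p %% 2L == 1L && n_c > n2)
    n_matched <- n2 + extra
    unmatched <- unmatched + (n_c - n_matched)
    partial <- partial + extra
    if (n_matched == 0L) next
    case_part <- cs[seq_len(n_matched), c(keep_cols, "case_offset_days"), with = FALSE]
    case_part[, `:=`(role = "case", case_person_id = person_id)]
    ctrl_idx <- c(rep(seq_len(n2), each = 2L), rep(n2 + 1L, extra))
    ctrl_part <- pool[seq_len(2L * n2 + extra), keep_cols, with = FALSE]
    ctrl_part[, `:=`(role = "control",
                     case_person_id = case_part$person_id[ctrl_idx],
                     case_offset_days = case_part$case_offset_days[ctrl_idx])]
    pieces[[length(pieces) + 1L]] <- rbind(case_part, ctrl_part)
  }
  matched <- if (length(pieces)) rbindlist(pieces) else empty_matched()
  if (nrow(matched)) {
    matched[, index_date := as.IDate(mdd_date + case_offset_days)]
    matched[, set_id := .GRP, by = case_person_id]
    setorder(matched, set_id, -role)     # case row first within each set
    setcolorder(matched, names(empty_matched()))
  }
  list(matched = matched,
       attrition = match_log(n_cases, sum(matched$role == "case") - partial,
                             partial, unmatched))
}

match_log <- function(eligible, full, partial, unmatched) {
  data.table(
    stage = c("eligible TRD cases", "matched 1:2", "matched 1:1 (partial)",
              "unmatched (no stratum controls)"),
    remaining = c(eligible, full, partial, NA_integer_),
    removed = c(0L, NA_integer_, NA_integer_, unmatched)
  )
}

empty_matched <- function() {
  data.table(person_id = character(0), mdd_date = as.IDate(integer(0)),
             age_group = character(0), sex = character(0),
             year_group = character(0), severity = character(0),
             case_offset_days = integer(0), role = character(0),
             case_person_id = character(0), index_date = as.IDate(integer(0)),
             set_id = integer(0))
}

#' Restrict matched sets to complete follow-up
#'
#' Removes any matched member (case or control) who dies, emigrates, or has
#' an exclusion-list diagnosis dated on or before `index_date + 365`. A set
#' losing its case is dissolved entirely; a set losing all its controls is
#' dissolved as well. Every removal reason is logged.
#'
#' @param sets `matched` table from [match_cohort()].
#' @param persons the persons table.
#' @param diagnoses the diagnosis table.
#' @param config a [default_code_config()].
#' @return list with `matched` (surviving rows) and `attrition`
#'   (data.table: `stage`, `remaining`, `removed`).
#' @export
condition_followup <- function(sets, persons, diagnoses,
                               config = default_code_config()) {
  m <- copy(as.data.table(sets))
  if (nrow(m) == 0L) {
    return(list(matched = m, attrition = data.table(
      stage = character(0), remaining = integer(0), removed = integer(0))))
  }
  p <- as.data.table(persons)[, .(person_id, death_date, emigration_date)]
  m <- p[m, on = "person_id"]
  fu_end <- m$index_date + 365L
  died <- !is.na(m$death_date) & m$death_date <= fu_end
  emig <- !is.na(m$emigration_date) & m$emigration_date <= fu_end

  dx <- as.data.table(diagnoses)
  dx <- dx[is_exclusion_code(icd_code, config), .(person_id, date)]
  excl <- rep(FALSE, nrow(m))
  if (nrow(dx)) {
    key <- m[, .(person_id, index_date)]
    key[, rk := .I]
    hit <- dx[key, on = "person_id", nomatch = 0L, allow.cartesian = TRUE]
    hit <- hit[date <= index_date + 365L]
    excl[unique(hit$rk)] <- TRUE
  }

  removed <- died | emig | excl
  log <- data.table(
    stage = c("member died within follow-up year",
              "member emigrated within follow-up year",
              "member developed exclusion diagnosis within follow-up year"),
    remaining = NA_integer_,
    removed = c(sum(died), sum(emig & !died), sum(excl & !died & !emig))
  )
  keep <- m[!removed]
  ok_sets <- keep[, .(has_case = any(role == "case"),
                      n_controls = sum(role == "control")), by = set_id]
  ok_ids <- ok_sets[has_case & n_controls >= 1L, set_id]
  dissolved <- setdiff(unique(keep$set_id), ok_ids)
  out <- keep[set_id %in% ok_ids]
  log <- rbind(log, data.table(
    stage = c("sets dissolved (case lost or all controls lost)",
              "matched population with complete follow-up"),
    remaining = c(NA_integer_, nrow(out)),
    removed = c(length(dissolved), NA_integer_)
  ))
  out[, `:=`(death_date = NULL, emigration_date = NULL)]
  setcolorder(out, names(empty_matched()))
  list(matched = out[], attrition = log)
}

utils::globalVariables(c("has_case"))
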