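# First-time MDD cohort construction: earliest MDD hospital contact,
# severity from the first contact's diagnosis code, diagnosis-based
# exclusions, age restriction, prevalent-TRD removal, and stratum attributes.

SEVERITY_LEVELS <- c("mild", "moderate", "severe")

#' Classify depression severity from an ICD-10 code
#'
#' Maps a diagnosis code to mild / moderate / severe depression according
#' to the configured severity partition of the MDD code list. Matching is
#' prefix-based after dot-stripping, so `"F322"` and `"F32.2"` are
#' equivalent.
#'
#' @param icd_code character vector of ICD-10 codes.
#' @param config a [default_code_config()].
#' @return character vector over `{"mild", "moderate", "severe"}`.
#' @export
#' @examples
#' classify_severity(c("F32.2", "F33.1", "F33.4"))
classify_severity <- function(icd_code, config = default_code_config()) {
  out <- rep(NA_character_, length(icd_code))
  for (cls in names(config$severity_map)) {
    out[icd_matches(icd_code, config$severity_map[[cls]])] <- cls
  }
  if (anyNA(out)) {
    stop(sprintf("icd_code '%s' is not in the configured severity map",
                 icd_code[which(is.na(out))[1]]))
  }
  out
}

#' Earliest MDD hospital contact per person
#'
#' Returns at most one row per person: the earliest MDD-coded diagnosis
#' event. Same-day ties are broken by severity rank (severe > moderate >
#' mild), then lexicographically by code, so the entry severity is
#' deterministic.
#'
#' @param diagnoses diagnosis table (`person_id`, `date`, `icd_code`,
#'   `setting`).
#' @param config a [default_code_config()].
#' @return data.table: `person_id`, `mdd_date`, `icd_code`, `severity`.
#' @export
first_mdd_contact <- function(diagnoses, config = default_code_config()) {
  d <- as.data.table(diagnoses)
  d <- d[is_mdd_code(icd_code, config)]
  if (nrow(d) == 0L) {
    return(data.table(person_id = character(0), mdd_date = as.IDate(integer(0)),
                      icd_code = character(0), severity = character(0)))
  }
  d[, severity := classify_severity(icd_code, config)]
  d[, sev_rank := match(severity, rev(SEVERITY_LEVELS))]  # severe first
  setorder(d, person_id, date, sev_rank, icd_code)
  first <- d[d[, .I[1], by = person_id]$V1]
  first[, .(person_id, mdd_date = date, icd_code, severity)]
}

# completed years between two dates
age_completed_years <- function(birth, ref) {
  by <- as.integer(format(as.Date(birth), "%Y"))
  ry <- as.integer(format(as.Date(ref), "%Y"))
  bmd <- format(as.Date(birth), "%m%d")
  rmd <- format(as.Date(ref), "%m%d")
  ry - by - as.integer(rmd < bmd)
}

assign_group <- function(x, breaks, labels) {
  idx <- findInterval(x, breaks)
  idx[idx < 1L] <- NA_integer_
  labels[idx]
}

#' Attach stratification attributes to cohort entries
#'
#' Adds age at diagnosis (completed years), the configured age group and
#' diagnosis-year group, plus sex, education and cohabitation status from
#' the persons table.
#'
#' @param entries data.table with `person_id` and `mdd_date`.
#' @param persons the persons table.
#' @param config a [default_code_config()].
#' @return `entries` with `age_at_dx`, `age_group`, `sex`, `year_group`,
#'   `education`, `cohabiting` columns added.
#' @export
attach_strata <- function(entries, persons, config = default_code_config()) {
  e <- as.data.table(entries)
  p <- as.data.table(persons)[, .(person_id, sex, birth_date, education, cohabiting)]
  e <- p[e, on = "person_id"]
  e[, age_at_dx := age_completed_years(birth_date, mdd_date)]
  e[, age_group := assign_group(age_at_dx, config$age_group_breaks,
                                config$age_group_labels)]
  e[, year_group := assign_group(as.integer(format(as.Date(mdd_date), "%Y")),
                                 config$year_group_breaks,
                                 config$year_group_labels)]
  e[, birth_date := NULL]
  e[]
}

#' Apply cohort in-/exclusion rules with an attrition log
#'
#' Starting from the first-contact candidates, removes in order: persons
#' whose first MDD contact falls outside the study period; persons younger
#' than 18 at diagnosis; persons with any exclusion-list diagnosis (bipolar,
#' other affective, persistent mood, schizophrenia-spectrum, dementia) dated
#' on or before the MDD date; and persons with prevalent treatment
#' resistance (second treatment shift on or before the MDD date). Each stage
#' is logged so entry count plus summed removals equals the candidate count.
#'
#' @param candidates output of [first_mdd_contact()] with strata attached
#'   (needs `age_at_dx`).
#' @param diagnoses full diagnosis table.
#' @param trd_statuses output of [classify_trd_cohort()] for the candidates
#'   (used for the prevalent-TRD stage).
#' @param config a [default_code_config()].
#' @return list with `cohort` (retained entries) and `attrition`
#'   (data.table: `stage`, `remaining`, `removed`).
#' @export
apply_exclusions <- function(candidates, diagnoses, trd_statuses,
                             config = default_code_config()) {
  cand <- as.data.table(candidates)
  d <- as.data.table(diagnoses)
  log <- data.table(stage = "first-time MDD contact",
                    remaining = nrow(cand), removed = 0L)
  add_stage <- function(log, stage, before, after) {
    rbind(log, data.table(stage = stage, remaining = after,
                          removed = before - after))
  }

  yr <- as.integer(format(as.Date(cand$mdd_date), "%Y"))
  keep <- yr >= config$study_years[1] & yr <= config$study_years[2]
  log <- add_stage(log, "first contact within study period", nrow(cand), sum(keep))
  cand <- cand[keep]

  keep <- cand$age_at_dx >= 18L
  log <- add_stage(log, "aged 18 or older at diagnosis", nrow(cand), sum(keep))
  cand <- cand[keep]

  ex <- d[is_exclusion_code(icd_code, config), .(person_id, date)]
  ex <- ex[cand[, .(person_id, mdd_date)], on = "person_id", nomatch = 0L]
  prior_ex <- unique(ex[date <= mdd_date, person_id])
  keep <- !(cand$person_id %in% prior_ex)
  log <- add_stage(log, "no prior exclusion diagnosis", nrow(cand), sum(keep))
  cand <- cand[keep]

  ts <- as.data.table(trd_statuses)
  prevalent <- ts[prevalent_trd == TRUE, person_id]
  keep <- !(cand$person_id %in% prevalent)
  log <- add_stage(log, "no prevalent TRD at diagnosis", nrow(cand), sum(keep))
  cand <- cand[keep]

  list(cohort = cand[], attrition = log)
}

#' Build the first-time MDD cohort from a registry bundle
#'
#' Runs [first_mdd_contact()], attaches strata, classifies treatment
#' resistance for every candidate (needed both for the prevalent-TRD
#' exclusion and for matching), applies the exclusion stages, and flags
#' anxiety and substance-abuse diagnoses in the five years before the MDD
#' date for baseline descriptives.
#'
#' @param bundle a `registry_bundle`.
#' @param config a [default_code_config()]; defaults to the bundle's.
#' @return list with `cohort` (one entry per retained person), `trd`
#'   (treatment-resistance status for retained persons) and `attrition`.
#' @export
build_cohort <- function(bundle, config = NULL) {
  config <- config %||% bundle$config
  cand <- first_mdd_contact(bundle$diagnoses, config)
  cand <- attach_strata(cand, bundle$persons, config)
  trd <- classify_trd_cohort(bundle, cand, config)
  res <- apply_exclusions(cand, bundle$diagnoses, trd, config)
  cohort <- res$cohort
  trd <- as.data.table(trd)[person_id %in% cohort$person_id]
  # 5-year pre-index comorbidity flags (descriptive only)
  d <- as.data.table(bundle$diagnoses)
  nc <- icd_normalize(d$icd_code)
  anx_ids <- flag_window(d[grepl("^F4[0-8]", nc)], cohort)
  sub_ids <- flag_window(d[grepl("^F1[0-9]", nc)], cohort)
  cohort[, anxiety := person_id %in% anx_ids]
  cohort[, substance_abuse := person_id %in% sub_ids]
  list(cohort = cohort[], trd = trd[], attrition = res$attrition)
}

flag_window <- function(dx, cohort, years = 5) {
  if (nrow(dx) == 0L) return(character(0))
  m <- dx[cohort[, .(person_id, mdd_date)], on = "person_id", nomatch = 0L]
  unique(m[date <= mdd_date & date >= mdd_date - round(years * 365.25), person_id])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

utils::globalVariables(c("anxiety", "substance_abuse"))
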