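# In-code fixtures: tiny registry tables and calibration configurations.

library(data.table)

persons_df <- function(ids, sex = "F", birth = "1960-01-01",
                       death = NA, emigration = NA,
                       education = "basic", cohabiting = "yes") {
  data.frame(person_id = ids, sex = sex, birth_date = as.Date(birth),
             death_date = as.Date(death), emigration_date = as.Date(emigration),
             education = education, cohabiting = cohabiting,
             stringsAsFactors = FALSE)
}

diagnoses_df <- function(ids = character(0), dates = as.Date(character(0)),
                         codes = character(0), setting = "psych_outpatient") {
  data.frame(person_id = ids, date = as.Date(dates), icd_code = codes,
             setting = if (length(ids)) setting else character(0),
             stringsAsFactors = FALSE)
}

prescriptions_df <- function(ids = character(0), dates = as.Date(character(0)),
                             atc = character(0), cost = 10) {
  data.frame(person_id = ids, redemption_date = as.Date(dates),
             atc_code = atc, cost_eur = if (length(ids)) cost else numeric(0),
             stringsAsFactors = FALSE)
}

procedures_df <- function(ids = character(0), dates = as.Date(character(0)),
                          sks = character(0)) {
  data.frame(person_id = ids, date = as.Date(dates),
             sks_code = if (length(ids)) sks else character(0),
             stringsAsFactors = FALSE)
}

contacts_df <- function(ids = character(0), start = as.Date(character(0)),
                        end = start, sector = character(0),
                        type = character(0), mode = "na", cost = 100) {
  data.frame(person_id = ids, start_date = as.Date(start),
             end_date = as.Date(end),
             sector = sector, contact_type = type,
             admission_mode = if (length(ids)) mode else character(0),
             cost_eur = if (length(ids)) cost else numeric(0),
             stringsAsFactors = FALSE)
}

# bundle with sensible empty defaults for unspecified tables
make_bundle <- function(persons, diagnoses = diagnoses_df(),
                        prescriptions = prescriptions_df(),
                        procedures = procedures_df(),
                        contacts = contacts_df(),
                        config = default_code_config()) {
  registry_bundle(persons, diagnoses, prescriptions, procedures, contacts,
                  config)
}

zero_rates <- local({
  nms <- c("psych_hospitalization", "psych_ed", "psych_outpatient",
           "psych_home_visit", "private_psychiatrist", "private_psychologist",
           "somatic_hospitalization", "somatic_ed", "somatic_outpatient",
           "gp", "other_specialist")
  stats::setNames(rep(0, length(nms)), nms)
})

# calibration-study configuration: deterministic TRD phenotype, one HRU
# category generated by any-use probabilities, no attrition hazards
calib_sim_config <- function(n_persons, seed, p_resistant = 1 / 3,
                             any_use = c(0.2, 0.4)) {
  sim_config(
    n_persons = n_persons, seed = seed, mode = "calibration",
    p_resistant = p_resistant,
    p_death = 0, p_emigrate = 0, p_exclusion_dx = 0,
    hru_base_rates = zero_rates,
    any_use_probs = list(psych_hospitalization = any_use)
  )
}

# one calibration replicate: simulate, run the pipeline, return the
# any-use effect estimate for psychiatric hospitalization
calib_replicate <- function(n_persons, seed, p_resistant = 1 / 3,
                            any_use = c(0.2, 0.4), null = FALSE,
                            scfg = NULL) {
  scfg <- scfg %||% calib_sim_config(n_persons, seed, p_resistant, any_use)
  sim <- if (null) simulate_null(scfg) else simulate_registry(scfg)
  res <- run_trd_pipeline(sim$bundle, seed = seed + 1L,
                          outcomes = "psych_hospitalization",
                          windows = "post")
  any_use_rr(res$summaries, "psych_hospitalization")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all multisets of size <= max_k over `items`, as a list of index vectors
multisets_upto <- function(n_items, max_k) {
  out <- list(integer(0))
  for (k in seq_len(max_k)) {
    cmb <- utils::combn(n_items + k - 1L, k)
    cmb <- cmb - (seq_len(k) - 1L)   # map combinations to multisets
    out <- c(out, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  out
}

# summaries stub: one outcome, post window, arbitrary covariates optional
stub_summaries <- function(n1, u1, n0, u0, values1 = NULL, values0 = NULL) {
  v1 <- if (is.null(values1)) c(rep(1, u1), rep(0, n1 - u1)) else values1
  v0 <- if (is.null(values0)) c(rep(1, u0), rep(0, n0 - u0)) else values0
  data.table::data.table(
    person_id = sprintf("s%05d", seq_len(length(v1) + length(v0))),
    outcome = "y", window = "post",
    group = c(rep("TRD", length(v1)), rep("nonTRD", length(v0))),
    value = c(v1, v0))
}

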