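# Synthetic registry generator. A single latent per-person resistance flag
# drives both antidepressant switching behaviour and HRU intensity, so the
# downstream phenotyping + two-part analysis can be tested against known
# ground truth. Calibration mode makes switching deterministic (resistant
# persons have exactly two treatment shifts inside the phenotyping window,
# non-resistant persons none), so algorithmic TRD status equals the latent
# flag exactly and effect sizes are recovered cleanly.

SIM_CATEGORIES <- c(
  "psych_hospitalization", "psych_ed", "psych_outpatient", "psych_home_visit",
  "private_psychiatrist", "private_psychologist",
  "somatic_hospitalization", "somatic_ed", "somatic_outpatient",
  "gp", "other_specialist"
)

sim_category_map <- data.frame(
  category = SIM_CATEGORIES,
  sector = c("psychiatric", "psychiatric", "psychiatric", "psychiatric",
             "primary", "primary",
             "somatic", "somatic", "somatic", "primary", "primary"),
  contact_type = c("hospitalization", "ed", "outpatient", "home_visit",
                   "private_psychiatrist", "private_psychologist",
                   "hospitalization", "ed", "outpatient", "gp",
                   "other_specialist"),
  stringsAsFactors = FALSE
)

ATC_POOL <- list(
  SSRI = c("N06AB03", "N06AB04", "N06AB06", "N06AB10"),
  SNRI = c("N06AX16", "N06AX21", "N06AX11"),
  TCA  = c("N06AA04", "N06AA09", "N06AA10"),
  MAOI = c("N06AF03", "N06AG02")
)

#' Simulation configuration for the synthetic registry
#'
#' All probabilities are per person unless stated otherwise; rates are
#' annual expected counts for non-resistant persons, multiplied by
#' `hru_multiplier` for resistant persons. `mode = "calibration"` replaces
#' stochastic prescription switching with a deterministic scheme: resistant
#' persons redeem three distinct antidepressant substances on days 0, 60 and
#' 120 after diagnosis (two treatment shifts; the second, on day 120, is the
#' TRD index), non-resistant persons redeem a single substance twice (no
#' shift). `any_use_probs` (named list, category -> c(p_control,
#' p_resistant)) replaces count generation for a category by a Bernoulli
#' any-use draw with one event placed inside the post-index year, which
#' gives the two-part model a known any-use relative risk to recover.
#'
#' @param n_persons number of simulated persons.
#' @param seed integer seed; each output table draws from its own derived
#'   substream so the bundle is reproducible table by table.
#' @param ... overrides for any documented field.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_persons = 1000L, seed = 1L, ...) {
  cfg <- list(
    n_persons = as.integer(n_persons),
    seed = as.integer(seed),
    mode = "realistic",
    sex_split = 0.62,
    age_distribution = c("18-24" = 0.12, "25-44" = 0.33, "45-64" = 0.26,
                         "65-84" = 0.23, "85+" = 0.06),
    severity_distribution = c(mild = 0.57, moderate = 0.31, severe = 0.12),
    education_distribution = c(basic = 0.38, medium = 0.39, high = 0.15,
                               unknown = 0.08),
    cohabiting_distribution = c(yes = 0.52, no = 0.47, unknown = 0.01),
    p_resistant = 0.15,
    switch_hazard = c(resistant = 0.35, non_resistant = 0.05),
    redemption_interval_days = 60,
    p_ect_severe = 0.10,
    hru_base_rates = c(
      psych_hospitalization = 0.1, psych_ed = 0.1, psych_outpatient = 4.7,
      psych_home_visit = 0.6, private_psychiatrist = 0.3,
      private_psychologist = 0.2, somatic_hospitalization = 0.5,
      somatic_ed = 0.4, somatic_outpatient = 3.2, gp = 7.7,
      other_specialist = 1.8
    ),
    hru_multiplier = c(
      psych_hospitalization = 2.4, psych_ed = 1.9, psych_outpatient = 2.0,
      psych_home_visit = 2.3, private_psychiatrist = 2.3,
      private_psychologist = 1.3, somatic_hospitalization = 1.0,
      somatic_ed = 1.0, somatic_outpatient = 1.0, gp = 1.2,
      other_specialist = 1.05
    ),
    nb_dispersion = 1.0,      # variance = dispersion * mean; 1 -> Poisson
    mean_stay_days = 7,
    p_acute = 0.8,
    cost_sigma = 0,           # lognormal noise sd on costs (log scale)
    any_use_probs = NULL,
    p_death = 0.02,
    p_emigrate = 0.005,
    p_exclusion_dx = 0.01,
    p_prior_exclusion_dx = 0.02,
    p_pretreated = 0.4,       # antidepressant course begun before diagnosis
    p_anxiety_5y = 0.30,
    p_substance_5y = 0.14,
    rx_cost_mean = c(antidepressant = 25, other_psychiatric = 15, other = 20)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown sim_config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  probs <- c(cfg$sex_split, cfg$p_resistant, cfg$p_ect_severe, cfg$p_death,
             cfg$p_emigrate, cfg$p_exclusion_dx, cfg$p_acute,
             unlist(cfg$any_use_probs))
  if (any(probs < 0 | probs > 1)) stop("sim_config: probabilities must be in [0, 1]")
  if (any(cfg$hru_multiplier <= 0)) stop("sim_config: hru_multiplier entries must be > 0")
  if (!cfg$mode %in% c("realistic", "calibration")) {
    stop("sim_config: mode must be 'realistic' or 'calibration'")
  }
  structure(cfg, class = "sim_config")
}

# one derived substream per output table; derived from the master seed only
derive_seeds <- function(seed, n = 8L) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

draw_count <- function(n, mu, dispersion) {
  if (dispersion <= 1) return(rpois(n, mu))
  size <- mu / (dispersion - 1)
  rnbinom(n, size = pmax(size, 1e-8), mu = mu)
}

# birth date such that the person is exactly `age` completed years old at
# `ref`, with the last birthday `r` days before `ref`
birth_from_age <- function(ref, age, r) {
  anniv <- as.Date(ref) - r
  y <- as.integer(format(anniv, "%Y")) - age
  m <- as.integer(format(anniv, "%m"))
  d <- as.integer(format(anniv, "%d"))
  leap <- (y %% 4 == 0 & y %% 100 != 0) | (y %% 400 == 0)
  d[m == 2L & d == 29L & !leap] <- 28L
  as.IDate(sprintf("%04d-%02d-%02d", y, m, d))
}

price_lookup <- function(config) {
  pt <- as.data.table(config$fixed_price_table)
  setkey(pt, sector, contact_type, admission_mode)
  pt
}

#' Simulate a synthetic registry bundle with ground truth
#'
#' Generates the five registry tables for `n_persons` first-time MDD
#' patients: one severity-coded first MDD hospital contact per person inside
#' the study period, antidepressant redemption sequences whose switching is
#' driven by the latent resistance flag, ECT procedures among resistant
#' severe patients, category-specific healthcare contacts with
#' resistance-dependent rates, medicine redemptions across the three cost
#' groups, and death / emigration / exclusion-diagnosis events injected
#' after diagnosis at the configured annual hazards. A fixed seed gives a
#' byte-identical bundle across runs.
#'
#' @param scfg a [sim_config()].
#' @param config a [default_code_config()] supplying ICD code lists and the
#'   fixed price table.
#' @return a list with elements `bundle` (a validated `registry_bundle`)
#'   and `ground_truth` (data.table: `person_id`, `resistant`, and the
#'   configured multiplier per HRU category as `mult_*` columns).
#' @export
simulate_registry <- function(scfg, config = default_code_config()) {
  stopifnot(inherits(scfg, "sim_config"))
  n <- scfg$n_persons
  seeds <- derive_seeds(scfg$seed)
  study_start <- as.IDate(sprintf("%d-01-01", config$study_years[1]))
  study_end   <- as.IDate(sprintf("%d-12-31", config$study_years[2]))

  ## ---- persons (substream 1) ----
  set.seed(seeds[1])
  person_id <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(runif(n) < scfg$sex_split, "F", "M")
  age_group <- sample(names(scfg$age_distribution), n, replace = TRUE,
                      prob = scfg$age_distribution)
  age_lo <- c("18-24" = 18L, "25-44" = 25L, "45-64" = 45L, "65-84" = 65L, "85+" = 85L)
  age_hi <- c("18-24" = 24L, "25-44" = 44L, "45-64" = 64L, "65-84" = 84L, "85+" = 94L)
  age <- age_lo[age_group] + floor(runif(n) * (age_hi[age_group] - age_lo[age_group] + 1L))
  severity <- sample(names(scfg$severity_distribution), n, replace = TRUE,
                     prob = scfg$severity_distribution)
  if (scfg$mode == "calibration") {
    k <- round(n * scfg$p_resistant)
    resistant <- rep(FALSE, n)
    resistant[sample.int(n, k)] <- TRUE
  } else {
    resistant <- runif(n) < scfg$p_resistant
  }
  mdd_date <- study_start + floor(runif(n) * (as.integer(study_end) - as.integer(study_start) + 1L))
  last_bday_offset <- floor(runif(n) * 365)
  birth_date <- birth_from_age(mdd_date, as.integer(age), last_bday_offset)
  education <- sample(names(scfg$education_distribution), n, replace = TRUE,
                      prob = scfg$education_distribution)
  cohabiting <- sample(names(scfg$cohabiting_distribution), n, replace = TRUE,
                       prob = scfg$cohabiting_distribution)
  two_year <- function(p) 1 - (1 - p)^2
  death_date <- rep(as.IDate(NA), n)
  dies <- runif(n) < two_year(scfg$p_death)
  death_date[dies] <- mdd_date[dies] + sample.int(730L, sum(dies), replace = TRUE)
  emigration_date <- rep(as.IDate(NA), n)
  emig <- !dies & runif(n) < two_year(scfg$p_emigrate)
  emigration_date[emig] <- mdd_date[emig] + sample.int(730L, sum(emig), replace = TRUE)
  persons <- data.table(person_id, sex, birth_date, death_date, emigration_date,
                        education, cohabiting)
  latent <- data.table(person_id, resistant, severity, mdd_date, age_group)

  ## ---- diagnoses (substream 2) ----
  set.seed(seeds[2])
  sev_code <- vapply(severity, function(s) {
    pool <- config$severity_map[[s]]
    pool[sample.int(length(pool), 1L)]
  }, character(1))
  mdd_setting <- ifelse(runif(n) < 0.3, "psych_inpatient", "psych_outpatient")
  diagnoses <- data.table(person_id = person_id, date = mdd_date,
                          icd_code = sev_code, setting = mdd_setting)
  excl <- runif(n) < two_year(scfg$p_exclusion_dx)
  if (any(excl)) {
    diagnoses <- rbind(diagnoses, data.table(
      person_id = person_id[excl],
      date = mdd_date[excl] + sample.int(730L, sum(excl), replace = TRUE),
      icd_code = sample(c("F31.0", "F20.9", "F34.1"), sum(excl), replace = TRUE),
      setting = "psych_outpatient"
    ))
  }
  prior_excl <- runif(n) < scfg$p_prior_exclusion_dx
  if (any(prior_excl) && scfg$mode != "calibration") {
    diagnoses <- rbind(diagnoses, data.table(
      person_id = person_id[prior_excl],
      date = mdd_date[prior_excl] -
        (30L + sample.int(1795L, sum(prior_excl), replace = TRUE)),
      icd_code = sample(c("F31.9", "F25.1", "F34.0"), sum(prior_excl),
                        replace = TRUE),
      setting = "psych_outpatient"
    ))
  }
  anx <- runif(n) < scfg$p_anxiety_5y
  if (any(anx)) {
    diagnoses <- rbind(diagnoses, data.table(
      person_id = person_id[anx],
      date = mdd_date[anx] - (30L + sample.int(1795L, sum(anx), replace = TRUE)),
      icd_code = "F41.9", setting = "psych_outpatient"
    ))
  }
  sub <- runif(n) < scfg$p_substance_5y
  if (any(sub)) {
    diagnoses <- rbind(diagnoses, data.table(
      person_id = person_id[sub],
      date = mdd_date[sub] - (30L + sample.int(1795L, sum(sub), replace = TRUE)),
      icd_code = "F10.9", setting = "somatic_outpatient"
    ))
  }

  ## ---- prescriptions (substream 3) ----
  set.seed(seeds[3])
  all_subs <- unlist(ATC_POOL, use.names = FALSE)
  ad_cost <- scfg$rx_cost_mean[["antidepressant"]]
  if (scfg$mode == "calibration") {
    pick3 <- replicate(n, all_subs[sample.int(length(all_subs), 3L)])
    res_idx <- which(resistant)
    non_idx <- which(!resistant)
    rx <- rbind(
      data.table(person_id = rep(person_id[res_idx], each = 4L),
                 redemption_date = rep(mdd_date[res_idx], each = 4L) +
                   rep(c(0L, 30L, 60L, 120L), length(res_idx)),
                 atc_code = as.vector(rbind(pick3[1, res_idx], pick3[1, res_idx],
                                            pick3[2, res_idx], pick3[3, res_idx]))),
      data.table(person_id = rep(person_id[non_idx], each = 2L),
                 redemption_date = rep(mdd_date[non_idx], each = 2L) +
                   rep(c(0L, 60L), length(non_idx)),
                 atc_code = rep(pick3[1, non_idx], each = 2L))
    )
    rx[, cost_eur := ad_cost]
  } else {
    # a fraction of patients begin antidepressant treatment (usually in
    # primary care) before the depression-defining hospital contact, so the
    # pre-diagnosis half of the phenotyping window is populated and
    # prevalent TRD occurs
    start_off <- as.integer(ifelse(runif(n) < scfg$p_pretreated,
                                   -(sample.int(181L, n, replace = TRUE) - 1L),
                                   sample.int(31L, n, replace = TRUE) - 1L))
    n_redeem <- 1L + rpois(n, (365 - start_off) / scfg$redemption_interval_days)
    rx <- data.table(person_id = rep(person_id, n_redeem),
                     mdd = rep(mdd_date, n_redeem),
                     day0 = rep(mdd_date + start_off, n_redeem),
                     res = rep(resistant, n_redeem))
    rx[, gap := pmax(7L, rpois(.N, scfg$redemption_interval_days))]
    rx[, redemption_date := day0 + cumsum(c(0L, gap[-1])), by = person_id]
    rx <- rx[redemption_date <= mdd + 365L]
    hz <- ifelse(rx$res, scfg$switch_hazard[["resistant"]],
                 scfg$switch_hazard[["non_resistant"]])
    switch_draw <- runif(nrow(rx)) < hz
    rx[, rk := seq_len(.N), by = person_id]
    switch_draw[rx$rk == 1L] <- FALSE
    rx[, substance := {
      idx <- pmin(1L + cumsum(switch_draw[.I]), length(all_subs))
      perm <- all_subs[sample.int(length(all_subs))]
      perm[idx]
    }, by = person_id]
    rx <- rx[, .(person_id, redemption_date, atc_code = substance)]
    rx[, cost_eur := ad_cost]
    # non-antidepressant medicine for the cost groups
    n_op <- rpois(n, 0.5)
    n_ot <- rpois(n, 2.0)
    extra <- rbind(
      data.table(person_id = rep(person_id, n_op),
                 redemption_date = rep(mdd_date, n_op) +
                   sample(-365:730, sum(n_op), replace = TRUE),
                 atc_code = sample(c("N05BA01", "N05AH04", "N05AN01"),
                                   sum(n_op), replace = TRUE),
                 cost_eur = scfg$rx_cost_mean[["other_psychiatric"]]),
      data.table(person_id = rep(person_id, n_ot),
                 redemption_date = rep(mdd_date, n_ot) +
                   sample(-365:730, sum(n_ot), replace = TRUE),
                 atc_code = sample(c("A02BC01", "C07AB02", "M01AE01"),
                                   sum(n_ot), replace = TRUE),
                 cost_eur = scfg$rx_cost_mean[["other"]])
    )
    rx <- rbind(rx, extra)
  }
  if (scfg$cost_sigma > 0) {
    rx[, cost_eur := cost_eur *
         exp(rnorm(.N, -scfg$cost_sigma^2 / 2, scfg$cost_sigma))]
  }
  setorder(rx, person_id, redemption_date, atc_code)

  ## ---- procedures (substream 4) ----
  set.seed(seeds[4])
  procedures <- data.table(person_id = character(0), date = as.IDate(integer(0)),
                           sks_code = character(0))
  if (scfg$mode != "calibration") {
    ect <- resistant & severity == "severe" & runif(n) < scfg$p_ect_severe
    if (any(ect)) {
      procedures <- data.table(
        person_id = person_id[ect],
        date = mdd_date[ect] + (30L + sample.int(270L, sum(ect), replace = TRUE)),
        sks_code = sample(config$ect_codes, sum(ect), replace = TRUE)
      )
    }
  }

  ## ---- contacts (substream 5) ----
  set.seed(seeds[5])
  prices <- price_lookup(config)
  contact_list <- vector("list", length(SIM_CATEGORIES))
  for (ci in seq_along(SIM_CATEGORIES)) {
    cat_nm <- SIM_CATEGORIES[ci]
    meta <- sim_category_map[sim_category_map$category == cat_nm, ]
    aup <- scfg$any_use_probs[[cat_nm]]
    if (!is.null(aup)) {
      p <- ifelse(resistant, aup[2], aup[1])
      use <- runif(n) < p
      k <- sum(use)
      if (k == 0L) next
      ev <- data.table(person_id = person_id[use],
                       start = mdd_date[use] +
                         (150L + sample.int(300L, k, replace = TRUE) - 1L))
    } else {
      mu <- scfg$hru_base_rates[[cat_nm]] *
        ifelse(resistant, scfg$hru_multiplier[[cat_nm]], 1)
      cnt <- draw_count(n, 3 * mu, scfg$nb_dispersion)  # 3-year horizon
      if (sum(cnt) == 0L) next
      ev <- data.table(person_id = rep(person_id, cnt),
                       start = rep(mdd_date, cnt) +
                         sample(-365:730, sum(cnt), replace = TRUE))
    }
    ev[, sector := meta$sector]
    ev[, contact_type := meta$contact_type]
    if (meta$contact_type == "hospitalization") {
      ev[, admission_mode := ifelse(runif(.N) < scfg$p_acute, "acute", "elective")]
      ev[, nights := rgeom(.N, 1 / scfg$mean_stay_days)]
      ev[, end_date := start + nights]
    } else {
      ev[, admission_mode := "na"]
      ev[, nights := 0L]
      ev[, end_date := start]
    }
    ev <- prices[ev, on = c("sector", "contact_type", "admission_mode")]
    ev[, cost_eur := ifelse(contact_type == "hospitalization",
                            price_eur * pmax(nights, 1L), price_eur)]
    contact_list[[ci]] <- ev[, .(person_id, start_date = start, end_date,
                                 sector, contact_type, admission_mode, cost_eur)]
  }
  contacts <- rbindlist(contact_list)
  if (nrow(contacts) == 0L) {
    contacts <- data.table(person_id = character(0),
                           start_date = as.IDate(integer(0)),
                           end_date = as.IDate(integer(0)),
                           sector = character(0), contact_type = character(0),
                           admission_mode = character(0), cost_eur = numeric(0))
  } else if (scfg$cost_sigma > 0) {
    contacts[, cost_eur := cost_eur *
               exp(rnorm(.N, -scfg$cost_sigma^2 / 2, scfg$cost_sigma))]
  }
  setorder(contacts, person_id, start_date, contact_type)

  bundle <- registry_bundle(persons, diagnoses, rx, procedures, contacts, config)
  gt <- data.table(person_id = person_id, resistant = resistant)
  for (cat_nm in SIM_CATEGORIES) {
    set(gt, j = paste0("mult_", cat_nm), value = scfg$hru_multiplier[[cat_nm]])
  }
  list(bundle = bundle, ground_truth = gt)
}

#' Simulate a registry under the null of no resistance effect on HRU
#'
#' Forces every HRU multiplier to 1.0 and equalizes any-use probabilities
#' across arms, so latent resistance affects prescription sequences (and
#' hence TRD classification) but not healthcare utilization. Used for
#' type-I-error calibration of the two-part model.
#'
#' @inheritParams simulate_registry
#' @return as [simulate_registry()]; the echoed multipliers are all 1.
#' @export
simulate_null <- function(scfg, config = default_code_config()) {
  stopifnot(inherits(scfg, "sim_config"))
  scfg$hru_multiplier[] <- 1.0
  if (!is.null(scfg$any_use_probs)) {
    scfg$any_use_probs <- lapply(scfg$any_use_probs, function(p) c(p[1], p[1]))
  }
  simulate_registry(scfg, config)
}

#' Write a simulated registry to disk
#'
#' Convenience wrapper: simulates and writes the five CSV tables plus
#' `ground_truth.csv` into a directory.
#'
#' @inheritParams simulate_registry
#' @param directory output directory.
#' @param null simulate under [simulate_null()] instead.
#' @return the directory, invisibly.
#' @export
simulate_to_dir <- function(scfg, directory, config = default_code_config(),
                            null = FALSE) {
  sim <- if (null) simulate_null(scfg, config) else simulate_registry(scfg, config)
  write_registry(sim$bundle, directory)
  fwrite(sim$ground_truth, file.path(directory, "ground_truth.csv"))
  invisible(directory)
}
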