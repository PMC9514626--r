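# Two-part model for semicontinuous HRU/cost outcomes.
#
# Part 1 ("any use"): modified Poisson regression — log-link Poisson GLM on
# the binary any-use indicator with heteroscedasticity-robust (sandwich)
# variance — whose exponentiated group coefficient is the relative risk of
# any utilization; reported as (RR - 1) x 100.
#
# Part 2 ("amount among users"): linear model of the natural-log outcome
# among users only, adjusted for the matching variables; the exponentiated
# group coefficient is the geometric-mean ratio, reported as
# (GMR - 1) x 100.

GROUP_LEVELS <- c("nonTRD", "TRD")
MATCH_COVARS <- c("age_group", "sex", "year_group", "severity")

effect_row <- function(outcome, part, pct = NA_real_, lo = NA_real_,
                       hi = NA_real_, p = NA_real_, n_cases = 0L,
                       n_controls = 0L, n_users = 0L, flagged = FALSE,
                       method = NA_character_) {
  data.table(outcome = outcome, part = part, pct_change = pct, ci_low = lo,
             ci_high = hi, p_value = p, n_cases = n_cases,
             n_controls = n_controls, n_users = n_users, flagged = flagged,
             method = method)
}

outcome_frame <- function(summaries, outcome_name, win = "post") {
  s <- as.data.table(summaries)
  s <- s[s$outcome == outcome_name]
  if ("window" %in% names(s)) s <- s[s$window == win]
  s <- copy(s)
  s[, group := factor(group, levels = GROUP_LEVELS)]
  s
}

# covariates that actually vary; constant factors are dropped from the design
varying_covars <- function(d, covars) {
  covars[vapply(covars, function(v) length(unique(d[[v]])) > 1L, logical(1))]
}

#' Relative risk of any utilization (modified Poisson part)
#'
#' Fits a log-link Poisson regression of the binary any-use indicator on
#' group (plus the four matching covariates when `adjusted = TRUE`), with
#' HC0 sandwich variance (cluster-robust on matched sets when
#' `config$cluster_by_set = TRUE`). The group coefficient, back-transformed,
#' is the relative risk; results are reported as the percent increase in
#' risk, `(RR - 1) x 100`, with a Wald 95% CI formed on the log scale. If
#' either arm has zero users the estimate is undefined and a flagged row is
#' returned; if the GLM fails to converge, the unadjusted fit falls back to
#' the crude risk ratio with its closed-form robust standard error.
#'
#' @param summaries long summaries from [compute_hru_summaries()] (post
#'   window is analysed).
#' @param outcome outcome name.
#' @param adjusted include the matching covariates in the design.
#' @param config a [default_code_config()].
#' @return one-row data.table (`outcome`, `part`, `pct_change`, `ci_low`,
#'   `ci_high`, `p_value`, `n_cases`, `n_controls`, `n_users`, `flagged`,
#'   `method`).
#' @export
any_use_rr <- function(summaries, outcome, adjusted = NULL,
                       config = default_code_config()) {
  adjusted <- adjusted %||% isTRUE(config$adjust_part1)
  d <- outcome_frame(summaries, outcome)
  d[, any_use := as.integer(value > 0)]
  n1 <- sum(d$group == "TRD"); n0 <- sum(d$group == "nonTRD")
  u1 <- sum(d$any_use[d$group == "TRD"]); u0 <- sum(d$any_use[d$group == "nonTRD"])
  if (n1 == 0L || n0 == 0L || u1 == 0L || u0 == 0L) {
    return(effect_row(outcome, "any_use", n_cases = n1, n_controls = n0,
                      n_users = u1 + u0, flagged = TRUE, method = "undefined"))
  }
  covars <- if (adjusted) varying_covars(d, MATCH_COVARS) else character(0)
  fml <- as.formula(paste("any_use ~ group",
                          if (length(covars)) paste("+", paste(covars, collapse = " + ")) else ""))
  fit <- tryCatch(
    glm(fml, data = d, family = poisson(link = "log"),
        control = glm.control(epsilon = 1e-12, maxit = 100)),
    error = function(e) NULL, warning = function(w) {
      suppressWarnings(glm(fml, data = d, family = poisson(link = "log"),
                           control = glm.control(epsilon = 1e-12, maxit = 100)))
    })
  if (!is.null(fit) && fit$converged) {
    vc <- if (isTRUE(config$cluster_by_set) && "set_id" %in% names(d)) {
      sandwich::vcovCL(fit, cluster = d$set_id, type = "HC0")
    } else {
      sandwich::vcovHC(fit, type = "HC0")
    }
    b <- coef(fit)[["groupTRD"]]
    se <- sqrt(vc["groupTRD", "groupTRD"])
    method <- if (adjusted) "poisson_robust_adjusted" else "poisson_robust"
  } else {
    # crude risk ratio with closed-form robust SE for log(RR)
    p1 <- u1 / n1; p0 <- u0 / n0
    b <- log(p1 / p0)
    se <- sqrt((1 - p1) / (n1 * p1) + (1 - p0) / (n0 * p0))
    method <- "crude_rr_fallback"
    message("any_use_rr: GLM did not converge for '", outcome,
            "'; crude risk ratio with closed-form robust SE reported")
  }
  z <- b / se
  effect_row(outcome, "any_use",
             pct = (exp(b) - 1) * 100,
             lo = (exp(b - qnorm(0.975) * se) - 1) * 100,
             hi = (exp(b + qnorm(0.975) * se) - 1) * 100,
             p = 2 * pnorm(-abs(z)),
             n_cases = n1, n_controls = n0, n_users = u1 + u0,
             method = method)
}

#' Percent change in the amount among users (positive part)
#'
#' Restricts to users (outcome value > 0), fits a linear model of the
#' natural-log outcome on group plus the matching covariates (categorical;
#' covariates without variation among the users are dropped), and reports
#' the back-transformed group effect as percent change, `(GMR - 1) x 100`,
#' with a normal-theory 95% CI. With a group-only design this equals the
#' geometric-mean ratio exactly. Fewer than two users in an arm yields a
#' flagged row.
#'
#' @inheritParams any_use_rr
#' @return one-row data.table as [any_use_rr()].
#' @export
amount_among_users <- function(summaries, outcome,
                               config = default_code_config()) {
  d <- outcome_frame(summaries, outcome)
  d <- d[value > 0]
  n1 <- sum(d$group == "TRD"); n0 <- sum(d$group == "nonTRD")
  if (n1 < 2L || n0 < 2L) {
    return(effect_row(outcome, "amount", n_cases = n1, n_controls = n0,
                      n_users = n1 + n0, flagged = TRUE, method = "undefined"))
  }
  covars <- varying_covars(d, intersect(MATCH_COVARS, names(d)))
  fml <- as.formula(paste("log(value) ~ group",
                          if (length(covars)) paste("+", paste(covars, collapse = " + ")) else ""))
  fit <- lm(fml, data = d)
  b <- coef(fit)[["groupTRD"]]
  ci <- confint(fit, "groupTRD", level = 0.95)
  p <- summary(fit)$coefficients["groupTRD", "Pr(>|t|)"]
  effect_row(outcome, "amount",
             pct = (exp(b) - 1) * 100,
             lo = (exp(ci[1]) - 1) * 100,
             hi = (exp(ci[2]) - 1) * 100,
             p = p, n_cases = n1, n_controls = n0, n_users = n1 + n0,
             method = if (length(covars)) "log_lm_adjusted" else "log_lm")
}

#' Full two-part outcome grid
#'
#' For every HRU count outcome and every cost category: descriptive mean
#' (sd) per group in the post-index year plus both two-part effect
#' estimates, emitted as tidy tables mirroring the usual HRU and cost
#' presentations.
#'
#' @param summaries long summaries from [compute_hru_summaries()].
#' @param config a [default_code_config()].
#' @return list with `hru` (count outcomes) and `costs` (cost outcomes);
#'   each a data.table with one row per outcome.
#' @export
run_outcome_grid <- function(summaries, config = default_code_config()) {
  desc <- summarize_by_group(as.data.table(summaries)[window == "post"])
  grid_for <- function(outcomes) {
    rows <- lapply(outcomes, function(o) {
      d1 <- desc[outcome == o & group == "TRD"]
      d0 <- desc[outcome == o & group == "nonTRD"]
      a <- any_use_rr(summaries, o, config = config)
      m <- amount_among_users(summaries, o, config = config)
      data.table(
        outcome = o,
        mean_trd = if (nrow(d1)) d1$mean else NA_real_,
        sd_trd = if (nrow(d1)) d1$sd else NA_real_,
        mean_nontrd = if (nrow(d0)) d0$mean else NA_real_,
        sd_nontrd = if (nrow(d0)) d0$sd else NA_real_,
        risk_pct_change = a$pct_change, risk_ci_low = a$ci_low,
        risk_ci_high = a$ci_high, risk_p = a$p_value,
        amount_pct_change = m$pct_change, amount_ci_low = m$ci_low,
        amount_ci_high = m$ci_high, amount_p = m$p_value,
        n_users = a$n_users, flagged = a$flagged | m$flagged
      )
    })
    rbindlist(rows)
  }
  list(hru = grid_for(hru_count_outcomes()),
       costs = grid_for(hru_cost_outcomes()))
}

#' Stratified any-use fractions and relative risks
#'
#' Per-stratum fraction of users by group and the unadjusted relative risk
#' (TRD vs non-TRD) with a 95% CI on the log scale, the per-stratum
#' analogue of the severity and quinquennial subgroup displays. Empty
#' strata (either arm absent) are omitted.
#'
#' @param summaries long summaries from [compute_hru_summaries()].
#' @param outcome outcome name.
#' @param by `"severity"` or `"year_group"`.
#' @param config a [default_code_config()].
#' @return data.table: stratum, user fractions per group, `rr`, `ci_low`,
#'   `ci_high`, arm sizes.
#' @export
stratified_risk <- function(summaries, outcome, by = c("severity", "year_group"),
                            config = default_code_config()) {
  by <- match.arg(by)
  d <- outcome_frame(summaries, outcome)
  d[, any_use := as.integer(value > 0)]
  rows <- lapply(split(d, d[[by]]), function(s) {
    n1 <- sum(s$group == "TRD"); n0 <- sum(s$group == "nonTRD")
    if (n1 == 0L || n0 == 0L) return(NULL)
    u1 <- sum(s$any_use[s$group == "TRD"]); u0 <- sum(s$any_use[s$group == "nonTRD"])
    p1 <- u1 / n1; p0 <- u0 / n0
    if (u1 == 0L || u0 == 0L) {
      return(data.table(stratum = s[[by]][1], frac_trd = p1, frac_nontrd = p0,
                        rr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        n_cases = n1, n_controls = n0))
    }
    se <- sqrt((1 - p1) / (n1 * p1) + (1 - p0) / (n0 * p0))
    data.table(stratum = s[[by]][1], frac_trd = p1, frac_nontrd = p0,
               rr = p1 / p0,
               ci_low = exp(log(p1 / p0) - qnorm(0.975) * se),
               ci_high = exp(log(p1 / p0) + qnorm(0.975) * se),
               n_cases = n1, n_controls = n0)
  })
  out <- rbindlist(Filter(Negate(is.null), rows))
  setattr(out, "stratum_variable", by)
  out[]
}

#' Baseline characteristics table with Chi-squared tests
#'
#' Counts and percentages per category per group, for the full cohort
#' (pre-matching TRD vs non-TRD) and the matched population, with a Pearson
#' Chi-squared p-value (no continuity correction) per variable in the
#' matched population. Variables with any expected cell below 5 carry a
#' small-sample warning flag.
#'
#' @param cohort cohort entries with `person_id` and descriptive columns.
#' @param trd TRD statuses for the cohort.
#' @param matched matched table from [condition_followup()].
#' @param variables character vector of cohort columns to tabulate.
#' @return list with `table` (long data.table: variable, category,
#'   population, group, n, pct) and `tests` (variable, chisq, df, p_value,
#'   small_sample).
#' @export
baseline_table <- function(cohort, trd, matched,
                           variables = c("sex", "age_group", "education",
                                         "cohabiting", "year_group",
                                         "severity", "anxiety",
                                         "substance_abuse")) {
  co <- as.data.table(cohort)
  ts <- as.data.table(trd)[, .(person_id, is_trd)]
  co <- ts[co, on = "person_id"]
  co[, group := ifelse(is_trd, "TRD", "nonTRD")]
  m <- as.data.table(matched)[, .(person_id, group = ifelse(role == "case", "TRD", "nonTRD"))]
  mm <- co[, -c("group")][m, on = "person_id"]
  variables <- intersect(variables, names(co))

  tab_rows <- list(); test_rows <- list()
  for (v in variables) {
    for (popn in c("cohort", "matched")) {
      d <- if (popn == "cohort") co else mm
      tt <- d[, .(n = .N), by = c("group", v)]
      setnames(tt, v, "category")
      tt[, pct := round(100 * n / sum(n), 1), by = group]
      tt[, `:=`(variable = v, population = popn)]
      tab_rows[[length(tab_rows) + 1L]] <- tt
    }
    xt <- table(mm$group, as.character(mm[[v]]))
    if (nrow(xt) == 2L && ncol(xt) >= 2L) {
      ht <- suppressWarnings(chisq.test(xt, correct = FALSE))
      test_rows[[length(test_rows) + 1L]] <- data.table(
        variable = v, chisq = unname(ht$statistic), df = unname(ht$parameter),
        p_value = ht$p.value, small_sample = any(ht$expected < 5))
    }
  }
  tab <- rbindlist(tab_rows, use.names = TRUE)
  setcolorder(tab, c("variable", "category", "population", "group", "n", "pct"))
  list(table = tab[], tests = rbindlist(test_rows))
}

#' Percentage of a count within its column total
#'
#' The percent convention of the baseline table: `count / total x 100`,
#' rounded to one decimal.
#'
#' @param n count(s).
#' @param total column total.
#' @return numeric vector of percentages.
#' @export
percent_of <- function(n, total) round(100 * n / total, 1)

utils::globalVariables(c("pct", "part", "i.value"))
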