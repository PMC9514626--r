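test_that("the unadjusted any-use part equals the crude risk ratio exactly", {
  s <- stub_summaries(100, 30, 100, 15)
  est <- any_use_rr(s, "y")
  expect_equal(est$pct_change, 100.0, tolerance = 1e-10)
  crude <- (30 / 100) / (15 / 100)
  expect_equal(est$pct_change / 100 + 1, crude, tolerance = 1e-10)
  expect_identical(est$method, "poisson_robust")
  # equal arms: identically zero percent change
  expect_equal(any_use_rr(stub_summaries(100, 20, 100, 20), "y")$pct_change,
               0.0, tolerance = 1e-10)
})

test_that("the sandwich SE matches the closed form for the saturated design", {
  s <- stub_summaries(100, 30, 100, 15)
  est <- any_use_rr(s, "y")
  p1 <- 0.30; p0 <- 0.15
  se <- sqrt((1 - p1) / (100 * p1) + (1 - p0) / (100 * p0))
  # recover the SE from the reported Wald CI on the log scale
  se_hat <- (log(est$ci_high / 100 + 1) - log(est$ci_low / 100 + 1)) /
    (2 * qnorm(0.975))
  expect_equal(se_hat, se, tolerance = 1e-7)
})

test_that("zero users in an arm gives a flagged result, not a crash", {
  est <- any_use_rr(stub_summaries(50, 10, 50, 0), "y")
  expect_true(est$flagged)
  expect_true(is.na(est$pct_change))
})

test_that("the users-only part equals the geometric-mean ratio exactly", {
  s <- stub_summaries(2, 2, 2, 2, values1 = c(2, 8), values0 = c(1, 4))
  est <- amount_among_users(s, "y")
  expect_equal(est$pct_change, 100.0, tolerance = 1e-10)  # GM 4 vs 2
  # identical outcome vectors: zero change
  s2 <- stub_summaries(3, 3, 3, 3, values1 = c(2, 5, 9), values0 = c(2, 5, 9))
  expect_equal(amount_among_users(s2, "y")$pct_change, 0.0, tolerance = 1e-10)
  # fewer than two users in an arm is flagged
  s3 <- stub_summaries(5, 1, 5, 3)
  expect_true(amount_among_users(s3, "y")$flagged)
})

test_that("the users-only part recovers a known lognormal ratio", {
  set.seed(101)
  n <- 5000
  s <- stub_summaries(n, n, n, n,
                      values1 = exp(rnorm(n, log(150) + log(1.5), 0.8)),
                      values0 = exp(rnorm(n, log(150), 0.8)))
  est <- amount_among_users(s, "y")
  se_pct <- (est$ci_high - est$ci_low) / (2 * qnorm(0.975))
  expect_lt(abs(est$pct_change - 50), 3 * se_pct)
})

test_that("effect estimates are invariant to row permutation", {
  set.seed(3)
  s <- stub_summaries(200, 60, 400, 80)
  perm <- s[sample(nrow(s))]
  expect_equal(any_use_rr(perm, "y")$pct_change,
               any_use_rr(s, "y")$pct_change, tolerance = 1e-12)
  s2 <- stub_summaries(50, 50, 50, 50,
                       values1 = runif(50, 1, 9), values0 = runif(50, 1, 9))
  perm2 <- s2[sample(nrow(s2))]
  expect_equal(amount_among_users(perm2, "y")$pct_change,
               amount_among_users(s2, "y")$pct_change, tolerance = 1e-12)
})

test_that("adjusted fits keep the group effect when covariates are balanced", {
  set.seed(11)
  s <- stub_summaries(400, 120, 800, 120)
  s[, `:=`(age_group = rep(c("25-44", "45-64"), length.out = .N),
           sex = rep(c("F", "M"), length.out = .N),
           year_group = "2001-2005", severity = "mild")]
  est <- any_use_rr(s, "y", adjusted = TRUE)
  expect_identical(est$method, "poisson_robust_adjusted")
  crude <- any_use_rr(s, "y", adjusted = FALSE)
  # perfectly balanced covariates leave the RR essentially unchanged
  expect_equal(est$pct_change, crude$pct_change, tolerance = 1e-6)
})

test_that("stratified user fractions and relative risks are crude per stratum", {
  s <- rbind(
    cbind(stub_summaries(50, 10, 50, 5), severity = "mild"),
    cbind(stub_summaries(40, 20, 60, 15), severity = "severe"))
  s[, person_id := sprintf("q%04d", .I)]
  st <- stratified_risk(s, "y", by = "severity")
  expect_equal(st[stratum == "mild", rr], 2.0, tolerance = 1e-12)
  expect_equal(st[stratum == "mild", frac_trd], 0.2)
  expect_equal(st[stratum == "severe", rr], (20 / 40) / (15 / 60),
               tolerance = 1e-12)
  # pooled user fractions equal the stratum-size-weighted average
  overall_trd <- sum(st$frac_trd * st$n_cases) / sum(st$n_cases)
  expect_equal(overall_trd, mean(s[group == "TRD", value] > 0))
})

test_that("the baseline Chi-squared test matches the hand-computed statistic", {
  # contingency [[30,10],[10,30]]: Pearson statistic 20 without correction
  x <- matrix(c(30, 10, 10, 30), nrow = 2, byrow = TRUE)
  expect_equal(unname(chisq.test(x, correct = FALSE)$statistic), 20.0)

  # blocks of one case + three controls, alternating block sex, so both
  # roles are exactly 50% F
  cohort <- data.table::data.table(
    person_id = sprintf("b%03d", 1:80),
    sex = rep(rep(c("F", "M"), each = 4), 10))
  trd <- data.table::data.table(person_id = cohort$person_id,
                                is_trd = rep(c(TRUE, FALSE, FALSE, FALSE), 20))
  matched <- data.table::data.table(
    person_id = cohort$person_id,
    role = rep(c("case", "control", "control", "control"), 20))
  bt <- baseline_table(cohort, trd, matched, variables = "sex")
  # perfectly balanced variable: statistic 0, p = 1
  expect_equal(bt$tests$chisq, 0, tolerance = 1e-12)
  expect_equal(bt$tests$p_value, 1, tolerance = 1e-12)
  expect_true(all(bt$table$pct == 50))
})

test_that("percentages follow the count/total convention at one decimal", {
  expect_identical(percent_of(16546, 25321), 65.3)
  expect_identical(percent_of(1, 3), 33.3)
  expect_identical(percent_of(0, 10), 0)
})

test_that("the outcome grid carries every count and cost outcome", {
  scfg <- calib_sim_config(n_persons = 800, seed = 61, any_use = c(0.2, 0.4))
  sim <- simulate_registry(scfg)
  res <- run_trd_pipeline(sim$bundle, seed = 62, fit = TRUE)
  expect_setequal(res$grid$hru$outcome, hru_count_outcomes())
  expect_setequal(res$grid$costs$outcome, hru_cost_outcomes())
  expect_identical(nrow(res$grid$hru), 21L)
  expect_identical(nrow(res$grid$costs), 9L)
  got <- res$grid$hru[outcome == "psych_hospitalization"]
  expect_false(is.na(got$risk_pct_change))
})
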