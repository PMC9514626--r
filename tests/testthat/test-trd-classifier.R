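mdd0 <- as.Date("2005-06-01")

rx_at <- function(days, atc) {
  prescriptions_df(rep("p", length(days)), mdd0 + days, atc)
}
ect_at <- function(days) {
  procedures_df(rep("p", length(days)), mdd0 + days, "BRTB1")
}

test_that("ATC prefixes map to antidepressant classes by longest match", {
  expect_identical(substance_class("N06AB06"), "SSRI")
  expect_identical(substance_class("N06AF03"), "MAOI")
  expect_identical(substance_class("N06AG02"), "MAOI")
  expect_identical(substance_class("N06AX16"), "SNRI")
  expect_identical(substance_class("N06AA09"), "TCA")
  expect_identical(substance_class("N05AH04"), "none")
})

test_that("shift detection follows the new-treatment semantics", {
  # repeat of the initiating substance is no event; the first new one is
  sh <- detect_shifts(rx_at(c(-30, 0, 40), c("N06AB04", "N06AB04", "N06AA09")),
                      NULL, mdd0)
  expect_identical(nrow(sh), 1L)
  expect_equal(sh$date, mdd0 + 40)
  expect_identical(sh$new_treatment, "N06AA09")

  # ECT after two substances: second shift at the ECT date
  sh2 <- detect_shifts(rx_at(c(0, 30), c("N06AB04", "N06AA09")), ect_at(60),
                       mdd0)
  expect_identical(nrow(sh2), 2L)
  expect_equal(sh2$date[2], mdd0 + 60)
  expect_identical(sh2$kind[2], "ect")

  # return to a previous substance: no shift by default, one under
  # change-from-previous semantics
  aba <- rx_at(c(0, 30, 90), c("N06AB04", "N06AA09", "N06AB04"))
  expect_identical(nrow(detect_shifts(aba, NULL, mdd0)), 1L)
  cfg_re <- default_code_config(re_initiation_counts = TRUE)
  expect_identical(nrow(detect_shifts(aba, NULL, mdd0, cfg_re)), 2L)
})

test_that("add-on labelling uses the activity window", {
  # second substance begun while the first is still being redeemed
  sh <- detect_shifts(rx_at(c(0, 40), c("N06AB04", "N06AA09")), NULL, mdd0)
  expect_identical(sh$kind, "add_on")
  expect_identical(sh$prior_active, "N06AB04")
  # long gap: a switch, nothing active
  sh2 <- detect_shifts(rx_at(c(0, 200), c("N06AB04", "N06AA09")), NULL, mdd0)
  expect_identical(sh2$kind, "switch")
  expect_identical(sh2$prior_active, "")
})

test_that("ECT alone is initiation by default, a shift when configured", {
  expect_identical(nrow(detect_shifts(NULL, ect_at(c(10, 20)), mdd0)), 0L)
  cfg <- default_code_config(ect_always_shift = TRUE)
  expect_identical(nrow(detect_shifts(NULL, ect_at(c(10, 20)), mdd0, cfg)), 1L)
})

test_that("minimum spacing between shifts discards early repeats", {
  rx <- rx_at(c(0, 20, 200), c("N06AB04", "N06AA09", "N06AX16"))
  expect_identical(nrow(detect_shifts(rx, NULL, mdd0)), 2L)
  cfg <- default_code_config(min_days_between_shifts = 28L)
  sh <- detect_shifts(rx, NULL, mdd0, cfg)
  expect_identical(nrow(sh), 1L)
  expect_equal(sh$date, mdd0 + 200)
  expect_equal(shift_oracle(rx, NULL, mdd0, cfg), sh$date)
})

test_that("TRD is defined at the second shift and prevalence at the MDD date", {
  entry <- list(person_id = "p", mdd_date = mdd0)
  # both shifts before diagnosis: prevalent
  st <- classify_trd(entry, detect_shifts(
    rx_at(c(-50, -10, -5), c("N06AB04", "N06AA09", "N06AX16")), NULL, mdd0))
  expect_true(st$is_trd)
  expect_true(st$prevalent_trd)
  # a single shift is not TRD
  st2 <- classify_trd(entry, detect_shifts(
    rx_at(c(0, 40), c("N06AB04", "N06AA09")), NULL, mdd0))
  expect_false(st2$is_trd)
  expect_identical(st2$n_shifts_in_window, 1L)
  # shifts at +20 and +200: index date is the second shift
  st3 <- classify_trd(entry, detect_shifts(
    rx_at(c(0, 20, 200), c("N06AB04", "N06AA09", "N06AX16")), NULL, mdd0))
  expect_true(st3$is_trd)
  expect_equal(st3$index_date, mdd0 + 200)
  expect_false(st3$prevalent_trd)
  # events outside +/- 365 days never contribute
  st4 <- classify_trd(entry, detect_shifts(
    rx_at(c(-400, 0, 40), c("N06AB04", "N06AA09", "N06AX16")), NULL, mdd0))
  expect_identical(st4$n_shifts_in_window, 1L)
})

test_that("shift detection is invariant to duplicates and row order", {
  set.seed(42)
  subs <- c("N06AB04", "N06AA09", "N06AX16", "N06AF03")
  for (i in 1:25) {
    k <- sample(1:6, 1)
    days <- sample(-300:300, k, replace = TRUE)
    atcs <- sample(subs, k, replace = TRUE)
    rx <- rx_at(days, atcs)
    base <- detect_shifts(rx, NULL, mdd0)
    # permuted rows
    perm <- rx[sample(nrow(rx)), ]
    expect_equal(detect_shifts(perm, NULL, mdd0), base,
                 ignore_attr = "row.names")
    # duplicated redemptions of already-seen substances
    dup <- rbind(rx, rx[sample(nrow(rx), 1), ])
    expect_equal(detect_shifts(dup, NULL, mdd0)$date, base$date)
  }
})

test_that("adding a never-seen substance never decreases the shift count", {
  set.seed(7)
  subs <- c("N06AB04", "N06AA09", "N06AX16")
  for (i in 1:25) {
    k <- sample(0:4, 1)
    rx <- rx_at(sample(-300:300, k, replace = TRUE),
                sample(subs, k, replace = TRUE))
    before <- nrow(detect_shifts(rx, NULL, mdd0))
    rx2 <- rbind(rx, rx_at(sample(-300:300, 1), "N06AG02"))
    after <- nrow(detect_shifts(rx2, NULL, mdd0))
    expect_gte(after, before)
  }
})

test_that("the vectorized cohort classifier equals the per-person path", {
  for (mode in c("calibration", "realistic")) {
    sc <- sim_config(n_persons = 200, seed = 31, mode = mode,
                     p_resistant = 0.4)
    sim <- simulate_registry(sc)
    cand <- first_mdd_contact(sim$bundle$diagnoses)
    bulk <- classify_trd_cohort(sim$bundle, cand)
    rx_s <- split(as.data.frame(sim$bundle$prescriptions),
                  sim$bundle$prescriptions$person_id)
    pr_s <- split(as.data.frame(sim$bundle$procedures),
                  sim$bundle$procedures$person_id)
    single <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
      pid <- cand$person_id[i]
      classify_trd(cand[i], detect_shifts(rx_s[[pid]], pr_s[[pid]],
                                          cand$mdd_date[i]))
    }))
    expect_identical(bulk$is_trd, single$is_trd)
    expect_identical(bulk$n_shifts_in_window, single$n_shifts_in_window)
    expect_equal(as.Date(bulk$index_date), as.Date(single$index_date))
    expect_identical(bulk$prevalent_trd, single$prevalent_trd)
  }
})
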