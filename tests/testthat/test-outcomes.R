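idx <- as.Date("2010-06-01")

test_that("index windows exclude the index day and span 365 days each", {
  post <- window_bounds(idx, "post")
  expect_equal(as.Date(post$start), as.Date("2010-06-02"))
  expect_equal(as.Date(post$end), as.Date("2011-06-01"))
  pre <- window_bounds(idx, "pre")
  expect_equal(as.Date(pre$start), as.Date("2009-06-01"))
  expect_equal(as.Date(pre$end), as.Date("2010-05-31"))
  # an event on the index day is in neither window
  ct <- contacts_df("p", idx, idx, "psychiatric", "outpatient")
  expect_identical(sum(count_hru(ct, post)), 0)
  expect_identical(sum(count_hru(ct, pre)), 0)
  # the optional convention pulls the index day into the post window
  cfg <- default_code_config(include_index_day_in_post = TRUE)
  expect_identical(count_hru(ct, window_bounds(idx, "post", cfg),
                             cfg)[["psych_outpatient"]], 1)
})

test_that("hospitalizations count at admission and bed days as clipped nights", {
  post <- window_bounds(idx, "post")
  ten <- contacts_df("p", idx + 10, idx + 20, "psychiatric",
                     "hospitalization", "acute")
  cnt <- count_hru(ten, post)
  expect_identical(cnt[["psych_hospitalization"]], 1)
  expect_identical(cnt[["psych_hospitalization_acute"]], 1)
  expect_identical(cnt[["psych_bed_days"]], 10)

  # stay straddling the window end by 3 days: nights clipped at the bound
  straddle <- contacts_df("p", idx + 360, idx + 368, "somatic",
                          "hospitalization", "elective")
  cnt2 <- count_hru(straddle, post)
  expect_identical(cnt2[["somatic_hospitalization"]], 1)
  expect_identical(cnt2[["somatic_bed_days"]], 5)   # idx+360 .. idx+365
  expect_identical(cnt2[["somatic_bed_days_elective"]], 5)

  # completed same-day inpatient stay: one bed day
  same <- contacts_df("p", idx + 5, idx + 5, "psychiatric",
                      "hospitalization", "acute")
  expect_identical(count_hru(same, post)[["psych_bed_days"]], 1)

  # a stay admitted before the window contributes nights but no admission
  carry <- contacts_df("p", idx - 10, idx + 4, "psychiatric",
                       "hospitalization", "acute")
  cnt3 <- count_hru(carry, post)
  expect_identical(cnt3[["psych_hospitalization"]], 0)
  expect_identical(cnt3[["psych_bed_days"]], 3)     # idx+1 .. idx+4 nights
})

test_that("costs are split by service category and ATC medicine group", {
  post <- window_bounds(idx, "post")
  rx <- prescriptions_df(c("p", "p"), c(idx + 10, idx + 20),
                         c("N06AB06", "N05BA01"), cost = c(30, 10))
  ct <- contacts_df("p", idx + 30, idx + 30, "primary", "gp", cost = 25)
  costs <- cost_hru(ct, rx, post)
  expect_identical(costs[["cost_medicine_antidepressant"]], 30)
  expect_identical(costs[["cost_medicine_other_psychiatric"]], 10)
  expect_identical(costs[["cost_gp"]], 25)
  expect_identical(costs[["cost_total_excl_medicine"]], 25)
  expect_identical(costs[["cost_total_incl_medicine"]], 65)
  # empty inputs give an all-zero map
  expect_true(all(cost_hru(contacts_df(), prescriptions_df(), post) == 0))
  # private psychiatrist and psychologist bill to the psychiatric category
  ct2 <- contacts_df(c("p", "p"), c(idx + 1, idx + 2), c(idx + 1, idx + 2),
                     "primary", c("private_psychiatrist", "private_psychologist"),
                     cost = c(90, 70))
  expect_identical(cost_hru(ct2, prescriptions_df(), post)[["cost_psychiatric"]],
                   160)
})

test_that("fixed-price costing prices hospitalizations per bed day", {
  cfg <- default_code_config(cost_mode = "fixed")
  post <- window_bounds(idx, "post", cfg)
  stay <- contacts_df("p", idx + 10, idx + 13, "psychiatric",
                      "hospitalization", "acute", cost = 0)
  pr <- cfg$fixed_price_table
  day_price <- pr$price_eur[pr$sector == "psychiatric" &
                              pr$contact_type == "hospitalization" &
                              pr$admission_mode == "acute"]
  expect_identical(cost_hru(stay, prescriptions_df(), post,
                            cfg)[["cost_psychiatric"]], day_price * 3)
  # a contact type absent from the table is a configuration error
  cfg2 <- cfg
  cfg2$fixed_price_table <- pr[pr$contact_type != "gp", ]
  gp <- contacts_df("p", idx + 1, idx + 1, "primary", "gp")
  expect_error(cost_hru(gp, prescriptions_df(), post, cfg2), "no entry")
})

test_that("group summaries report mean and a guarded sd", {
  s <- data.table::data.table(
    outcome = "x", window = "post",
    group = c("TRD", "TRD", "TRD", "nonTRD"),
    value = c(0, 0, 3, 5))
  out <- summarize_by_group(s)
  expect_equal(out[group == "TRD", mean], 1.0)
  expect_equal(out[group == "TRD", sd], sd(c(0, 0, 3)))
  expect_equal(out[group == "nonTRD", sd], 0)       # single observation
  expect_true(out[group == "nonTRD", sd_undefined])
})

test_that("bulk window aggregation equals the per-person functions", {
  sc <- sim_config(n_persons = 600, seed = 13)
  sim <- simulate_registry(sc)
  res <- run_trd_pipeline(sim$bundle, seed = 14)
  s <- res$summaries
  cfg <- sim$bundle$config
  ct <- data.table::as.data.table(sim$bundle$contacts)
  rx <- data.table::as.data.table(sim$bundle$prescriptions)
  some <- res$matched[seq_len(min(25, nrow(res$matched)))]
  for (i in seq_len(nrow(some))) {
    pid <- some$person_id[i]
    for (w in c("pre", "post")) {
      wb <- window_bounds(some$index_date[i], w, cfg)
      counts <- count_hru(ct[person_id == pid], wb, cfg)
      costs <- cost_hru(ct[person_id == pid], rx[person_id == pid], wb, cfg)
      got <- s[person_id == pid & window == w]
      expect_equal(got[match(names(counts), outcome), value],
                   unname(counts), info = paste(pid, w))
      expect_equal(got[match(names(costs), outcome), value],
                   unname(costs), info = paste(pid, w))
    }
  }
  # pre and post windows are disjoint: no event is counted twice
  both <- s[outcome == "psych_outpatient",
            .(tot = sum(value)), by = person_id]
  full_ct <- ct[contact_type == "outpatient" & sector == "psychiatric"]
  for (pid in head(some$person_id, 10)) {
    expect_lte(both[person_id == pid, tot],
               nrow(full_ct[person_id == pid]))
  }
})

test_that("cost totals are invariant to event order", {
  post <- window_bounds(idx, "post")
  set.seed(9)
  ct <- contacts_df(rep("p", 6), idx + sample(1:300, 6), idx + sample(1:300, 6),
                    "primary", "gp", cost = runif(6, 10, 50))
  ct$end_date <- ct$start_date
  rx <- prescriptions_df(rep("p", 4), idx + sample(1:300, 4),
                         c("N06AB06", "N05AH04", "A02BC01", "N06AA09"),
                         cost = runif(4, 5, 40))
  base <- cost_hru(ct, rx, post)
  perm <- cost_hru(ct[sample(6), ], rx[sample(4), ], post)
  expect_identical(base, perm)
})

test_that("windowed count means recover the configured rates", {
  # rate-based generation with the deterministic calibration phenotype, so
  # the matched arms coincide with the latent flag and the expected
  # post-index count equals the configured annual rate exactly
  rates <- zero_rates
  rates["psych_outpatient"] <- 4
  sc <- sim_config(n_persons = 3000, seed = 55, mode = "calibration",
                   p_resistant = 1 / 3, p_death = 0, p_emigrate = 0,
                   p_exclusion_dx = 0, hru_base_rates = rates,
                   hru_multiplier = stats::setNames(rep(2, length(zero_rates)),
                                                    names(zero_rates)))
  sim <- simulate_registry(sc)
  res <- run_trd_pipeline(sim$bundle, seed = 56,
                          outcomes = "psych_outpatient", windows = "post")
  cell <- summarize_by_group(res$summaries)
  m0 <- cell[group == "nonTRD"]
  m1 <- cell[group == "TRD"]
  expect_lt(abs(m0$mean - 4), 3 * m0$sd / sqrt(m0$n))
  expect_lt(abs(m1$mean - 8), 3 * m1$sd / sqrt(m1$n))
})
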