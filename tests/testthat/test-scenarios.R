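reg <- standard_scenarios(canon)

test_that("the scenario registry is complete and well-formed", {
  expect_gte(length(reg), 13L)
  expect_identical(anyDuplicated(names(reg)), 0L)
  needed <- c("tm_low", "tm_high", "tg_low", "tg_high", "dtt_low",
              "inducer_pre_tm_high", "inducer_co_tm_high",
              "inducer_delayed_tm_high", "inducer_pre_tg_high",
              "inducer_co_tg_high", "inducer_delayed_tg_high",
              "escalation", "washout_low", "washout_high_early",
              "washout_high_late")
  expect_true(all(needed %in% names(reg)))
  for (sc in reg) {
    expect_s3_class(sc$schedule, "ers_schedule")
    expect_true(sc$expected_label %in%
                  c("homeostasis", "autophagy", "apoptosis"))
  }
})

test_that("every registered scenario reaches its expected fate", {
  for (sc in reg) {
    out <- run_scenario(canon, sc)$outcome
    expect_identical(out$label, sc$expected_label, label = sc$name)
  }
})

test_that("high tunicamycin admits a finite rescue window, thapsigargin none", {
  res_tm <- rescue_window_scan(canon, reg$tm_high,
                               delays = c(1, 5, 20, 40, 60))
  expect_true(res_tm$window_exists)
  expect_gt(res_tm$latest_delay, 1)
  expect_lt(res_tm$latest_delay, 60)
  # rescue success is monotone in delay (threshold structure)
  ok <- res_tm$grid$label != "apoptosis"
  expect_true(all(diff(ok) <= 0))
  # beyond the threshold the switch is irreversible
  km <- inducer_mult()
  late <- erswitch:::.with_event(reg$tm_high$schedule,
                                 treatment_event(res_tm$latest_delay + 5,
                                                 "kaua_mult", km))
  expect_identical(classify_outcome(simulate_model(canon, late,
                                                   init = phys0))$label,
                   "apoptosis")
  res_tg <- rescue_window_scan(canon, reg$tg_high, delays = c(1, 5, 20))
  expect_false(res_tg$window_exists)
  expect_null(res_tg$latest_delay)
})

test_that("inducer pre/co-treatment delays apoptosis onset when death still occurs", {
  onset <- function(name) run_scenario(canon, reg[[name]])$outcome$onset_time_apoptosis
  o_ctrl <- onset("tg_high")
  o_co <- onset("inducer_co_tg_high")
  o_pre <- onset("inducer_pre_tg_high")
  lead <- vapply(reg$inducer_pre_tg_high$schedule$events, `[[`, 0, "time")[1]
  expect_gt(o_co, o_ctrl)
  expect_gt(o_pre - lead, o_ctrl)   # onset relative to stressor addition
})

test_that("washout reversibility has the expected threshold structure", {
  w5 <- washout_scan(canon, 5, washout_times = c(5, 20, 80))
  expect_true(w5$always_reversible)
  expect_identical(w5$threshold, Inf)
  w50 <- washout_scan(canon, 50, washout_times = c(5, 20, 40, 80))
  expect_false(w50$always_reversible)
  expect_true(is.finite(w50$threshold))
  expect_gt(w50$threshold, 5)
  ok <- w50$grid$label == "homeostasis"
  expect_true(all(diff(ok) <= 0))  # monotone in washout time
  # just before / just after the refined threshold
  lab_at <- function(w) {
    sch <- treatment_schedule(ers_input(stress = 50),
                              list(treatment_event(w, "stress", 0)),
                              t_end = w + 300)
    classify_outcome(simulate_model(canon, sch, init = phys0))$label
  }
  expect_identical(lab_at(w50$threshold - 1), "homeostasis")
  expect_identical(lab_at(w50$threshold + 1), "apoptosis")
})

test_that("escalation to high stress is equivalent to constant high stress", {
  ref <- classify_outcome(run_input(ers_input(stress = 50)))$label
  for (tesc in c(10, 20, 40, 60, 80)) {
    sch <- treatment_schedule(ers_input(stress = 5),
                              list(treatment_event(tesc, "stress", 50)),
                              t_end = tesc + 250)
    lab <- classify_outcome(simulate_model(canon, sch, init = phys0))$label
    expect_identical(lab, ref)
  }
})

test_that("perturbation ensembles are reproducible and degenerate correctly", {
  e0 <- perturbation_ensemble(canon, n = 3, cv = 0, seed = 10)
  expect_identical(e0$preserved_fraction, 1)
  for (d in e0$draws)
    expect_identical(unclass(d)[erswitch:::.rate_names],
                     unclass(canon)[erswitch:::.rate_names])
  e1 <- perturbation_ensemble(canon, n = 12, cv = 0.1, seed = 20)
  e2 <- perturbation_ensemble(canon, n = 12, cv = 0.1, seed = 20)
  expect_identical(e1$labels, e2$labels)
  expect_identical(e1$preserved_fraction, e2$preserved_fraction)
  expect_identical(unclass(e1$draws[[5]]), unclass(e2$draws[[5]]))
  expect_error(perturbation_ensemble(canon, n = 2, cv = 0.9), "0.5")
})

test_that("two independent seeds agree on robustness within sampling error", {
  f1 <- perturbation_ensemble(canon, n = 40, cv = 0.1, seed = 101)$preserved_fraction
  f2 <- perturbation_ensemble(canon, n = 40, cv = 0.1, seed = 202)$preserved_fraction
  # binomial sampling error at n = 40 (3 x pooled standard error + continuity)
  pbar <- (f1 + f2) / 2
  se <- sqrt(2 * max(pbar * (1 - pbar), 0.05) / 40)
  expect_lt(abs(f1 - f2), 3 * se + 0.05)
})
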