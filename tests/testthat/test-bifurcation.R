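# Continuation diagrams; the multi-start root finder is the module's oracle.

diag_tm <- continue_in_stress(canon, ers_input(), stress_range = c(0, 60))

# Newton-refined diagram states at an exact stress value, for set comparison
refined_states_at <- function(diagram, s, params = canon,
                              input_template = ers_input()) {
  P <- unclass(params)
  inp <- input_template; inp$stress <- s
  out <- list()
  for (br in diagram$branches) {
    if (s < min(br$stress) - 0.5 || s > max(br$stress) + 0.5) next
    # seed a refinement from every branch point within one step of s
    d <- abs(br$stress - s)
    for (j in which(d <= max(min(d) + 1e-9, 0.6))) {
      y <- erswitch:::.newton_full(as.numeric(br[j, erswitch:::.state_names]),
                                   P, inp)
      if (is.null(y) || !erswitch:::.in_box(y, P)) next
      if (!any(vapply(out, function(z) max(abs(z - y)) < 1e-6, TRUE)))
        out[[length(out) + 1L]] <- y
    }
  }
  out
}

test_that("the stress response is a folded bistable switch", {
  expect_gte(length(diag_tm$limit_points), 1L)
  fold <- max(diag_tm$limit_points)
  expect_gt(fold, 5); expect_lt(fold, 50)
  bi <- diag_tm$bistable_interval
  expect_false(is.null(bi))
  expect_lte(bi[1], 1e-6)          # bistability persists down to zero stress
  expect_gt(bi[2], 5); expect_lt(bi[2], 50)
  expect_lt(abs(bi[2] - fold), 0.5)
  # residual invariant along branches
  for (br in diag_tm$branches) {
    ix <- round(seq(1, nrow(br), length.out = 10))
    for (j in ix) {
      inp <- ers_input(stress = br$stress[j])
      y <- as.numeric(br[j, erswitch:::.state_names])
      expect_lt(max(abs(erswitch:::.rhs_fast(y, unclass(canon), inp))), 1e-8)
    }
  }
})

test_that("at rest the diagram carries two stable points and one saddle", {
  states <- refined_states_at(diag_tm, 0)
  stab <- vapply(states, function(y) classify_stability(
    eigen(erswitch:::.jac_fast(y, unclass(canon), ers_input()),
          only.values = TRUE)$values), "")
  expect_identical(sum(stab == "stable"), 2L)
  expect_identical(sum(stab == "saddle"), 1L)
})

test_that("branch shapes: S-shaped apoptosis response, Z-shaped autophagy response", {
  # low-apoptosis stable points ordered by stress
  low <- do.call(rbind, lapply(diag_tm$branches, function(br)
    br[br$stability == "stable" & br$apo_a < 0.5, ]))
  # keep clear of the fold neighborhood, where the branch turns
  low <- low[low$stress < max(diag_tm$limit_points) - 0.1, ]
  low <- low[order(low$stress), ]
  expect_gt(nrow(low), 10)
  # apo_a monotone along the lower branch up to the small dip where the
  # autophagy arm switches on and deepens its suppression of the apoptosis
  # arm (bounded by 1% of the pool)
  expect_true(all(diff(low$apo_a) > -0.01 * canon$APO_T))
  expect_gt(low$apo_a[nrow(low)], low$apo_a[1])
  # aut_a rises, then (beyond its rise) comes back down toward the fold
  expect_gt(max(low$aut_a), 0.6)
  expect_lt(low$aut_a[nrow(low)], max(low$aut_a) - 0.01)
  # the high branch is stable wherever the scan reaches beyond the fold
  high <- do.call(rbind, lapply(diag_tm$branches, function(br)
    br[br$apo_a > 0.5 & br$stress > max(diag_tm$limit_points), ]))
  expect_true(all(high$stability == "stable"))
  # the jump: stable apoptosis activity above vs below the fold
  expect_gt(min(high$apo_a), 0.5)
  expect_lt(max(low$apo_a), 0.5)
})

test_that("continuation and multi-start root finding agree at sampled stress levels", {
  for (s in seq(0, 60, length.out = 11)) {
    eqs <- find_equilibria(canon, ers_input(stress = s))
    states <- refined_states_at(diag_tm, s)
    expect_identical(length(states), length(eqs))
    for (e in eqs) {
      d <- vapply(states, function(y) max(abs(y - e$state)), 0)
      expect_lt(min(d), 1e-4)
    }
  }
})

test_that("the fold location is independent of the scan window", {
  wide <- continue_in_stress(canon, ers_input(), stress_range = c(0, 70))
  expect_identical(length(wide$limit_points), length(diag_tm$limit_points))
  expect_lt(max(abs(wide$limit_points - diag_tm$limit_points)), 1e-3)
})

test_that("simulated fates agree with the diagram's fold", {
  fold <- max(diag_tm$limit_points)
  for (s in c(2, 10, 25, 35)) {
    expect_lt(s, fold)
    lab <- classify_outcome(run_input(ers_input(stress = s), t_end = 600))$label
    expect_true(lab %in% c("autophagy", "homeostasis"))
  }
  for (s in c(45, 55)) {
    expect_gt(s, fold)
    expect_identical(
      classify_outcome(run_input(ers_input(stress = s), t_end = 600))$label,
      "apoptosis")
  }
})

test_that("a trivial monostable diagram has no bistable interval", {
  br <- data.frame(stress = seq(0, 60, by = 0.5),
                   upr = 0, bcl2 = 0.9, aut_a = 0.1, aut_i = 0,
                   apo_a = 0.01, stability = "stable")
  d <- structure(list(branches = list(br), limit_points = numeric(0),
                      stress_range = c(0, 60)), class = "ers_bifdiag")
  expect_null(bistable_interval(d))
})

test_that("under thapsigargin the survival state is gone at low stress", {
  d_tg <- continue_in_stress(canon, ers_input(tg = 0.25),
                             stress_range = c(0, 60))
  bi <- d_tg$bistable_interval
  if (!is.null(bi)) expect_true(bi[1] > 5 || bi[2] < 5)
  states <- refined_states_at(d_tg, 5, input_template = ers_input(tg = 0.25))
  stab <- vapply(states, function(y) classify_stability(
    eigen(erswitch:::.jac_fast(y, unclass(canon),
                               ers_input(stress = 5, tg = 0.25)),
          only.values = TRUE)$values), "")
  expect_identical(sum(stab == "stable"), 1L)
})
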