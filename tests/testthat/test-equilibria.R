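test_that("stability classification follows the eigenvalue sign pattern", {
  expect_identical(classify_stability(c(-1, -2, -3, -4, -5)), "stable")
  expect_identical(classify_stability(c(1, -1, -1, -1, -1)), "saddle")
  expect_identical(classify_stability(c(1, 2, 3, 4, 5)), "unstable")
  expect_identical(classify_stability(c(-1, -1, -1, -1, 1e-12)), "marginal")
  expect_identical(classify_stability(complex(real = c(-1, -1, -1, -2, -2),
                                              imaginary = c(0, 1, -1, 2, -2))),
                   "stable")
})

test_that("the unstressed network is bistable with a quiet physiological state", {
  eqs <- find_equilibria(canon, ers_input())
  expect_length(eqs, 3L)
  expect_identical(n_stable(eqs), 2L)
  expect_identical(sum(vapply(eqs, function(e)
    e$stability %in% c("saddle", "unstable"), TRUE)), 1L)
  expect_true(all(vapply(eqs, function(e) e$residual < 1e-8, TRUE)))
  expect_true(all(vapply(eqs, function(e) e$stability != "marginal", TRUE)))
  # survival state: apoptosis off, small but nonzero basal autophagy
  surv <- eqs[[1L]]$state                     # sorted by apo_a
  expect_lt(surv[["apo_a"]], 0.1 * canon$APO_T)
  expect_gt(surv[["aut_a"]], 0)
  expect_lt(surv[["aut_a"]], 0.35 * canon$AUT_T)
})

test_that("low thapsigargin leaves a single, apoptotic steady state", {
  eqs <- find_equilibria(canon, ers_input(stress = 5, tg = 0.25))
  expect_identical(n_stable(eqs), 1L)
  st <- eqs[[which(vapply(eqs, function(e) e$stability == "stable", TRUE))]]
  expect_gt(st$state[["apo_a"]], 0.5 * canon$APO_T)
  expect_lt(st$state[["aut_a"]], 0.5 * canon$AUT_T)
})

test_that("the equilibrium set is saturated in the number of starts", {
  for (inp in list(ers_input(), ers_input(stress = 5))) {
    base <- find_equilibria(canon, inp, n_starts = 81)
    more <- find_equilibria(canon, inp, n_starts = 162, seed = 2L)
    brute <- find_equilibria(canon, inp, n_starts = 2000, seed = 3L)
    expect_identical(length(base), length(brute))
    expect_identical(length(more), length(brute))
    for (k in seq_along(base))
      expect_lt(max(abs(base[[k]]$state - brute[[k]]$state)), 1e-6)
  }
  expect_error(find_equilibria(canon, ers_input(), n_starts = 10), "27")
})

test_that("stable states attract and the saddle separates the basins", {
  eqs <- find_equilibria(canon, ers_input())
  stables <- Filter(function(e) e$stability == "stable", eqs)
  saddle <- Filter(function(e) e$stability == "saddle", eqs)[[1L]]
  set.seed(5)
  for (e in stables) {
    pert <- pmax(e$state + stats::runif(5, -1e-3, 1e-3), 0)
    names(pert) <- names(e$state)
    tr <- run_input(ers_input(), init = ers_state(
      upr = pert[["upr"]], bcl2 = pert[["bcl2"]], aut_a = pert[["aut_a"]],
      aut_i = pert[["aut_i"]], apo_a = pert[["apo_a"]]), t_end = 300)
    expect_lt(max(abs(tr$states[nrow(tr$states), ] - e$state)), 1e-4)
  }
  for (k in 1:4) {
    pert <- pmax(saddle$state + stats::runif(5, -1e-3, 1e-3), 0)
    names(pert) <- names(saddle$state)
    tr <- run_input(ers_input(), init = ers_state(
      upr = pert[["upr"]], bcl2 = pert[["bcl2"]], aut_a = pert[["aut_a"]],
      aut_i = pert[["aut_i"]], apo_a = pert[["apo_a"]]), t_end = 600)
    fin <- tr$states[nrow(tr$states), ]
    dists <- vapply(stables, function(e) max(abs(fin - e$state)), 0)
    expect_lt(min(dists), 1e-3)
  }
})

test_that("no stable state activates autophagy and apoptosis together", {
  km <- inducer_mult()
  inputs <- list(ers_input(), ers_input(stress = 5), ers_input(stress = 50),
                 ers_input(stress = 5, tg = 0.25),
                 ers_input(stress = 50, tg = 0.25),
                 ers_input(stress = 50, kaua_mult = km),
                 ers_input(stress = 5, dtt = 0.25))
  for (inp in inputs) {
    for (e in find_equilibria(canon, inp)) {
      if (e$stability != "stable") next
      expect_false(e$state[["aut_a"]] > 0.5 * canon$AUT_T &&
                     e$state[["apo_a"]] > 0.5 * canon$APO_T)
    }
  }
})

test_that("balance-curve crossings coincide with the located equilibria", {
  for (s in c(0, 5, 12.5, 25, 50)) {
    inp <- ers_input(stress = s)
    nc <- nullclines(canon, inp, resolution = 121)
    xi <- nullcline_intersections(nc)
    eqs <- find_equilibria(canon, inp)
    expect_identical(nrow(xi), length(eqs))
    proj <- cbind(vapply(eqs, function(e) e$state[["aut_a"]], 0),
                  vapply(eqs, function(e) e$state[["apo_a"]], 0))
    for (r in seq_len(nrow(xi))) {
      d <- apply(abs(sweep(proj, 2, as.numeric(xi[r, ]))), 1, max)
      expect_lt(min(d), 1e-3)
    }
  }
})

test_that("balance-curve points satisfy the reduced balance condition", {
  inp <- ers_input(stress = 5)
  nc <- nullclines(canon, inp, resolution = 121)
  P <- unclass(canon)
  check_curve <- function(df, var_idx) {
    ix <- round(seq(1, nrow(df), length.out = 25))
    for (r in ix) {
      z <- erswitch:::.qss_solve(df$aut_a[r], df$apo_a[r], P, inp)
      w <- numeric(5); w[c(1, 2, 4)] <- z
      w[3] <- df$aut_a[r]; w[5] <- df$apo_a[r]
      expect_lt(abs(erswitch:::.rhs_fast(w, P, inp)[var_idx]), 1e-6)
    }
  }
  check_curve(nc$aut_a, 3L)
  check_curve(nc$apo_a, 5L)
})
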