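# shared fixtures: all inputs are generated in code

canon <- canonical_parameters()
phys0 <- physiological_state(canon)

# seeded admissible random state inside the box [0, totals]
random_state <- function(P = unclass(canon)) {
  a_tot <- stats::runif(1, 0, P$AUT_T)
  split <- stats::runif(1)
  ers_state(upr = stats::runif(1, 0, P$UPR_T),
            bcl2 = stats::runif(1, 0, P$BCL2_T),
            aut_a = a_tot * split, aut_i = a_tot * (1 - split),
            apo_a = stats::runif(1, 0, P$APO_T))
}

# central finite-difference Jacobian oracle
fd_jacobian <- function(state, params, input, h = 1e-6) {
  y0 <- as.numeric(state)
  J <- matrix(0, 5, 5)
  for (j in 1:5) {
    yp <- y0; ym <- y0
    yp[j] <- yp[j] + h; ym[j] <- max(ym[j] - h, 0)
    names(yp) <- names(ym) <- names(state)
    J[, j] <- (ers_rhs(yp, params, input) - ers_rhs(ym, params, input)) /
      (yp[j] - ym[j])
  }
  J
}

run_input <- function(inp, params = canon, t_end = 200, init = phys0, ...) {
  simulate_model(params, treatment_schedule(inp, list(), t_end = t_end),
                 init = init, ...)
}

label_of <- function(inp, ...) classify_outcome(run_input(inp, ...))$label

n_stable <- function(eqs) sum(vapply(eqs, function(e)
  e$stability == "stable", TRUE))

inducer_mult <- function(params = canon, kaua_abs = 10) kaua_abs / params$kaua_base
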