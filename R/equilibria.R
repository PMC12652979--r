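# Steady-state location, stability classification and balance-curve
# (nullcline) computation.

# Damped Newton iteration on the full 5-variable vector field, keeping the
# iterate inside the non-negative orthant. Returns NULL on failure.
.newton_full <- function(y0, P, inp, tol = 1e-12, maxit = 80) {
  y <- pmax(as.numeric(y0), 0)
  for (k in seq_len(maxit)) {
    f <- .rhs_fast(y, P, inp)
    if (max(abs(f)) < tol) break
    J <- .jac_fast(y, P, inp)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    f0 <- max(abs(f))
    repeat {
      yn <- pmax(y - lam * step, 0)
      if (max(abs(.rhs_fast(yn, P, inp))) < f0 || lam < 1e-3) break
      lam <- lam / 2
    }
    y <- pmax(y - lam * step, 0)
  }
  if (max(abs(.rhs_fast(y, P, inp))) >= 1e-10) return(NULL)
  y
}

.in_box <- function(y, P, tol = 1e-6) {
  y[1L] <= P$UPR_T + tol && y[2L] <= P$BCL2_T + tol &&
    y[3L] + y[4L] <= P$AUT_T + tol && y[5L] <= P$APO_T + tol &&
    all(y >= -tol)
}

#' Classify stability from Jacobian eigenvalues
#'
#' A hyperbolic equilibrium is `stable` when every eigenvalue has real part
#' below `-eps`, `unstable` when every real part exceeds `+eps`, and
#' `saddle` for mixed signs. If any real part lies within `eps` of zero the
#' equilibrium is `marginal` (non-hyperbolic at numerical resolution) and
#' downstream analyses refuse to draw conclusions from it.
#'
#' @param eigenvalues complex vector of the 5 Jacobian eigenvalues.
#' @param eps hyperbolicity margin (default 1e-9).
#' @return one of `"stable"`, `"unstable"`, `"saddle"`, `"marginal"`.
#' @export
classify_stability <- function(eigenvalues, eps = 1e-9) {
  re <- Re(eigenvalues)
  if (any(abs(re) <= eps)) return("marginal")
  if (all(re < 0)) return("stable")
  if (all(re > 0)) return("unstable")
  "saddle"
}

.make_equilibrium <- function(y, P, inp) {
  names(y) <- .state_names
  J <- .jac_fast(y, P, inp)
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(state = y, eigenvalues = ev,
                 stability = classify_stability(ev),
                 residual = max(abs(.rhs_fast(y, P, inp)))),
            class = "ers_equilibrium")
}

#' @export
print.ers_equilibrium <- function(x, ...) {
  cat(sprintf("<equilibrium> %-8s aut_a=%.3f apo_a=%.3f bcl2=%.3f (residual %.1e)\n",
              x$stability, x$state[["aut_a"]], x$state[["apo_a"]],
              x$state[["bcl2"]], x$residual))
  invisible(x)
}

#' Locate all steady states of the model
#'
#' Multi-start damped Newton refinement: starts are a regular 3-per-axis
#' grid over the (bcl2, aut_a, apo_a) box (UPR started at its closed-form
#' steady state, the cleaved pool at two levels) plus seeded uniform random
#' starts up to `n_starts`. Converged roots are kept when they lie in the
#' admissible box, merged at max-norm tolerance `merge_tol`, refined to
#' residual below 1e-10, classified via the analytic Jacobian, and returned
#' sorted by increasing apoptosis-inducer activity.
#'
#' @param params an [ers_params()].
#' @param input an [ers_input()].
#' @param n_starts total number of starts (>= 27; default 81).
#' @param seed RNG seed for the random starts (local to this call).
#' @param merge_tol duplicate-merge tolerance in max-norm.
#' @return list of `ers_equilibrium`; empty (with a warning) if nothing
#'   converged.
#' @export
#' @examples
#' eqs <- find_equilibria(canonical_parameters(), ers_input(stress = 0))
#' vapply(eqs, function(e) e$stability, "")
find_equilibria <- function(params, input = ers_input(), n_starts = 81,
                            seed = 1L, merge_tol = 1e-6) {
  validate_params(params); validate_input(input)
  if (n_starts < 27) stop("n_starts must be at least 27", call. = FALSE)
  P <- unclass(params)
  u0 <- P$ka_upr * input$stress * P$UPR_T /
    (P$ka_upr * input$stress + P$ki_upr)
  grid <- as.matrix(expand.grid(
    upr   = u0,
    bcl2  = c(0.1, 0.5, 0.9) * P$BCL2_T,
    aut_a = c(0.05, 0.5, 0.95) * P$AUT_T,
    aut_i = c(0.02, 0.3) * P$AUT_T,
    apo_a = c(0.02, 0.5, 0.95) * P$APO_T))
  n_rand <- max(0L, n_starts - nrow(grid))
  starts <- grid
  if (n_rand > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    rnd <- cbind(stats::runif(n_rand, 0, P$UPR_T),
                 stats::runif(n_rand, 0, P$BCL2_T),
                 stats::runif(n_rand, 0, P$AUT_T),
                 stats::runif(n_rand, 0, P$AUT_T),
                 stats::runif(n_rand, 0, P$APO_T))
    colnames(rnd) <- colnames(grid)
    starts <- rbind(grid, rnd)
  }
  roots <- list()
  for (r in seq_len(nrow(starts))) {
    y <- .newton_full(starts[r, ], P, input)
    if (is.null(y) || !.in_box(y, P)) next
    if (!any(vapply(roots, function(z) max(abs(z - y)) < merge_tol, TRUE)))
      roots[[length(roots) + 1L]] <- y
  }
  if (!length(roots)) {
    warning("no equilibrium converged for the given parameters/input")
    return(list())
  }
  eqs <- lapply(roots, .make_equilibrium, P = P, inp = input)
  eqs[order(vapply(eqs, function(e) e$state[["apo_a"]], 0))]
}

# save/restore global RNG state so seeded internals do not disturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Physiological resting state
#'
#' The stable equilibrium with the lowest apoptosis-inducer activity at zero
#' stressor input: active BCL-2 high, basal (insignificant) autophagy, and
#' the apoptosis inducer off.
#'
#' @param params an [ers_params()].
#' @return an `ers_state`.
#' @export
physiological_state <- function(params) {
  validate_params(params)
  P <- unclass(params)
  inp <- ers_input()
  # fast path: Newton from a quiet start (high BCL-2, basal inducers)
  y <- .newton_full(c(0, 0.9 * P$BCL2_T, 0.05 * P$AUT_T, 0, 0.01 * P$APO_T),
                    P, inp)
  if (!is.null(y) && .in_box(y, P) &&
      y[5L] < 0.35 * P$APO_T &&
      classify_stability(eigen(.jac_fast(y, P, inp),
                               only.values = TRUE)$values) == "stable") {
    names(y) <- .state_names
    return(structure(y, class = "ers_state"))
  }
  eqs <- find_equilibria(params, inp)
  st <- Filter(function(e) e$stability == "stable", eqs)
  if (!length(st))
    stop("no stable resting state found at zero input", call. = FALSE)
  s <- st[[1L]]$state  # sorted by apo_a ascending
  structure(s, class = "ers_state")
}

# Quasi-steady-state reduction: solve (upr, bcl2, aut_i) to steady state for
# fixed (aut_a, apo_a) by Newton on the 3-subsystem.
.qss_solve <- function(a, p, P, inp, guess = NULL) {
  idx <- c(1L, 2L, 4L)
  y <- c(if (is.null(guess))
    c(P$ka_upr * inp$stress * P$UPR_T / (P$ka_upr * inp$stress + P$ki_upr),
      0.5 * P$BCL2_T, 0.1 * P$AUT_T) else guess)
  full <- function(z) { w <- numeric(5); w[idx] <- z; w[3L] <- a; w[5L] <- p; w }
  for (k in 1:50) {
    f <- .rhs_fast(full(y), P, inp)[idx]
    if (max(abs(f)) < 1e-12) break
    J <- .jac_fast(full(y), P, inp)[idx, idx]
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    y <- pmax(y - step, 0)
  }
  if (max(abs(.rhs_fast(full(y), P, inp))[c(1, 2)]) > 1e-8 ||
      abs(.rhs_fast(full(y), P, inp)[4L]) > 1e-8) return(NULL)
  y
}

#' Balance curves (nullclines) in the autophagy/apoptosis plane
#'
#' Reduces the model to the (aut_a, apo_a) plane by holding upr, bcl2 and
#' aut_i at their steady state for each plane point (solved numerically, so
#' the reduction does not depend on the kinetic terms being invertible in
#' closed form), then traces the locus where the net rate of the given
#' variable vanishes. For each grid value of `aut_a` the balance condition
#' is solved for all `apo_a` roots by sign-change bracketing and bisection,
#' giving possibly multi-branch polylines.
#'
#' @param params an [ers_params()].
#' @param input an [ers_input()].
#' @param resolution grid size along each axis (>= 100).
#' @return a list of class `ers_nullclines` with elements `aut_a` and
#'   `apo_a`, each a data.frame with columns `aut_a`, `apo_a`, `branch`,
#'   plus the `input` used.
#' @export
nullclines <- function(params, input = ers_input(), resolution = 201) {
  validate_params(params); validate_input(input)
  if (resolution < 100) stop("resolution must be >= 100", call. = FALSE)
  P <- unclass(params)
  a_grid <- seq(0, P$AUT_T, length.out = resolution)
  p_grid <- seq(0, P$APO_T, length.out = resolution)
  # reduced rates of both plotted variables on a shared QSS grid
  z_aut <- matrix(NA_real_, resolution, resolution)
  z_apo <- matrix(NA_real_, resolution, resolution)
  skipped <- 0L
  reduced_rate <- function(a, p, guess = NULL) {
    z <- .qss_solve(a, p, P, input, guess)
    if (is.null(z)) return(NULL)
    w <- numeric(5); w[c(1L, 2L, 4L)] <- z; w[3L] <- a; w[5L] <- p
    list(f = .rhs_fast(w, P, input), qss = z)
  }
  for (gi in seq_along(a_grid)) {
    guess <- NULL
    for (pj in seq_along(p_grid)) {
      r <- reduced_rate(a_grid[gi], p_grid[pj], guess)
      if (is.null(r)) { skipped <- skipped + 1L; next }
      guess <- r$qss
      z_aut[gi, pj] <- r$f[3L]
      z_apo[gi, pj] <- r$f[5L]
    }
  }
  if (skipped > 0.2 * resolution^2)
    stop("QSS reduction failed on more than 20% of grid points", call. = FALSE)
  # zero-level contours, then per-vertex refinement onto the balance locus
  extract <- function(z, var_idx) {
    cls <- grDevices::contourLines(a_grid, p_grid, z, levels = 0)
    if (!length(cls)) return(data.frame(aut_a = numeric(0),
                                        apo_a = numeric(0),
                                        branch = integer(0)))
    h_a <- a_grid[2L] - a_grid[1L]; h_p <- p_grid[2L] - p_grid[1L]
    fval <- function(a, p) {
      r <- reduced_rate(a, p)
      if (is.null(r)) NA_real_ else r$f[var_idx]
    }
    root_along <- function(a, p, along_p) {
      g <- if (along_p) function(x) fval(a, x) else function(x) fval(x, p)
      x0 <- if (along_p) p else a
      h <- if (along_p) h_p else h_a
      lo <- max(x0 - 1.5 * h, 0); hi <- x0 + 1.5 * h
      flo <- g(lo); fhi <- g(hi)
      if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NULL)
      x <- stats::uniroot(g, lower = lo, upper = hi, tol = 1e-12)$root
      if (along_p) c(a, x) else c(x, p)
    }
    refine <- function(a, p) {
      # 1-D root refinement along the steeper axis of the reduced rate,
      # falling back to the other axis, then to damped Newton along the
      # gradient for near-tangent vertices
      fa1 <- fval(a + h_a / 2, p); fa0 <- fval(max(a - h_a / 2, 0), p)
      fp1 <- fval(a, p + h_p / 2); fp0 <- fval(a, max(p - h_p / 2, 0))
      if (anyNA(c(fa1, fa0, fp1, fp0))) return(c(a, p))
      along_p_first <- abs(fp1 - fp0) >= abs(fa1 - fa0)
      res <- root_along(a, p, along_p_first)
      if (is.null(res)) res <- root_along(a, p, !along_p_first)
      if (!is.null(res)) return(res)
      ga <- (fa1 - fa0) / (a + h_a / 2 - max(a - h_a / 2, 0))
      gp <- (fp1 - fp0) / (p + h_p / 2 - max(p - h_p / 2, 0))
      x <- c(a, p)
      for (it in 1:8) {
        f0 <- fval(x[1], x[2])
        if (is.na(f0) || abs(f0) < 1e-10) break
        nrm2 <- ga^2 + gp^2
        if (nrm2 < 1e-14) break
        x <- pmax(x - f0 * c(ga, gp) / nrm2, 0)
      }
      x
    }
    out <- lapply(seq_along(cls), function(b) {
      pts <- t(mapply(refine, cls[[b]]$x, cls[[b]]$y))
      data.frame(aut_a = pts[, 1L], apo_a = pts[, 2L], branch = b)
    })
    do.call(rbind, out)
  }
  structure(list(aut_a = extract(z_aut, 3L), apo_a = extract(z_apo, 5L),
                 input = input, resolution = resolution),
            class = "ers_nullclines")
}

#' Intersections of the balance curves
#'
#' Detects crossings by pairwise segment intersection between the two
#' polylines (segments connect consecutive sweep points on the same
#' branch). Serves as an independent cross-check of [find_equilibria()]:
#' every intersection should match the (aut_a, apo_a) projection of an
#' equilibrium.
#'
#' @param nc an `ers_nullclines` object.
#' @return data.frame with columns `aut_a`, `apo_a`, one row per crossing.
#' @export
nullcline_intersections <- function(nc) {
  stopifnot(inherits(nc, "ers_nullclines"))
  seg <- function(df) {
    if (is.null(df) || nrow(df) < 2) return(NULL)
    out <- list()
    for (b in split(df, df$branch)) {
      n <- nrow(b)  # contour path order is preserved
      if (n >= 2)
        out[[length(out) + 1L]] <-
          cbind(b$aut_a[-n], b$apo_a[-n], b$aut_a[-1], b$apo_a[-1])
    }
    do.call(rbind, out)
  }
  s1 <- seg(nc$aut_a); s2 <- seg(nc$apo_a)
  if (is.null(s1) || is.null(s2))
    return(data.frame(aut_a = numeric(0), apo_a = numeric(0)))
  hits <- list()
  for (i in seq_len(nrow(s1))) for (j in seq_len(nrow(s2))) {
    p <- .seg_intersect(s1[i, ], s2[j, ])
    if (!is.null(p)) hits[[length(hits) + 1L]] <- p
  }
  if (!length(hits)) return(data.frame(aut_a = numeric(0), apo_a = numeric(0)))
  pts <- do.call(rbind, hits)
  # merge near-duplicates (adjacent segments sharing a crossing)
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) if (keep[i]) {
    for (j in seq_len(nrow(pts))) if (j > i && keep[j] &&
        max(abs(pts[i, ] - pts[j, ])) < 1e-4) keep[j] <- FALSE
  }
  out <- as.data.frame(pts[keep, , drop = FALSE])
  names(out) <- c("aut_a", "apo_a")
  out
}

# intersection of two closed 2-D segments (x1,y1,x2,y2); NULL if none
.seg_intersect <- function(s, t) {
  d1 <- c(s[3] - s[1], s[4] - s[2]); d2 <- c(t[3] - t[1], t[4] - t[2])
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-14) return(NULL)
  dx <- t[1] - s[1]; dy <- t[2] - s[2]
  u <- (dx * d2[2] - dy * d2[1]) / den
  v <- (dx * d1[2] - dy * d1[1]) / den
  if (u < -1e-9 || u > 1 + 1e-9 || v < -1e-9 || v > 1 + 1e-9) return(NULL)
  c(s[1] + u * d1[1], s[2] + u * d1[2])
}

#' Export an equilibrium set to CSV
#'
#' @param eqs list of `ers_equilibrium` (from [find_equilibria()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_equilibria_csv <- function(eqs, path) {
  df <- do.call(rbind, lapply(eqs, function(e)
    data.frame(t(e$state), stability = e$stability, residual = e$residual)))
  if (is.null(df)) df <- data.frame()
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
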