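# One-parameter bifurcation (signal-response) diagrams in the stress level.
#
# Branches of equilibria are traced by pseudo-arclength continuation with a
# secant predictor and a Newton corrector on the bordered system, so
# saddle-node folds are traversed rather than lost.  A dense multi-start
# sweep (find_equilibria on a stress grid) is kept as an independent oracle.

# corrector: solve f(y, s) = 0 together with the arclength normalization
# t . (z - z_pred) = 0, z = (y, s)
.continuation_correct <- function(z_pred, tang, P, inp_template, maxit = 30) {
  z <- z_pred
  inp_at <- function(s) { inp <- inp_template; inp$stress <- max(s, 0); inp }
  for (k in seq_len(maxit)) {
    y <- pmax(z[1:5], 0); s <- z[6]
    f <- .rhs_fast(y, P, inp_at(s))
    g <- sum(tang * (z - z_pred))
    if (max(abs(f)) < 1e-11 && abs(g) < 1e-11) break
    J <- .jac_fast(y, P, inp_at(s))
    # df/ds: stress enters the UPR equation only
    dfds <- c(P$ka_upr * (P$UPR_T - y[1]), 0, 0, 0, 0)
    A <- rbind(cbind(J, dfds), tang)
    step <- tryCatch(solve(A, c(f, g)), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    z <- z - step
    if (!all(is.finite(z))) return(NULL)
  }
  y <- pmax(z[1:5], 0)
  if (max(abs(.rhs_fast(y, P, inp_at(z[6])))) > 1e-9) return(NULL)
  c(y, z[6])
}

#' Continue equilibrium branches in the stress parameter
#'
#' Builds the signal-response (one-parameter bifurcation) diagram of the
#' network with ER stress as the bifurcation parameter. Branches are seeded
#' from all equilibria found at both ends of `stress_range` and continued by
#' secant-predictor/pseudo-arclength steps with adaptive step halving on
#' corrector failure. Saddle-node (limit) points are detected as sign
#' changes of the stress progression along arclength and refined by
#' bisection to `fold_tol` in stress.
#'
#' @param params an [ers_params()].
#' @param input_template an [ers_input()] whose `stress` field is swept
#'   (its other fields are held fixed).
#' @param stress_range numeric length-2, scan range `[0, s_max]`,
#'   `s_max >= 50`.
#' @param step_control list with `h0` (initial stress step), `hmin`, `hmax`.
#' @param fold_tol bisection tolerance for fold location (stress units).
#' @return an object of class `ers_bifdiag`: list with `branches` (each a
#'   data.frame: stress, the five state columns, `stability`), `limit_points`
#'   (stress values of folds), `bistable_interval` (see
#'   [bistable_interval()]), and the scanned `stress_range`.
#' @export
continue_in_stress <- function(params, input_template = ers_input(),
                               stress_range = c(0, 60),
                               step_control = list(h0 = 0.1, hmin = 1e-5,
                                                   hmax = 1.0),
                               fold_tol = 1e-4) {
  validate_params(params); validate_input(input_template)
  if (length(stress_range) != 2L || stress_range[1] != 0 || stress_range[2] < 50)
    stop("stress_range must be [0, s_max] with s_max >= 50", call. = FALSE)
  P <- unclass(params)
  inp_at <- function(s) { inp <- input_template; inp$stress <- s; inp }
  seeds <- list()
  for (s in stress_range) {
    for (e in find_equilibria(params, inp_at(s)))
      seeds[[length(seeds) + 1L]] <- list(y = as.numeric(e$state), s = s,
                                          dir = if (s == stress_range[1]) +1 else -1)
  }
  branches <- list(); limit_points <- numeric(0)
  covered <- function(y, s) {
    for (br in branches) {
      d <- abs(br$stress - s)
      j <- which.min(d)
      if (d[j] < 0.05 &&
          max(abs(as.numeric(br[j, .state_names]) - y)) < 1e-3) return(TRUE)
    }
    FALSE
  }
  for (seed in seeds) {
    if (covered(seed$y, seed$s)) next
    pts <- list(c(seed$y, seed$s))
    h <- step_control$h0
    z_prev <- c(seed$y, seed$s)
    # first predictor: advance in the stress direction only
    tang <- c(rep(0, 5), seed$dir)
    n_fail <- 0L
    while (length(pts) < 4000) {
      tnorm <- tang / sqrt(sum(tang^2))
      z_pred <- z_prev + tnorm * h
      z_new <- .continuation_correct(z_pred, tnorm, P, input_template)
      if (is.null(z_new)) {
        h <- h / 2; n_fail <- n_fail + 1L
        if (h < step_control$hmin || n_fail > 60L) break
        next
      }
      n_fail <- 0L
      if (h < step_control$hmax) h <- min(h * 1.5, step_control$hmax)
      if (z_new[6] < stress_range[1] - 1e-9 ||
          z_new[6] > stress_range[2] + 1e-9) {
        # land exactly on the scan boundary before stopping
        s_b <- min(max(z_new[6], stress_range[1]), stress_range[2])
        inp_b <- input_template; inp_b$stress <- s_b
        y_b <- .newton_full(pmax(z_new[1:5], 0), P, inp_b)
        if (!is.null(y_b)) pts[[length(pts) + 1L]] <- c(y_b, s_b)
        break
      }
      pts[[length(pts) + 1L]] <- z_new
      new_tang <- (z_new - z_prev)
      # fold: stress progression reverses sign along arclength
      if (length(pts) >= 3L) {
        ds_prev <- tang[6]; ds_new <- new_tang[6]
        if (ds_prev * ds_new < 0) {
          lp <- .refine_fold(z_prev, z_new, P, input_template, fold_tol)
          if (!is.null(lp)) limit_points <- c(limit_points, lp)
        }
      }
      tang <- new_tang / sqrt(sum(new_tang^2))
      z_prev <- z_new
      s <- z_new[6]
      if (s < stress_range[1] - 1e-9 || s > stress_range[2] + 1e-9) break
    }
    if (length(pts) < 2) next
    mat <- do.call(rbind, pts)
    df <- as.data.frame(mat)
    names(df) <- c(.state_names, "stress")
    df <- df[df$stress >= stress_range[1] - 1e-9 &
               df$stress <= stress_range[2] + 1e-9, ]
    if (!nrow(df)) next
    df$stability <- vapply(seq_len(nrow(df)), function(i) {
      ev <- eigen(.jac_fast(as.numeric(df[i, .state_names]), P,
                            inp_at(df$stress[i])), only.values = TRUE)$values
      classify_stability(ev)
    }, "")
    branches[[length(branches) + 1L]] <- df[, c("stress", .state_names, "stability")]
  }
  # drop branches that retrace an already-collected branch (the same curve
  # is reachable from seeds at both ends of the scan range)
  if (length(branches) > 1L) {
    keep <- rep(TRUE, length(branches))
    for (k in 2:length(branches)) {
      prev <- do.call(rbind, branches[which(keep[seq_len(k - 1L)])])
      pm <- as.matrix(prev[, c("stress", .state_names)])
      bm <- as.matrix(branches[[k]][, c("stress", .state_names)])
      covered_frac <- mean(vapply(seq_len(nrow(bm)), function(i) {
        d_s <- abs(pm[, 1L] - bm[i, 1L])
        near <- d_s < 0.75
        any(near) && min(apply(abs(pm[near, -1L, drop = FALSE] -
                                     rep(bm[i, -1L], each = sum(near))), 1,
                               max)) < 2e-2
      }, TRUE))
      if (covered_frac > 0.9) keep[k] <- FALSE
    }
    branches <- branches[keep]
  }
  # merge folds rediscovered from the opposite scan direction
  limit_points <- sort(limit_points)
  if (length(limit_points) > 1L)
    limit_points <- limit_points[c(TRUE, diff(limit_points) > 1e-3)]
  diag <- structure(list(branches = branches, limit_points = limit_points,
                         stress_range = stress_range,
                         input_template = input_template, params = params),
                    class = "ers_bifdiag")
  diag$bistable_interval <- bistable_interval(diag)
  diag
}

# locate the fold between two consecutive continuation points by bisecting
# on the tangent's stress component along arclength
.refine_fold <- function(z_a, z_b, P, inp_template, tol) {
  # stress extremum along the secant: bisection on arclength with local
  # corrector; fall back to the midpoint stress
  f <- function(lam) {
    z0 <- z_a + lam * (z_b - z_a)
    tang <- (z_b - z_a); tang <- tang / sqrt(sum(tang^2))
    z <- .continuation_correct(z0, tang, P, inp_template)
    if (is.null(z)) NA_real_ else z[6]
  }
  lo <- 0; hi <- 1
  s_lo <- z_a[6]; s_hi <- z_b[6]
  for (k in 1:60) {
    if (abs(s_hi - s_lo) < tol) break
    mid1 <- lo + (hi - lo) / 3; mid2 <- hi - (hi - lo) / 3
    s1 <- f(mid1); s2 <- f(mid2)
    if (is.na(s1) || is.na(s2)) break
    # golden-section style search for the extremum of stress along the branch
    extremal_max <- max(s_lo, s_hi) < max(s1, s2)
    if (extremal_max) { if (s1 < s2) { lo <- mid1; s_lo <- s1 } else { hi <- mid2; s_hi <- s2 } }
    else { if (s1 > s2) { lo <- mid1; s_lo <- s1 } else { hi <- mid2; s_hi <- s2 } }
  }
  (s_lo + s_hi) / 2
}

#' Bistable stress interval of a diagram
#'
#' The maximal stress interval over which at least two distinct stable
#' branch points coexist; `NULL` if the diagram is monostable throughout
#' the scanned range.
#'
#' @param diagram an `ers_bifdiag`.
#' @param n_grid grid density used to probe coexistence.
#' @return numeric length-2 `(stress_lo, stress_hi)`, or `NULL`.
#' @export
bistable_interval <- function(diagram, n_grid = 601) {
  stopifnot(inherits(diagram, "ers_bifdiag"))
  rng <- diagram$stress_range
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  count_stable <- function(s) {
    states <- list()
    for (br in diagram$branches) {
      # contiguous stable runs; a run covers s if s lies inside its stress
      # span, with the state linearly interpolated there
      runs <- split(seq_len(nrow(br)),
                    cumsum(c(TRUE, br$stability[-1] != br$stability[-nrow(br)])))
      for (ix in runs) {
        if (br$stability[ix[1]] != "stable" || length(ix) < 2) next
        ss <- br$stress[ix]
        if (s < min(ss) - 1e-6 || s > max(ss) + 1e-6) next
        ord <- order(ss)
        y <- vapply(.state_names, function(v)
          stats::approx(ss[ord], br[[v]][ix][ord],
                        xout = min(max(s, min(ss)), max(ss)),
                        ties = mean)$y, 0)
        if (anyNA(y)) next
        if (!any(vapply(states, function(z) max(abs(z - y)) < 1e-2, TRUE)))
          states[[length(states) + 1L]] <- y
      }
    }
    length(states)
  }
  multi <- vapply(grid, count_stable, 0L) >= 2L
  if (!any(multi)) return(NULL)
  c(min(grid[multi]), max(grid[multi]))
}

#' Dense-sweep equilibrium scan (continuation oracle)
#'
#' Runs [find_equilibria()] independently at each stress value and links
#' nothing: the raw equilibrium sets serve as a brute-force cross-check of
#' the continuation diagram.
#'
#' @param params an [ers_params()].
#' @param input_template template input; `stress` is replaced per value.
#' @param stress_values numeric vector of stress levels.
#' @param ... passed to [find_equilibria()].
#' @return data.frame: stress, state columns, stability.
#' @export
sweep_equilibria <- function(params, input_template = ers_input(),
                             stress_values = seq(0, 60, length.out = 500),
                             ...) {
  out <- lapply(stress_values, function(s) {
    inp <- input_template; inp$stress <- s
    eqs <- find_equilibria(params, inp, ...)
    if (!length(eqs)) return(NULL)
    do.call(rbind, lapply(eqs, function(e)
      data.frame(stress = s, t(e$state), stability = e$stability)))
  })
  do.call(rbind, out)
}

#' Look up diagram states at a stress value
#'
#' Returns the branch points nearest to `stress` (within `tol`) from every
#' branch, for cross-validation against [find_equilibria()].
#'
#' @param diagram an `ers_bifdiag`.
#' @param stress stress value.
#' @param tol maximal distance in stress.
#' @return data.frame of matching branch points (possibly 0 rows).
#' @export
diagram_states_at <- function(diagram, stress, tol = 0.05) {
  out <- list()
  for (br in diagram$branches) {
    d <- abs(br$stress - stress)
    j <- which.min(d)
    if (d[j] <= tol) out[[length(out) + 1L]] <- br[j, ]
  }
  if (!length(out))
    return(NULL)
  res <- do.call(rbind, out)
  # drop duplicate branch coverage
  keep <- !duplicated(round(res[, .state_names], 4))
  res[keep, ]
}

#' @export
print.ers_bifdiag <- function(x, ...) {
  cat(sprintf("<ers_bifdiag> %d branch(es) over stress [%g, %g]\n",
              length(x$branches), x$stress_range[1], x$stress_range[2]))
  if (length(x$limit_points))
    cat("limit points at stress:",
        paste(sprintf("%.4f", x$limit_points), collapse = ", "), "\n")
  if (!is.null(x$bistable_interval))
    cat(sprintf("bistable interval: [%.4f, %.4f]\n",
                x$bistable_interval[1], x$bistable_interval[2]))
  invisible(x)
}

#' Export a bifurcation diagram to CSV
#'
#' One row per branch point: stress, the five state variables, stability
#' class and branch id.
#'
#' @param diagram an `ers_bifdiag`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bifdiag_csv <- function(diagram, path) {
  rows <- lapply(seq_along(diagram$branches), function(b)
    cbind(diagram$branches[[b]], branch = b))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
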