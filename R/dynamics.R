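#' Treatment events and schedules
#'
#' A treatment schedule is a constant stressor input plus an ordered list of
#' step changes applied at fixed times: stressor addition, escalation to a
#' higher level, washout (reset to zero) or addition of an autophagy
#' inducer. Only the inputs jump at an event; the state is continuous.
#'
#' @param time event time (a.u., >= 0).
#' @param field name of the [ers_input()] field to change
#'   (`"stress"`, `"tg"`, `"dtt"` or `"kaua_mult"`).
#' @param value new level (>= 0).
#' @return `treatment_event`: a list of class `ers_event`.
#' @export
treatment_event <- function(time, field, value) {
  if (!is.numeric(time) || length(time) != 1L || !is.finite(time) || time < 0)
    stop("event time must be a finite non-negative scalar", call. = FALSE)
  if (!is.character(field) || length(field) != 1L || !field %in% .input_names)
    stop("event field must be one of ", paste(.input_names, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value < 0)
    stop("event value must be a finite non-negative scalar", call. = FALSE)
  structure(list(time = time, field = field, value = value),
            class = "ers_event")
}

#' @rdname treatment_event
#' @param initial_input an [ers_input()] holding from `t = 0`.
#' @param events list of [treatment_event()]s, strictly increasing in time.
#' @param t_end simulation horizon (a.u.); all event times must be `< t_end`.
#' @return `treatment_schedule`: a list of class `ers_schedule`.
#' @export
#' @examples
#' # high tunicamycin washed out at t = 30
#' treatment_schedule(ers_input(stress = 50),
#'                    list(treatment_event(30, "stress", 0)), t_end = 200)
treatment_schedule <- function(initial_input, events = list(), t_end = 200) {
  validate_input(initial_input)
  if (inherits(events, "ers_event")) events <- list(events)
  lapply(events, function(e) {
    if (!inherits(e, "ers_event")) stop("events must be treatment_event objects",
                                        call. = FALSE)
  })
  tt <- vapply(events, `[[`, 0, "time")
  if (length(tt) > 1 && any(diff(tt) <= 0))
    stop("event times must be strictly increasing", call. = FALSE)
  if (!is.numeric(t_end) || t_end <= 0 || !is.finite(t_end))
    stop("t_end must be a positive finite scalar", call. = FALSE)
  if (length(tt) && max(tt) >= t_end)
    stop("all event times must be < t_end", call. = FALSE)
  structure(list(initial_input = initial_input, events = events, t_end = t_end),
            class = "ers_schedule")
}

# piecewise-constant input sequence: segment k holds inputs[[k]] on
# [times[k], times[k+1]]
.schedule_segments <- function(schedule) {
  tt <- c(0, vapply(schedule$events, `[[`, 0, "time"), schedule$t_end)
  inp <- schedule$initial_input
  inps <- vector("list", length(tt) - 1L)
  inps[[1L]] <- inp
  for (k in seq_along(schedule$events)) {
    e <- schedule$events[[k]]
    inp[[e$field]] <- e$value
    inps[[k + 1L]] <- inp
  }
  list(times = tt, inputs = inps)
}

#' Simulate the model under a treatment schedule
#'
#' Integrates the model piecewise between events with a stiff-capable solver
#' (`deSolve::lsoda` with the analytic Jacobian), restarting at each event so
#' that input discontinuities never fall inside an integration step. The
#' state is continuous across events; each event time appears twice in the
#' output grid (pre- and post-event rows).
#'
#' @param params an [ers_params()].
#' @param schedule a [treatment_schedule()].
#' @param init initial [ers_state()]; defaults to the physiological resting
#'   state computed by [physiological_state()].
#' @param n_per_segment number of output points per segment (>= 500 by
#'   default so plots resolve the fast transients).
#' @param rtol,atol integrator tolerances.
#' @return an object of class `ers_trajectory`: a list with `times`,
#'   a numeric `states` matrix (one row per time, columns the five state
#'   variables), the `schedule`, the `params`, and `integrator_stats`.
#' @export
simulate_model <- function(params, schedule, init = NULL,
                           n_per_segment = 500, rtol = 1e-8, atol = 1e-10) {
  validate_params(params)
  if (!inherits(schedule, "ers_schedule"))
    stop("schedule must be a treatment_schedule object", call. = FALSE)
  if (is.null(init)) init <- physiological_state(params)
  validate_state(init)
  P <- unclass(params)
  .check_admissible(init, P)
  seg <- .schedule_segments(schedule)
  derivs <- function(t, y, parms) list(.rhs_fast(y, P, parms))
  jacf <- function(t, y, parms) .jac_fast(y, P, parms)
  times <- numeric(0); states <- NULL; nsteps <- 0L
  y <- as.numeric(init)
  for (k in seq_along(seg$inputs)) {
    grid <- seq(seg$times[k], seg$times[k + 1L], length.out = max(n_per_segment, 2L))
    out <- tryCatch(
      deSolve::lsoda(y, grid, derivs, parms = seg$inputs[[k]],
                     jacfunc = jacf, jactype = "fullusr",
                     rtol = rtol, atol = atol),
      warning = function(w)
        stop("integrator failure in segment ", k, " [",
             format(seg$times[k]), ", ", format(seg$times[k + 1L]), "]: ",
             conditionMessage(w), call. = FALSE))
    nsteps <- nsteps + attr(out, "istate")[3L]
    times <- c(times, out[, 1L])
    states <- rbind(states, out[, -1L, drop = FALSE])
    y <- as.numeric(out[nrow(out), -1L])
  }
  colnames(states) <- .state_names
  structure(list(times = times, states = states, schedule = schedule,
                 params = params,
                 integrator_stats = list(rtol = rtol, atol = atol,
                                         n_segments = length(seg$inputs),
                                         n_steps = nsteps)),
            class = "ers_trajectory")
}

.check_admissible <- function(state, P) {
  if (state[["upr"]] > P$UPR_T + 1e-9 || state[["bcl2"]] > P$BCL2_T + 1e-9 ||
      state[["apo_a"]] > P$APO_T + 1e-9 ||
      state[["aut_a"]] + state[["aut_i"]] > P$AUT_T + 1e-9)
    stop("initial state outside the admissible box [0, totals]", call. = FALSE)
  invisible(state)
}

#' @export
print.ers_trajectory <- function(x, ...) {
  cat(sprintf("<ers_trajectory> %d points on [0, %g], %d segment(s)\n",
              length(x$times), max(x$times), x$integrator_stats$n_segments))
  fin <- x$states[nrow(x$states), ]
  cat("final state:", paste(sprintf("%s=%.3g", names(fin), fin), collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.ers_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Write a trajectory to CSV
#'
#' Columns: time, upr, bcl2, aut_a, aut_i, apo_a.
#'
#' @param traj an `ers_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Classify the long-run outcome of a trajectory
#'
#' Judges the cell-fate outcome on the final 10% of the horizon: apoptosis
#' if the apoptosis inducer stays above its threshold over the whole window,
#' otherwise autophagy if the active autophagy inducer stays above its
#' threshold, otherwise homeostasis. The default thresholds are half of the
#' respective total pool; the network's attracting states sit near fully
#' on/off, so any mid-range threshold separates them.
#'
#' @param traj an `ers_trajectory`.
#' @param theta_apo,theta_aut classification thresholds (a.u.); default half
#'   the respective total.
#' @return a list of class `ers_outcome` with fields `label` (one of
#'   `"homeostasis"`, `"autophagy"`, `"apoptosis"`),
#'   `onset_time_apoptosis` (first crossing time, `NULL` unless apoptotic)
#'   and `aut_peak` (time and height of the maximal autophagy excursion, or
#'   `NULL` if the trace never leaves zero).
#' @export
classify_outcome <- function(traj,
                             theta_apo = 0.5 * traj$params$APO_T,
                             theta_aut = 0.5 * traj$params$AUT_T) {
  stopifnot(inherits(traj, "ers_trajectory"))
  tt <- traj$times
  last_event <- if (length(traj$schedule$events))
    max(vapply(traj$schedule$events, `[[`, 0, "time")) else 0
  if (max(tt) - last_event < 10)
    stop("horizon too short: need >= 10 time units after the last event; ",
         "increase t_end", call. = FALSE)
  win <- tt >= max(tt) - 0.1 * (max(tt) - min(tt))
  apo <- traj$states[, "apo_a"]; aut <- traj$states[, "aut_a"]
  label <- if (all(apo[win] > theta_apo)) "apoptosis"
  else if (all(aut[win] > theta_aut)) "autophagy"
  else "homeostasis"
  onset <- NULL
  if (label == "apoptosis") {
    ix <- which(apo > theta_apo)[1L]
    onset <- tt[ix]
  }
  pk <- which.max(aut)
  aut_peak <- if (aut[pk] > 0) list(time = tt[pk], height = aut[pk]) else NULL
  structure(list(label = label, onset_time_apoptosis = onset,
                 aut_peak = aut_peak,
                 thresholds = c(theta_apo = theta_apo, theta_aut = theta_aut)),
            class = "ers_outcome")
}

#' @export
print.ers_outcome <- function(x, ...) {
  cat("<ers_outcome>", x$label)
  if (!is.null(x$onset_time_apoptosis))
    cat(sprintf(" (onset t=%.2f)", x$onset_time_apoptosis))
  if (!is.null(x$aut_peak))
    cat(sprintf(" | AUT-A peak %.3f @ t=%.2f", x$aut_peak$height, x$aut_peak$time))
  cat("\n")
  invisible(x)
}

#' Detect a transient peak in a state variable
#'
#' Returns the global maximum of the variable if the trace later falls below
#' 25% of that height before the end of the trajectory (the package's
#' operational definition of a transient excursion), and `NULL` otherwise.
#'
#' @param traj an `ers_trajectory`.
#' @param variable one of `"upr"`, `"bcl2"`, `"aut_a"`, `"aut_i"`, `"apo_a"`.
#' @param falloff fraction of the peak height the trace must drop below
#'   (default 0.25).
#' @return `NULL`, or a list with `time`, `height` and `fall_time` (first
#'   time the trace drops below `falloff * height` after the peak).
#' @export
detect_transient_peak <- function(traj, variable = "aut_a", falloff = 0.25) {
  stopifnot(inherits(traj, "ers_trajectory"))
  if (!variable %in% .state_names)
    stop("unknown state variable '", variable, "'", call. = FALSE)
  x <- traj$states[, variable]
  pk <- which.max(x)
  h <- x[pk]
  if (h <= 0) return(NULL)
  after <- which(seq_along(x) > pk & x < falloff * h)
  if (!length(after)) return(NULL)
  list(time = traj$times[pk], height = h, fall_time = traj$times[after[1L]])
}

#' Write an outcome record to JSON
#'
#' @param outcome an `ers_outcome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_outcome_json <- function(outcome, path) {
  jsonlite::write_json(
    list(label = outcome$label,
         onset_time_apoptosis = outcome$onset_time_apoptosis,
         aut_peak = outcome$aut_peak,
         thresholds = as.list(outcome$thresholds)),
    path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
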