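# Named treatment scenarios, rescue-window and washout scans, and seeded
# parameter-perturbation ensembles.

#' Standard treatment scenarios
#'
#' The registry of named treatment schedules the package's analyses are
#' built on: low/high tunicamycin (pure `stress` input at 5 and 50),
#' low/high thapsigargin (`tg = 0.25` on top of the same stress levels),
#' a dithiothreitol scenario at low stress (`dtt = 0.25`, a calibrated,
#' model-extrapolated level), autophagy-inducer pre-/co-/delayed treatment
#' against high TM and high TG (inducer at absolute activation rate 10,
#' i.e. `kaua_mult = 10 / kaua_base`; pre-treatment lead time 20 a.u.),
#' stress escalation 5 to 50, and washouts of low and high stress (the
#' high-stress washout at an early and a late time straddling the
#' reversibility threshold). Each scenario carries the long-run outcome
#' label expected under the canonical calibrated parameters.
#'
#' @param params an [ers_params()] (used to convert the absolute inducer
#'   activation rate into the `kaua_mult` factor).
#' @param kaua_abs absolute activation rate of the treated autophagy
#'   inducer (default 10).
#' @param t_post horizon after the last event (default 200 a.u.).
#' @return named list of `ers_scenario` objects (fields: `name`,
#'   `schedule`, `expected_label`, `note`).
#' @export
standard_scenarios <- function(params = canonical_parameters(),
                               kaua_abs = 10, t_post = 200) {
  km <- kaua_abs / params$kaua_base
  lead <- 20  # pre-treatment lead time, a.u.
  sc <- function(name, initial, events, expected, note, t_end = NULL) {
    tt <- vapply(events, `[[`, 0, "time")
    if (is.null(t_end)) t_end <- (if (length(tt)) max(tt) else 0) + t_post
    structure(list(name = name,
                   schedule = treatment_schedule(initial, events, t_end),
                   expected_label = expected, note = note),
              class = "ers_scenario")
  }
  ev <- treatment_event
  out <- list(
    sc("tm_low", ers_input(stress = 5), list(), "autophagy",
       "low tunicamycin: sustained autophagy-dependent survival"),
    sc("tm_high", ers_input(stress = 50), list(), "apoptosis",
       "high tunicamycin: transient autophagy peak, then apoptosis"),
    sc("tg_low", ers_input(stress = 5, tg = 0.25), list(), "apoptosis",
       "low thapsigargin: direct inducer activation abolishes the survival state"),
    sc("tg_high", ers_input(stress = 50, tg = 0.25), list(), "apoptosis",
       "high thapsigargin"),
    sc("dtt_low", ers_input(stress = 5, dtt = 0.25), list(), "apoptosis",
       "dithiothreitol at calibrated direct-action level (model-extrapolated)"),
    sc("inducer_pre_tm_high", ers_input(kaua_mult = km),
       list(ev(lead, "stress", 50)), "autophagy",
       "autophagy inducer 20 a.u. before high TM: rescue"),
    sc("inducer_co_tm_high", ers_input(stress = 50, kaua_mult = km), list(),
       "autophagy", "inducer together with high TM: rescue"),
    sc("inducer_delayed_tm_high", ers_input(stress = 50),
       list(ev(2, "kaua_mult", km)), "autophagy",
       "inducer shortly after high TM, inside the rescue window"),
    sc("inducer_pre_tg_high", ers_input(kaua_mult = km),
       list(ev(lead, "stress", 50), ev(lead + 1e-6, "tg", 0.25)), "apoptosis",
       "inducer before high TG: apoptosis still wins, onset delayed"),
    sc("inducer_co_tg_high",
       ers_input(stress = 50, tg = 0.25, kaua_mult = km), list(),
       "apoptosis", "inducer together with high TG: apoptosis, onset delayed"),
    sc("inducer_delayed_tg_high", ers_input(stress = 50, tg = 0.25),
       list(ev(2, "kaua_mult", km)), "apoptosis",
       "inducer after high TG: no rescue"),
    sc("escalation", ers_input(stress = 5), list(ev(40, "stress", 50)),
       "apoptosis", "low TM escalated to high TM: stressor effects add up"),
    sc("washout_low", ers_input(stress = 5), list(ev(40, "stress", 0)),
       "homeostasis", "low TM washed out: always reversible"),
    sc("washout_high_early", ers_input(stress = 50),
       list(ev(4, "stress", 0)), "homeostasis",
       "high TM washed out before apoptotic commitment"),
    sc("washout_high_late", ers_input(stress = 50),
       list(ev(60, "stress", 0)), "apoptosis",
       "high TM washed out after commitment: irreversible")
  )
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' @export
print.ers_scenario <- function(x, ...) {
  cat(sprintf("<scenario %s> expected %s | %s\n", x$name,
              x$expected_label %||% "?", x$note))
  invisible(x)
}

#' Run a scenario through simulation and outcome classification
#'
#' @param params an [ers_params()].
#' @param scenario an `ers_scenario` (from [standard_scenarios()]) or a
#'   scenario name.
#' @param init initial state (default: physiological state).
#' @param ... passed to [simulate_model()].
#' @return list with `trajectory` (`ers_trajectory`) and `outcome`
#'   (`ers_outcome`).
#' @export
run_scenario <- function(params, scenario, init = NULL, ...) {
  if (is.character(scenario)) {
    reg <- standard_scenarios(params)
    if (!scenario %in% names(reg))
      stop("unknown scenario '", scenario, "'", call. = FALSE)
    scenario <- reg[[scenario]]
  }
  traj <- simulate_model(params, scenario$schedule, init = init, ...)
  list(trajectory = traj, outcome = classify_outcome(traj))
}

# append an event to a schedule (the new event may not be last in time)
.with_event <- function(schedule, event, t_post = 200) {
  evs <- c(schedule$events, list(event))
  tt <- vapply(evs, `[[`, 0, "time")
  evs <- evs[order(tt)]
  treatment_schedule(schedule$initial_input, evs,
                     t_end = max(max(tt) + t_post, schedule$t_end))
}

#' Latest rescue delay for an autophagy-inducer treatment
#'
#' Scans delays at which an autophagy inducer (activation rate multiplier
#' raising the absolute rate to `kaua_abs`) is added after the stressor of
#' the base scenario, classifies each outcome, and returns the largest
#' delay that still avoids apoptosis, refined by bisection between the last
#' success and the first failure to `resolution` time units. Returns `NULL`
#' when no tested delay (including the smallest) rescues.
#'
#' @param params an [ers_params()].
#' @param base an `ers_scenario` whose schedule starts the stressor at
#'   `t = 0` (e.g. `tm_high`, `tg_high`).
#' @param kaua_abs absolute treated activation rate (default 10).
#' @param delays increasing delays (a.u.) to probe.
#' @param resolution bisection resolution (default 0.01 a.u.).
#' @param t_post horizon after the inducer event.
#' @return list with `latest_delay` (numeric or `NULL`), `grid`
#'   (data.frame delay/label), and `window_exists`.
#' @export
rescue_window_scan <- function(params, base, kaua_abs = 10,
                               delays = c(0.5, 1, 2, 5, 10, 20, 40),
                               resolution = 0.01, t_post = 200) {
  stopifnot(inherits(base, "ers_scenario"))
  if (is.unsorted(delays, strictly = TRUE))
    stop("delays must be sorted ascending", call. = FALSE)
  km <- kaua_abs / params$kaua_base
  init <- physiological_state(params)
  lab <- function(d) {
    sch <- .with_event(base$schedule, treatment_event(d, "kaua_mult", km),
                       t_post)
    traj <- simulate_model(params, sch, init = init)
    classify_outcome(traj)$label
  }
  labels <- vapply(delays, lab, "")
  ok <- labels != "apoptosis"
  if (any(diff(ok) > 0))
    stop("non-monotone rescue pattern across the delay grid; ",
         "threshold structure violated", call. = FALSE)
  if (!any(ok))
    return(list(latest_delay = NULL, window_exists = FALSE,
                grid = data.frame(delay = delays, label = labels)))
  if (all(ok)) {
    # threshold beyond the scanned grid
    return(list(latest_delay = max(delays), window_exists = TRUE,
                censored = TRUE,
                grid = data.frame(delay = delays, label = labels)))
  }
  lo <- max(delays[ok]); hi <- min(delays[!ok])
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (lab(mid) != "apoptosis") lo <- mid else hi <- mid
  }
  list(latest_delay = lo, window_exists = TRUE,
       grid = data.frame(delay = delays, label = labels))
}

#' Reversibility threshold of stressor washout
#'
#' For each washout time, resets the stress input to zero and classifies
#' the long-run outcome. Returns the bisection-refined latest washout time
#' after which the cell still returns to homeostasis; the sentinel
#' `"always"` (with `threshold = Inf`) when every tested washout is
#' reversible (low-stress trajectories never cross into the apoptotic
#' basin).
#'
#' @param params an [ers_params()].
#' @param stress_level stress held from `t = 0` until washout.
#' @param washout_times increasing washout times (a.u.).
#' @param resolution bisection resolution (default 0.01 a.u.).
#' @param t_post horizon after washout.
#' @return list with `threshold` (numeric, or `Inf`), `always_reversible`,
#'   and the classification `grid`.
#' @export
washout_scan <- function(params, stress_level,
                         washout_times = c(2, 5, 10, 20, 40, 80),
                         resolution = 0.01, t_post = 200) {
  if (is.unsorted(washout_times, strictly = TRUE))
    stop("washout_times must be sorted ascending", call. = FALSE)
  init <- physiological_state(params)
  lab <- function(w) {
    if (w <= 0) return("homeostasis")  # degenerate: never stressed
    sch <- treatment_schedule(ers_input(stress = stress_level),
                              list(treatment_event(w, "stress", 0)),
                              t_end = w + t_post)
    classify_outcome(simulate_model(params, sch, init = init))$label
  }
  labels <- vapply(washout_times, lab, "")
  ok <- labels == "homeostasis"
  if (any(diff(ok) > 0))
    stop("non-monotone washout pattern across the time grid", call. = FALSE)
  if (all(ok))
    return(list(threshold = Inf, always_reversible = TRUE,
                grid = data.frame(washout_time = washout_times, label = labels)))
  if (!any(ok))
    return(list(threshold = 0, always_reversible = FALSE,
                grid = data.frame(washout_time = washout_times, label = labels)))
  lo <- max(washout_times[ok]); hi <- min(washout_times[!ok])
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (lab(mid) == "homeostasis") lo <- mid else hi <- mid
  }
  list(threshold = lo, always_reversible = FALSE,
       grid = data.frame(washout_time = washout_times, label = labels))
}

#' Seeded parameter-perturbation ensemble
#'
#' Multiplies every rate constant (not the Michaelis constants or total
#' pools) by an independent log-normal factor with median 1 and the given
#' coefficient of variation, re-runs the core outcome matrix (low TM, high
#' TM, low TG) for each draw, and reports the fraction of draws that
#' preserve all three qualitative labels. Identical seeds yield identical
#' ensembles.
#'
#' @param params baseline [ers_params()].
#' @param n ensemble size.
#' @param cv coefficient of variation of the multiplicative perturbation
#'   (<= 0.5).
#' @param seed integer seed.
#' @return list of class `ers_ensemble`: `draws` (list of `ers_params`),
#'   `labels` (n x 3 character matrix), `preserved_fraction`, `n_redrawn`,
#'   and the `reference` labels.
#' @export
perturbation_ensemble <- function(params, n = 100, cv = 0.1, seed = 1L) {
  validate_params(params)
  if (cv < 0) stop("cv must be non-negative", call. = FALSE)
  if (cv > 0.5) stop("cv above 0.5 is outside the supported range", call. = FALSE)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  sdlog <- sqrt(log1p(cv^2))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  draws <- vector("list", n)
  n_redrawn <- 0L
  for (k in seq_len(n)) {
    repeat {
      fac <- stats::rlnorm(length(.rate_names), meanlog = 0, sdlog = sdlog)
      b <- unclass(params)
      b[.rate_names] <- Map(`*`, b[.rate_names], fac)
      p_k <- tryCatch(ers_params(.base = b), error = function(e) NULL)
      if (!is.null(p_k)) break
      n_redrawn <- n_redrawn + 1L
    }
    draws[[k]] <- p_k
  }
  core <- function(p_k) {
    init <- tryCatch(physiological_state(p_k), error = function(e) NULL)
    if (is.null(init)) return(c(NA_character_, NA_character_, NA_character_))
    one <- function(inp) {
      sch <- treatment_schedule(inp, list(), t_end = 200)
      tr <- tryCatch(simulate_model(p_k, sch, init = init,
                                    n_per_segment = 200),
                     error = function(e) NULL)
      if (is.null(tr)) NA_character_ else classify_outcome(tr)$label
    }
    c(one(ers_input(stress = 5)), one(ers_input(stress = 50)),
      one(ers_input(stress = 5, tg = 0.25)))
  }
  ref <- c("autophagy", "apoptosis", "apoptosis")
  labels <- t(vapply(draws, core, character(3)))
  colnames(labels) <- c("tm_low", "tm_high", "tg_low")
  preserved <- mean(apply(labels, 1L, function(r) all(!is.na(r) & r == ref)))
  structure(list(draws = draws, labels = labels,
                 preserved_fraction = preserved, n_redrawn = n_redrawn,
                 reference = ref, cv = cv, seed = seed),
            class = "ers_ensemble")
}

#' @export
print.ers_ensemble <- function(x, ...) {
  cat(sprintf("<ers_ensemble> n=%d cv=%g seed=%d | preserved fraction %.3f\n",
              nrow(x$labels), x$cv, x$seed, x$preserved_fraction))
  invisible(x)
}

#' Export an ensemble report to CSV
#'
#' @param ens an `ers_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ens, path) {
  df <- data.frame(draw = seq_len(nrow(ens$labels)), ens$labels,
                   preserved = apply(ens$labels, 1L, function(r)
                     all(!is.na(r) & r == ens$reference)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
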