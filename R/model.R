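.state_names <- c("upr", "bcl2", "aut_a", "aut_i", "apo_a")

#' Model state vector
#'
#' Constructs the five-component state of the ER stress decision network:
#' activity of the lumped UPR sensor (`upr`), active BCL-2 (`bcl2`), active
#' autophagy inducer (`aut_a`), its caspase-cleaved inactive form (`aut_i`)
#' and the active apoptosis inducer (`apo_a`). All activities are in
#' arbitrary units; each pool is bounded by the corresponding total in the
#' parameter set (the autophagy pool shares one total between `aut_a`,
#' `aut_i` and the uncleaved inactive fraction).
#'
#' @param upr,bcl2,aut_a,aut_i,apo_a non-negative activities (a.u.).
#' @return a named numeric vector of class `ers_state`.
#' @export
#' @examples
#' ers_state(upr = 0, bcl2 = 0.9, aut_a = 0.05, aut_i = 0, apo_a = 0.01)
ers_state <- function(upr = 0, bcl2 = 0, aut_a = 0, aut_i = 0, apo_a = 0) {
  x <- c(upr = upr, bcl2 = bcl2, aut_a = aut_a, aut_i = aut_i, apo_a = apo_a)
  validate_state(x)
  structure(x, class = "ers_state")
}

validate_state <- function(x) {
  if (!is.numeric(x) || length(x) != 5L)
    stop("state must be a numeric vector of length 5", call. = FALSE)
  if (is.null(names(x))) names(x) <- .state_names
  if (!identical(names(x), .state_names))
    stop("state components must be named ", paste(.state_names, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(x)))
    stop("non-finite state component: ",
         paste(names(x)[!is.finite(x)], collapse = ", "), call. = FALSE)
  neg <- x < 0
  if (any(neg))
    stop("negative state component: ", paste(names(x)[neg], collapse = ", "),
         call. = FALSE)
  invisible(x)
}

#' External stressor input
#'
#' Time-constant inputs to the network. `stress` is the ER stress level that
#' drives UPR activation; tunicamycin (TM) acts exclusively through this
#' input, so "TM at level s" simply means `stress = s`. `tg` is the
#' thapsigargin direct-action level, which adds activation terms on both the
#' autophagy and apoptosis inducers on top of its UPR induction. `dtt` is
#' the dithiothreitol direct-action level, adding activation on the
#' apoptosis inducer only. `kaua_mult` multiplies the autophagy-inducer
#' activation rate constant and represents treatment with a pure autophagy
#' inducer (baseline 1 = untreated).
#'
#' @param stress,tg,dtt non-negative input levels (a.u.).
#' @param kaua_mult autophagy-inducer activation multiplier (dimensionless).
#' @return a list of class `ers_input`.
#' @export
ers_input <- function(stress = 0, tg = 0, dtt = 0, kaua_mult = 1) {
  inp <- list(stress = stress, tg = tg, dtt = dtt, kaua_mult = kaua_mult)
  validate_input(inp)
  structure(inp, class = "ers_input")
}

.input_names <- c("stress", "tg", "dtt", "kaua_mult")

validate_input <- function(inp) {
  for (nm in .input_names) {
    v <- inp[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("input field '", nm, "' must be a finite scalar", call. = FALSE)
    if (v < 0)
      stop("input field '", nm, "' must be non-negative", call. = FALSE)
  }
  invisible(inp)
}

.param_names <- c(
  "UPR_T", "BCL2_T", "AUT_T", "APO_T",
  "ka_upr", "ki_upr",
  "ka_bcl2", "ki_bcl2", "upr_on_bcl2", "apo_on_bcl2",
  "ks_aut", "kaua_base", "tg_on_aut", "ki_aut", "bcl2_on_aut", "apo_on_aut",
  "cleave_rate", "kd_auti", "J_aut_act", "J_aut_in",
  "ks_apo", "auti_on_apo", "tg_on_apo", "dtt_on_apo",
  "ki_apo", "bcl2_on_apo", "aut_on_apo", "J_apo_act", "J_apo_in"
)

.michaelis_names <- c("J_aut_act", "J_aut_in", "J_apo_act", "J_apo_in")
.total_names    <- c("UPR_T", "BCL2_T", "AUT_T", "APO_T")
# every parameter that scales a flux; setting all of them to zero silences the
# vector field entirely
.rate_names <- setdiff(.param_names, c(.michaelis_names, .total_names))

#' Parameter set of the ER stress decision model
#'
#' All rate constants have dimension 1/time (relative time units), the
#' Michaelis constants (`J_*`) are dimensionless, and the totals (`*_T`) are
#' in arbitrary units. Interaction coefficients follow the wiring of the
#' network: `upr_on_bcl2` (UPR-driven BCL-2 inactivation), `apo_on_bcl2`
#' (caspase cleavage of BCL-2), `bcl2_on_aut`/`bcl2_on_apo` (BCL-2 holding
#' both inducers off), `apo_on_aut`/`aut_on_apo` (the mutual antagonism),
#' `cleave_rate` (caspase-dependent cleavage of active autophagy inducer
#' into its inactive fragment) and `auti_on_apo` (the cleaved fragment
#' feeding back positively on apoptosis activation).
#'
#' Values default to the package's pinned calibrated set; see
#' [canonical_parameters()].
#'
#' @param ... named parameter overrides, see [canonical_parameters()] for the
#'   full list of names.
#' @param .base parameter list to start from (default: the calibrated set).
#' @return a named list of class `ers_params`.
#' @export
ers_params <- function(..., .base = calibrated_default_values()) {
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), .param_names)
    if (length(bad))
      stop("unknown parameter: ", paste(bad, collapse = ", "), call. = FALSE)
    .base[names(over)] <- over
  }
  p <- .base[.param_names]
  validate_params(p)
  structure(p, class = "ers_params")
}

validate_params <- function(p) {
  miss <- setdiff(.param_names, names(p))
  if (length(miss))
    stop("missing parameter: ", paste(miss, collapse = ", "), call. = FALSE)
  for (nm in .param_names) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite scalar", call. = FALSE)
  }
  if (any(unlist(p[.rate_names]) < 0))
    stop("rate constants must be non-negative", call. = FALSE)
  if (any(unlist(p[.michaelis_names]) <= 0))
    stop("Michaelis constants must be positive", call. = FALSE)
  if (any(unlist(p[.total_names]) <= 0))
    stop("total pools must be positive", call. = FALSE)
  invisible(p)
}

# Pinned calibrated parameter set (schema version 1).  Totals are normalized
# to 1 a.u.  The set is tuned so that, simultaneously: the unstressed system
# is bistable (survival state with basal autophagy + apoptotic state,
# separated by a saddle); stress = 5 gives sustained autophagy; stress = 50
# gives a transient autophagy peak followed by apoptosis; stress = 5 with
# tg = 0.25 leaves a single (apoptotic) stable state.
calibrated_default_values <- function() {
  list(
    UPR_T = 1, BCL2_T = 1, AUT_T = 1, APO_T = 1,
    ka_upr = 0.05, ki_upr = 1.0,
    ka_bcl2 = 0.5, ki_bcl2 = 0.05, upr_on_bcl2 = 3.0, apo_on_bcl2 = 3.0,
    ks_aut = 0.01, kaua_base = 0.45, tg_on_aut = 1.0,
    ki_aut = 0.05, bcl2_on_aut = 0.8, apo_on_aut = 0.45,
    cleave_rate = 0.4, kd_auti = 0.2, J_aut_act = 0.05, J_aut_in = 0.05,
    ks_apo = 0.228, auti_on_apo = 0.24, tg_on_apo = 1.2, dtt_on_apo = 1.2,
    ki_apo = 0.015, bcl2_on_apo = 0.6, aut_on_apo = 0.228,
    J_apo_act = 0.05, J_apo_in = 0.02
  )
}

#' Canonical parameter sets
#'
#' Returns the pinned parameter set the package's analyses are based on.
#' Only the `"calibrated_default"` variant is available: a calibrated set
#' with all totals normalized to 1 a.u., tuned once (tuning script under
#' `tools/`) to reproduce the qualitative outcome matrix of the network —
#' bistability without stress, sustained autophagy at stress = 5, transient
#' autophagy followed by apoptosis at stress = 50, and loss of the survival
#' state at stress = 5 when thapsigargin acts directly (`tg = 0.25`).
#'
#' @param variant parameter-set name; `"calibrated_default"`.
#' @return an `ers_params` object carrying `variant` and `schema_version`
#'   attributes.
#' @export
#' @examples
#' p <- canonical_parameters()
#' p$kaua_base
canonical_parameters <- function(variant = "calibrated_default") {
  if (!is.character(variant) || length(variant) != 1L)
    stop("variant must be a single string", call. = FALSE)
  if (variant != "calibrated_default")
    stop("unknown parameter variant: '", variant,
         "' (available: calibrated_default)", call. = FALSE)
  p <- ers_params()
  attr(p, "variant") <- variant
  attr(p, "schema_version") <- 1L
  attr(p, "aut_pool") <- "conserved" # activation/inactivation/cleavage only
  p
}

#' Right-hand side of the model ODEs
#'
#' Each state variable follows a production-minus-consumption kinetic
#' equation. The switch-forming interactions (BCL-2 against both inducers,
#' and the mutual antagonism between the inducers) use saturating
#' Michaelis-Menten activation/inactivation terms, giving zero-order
#' ultrasensitivity; cleavage reactions (caspase acting on the autophagy
#' inducer and on BCL-2) are mass action. Stress enters only through UPR
#' activation; `tg` adds direct activation on both inducers, `dtt` on the
#' apoptosis inducer only, and `kaua_mult` scales the autophagy-inducer
#' activation rate constant.
#'
#' @param state an [ers_state()] (or named numeric vector).
#' @param params an [ers_params()].
#' @param input an [ers_input()].
#' @return named numeric vector of time derivatives (a.u. per time unit).
#' @export
ers_rhs <- function(state, params, input = ers_input()) {
  validate_state(state); validate_params(params); validate_input(input)
  d <- .rhs_fast(as.numeric(state), unclass(params), input)
  names(d) <- .state_names
  d
}

# Unvalidated core of the vector field; `y` is numeric(5) in .state_names
# order, `P` a plain list, `inp` a plain list of the four inputs.  The
# autophagy-inducer activation draws on the uncleaved inactive pool
# q = AUT_T - aut_a - aut_i; the Michaelis term is clamped at q = 0 so an
# (only numerically reachable) overdrawn pool yields zero activation rather
# than a spurious positive flux.
.rhs_fast <- function(y, P, inp) {
  u <- y[1L]; b <- y[2L]; a <- y[3L]; i <- y[4L]; p <- y[5L]
  q <- P$AUT_T - a - i
  if (q < 0) q <- 0
  v_act_a <- P$ks_aut + P$kaua_base * inp$kaua_mult + P$tg_on_aut * inp$tg
  v_in_a  <- P$ki_aut + P$bcl2_on_aut * b + P$apo_on_aut * p
  v_act_p <- P$ks_apo + P$auti_on_apo * i + P$tg_on_apo * inp$tg +
    P$dtt_on_apo * inp$dtt
  v_in_p  <- P$ki_apo + P$bcl2_on_apo * b + P$aut_on_apo * a
  r <- P$APO_T - p
  c(
    P$ka_upr * inp$stress * (P$UPR_T - u) - P$ki_upr * u,
    P$ka_bcl2 * (P$BCL2_T - b) -
      (P$ki_bcl2 + P$upr_on_bcl2 * u + P$apo_on_bcl2 * p) * b,
    v_act_a * q / (P$J_aut_act + q) -
      v_in_a * a / (P$J_aut_in + a) - P$cleave_rate * p * a,
    P$cleave_rate * p * a - P$kd_auti * i,
    v_act_p * r / (P$J_apo_act + r) - v_in_p * p / (P$J_apo_in + p)
  )
}

#' Analytic Jacobian of the model
#'
#' Exact partial derivatives of [ers_rhs()] with respect to the state, used
#' for stability classification, Newton refinement of steady states and
#' stiff integration.
#'
#' @inheritParams ers_rhs
#' @return a 5 x 5 matrix, entry (i, j) = d(rhs_i)/d(state_j).
#' @export
ers_jacobian <- function(state, params, input = ers_input()) {
  validate_state(state); validate_params(params); validate_input(input)
  J <- .jac_fast(as.numeric(state), unclass(params), input)
  dimnames(J) <- list(.state_names, .state_names)
  J
}

.jac_fast <- function(y, P, inp) {
  u <- y[1L]; b <- y[2L]; a <- y[3L]; i <- y[4L]; p <- y[5L]
  J <- matrix(0, 5L, 5L)
  q <- P$AUT_T - a - i
  v_act_a <- P$ks_aut + P$kaua_base * inp$kaua_mult + P$tg_on_aut * inp$tg
  v_in_a  <- P$ki_aut + P$bcl2_on_aut * b + P$apo_on_aut * p
  v_act_p <- P$ks_apo + P$auti_on_apo * i + P$tg_on_apo * inp$tg +
    P$dtt_on_apo * inp$dtt
  v_in_p  <- P$ki_apo + P$bcl2_on_apo * b + P$aut_on_apo * a
  # derivative of the clamped pool term q/(Ja+q): zero once the pool is empty
  dgdq <- if (q > 0) P$J_aut_act / (P$J_aut_act + q)^2 else 0
  h_a  <- a / (P$J_aut_in + a)
  dhda <- P$J_aut_in / (P$J_aut_in + a)^2
  r <- P$APO_T - p
  G_p  <- r / (P$J_apo_act + r)
  dGdp <- -P$J_apo_act / (P$J_apo_act + r)^2
  H_p  <- p / (P$J_apo_in + p)
  dHdp <- P$J_apo_in / (P$J_apo_in + p)^2

  J[1L, 1L] <- -P$ka_upr * inp$stress - P$ki_upr

  J[2L, 1L] <- -P$upr_on_bcl2 * b
  J[2L, 2L] <- -P$ka_bcl2 -
    (P$ki_bcl2 + P$upr_on_bcl2 * u + P$apo_on_bcl2 * p)
  J[2L, 5L] <- -P$apo_on_bcl2 * b

  J[3L, 2L] <- -P$bcl2_on_aut * h_a
  J[3L, 3L] <- -v_act_a * dgdq - v_in_a * dhda - P$cleave_rate * p
  J[3L, 4L] <- -v_act_a * dgdq
  J[3L, 5L] <- -P$apo_on_aut * h_a - P$cleave_rate * a

  J[4L, 3L] <- P$cleave_rate * p
  J[4L, 4L] <- -P$kd_auti
  J[4L, 5L] <- P$cleave_rate * a

  J[5L, 2L] <- -P$bcl2_on_apo * H_p
  J[5L, 3L] <- -P$aut_on_apo * H_p
  J[5L, 4L] <- P$auti_on_apo * G_p
  J[5L, 5L] <- v_act_p * dGdp - v_in_p * dHdp
  J
}

#' Serialize / read a parameter set
#'
#' Parameter sets are stored as flat YAML with `schema_version`, `variant`
#' and `aut_pool` metadata fields, one file per variant.
#'
#' @param params an `ers_params`.
#' @param path file path.
#' @return `write_params_yaml` returns `path` invisibly; `read_params_yaml`
#'   returns an `ers_params`.
#' @export
write_params_yaml <- function(params, path) {
  validate_params(params)
  doc <- c(
    list(schema_version = as.integer(attr(params, "schema_version") %||% 1L),
         variant = attr(params, "variant") %||% "custom",
         aut_pool = attr(params, "aut_pool") %||% "conserved"),
    lapply(unclass(params)[.param_names], as.numeric)
  )
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  p <- ers_params(.base = doc[.param_names])
  attr(p, "variant") <- doc$variant
  attr(p, "schema_version") <- as.integer(doc$schema_version %||% 1L)
  attr(p, "aut_pool") <- doc$aut_pool %||% "conserved"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export the model as an XPP .ode file
#'
#' Writes a plain-text description of the ODE system in the XPP dialect so
#' the model can be cross-checked in XPP-AUT, with parameter values printed
#' at full double precision.
#'
#' @param params an `ers_params`.
#' @param path output file path.
#' @param input an [ers_input()] giving the stressor levels written into the
#'   file as parameters.
#' @return `path`, invisibly.
#' @export
export_ode <- function(params, path, input = ers_input()) {
  validate_params(params); validate_input(input)
  fmt <- function(x) trimws(formatC(x, format = "g", digits = 17))
  pl <- unclass(params)
  par_lines <- vapply(
    .param_names, function(nm) paste0("par ", nm, "=", fmt(pl[[nm]])), "")
  inp_lines <- vapply(
    .input_names, function(nm) paste0("par ", nm, "=", fmt(input[[nm]])), "")
  lines <- c(
    "# ER stress decision network: UPR -| BCL2 -| {AUT, APO}; AUT -| APO;",
    "# APO cleaves AUT -> AUTI; AUTI -> APO; APO cleaves BCL2.",
    par_lines, inp_lines,
    "upr'=ka_upr*stress*(UPR_T-upr)-ki_upr*upr",
    "bcl2'=ka_bcl2*(BCL2_T-bcl2)-(ki_bcl2+upr_on_bcl2*upr+apo_on_bcl2*apo_a)*bcl2",
    paste0("aut_a'=(ks_aut+kaua_base*kaua_mult+tg_on_aut*tg)*",
           "(AUT_T-aut_a-aut_i)/(J_aut_act+AUT_T-aut_a-aut_i)",
           "-(ki_aut+bcl2_on_aut*bcl2+apo_on_aut*apo_a)*aut_a/(J_aut_in+aut_a)",
           "-cleave_rate*apo_a*aut_a"),
    "aut_i'=cleave_rate*apo_a*aut_a-kd_auti*aut_i",
    paste0("apo_a'=(ks_apo+auti_on_apo*aut_i+tg_on_apo*tg+dtt_on_apo*dtt)*",
           "(APO_T-apo_a)/(J_apo_act+APO_T-apo_a)",
           "-(ki_apo+bcl2_on_apo*bcl2+aut_on_apo*aut_a)*apo_a/(J_apo_in+apo_a)"),
    "init upr=0 bcl2=0.9 aut_a=0.05 aut_i=0 apo_a=0.01",
    "@ total=200,meth=stiff",
    "done"
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.ers_params <- function(x, ...) {
  cat("<ers_params>", attr(x, "variant") %||% "custom",
      "(schema", paste0("v", attr(x, "schema_version") %||% 1L, ")"), "\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.ers_input <- function(x, ...) {
  cat(sprintf("<ers_input> stress=%g tg=%g dtt=%g kaua_mult=%g\n",
              x$stress, x$tg, x$dtt, x$kaua_mult))
  invisible(x)
}
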