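# Optional ggplot2 figures (ggplot2 in Suggests); CSV/JSON artifacts remain
# the canonical outputs.

#' Phase-plane plot of balance curves and equilibria
#'
#' Balance curves for the autophagy inducer (green) and apoptosis inducer
#' (red) in the (aut_a, apo_a) plane; stable steady states drawn as filled
#' dots, unstable/saddle ones as open circles.
#'
#' @param nc an `ers_nullclines` object.
#' @param eqs optional list of `ers_equilibrium` to overlay.
#' @return a ggplot object.
#' @export
plot_phase_plane <- function(nc, eqs = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  curves <- rbind(cbind(nc$aut_a, curve = "AUT-A balance"),
                  cbind(nc$apo_a, curve = "APO-A balance"))
  g <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$aut_a, y = .data$apo_a,
                                    colour = .data$curve,
                                    group = interaction(.data$curve, .data$branch))) +
    ggplot2::geom_path() +
    ggplot2::scale_colour_manual(values = c("AUT-A balance" = "forestgreen",
                                            "APO-A balance" = "firebrick")) +
    ggplot2::labs(x = "AUT-A (a.u.)", y = "APO-A (a.u.)", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(eqs) && length(eqs)) {
    pts <- do.call(rbind, lapply(eqs, function(e)
      data.frame(aut_a = e$state[["aut_a"]], apo_a = e$state[["apo_a"]],
                 stable = e$stability == "stable")))
    g <- g +
      ggplot2::geom_point(data = pts,
                          ggplot2::aes(x = .data$aut_a, y = .data$apo_a,
                                       shape = .data$stable),
                          inherit.aes = FALSE, size = 3) +
      ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                  labels = c(`TRUE` = "stable",
                                             `FALSE` = "unstable"),
                                  name = NULL)
  }
  g
}

#' Time-course plot of a trajectory
#'
#' @param traj an `ers_trajectory`.
#' @param variables state variables to draw.
#' @return a ggplot object.
#' @export
plot_trajectory <- function(traj, variables = c("aut_a", "apo_a", "aut_i")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- as.data.frame(traj)
  long <- do.call(rbind, lapply(variables, function(v)
    data.frame(time = df$time, value = df[[v]], variable = v)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (a.u.)", y = "activity (a.u.)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Signal-response (bifurcation) plot
#'
#' Stable branches as solid lines, unstable/saddle branches dashed.
#'
#' @param diagram an `ers_bifdiag`.
#' @param variable state variable for the response axis.
#' @return a ggplot object.
#' @export
plot_bifurcation <- function(diagram, variable = "apo_a") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  rows <- do.call(rbind, lapply(seq_along(diagram$branches), function(b) {
    df <- diagram$branches[[b]]
    data.frame(stress = df$stress, value = df[[variable]],
               stable = df$stability == "stable", branch = b)
  }))
  rows$seg <- cumsum(c(TRUE, diff(rows$stable) != 0 | diff(rows$branch) != 0))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$stress, y = .data$value,
                                     linetype = .data$stable,
                                     group = .data$seg)) +
    ggplot2::geom_path() +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dashed"),
                                   labels = c(`TRUE` = "stable",
                                              `FALSE` = "unstable"),
                                   name = NULL) +
    ggplot2::labs(x = "ER stress (a.u.)", y = paste(variable, "(a.u.)")) +
    ggplot2::theme_minimal()
}
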