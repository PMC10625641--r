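# ggplot2 figures for the common result types.

#' Plot the per-frame energy decomposition of a trajectory
#'
#' @param traj A `dna_trajectory`.
#' @param which Energy components to show.
#' @return A ggplot object.
#' @export
plot_energy <- function(traj, which = c("elastic", "electrostatic",
                                        "stacking", "kinetic")) {
  en <- traj$energies[, which, drop = FALSE]
  d <- data.frame(time = rep(traj$time, length(which)),
                  component = rep(which, each = length(traj$time)),
                  energy = unlist(en, use.names = FALSE))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$energy,
                                  colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = "energy (pN nm)", colour = NULL)
}

#' Plot an RMSD series
#' @param rmsd Output of [rmsd_series()].
#' @return A ggplot object.
#' @export
plot_rmsd <- function(rmsd) {
  ggplot2::ggplot(rmsd, ggplot2::aes(x = .data$time, y = .data$rmsd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = "RMSD (nm)")
}

#' Plot a PMF table and optionally a fitted Morse curve
#'
#' @param pmf A `pmf_table`.
#' @param fit Optional [morse_params()] (e.g. from [fit_morse_to_pmf()]).
#' @return A ggplot object.
#' @export
plot_pmf <- function(pmf, fit = NULL) {
  g <- ggplot2::ggplot(pmf[is.finite(pmf$pmf), ],
                       ggplot2::aes(x = .data$r, y = .data$pmf)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "stacking distance (nm)", y = "PMF (pN nm)")
  if (!is.null(fit)) {
    rr <- seq(min(pmf$r), max(pmf$r), length.out = 300)
    off <- attr(fit, "offset") %||% 0
    d <- data.frame(r = rr, pmf = morse_energy(rr, fit) + off)
    g <- g + ggplot2::geom_line(data = d, colour = "firebrick")
  }
  g
}

#' Plot an opening-angle series
#' @param angles Output of [opening_angle_series()].
#' @return A ggplot object.
#' @export
plot_opening_angle <- function(angles) {
  ggplot2::ggplot(angles, ggplot2::aes(x = .data$time, y = .data$angle)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = "opening angle (deg)")
}

#' @export
autoplot.dna_trajectory <- function(object, ...) plot_energy(object, ...)
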