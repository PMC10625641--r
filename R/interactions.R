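#' Ionic condition of the solvent
#'
#' @param mg_mM Mg2+ concentration, mM.
#' @param na_mM Na+ concentration, mM.
#' @param temperature Temperature, K.
#' @return An `ion_condition`.
#' @export
ion_condition <- function(mg_mM = 0, na_mM = 0, temperature = 300) {
  if (mg_mM < 0 || na_mM < 0) stop("concentrations must be non-negative")
  if (mg_mM == 0 && na_mM == 0) stop("at least one ion concentration must be positive")
  structure(list(mg_mM = mg_mM, na_mM = na_mM, temperature = temperature),
            class = "ion_condition")
}

#' Debye screening length
#'
#' kappa^-1 = 0.304 / sqrt(I) nm with the ionic strength I (in M) summed over
#' Mg2+, Na+ and the balancing Cl-: I = c_Na + 3 c_Mg.
#'
#' @param ion An [ion_condition()].
#' @return Screening length in nm.
#' @export
debye_length <- function(ion) {
  I <- ion$na_mM / 1000 + 3 * ion$mg_mM / 1000
  if (I <= 0) stop("zero ionic strength")
  0.304 / sqrt(I)
}

#' Screened electrostatic forces
#'
#' Pairwise screened-Coulomb repulsion
#' E(r) = q_eff^2 l_B kBT exp(-kappa r) / r between all non-excluded node
#' pairs within a cutoff of three Debye lengths, with the
#' counterion-condensation effective charge per base pair. Forces are central
#' and equal-and-opposite; node pairs joined by any element are excluded.
#'
#' @param structure A `dna_structure`.
#' @param state A `dna_state`.
#' @param ion An [ion_condition()].
#' @return List with `force` (6N), `energy` (pN nm) and `debye_length` (nm).
#' @export
electrostatic_forces <- function(structure, state = NULL, ion) {
  st <- if (is.null(state)) dna_state(structure) else state
  kap <- 1 / debye_length(ion)
  r <- .cpp_eval_forces(as_cpp_sys(structure), st$pos, st$quat, kap,
                        TRUE, FALSE, kBT(ion$temperature))
  # subtract the elastic part: evaluate elastic-only and difference
  r0 <- .cpp_eval_forces(as_cpp_sys(structure), st$pos, st$quat, -1,
                         FALSE, FALSE, kBT(ion$temperature))
  list(force = as.numeric(r$force) - as.numeric(r0$force),
       energy = r$electrostatic, debye_length = 1 / kap)
}

#' Morse stacking parameters
#'
#' Defaults are the parameters fitted from potential-of-mean-force data for
#' blunt-end base stacking: well depth epsilon = 42.79 pN nm, shape
#' a = 2.668 nm^-1, equilibrium distance r0 = 0.3742 nm.
#'
#' @param epsilon Well depth, pN nm.
#' @param a Shape parameter, nm^-1.
#' @param r0 Equilibrium distance, nm.
#' @return A `morse_params` object.
#' @export
morse_params <- function(epsilon = 42.79, a = 2.668, r0 = 0.3742) {
  if (epsilon <= 0 || a <= 0 || r0 <= 0) stop("Morse parameters must be positive")
  structure(list(epsilon = epsilon, a = a, r0 = r0), class = "morse_params")
}

#' Morse stacking potential and force
#'
#' Pi(r) = epsilon (1 - exp(-a (r - r0)))^2 - epsilon, so Pi(r0) = -epsilon
#' and Pi -> 0 as r -> infinity. The maximum attractive force epsilon a / 2
#' occurs at r0 + ln(2)/a, which is also used as the stacked/unstacked
#' reporting threshold (half-depth point).
#'
#' @param r Distance(s), nm.
#' @param p A [morse_params()].
#' @return `morse_energy`: energy in pN nm; `morse_force`: force along
#'   increasing r in pN (negative = attractive), equal to -dPi/dr.
#' @export
morse_energy <- function(r, p = morse_params()) {
  ex <- exp(-p$a * (r - p$r0))
  p$epsilon * (1 - ex)^2 - p$epsilon
}

#' @rdname morse_energy
#' @export
morse_force <- function(r, p = morse_params()) {
  ex <- exp(-p$a * (r - p$r0))
  -2 * p$epsilon * p$a * ex * (1 - ex)
}

#' Stacking threshold distance
#'
#' Half-depth point r0 + ln(2)/a below which a stacking bond is reported as
#' stacked.
#' @param p A [morse_params()].
#' @return Distance in nm.
#' @export
stacking_threshold <- function(p = morse_params()) p$r0 + log(2) / p$a

#' Stacking forces of a structure
#'
#' Evaluates every stacking element: central Morse forces from the gradient
#' of the stacking energy, per-element distances and stacked/unstacked flags.
#'
#' @param structure A `dna_structure` containing stacking elements.
#' @param state A `dna_state`.
#' @return List with `force` (6N), `energy`, `distance` (per element, nm) and
#'   `stacked` (logical, r below the half-depth threshold).
#' @export
stacking_forces <- function(structure, state = NULL) {
  if (!any(structure$elements$kind == "stacking"))
    stop("structure has no stacking elements")
  st <- if (is.null(state)) dna_state(structure) else state
  r <- .cpp_eval_forces(as_cpp_sys(structure), st$pos, st$quat, -1,
                        FALSE, TRUE, kBT(structure$parameters$temperature))
  r0 <- .cpp_eval_forces(as_cpp_sys(structure), st$pos, st$quat, -1,
                         FALSE, FALSE, kBT(structure$parameters$temperature))
  idx <- which(structure$elements$kind == "stacking")
  thr <- vapply(idx, function(e)
    stacking_threshold(morse_params(structure$elements$morse[e, 1],
                                    structure$elements$morse[e, 2],
                                    structure$elements$morse[e, 3])),
    numeric(1))
  d <- as.numeric(r$stack_dist)
  list(force = as.numeric(r$force) - as.numeric(r0$force),
       energy = r$stacking, distance = d, stacked = d < thr)
}

#' Potential of mean force from distance samples
#'
#' Histogram-based distribution of a one-dimensional stacking-distance
#' reaction coordinate (no spherical-shell Jacobian), inverted to a potential
#' of mean force Pi(r) = -kBT log g(r). Empty bins are masked (NA), not
#' zero-filled, and the PMF is shifted so its global minimum is zero.
#'
#' @param samples Distance samples, nm (at least 1000).
#' @param bins Number of histogram bins (or a vector of breakpoints).
#' @param temperature Temperature, K.
#' @return A `pmf_table` data frame with columns `r` (bin centers), `g`
#'   (normalized density), `pmf` (pN nm) and `count`.
#' @export
pmf_from_distances <- function(samples, bins = 100, temperature = 300) {
  if (length(samples) < 1000) stop("at least 1000 samples are required")
  h <- graphics::hist(samples, breaks = bins, plot = FALSE)
  g <- h$density
  pmf <- ifelse(g > 0, -kBT(temperature) * log(g), NA_real_)
  pmf <- pmf - min(pmf, na.rm = TRUE)
  out <- data.frame(r = h$mids, g = g, pmf = pmf, count = h$counts)
  class(out) <- c("pmf_table", "data.frame")
  attr(out, "temperature") <- temperature
  out
}

#' Fit a Morse potential to a PMF
#'
#' Weighted least squares (weights = bin counts when available) of
#' Pi(r) = epsilon (1 - exp(-a (r - r0)))^2 - epsilon + C over the valid
#' window of the table. The PMF must show a well: its minimum must lie below
#' the right-tail plateau.
#'
#' @param pmf A `pmf_table` (columns `r`, `pmf`, optionally `count`).
#' @param p0 Optional starting [morse_params()].
#' @return A [morse_params()] with attributes `offset`, `residual` (RMS, pN
#'   nm) and `fit` (the nls object).
#' @export
fit_morse_to_pmf <- function(pmf, p0 = NULL) {
  d <- pmf[is.finite(pmf$pmf), , drop = FALSE]
  if (nrow(d) < 6) stop("too few valid PMF bins to fit")
  i_min <- which.min(d$pmf)
  tail_lvl <- stats::median(d$pmf[d$r > stats::quantile(d$r, 0.8)])
  depth <- tail_lvl - d$pmf[i_min]
  if (!is.finite(depth) || depth < 1 || i_min <= 1 || i_min >= nrow(d))
    stop("no well detected in the PMF (minimum not interior and below the right tail)")
  w <- if ("count" %in% names(d)) d$count else rep(1, nrow(d))
  start <- if (is.null(p0)) {
    list(eps = depth, a = 2.5, r0 = d$r[i_min], C = d$pmf[i_min] + depth)
  } else {
    list(eps = p0$epsilon, a = p0$a, r0 = p0$r0, C = min(d$pmf) + p0$epsilon)
  }
  fit <- minpack.lm::nlsLM(
    pmf ~ eps * (1 - exp(-a * (r - r0)))^2 - eps + C,
    data = d, start = start, weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  if (cf[["eps"]] <= 0 || cf[["a"]] <= 0 || cf[["r0"]] <= 0)
    stop("Morse fit did not converge to physical parameters")
  out <- morse_params(cf[["eps"]], cf[["a"]], cf[["r0"]])
  attr(out, "offset") <- cf[["C"]]
  attr(out, "residual") <- sqrt(mean(stats::residuals(fit)^2))
  attr(out, "fit") <- fit
  out
}

#' Read or write a PMF table
#'
#' Two-column delimited text (r_nm, pmf_pNnm) with `#`-prefixed header
#' metadata; a third and fourth column carry the density and counts when
#' available.
#'
#' @param pmf A `pmf_table`.
#' @param path File path.
#' @return `read_pmf_table` returns a `pmf_table`.
#' @export
write_pmf_table <- function(pmf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pmf_table temperature_K=%s",
                     attr(pmf, "temperature") %||% 300), con)
  writeLines("# r_nm pmf_pNnm g count", con)
  utils::write.table(pmf[, c("r", "pmf", "g", "count")], con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pmf_table
#' @export
read_pmf_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  temp <- 300
  m <- regmatches(hdr, regexpr("temperature_K=[0-9.]+", hdr))
  if (length(m) > 0) temp <- as.numeric(sub("temperature_K=", "", m[[1]]))
  d <- utils::read.table(text = lines[!grepl("^#", lines)],
                         col.names = c("r", "pmf", "g", "count"))
  class(d) <- c("pmf_table", "data.frame")
  attr(d, "temperature") <- temp
  d
}
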