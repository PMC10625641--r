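#' Base-pair step parameters between two frames
#'
#' Mid-step-triad (CEHS / 3DNA) decomposition of the relative rigid-body
#' geometry of two base-pair frames: the bending angle is split symmetrically
#' about the hinge axis, twist is measured about the mid z axis, and the
#' displacement is expressed in the mid triad as shift / slide / rise.
#' The six parameters are invariant under any rigid transform applied jointly
#' to both frames.
#'
#' @param frame_a,frame_b 3x3 orthonormal triads (columns = frame axes).
#' @param origin_a,origin_b Positions, nm.
#' @return Named numeric: shift, slide, rise (nm), tilt, roll, twist (degrees).
#' @export
compute_step_parameters <- function(frame_a, origin_a, frame_b, origin_b) {
  chk <- function(R, lab) {
    if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8)
      stop(lab, " is not an orthonormal right-handed triad")
  }
  chk(frame_a, "frame_a"); chk(frame_b, "frame_b")
  p <- .cpp_step_parameters(frame_a, origin_a, frame_b, origin_b)
  p <- as.numeric(p)
  p[4:6] <- p[4:6] * 180 / pi
  names(p) <- c("shift", "slide", "rise", "tilt", "roll", "twist")
  p
}

#' Step parameters of every element of a structure at a state
#'
#' @param structure A `dna_structure`.
#' @param state A `dna_state` (defaults to the as-built configuration).
#' @param kinds Element kinds to evaluate ("step" and/or "crossover").
#' @return A data frame with one row per element: element id, kind, node ids
#'   and the six step parameters (crossovers are evaluated with their stored
#'   frame-flip convention).
#' @export
structure_step_parameters <- function(structure, state = NULL,
                                      kinds = c("step", "crossover")) {
  st <- if (is.null(state)) dna_state(structure) else state
  el <- structure$elements
  idx <- which(el$kind %in% kinds)
  out <- lapply(idx, function(e) {
    i <- el$nodes[e, 1]; j <- el$nodes[e, 2]
    Ta <- matrix_from_quat(st$quat[i, ])
    Tb <- matrix_from_quat(st$quat[j, ])
    if (isTRUE(el$flip[e])) Tb <- Tb %*% diag(c(1, -1, -1))
    p <- as.numeric(.cpp_step_parameters(Ta, st$pos[i, ], Tb, st$pos[j, ]))
    p[4:6] <- p[4:6] * 180 / pi
    data.frame(element = e, kind = el$kind[e], node_a = i, node_b = j,
               shift = p[1], slide = p[2], rise = p[3],
               tilt = p[4], roll = p[5], twist = p[6])
  })
  do.call(rbind, out)
}

#' Assemble the diagonal mass matrix
#'
#' Time-independent diagonal generalized mass matrix with per-node blocks
#' (m, m, m, I1, I2, I3); masses follow from the node sequences, inertia from
#' the rigid-cylinder model.
#'
#' @param structure A `dna_structure`.
#' @return An object of class `dna_mass_matrix` with the 6N diagonal.
#' @export
assemble_mass_matrix <- function(structure) {
  if (n_nodes(structure) < 1) stop("empty structure")
  nd <- structure$nodes
  d <- as.numeric(t(cbind(nd$mass, nd$mass, nd$mass, nd$inertia)))
  out <- list(diag = d, n_nodes = n_nodes(structure))
  class(out) <- "dna_mass_matrix"
  out
}

#' @export
print.dna_mass_matrix <- function(x, ...) {
  cat("<dna_mass_matrix> 6N diagonal, N =", x$n_nodes,
      "; total mass", format(sum(x$diag[seq(1, length(x$diag), by = 6)]) * 3 / 3, digits = 5),
      "\n")
  invisible(x)
}

# Full internal force evaluation via the C++ kernel.
internal_forces <- function(structure, state = NULL, ion = NULL,
                            electrostatics = !is.null(ion), stacking = TRUE) {
  st <- if (is.null(state)) dna_state(structure) else state
  kap <- if (electrostatics && !is.null(ion)) 1 / debye_length(ion) else -1
  temp <- if (!is.null(ion)) ion$temperature else structure$parameters$temperature
  r <- .cpp_eval_forces(as_cpp_sys(structure), st$pos, st$quat, kap,
                        electrostatics, stacking, kBT(temp))
  list(force = as.numeric(r$force), elastic = r$elastic,
       electrostatic = r$electrostatic, stacking = r$stacking,
       stack_dist = as.numeric(r$stack_dist),
       energy = r$elastic + r$electrostatic + r$stacking)
}

#' Elastic internal forces of a structure at a state
#'
#' Scatter-add of all elastic element forces (steps, crossovers and
#' single-stranded springs); equals minus the gradient of the total elastic
#' energy with respect to the 6N nodal degrees of freedom (translations and
#' lab-frame rotation increments).
#'
#' @param structure A `dna_structure`.
#' @param state A `dna_state`.
#' @return List with `force` (6N generalized forces: pN and pN nm, node-major
#'   blocks) and `energy` (total elastic energy, pN nm).
#' @export
assemble_elastic_forces <- function(structure, state = NULL) {
  r <- internal_forces(structure, state, ion = NULL,
                       electrostatics = FALSE, stacking = FALSE)
  list(force = r$force, energy = r$elastic)
}

#' Total elastic energy
#' @inheritParams assemble_elastic_forces
#' @return Elastic energy in pN nm (non-negative; zero iff every element sits
#'   at its intrinsic geometry).
#' @export
elastic_energy <- function(structure, state = NULL) {
  assemble_elastic_forces(structure, state)$energy
}

#' Force and torque of a single element
#'
#' @param structure A `dna_structure`.
#' @param element Element index.
#' @param state A `dna_state`.
#' @return List with the 6-component generalized forces on the two nodes and
#'   the element energy. The two force resultants are equal and opposite,
#'   including the transported torque.
#' @export
elastic_element_force <- function(structure, element, state = NULL) {
  el <- structure$elements
  if (element < 1 || element > length(el$kind)) stop("no such element")
  sub <- structure
  keep <- element
  sub$elements <- list(kind = el$kind[keep],
                       nodes = el$nodes[keep, , drop = FALSE],
                       intrinsic = el$intrinsic[keep, , drop = FALSE],
                       stiffness = el$stiffness[, , keep, drop = FALSE],
                       morse = el$morse[keep, , drop = FALSE],
                       flip = el$flip[keep])
  sub$electro_exclusions <- element_pair_exclusions(sub)
  r <- internal_forces(sub, state, ion = NULL, electrostatics = FALSE,
                       stacking = TRUE)
  i <- el$nodes[element, 1]; j <- el$nodes[element, 2]
  list(node_a = i, node_b = j,
       force_a = r$force[(6 * (i - 1) + 1):(6 * i)],
       force_b = r$force[(6 * (j - 1) + 1):(6 * j)],
       energy = r$energy)
}

# Apply a 6N displacement chart (translations + lab rotation increments,
# node-major) to a state.
apply_displacement <- function(state, dx) {
  n <- nrow(state$pos)
  pos <- state$pos; quat <- state$quat
  for (i in seq_len(n)) {
    b <- 6 * (i - 1)
    pos[i, ] <- pos[i, ] + dx[b + 1:3]
    th <- dx[b + 4:6]
    a <- sqrt(sum(th^2))
    dq <- if (a < 1e-14) c(1, th / 2) else c(cos(a / 2), sin(a / 2) * th / a)
    q <- quat_mul_r(dq, quat[i, ])
    quat[i, ] <- q / sqrt(sum(q^2))
  }
  state$pos <- pos; state$quat <- quat
  state
}

quat_mul_r <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Static energy minimization
#'
#' Minimizes the total internal energy (elastic, plus screened electrostatics
#' when an ion condition is given, plus stacking) over the 6N-dimensional
#' configuration manifold. Rotations are updated multiplicatively through a
#' local chart that is re-centered between quasi-Newton sweeps (L-BFGS-B on
#' the chart). Deterministic given the structure and settings.
#'
#' @param structure A `dna_structure`.
#' @param ion Optional [ion_condition()]; `NULL` disables electrostatics.
#' @param tol Convergence tolerance on the max-norm of the internal force
#'   vector, pN (default 1e-3).
#' @param state Starting `dna_state` (defaults to as-built).
#' @param max_outer Maximum number of quasi-Newton sweeps.
#' @param stacking Include stacking bonds in the minimized energy.
#' @return The minimized `dna_state`, with attributes `residual` (pN),
#'   `iterations` and `energy`.
#' @export
static_minimize <- function(structure, ion = NULL, tol = 1e-3, state = NULL,
                            max_outer = 100, stacking = TRUE) {
  st <- if (is.null(state)) dna_state(structure) else state
  nd <- 6L * n_nodes(structure)
  use_elec <- !is.null(ion)
  resid <- function(s) max(abs(internal_forces(structure, s, ion,
                                               use_elec, stacking)$force))
  r0 <- resid(st)
  if (r0 <= tol) {
    attr(st, "residual") <- r0; attr(st, "iterations") <- 0L
    attr(st, "energy") <- internal_forces(structure, st, ion, use_elec, stacking)$energy
    return(st)
  }
  it <- 0L
  repeat {
    it <- it + 1L
    fn <- function(dx) {
      s <- apply_displacement(st, dx)
      internal_forces(structure, s, ion, use_elec, stacking)$energy
    }
    gr <- function(dx) {
      s <- apply_displacement(st, dx)
      -internal_forces(structure, s, ion, use_elec, stacking)$force
    }
    opt <- stats::optim(rep(0, nd), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = 50, factr = 1e4))
    st <- apply_displacement(st, opt$par)
    r <- resid(st)
    if (r <= tol) break
    if (it >= max_outer)
      stop(sprintf("static_minimize did not converge: residual %.3g pN after %d sweeps (tol %.3g)",
                   r, it, tol))
  }
  attr(st, "residual") <- resid(st)
  attr(st, "iterations") <- it
  attr(st, "energy") <- internal_forces(structure, st, ion, use_elec, stacking)$energy
  st
}
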