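#' Solvent model
#'
#' @param viscosity Dynamic viscosity in pN ns / nm^2 (0.89 corresponds to
#'   890 uN s/m^2, water at 300 K).
#' @param temperature Temperature, K.
#' @return A `solvent_model` with the derived thermal energy `kBT` (pN nm).
#' @export
solvent_model <- function(viscosity = 0.89, temperature = 300) {
  if (viscosity <= 0 || temperature < 0) stop("invalid solvent parameters")
  structure(list(viscosity = viscosity, temperature = temperature,
                 kBT = kBT(temperature)),
            class = "solvent_model")
}

#' Single-sphere mobility block
#'
#' Diagonal 6x6 block of the generalized Rotne-Prager-Yamakawa tensor for one
#' sphere: translational mobility 1/(6 pi eta a) I3, rotational
#' 1/(8 pi eta a^3) I3, no coupling.
#'
#' @param radius Hydrodynamic radius, nm.
#' @param solvent A [solvent_model()].
#' @return 6x6 mobility block (nm/(pN ns) and 1/(pN nm ns)).
#' @export
self_mobility_block <- function(radius, solvent = solvent_model()) {
  if (radius <= 0) stop("radius must be positive")
  eta <- solvent$viscosity
  diag(c(rep(1 / (6 * pi * eta * radius), 3),
         rep(1 / (8 * pi * eta * radius^3), 3)))
}

#' Pair mobility coupling block
#'
#' 6x6 generalized Rotne-Prager-Yamakawa coupling between two equal spheres:
#' translation-translation (Oseen plus finite-size correction),
#' rotation-rotation, and the antisymmetric translation-rotation coupling;
#' for separations below 2a the regularized overlapping-sphere expressions
#' are used, continuous at r = 2a.
#'
#' @param r_vec Separation vector (from the first to the second sphere), nm.
#' @param radius Common hydrodynamic radius, nm.
#' @param solvent A [solvent_model()].
#' @return 6x6 coupling block (motion of sphere 1 in response to force and
#'   torque on sphere 2).
#' @export
pair_mobility_block <- function(r_vec, radius, solvent = solvent_model()) {
  if (radius <= 0) stop("radius must be positive")
  if (sqrt(sum(r_vec^2)) < 1e-12) stop("r = 0 with distinct node ids")
  .cpp_pair_mobility(as.numeric(r_vec), radius, solvent$viscosity)
}

#' Assemble the mobility matrix of a structure
#'
#' Dense symmetric positive-definite 6N x 6N generalized
#' Rotne-Prager-Yamakawa operator built from identical spheres at the node
#' positions; positive definiteness is certified by a Cholesky factorization.
#'
#' @param structure A `dna_structure` (all nodes must share one hydrodynamic
#'   radius).
#' @param state A `dna_state` (defaults to as-built).
#' @param solvent A [solvent_model()].
#' @return A `dna_mobility` object wrapping the matrix.
#' @export
assemble_mobility <- function(structure, state = NULL, solvent = solvent_model()) {
  st <- if (is.null(state)) dna_state(structure) else state
  rad <- unique(structure$nodes$radius)
  if (length(rad) != 1)
    stop("all nodes must share one hydrodynamic radius")
  Xi <- .cpp_assemble_mobility(st$pos, rad, solvent$viscosity)
  ch <- tryCatch(chol(Xi), error = function(e) NULL)
  if (is.null(ch))
    stop("mobility matrix is not positive definite for this configuration")
  out <- list(matrix = Xi, radius = rad, solvent = solvent)
  class(out) <- "dna_mobility"
  out
}

#' Friction matrix from a mobility matrix
#'
#' Z = Xi^-1 via symmetric factorization; the Cholesky factor of Z is
#' retained for drawing correlated random forces.
#'
#' @param mobility A `dna_mobility` (or a bare SPD matrix).
#' @return A `dna_friction` with elements `matrix` (Z) and `chol` (lower
#'   factor L with Z = L L').
#' @export
friction_from_mobility <- function(mobility) {
  Xi <- if (inherits(mobility, "dna_mobility")) mobility$matrix else mobility
  if (kappa_cond(Xi) > 1e12)
    stop("mobility matrix is ill-conditioned (condition number > 1e12)")
  ch_xi <- chol(Xi)
  Z <- chol2inv(ch_xi)
  Z <- (Z + t(Z)) / 2
  L <- t(chol(Z))
  structure(list(matrix = Z, chol = L), class = "dna_friction")
}

kappa_cond <- function(A) {
  ev <- range(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  if (ev[1] <= 0) return(Inf)
  ev[2] / ev[1]
}
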