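#' Finite-element representation of a structured DNA assembly
#'
#' A `dna_structure` holds rigid base-pair nodes (position, orientation triad,
#' mass, principal inertia, hydrodynamic radius, sequence) and typed finite
#' elements connecting them: intrahelical steps, interhelical crossovers,
#' single-stranded connections and breakable Morse stacking bonds. Elastic
#' elements carry a six-component intrinsic geometry (shift, slide, rise in
#' nm; tilt, roll, twist in degrees) and a 6x6 stiffness matrix (pN/nm and
#' pN nm/rad^2); stacking elements carry Morse parameters instead.
#'
#' @param nodes List with matrices `pos` (N x 3, nm), `quat` (N x 4 unit
#'   quaternions), vectors `mass`, `radius`, `sequence`, and matrix `inertia`
#'   (N x 3).
#' @param elements List with `kind` (character), `nodes` (m x 2 integer),
#'   `intrinsic` (m x 6), `stiffness` (6 x 6 x m), `morse` (m x 3),
#'   `flip` (logical; evaluate the second frame flipped by 180 degrees about
#'   its x axis, used for crossovers between antiparallel helices).
#' @param metadata Named list (name, provenance, parameter table name,
#'   annotations such as arm or edge node sets).
#' @param parameters Parameter table used to build the structure.
#' @return An object of class `dna_structure`.
#' @seealso [build_duplex()], [build_bundle()], [build_switch_toy()],
#'   [build_wireframe_polygon()]
#' @export
dna_structure <- function(nodes, elements, metadata = list(),
                          parameters = default_parameter_table()) {
  x <- structure(list(nodes = nodes, elements = elements,
                      metadata = metadata, parameters = parameters),
                 class = "dna_structure")
  x$electro_exclusions <- element_pair_exclusions(x)
  validate_structure(x)
  x
}

element_kinds <- c("step", "crossover", "ssdna", "stacking")

# Electrostatic exclusions: bonded neighborhoods. Every node pair joined by
# an element is excluded, and so are second neighbors (graph distance 2 in
# the element graph): those contacts are governed by the bonded model, and a
# point-charge interaction at sub-nanometre bonded distances would only add
# spurious stiffness and near-overlap singularities.
element_pair_exclusions <- function(x) {
  en <- x$elements$nodes
  extra <- x$metadata$exclusion_edges
  if (!is.null(extra)) en <- rbind(en, matrix(as.integer(as.matrix(extra)), ncol = 2))
  if (is.null(en) || nrow(en) == 0) return(matrix(integer(), 0, 2))
  n <- nrow(x$nodes$pos)
  nb <- vector("list", n)
  for (r in seq_len(nrow(en))) {
    i <- en[r, 1]; j <- en[r, 2]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  out <- list()
  for (i in seq_len(n)) {
    d2 <- unique(c(nb[[i]], unlist(nb[nb[[i]]])))
    d2 <- d2[d2 > i]
    if (length(d2) > 0) out[[length(out) + 1]] <- cbind(i, d2)
  }
  pr <- do.call(rbind, out)
  colnames(pr) <- NULL
  unique(pr)
}

#' Validate a dna_structure
#'
#' Checks the type invariants: orthonormal right-handed frames (tolerance
#' 1e-9), positive masses and radii, element node references, symmetric
#' positive-semidefinite-shaped stiffness storage, no stiffness on stacking
#' elements, and no duplicate element on the same ordered pair and kind.
#'
#' @param x A `dna_structure`.
#' @return Invisibly `x`; errors describe the offending record.
#' @export
validate_structure <- function(x) {
  nd <- x$nodes
  n <- nrow(nd$pos)
  if (n < 1) stop("structure has no nodes")
  stopifnot(nrow(nd$quat) == n, length(nd$mass) == n, length(nd$radius) == n)
  if (any(nd$mass <= 0)) stop("node masses must be positive")
  if (any(nd$radius <= 0)) stop("hydrodynamic radii must be positive")
  for (i in seq_len(n)) {
    R <- matrix_from_quat(nd$quat[i, ])
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      stop("node ", i, ": orientation triad is not orthonormal")
    if (abs(det(R) - 1) > 1e-9)
      stop("node ", i, ": orientation is not a proper rotation")
  }
  el <- x$elements
  m <- length(el$kind)
  if (m > 0) {
    if (!all(el$kind %in% element_kinds))
      stop("unknown element kind: ", paste(setdiff(el$kind, element_kinds), collapse = ", "))
    if (any(el$nodes < 1 | el$nodes > n))
      stop("element ", which(el$nodes[, 1] < 1 | el$nodes[, 1] > n |
                               el$nodes[, 2] < 1 | el$nodes[, 2] > n)[1],
           ": node reference out of range")
    if (any(el$nodes[, 1] == el$nodes[, 2]))
      stop("element node ids must be distinct")
    key <- paste(el$kind, el$nodes[, 1], el$nodes[, 2])
    if (anyDuplicated(key))
      stop("duplicate element on the same ordered pair and kind: ", key[duplicated(key)][1])
    for (e in seq_len(m)) {
      K <- el$stiffness[, , e]
      if (max(abs(K - t(K))) > 1e-9)
        stop("element ", e, ": stiffness matrix is not symmetric")
      if (el$kind[e] == "stacking") {
        if (any(K != 0)) stop("element ", e, ": stacking elements carry no stiffness matrix")
        if (any(!is.finite(el$morse[e, ])) || any(el$morse[e, ] <= 0))
          stop("element ", e, ": invalid Morse parameters")
      }
    }
  }
  invisible(x)
}

#' @export
print.dna_structure <- function(x, ...) {
  n <- nrow(x$nodes$pos)
  tab <- table(factor(x$elements$kind, levels = element_kinds))
  cat("<dna_structure>", x$metadata$name %||% "", "\n")
  cat("  nodes:", n, " (", format(sum(x$nodes$mass), digits = 4), "mass units )\n")
  cat("  elements:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

n_nodes <- function(x) nrow(x$nodes$pos)
n_elements <- function(x) length(x$elements$kind)

#' Current configuration and velocities of a structure
#'
#' A `dna_state` bundles the 6N generalized coordinates (positions plus
#' orientation quaternions) and optionally velocities (nm/ns and rad/ns, lab
#' frame) at a simulation time.
#'
#' @param structure A `dna_structure` (supplies the initial configuration).
#' @param vel Optional 6N velocity vector (node-major blocks of three
#'   translational then three angular components).
#' @param time Time stamp in ns.
#' @return A `dna_state`.
#' @export
dna_state <- function(structure, vel = NULL, time = 0) {
  out <- list(pos = structure$nodes$pos, quat = structure$nodes$quat,
              vel = vel, time = time)
  class(out) <- "dna_state"
  out
}

as_state <- function(x, structure) {
  if (inherits(x, "dna_state")) x else dna_state(structure)
}

# Flatten a structure into the list consumed by the C++ kernels. Angles are
# converted to radians; node charges follow the counterion-condensation
# effective charge per base pair (half for single-stranded marker nodes).
as_cpp_sys <- function(x) {
  nd <- x$nodes
  n <- nrow(nd$pos)
  mass6 <- as.numeric(t(cbind(nd$mass, nd$mass, nd$mass, nd$inertia)))
  kind_code <- match(x$elements$kind, element_kinds) - 1L
  m <- length(kind_code)
  intr <- x$elements$intrinsic
  if (m > 0) {
    intr[, 4:6] <- intr[, 4:6] * pi / 180
  } else {
    intr <- matrix(0, 0, 6)
  }
  morse <- x$elements$morse
  morse[is.na(morse)] <- 0
  q <- ifelse(nd$sequence == "-", x$parameters$q_eff / 2, x$parameters$q_eff)
  excl <- x$electro_exclusions
  list(
    mass6 = mass6,
    radius = nd$radius,
    charge = q,
    el_kind = kind_code,
    el_nodes = matrix(as.integer(x$elements$nodes - 1L), ncol = 2),
    el_intrinsic = intr,
    el_stiff = if (m > 0) x$elements$stiffness else array(0, c(6, 6, 0)),
    el_morse = if (m > 0) morse else matrix(0, 0, 3),
    el_flip = as.logical(x$elements$flip %||% rep(FALSE, m)),
    exclusions = matrix(as.integer(excl - 1L), ncol = 2),
    lB = x$parameters$bjerrum_length
  )
}

# Empty element set, appended to by the builders.
empty_elements <- function() {
  list(kind = character(), nodes = matrix(integer(), 0, 2),
       intrinsic = matrix(numeric(), 0, 6),
       stiffness = array(numeric(), c(6, 6, 0)),
       morse = matrix(numeric(), 0, 3), flip = logical())
}

add_element <- function(el, kind, i, j, intrinsic = rep(0, 6),
                        stiffness = matrix(0, 6, 6), morse = rep(NA_real_, 3),
                        flip = FALSE) {
  el$kind <- c(el$kind, kind)
  el$nodes <- rbind(el$nodes, c(as.integer(i), as.integer(j)))
  el$intrinsic <- rbind(el$intrinsic, as.numeric(intrinsic))
  el$stiffness <- array(c(el$stiffness, stiffness),
                        c(6, 6, dim(el$stiffness)[3] + 1))
  el$morse <- rbind(el$morse, as.numeric(morse))
  el$flip <- c(el$flip, flip)
  dimnames(el$intrinsic) <- NULL
  dimnames(el$morse) <- NULL
  dimnames(el$nodes) <- NULL
  el
}
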