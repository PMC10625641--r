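# Trajectory analysis: superposition, fluctuations, quasi-harmonic and
# normal-mode frequencies, correlated motions, step-parameter statistics and
# angle observables.

# Kabsch superposition: rotation/translation minimizing weighted RMSD of
# x (n x 3) onto ref (n x 3).
kabsch <- function(x, ref, w = NULL) {
  n <- nrow(x)
  if (is.null(w)) w <- rep(1, n)
  w <- w / sum(w)
  cx <- colSums(x * w); cr <- colSums(ref * w)
  xc <- sweep(x, 2, cx); rc <- sweep(ref, 2, cr)
  H <- t(xc * w) %*% rc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, shift = cr, center = cx,
       aligned = sweep(xc %*% t(R), 2, cr, `+`))
}

# Positions of all frames superposed onto a reference (mass-weighted).
superposed_positions <- function(traj, ref = NULL, weights = NULL) {
  nf <- n_frames(traj)
  n <- dim(traj$pos)[1]
  ref <- ref %||% traj$pos[, , 1]
  out <- array(0, c(n, 3, nf))
  for (k in seq_len(nf)) out[, , k] <- kabsch(traj$pos[, , k], ref, weights)$aligned
  out
}

#' RMSD time series
#'
#' Root-mean-square deviation of node positions from a reference state after
#' optimal (least-squares) rigid superposition of every frame.
#'
#' @param traj A `dna_trajectory`.
#' @param ref Reference `dna_state` (defaults to the first frame).
#' @return Data frame with `time` (ns) and `rmsd` (nm).
#' @export
rmsd_series <- function(traj, ref = NULL) {
  refp <- if (is.null(ref)) traj$pos[, , 1] else ref$pos
  nf <- n_frames(traj)
  r <- vapply(seq_len(nf), function(k) {
    al <- kabsch(traj$pos[, , k], refp)$aligned
    sqrt(mean(rowSums((al - refp)^2)))
  }, numeric(1))
  data.frame(time = traj$time, rmsd = r)
}

#' RMSF profile
#'
#' Per-node root-mean-square fluctuation about the mean configuration of the
#' superposed trajectory.
#'
#' @param traj A `dna_trajectory`.
#' @return Data frame with `node` and `rmsf` (nm); the mean configuration is
#'   attached as attribute `mean`.
#' @export
rmsf_profile <- function(traj) {
  al <- superposed_positions(traj)
  mean_cfg <- apply(al, c(1, 2), mean)
  al2 <- superposed_positions(traj, ref = mean_cfg)
  mean_cfg <- apply(al2, c(1, 2), mean)
  dev <- sweep(al2, c(1, 2), mean_cfg)
  rmsf <- sqrt(apply(dev^2, 1, sum) / dim(al2)[3])
  out <- data.frame(node = seq_len(nrow(mean_cfg)), rmsf = rmsf)
  attr(out, "mean") <- mean_cfg
  attr(out, "deviations") <- dev
  out
}

#' Overlap coefficient between two fluctuation profiles
#'
#' Normalized dot product x . y / (|x| |y|) of two vectorized per-node
#' profiles; 1 for identical shapes, 0 for orthogonal ones, invariant under
#' scaling.
#'
#' @param x,y Numeric vectors (or `rmsf_profile()` outputs).
#' @return Scalar in [-1, 1].
#' @export
overlap_coefficient <- function(x, y) {
  if (is.data.frame(x)) x <- x$rmsf
  if (is.data.frame(y)) y <- y$rmsf
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero-norm profile")
  sum(x * y) / (nx * ny)
}

new_mode_set <- function(values, vectors, freq, shapes, zero) {
  out <- list(values = values, vectors = vectors, frequency = freq,
              shapes = shapes, zero = zero)
  class(out) <- "dna_modes"
  out
}

#' @export
print.dna_modes <- function(x, ...) {
  nz <- sum(!x$zero)
  cat("<dna_modes>", length(x$values), "modes (", nz, "with finite frequency )\n")
  if (nz > 0)
    cat("  lowest frequencies (rad/ns):",
        paste(format(utils::head(sort(x$frequency[!x$zero]), 5), digits = 4),
              collapse = ", "), "\n")
  invisible(x)
}

#' Quasi-harmonic (PCA) modes of a trajectory
#'
#' Builds the fluctuation matrix sigma of the superposed position trajectory,
#' mass-weights it (Sigma = M^1/2 sigma M^1/2 with the translational masses),
#' and eigen-decomposes. Frequencies follow the quasi-harmonic relation
#' omega_i = sqrt(kBT / Lambda_i); mode shapes are M^-1/2 phi_i. Rigid-body
#' motion is removed by the superposition; near-zero-variance modes are
#' flagged and excluded from the frequency report.
#'
#' @param traj A `dna_trajectory`.
#' @param mass_matrix A [assemble_mass_matrix()] result.
#' @param temperature Temperature, K.
#' @return A `dna_modes` object (eigenvalues sorted descending).
#' @export
pca_modes <- function(traj, mass_matrix, temperature = 300) {
  al <- superposed_positions(traj)
  n <- dim(al)[1]; nf <- dim(al)[3]
  X <- matrix(aperm(al, c(2, 1, 3)), nrow = 3 * n)  # 3N x F, node-major xyz
  X <- X - rowMeans(X)
  sig <- tcrossprod(X) / nf
  m3 <- rep(mass_matrix$diag[seq(1, 6 * n, by = 6)], each = 3)
  sq <- sqrt(m3)
  Sig <- sig * (sq %o% sq)
  e <- eigen(Sig, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  zero <- vals < max(vals) * 1e-10
  freq <- ifelse(zero, NA_real_, sqrt(kBT(temperature) / vals))
  shapes <- e$vectors / sq
  new_mode_set(vals, e$vectors, freq, shapes, zero)
}

#' Normal mode analysis at an equilibrium state
#'
#' Numerically differentiates the total internal force to obtain the
#' stiffness matrix and solves the generalized eigenproblem
#' K phi = omega^2 M phi in vacuum (no solvent damping). The state must be an
#' equilibrium (force residual below `force_tol`); a free structure has
#' exactly six near-zero rigid-body modes.
#'
#' @param structure A `dna_structure`.
#' @param state An equilibrium `dna_state`.
#' @param ion Optional [ion_condition()] matching the minimization.
#' @param force_tol Maximum allowed force residual, pN.
#' @param h Finite-difference step (nm / rad).
#' @return A `dna_modes` object: eigenvalues are omega^2 (rad^2/ns^2) sorted
#'   ascending, `frequency` in rad/ns, `zero` flags the rigid-body block
#'   (|omega| below 1e-3 times the smallest internal mode).
#' @export
nma_modes <- function(structure, state = NULL, ion = NULL, force_tol = 1e-2,
                      h = 1e-5) {
  st <- if (is.null(state)) dna_state(structure) else state
  fr <- internal_forces(structure, st, ion, !is.null(ion), TRUE)
  if (max(abs(fr$force)) > force_tol)
    stop(sprintf("state is not an equilibrium: max |F| = %.3g pN exceeds %g",
                 max(abs(fr$force)), force_tol))
  n6 <- 6L * n_nodes(structure)
  K <- matrix(0, n6, n6)
  for (k in seq_len(n6)) {
    dx <- rep(0, n6); dx[k] <- h
    fp <- internal_forces(structure, apply_displacement(st, dx), ion,
                          !is.null(ion), TRUE)$force
    fm <- internal_forces(structure, apply_displacement(st, -dx), ion,
                          !is.null(ion), TRUE)$force
    K[, k] <- -(fp - fm) / (2 * h)
  }
  K <- (K + t(K)) / 2
  M <- assemble_mass_matrix(structure)$diag
  isq <- 1 / sqrt(M)
  A <- K * (isq %o% isq)
  e <- eigen(A, symmetric = TRUE)
  w2 <- rev(pmax(e$values, 0))            # ascending
  vec <- e$vectors[, rev(seq_len(n6))]
  freq <- sqrt(w2)
  # rigid-body (and other unconstrained) modes: below 1e-3 times the
  # smallest genuinely finite mode, identified across the numerical-zero gap
  finite_w2 <- w2[w2 > max(w2) * 1e-10]
  internal_min <- if (length(finite_w2)) sqrt(min(finite_w2)) else Inf
  zero <- freq < 1e-3 * internal_min
  shapes <- vec * isq
  new_mode_set(w2, vec, freq, shapes, zero)
}

#' Pearson and generalized correlation maps
#'
#' Node-by-node correlated-motion maps from the superposed trajectory.
#' Pearson: scalar correlation of the 3-D displacement vectors via the trace
#' of the cross-covariance over the product of RMSFs. Generalized: mutual
#' information I between the two 3-D displacement sets mapped to
#' r = sqrt(1 - exp(-2 I / 3)), estimated with the Kraskov k-nearest-neighbor
#' estimator (default k = 6) or a Gaussian-copula fallback for small samples.
#'
#' @param traj A `dna_trajectory` with at least 100 frames.
#' @param estimator "ksg" or "gaussian".
#' @param k Neighbor count for the KSG estimator.
#' @return List with matrices `pearson` (unit diagonal, values in [-1, 1])
#'   and `generalized` (values in [0, 1]).
#' @export
correlation_maps <- function(traj, estimator = c("ksg", "gaussian"), k = 6) {
  estimator <- match.arg(estimator)
  if (n_frames(traj) < 100) stop("at least 100 frames are required")
  prof <- rmsf_profile(traj)
  dev <- attr(prof, "deviations")      # n x 3 x F
  n <- dim(dev)[1]
  pear <- matrix(1, n, n)
  gen <- matrix(1, n, n)
  for (i in seq_len(n)) {
    di <- t(dev[i, , ])                # F x 3
    for (j in seq_len(n)) {
      if (j < i) next
      dj <- t(dev[j, , ])
      cc <- sum(diag(crossprod(di, dj))) / dim(di)[1]
      pear[i, j] <- pear[j, i] <- cc / (prof$rmsf[i] * prof$rmsf[j])
      if (j == i) next
      g <- generalized_correlation(di, dj, estimator = estimator, k = k)
      gen[i, j] <- gen[j, i] <- g
    }
  }
  list(pearson = pear, generalized = gen)
}

#' Generalized (mutual-information) correlation of two displacement sets
#'
#' @param x,y Matrices (samples x d).
#' @param estimator "ksg" (Kraskov k-NN) or "gaussian" (Gaussian-copula /
#'   normal-scores covariance determinant).
#' @param k Neighbor count for KSG.
#' @return r = sqrt(1 - exp(-2 I / d)) in [0, 1].
#' @export
generalized_correlation <- function(x, y, estimator = c("ksg", "gaussian"),
                                    k = 6) {
  estimator <- match.arg(estimator)
  x <- as.matrix(x); y <- as.matrix(y)
  d <- ncol(x)
  I <- mutual_information(x, y, estimator = estimator, k = k)
  sqrt(1 - exp(-2 * I / d))
}

#' Mutual information between two multivariate samples
#'
#' @inheritParams generalized_correlation
#' @return Mutual information in nats (non-negative).
#' @export
mutual_information <- function(x, y, estimator = c("ksg", "gaussian"), k = 6) {
  estimator <- match.arg(estimator)
  x <- as.matrix(x); y <- as.matrix(y)
  if (estimator == "ksg") {
    .cpp_knn_mi(x, y, as.integer(k))
  } else {
    ns <- function(m) apply(m, 2, function(c) stats::qnorm(rank(c) / (length(c) + 1)))
    xs <- ns(x); ys <- ns(y)
    C <- stats::cov(cbind(xs, ys))
    dx <- ncol(x)
    I <- -0.5 * log(det(C) / (det(C[1:dx, 1:dx, drop = FALSE]) *
                                det(C[-(1:dx), -(1:dx), drop = FALSE])))
    max(I, 0)
  }
}

#' Step-parameter distributions along a trajectory
#'
#' Evaluates the six base-pair step parameters for every element of the
#' requested kinds in every frame.
#'
#' @param traj A `dna_trajectory`.
#' @param structure The `dna_structure` that produced it.
#' @param kinds Element kinds ("step", "crossover").
#' @return List with `samples` (long data frame: frame, element, parameter,
#'   value) and `summary` (mean and sd per element and parameter).
#' @export
step_parameter_distributions <- function(traj, structure,
                                         kinds = c("step", "crossover")) {
  el <- structure$elements
  idx <- which(el$kind %in% kinds)
  if (length(idx) == 0) stop("no elements of the requested kind")
  nf <- n_frames(traj)
  pieces <- vector("list", nf)
  for (f in seq_len(nf)) {
    st <- frame_state(traj, f)
    sp <- structure_step_parameters(structure, st, kinds)
    sp$frame <- f
    pieces[[f]] <- sp
  }
  all <- do.call(rbind, pieces)
  long <- stats::reshape(
    all, direction = "long",
    varying = c("shift", "slide", "rise", "tilt", "roll", "twist"),
    v.names = "value", timevar = "parameter",
    times = c("shift", "slide", "rise", "tilt", "roll", "twist"))
  rownames(long) <- NULL
  agg_m <- stats::aggregate(value ~ parameter + element,
                            long, function(v) c(mean = mean(v), sd = stats::sd(v)))
  summ <- data.frame(parameter = agg_m$parameter, element = agg_m$element,
                     mean = agg_m$value[, "mean"], sd = agg_m$value[, "sd"])
  list(samples = long[, c("frame", "element", "kind", "parameter", "value")],
       summary = summ)
}

# Least-squares line direction through a set of points (unit vector).
fit_axis <- function(p) {
  pc <- sweep(p, 2, colMeans(p))
  s <- svd(pc)
  if (s$d[1] < 1e-9 || (nrow(p) > 2 && s$d[1] < 3 * s$d[2]))
    stop("degenerate axis fit: node set is not elongated")
  s$v[, 1]
}

#' Angle observables along a trajectory
#'
#' Computes per-frame angles from node-set annotations created by the
#' builders: `opening` (angle between the two fitted arm axes, 0 for the
#' closed/collinear state), `interior_vertex` (in-plane angle between
#' adjacent polygon edges at each vertex) and `out_of_plane` (angle between
#' each edge axis and the best-fit structure plane).
#'
#' @param traj A `dna_trajectory`.
#' @param structure The annotated `dna_structure`.
#' @param definition One of "opening", "interior_vertex", "out_of_plane".
#' @return Data frame with `time`, `angle` (degrees) and, for per-vertex or
#'   per-edge definitions, an index column.
#' @export
measure_angles <- function(traj, structure,
                           definition = c("opening", "interior_vertex",
                                          "out_of_plane")) {
  definition <- match.arg(definition)
  ann <- structure$metadata$annotations
  nf <- n_frames(traj)
  if (definition == "opening") {
    arms <- ann$arms
    if (is.null(arms)) stop("structure carries no arm annotation")
    refs <- ann$arm_axis_ref
    ang <- vapply(seq_len(nf), function(f) {
      p <- traj$pos[, , f]
      axes <- lapply(1:2, function(a) {
        if (!is.null(refs)) {
          # rigid-body arm axis: superpose the as-built arm onto the frame
          # and carry its reference axis along (immune to internal bending)
          fit <- kabsch(structure$nodes$pos[arms[[a]], ], p[arms[[a]], ])
          as.numeric(fit$R %*% refs[[a]])
        } else {
          fit_axis(p[arms[[a]], ])
        }
      })
      acos(pmin(1, abs(sum(axes[[1]] * axes[[2]])))) * 180 / pi
    }, numeric(1))
    return(data.frame(time = traj$time, angle = ang))
  }
  edges <- ann$edges
  if (is.null(edges)) stop("structure carries no edge annotation")
  ne <- length(edges)
  out <- list()
  for (f in seq_len(nf)) {
    p <- traj$pos[, , f]
    axes <- lapply(edges, function(id) fit_axis(p[id, ]))
    cents <- lapply(edges, function(id) colMeans(p[id, ]))
    if (definition == "interior_vertex") {
      endpoints <- lapply(seq_len(ne), function(e) {
        pr <- as.numeric((p[edges[[e]], ] %*% axes[[e]]) - sum(cents[[e]] * axes[[e]]))
        rbind(cents[[e]] + min(pr) * axes[[e]], cents[[e]] + max(pr) * axes[[e]])
      })
      for (v in seq_len(ne)) {
        e_in <- v; e_out <- (v %% ne) + 1
        # the shared vertex is where the two closest edge ends meet
        dmat <- as.matrix(stats::dist(rbind(endpoints[[e_in]], endpoints[[e_out]])))[1:2, 3:4]
        idx <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
        vpos <- (endpoints[[e_in]][idx[1], ] + endpoints[[e_out]][idx[2], ]) / 2
        d1 <- axes[[e_in]]; d2 <- axes[[e_out]]
        if (sum(d1 * (cents[[e_in]] - vpos)) < 0) d1 <- -d1
        if (sum(d2 * (cents[[e_out]] - vpos)) < 0) d2 <- -d2
        a <- acos(pmin(1, pmax(-1, sum(d1 * d2)))) * 180 / pi
        out[[length(out) + 1]] <- data.frame(time = traj$time[f], index = v,
                                             angle = a)
      }
    } else {
      pc <- sweep(p, 2, colMeans(p))
      nrm <- svd(pc)$v[, 3]
      for (e in seq_len(ne)) {
        a <- asin(pmin(1, abs(sum(axes[[e]] * nrm)))) * 180 / pi
        out[[length(out) + 1]] <- data.frame(time = traj$time[f], index = e,
                                             angle = a)
      }
    }
  }
  do.call(rbind, out)
}

#' Opening-angle time series of a switch structure
#'
#' The axis of each arm is obtained per frame by rigid superposition of the
#' as-built arm onto the frame (carrying the reference axis along), so the
#' measure reflects whole-arm motion rather than internal bending. An
#' optional running mean over the axis vectors separates the slow opening
#' motion from fast thermal bending noise of the short arms.
#'
#' @param traj A `dna_trajectory`.
#' @param structure The annotated switch `dna_structure`.
#' @param smooth_frames Odd window length (frames) for a running mean of the
#'   arm axis vectors; 1 disables smoothing.
#' @return Data frame with `time` and `angle` (degrees).
#' @export
opening_angle_series <- function(traj, structure, smooth_frames = 1L) {
  if (smooth_frames <= 1L) return(measure_angles(traj, structure, "opening"))
  ann <- structure$metadata$annotations
  arms <- ann$arms; refs <- ann$arm_axis_ref
  nf <- n_frames(traj)
  axes <- lapply(1:2, function(a) {
    t(vapply(seq_len(nf), function(f) {
      fit <- kabsch(structure$nodes$pos[arms[[a]], ], traj$pos[arms[[a]], , f])
      as.numeric(fit$R %*% refs[[a]])
    }, numeric(3)))
  })
  w <- rep(1 / smooth_frames, smooth_frames)
  smooth_axis <- function(A) {
    S <- apply(A, 2, function(col) {
      s <- stats::filter(col, w, sides = 2)
      s[is.na(s)] <- col[is.na(s)]
      as.numeric(s)
    })
    S / sqrt(rowSums(S^2))
  }
  a1 <- smooth_axis(axes[[1]]); a2 <- smooth_axis(axes[[2]])
  ang <- acos(pmin(1, abs(rowSums(a1 * a2)))) * 180 / pi
  data.frame(time = traj$time, angle = ang)
}
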