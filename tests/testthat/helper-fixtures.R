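# Shared fixtures and small oracles, all generated in code.

random_rotation_matrix <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  dnadyn:::matrix_from_quat(q)
}

# A single free hydrodynamic bead (no elements).
free_node_structure <- function(radius = 1.1) {
  m <- dnadyn:::base_pair_mass("avg")
  nodes <- list(pos = matrix(0, 1, 3), quat = matrix(c(1, 0, 0, 0), 1, 4),
                mass = m, inertia = dnadyn:::node_inertia(m),
                radius = radius, sequence = "avg")
  dna_structure(nodes, dnadyn:::empty_elements(), metadata = list(name = "free_node"))
}

# Two nodes joined by one isotropic spring with rest length L0 (the linear
# system used for PCA/NMA equivalence checks). Rotational DOFs are free.
spring_dimer_structure <- function(k = 200, L0 = 2) {
  m <- dnadyn:::base_pair_mass("avg")
  nodes <- list(pos = rbind(c(0, 0, 0), c(0, 0, L0)),
                quat = rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)),
                mass = rep(m, 2), inertia = dnadyn:::node_inertia(rep(m, 2)),
                radius = rep(1.1, 2), sequence = rep("avg", 2))
  K <- matrix(0, 6, 6); K[1, 1] <- k
  el <- dnadyn:::add_element(dnadyn:::empty_elements(), "ssdna", 1, 2,
                             intrinsic = c(0, 0, L0, 0, 0, 0), stiffness = K)
  dna_structure(nodes, el, metadata = list(name = "spring_dimer"))
}

# Randomly perturb positions and orientations of a state.
perturb_state <- function(state, sd_pos = 0.05, sd_rot = 0.1) {
  n <- nrow(state$pos)
  state$pos <- state$pos + matrix(rnorm(3 * n, 0, sd_pos), ncol = 3)
  for (i in seq_len(n)) {
    th <- rnorm(3, 0, sd_rot)
    a <- sqrt(sum(th^2))
    dq <- c(cos(a / 2), sin(a / 2) * th / a)
    q <- dnadyn:::quat_mul_r(dq, state$quat[i, ])
    state$quat[i, ] <- q / sqrt(sum(q^2))
  }
  state
}

# Rigidly transform a whole state (same rotation and shift for every node).
rigid_transform_state <- function(state, R, shift) {
  n <- nrow(state$pos)
  state$pos <- t(R %*% t(state$pos)) + matrix(shift, n, 3, byrow = TRUE)
  qR <- dnadyn:::quat_from_matrix(R)
  for (i in seq_len(n)) {
    q <- dnadyn:::quat_mul_r(qR, state$quat[i, ])
    state$quat[i, ] <- q / sqrt(sum(q^2))
  }
  state
}

# Wrap a single state as a one-frame trajectory (for the angle observables).
state_as_trajectory <- function(state) {
  n <- nrow(state$pos)
  tr <- list(pos = array(state$pos, c(n, 3, 1)),
             quat = array(state$quat, c(n, 4, 1)),
             vel = matrix(0, 6 * n, 1), time = 0,
             energies = data.frame(elastic = 0, electrostatic = 0,
                                   stacking = 0, kinetic = 0),
             n_nodes = n)
  class(tr) <- "dna_trajectory"
  tr
}

# Central-difference gradient of the total energy on the 6N chart.
numeric_energy_gradient <- function(structure, state, h = 1e-6,
                                    ion = NULL, stacking = TRUE) {
  n6 <- 6L * nrow(state$pos)
  g <- numeric(n6)
  for (k in seq_len(n6)) {
    dx <- rep(0, n6); dx[k] <- h
    ep <- dnadyn:::internal_forces(structure, dnadyn:::apply_displacement(state, dx),
                                   ion, !is.null(ion), stacking)$energy
    em <- dnadyn:::internal_forces(structure, dnadyn:::apply_displacement(state, -dx),
                                   ion, !is.null(ion), stacking)$energy
    g[k] <- (ep - em) / (2 * h)
  }
  g
}

# Net force and net torque (about the origin) of a 6N generalized force.
net_force_torque <- function(force, pos) {
  fm <- matrix(force, ncol = 6, byrow = TRUE)
  net_f <- colSums(fm[, 1:3, drop = FALSE])
  tq <- fm[, 4:6, drop = FALSE]
  for (i in seq_len(nrow(pos)))
    tq[i, ] <- tq[i, ] + c(pos[i, 2] * fm[i, 3] - pos[i, 3] * fm[i, 2],
                           pos[i, 3] * fm[i, 1] - pos[i, 1] * fm[i, 3],
                           pos[i, 1] * fm[i, 2] - pos[i, 2] * fm[i, 1])
  list(force = net_f, torque = colSums(tq))
}

# Minimal caDNAno-dialect design: two antiparallel helices, scaffold crossover
# at the right end.
write_minimal_cadnano <- function(path, n = 12) {
  seg <- function(prev_h, prev_i, next_h, next_i) list(prev_h, prev_i, next_h, next_i)
  scaf0 <- lapply(seq_len(n) - 1L, function(i) {
    seg(if (i == 0) -1 else 0, i - 1, if (i == n - 1) 1 else 0,
        if (i == n - 1) n - 1 else i + 1)
  })
  scaf1 <- lapply(seq_len(n) - 1L, function(i) {
    # helix 1 runs 3'->5' along increasing i: next index decreases
    seg(if (i == n - 1) 0 else 1, if (i == n - 1) n - 1 else i + 1,
        if (i == 0) -1 else 1, i - 1)
  })
  empty <- lapply(seq_len(n), function(i) seg(-1, -1, -1, -1))
  doc <- list(name = "minimal_two_helix",
              vstrands = list(
                list(num = 0, row = 0, col = 0, scaf = scaf0, stap = empty,
                     loop = as.list(rep(0, n)), skip = as.list(rep(0, n))),
                list(num = 1, row = 0, col = 1, scaf = scaf1, stap = empty,
                     loop = as.list(rep(0, n)), skip = as.list(rep(0, n)))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  path
}
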