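test_that("step parameters reproduce canonical cases and frame invariance", {
  # coincident frames displaced along z
  p <- compute_step_parameters(diag(3), c(0, 0, 0), diag(3), c(0, 0, 0.34))
  expect_equal(unname(p), c(0, 0, 0.34, 0, 0, 0), tolerance = 1e-12)

  # ideal duplex step
  d <- build_duplex(5)
  sp <- structure_step_parameters(d)
  expect_equal(sp$rise, rep(0.34, 4), tolerance = 1e-10)
  expect_equal(sp$twist, rep(34.3, 4), tolerance = 1e-10)
  expect_equal(max(abs(c(sp$shift, sp$slide, sp$tilt, sp$roll))), 0, tolerance = 1e-10)

  # invariance under a joint rigid transform
  set.seed(42)
  for (rep in 1:5) {
    Ta <- random_rotation_matrix(); Tb <- random_rotation_matrix()
    ra <- rnorm(3); rb <- rnorm(3)
    p1 <- compute_step_parameters(Ta, ra, Tb, rb)
    R <- random_rotation_matrix(); s <- rnorm(3)
    p2 <- compute_step_parameters(R %*% Ta, R %*% ra + s, R %*% Tb, R %*% rb + s)
    expect_equal(p1, p2, tolerance = 1e-10)
  }

  # round trip through the inverse construction
  set.seed(7)
  for (rep in 1:10) {
    Ta <- random_rotation_matrix(); ra <- rnorm(3)
    pr <- c(rnorm(3, 0, 0.3), runif(3, -60, 60))
    fb <- dnadyn:::step_frame_from_parameters(Ta, ra, pr)
    expect_equal(unname(compute_step_parameters(Ta, ra, fb$frame, fb$origin)),
                 pr, tolerance = 1e-8)
  }

  # degenerate anti-parallel frames
  expect_error(compute_step_parameters(diag(3), c(0, 0, 0),
                                       dnadyn:::rot_x(pi), c(0, 0, 1)),
               "degenerate")
})

test_that("mass matrix is diagonal with sequence masses and cylinder inertia", {
  d <- build_duplex(6, "AAAAAA")
  M <- assemble_mass_matrix(d)
  expect_equal(length(M$diag), 36)
  mt <- M$diag[seq(1, 36, by = 6)]
  expect_equal(sum(mt), sum(d$nodes$mass))
  expect_true(all(mt == mt[1]))
  # rotational entries follow the rigid-cylinder model
  expect_equal(M$diag[4], d$nodes$mass[1] * (3 + 0.34^2) / 12)
  expect_equal(M$diag[6], d$nodes$mass[1] / 2)
  empty <- build_duplex(2)
  empty$nodes$pos <- empty$nodes$pos[0, , drop = FALSE]
  expect_error(assemble_mass_matrix(empty), "empty")
})

test_that("element forces are equilibrium-consistent, restoring and third-law", {
  d <- build_duplex(3)
  ef <- elastic_element_force(d, 1)
  expect_lt(max(abs(c(ef$force_a, ef$force_b))), 1e-9)
  expect_equal(ef$energy, 0, tolerance = 1e-12)

  # stretch the rise by delta: restoring axial force ~ K_rise * delta
  delta <- 1e-4
  st <- dna_state(d)
  st$pos[2, 3] <- st$pos[2, 3] + delta
  st$pos[3, 3] <- st$pos[3, 3] + delta
  ef2 <- elastic_element_force(d, 1, st)
  k_rise <- default_parameter_table()$k_stretch
  expect_equal(ef2$force_b[3], -k_rise * delta, tolerance = 1e-3)
  expect_lt(ef2$force_b[3], 0) # restoring, pushes node 2 back down
  # third law including torque transport: net force and torque vanish
  # (element 1 joins nodes 1 and 2)
  f12 <- rep(0, 18)
  f12[1:6] <- ef2$force_a; f12[7:12] <- ef2$force_b
  nt <- net_force_torque(f12, st$pos)
  expect_lt(max(abs(c(nt$force, nt$torque))), 1e-9)
})

test_that("assembled elastic forces equal minus the energy gradient", {
  set.seed(3)
  d <- build_duplex(6)
  st <- perturb_state(dna_state(d))
  f <- assemble_elastic_forces(d, st)
  g <- numeric_energy_gradient(d, st, stacking = FALSE)
  expect_lt(max(abs(f$force + g)) / max(abs(g)), 1e-6)

  # zero force at the as-built equilibrium, also after a global rigid motion
  st0 <- dna_state(d)
  expect_lt(max(abs(assemble_elastic_forces(d, st0)$force)), 1e-8)
  str <- rigid_transform_state(st0, random_rotation_matrix(), rnorm(3))
  expect_lt(max(abs(assemble_elastic_forces(d, str)$force)), 1e-8)
  # elastic energy is invariant and non-negative
  expect_equal(elastic_energy(d, str), 0, tolerance = 1e-12)
  expect_gte(elastic_energy(d, st), 0)
})

test_that("internal forces of an isolated structure conserve momentum", {
  set.seed(11)
  w <- build_switch_toy(8, 2, n_helices = 2)
  st <- perturb_state(dna_state(w), 0.03, 0.05)
  r <- dnadyn:::internal_forces(w, st, ion = NULL, electrostatics = FALSE)
  nt <- net_force_torque(r$force, st$pos)
  scale <- max(abs(r$force))
  expect_lt(max(abs(c(nt$force, nt$torque))) / scale, 1e-7)
})

test_that("twist deviations wrap at +-180 degrees", {
  # a crossover-like element whose intrinsic twist is near -180 while the
  # configuration sits near +180 must carry near-zero energy, not ~360 deg^2
  d <- build_duplex(2, twist = 179)
  d$elements$intrinsic[1, 6] <- -181 # same geometry modulo 360
  e <- elastic_energy(d)
  expect_lt(e, 1e-6)
})

test_that("static minimization restores a perturbed duplex", {
  d <- build_duplex(8)
  # already minimal: returned unchanged with zero iterations
  st0 <- static_minimize(d, tol = 1e-3)
  expect_equal(attr(st0, "iterations"), 0L)
  expect_equal(st0$pos, d$nodes$pos)

  # one step twisted by 5 degrees: converges back to zero elastic energy
  st <- dna_state(d)
  qz <- dnadyn:::quat_from_matrix(dnadyn:::rot_z(5 * pi / 180))
  for (i in 5:8) {
    q <- dnadyn:::quat_mul_r(qz, st$quat[i, ])
    st$quat[i, ] <- q / sqrt(sum(q^2))
  }
  expect_gt(elastic_energy(d, st), 1)
  stm <- static_minimize(d, state = st, tol = 1e-4)
  expect_lt(attr(stm, "energy"), 1e-6)
  expect_lt(attr(stm, "residual"), 1e-4)

  # two disconnected, mutually repelling duplexes have no bound state
  d1 <- build_duplex(4)
  nodes <- d1$nodes
  d2pos <- d1$nodes$pos; d2pos[, 1] <- d2pos[, 1] + 1.5
  nodes$pos <- rbind(d1$nodes$pos, d2pos)
  nodes$quat <- rbind(d1$nodes$quat, d1$nodes$quat)
  nodes$mass <- rep(d1$nodes$mass, 2)
  nodes$inertia <- rbind(d1$nodes$inertia, d1$nodes$inertia)
  nodes$radius <- rep(1.1, 8)
  nodes$sequence <- rep("avg", 8)
  el <- d1$elements
  el2 <- dnadyn:::empty_elements()
  for (k in 1:3) {
    el2 <- dnadyn:::add_element(el2, "step", k, k + 1,
                                intrinsic = el$intrinsic[k, ], stiffness = el$stiffness[, , k])
    el2 <- dnadyn:::add_element(el2, "step", 4 + k, 5 + k,
                                intrinsic = el$intrinsic[k, ], stiffness = el$stiffness[, , k])
  }
  pair <- dna_structure(nodes, el2, metadata = list(name = "repelling_pair"))
  expect_error(static_minimize(pair, ion = ion_condition(na_mM = 20),
                               tol = 1e-6, max_outer = 2),
               "did not converge")
})
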