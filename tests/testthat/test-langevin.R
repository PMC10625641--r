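test_that("initial velocities are Maxwell-Boltzmann with variance kBT/m", {
  d <- build_duplex(4)
  M <- assemble_mass_matrix(d)
  set.seed(1)
  draws <- replicate(4000, init_velocities(M, 300))
  v1 <- draws[1, ] # a translational DOF
  expect_equal(var(v1), kBT(300) / M$diag[1], tolerance = 0.05)
  expect_lt(abs(mean(v1)), 3 * sd(v1) / sqrt(length(v1)))
  expect_equal(init_velocities(M, 0), rep(0, 24))
})

test_that("random forces satisfy the discrete fluctuation-dissipation relation", {
  # correlated 2x2 friction block (diagonal plus coupling)
  Z <- matrix(c(2, 0.8, 0.8, 1.5), 2)
  fr <- list(matrix = Z, chol = t(chol(Z)))
  class(fr) <- "dna_friction"
  set.seed(2)
  R <- replicate(1e5, draw_random_force(fr, dt_ps = 5, temperature = 300))
  target <- 2 * kBT(300) * Z / 0.005
  expect_equal(var(R[1, ]), target[1, 1], tolerance = 0.02)
  expect_equal(var(R[2, ]), target[2, 2], tolerance = 0.02)
  expect_equal(cov(R[1, ], R[2, ]), target[1, 2], tolerance = 0.03)
  expect_equal(draw_random_force(fr, 5, 0), c(0, 0))
})

test_that("the scheme damps velocities by the exact GJF factor at T = 0", {
  m <- 0.01; g <- 1.3; dt <- 5
  s <- gjf_step(0.7, 1.2, function(x) 0 * x, m, g, dt, temperature = 0)
  c0 <- (dt / 1000) * g / (2 * m)
  expect_equal(s$v, 1.2 * (1 - c0) / (1 + c0), tolerance = 1e-12)
  # and positions advance by b dt v
  expect_equal(s$x, 0.7 + (dt / 1000) * 1.2 * m / (m + (dt / 1000) * g / 2),
               tolerance = 1e-12)
})

test_that("flat-potential dynamics diffuses with D = kBT / gamma", {
  set.seed(3)
  g <- 18.45
  x <- dnadyn:::.cpp_gjf1d(400000L, 0.005, 0.001, g, kBT(300), 0L,
                           0, 0, 0, 0, 0, 0, 0, 1L)
  lag <- 200L # 1 ns
  dx <- diff(x[seq(1, length(x), by = lag)])
  D <- mean(dx^2) / 2
  se <- sd(dx^2) / sqrt(length(dx)) / 2
  expect_lt(abs(D - kBT(300) / g), 3 * se)
})

test_that("simulations are bit-reproducible given the seed", {
  d <- build_duplex(5)
  proto <- simulation_protocol(n_steps = 400L, output_stride = 100L, seed = 42,
                               stacking = FALSE)
  t1 <- run_simulation(d, proto)
  t2 <- run_simulation(d, proto)
  expect_identical(t1$pos, t2$pos)
  expect_identical(t1$vel, t2$vel)
  proto$seed <- 43
  t3 <- run_simulation(d, proto)
  expect_false(identical(t1$pos, t3$pos))
})

test_that("orientations stay normalized along a trajectory", {
  d <- build_duplex(6)
  proto <- simulation_protocol(n_steps = 2000L, output_stride = 500L, seed = 7,
                               stacking = FALSE)
  tr <- run_simulation(d, proto)
  qn <- apply(tr$quat, c(1, 3), function(q) abs(sqrt(sum(q^2)) - 1))
  expect_lt(max(qn), 1e-9)
})

test_that("deterministic dynamics is dissipative", {
  set.seed(8)
  d <- build_duplex(6)
  st <- perturb_state(dna_state(d), 0.02, 0.03)
  st$vel <- rep(0, 36)
  proto <- simulation_protocol(n_steps = 3000L, temperature = 0,
                               output_stride = 100L, seed = 1, stacking = FALSE)
  tr <- run_simulation(d, proto, start = st)
  etot <- tr$energies$elastic + tr$energies$kinetic
  expect_true(all(diff(etot) <= 1e-8 * max(etot)))
  expect_lt(tail(etot, 1), 1e-6 * etot[1])
})

test_that("an equilibrated duplex satisfies equipartition of elastic energy", {
  d <- build_duplex(12)
  proto <- simulation_protocol(n_steps = 20000L, output_stride = 40L,
                               friction_update_interval = 2000L, seed = 5,
                               stacking = FALSE)
  tr <- run_simulation(d, proto)
  i0 <- seq_len(floor(n_frames(tr) * 0.2))
  e_mean <- mean(tr$energies$elastic[-i0])
  # 6 (N-1) internal quadratic coordinates, kBT/2 each
  expect_equal(e_mean, 3 * 11 * kBT(300), tolerance = 0.10)
  # kinetic energy carries kBT/2 per DOF as well
  expect_equal(mean(tr$energies$kinetic[-i0]), 0.5 * 72 * kBT(300),
               tolerance = 0.10)
})

test_that("ion schedules step the screening and are recorded per frame", {
  w <- build_switch_toy(8, 2, n_helices = 2)
  sched <- ion_schedule(list(ion_condition(25), ion_condition(5)), c(0.5, 0.5))
  proto <- simulation_protocol(n_steps = 200L, ion_schedule = sched,
                               output_stride = 50L, seed = 2,
                               friction_update_interval = 1000L)
  tr <- run_simulation(w, proto)
  expect_equal(length(unique(round(tr$kappa, 6))), 2)
  # electrostatic energy drops when the screening strengthens? here salt is
  # lowered, so the recorded electrostatic energy must rise at the switch
  e_by_seg <- tapply(tr$energies$electrostatic, tr$kappa, mean)
  expect_gt(max(e_by_seg), min(e_by_seg))
})
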