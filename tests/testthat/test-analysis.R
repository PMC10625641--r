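make_traj <- function(pos_list, quat = NULL) {
  n <- nrow(pos_list[[1]])
  nf <- length(pos_list)
  tr <- list(pos = array(unlist(pos_list), c(n, 3, nf)),
             quat = array(rep(c(1, 0, 0, 0), each = n, times = nf), c(n, 4, nf)),
             vel = matrix(0, 6 * n, nf), time = seq_len(nf) - 1,
             n_nodes = n)
  class(tr) <- "dna_trajectory"
  tr
}

test_that("RMSD is superposition-invariant with a closed-form single-node case", {
  set.seed(1)
  ref <- matrix(rnorm(30), 10, 3)
  # copies of the reference: zero
  tr <- make_traj(list(ref, ref, ref))
  expect_equal(rmsd_series(tr)$rmsd, rep(0, 3), tolerance = 1e-10)
  # rigidly moved copies: still zero after superposition
  R <- random_rotation_matrix()
  moved <- t(R %*% t(ref)) + matrix(c(3, -1, 2), 10, 3, byrow = TRUE)
  tr2 <- make_traj(list(ref, moved))
  expect_lt(rmsd_series(tr2)$rmsd[2], 1e-10)
  # one node displaced by d in an N-node frame -> d/sqrt(N) before fitting;
  # with optimal superposition the value can only decrease
  disp <- ref; disp[1, ] <- disp[1, ] + c(0, 0, 1)
  raw <- sqrt(sum((disp - ref)^2) / 10)
  expect_equal(raw, 1 / sqrt(10), tolerance = 1e-12)
  expect_lte(rmsd_series(make_traj(list(ref, disp)))$rmsd[2], raw)
})

test_that("RMSF profiles and overlap coefficients behave as documented", {
  set.seed(2)
  base <- matrix(rnorm(24, sd = 3), 8, 3)
  frames <- lapply(1:200, function(i) base + matrix(rnorm(24, 0, 0.1), 8, 3))
  tr <- make_traj(frames)
  prof <- rmsf_profile(tr)
  expect_true(all(prof$rmsf > 0))
  # superposition absorbs 6 of the 24 DOFs: sqrt(3)*0.1*sqrt(1 - 6/24)
  expect_equal(mean(prof$rmsf), sqrt(3) * 0.1 * sqrt(0.75), tolerance = 0.1)
  expect_equal(overlap_coefficient(prof, prof), 1, tolerance = 1e-12)
  expect_equal(overlap_coefficient(prof$rmsf, 2 * prof$rmsf), 1, tolerance = 1e-12)
  expect_equal(overlap_coefficient(c(1, 0), c(0, 1)), 0)
  expect_error(overlap_coefficient(c(0, 0), c(1, 1)), "zero-norm")
  # rigid transforms of the whole trajectory leave the profile unchanged
  R <- random_rotation_matrix()
  frames2 <- lapply(frames, function(p) t(R %*% t(p)) + 5)
  prof2 <- rmsf_profile(make_traj(frames2))
  expect_equal(prof2$rmsf, prof$rmsf, tolerance = 1e-8)
})

test_that("PCA and NMA agree on a linear system and count rigid modes", {
  # two nodes bound by an isotropic spring: one internal position mode with
  # omega = sqrt(2k/m) (reduced mass m/2)
  k <- 200
  s <- spring_dimer_structure(k = k, L0 = 2)
  m <- s$nodes$mass[1]
  omega_ref <- sqrt(2 * k / m)

  nm <- nma_modes(s)
  # 12 DOF, one internal mode: 6 rigid-body plus 5 free node rotations
  expect_equal(sum(nm$zero), 11)
  expect_equal(max(nm$frequency[!nm$zero]), omega_ref, tolerance = 1e-4)

  proto <- simulation_protocol(n_steps = 60000L, output_stride = 10L,
                               friction_update_interval = 3000L, seed = 13,
                               stacking = FALSE)
  tr <- run_simulation(s, proto)
  M <- assemble_mass_matrix(s)
  pc <- pca_modes(tr, M)
  # superposition removes 5 DOFs of a 2-point cloud; one dominant mode remains
  omega_pca <- min(pc$frequency[!pc$zero], na.rm = TRUE)
  expect_equal(omega_pca, omega_ref, tolerance = 0.05)

  # a free elastic structure has exactly six near-zero modes
  nmd <- nma_modes(build_duplex(5))
  expect_equal(sum(nmd$zero), 6)
  # non-equilibrium states are rejected
  st <- dna_state(s); st$pos[2, 3] <- st$pos[2, 3] + 0.5
  expect_error(nma_modes(s, st), "not an equilibrium")
})

test_that("correlation maps have unit diagonals and detect known correlation", {
  set.seed(6)
  n_f <- 1000
  # two correlated nodes embedded in a rigid anchor frame of independent
  # nodes far away, so superposition barely distorts the displacements
  rho <- 0.6
  z <- matrix(rnorm(n_f * 3, 0, 0.3), n_f, 3)
  x2n <- rho * z + sqrt(1 - rho^2) * matrix(rnorm(n_f * 3, 0, 0.3), n_f, 3)
  anchors <- 100 * rbind(diag(3), -diag(3), c(1, 1, 1) / sqrt(3),
                         -c(1, 1, 1) / sqrt(3))
  frames <- lapply(seq_len(n_f), function(i)
    rbind(c(10, 0, 0) + z[i, ], c(-10, 0, 0) + x2n[i, ],
          anchors + matrix(rnorm(24, 0, 0.3), 8, 3)))
  tr <- make_traj(frames)
  cm <- correlation_maps(tr)
  expect_equal(diag(cm$pearson), rep(1, 10), tolerance = 1e-12)
  expect_equal(diag(cm$generalized), rep(1, 10))
  expect_true(isSymmetric(cm$pearson))
  expect_true(all(cm$generalized >= 0 & cm$generalized <= 1))
  # mean-removal in the superposition attenuates pairwise correlations by
  # ~(n_sub terms)/N; the correlated pair must still stand far above the
  # independent background (exact rho recovery is checked on the direct
  # estimator below)
  expect_gt(cm$pearson[1, 2], 0.35)
  expect_gt(cm$generalized[1, 2], 0.3)
  bg <- abs(cm$pearson[3:10, 3:10][upper.tri(diag(8))])
  expect_lt(median(bg), 0.2)
  expect_gt(cm$pearson[1, 2], max(bg))
  expect_error(correlation_maps(make_traj(list(diag(3), diag(3)))), "100")
})

test_that("mutual information estimators match the Gaussian closed form", {
  set.seed(7)
  rho <- 0.6
  n <- 1500
  z <- matrix(rnorm(n * 3), n, 3)
  y <- rho * z + sqrt(1 - rho^2) * matrix(rnorm(n * 3), n, 3)
  I_ref <- -1.5 * log(1 - rho^2)
  expect_equal(mutual_information(z, y, "ksg", k = 6), I_ref, tolerance = 0.15)
  expect_equal(mutual_information(z, y, "gaussian"), I_ref, tolerance = 0.1)
  # independence
  expect_lt(mutual_information(z, matrix(rnorm(n * 3), n, 3), "ksg"), 0.05)
  expect_equal(generalized_correlation(z, y), rho, tolerance = 0.05)
})

test_that("step-parameter distributions are deltas for a static trajectory", {
  d <- build_duplex(6)
  tr <- state_as_trajectory(dna_state(d))
  sd0 <- step_parameter_distributions(tr, d, "step")
  expect_equal(unique(sd0$summary$sd[!is.na(sd0$summary$sd)]), numeric(0))
  m_rise <- sd0$summary$mean[sd0$summary$parameter == "rise"]
  expect_equal(m_rise, rep(0.34, 5), tolerance = 1e-10)
})

test_that("angle observables read the builder annotations", {
  w <- build_switch_toy(12, 2, n_helices = 4)
  st <- dna_state(w)
  # rotate arm B rigidly by 50 degrees about the hinge axis (z through origin)
  arm2 <- w$metadata$annotations$arm_nodes[[2]]
  R <- dnadyn:::rot_z(-50 * pi / 180)
  st$pos[arm2, ] <- t(R %*% t(st$pos[arm2, ]))
  oa <- opening_angle_series(state_as_trajectory(st), w)
  expect_equal(oa$angle[1], 50, tolerance = 0.5)
})
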