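test_that("Debye length follows the ionic-strength closed form", {
  expect_equal(debye_length(ion_condition(na_mM = 100)), 0.304 / sqrt(0.1),
               tolerance = 1e-12)
  expect_equal(debye_length(ion_condition(mg_mM = 5)), 0.304 / sqrt(0.015),
               tolerance = 1e-12) # 2.48 nm
  k25 <- debye_length(ion_condition(mg_mM = 25))
  expect_equal(k25, 1.110, tolerance = 1e-3)
  expect_lt(k25, debye_length(ion_condition(mg_mM = 5)))
  expect_error(ion_condition(0, 0), "positive")
})

test_that("screened electrostatics is repulsive, cut off, and salt-monotone", {
  # two free nodes at controlled separation
  s <- spring_dimer_structure(k = 0, L0 = 2)
  st <- dna_state(s)
  # the bonded pair is excluded: use a third detached node instead
  m <- dnadyn:::base_pair_mass("avg")
  nodes <- list(pos = rbind(c(0, 0, 0), c(2, 0, 0)),
                quat = rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)),
                mass = rep(m, 2), inertia = dnadyn:::node_inertia(rep(m, 2)),
                radius = rep(1.1, 2), sequence = rep("avg", 2))
  pairS <- dna_structure(nodes, dnadyn:::empty_elements(),
                         metadata = list(name = "charge_pair"))
  ion5 <- ion_condition(mg_mM = 5)
  r <- electrostatic_forces(pairS, ion = ion5)
  f2 <- r$force[7:9]
  expect_gt(f2[1], 0)                       # pushes node 2 away from node 1
  expect_equal(f2[2:3], c(0, 0), tolerance = 1e-12)
  expect_gt(r$energy, 0)
  # closed form: E = q^2 lB kBT exp(-kr)/r
  pt <- default_parameter_table()
  kap <- 1 / debye_length(ion5)
  expect_equal(r$energy,
               pt$q_eff^2 * pt$bjerrum_length * kBT(300) * exp(-kap * 2) / 2,
               tolerance = 1e-10)
  # screening monotonicity: raising Mg 5 -> 25 mM lowers the pair energy
  r25 <- electrostatic_forces(pairS, ion = ion_condition(mg_mM = 25))
  expect_lt(r25$energy, r$energy)
  # beyond the 3/kappa cutoff the interaction vanishes
  far <- pairS; far$nodes$pos[2, 1] <- 3 / kap + 1
  expect_equal(electrostatic_forces(far, ion = ion5)$energy, 0)
  # overlapping nodes are a hard error
  ovl <- pairS; ovl$nodes$pos[2, 1] <- 0.05
  expect_error(electrostatic_forces(ovl, ion = ion5), "overlap")
})

test_that("Morse potential has the documented well, tail and force extremum", {
  p <- morse_params()
  expect_equal(morse_energy(p$r0, p), -42.79, tolerance = 1e-12)
  expect_equal(morse_energy(1e4, p), 0, tolerance = 1e-10)
  expect_equal(morse_force(1e4, p), 0, tolerance = 1e-10)
  # maximum attractive force eps*a/2 at r0 + ln 2 / a
  rstar <- p$r0 + log(2) / p$a
  expect_equal(rstar, 0.634, tolerance = 1e-3)
  expect_equal(morse_force(rstar, p), -p$epsilon * p$a / 2, tolerance = 1e-12)
  expect_equal(-p$epsilon * p$a / 2, -57.08, tolerance = 1e-3)
  rg <- seq(0.2, 3, by = 1e-4)
  expect_equal(min(morse_force(rg, p)), -p$epsilon * p$a / 2, tolerance = 1e-6)
  expect_error(morse_params(-1, 2, 0.3), "positive")
})

test_that("stacking forces report per-element state and obey the third law", {
  w <- build_switch_toy(12, 3, n_helices = 4)
  sf <- stacking_forces(w)
  expect_equal(sf$energy, -3 * 42.79, tolerance = 1e-9)
  expect_true(all(sf$stacked))
  # stretch one arm away along x: attractive restoring force below eps*a/2
  st <- dna_state(w)
  arm2 <- w$metadata$annotations$arm_nodes[[2]]
  st$pos[arm2, 1] <- st$pos[arm2, 1] - 2
  sf2 <- stacking_forces(w, st)
  expect_true(all(!sf2$stacked))
  fm <- matrix(sf2$force, ncol = 6, byrow = TRUE)
  expect_lt(max(abs(fm[, 1])), morse_params()$epsilon * morse_params()$a / 2)
  nt <- net_force_torque(sf2$force, st$pos)
  expect_lt(max(abs(c(nt$force, nt$torque))), 1e-9)
  expect_error(stacking_forces(build_duplex(4)), "no stacking")
})

test_that("PMF construction masks empty bins and is flat for uniform samples", {
  set.seed(1)
  u <- runif(1e5, 0.3, 0.8)
  tab <- pmf_from_distances(u, bins = seq(0.25, 0.85, by = 0.02))
  inside <- tab$r > 0.32 & tab$r < 0.78
  expect_true(all(is.finite(tab$pmf[inside])))
  expect_lt(max(tab$pmf[inside], na.rm = TRUE), 0.4) # flat within sampling noise
  expect_true(all(is.na(tab$pmf[tab$count == 0])))
  expect_error(pmf_from_distances(runif(100)), "1000")
})

test_that("Boltzmann inversion of Morse-distributed samples recovers the PMF", {
  set.seed(4)
  p <- morse_params()
  lo <- 0.05; hi <- 1.3
  # rejection sampling from exp(-Pi/kBT)
  n_target <- 1e6
  samp <- numeric(0)
  while (length(samp) < n_target) {
    x <- runif(3e6, lo, hi)
    w <- exp(-(morse_energy(x, p) + p$epsilon) / kBT(300))
    samp <- c(samp, x[runif(3e6) < w])
  }
  samp <- samp[seq_len(n_target)]
  tab <- pmf_from_distances(samp, bins = 150)
  ok <- tab$count >= 100
  ref <- morse_energy(tab$r[ok], p)
  dif <- tab$pmf[ok] - ref
  rms <- sqrt(mean((dif - mean(dif))^2))
  expect_lt(rms, 0.5)
})

test_that("Morse fitting recovers generating parameters", {
  rr <- seq(0.2, 1.6, length.out = 200)
  gen <- morse_params(40, 2.5, 0.37)
  exact <- data.frame(r = rr, pmf = morse_energy(rr, gen) + 40 + 3.3)
  class(exact) <- c("pmf_table", "data.frame")
  fit <- fit_morse_to_pmf(exact)
  expect_equal(fit$epsilon, 40, tolerance = 1e-6)
  expect_equal(fit$a, 2.5, tolerance = 1e-6)
  expect_equal(fit$r0, 0.37, tolerance = 1e-6)

  set.seed(9)
  noisy <- exact
  noisy$pmf <- noisy$pmf + rnorm(200, 0, 0.2)
  fitn <- fit_morse_to_pmf(noisy)
  expect_lt(abs(fitn$epsilon - 40) / 40, 0.05)
  expect_lt(abs(fitn$a - 2.5) / 2.5, 0.05)
  expect_lt(abs(fitn$r0 - 0.37) / 0.37, 0.05)

  mono <- data.frame(r = rr, pmf = 5 * rr)
  class(mono) <- c("pmf_table", "data.frame")
  expect_error(fit_morse_to_pmf(mono), "well")
})

test_that("PMF tables round trip through the two-column text format", {
  set.seed(2)
  tab <- pmf_from_distances(rnorm(5000, 0.5, 0.05), bins = 60, temperature = 320)
  f <- tempfile(fileext = ".txt")
  write_pmf_table(tab, f)
  tab2 <- read_pmf_table(f)
  expect_equal(tab2$r, tab$r, tolerance = 1e-12)
  expect_equal(tab2$pmf, tab$pmf, tolerance = 1e-12)
  expect_equal(attr(tab2, "temperature"), 320)
})

test_that("per-bond stacking free energy converts to the molar scale", {
  expect_equal(pnnm_to_kcal_per_mol(42.2), 6.08, tolerance = 0.01 / 6.08)
  # kBT at 300 K in this unit system
  expect_equal(kBT(300), 4.1419, tolerance = 1e-4)
})
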