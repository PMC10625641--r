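test_that("single-sphere mobility blocks match the Stokes closed forms", {
  sv <- solvent_model() # eta = 0.89 pN ns/nm^2, 300 K
  B <- self_mobility_block(1.1, sv)
  expect_equal(1 / B[1, 1], 6 * pi * 0.89 * 1.1, tolerance = 1e-12)  # 18.45
  expect_equal(1 / B[4, 4], 8 * pi * 0.89 * 1.1^3, tolerance = 1e-12) # 29.77
  expect_equal(unname(B[1, 4]), 0)
  # linearity in viscosity
  B2 <- self_mobility_block(1.1, solvent_model(viscosity = 1.78))
  expect_equal(B2, B / 2, tolerance = 1e-12)
  expect_error(self_mobility_block(-1), "positive")
})

test_that("pair mobility has the Oseen limit, 2a continuity and exchange antisymmetry", {
  sv <- solvent_model()
  a <- 1.1
  r <- 50 * a
  P <- pair_mobility_block(c(r, 0, 0), a, sv)
  oseen <- (diag(3) + c(1, 0, 0) %o% c(1, 0, 0)) / (8 * pi * sv$viscosity * r)
  expect_lt(max(abs(P[1:3, 1:3] - oseen)) / max(abs(oseen)), 0.01)

  rv <- c(2 * a, 0.3, -0.1); rv <- rv / sqrt(sum(rv^2))
  Pm <- pair_mobility_block(rv * (2 * a - 1e-9), a, sv)
  Pp <- pair_mobility_block(rv * (2 * a + 1e-9), a, sv)
  expect_lt(max(abs(Pm - Pp)), 1e-8)

  # translation-rotation coupling is antisymmetric under particle exchange
  P1 <- pair_mobility_block(c(1.7, 0.4, 0.2), a, sv)
  P2 <- pair_mobility_block(-c(1.7, 0.4, 0.2), a, sv)
  expect_equal(P1[4:6, 1:3], -P2[4:6, 1:3], tolerance = 1e-12)
  expect_error(pair_mobility_block(c(0, 0, 0), a, sv), "r = 0")
})

test_that("assembled mobility is SPD, decays with distance, and inverts", {
  # single node: block-diagonal self mobility
  s1 <- free_node_structure()
  mob1 <- assemble_mobility(s1)
  expect_equal(mob1$matrix, self_mobility_block(1.1), tolerance = 1e-12)

  # far pairs: off-diagonal couplings decay toward independent spheres
  # (longitudinal Oseen over self mobility = 1.5 a / r)
  s2 <- spring_dimer_structure(k = 0, L0 = 100)
  mob2 <- assemble_mobility(s2)
  expect_lt(max(abs(mob2$matrix[1:6, 7:12])), 2e-2 * max(diag(mob2$matrix)))
  s3 <- spring_dimer_structure(k = 0, L0 = 1000)
  mob3 <- assemble_mobility(s3)
  expect_lt(max(abs(mob3$matrix[1:6, 7:12])), 2e-3 * max(diag(mob3$matrix)))
  expect_lt(max(abs(mob3$matrix[1:6, 7:12])),
            0.11 * max(abs(mob2$matrix[1:6, 7:12]))) # ~1/r decay

  # random cloud including overlapping spheres stays positive definite
  set.seed(5)
  n <- 20
  m <- dnadyn:::base_pair_mass("avg")
  nodes <- list(pos = matrix(runif(3 * n, 0, 5), ncol = 3),
                quat = matrix(rep(c(1, 0, 0, 0), n), ncol = 4, byrow = TRUE),
                mass = rep(m, n), inertia = dnadyn:::node_inertia(rep(m, n)),
                radius = rep(1.1, n), sequence = rep("avg", n))
  cloud <- dna_structure(nodes, dnadyn:::empty_elements(),
                         metadata = list(name = "cloud"))
  mob <- assemble_mobility(cloud)
  ev <- eigen(mob$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_lt(max(abs(mob$matrix - t(mob$matrix))), 1e-10)

  Z <- friction_from_mobility(mob)
  expect_lt(max(abs(Z$matrix %*% mob$matrix - diag(6 * n))), 1e-8)
  expect_lt(max(abs(Z$chol %*% t(Z$chol) - Z$matrix)), 1e-8)
  # single sphere: translational friction entries are 6 pi eta a
  Z1 <- friction_from_mobility(mob1)
  expect_equal(Z1$matrix[1, 1], 18.45, tolerance = 1e-3)

  # ill-conditioned operator is rejected
  Q <- diag(c(rep(1, 5), 1e-14))
  expect_error(friction_from_mobility(Q), "ill-conditioned")
  # mixed radii are rejected (the model assumes identical spheres)
  s2$nodes$radius[2] <- 0.9
  expect_error(assemble_mobility(s2), "share one")
})
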