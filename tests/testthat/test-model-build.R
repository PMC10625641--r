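test_that("duplex builder produces the closed-form geometry", {
  d <- build_duplex(2, "average", 0.34, 34.3)
  expect_equal(nrow(d$nodes$pos), 2)
  expect_equal(d$elements$kind, "step")
  expect_equal(unname(d$elements$intrinsic[1, ]), c(0, 0, 0.34, 0, 0, 34.3))

  d21 <- build_duplex(21)
  expect_equal(d21$nodes$pos[21, 3], 6.8)
  # cumulative twist 20 * 34.3 = 686 deg == 326 deg mod 360
  R20 <- dnadyn:::matrix_from_quat(d21$nodes$quat[21, ])
  expect_equal(R20, dnadyn:::rot_z(326 * pi / 180), tolerance = 1e-10)

  expect_error(build_duplex(1), "at least 2")
  expect_error(build_duplex(4, "ACGX"), "invalid base")
})

test_that("sequence masses follow the nucleotide table", {
  d <- build_duplex(4, "ACGT")
  da <- dnadyn:::dna_constants()$dalton
  # A-T pair: 313.2 + 304.2; C-G pair: 289.2 + 329.2 (Da)
  expect_equal(d$nodes$mass[1], 617.4 * da)
  expect_equal(d$nodes$mass[2], 618.4 * da)
  expect_equal(d$nodes$mass[3], 618.4 * da)
  expect_equal(d$nodes$mass[4], 617.4 * da)
  davg <- build_duplex(3)
  expect_true(all(davg$nodes$mass == davg$nodes$mass[1]))
})

test_that("bundle builder matches the construction counting rule", {
  b <- build_bundle(2, "square", 32, 16)
  expect_equal(nrow(b$nodes$pos), 64)
  expect_equal(sum(b$elements$kind == "step"), 62)
  expect_equal(sum(b$elements$kind == "crossover"), 2)
  # the as-built bundle is an elastic equilibrium
  f <- assemble_elastic_forces(b)
  expect_lt(max(abs(f$force)), 1e-8)

  hb <- build_bundle(12, "honeycomb", 64, 21)
  expect_equal(nrow(hb$nodes$pos), 768)
  xo <- which(hb$elements$kind == "crossover")
  helix_of <- (hb$elements$nodes[xo, ] - 1L) %/% 64L
  expect_true(all(abs(helix_of[, 1] - helix_of[, 2]) == 1))

  expect_error(build_bundle(1, "square", 32, 16), "at least 2")
  expect_error(build_bundle(2, "square", 10, 16), "incompatible")
})

test_that("switch toy is built closed with stacking bonds at equilibrium", {
  w <- build_switch_toy(24, 4)
  sf <- stacking_forces(w)
  expect_equal(length(sf$distance), 4)
  expect_true(all(abs(sf$distance - 0.3742) < 1e-6))
  expect_true(all(sf$stacked))
  expect_equal(sf$energy, -4 * 42.79, tolerance = 1e-8)
  # zero stacking force in the closed state
  expect_lt(max(abs(sf$force)), 1e-6)
  # opening angle of the as-built structure is zero
  oa <- opening_angle_series(state_as_trajectory(dna_state(w)), w)
  expect_lt(oa$angle[1], 1e-6)

  expect_error(build_switch_toy(24, 1000), "exceeds")
  expect_error(build_switch_toy(4, 1), "at least 8")
})

test_that("wireframe polygons have the ideal vertex geometry", {
  for (ne in c(3, 6)) {
    wf <- build_wireframe_polygon(ne, "DX", if (ne == 3) 25 else 40)
    tr <- state_as_trajectory(dna_state(wf))
    ia <- measure_angles(tr, wf, "interior_vertex")
    expect_equal(ia$angle, rep(180 * (ne - 2) / ne, ne), tolerance = 0.02)
    oop <- measure_angles(tr, wf, "out_of_plane")
    expect_lt(max(oop$angle), 1e-6)
  }
  # 6HB edges carry six helices on a 2.5 nm honeycomb ring
  wh <- build_wireframe_polygon(3, "6HB", 25)
  e1 <- wh$metadata$annotations$edges[[1]]
  nbp <- length(e1) / 6
  cents <- t(sapply(0:5, function(h)
    colMeans(wh$nodes$pos[e1[h * nbp + seq_len(nbp)], ])))
  expect_equal(nrow(cents), 6)
  expect_equal(min(dist(cents)), 2.5, tolerance = 0.01)
  expect_error(build_wireframe_polygon(3, "DX", 3), "infeasib")
})

test_that("structure invariants are enforced", {
  d <- build_duplex(4)
  bad <- d
  bad$nodes$quat[2, ] <- c(1, 0.5, 0, 0) # not unit
  expect_error(validate_structure(bad), "orthonormal")

  bad2 <- d
  bad2$elements$nodes[2, ] <- c(1, 2) # duplicates element 1
  expect_error(validate_structure(bad2), "duplicate")

  bad3 <- d
  bad3$elements$stiffness[1, 2, 1] <- 99 # asymmetric
  expect_error(validate_structure(bad3), "symmetric")
})
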