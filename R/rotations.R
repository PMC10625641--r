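# Rotation helpers. Orientations are stored internally as unit quaternions
# (w, x, y, z) and exposed as right-handed orthonormal triads whose columns
# are the base-pair frame axes in the lab frame.

rot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

rot_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

rot_about_axis <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  c <- cos(theta); s <- sin(theta)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * c + s * ux + (1 - c) * (u %o% u)
}

quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

matrix_from_quat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# Uniform random rotation (used by tests and fixtures).
random_rotation <- function() {
  q <- stats::rnorm(4)
  matrix_from_quat(q / sqrt(sum(q^2)))
}

# Inverse of the mid-step-triad decomposition: given the frame/origin of node
# a and six step parameters (nm, degrees), construct the frame and origin of
# node b. Used by tests as an independent geometric oracle and by builders.
step_frame_from_parameters <- function(Ta, ra, params) {
  p <- as.numeric(params)
  d2r <- pi / 180
  tilt <- p[4] * d2r; roll <- p[5] * d2r; twist <- p[6] * d2r
  gamma <- sqrt(tilt^2 + roll^2)
  phi <- atan2(tilt, roll)
  # In mid-frame coordinates the hinge is e2 rotated by -phi about e3.
  hinge_m <- c(sin(phi), cos(phi), 0)
  A <- rot_about_axis(hinge_m, -gamma / 2) %*% rot_z(-twist / 2)
  B <- rot_about_axis(hinge_m, +gamma / 2) %*% rot_z(+twist / 2)
  Tm <- Ta %*% t(A)
  Tb <- Tm %*% B
  rb <- ra + Tm %*% p[1:3]
  list(frame = Tb, origin = as.numeric(rb))
}
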