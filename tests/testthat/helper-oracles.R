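# Independent oracles and generators shared across test files.

# Projection-based signed torsion: project the outer bonds onto the plane
# perpendicular to the central bond and measure the signed angle between
# the projections. Independent of the atan2 cross-product formulation in
# the package.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b <- p3 - p2
  b <- b / sqrt(sum(b^2))
  v1 <- p1 - p2
  v1 <- v1 - sum(v1 * b) * b
  v2 <- p4 - p3
  v2 <- v2 - sum(v2 * b) * b
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  crs <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  if (sum(crs * b) < 0) ang <- -ang
  if (ang == -180) ang <- 180
  ang
}

# random rigid motion (proper rotation + translation)
random_rigid_motion <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qrd <- qr(M)
  R <- qr.Q(qrd)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 5))
}

apply_rigid <- function(coords, motion) {
  sweep(coords %*% t(motion$R), 2, motion$t, "+")
}

# seeded two-well Fourier potential battery: a dominant 2-fold term with
# 1-fold (well bias) and 3-fold (directional asymmetry) perturbations and
# modest phase shifts, guaranteeing two wells near 0/180 and two barriers
# near +/-90
random_two_well <- function(i) {
  set.seed(1000 + i)
  v2 <- runif(1, 8, 20)
  v1 <- runif(1, -0.3, 0.3) * v2
  v3 <- runif(1, -0.12, 0.12) * v2
  g1 <- runif(1, -20, 20)
  g2 <- runif(1, -8, 8)
  g3 <- runif(1, -20, 20)
  make_potential(data.frame(k = 1:3, v = c(v1, v2, v3), gamma = c(g1, g2, g3)),
                 name = sprintf("battery-%02d", i))
}

# smallest difference between two angles, accounting for wrap
ang_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
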