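test_that("dihedral reproduces planar references and the independent oracles", {
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)), 180)

  set.seed(7)
  for (i in 1:100) {
    P <- matrix(rnorm(12), 4, 3)
    d <- dihedral(P[1, ], P[2, ], P[3, ], P[4, ])
    expect_equal(d, oracle_dihedral(P[1, ], P[2, ], P[3, ], P[4, ]),
                 tolerance = 1e-9)
  }
  # cross-check the convention against an established implementation
  skip_if_not_installed("bio3d")
  set.seed(8)
  for (i in 1:25) {
    P <- matrix(rnorm(12), 4, 3)
    d <- dihedral(P[1, ], P[2, ], P[3, ], P[4, ])
    b <- suppressWarnings(bio3d::torsion.xyz(as.numeric(t(P)), atm.inc = 4))[1]
    expect_lt(ang_diff(d, b), 1e-6)
  }
})

test_that("dihedral symmetry properties hold", {
  # the signed torsion reads the same from either chain end, flips sign
  # under mirror reflection, and is invariant under proper rigid motion
  set.seed(11)
  for (i in 1:50) {
    P <- matrix(rnorm(12, sd = 2), 4, 3)
    d <- dihedral(P[1, ], P[2, ], P[3, ], P[4, ])
    drev <- dihedral(P[4, ], P[3, ], P[2, ], P[1, ])
    expect_lt(ang_diff(d, drev), 1e-9)
    M <- P %*% diag(c(1, 1, -1))
    dmir <- dihedral(M[1, ], M[2, ], M[3, ], M[4, ])
    expect_lt(ang_diff(d, -dmir), 1e-9)
    m <- random_rigid_motion()
    Q <- apply_rigid(P, m)
    expect_lt(ang_diff(d, dihedral(Q[1, ], Q[2, ], Q[3, ], Q[4, ])), 1e-9)
  }
})

test_that("degenerate point sets raise torsion errors", {
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)),
               "coincide")
  expect_error(dihedral(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0), c(-1, 0, 1)),
               "collinear")
})

test_that("backbone_dihedrals evaluates the named torsions through the map", {
  frag <- make_backbone_fragment(c(psi_n = -23.8, omega = 169.5,
                                   phi_c = -114.3, psi_c = 141.2))
  dh <- backbone_dihedrals(frag$structure, frag$map)
  expect_equal(unname(dh["omega"]), 169.5, tolerance = 1e-6)
  expect_equal(unname(dh["psi_n"]), -23.8, tolerance = 1e-6)

  # permuting the map relabels the values accordingly
  m2 <- atom_map(psi_n = frag$map$omega, omega = frag$map$psi_n,
                 phi_c = frag$map$phi_c, psi_c = frag$map$psi_c)
  dh2 <- backbone_dihedrals(frag$structure, m2)
  expect_equal(unname(dh2["psi_n"]), unname(dh["omega"]))
  expect_equal(unname(dh2["omega"]), unname(dh["psi_n"]))

  planar <- make_backbone_fragment()
  expect_equal(unname(backbone_dihedrals(planar$structure, planar$map)["omega"]),
               180, tolerance = 1e-9)
})

test_that("planarity deviation folds to the nearer planar reference", {
  expect_equal(planarity_deviation(169.5), 10.5)
  expect_equal(planarity_deviation(-177.9), 2.1)
  expect_equal(planarity_deviation(180), 0)
  expect_equal(planarity_deviation(-8.5), 8.5)
  expect_equal(planarity_deviation(90), 90)
  expect_true(is_distorted(169.5))
  expect_false(is_distorted(-177.9))

  omega <- seq(-179.9, 180, by = 7.3)
  dev <- planarity_deviation(omega)
  expect_true(all(dev >= 0 & dev <= 90))
})

test_that("distortion flags on the trans-dihedral table match the highlighted rows", {
  t2 <- amide_table(2)
  lab <- split_isomer_label(t2$compound)
  gas <- lab$code[is_distorted(t2$omega_gas)]
  water <- lab$code[is_distorted(t2$omega_water)]
  expect_setequal(gas, c("N0110", "N1110", "N111'0"))
  expect_setequal(water, c("N0110", "N1100", "N1110", "N111'0"))
})

test_that("the hydrogen-bond criterion is distance-only and cutoff-inclusive", {
  expect_true(hbond_present(2.0))
  expect_true(hbond_present(2.30))
  expect_false(hbond_present(2.31))
  expect_error(hbond_present(-0.1), "non-negative")
})

test_that("superposition recovers rigid motions and matches an independent fit", {
  set.seed(21)
  coords <- matrix(rnorm(24, sd = 3), 8, 3)
  s <- xyz_structure(rep("C", 8), coords)

  ident <- superpose(s, s, cbind(1:8, 1:8))
  expect_equal(ident$rmsd, 0, tolerance = 1e-12)

  m <- random_rigid_motion()
  moved <- xyz_structure(s$elements, apply_rigid(coords, m))
  fit <- superpose(moved, s, cbind(1:8, 1:8))
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$transformed$coords, coords, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_gt(det(fit$rotation), 0.99)

  # noisy pairs: rmsd agrees with an established least-squares fit
  skip_if_not_installed("bio3d")
  noisy <- xyz_structure(s$elements,
                         apply_rigid(coords + matrix(rnorm(24, sd = 0.3), 8, 3), m))
  ours <- superpose(noisy, s, cbind(1:5, 1:5))
  ref_xyz <- as.numeric(t(s$coords))
  mob_xyz <- as.numeric(t(noisy$coords))
  inds <- sort(c(3 * (1:5) - 2, 3 * (1:5) - 1, 3 * (1:5)))
  fitted <- bio3d::fit.xyz(ref_xyz, mob_xyz, fixed.inds = inds, mobile.inds = inds)
  rmsd_bio <- sqrt(mean(rowSums(
    (matrix(fitted[inds], ncol = 3, byrow = TRUE) -
       s$coords[1:5, , drop = FALSE])^2)))
  expect_equal(ours$rmsd, rmsd_bio, tolerance = 1e-6)
})

test_that("reflections are rejected even when they would fit better", {
  # a chiral 4-point set and its mirror image: a proper rotation cannot
  # superpose them exactly, and the guard must keep det(R) = +1
  P <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.2, 0), c(0, 0, 0.9),
             c(0.7, 0.7, 0.7))
  M <- P %*% diag(c(1, 1, -1))
  a <- xyz_structure(rep("C", 5), M)
  b <- xyz_structure(rep("C", 5), P)
  fit <- superpose(a, b, cbind(1:5, 1:5))
  expect_gt(det(fit$rotation), 0.99)
  expect_gt(fit$rmsd, 0.1)
})

test_that("degenerate superposition inputs raise alignment errors", {
  s3 <- xyz_structure(rep("C", 3), rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_error(superpose(s3, s3, cbind(1:2, 1:2)), "at least 3")
  expect_error(superpose(s3, s3, cbind(1:3, 1:3)), "collinear")
})

test_that("minimum group distance equals the brute-force pairwise minimum", {
  s <- xyz_structure(c("C", "C"), rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(min_group_distance(s, 1, 2), 3)
  expect_error(min_group_distance(s, 1, 1), "disjoint")
  expect_error(min_group_distance(s, integer(0), 2), "non-empty")

  set.seed(31)
  for (i in 1:20) {
    coords <- matrix(rnorm(30, sd = 4), 10, 3)
    s <- xyz_structure(rep("C", 10), coords)
    ga <- 1:4
    gb <- 5:10
    brute <- min(as.matrix(stats::dist(coords))[ga, gb])
    expect_equal(min_group_distance(s, ga, gb), brute, tolerance = 1e-12)
  }
})
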