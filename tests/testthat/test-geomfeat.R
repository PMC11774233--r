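# Pairwise-distance family, angles/dihedrals, Z-matrix and its variants.

test_that("pairwise distance vector: values, names, length, invariance", {
  g <- geometry(rep("C", 3), rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  v <- pairwise_distance_vector(g)
  expect_equal(unname(v), c(1, 1, sqrt(2)), tolerance = 1e-12)
  expect_equal(names(v), c("R_1_0", "R_2_0", "R_2_1"))

  g12 <- make_template("fulvene_like")
  expect_length(pairwise_distance_vector(g12), 66)

  set.seed(1)
  for (i in 1:5) {
    gr <- random_geometry(7)
    moved <- transform_geometry(gr, random_rotation(), stats::rnorm(3, sd = 5))
    expect_equal(pairwise_distance_vector(moved), pairwise_distance_vector(gr),
                 tolerance = 1e-10)
  }
  expect_error(pairwise_distance_vector(geometry("C", matrix(0, 1, 3))),
               "at least 2")
})

test_that("R2 variants implement inverse, delta and re", {
  v <- c(a = 2.0, b = 0.5)
  expect_equal(r2_variant(v, variant = "inverse"), c(a = 0.5, b = 2.0))
  expect_equal(unname(r2_variant(v, v, "delta")), c(0, 0))
  expect_equal(unname(r2_variant(v, v, "re")), c(1, 1))
  expect_error(r2_variant(c(0, 1), variant = "inverse"), "zero")
  expect_error(r2_variant(v, v[1], "delta"), "length")
})

test_that("bond angle matches the arccos oracle on random triples", {
  g <- geometry(rep("C", 3), rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)))
  expect_equal(bond_angle(g, 1, 2, 3), 90)
  gl <- geometry(rep("C", 3), rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_equal(bond_angle(gl, 1, 2, 3), 180)
  set.seed(2)
  for (i in 1:200) {
    gr <- random_geometry(3)
    u <- gr$coords[1, ] - gr$coords[2, ]
    w <- gr$coords[3, ] - gr$coords[2, ]
    oracle <- acos(sum(u * w) / sqrt(sum(u^2) * sum(w^2))) * 180 / pi
    expect_equal(bond_angle(gr, 1, 2, 3), oracle, tolerance = 1e-9)
  }
  gc <- geometry(rep("C", 3), rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_error(bond_angle(gc, 1, 2, 3), "coincident")
})

test_that("dihedral angle follows the right-handed atan2 convention", {
  cis <- geometry(rep("C", 4), rbind(c(0, 0, 0), c(1, 0, 0),
                                     c(1, 1, 0), c(0, 1, 0)))
  expect_equal(dihedral_angle(cis, 1, 2, 3, 4), 0)
  anti <- geometry(rep("C", 4), rbind(c(0, 0, 0), c(1, 0, 0),
                                      c(1, 1, 0), c(2, 1, 0)))
  expect_equal(dihedral_angle(anti, 1, 2, 3, 4), 180)
  perp <- geometry(rep("C", 4), rbind(c(0, 0, 0), c(1, 0, 0),
                                      c(1, 1, 0), c(1, 1, 1)))
  expect_equal(dihedral_angle(perp, 1, 2, 3, 4), 90)

  # independent vector-algebra oracle on random quadruples
  oracle <- function(p) {
    b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
    cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
    n1 <- cr(b1, b2); n2 <- cr(b2, b3)
    atan2(sum(cr(n1, n2) * b2 / sqrt(sum(b2^2))), sum(n1 * n2)) * 180 / pi
  }
  set.seed(3)
  for (i in 1:1000) {
    gr <- random_geometry(4)
    expect_equal(dihedral_angle(gr, 1, 2, 3, 4), oracle(gr$coords),
                 tolerance = 1e-9)
  }
  coll <- geometry(rep("C", 4), rbind(c(0, 0, 0), c(1, 0, 0),
                                      c(2, 0, 0), c(3, 1, 0)))
  expect_error(dihedral_angle(coll, 1, 2, 3, 4), "collinear")
})

test_that("Z-matrix counts 3n-6 features and round-trips through Cartesian", {
  g4 <- geometry(rep("C", 4), rbind(c(0, 0, 0), c(1, 0, 0),
                                    c(1, 1, 0), c(0, 1, 0)))
  z4 <- zmatrix(g4)
  expect_length(z4$bonds, 3)
  expect_length(z4$angles, 2)
  expect_length(z4$dihedrals, 1)
  expect_equal(unname(z4$dihedrals), 0)  # square path is cis

  g12 <- make_template("fulvene_like")
  expect_length(zmatrix_vector(zmatrix(g12)), 30)

  set.seed(4)
  for (i in 1:20) {
    gr <- random_geometry(6)
    z <- zmatrix(gr)
    rebuilt <- zmatrix_to_cartesian(z, gr$labels)
    expect_equal(zmatrix_vector(zmatrix(rebuilt)), zmatrix_vector(z),
                 tolerance = 1e-8)
  }
  bad <- default_connectivity(4)
  bad$bond[2] <- 3  # forward reference
  expect_error(zmatrix(g4, bad), "not yet defined")
})

test_that("delta Z-matrix wraps angles and applies bounded transforms", {
  set.seed(5)
  g <- random_geometry(5)
  z <- zmatrix(g)
  expect_equal(unname(delta_zmatrix(z, z, "none")), rep(0, 9))
  expect_equal(unname(delta_zmatrix(z, z, "sig")), rep(0.5, 9))

  # wrap rule: 179 vs -179 is a -2 degree step, not 358
  expect_equal(wrap_angle(179 - (-179)), -2)
  expect_equal(wrap_angle(-179 - 179), 2)
  expect_equal(wrap_angle(180), 180)

  # a 5 Angstrom stretch saturates tanh near 1 (tanh(5) by direct eval)
  z2 <- z
  z2$bonds[1] <- z$bonds[1] + 5
  d <- delta_zmatrix(z2, z, "tanh")
  expect_equal(unname(d[1]), tanh(5), tolerance = 1e-12)
  expect_lt(abs(unname(d[1])), 1)

  z3 <- z
  z3$connectivity$bond[3] <- 1L
  expect_error(delta_zmatrix(z3, z, "none"), "connectivity mismatch")
})

test_that("angular transforms use radians so one degree stays near-linear", {
  set.seed(6)
  g <- random_geometry(5)
  z <- zmatrix(g)
  z2 <- z
  z2$dihedrals[1] <- wrap_angle(z$dihedrals[1] + 1)
  d <- delta_zmatrix(z2, z, "tanh")
  expect_equal(unname(d[names(z$dihedrals)[1]]), tanh(pi / 180),
               tolerance = 1e-9)
})
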