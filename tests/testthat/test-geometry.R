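test_that("centroid is the arithmetic mean; hexagon centers at the origin", {
  expect_equal(centroid(rbind(c(1, 2, 3))), c(x = 1, y = 2, z = 3),
               ignore_attr = TRUE)
  expect_equal(centroid(rbind(c(0, 0, 0), c(2, 4, 6))), c(1, 2, 3),
               ignore_attr = TRUE)
  hexagon <- t(sapply(0:5, function(k)
    c(7 * cos(k * pi / 3), 7 * sin(k * pi / 3), 2)))
  expect_equal(centroid(hexagon), c(0, 0, 2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(centroid(matrix(numeric(0), ncol = 3)), "empty")
})

test_that("superpose recovers a known rigid motion and rejects degenerate input", {
  set.seed(11)
  pts <- matrix(rnorm(45, sd = 5), ncol = 3)
  rot <- random_rotation()
  tr <- c(3, -7, 12)
  moved <- sweep(pts %*% t(rot), 2, tr, "+")
  fit <- superpose(pts, moved)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(apply_transform(fit, moved), pts, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-9)
  # identical sets
  self <- superpose(pts, pts)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)
  expect_error(superpose(pts[1:2, ], pts[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line), "collinear|degenerate")
})

test_that("proper-rotation constraint keeps mirror images apart", {
  # chiral 4-point set; its mirror image cannot be superposed by any proper
  # rotation.  Brute-force over a dense rotation sample confirms the returned
  # RMSD is the floor.
  chiral <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0), c(0, 0, 5))
  mirror <- chiral %*% diag(c(-1, 1, 1))
  fit <- superpose(chiral, mirror)
  expect_gt(fit$rmsd, 0.5)
  set.seed(23)
  for (i in 1:400) {
    rot <- random_rotation()
    cand <- sweep(mirror, 2, colMeans(mirror)) %*% t(rot)
    ref <- sweep(chiral, 2, colMeans(chiral))
    expect_gte(sqrt(mean(rowSums((cand - ref)^2))), fit$rmsd - 1e-9)
  }
})

test_that("superpose is optimal against a dense random-rotation search", {
  set.seed(31)
  for (rep in 1:5) {
    a <- matrix(rnorm(24, sd = 4), ncol = 3)
    b <- matrix(rnorm(24, sd = 4), ncol = 3)
    fit <- superpose(a, b)
    ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
    best_grid <- min(replicate(800, {
      rot <- random_rotation()
      sqrt(mean(rowSums((bc %*% t(rot) - ac)^2)))
    }))
    expect_lte(fit$rmsd, best_grid + 1e-9)
    # independent oracle: bio3d least-squares fit (rounds to 2 decimals)
    expect_equal(fit$rmsd,
                 bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE),
                 tolerance = 0.006)
  }
})

test_that("superpose RMSD is invariant under a common rigid motion", {
  set.seed(41)
  a <- matrix(rnorm(30, sd = 5), ncol = 3)
  b <- matrix(rnorm(30, sd = 5), ncol = 3)
  base <- superpose(a, b)$rmsd
  for (i in 1:5) {
    rot <- random_rotation(); tr <- rnorm(3, sd = 20)
    a2 <- sweep(a %*% t(rot), 2, tr, "+")
    b2 <- sweep(b %*% t(rot), 2, tr, "+")
    expect_equal(superpose(a2, b2)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("dihedral sign convention fixed by explicit rotation construction", {
  p2 <- c(0, 0, 0); p3 <- c(0, 0, 2)
  p1 <- c(1.5, 0, -0.7)
  for (ang in c(25, -25, 90, 170, -135, 1e-3)) {
    p4 <- as.numeric(rot_z(ang) %*% p1)
    expect_equal(dihedral_angle(p1, p2, p3, p4), ang, tolerance = 1e-9)
  }
  # cis and trans planar arrangements
  expect_equal(dihedral_angle(c(1, 0, 0), p2, p3, c(1, 0, 2)), 0,
               tolerance = 1e-9)
  expect_equal(dihedral_angle(c(1, 0, 0), p2, p3, c(-1, 0, 2)), 180,
               tolerance = 1e-9)
})

test_that("dihedral agrees with an independent torsion implementation and is
          symmetric under sequence reversal", {
  set.seed(53)
  for (i in 1:25) {
    p <- matrix(rnorm(12, sd = 3), ncol = 3)
    d <- tryCatch(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                  error = function(e) NULL)
    if (is.null(d)) next
    expect_equal(d, bio3d::torsion.xyz(as.vector(t(p))), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(dihedral_angle(p[4, ], p[3, ], p[2, ], p[1, ]), d,
                 tolerance = 1e-9)
  }
  expect_error(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 1, 0)),
               "coincide")
  expect_error(dihedral_angle(c(0, 0, -1), c(0, 0, 0), c(0, 0, 1), c(0, 1, 2)),
               "collinear")
})

test_that("wrap_angle maps into (-180, 180]", {
  expect_equal(wrap_angle(c(190, -190, 360, 180, -180, 540)),
               c(-170, 170, 0, 180, 180, 180))
})
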