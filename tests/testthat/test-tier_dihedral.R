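test_that("tier centroids sit on the ring axis for the symmetric construction", {
  r <- make_ring(ring_spec(ring_radius = 40, tier_separation = 45))
  an <- archaeal_anchors()
  tc <- tier_centroids(r$model, r$truth$ring, an)
  expect_equal(tc$n_tier_centroid, c(0, 0, 0), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(tc$c_tier_centroid, c(0, 0, 45), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("per-subunit dihedrals recover the programmed twists exactly", {
  an <- archaeal_anchors()
  for (tw in list(rep(0, 6), rep(-31, 6), rep(-20, 6),
                  c(-10, -20, -30, 5, 15, 25))) {
    r <- make_ring(ring_spec(per_subunit_twist = tw))
    dih <- ring_dihedral(r$model, r$truth$ring, an)
    expect_equal(unname(dih$per_subunit), tw, tolerance = 1e-6)
  }
})

test_that("mean binning: eclipsed above -15, staggered below -25, gap honest", {
  expect_equal(mean_and_classify(rep(0, 6))$tier_class, "eclipsed")
  expect_equal(mean_and_classify(rep(0, 6))$mean_dihedral, 0)
  expect_equal(mean_and_classify(rep(-31, 6))$tier_class, "staggered")
  expect_equal(mean_and_classify(rep(-20, 6))$tier_class, "indeterminate")
  expect_equal(mean_and_classify(c(-14.9))$tier_class, "eclipsed")
  expect_equal(mean_and_classify(c(-15))$tier_class, "indeterminate")
  expect_equal(mean_and_classify(c(-25))$tier_class, "indeterminate")
  expect_equal(mean_and_classify(c(-25.1))$tier_class, "staggered")
  # wrapping applied before averaging
  expect_equal(mean_and_classify(c(350, -10))$mean_dihedral, -10)
  expect_error(mean_and_classify(numeric(0)), "no dihedrals")
  # generator + classifier round trip at the class conditions
  an <- archaeal_anchors()
  for (cond in list(list(tw = 3, cls = "eclipsed"),
                    list(tw = -32, cls = "staggered"),
                    list(tw = -31, cls = "staggered"),
                    list(tw = -20, cls = "indeterminate"))) {
    r <- make_ring(ring_spec(per_subunit_twist = rep(cond$tw, 6)))
    dih <- ring_dihedral(r$model, r$truth$ring, an)
    expect_equal(dih$mean_dihedral, cond$tw, tolerance = 1e-6)
    expect_equal(dih$tier_class, cond$cls)
  }
})

test_that("dihedrals are rigid-motion invariant and C-tier-rotation equivariant", {
  an <- archaeal_anchors()
  r <- asymmetric_ring()
  ring <- r$truth$ring
  base <- ring_dihedral(r$model, ring, an)$per_subunit
  set.seed(97)
  rot <- random_rotation()
  moved <- transform_model(r$model, rot, c(11, -6, 30))
  expect_equal(ring_dihedral(moved, ring, an)$per_subunit, base,
               tolerance = 1e-6)
  # rotate only the C-tier (core residues) about the ring axis by delta
  for (delta in c(12, -40)) {
    m2 <- r$model
    sel <- m2$atoms$resno >= 1319
    xyz <- as.matrix(m2$atoms[sel, c("x", "y", "z")])
    m2$atoms[sel, c("x", "y", "z")] <- xyz %*% t(rot_z(delta))
    shifted <- ring_dihedral(m2, ring, an)$per_subunit
    expect_equal(wrap_angle(shifted - base), rep(delta, 6),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("template mode matches direct mode on a uniform ring", {
  an <- archaeal_anchors()
  r <- make_ring(ring_spec(per_subunit_twist = rep(-31, 6)))
  ring <- r$truth$ring
  direct <- ring_dihedral(r$model, ring, an)
  tmpl <- ring_dihedral(r$model, ring, an,
                        template = list(model = r$model, chain = "F"))
  expect_equal(tmpl$per_subunit, direct$per_subunit, tolerance = 0.5)
  expect_equal(tmpl$mean_dihedral, direct$mean_dihedral, tolerance = 0.5)
  tcd <- tier_centroids(r$model, ring, an)
  tct <- tier_centroids(r$model, ring, an,
                        template = list(model = r$model, chain = "F"))
  expect_equal(tct$n_tier_centroid, tcd$n_tier_centroid, tolerance = 0.5,
               ignore_attr = TRUE)
  expect_equal(tct$c_tier_centroid, tcd$c_tier_centroid, tolerance = 0.5,
               ignore_attr = TRUE)
})

test_that("a missing OB-fold is an error; a missing dihedral anchor omits the chain", {
  an <- archaeal_anchors()
  r <- make_ring(ring_spec(seed = 5L))
  ring <- r$truth$ring
  m <- r$model
  m$atoms <- m$atoms[!(m$atoms$chain == "C" & m$atoms$resno <= 265), ]
  expect_error(tier_centroids(m, ring, an), "OB-fold")
  m2 <- r$model
  m2$atoms <- m2$atoms[!(m2$atoms$chain == "B" & m2$atoms$resno == 1755), ]
  dih <- ring_dihedral(m2, ring, an)
  expect_equal(dih$omitted, "B")
  expect_length(dih$per_subunit, 5)
})
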