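test_that("core hexamer construction recovers rigid template placements", {
  an <- archaeal_anchors()
  r <- make_ring(ring_spec(per_subunit_twist = rep(-31, 6)))
  ring <- r$truth$ring
  tpl <- core_template(r$model, "F", an)
  expect_equal(nrow(tpl), 152)
  hex <- build_core_hexamer(r$model, ring, tpl)
  # uniform ring: all six subunits are exact rigid copies, so every fit is 0
  expect_true(all(hex$fit_rmsd < 1e-6))
  # each stored copy coincides with the chain's own core CAs
  for (p in 1:6) {
    own <- ringmetrics:::chain_ca_in_ranges(
      r$model, ring$chain[p], an$subunits$archaeal$core_ranges)
    expect_equal(hex$copies[[p]], own, tolerance = 1e-6, ignore_attr = TRUE)
  }
  # chain below the coverage floor is an error naming the chain
  m2 <- r$model
  drop <- which(m2$atoms$chain == "E" & m2$atoms$resno >= 1729 &
                  m2$atoms$resno <= 1748 & m2$atoms$elety == "CA")
  m2$atoms <- m2$atoms[-drop, ]
  expect_error(build_core_hexamer(m2, ring, tpl), "E")
  # mild disorder below the floor is tolerated
  m3 <- r$model
  drop <- which(m3$atoms$chain == "E" & m3$atoms$resno >= 1729 &
                  m3$atoms$resno <= 1733 & m3$atoms$elety == "CA")
  m3$atoms <- m3$atoms[-drop, ]
  hex3 <- build_core_hexamer(m3, ring, tpl)
  expect_true(all(is.finite(hex3$fit_rmsd)))
})

test_that("setting RMSD: self-identity, relabel equivariance, rigid invariance", {
  an <- archaeal_anchors()
  r <- asymmetric_ring()
  ring <- r$truth$ring
  tpl <- core_template(r$model, "F", an)
  hex <- build_core_hexamer(r$model, ring, tpl)
  tab <- setting_rmsd_table(hex, hex)
  expect_equal(tab$best_setting, 1)
  expect_lt(tab$best_rmsd, 1e-9)
  expect_true(all(tab$rmsd_by_setting[2:6] > 0.1))
  # relabel equivariance: rotating target ring labels by k shifts the best
  # setting by k (mod 6) and leaves the best RMSD unchanged
  for (k in 1:5) {
    chains <- ring$chain[((seq_len(6) - 1 + k) %% 6) + 1]
    hex_k <- build_core_hexamer(r$model, ring_map(chains), tpl)
    tab_k <- setting_rmsd_table(hex, hex_k)
    expect_equal(tab_k$best_setting, k + 1)
    expect_equal(tab_k$best_rmsd, tab$best_rmsd, tolerance = 1e-9)
    expect_lt(tab_k$rmsd_by_setting[[k + 1]], 1e-9)
    expect_gt(tab_k$rmsd_by_setting[[1]], 0.1)
  }
  # applying one rigid motion to the whole target changes nothing
  set.seed(113)
  moved <- transform_model(r$model, random_rotation(), c(5, -9, 17))
  hex_m <- build_core_hexamer(moved, ring, tpl)
  tab_m <- setting_rmsd_table(hex, hex_m)
  expect_equal(tab_m$rmsd_by_setting, tab$rmsd_by_setting, tolerance = 1e-6)
  expect_error(setting_rmsd(hex, hex, 7), "1-6")
})

test_that("global 912-point RMSD is at least any single-copy RMSD", {
  an <- archaeal_anchors()
  ra <- asymmetric_ring(seed = 1L)
  rb <- make_ring(ring_spec(per_subunit_twist = c(-5, -25, -35, 0, 20, 10),
                            seed = 2L))
  tpl_a <- core_template(ra$model, "F", an)
  hex_a <- build_core_hexamer(ra$model, ra$truth$ring, tpl_a)
  hex_b <- build_core_hexamer(rb$model, rb$truth$ring, tpl_a)
  for (s in 1:6) {
    whole <- setting_rmsd(hex_a, hex_b, s)
    ref_idx <- ((seq_len(6) - 1 + (s - 1)) %% 6) + 1
    parts <- sapply(1:6, function(p)
      superpose(hex_a$copies[[ref_idx[p]]], hex_b$copies[[p]])$rmsd)
    expect_gte(whole + 1e-9, min(parts))
  }
})

test_that("bin_and_sort orders by class, best setting, then descending RMSD", {
  recs <- data.frame(
    structure_id = c("s1", "s2", "e1", "s3", "s4", "s5"),
    mean_dihedral = c(-30, -31, -10, -33, -29, -35),
    tier_class = c("staggered", "staggered", "eclipsed", "staggered",
                   "staggered", "staggered"),
    best_setting = c(4L, 1L, 2L, 4L, 1L, 1L),
    best_rmsd = c(5.2, 3.1, 2.0, 4.8, 3.1, 7.4),
    stringsAsFactors = FALSE)
  out <- bin_and_sort(recs)
  expect_equal(out$structure_id, c("e1", "s5", "s2", "s4", "s1", "s3"))
  # eclipsed bin first; staggered setting-1 sub-bin precedes setting-4;
  # within sub-bins descending RMSD with stable id order on ties
  expect_equal(nrow(bin_and_sort(recs[0, ])), 0)
  single <- bin_and_sort(recs[1, ])
  expect_equal(single$structure_id, "s1")
})

test_that("survey separates eclipsed and staggered synthetic rings", {
  an <- archaeal_anchors()
  r_ecl <- make_ring(ring_spec(per_subunit_twist = rep(0, 6), seed = 7L),
                     id = "ring_eclipsed")
  r_stg <- make_ring(ring_spec(per_subunit_twist = rep(-31, 6), seed = 8L),
                     id = "ring_staggered")
  tpl <- core_template(r_stg$model, "F", an)
  ref <- build_core_hexamer(r_stg$model, r_stg$truth$ring, tpl)
  out <- survey_models(list(r_ecl$model, r_stg$model),
                       list(r_ecl$truth$ring, r_stg$truth$ring),
                       an, ref, tpl)
  expect_equal(out$tier_class, c("eclipsed", "staggered"))
  expect_equal(out$structure_id, c("ring_eclipsed", "ring_staggered"))
  expect_equal(out$best_setting[out$structure_id == "ring_staggered"], 1L)
})
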