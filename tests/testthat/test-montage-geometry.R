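test_that("midline sites sit at their arc fractions on the scalp", {
  # head scaled so the nasion-inion arc is exactly 360 mm
  R <- 360 / pi
  m <- build_sphere_phantom(default_head_spec(outer_radius = R), h = 4,
                            check = "none")
  sites <- midline_sites(m)
  expect_equal(attr(sites, "arc_length"), 360)
  cz <- sites[sites$site == "Cz", ]
  expect_equal(cz$arc_frac, 0.5)
  expect_equal(c(cz$x, cz$y, cz$z), c(0, 0, R), tolerance = 1e-12)

  named <- sites[sites$site != "extracephalic", ]
  r <- sqrt(named$x^2 + named$y^2 + named$z^2)
  expect_equal(r, rep(R, nrow(named)), tolerance = 1e-12)
  # consecutive sites are spaced by their arc-fraction differences
  # (Fpz to Fz spans 20% of the arc, all others 10% = 36 mm)
  ang <- acos(pmin(1, (named$x[-1] * named$x[-nrow(named)] +
                         named$y[-1] * named$y[-nrow(named)] +
                         named$z[-1] * named$z[-nrow(named)]) / R^2))
  expect_equal(ang * R, diff(named$arc_frac) * 360, tolerance = 1e-9)
  expect_equal(diff(named$arc_frac)[-1], rep(0.1, nrow(named) - 2))
})

test_that("arc fractions are invariant to head size", {
  m1 <- default_model(4)
  m2 <- build_sphere_phantom(default_head_spec(outer_radius = 105), h = 4,
                             check = "none")
  s1 <- midline_sites(m1); s2 <- midline_sites(m2)
  expect_equal(s1$arc_frac, s2$arc_frac)
  expect_equal(s1[, c("x", "y", "z")] / m1$meta$outer_radius,
               s2[, c("x", "y", "z")] / 105, tolerance = 1e-12)
})

test_that("footprint overlap follows the 5 cm arc rule", {
  expect_true(electrodes_overlap("CPz", "Pz"))    # 10% arc = 28.9 mm < 50 mm
  expect_true(electrodes_overlap("Pz", "POz"))
  expect_false(electrodes_overlap("Cz", "POz"))   # 30% arc >= 50 mm
  expect_false(electrodes_overlap("Pz", "extracephalic"))
  # symmetry, and invariance across plausible head sizes
  for (arc in c(300, 360)) {
    expect_equal(electrodes_overlap("CPz", "Pz", arc_length = arc),
                 electrodes_overlap("Pz", "CPz", arc_length = arc))
    expect_true(electrodes_overlap("CPz", "Pz", arc_length = arc))
    expect_false(electrodes_overlap("Cz", "POz", arc_length = arc))
  }
  expect_error(electrodes_overlap("XX", "Pz"), "unknown site")
})

test_that("candidate enumeration yields the reference 23 montages in order", {
  mt <- enumerate_candidates()
  expect_equal(nrow(mt), 23)
  expect_equal(mt$anode, reference_montages()$anode)
  expect_equal(mt$cathode, reference_montages()$cathode)
  keys <- paste(mt$anode, mt$cathode)
  expect_true(all(c("FCz POz", "Fz Pz", "POz Fpz") %in% keys))
  expect_false(any(c("Pz Pz", "CPz Pz", "Pz POz") %in% keys))
  expect_equal(anyDuplicated(t(apply(mt[, 1:2], 1, sort))), 0)
  # head-size invariance across the plausible adult range
  for (arc in c(270, 320, 420))
    expect_equal(enumerate_candidates(arc_length = arc)[, 1:2], mt[, 1:2])
})

test_that("electrode assemblies conform to the scalp with the right footprint", {
  sim <- cached_sim("FCz", "POz", h = 4)
  el <- sim$model$electrodes
  e <- electrode_spec()
  # rubber sheet: one voxel layer whose area approximates 35 cm^2
  for (rub in list(el$anode, el$cathode)) {
    area <- length(rub) * sim$model$h^2
    expect_lt(abs(area - 3500) / 3500, 0.10)
  }
  expect_length(intersect(el$anode_assembly, el$cathode_assembly), 0)
  # stamped labels present
  expect_true(any(sim$model$labels == tissue_codes()["saline_sponge"]))
  expect_true(any(sim$model$labels == tissue_codes()["rubber_sheet"]))

  # footprint area also holds at finer resolution
  m2 <- build_sphere_phantom(default_head_spec(), h = 2, check = "none")
  p2 <- place_electrodes(m2, montage("Cz", "extracephalic"))
  expect_lt(abs(length(p2$electrodes$anode) * 4 - 3500) / 3500, 0.10)
})

test_that("anode/cathode swap gives identical geometry with swapped roles", {
  m <- default_model(4)
  a <- place_electrodes(m, montage("FCz", "POz"))
  b <- place_electrodes(m, montage("POz", "FCz"))
  expect_identical(a$labels, b$labels)
  expect_identical(sort(a$electrodes$anode), sort(b$electrodes$cathode))
  expect_identical(sort(a$electrodes$cathode), sort(b$electrodes$anode))
})

test_that("overlapping montages are refused at placement", {
  m <- default_model(4)
  expect_error(place_electrodes(m, montage("CPz", "Pz")), "overlap")
  expect_error(montage("Pz", "Pz"), "differ")
})
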