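test_that("conductivity table carries the standard tissue values", {
  tab <- conductivity_table()
  expect_equal(unname(tab["gray_matter"]), 0.2)
  expect_equal(unname(tab["white_matter"]), 0.14)
  expect_equal(unname(tab["blood"]), 0.7)
  expect_equal(unname(tab["compact_bone"]), 0.008)
  expect_equal(unname(tab["spongy_bone"]), 0.027)
  expect_equal(unname(tab["dura"]), 0.16)
  expect_equal(unname(tab["csf"]), 1.8)
  expect_equal(unname(tab["muscle"]), 0.16)
  expect_equal(unname(tab["skin_fat"]), 0.08)
  expect_equal(unname(tab["eye"]), 1.5)
  expect_equal(unname(tab["saline_sponge"]), 1.6)
  expect_true(all(tab > 0))
  expect_false("air" %in% names(tab))
})

test_that("conductivity overrides touch only the named tissue", {
  tab <- conductivity_table(csf = 2.2)
  ref <- conductivity_table()
  expect_equal(unname(tab["csf"]), 2.2)
  other <- setdiff(names(ref), "csf")
  expect_equal(tab[other], ref[other])
  expect_error(conductivity_table(bogus = 1), "unknown tissue")
  expect_error(conductivity_table(csf = -1), "positive")
  expect_error(scale_conductivity(ref, c(csf = 0)), "positive")
})

test_that("sphere voxelization reproduces analytic volumes", {
  spec <- sphere_layer_spec(c(80, 40), c("skin_fat", "white_matter"))
  m <- build_sphere_phantom(spec, h = 4, check = "none")
  nvox <- sum(m$labels != 0L)
  expect_lt(abs(nvox * 4^3 - 4 / 3 * pi * 80^3) / (4 / 3 * pi * 80^3), 0.05)

  # center voxel of the default head is white matter
  md <- suppressWarnings(build_sphere_phantom(default_head_spec(), h = 2))
  cc <- (dim(md$labels) + 1L) / 2L
  expect_equal(md$labels[cc[1], cc[2], cc[3]],
               unname(tissue_codes()["white_matter"]))
})

test_that("thin layers are rejected in strict mode, naming the layer", {
  expect_error(build_sphere_phantom(default_head_spec(), h = 4, check = "strict"),
               "csf")
  expect_error(sphere_layer_spec(c(80, 85), c("skin_fat", "white_matter")),
               "decreasing")
  expect_error(sphere_layer_spec(c(80, 40), c("white_matter", "skin_fat")))
})

test_that("voxelized shell volumes converge monotonically as h decreases", {
  spec <- thick_spec()
  shells <- spec$radii
  analytic <- 4 / 3 * pi * (shells^3 - c(shells[-1], 0)^3)
  codes <- tissue_codes()[spec$tissues]
  err <- vapply(c(4, 2, 1), function(h) {
    m <- build_sphere_phantom(spec, h, check = "none")
    got <- vapply(codes, function(cd) sum(m$labels == cd) * h^3, numeric(1))
    max(abs(got - analytic) / analytic)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[2], 0.05)          # within 5% at h <= 2 mm
})

test_that("population sampling is deterministic and honors zero variance", {
  pop0 <- population_spec(thick_spec(), n = 4, thickness_cv = 0, size_cv = 0,
                          seed = 11)
  mods <- sample_population(pop0, h = 8)
  expect_length(mods, 4)
  for (k in 2:4) expect_identical(mods[[k]]$labels, mods[[1]]$labels)

  pop <- population_spec(thick_spec(), n = 5, seed = 3)
  a <- sample_population(pop, h = 8)
  b <- sample_population(pop, h = 8)
  expect_identical(lapply(a, `[[`, "labels"), lapply(b, `[[`, "labels"))
  expect_false(identical(a[[1]]$labels, a[[2]]$labels))
})

test_that("population variability matches the requested spread", {
  pop <- population_spec(default_head_spec(), n = 12, thickness_cv = 0,
                         size_cv = 0.05, seed = 21)
  mods <- sample_population(pop, h = 8)
  R <- vapply(mods, function(m) m$meta$outer_radius, numeric(1))
  nominal <- 92 * 0.05
  expect_gt(sd(R), nominal / 2)
  expect_lt(sd(R), nominal * 2)

  pop2 <- population_spec(default_head_spec(), n = 12, thickness_cv = 0.05,
                          size_cv = 0, seed = 22)
  mods2 <- sample_population(pop2, h = 8)
  skin <- vapply(mods2, function(m) m$meta$spec$thickness[["skin_fat"]], numeric(1))
  expect_gt(sd(skin), 0.3 * 0.5)   # nominal sd = 0.05 * 6 mm, within factor 2
  expect_lt(sd(skin), 0.3 * 2)
})

test_that("impossible perturbations error after resampling", {
  tiny_core <- sphere_layer_spec(c(80, 30, 26, 22, 10),
                                 c("skin_fat", "compact_bone", "csf",
                                   "gray_matter", "white_matter"))
  pop <- population_spec(tiny_core, n = 1, thickness_cv = 0, size_cv = 0, seed = 1)
  expect_error(sample_population(pop, h = 8), "resampling")
})

test_that("RNG state is restored after population sampling", {
  set.seed(99)
  before <- .Random.seed
  invisible(sample_population(population_spec(thick_spec(), n = 2, seed = 5), h = 8))
  expect_identical(.Random.seed, before)
})
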