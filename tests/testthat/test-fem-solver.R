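# a tiny all-tissue block model for source/interpolation tests
block_model <- function(n = 8L, h = 2) {
  lab <- array(tissue_codes()[["gray_matter"]], dim = c(n, n, n))
  structure(list(labels = lab, h = h, origin = rep(-h * (n - 1) / 2, 3),
                 meta = list(id = "block", spec = list(center = c(0, 0, 0)),
                             outer_radius = NA, arc_length = NA,
                             gm_outer = NA, gm_thickness = NA),
                 electrodes = NULL), class = "voxel_model")
}

test_that("source construction matches the volumetric density definition", {
  m <- block_model(10L, h = 1)
  src <- build_source(m, I_mA = 2, anode = 1L, cathode = 1000L)
  # one (1 mm)^3 anode voxel: density = 2e-3 A / 1e-9 m^3
  expect_equal(unname(src$density["anode"]), 2e-3 / 1e-9)
  expect_equal(sum(src$f), 0)
  expect_equal(sum(src$f[src$f > 0]), 2e-3, tolerance = 1e-12)

  z <- build_source(m, I_mA = 0, anode = 1L, cathode = 1000L)
  expect_true(all(z$f == 0))

  sw <- build_source(m, I_mA = 2, anode = 1000L, cathode = 1L)
  expect_equal(sw$f, -src$f)
  expect_error(build_source(m, anode = integer(0), cathode = 1L), "empty")
  expect_error(build_source(m, I_mA = 2, anode = 5L, cathode = 5L), "overlap")
})

test_that("zero source yields the zero potential without iterating", {
  m <- thick_model(8)
  sig <- tdcsim:::sigma_volume(m)
  sol <- fem_solve(sig, numeric(prod(dim(sig) + 1L)), m$h)
  expect_true(all(sol$phi == 0))
  expect_equal(sol$iterations, 0)
  expect_true(sol$converged)
})

test_that("uniform conduction in a homogeneous block gives E = J / sigma", {
  n <- 16L; h <- 2; d <- c(n, n, n)
  sig <- array(0.3, d)
  f <- numeric(prod(d + 1L))
  idx <- array(seq_len(prod(d)), d)
  lo <- as.vector(idx[1, , ]); hi <- as.vector(idx[n, , ])
  I <- 2e-3
  for (vox in list(list(lo, I), list(hi, -I))) {
    cn <- tdcsim:::.voxel_corner_nodes(vox[[1]], d)
    for (k in 1:8) f[cn[, k]] <- f[cn[, k]] + vox[[2]] / length(vox[[1]]) / 8
  }
  sol <- fem_solve(sig, f, h, tol = 1e-8)
  E <- tdcsim:::.efield_cpp(as.integer(d), as.numeric(sol$phi), h / 1000)
  expected <- I / (n * h / 1000)^2 / 0.3
  interior <- array(E$Ex, d)[4:13, 4:13, 4:13]
  expect_equal(mean(interior), expected, tolerance = 1e-6)
  expect_lt(max(abs(array(E$Ey, d)[4:13, 4:13, 4:13])), expected * 1e-6)
  # potential is linear along x in the interior
  ph <- sol$phi[, 9, 9]
  expect_lt(sd(diff(ph[4:13])), 1e-5 * abs(mean(diff(ph[4:13]))))
})

test_that("gradient of a linear potential is the exact constant field", {
  m <- block_model(8L, h = 2)
  d <- dim(m$labels)
  nod <- d + 1L
  xw <- m$origin[1] - m$h / 2 + (seq_len(nod[1]) - 1) * m$h
  phi <- array(rep(-xw / 1000, times = nod[2] * nod[3]), nod)  # -x in volts, x in m
  ef <- compute_efield(phi, m)
  expect_equal(max(abs(ef$Ex - 1)), 0, tolerance = 1e-9)
  expect_equal(max(abs(ef$Ey)), 0, tolerance = 1e-12)
  expect_equal(unname(ef$emag[3, 3, 3]), 1, tolerance = 1e-9)
})

test_that("solutions are linear in the source and antisymmetric in polarity", {
  m <- thick_model(8)
  p1 <- place_electrodes(m, montage("FCz", "POz"))
  s1 <- build_source(p1)
  sig <- tdcsim:::sigma_volume(p1)
  a <- fem_solve(sig, s1$f, m$h, tol = 1e-8)
  # polarity swap: exactly negated potential, |E| unchanged
  b <- fem_solve(sig, -s1$f, m$h, tol = 1e-8)
  expect_identical(b$phi, -a$phi)
  # superposition against a second montage's source on the same domain
  p2 <- place_electrodes(m, montage("Fz", "Pz"))
  sig2 <- tdcsim:::sigma_volume(p2)
  s2 <- build_source(p2)
  # solve both sources on a common conductivity map (both electrode sets stamped)
  lab <- p1$labels
  lab[p2$labels != tissue_codes()["air"] & lab == tissue_codes()["air"]] <-
    p2$labels[p2$labels != tissue_codes()["air"] & lab == tissue_codes()["air"]]
  pc <- p1; pc$labels <- lab
  sigc <- tdcsim:::sigma_volume(pc)
  u1 <- fem_solve(sigc, s1$f, m$h, tol = 1e-10)
  u2 <- fem_solve(sigc, s2$f, m$h, tol = 1e-10)
  u12 <- fem_solve(sigc, s1$f + s2$f, m$h, tol = 1e-10)
  expect_lt(max(abs(u12$phi - u1$phi - u2$phi)), 1e-6 * max(abs(u12$phi)))
})

test_that("global conductivity scaling rescales the field by 1/k", {
  m <- thick_model(8)
  sim <- cached_sim("FCz", "POz", model = m)
  k <- 2
  tab <- scale_conductivity(conductivity_table(),
                            setNames(rep(k, 12), names(conductivity_table())))
  sim2 <- simulate_montage(m, montage("FCz", "POz"), sigma_table = tab)
  expect_equal(sim2$efield$emag, sim$efield$emag / k, tolerance = 1e-10)
})

test_that("the gauge does not affect the field", {
  m <- block_model(6L, h = 2)
  nod <- dim(m$labels) + 1L
  set.seed(1)
  phi <- array(rnorm(prod(nod)), nod)
  e1 <- compute_efield(phi, m)
  e2 <- compute_efield(phi + 5, m)
  expect_equal(e1$Ex, e2$Ex, tolerance = 1e-9)
  expect_equal(e1$emag, e2$emag, tolerance = 1e-9)
})

test_that("enclosed-surface current matches the injection and degrades with tol", {
  m <- default_model(4)
  placed <- place_electrodes(m, montage("FCz", "POz"))
  src <- build_source(placed)
  tab <- conductivity_table()
  hi <- solve_potential(placed, tab, src, tol = 1e-6)
  rep_hi <- check_current_conservation(placed, tab, hi, src)
  expect_lt(rep_hi$rel_error, 0.01)
  expect_equal(rep_hi$I_injected_mA, 2)

  lo <- solve_potential(placed, tab, src, tol = 1e-2)
  rep_lo <- check_current_conservation(placed, tab, lo, src)
  expect_gt(rep_lo$rel_error, rep_hi$rel_error)

  zero <- build_source(placed, I_mA = 0)
  sol0 <- solve_potential(placed, tab, zero)
  rep0 <- check_current_conservation(placed, tab, sol0, zero)
  expect_equal(rep0$I_enclosed_mA, 0)
})

test_that("grid refinement shrinks the oracle error monotonically", {
  sp <- layered_sphere_spec(radii = 60, sigma = 0.2, L = 300)
  errs <- vapply(c(6, 3, 1.5), function(h)
    compare_with_fem(sp, h, shell_radius = 50)$rel_l2_emag, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.05)
})

test_that("unbalanced sources are rejected", {
  m <- thick_model(8)
  sig <- tdcsim:::sigma_volume(m)
  f <- numeric(prod(dim(sig) + 1L))
  f[5000] <- 1e-3
  expect_error(fem_solve(sig, f, m$h), "unbalanced")
})
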