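test_that("surface samples sit on the sphere 1 mm below the gray matter", {
  m <- default_model(4)
  s <- cortical_samples(m, d = 1, n_points = 2000)
  r <- sqrt(rowSums(s^2))
  expect_equal(r, rep(m$meta$gm_outer - 1, length(r)), tolerance = 1e-9)
  expect_error(cortical_samples(m, d = 10), "thinner")
})

test_that("the sampling lattice is quasi-uniform and mirror-symmetric", {
  p <- fibonacci_sphere(10000)
  expect_equal(nrow(p), 10000)
  # exact left/right pairing by construction
  half <- nrow(p) / 2
  expect_identical(p[seq_len(half) + half, ],
                   cbind(-p[seq_len(half), 1], p[seq_len(half), 2:3]))
  # nearest-neighbor spacing has CV < 15%
  nn <- numeric(nrow(p))
  for (i0 in seq(1, nrow(p), by = 1000)) {
    i1 <- min(i0 + 999, nrow(p))
    D <- 2 - 2 * p[i0:i1, ] %*% t(p)
    for (k in seq_len(i1 - i0 + 1)) D[k, i0 + k - 1] <- Inf
    nn[i0:i1] <- sqrt(pmax(apply(D, 1, min), 0))
  }
  expect_lt(sd(nn) / mean(nn), 0.15)
  # deterministic in n
  expect_identical(fibonacci_sphere(500), fibonacci_sphere(500))
})

test_that("component-then-norm interpolation reproduces simple fields", {
  n <- 8L; h <- 2
  lab <- array(tissue_codes()[["gray_matter"]], dim = c(n, n, n))
  m <- structure(list(labels = lab, h = h, origin = rep(-h * (n - 1) / 2, 3),
                      meta = list(id = "blk", spec = list(center = c(0, 0, 0)),
                                  gm_outer = NA, gm_thickness = NA),
                      electrodes = NULL), class = "voxel_model")
  # constant field
  E0 <- c(0.3, -0.4, 1.2)
  ef <- structure(list(
    Ex = array(E0[1], dim(lab)), Ey = array(E0[2], dim(lab)),
    Ez = array(E0[3], dim(lab)), emag = array(sqrt(sum(E0^2)), dim(lab)),
    h = h, origin = m$origin), class = "efield_sample")
  rec <- tdcsim:::.recover_nodes(ef$Ex, ef$Ey, ef$Ez)
  ef$Exn <- rec$x; ef$Eyn <- rec$y; ef$Ezn <- rec$z
  set.seed(2)
  pts <- matrix(runif(30, -4, 4), 10)
  expect_equal(interpolate_ef_magnitude(ef, pts),
               rep(sqrt(sum(E0^2)), 10), tolerance = 1e-12)
  # a point at an element center returns that element's field
  ctr <- matrix(m$origin + h * c(3, 3, 3), 1)
  expect_equal(interpolate_ef_magnitude(ef, ctr), sqrt(sum(E0^2)))

  # linear components are reproduced exactly away from the boundary
  cx <- m$origin[1] + (seq_len(n) - 1) * h
  lin <- outer(outer(cx, cx, function(a, b) 0.1 * a + 0.2 * b), cx,
               function(ab, c) ab + 0.05 * c)
  ef2 <- structure(list(Ex = lin, Ey = lin * 2, Ez = lin * 0,
                        emag = abs(lin) * sqrt(5), h = h, origin = m$origin),
                   class = "efield_sample")
  rec2 <- tdcsim:::.recover_nodes(ef2$Ex, ef2$Ey, ef2$Ez)
  ef2$Exn <- rec2$x; ef2$Eyn <- rec2$y; ef2$Ezn <- rec2$z
  pin <- matrix(runif(30, -3, 3), 10)
  want <- (0.1 * pin[, 1] + 0.2 * pin[, 2] + 0.05 * pin[, 3]) * sqrt(5)
  expect_equal(interpolate_ef_magnitude(ef2, pin), abs(want), tolerance = 1e-9)
  expect_error(interpolate_ef_magnitude(ef2, matrix(c(40, 0, 0), 1)), "outside")
})

test_that("interpolated |E| never exceeds the contributing elements' maximum", {
  sim <- cached_sim("FCz", "POz", h = 4)
  s <- cortical_samples(sim$model, d = 1, n_points = 1000)
  v <- interpolate_ef_magnitude(sim$efield, s)
  expect_true(all(v <= max(sim$efield$emag, na.rm = TRUE) + 1e-12))
  expect_true(all(v >= 0))
})

test_that("ROI mapping gives geodesic discs of the right area", {
  m <- default_model(4)
  s <- cortical_samples(m, d = 1, n_points = 10000)
  r_s <- attr(s, "radius")
  roi <- default_rois()[1, ]
  idx <- map_roi_to_model(roi, s)
  area_est <- length(idx) / nrow(s) * 4 * pi * r_s^2
  expect_lt(abs(area_est - pi * 100) / (pi * 100), 0.10)
  # left/right ROIs are exact mirror images on the symmetric lattice
  idxL <- map_roi_to_model(default_rois()[1, ], s)   # M1_left
  idxR <- map_roi_to_model(default_rois()[2, ], s)   # M1_right
  expect_identical(sort(abs(s[idxL, 1])), sort(abs(s[idxR, 1])))
  expect_identical(sort(s[idxL, 2]), sort(s[idxR, 2]))
  # zero radius selects the single nearest point
  roi0 <- roi; roi0$radius <- 0
  expect_length(map_roi_to_model(roi0, s), 1)
})

test_that("ROI means are simple arithmetic means of |E|", {
  expect_equal(roi_mean_ef(c(0.4, 0.6), c(1, 2)), 0.5)
  expect_equal(roi_mean_ef(rep(0.5, 10), 1:10), 0.5)
  expect_error(roi_mean_ef(c(1, 2), integer(0)), "empty")
})

test_that("ROI means are stable in the lattice density", {
  sim <- cached_sim("FCz", "POz", h = 4)
  a <- roi_means(sim, n_points = 10000)
  b <- roi_means(sim, n_points = 20000)
  expect_lt(max(abs(a - b) / a), 0.02)
})
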