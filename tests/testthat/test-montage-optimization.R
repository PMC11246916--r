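three_montages <- function() {
  mt <- enumerate_candidates()
  mt[paste(mt$anode, mt$cathode) %in% c("FCz POz", "Fz Pz", "Cz Iz"), ]
}

test_that("zero-variance populations have zero across-model spread", {
  pop <- population_spec(thick_spec(), n = 3, thickness_cv = 0, size_cv = 0,
                         seed = 9)
  models <- sample_population(pop, h = 8)
  ev <- evaluate_montages(models, three_montages(), n_points = 4000)
  sds <- unlist(ev$table[grep("_sd$", names(ev$table))])
  expect_true(all(sds == 0))
  cnt <- per_model_optima(ev)
  expect_equal(sum(cnt), 3)
  expect_equal(max(cnt), 3)        # all models agree on one optimum
  expect_false(any(ev$table$incomplete))
})

test_that("polarity swap and current scaling act as expected on evaluations", {
  m <- thick_model(8)
  mt1 <- data.frame(anode = "FCz", cathode = "POz", current_mA = 2)
  mt2 <- data.frame(anode = "POz", cathode = "FCz", current_mA = 2)
  e1 <- evaluate_montages(list(m), mt1, n_points = 4000)
  e2 <- evaluate_montages(list(m), mt2, n_points = 4000)
  expect_equal(e1$table$average_mean, e2$table$average_mean, tolerance = 1e-12)
  mt4 <- data.frame(anode = "FCz", cathode = "POz", current_mA = 4)
  e4 <- evaluate_montages(list(m), mt4, n_points = 4000)
  expect_equal(e4$table$average_mean, 2 * e1$table$average_mean,
               tolerance = 1e-12)
  expect_equal(e4$roi, 2 * e1$roi, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the population mean of averages equals the average of ROI means", {
  pop <- population_spec(thick_spec(), n = 3, seed = 13)
  models <- sample_population(pop, h = 8)
  ev <- evaluate_montages(models, three_montages()[1:2, ], n_points = 4000)
  roi_cols <- paste0(ev$rois$roi, "_mean")
  expect_equal(rowMeans(as.matrix(ev$table[, roi_cols])),
               ev$table$average_mean, tolerance = 1e-12)
})

test_that("ranking sorts by the population mean and flags ties", {
  m <- thick_model(8)
  ev <- evaluate_montages(list(m), three_montages(), n_points = 4000)
  rk <- rank_montages(ev)
  expect_true(all(diff(rk$average_mean) <= 0))
  expect_equal(rk$rank, 1:3)
  expect_false(attr(rk, "ties"))
  # a deliberate tie is flagged and resolved by list order
  ev2 <- ev
  ev2$avg[, 2] <- ev2$avg[, 1]
  ev2$table$average_mean[2] <- ev2$table$average_mean[1]
  rk2 <- rank_montages(ev2)
  expect_true(attr(rk2, "ties"))
  cnt <- per_model_optima(ev2)
  expect_equal(sum(cnt), 1)
  expect_length(attr(cnt, "ties"), 1)
  expect_equal(unname(which(cnt == 1)), unname(which.max(ev2$avg[1, ])))
})

test_that("ranking is invariant under global conductivity scaling", {
  m <- thick_model(8)
  ev <- evaluate_montages(list(m), three_montages(), n_points = 4000)
  k <- 1.7
  tab <- scale_conductivity(conductivity_table(),
                            setNames(rep(k, 12), names(conductivity_table())))
  evk <- evaluate_montages(list(m), three_montages(), sigma_table = tab,
                           n_points = 4000)
  expect_equal(evk$table$average_mean, ev$table$average_mean / k,
               tolerance = 1e-9)
  expect_equal(rank_montages(evk)[, c("anode", "cathode")],
               rank_montages(ev)[, c("anode", "cathode")])
})

test_that("the sensitivity machinery honors identity and scaling laws", {
  pop <- population_spec(thick_spec(), n = 1, thickness_cv = 0, size_cv = 0,
                         seed = 1)
  models <- sample_population(pop, h = 8)
  mt <- three_montages()
  sens <- sensitivity_analysis(models, mt, scenarios = list(
    baseline = c(),
    all_x1 = c(csf = 1, compact_bone = 1, spongy_bone = 1),
    uniform_x2 = setNames(rep(2, 12), names(conductivity_table())),
    bone_x0.5 = c(compact_bone = 0.5, spongy_bone = 0.5)
  ), n_points = 4000)
  b <- sens$evaluations$baseline$table
  expect_identical(sens$evaluations$all_x1$table, b)
  expect_equal(sens$evaluations$uniform_x2$table$average_mean,
               b$average_mean / 2, tolerance = 1e-12)
  expect_equal(rank_montages(sens$evaluations$uniform_x2)[, 1:2],
               rank_montages(sens$evaluations$baseline)[, 1:2])
  # perturbing the bone really changes the cortical field
  expect_true(all(abs(sens$evaluations$bone_x0.5$table$average_mean -
                        b$average_mean) > 1e-8))
  expect_error(sensitivity_analysis(models, mt,
                                    scenarios = list(bad = c(csf = -1))),
               "positive")
})

test_that("the default sensitivity scenarios perturb bone jointly and CSF by 10%", {
  sc <- default_scenarios()
  expect_named(sc, c("baseline", "bone_x0.5", "bone_x1.5", "csf_x0.9", "csf_x1.1"))
  expect_equal(sc$bone_x0.5[["compact_bone"]], 0.5)
  expect_equal(sc$bone_x0.5[["spongy_bone"]], 0.5)
  expect_equal(sc$csf_x1.1[["csf"]], 1.1)
})

test_that("front-back reflection of a midline montage preserves |E|", {
  # |E| of Fz-Pz is invariant under y -> -y on a symmetric phantom: the
  # reflected configuration is the polarity-swapped montage, whose magnitude
  # field is identical.
  sim <- cached_sim("Fz", "Pz", h = 4)
  set.seed(6)
  pts <- matrix(rnorm(60), 20)
  pts <- pts / sqrt(rowSums(pts^2)) * 70
  refl <- cbind(pts[, 1], -pts[, 2], pts[, 3])
  a <- interpolate_ef_magnitude(sim$efield, pts)
  b <- interpolate_ef_magnitude(sim$efield, refl)
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("solve failures are recorded and flagged, not fatal", {
  m <- thick_model(8)
  mt <- data.frame(anode = c("FCz", "CPz"), cathode = c("POz", "Pz"),
                   current_mA = 2)   # second pair overlaps -> placement error
  ev <- evaluate_montages(list(m), mt, n_points = 4000)
  expect_false(ev$table$incomplete[1])
  expect_true(ev$table$incomplete[2])
  expect_length(ev$errors, 1)
  expect_error(per_model_optima(ev), "incomplete")
})
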