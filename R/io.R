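# ---- NIfTI volume I/O -------------------------------------------------------

.model_affine <- function(origin, h) {
  rbind(cbind(diag(h, 3), origin), c(0, 0, 0, 1))
}

#' Write a label volume as NIfTI
#'
#' Stores the tissue-label array as int16 with an affine carrying the voxel
#' size and world origin.
#'
#' @param model A `voxel_model`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_label_nifti <- function(model, path) {
  stopifnot(inherits(model, "voxel_model"))
  img <- RNifti::asNifti(model$labels, datatype = "int16")
  img <- RNifti::`sform<-`(img, structure(.model_affine(model$origin, model$h), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a scalar volume as NIfTI
#'
#' @param arr 3-D numeric array on the voxel or node grid.
#' @param origin World coordinate of the first array element's center (mm).
#' @param h Grid spacing (mm).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_volume_nifti <- function(arr, origin, h, path) {
  arr[is.na(arr)] <- 0
  img <- RNifti::asNifti(arr, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(.model_affine(origin, h), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an externally supplied label volume
#'
#' Loads a NIfTI label volume (integer tissue codes as in [tissue_codes()])
#' into a `voxel_model`. Geometry metadata that a sphere phantom carries by
#' construction (outer radius, gray-matter radius, midline arc) is estimated
#' from the labels, assuming an approximately spherical head centered at the
#' label centroid.
#'
#' @param path NIfTI file with integer labels.
#' @param id Provenance tag.
#' @return A `voxel_model`.
#' @export
read_label_nifti <- function(path, id = basename(path)) {
  img <- RNifti::readNifti(path)
  lab <- array(as.integer(img), dim = dim(img))
  xf <- RNifti::xform(img)
  sp <- sqrt(colSums(xf[1:3, 1:3]^2))      # voxel spacing from the affine
  if (max(abs(sp - sp[1])) > 1e-6 * sp[1])
    stop("label volume must have isotropic voxels")
  h <- sp[1]
  origin <- xf[1:3, 4]
  bad <- setdiff(unique(as.integer(lab)), unname(.TISSUE_CODES))
  if (length(bad)) stop("unknown label code(s): ", paste(bad, collapse = ", "))
  idx <- which(lab != .TISSUE_CODES[["air"]])
  if (!length(idx)) stop("volume contains no tissue")
  ijk <- arrayInd(idx, dim(lab))
  wc <- sweep((ijk - 1) * h, 2, origin, `+`)
  ctr <- colMeans(wc)
  rr <- sqrt(rowSums(sweep(wc, 2, ctr)^2))
  R <- max(rr) + h / 2
  gm <- which(lab == .TISSUE_CODES[["gray_matter"]])
  gm_outer <- gm_thick <- NA_real_
  if (length(gm)) {
    gijk <- arrayInd(gm, dim(lab))
    gwc <- sweep((gijk - 1) * h, 2, origin, `+`)
    gr <- sqrt(rowSums(sweep(gwc, 2, ctr)^2))
    gm_outer <- max(gr) + h / 2
    gm_thick <- gm_outer - (min(gr) - h / 2)
  }
  spec <- structure(list(center = ctr), class = "external_volume_spec")
  structure(list(labels = lab, h = h, origin = origin,
                 meta = list(id = id, spec = spec, seed = NA_integer_,
                             anterior = c(0, 1, 0), superior = c(0, 0, 1),
                             outer_radius = R, arc_length = pi * R,
                             gm_outer = gm_outer, gm_thickness = gm_thick),
                 electrodes = NULL),
            class = "voxel_model")
}

# ---- run configuration ------------------------------------------------------

#' Default run configuration
#'
#' The fully serializable configuration consumed by the pipeline commands.
#'
#' @param ... Overrides of top-level entries (partial lists are merged).
#' @return Nested list of class `"run_config"`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    phantom = list(outer_radius = 92, spongy_bone = FALSE, extended = FALSE),
    population = list(n = 62, thickness_cv = 0.10, size_cv = 0.03, seed = 1),
    electrode = list(length_mm = 70, width_mm = 50, sponge_mm = 5, rubber_mm = 1),
    montage = list(anode = "FCz", cathode = "POz", current_mA = 2),
    solver = list(h = 2, tol = 1e-6, maxit = 10000, precond = "ic0"),
    sampling = list(depth = 1, n_points = 10000),
    roi_radius = 10,
    conductivity = list(),        # named per-tissue overrides
    seed = 1
  )
  ov <- list(...)
  for (nm in names(ov)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
      modifyList(cfg[[nm]], ov[[nm]]) else ov[[nm]]
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' Entries missing from the file take their defaults from
#' [default_run_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(default_run_config, raw)
}

.cfg_sigma <- function(cfg) do.call(conductivity_table, as.list(cfg$conductivity))
.cfg_espec <- function(cfg) do.call(electrode_spec, cfg$electrode)
.cfg_phantom_spec <- function(cfg)
  default_head_spec(cfg$phantom$outer_radius, cfg$phantom$spongy_bone,
                    cfg$phantom$extended)

.write_config_copy <- function(cfg, out_dir) {
  cp <- unclass(cfg)
  cp$tool_version <- as.character(packageVersion("tdcsim"))
  yaml::write_yaml(cp, file.path(out_dir, "run_config.yaml"))
}

# fixed-precision CSV so repeated runs are byte-identical
.write_csv6 <- function(df, path) {
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- signif(df[[nm]], 6)
  write.csv(df, path, row.names = FALSE)
}

# ---- pipeline commands ------------------------------------------------------

#' Simulate one montage on one phantom and write the artifacts
#'
#' Builds the configured phantom, runs the montage simulation, and writes the
#' potential and |E| NIfTI volumes, the cortical surface samples
#' (`surface_samples.csv`: x, y, z, emag), the ROI means
#' (`roi_means.csv`), and a copy of the configuration into `out_dir`.
#'
#' @param config A `run_config` (or path to one).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the `tdcs_sim` object and the ROI means.
#' @export
run_simulate <- function(config = default_run_config(), out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- config$solver$h
  model <- build_sphere_phantom(.cfg_phantom_spec(config), h, check = "none",
                                id = "phantom001")
  m <- montage(config$montage$anode, config$montage$cathode,
               config$montage$current_mA)
  if (!quiet) message(sprintf("simulating %s-%s at h = %g mm", m$anode, m$cathode, h))
  sim <- simulate_montage(model, m, .cfg_sigma(config), .cfg_espec(config),
                          tol = config$solver$tol, maxit = config$solver$maxit,
                          precond = config$solver$precond)
  if (!quiet) message(sprintf("CG converged in %d iterations", sim$potential$iterations))

  write_volume_nifti(sim$potential$phi, sim$model$origin - h / 2, h,
                     file.path(out_dir, "phi.nii.gz"))
  emag <- sim$efield$emag
  write_volume_nifti(emag, sim$model$origin, h, file.path(out_dir, "emag.nii.gz"))

  samples <- cortical_samples(sim$model, config$sampling$depth,
                              config$sampling$n_points)
  ev <- interpolate_ef_magnitude(sim$efield, samples)
  .write_csv6(data.frame(x = samples[, 1], y = samples[, 2], z = samples[, 3],
                         emag = ev),
              file.path(out_dir, "surface_samples.csv"))
  rois <- default_rois(config$roi_radius)
  rm_ <- roi_means(sim, rois, d = config$sampling$depth,
                   n_points = config$sampling$n_points, samples = samples)
  .write_csv6(data.frame(roi = names(rm_), mean_emag = as.numeric(rm_)),
              file.path(out_dir, "roi_means.csv"))
  .write_config_copy(config, out_dir)
  invisible(list(sim = sim, roi_means = rm_))
}

#' Optimize the montage over a phantom population and write the tables
#'
#' Samples the configured phantom population, evaluates every candidate
#' montage, and writes `montage_table.csv` (per-montage population mean and
#' SD of each ROI mean and of the four-ROI average, in candidate order),
#' `montage_ranking.csv`, and `optima_counts.csv`.
#'
#' @param config A `run_config` (or path).
#' @param out_dir Output directory.
#' @param montages Optional montage subset (default: all candidates).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the `montage_eval`.
#' @export
run_optimize <- function(config = default_run_config(), out_dir,
                         montages = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- config$solver$h
  pop <- population_spec(.cfg_phantom_spec(config), n = config$population$n,
                         thickness_cv = config$population$thickness_cv,
                         size_cv = config$population$size_cv,
                         seed = config$population$seed)
  models <- sample_population(pop, h)
  espec <- .cfg_espec(config)
  if (is.null(montages))
    montages <- enumerate_candidates(espec, models[[1]]$meta$arc_length,
                                     config$montage$current_mA)
  if (!quiet)
    message(sprintf("evaluating %d montages on %d models at h = %g mm",
                    nrow(montages), length(models), h))
  ev <- evaluate_montages(models, montages, default_rois(config$roi_radius),
                          .cfg_sigma(config), espec,
                          d = config$sampling$depth,
                          n_points = config$sampling$n_points,
                          tol = config$solver$tol, maxit = config$solver$maxit)
  .write_csv6(ev$table, file.path(out_dir, "montage_table.csv"))
  .write_csv6(rank_montages(ev), file.path(out_dir, "montage_ranking.csv"))
  cnt <- per_model_optima(ev)
  .write_csv6(data.frame(montage = names(cnt), count = as.integer(cnt)),
              file.path(out_dir, "optima_counts.csv"))
  .write_config_copy(config, out_dir)
  if (any(ev$table$incomplete))
    warning("some montages are incomplete; see the evaluation's error list")
  invisible(ev)
}

#' Run the conductivity sensitivity analysis and write the summary
#'
#' @param config A `run_config` (or path).
#' @param out_dir Output directory.
#' @param montages Optional montage subset.
#' @param scenarios Scenario list, see [default_scenarios()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, the `sensitivity_result`.
#' @export
run_sensitivity <- function(config = default_run_config(), out_dir,
                            montages = NULL, scenarios = default_scenarios(),
                            quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- config$solver$h
  pop <- population_spec(.cfg_phantom_spec(config), n = config$population$n,
                         thickness_cv = config$population$thickness_cv,
                         size_cv = config$population$size_cv,
                         seed = config$population$seed)
  models <- sample_population(pop, h)
  espec <- .cfg_espec(config)
  if (is.null(montages))
    montages <- enumerate_candidates(espec, models[[1]]$meta$arc_length,
                                     config$montage$current_mA)
  sens <- sensitivity_analysis(models, montages, scenarios,
                               default_rois(config$roi_radius),
                               .cfg_sigma(config), espec,
                               d = config$sampling$depth,
                               n_points = config$sampling$n_points,
                               tol = config$solver$tol,
                               maxit = config$solver$maxit,
                               verbose = !quiet)
  for (nm in names(sens$evaluations))
    .write_csv6(sens$evaluations[[nm]]$table,
                file.path(out_dir, sprintf("montage_table_%s.csv", nm)))
  jsonlite::write_json(list(optimal = as.list(sens$optimal),
                            robust_set = sens$robust_set),
                       file.path(out_dir, "sensitivity_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  .write_config_copy(config, out_dir)
  invisible(sens)
}

#' Validate the solver against the analytic oracle
#'
#' Runs the layered-sphere oracle comparison at the configured resolution and
#' a current-conservation check on a montage solve, writes
#' `oracle_report.csv`, and reports pass/fail against the 10% relative-L2
#' field-error and 1% conservation thresholds.
#'
#' @param config A `run_config` (or path).
#' @param out_dir Output directory.
#' @param l2_threshold Pass threshold for the |E| relative L2 error.
#' @param conservation_threshold Pass threshold for the enclosed-current
#'   relative error.
#' @param quiet Suppress progress messages.
#' @return Invisibly, list with the `oracle_comparison`, the
#'   `conservation_report` and `pass` (logical).
#' @export
run_validate <- function(config = default_run_config(), out_dir,
                         l2_threshold = 0.10, conservation_threshold = 0.01,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- config$solver$h
  if (!quiet) message(sprintf("oracle comparison at h = %g mm", h))
  cmp <- compare_with_fem(layered_sphere_spec(), h, tol = config$solver$tol,
                          maxit = config$solver$maxit)

  model <- build_sphere_phantom(.cfg_phantom_spec(config), max(h, 4),
                                check = "none")
  m <- montage(config$montage$anode, config$montage$cathode,
               config$montage$current_mA)
  placed <- place_electrodes(model, m, .cfg_espec(config))
  src <- build_source(placed)
  pot <- solve_potential(placed, .cfg_sigma(config), src,
                         tol = config$solver$tol, maxit = config$solver$maxit)
  cons <- check_current_conservation(placed, .cfg_sigma(config), pot, src)

  rep <- data.frame(
    quantity = c("rel_l2_phi", "rel_l2_emag", "max_rel_phi", "max_rel_emag",
                 "conservation_rel_error"),
    value = c(cmp$rel_l2_phi, cmp$rel_l2_emag, cmp$max_rel_phi,
              cmp$max_rel_emag, cons$rel_error)
  )
  .write_csv6(rep, file.path(out_dir, "oracle_report.csv"))
  pass <- cmp$rel_l2_emag <= l2_threshold && cons$rel_error <= conservation_threshold
  if (!quiet) {
    print(cmp); print(cons)
    message(if (pass) "validation PASSED" else "validation FAILED")
  }
  invisible(list(oracle = cmp, conservation = cons, pass = pass))
}
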