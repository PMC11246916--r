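#' Mirror-symmetric quasi-uniform directions on the unit sphere
#'
#' A Fibonacci-type lattice constructed on the x > 0 hemisphere and completed
#' by its mirror image in the x = 0 plane. The mirror symmetry gives exact
#' point-for-point left/right correspondence, so bilateral ROI comparisons on
#' a symmetric head model measure field asymmetry only, not sampling noise —
#' the phantom analog of registering both hemispheres to a common template.
#'
#' @param n Requested number of points (rounded up to an even count).
#' @return Matrix (n x 3) of unit vectors, deterministic in `n`.
#' @export
fibonacci_sphere <- function(n) {
  m <- ceiling(n / 2)
  i <- seq_len(m) - 1
  x <- (i + 0.5) / m                 # cos(colatitude about the +x axis)
  ga <- pi * (3 - sqrt(5))
  phi <- i * ga
  s <- sqrt(pmax(1 - x^2, 0))
  half <- cbind(x, s * cos(phi), s * sin(phi))
  out <- rbind(half, cbind(-half[, 1], half[, 2], half[, 3]))
  dimnames(out) <- NULL
  out
}

#' Cortical-surface sample points
#'
#' Places quasi-uniform sample points on the sphere `d` mm below the outer
#' gray-matter boundary (default depth 1 mm), the surface on which the field
#' magnitude is interpolated and ROI statistics are taken. All models of a
#' population share the same angular lattice, so sample `i` corresponds
#' across models by construction (the phantom surrogate for surface
#' registration).
#'
#' @param model A `voxel_model` built from a sphere phantom.
#' @param d Depth below the gray-matter surface in mm.
#' @param n_points Number of lattice points (default 10000).
#' @return Object of class `"cortical_samples"`: matrix of world coordinates
#'   with attributes `radius`, `directions`, `depth`.
#' @export
cortical_samples <- function(model, d = 1, n_points = 10000) {
  stopifnot(inherits(model, "voxel_model"))
  gm <- model$meta$gm_outer
  if (is.na(gm)) stop("model has no gray-matter shell")
  if (d >= model$meta$gm_thickness)
    stop(sprintf("gray-matter shell (%g mm) is thinner than the sampling depth %g mm",
                 model$meta$gm_thickness, d))
  dirs <- fibonacci_sphere(n_points)
  ctr <- model$meta$spec$center
  pts <- sweep(dirs * (gm - d), 2, ctr, `+`)
  structure(pts, class = c("cortical_samples", "matrix"),
            radius = gm - d, directions = dirs, depth = d,
            center = ctr)
}

#' Interpolate the field magnitude at surface points
#'
#' Interpolates the three field components and then takes the norm
#' (component-then-norm convention), so the result never exceeds the largest
#' |E| among the contributing elements. Components are carried from the
#' element centers to the query points through the node-recovered arrays of
#' [compute_efield()] (adjacent-element averaging followed by trilinear
#' interpolation), which suppresses staircase noise at voxelized tissue
#' boundaries. Air elements carry no field and are excluded by weight
#' renormalization during recovery.
#'
#' @param efield An `efield_sample` from [compute_efield()].
#' @param pts Matrix (n x 3) of world points inside the solved grid.
#' @return Numeric vector of |E| values (V/m).
#' @export
interpolate_ef_magnitude <- function(efield, pts) {
  stopifnot(inherits(efield, "efield_sample"))
  pts <- as.matrix(pts)
  g0 <- efield$origin - efield$h / 2        # node grid origin
  ex <- .trilinear(efield$Exn, pts, g0, efield$h)
  ey <- .trilinear(efield$Eyn, pts, g0, efield$h)
  ez <- .trilinear(efield$Ezn, pts, g0, efield$h)
  sqrt(ex^2 + ey^2 + ez^2)
}

#' Stimulation target ROIs
#'
#' The four cortical regions of interest for joint M1+SMA stimulation:
#' bilateral primary motor cortex leg areas at template coordinates
#' `[+/-9, -39, 54]` mm and bilateral supplementary motor area at
#' `[+/-3, -9, 60]` mm, each a geodesic disc of 10 mm radius on the sampling
#' surface. Coordinates are interpreted as MNI-style template millimeters
#' (x right, y anterior, z superior).
#'
#' @param radius Geodesic ROI radius in mm (default 10).
#' @return `data.frame` with columns `roi`, `cx`, `cy`, `cz`, `radius`.
#' @export
default_rois <- function(radius = 10) {
  data.frame(
    roi = c("M1_left", "M1_right", "SMA_left", "SMA_right"),
    cx = c(-9, 9, -3, 3),
    cy = c(-39, -39, -9, -9),
    cz = c(54, 54, 60, 60),
    radius = radius,
    stringsAsFactors = FALSE
  )
}

#' Map a template-space ROI onto a phantom's sampling surface
#'
#' The declared template-to-phantom mapping is an isotropic affine about the
#' head center (template cortical extent scaled onto the phantom's
#' gray-matter sphere, axes aligned: x right, y anterior, z superior)
#' followed by radial projection onto the sampling surface — so only the
#' direction of the template coordinate matters. ROI membership is geodesic:
#' all sample points within the ROI radius of arc distance from the
#' projected center. A zero radius selects the single nearest sample point.
#'
#' @param roi One row of [default_rois()] (or a compatible list).
#' @param samples A [cortical_samples()] object.
#' @return Integer vector of sample-point indices.
#' @export
map_roi_to_model <- function(roi, samples) {
  stopifnot(inherits(samples, "cortical_samples"))
  dirs <- attr(samples, "directions")
  r_s <- attr(samples, "radius")
  ctr_dir <- .unitize(c(roi$cx, roi$cy, roi$cz))
  cosang <- pmin(pmax(dirs %*% ctr_dir, -1), 1)
  arc <- r_s * acos(cosang)
  if (roi$radius == 0) return(which.min(arc))
  idx <- which(arc <= roi$radius)
  if (!length(idx)) stop("ROI '", roi$roi, "' contains no sample points")
  idx
}

#' Mean field strength over an ROI
#'
#' Arithmetic mean of the per-point |E| values over an ROI's sample points.
#'
#' @param emag Per-sample |E| values (V/m), aligned with the sample matrix.
#' @param roi_idx Integer indices from [map_roi_to_model()].
#' @return Mean |E| in V/m.
#' @export
roi_mean_ef <- function(emag, roi_idx) {
  if (!length(roi_idx)) stop("empty ROI")
  if (anyNA(emag[roi_idx])) stop("ROI contains points with undefined field")
  mean(emag[roi_idx])
}

#' ROI-mean field strengths for a simulation
#'
#' Convenience wrapper: samples the cortical surface, interpolates |E|, and
#' returns the four ROI means plus their unweighted average — the montage
#' optimization objective.
#'
#' @param sim A `tdcs_sim` from [simulate_montage()].
#' @param rois ROI table, see [default_rois()].
#' @param d,n_points Sampling parameters, see [cortical_samples()].
#' @param samples Optional precomputed [cortical_samples()] (saves rebuilding
#'   the lattice across montages).
#' @return Named numeric vector: one mean per ROI plus `average` (V/m).
#' @export
roi_means <- function(sim, rois = default_rois(), d = 1, n_points = 10000,
                      samples = NULL) {
  stopifnot(inherits(sim, "tdcs_sim"))
  if (is.null(samples)) samples <- cortical_samples(sim$model, d, n_points)
  emag <- interpolate_ef_magnitude(sim$efield, samples)
  vals <- vapply(seq_len(nrow(rois)), function(i) {
    roi_mean_ef(emag, map_roi_to_model(rois[i, ], samples))
  }, numeric(1))
  names(vals) <- rois$roi
  c(vals, average = mean(vals))
}
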