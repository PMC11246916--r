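#' Concentric-shell head phantom specification
#'
#' Describes a layered-sphere head phantom: a list of shell outer radii
#' (strictly decreasing toward the core) with one tissue label per shell. The
#' innermost shell extends from its outer radius down to the center. The
#' nasion-inion midline scalp arc is the half great circle over the vertex, so
#' its length is `pi * outer_radius`.
#'
#' @param radii Numeric vector of shell outer radii in mm, strictly
#'   decreasing; `radii[1]` is the scalp (outermost) radius.
#' @param tissues Character vector of tissue labels, one per shell, outermost
#'   first. Must start with `"skin_fat"` and end with `"white_matter"`.
#' @param center Head center in world coordinates (mm).
#' @return List of class `"sphere_layer_spec"` with fields `radii`, `tissues`,
#'   `center`, `arc_length` and per-shell `thickness`.
#' @seealso [default_head_spec()], [build_sphere_phantom()]
#' @export
sphere_layer_spec <- function(radii, tissues, center = c(0, 0, 0)) {
  radii <- as.numeric(radii)
  if (length(radii) != length(tissues))
    stop("one tissue label per shell required")
  if (any(diff(radii) >= 0) || any(radii <= 0))
    stop("shell radii must be positive and strictly decreasing toward the core")
  bad <- setdiff(tissues, names(.TISSUE_CODES))
  if (length(bad)) stop("unknown tissue label(s): ", paste(bad, collapse = ", "))
  if (tissues[1] != "skin_fat")
    stop("outermost shell must be 'skin_fat'")
  if (tissues[length(tissues)] != "white_matter")
    stop("innermost shell must be 'white_matter'")
  thickness <- c(-diff(radii), radii[length(radii)])
  structure(list(
    radii = radii, tissues = tissues, center = as.numeric(center),
    thickness = setNames(thickness, tissues),
    arc_length = pi * radii[1]
  ), class = "sphere_layer_spec")
}

#' Default six-shell head phantom
#'
#' Anatomically plausible defaults for an adult head: outer radius 92 mm with
#' scalp (skin/fat) 6 mm, compact bone 4 mm (optionally split 1/2/1 mm around
#' a spongy-bone core), dura 1.5 mm, CSF 3 mm, gray matter 4 mm, and white
#' matter filling the remainder.
#'
#' @param outer_radius Scalp radius in mm (default 92).
#' @param spongy_bone If `TRUE`, insert a 2 mm spongy-bone mid-layer inside
#'   the compact bone.
#' @param extended If `TRUE`, split the scalp into a 3 mm skin/fat shell over
#'   a 3 mm muscle shell (the blood and eye compartments of real anatomy are
#'   supported by the conductivity table but are not part of the spherical
#'   default geometry).
#' @return A [sphere_layer_spec()].
#' @export
default_head_spec <- function(outer_radius = 92, spongy_bone = FALSE,
                              extended = FALSE) {
  R <- outer_radius
  if (extended) {
    radii <- c(R, R - 3); tissues <- c("skin_fat", "muscle"); base <- R - 6
  } else {
    radii <- R; tissues <- "skin_fat"; base <- R - 6
  }
  if (spongy_bone) {
    radii <- c(radii, base, base - 1, base - 3)
    tissues <- c(tissues, "compact_bone", "spongy_bone", "compact_bone")
  } else {
    radii <- c(radii, base)
    tissues <- c(tissues, "compact_bone")
  }
  skull_in <- base - 4
  radii <- c(radii, skull_in, skull_in - 1.5, skull_in - 4.5, skull_in - 8.5)
  tissues <- c(tissues, "dura", "csf", "gray_matter", "white_matter")
  # 'extended' keeps skin_fat outermost per the shell convention; the muscle
  # shell sits directly beneath it.
  spec <- sphere_layer_spec(radii, tissues)
  spec
}

#' Voxelize a layered-sphere phantom
#'
#' Labels each voxel by the shell containing its center. Air fills the volume
#' outside the outermost radius. The grid is centered on the head center with
#' an odd number of voxels per axis, so the phantom is exactly
#' mirror-symmetric about its three mid-planes; the margin leaves room for
#' scalp electrode assemblies.
#'
#' @param spec A [sphere_layer_spec()].
#' @param h Voxel edge length in mm (isotropic). The reference resolution for
#'   production runs is 0.5 mm; coarser grids trade accuracy for speed.
#' @param margin Air margin around the scalp in mm (default 14, enough for an
#'   11 mm electrode assembly).
#' @param check Thin-layer policy. Every shell should be at least `2 * h`
#'   thick for faithful voxelization. `"warn"` (default) warns about thinner
#'   shells, `"strict"` makes them an error (naming the shell), `"none"` stays
#'   silent. Coarse grids over thin shells are legitimate for quick,
#'   qualitative runs, which is why the default does not error.
#' @param id Provenance tag stored in the model metadata.
#' @return List of class `"voxel_model"`: integer `labels` array, voxel size
#'   `h`, world `origin` (center of voxel `[1,1,1]`), and `meta` (spec,
#'   derived radii, anterior axis, id).
#' @examples
#' m <- build_sphere_phantom(default_head_spec(), h = 4)
#' table(m$labels)[-1]
#' @export
build_sphere_phantom <- function(spec, h, margin = 14,
                                 check = c("warn", "strict", "none"),
                                 id = "phantom") {
  stopifnot(inherits(spec, "sphere_layer_spec"))
  check <- match.arg(check)
  if (!is.numeric(h) || h <= 0) stop("voxel size h must be positive")
  thin <- spec$thickness[spec$thickness < 2 * h]
  # the white-matter core is a filled ball, not a thin shell
  thin <- thin[names(thin) != "white_matter"]
  if (length(thin)) {
    msg <- sprintf("shell(s) thinner than 2*h = %g mm: %s", 2 * h,
                   paste(sprintf("%s (%g mm)", names(thin), thin), collapse = ", "))
    if (check == "strict") stop(msg)
    if (check == "warn") warning(msg)
  }

  R <- spec$radii[1]
  half <- R + margin
  n <- ceiling(2 * half / h)
  if (n %% 2 == 0) n <- n + 1L            # odd: voxel centers include the origin
  n <- as.integer(n)
  ax <- (seq_len(n) - (n + 1) / 2) * h    # voxel-center coordinates about 0
  origin <- spec$center + ax[1]

  r2 <- outer(outer((ax - 0)^2, (ax)^2, `+`), (ax)^2, `+`)
  r <- sqrt(r2)
  # shells: tissue i occupies (radii[i+1], radii[i]]; innermost fills the core
  bounds <- c(spec$radii, 0)
  codes <- .TISSUE_CODES[spec$tissues]
  lab <- array(.TISSUE_CODES[["air"]], dim = c(n, n, n))
  idx <- findInterval(-r, -bounds, left.open = TRUE)  # descending bounds
  inside <- idx >= 1 & idx <= length(codes) & r <= R
  lab[inside] <- codes[idx[inside]]
  storage.mode(lab) <- "integer"

  gm_i <- match("gray_matter", spec$tissues)
  structure(list(
    labels = lab, h = h, origin = origin,
    meta = list(
      id = id, spec = spec, seed = NA_integer_,
      anterior = c(0, 1, 0), superior = c(0, 0, 1),
      outer_radius = R, arc_length = spec$arc_length,
      gm_outer = if (!is.na(gm_i)) spec$radii[gm_i] else NA_real_,
      gm_thickness = if (!is.na(gm_i)) spec$thickness[["gray_matter"]] else NA_real_
    ),
    electrodes = NULL
  ), class = "voxel_model")
}

#' @export
print.voxel_model <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("Voxel head model '%s': %d x %d x %d voxels at h = %g mm\n",
              x$meta$id, d[1], d[2], d[3], x$h))
  cat(sprintf("  outer radius %.1f mm, midline arc %.1f mm\n",
              x$meta$outer_radius, x$meta$arc_length))
  tb <- table(factor(as.integer(x$labels), levels = .TISSUE_CODES,
                     labels = names(.TISSUE_CODES)))
  tb <- tb[tb > 0]
  cat("  voxels per label:\n")
  print(tb)
  if (!is.null(x$electrodes))
    cat(sprintf("  electrodes placed: %s-%s\n",
                x$electrodes$montage$anode, x$electrodes$montage$cathode))
  invisible(x)
}

# World coordinates of all voxel centers along one axis.
.axis_coords <- function(model, axis) {
  n <- dim(model$labels)[axis]
  model$origin[axis] + (seq_len(n) - 1) * model$h
}

#' Phantom population specification
#'
#' Describes a population of head phantoms standing in for a cohort of
#' MRI-derived anatomical models. Inter-individual variability is modelled as
#' a global size factor plus independent per-shell thickness jitter, both
#' truncated-normal.
#'
#' @param base A [sphere_layer_spec()] giving the nominal anatomy.
#' @param n Number of models (default 62).
#' @param thickness_cv Coefficient of variation of each shell thickness
#'   (default 0.10, typical of adult skull/CSF thickness variability).
#' @param size_cv Coefficient of variation of global head size (default 0.03,
#'   typical of adult head-circumference variability).
#' @param seed Integer RNG seed; identical seeds give identical populations.
#' @return List of class `"population_spec"`.
#' @export
population_spec <- function(base = default_head_spec(), n = 62,
                            thickness_cv = 0.10, size_cv = 0.03, seed = 1L) {
  stopifnot(inherits(base, "sphere_layer_spec"))
  if (n < 1) stop("population size n must be >= 1")
  if (thickness_cv < 0 || size_cv < 0) stop("CVs must be >= 0")
  structure(list(base = base, n = as.integer(n),
                 thickness_cv = thickness_cv, size_cv = size_cv,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Sample a phantom population
#'
#' Draws `pop$n` voxelized phantoms. Per model, a global scale factor
#' `s ~ N(1, size_cv)` and per-shell thicknesses `t_i ~ N(s * t0_i,
#' thickness_cv * s * t0_i)` are drawn (truncated normal: draws are rejected
#' and resampled while any thickness is non-positive or the white-matter core
#' would vanish). Deterministic for a fixed seed.
#'
#' @param pop A [population_spec()].
#' @param h Voxel size in mm.
#' @param check Thin-layer policy passed to [build_sphere_phantom()]
#'   (default `"none"`: jittered thin shells are expected at coarse h).
#' @param max_attempts Resampling attempts per model before erroring.
#' @return List of `voxel_model` objects.
#' @export
sample_population <- function(pop, h, check = "none", max_attempts = 100L) {
  stopifnot(inherits(pop, "population_spec"))
  base <- pop$base
  t0 <- c(-diff(base$radii), base$radii[length(base$radii)])
  nshell <- length(base$radii)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(pop$seed)
  models <- vector("list", pop$n)
  for (i in seq_len(pop$n)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      s <- 1 + pop$size_cv * rnorm(1)
      tt <- t0[-nshell] * s * (1 + pop$thickness_cv * rnorm(nshell - 1))
      if (s <= 0.2 || any(tt <= 0)) next
      R <- base$radii[1] * s
      core <- R - sum(tt)
      if (core <= max(1, 2 * h)) next     # white-matter core must survive
      radii <- R - cumsum(c(0, tt))
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf("model %d: no valid geometry after %d resampling attempts",
                   i, max_attempts))
    spec_i <- sphere_layer_spec(radii, base$tissues, base$center)
    models[[i]] <- build_sphere_phantom(spec_i, h, check = check,
                                        id = sprintf("phantom%03d", i))
    models[[i]]$meta$seed <- pop$seed
  }
  models
}
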