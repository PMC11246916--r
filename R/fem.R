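# Reference stiffness matrix for a trilinear element on the unit cube with
# unit conductivity, by 2x2x2 Gauss quadrature (exact for this integrand).
# The stiffness of an element of edge h (meters) is sigma * h * Kref.
.kref <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gp <- (c(-1, 1) / sqrt(3) + 1) / 2
    corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))  # a = ax + 2 ay + 4 az
    K <- matrix(0, 8, 8)
    shp <- function(c, t) if (c == 1) t else 1 - t
    dshp <- function(c) if (c == 1) 1 else -1
    for (gx in gp) for (gy in gp) for (gz in gp) {
      G <- matrix(0, 8, 3)
      for (a in 1:8) {
        cx <- corners[a, 1]; cy <- corners[a, 2]; cz <- corners[a, 3]
        G[a, 1] <- dshp(cx) * shp(cy, gy) * shp(cz, gz)
        G[a, 2] <- shp(cx, gx) * dshp(cy) * shp(cz, gz)
        G[a, 3] <- shp(cx, gx) * shp(cy, gy) * dshp(cz)
      }
      K <- K + G %*% t(G) / 8
    }
    cache <<- K
    K
  }
})

#' Current source distribution for a placed montage
#'
#' Distributes the injected current uniformly over the anode rubber-sheet
#' voxels (+I) and the cathode rubber voxels (-I) as a volumetric source
#' density, then converts it to the consistent nodal load vector (each voxel
#' spreads its current equally over its 8 corner nodes). Global balance is
#' enforced exactly by removing any floating-point residue.
#'
#' @param model A `voxel_model` with electrodes placed (see
#'   [place_electrodes()]), or any model if `anode`/`cathode` voxel sets are
#'   given explicitly.
#' @param I_mA Injected current in mA. Defaults to the placed montage's
#'   current. `I_mA = 0` gives an all-zero source (sham).
#' @param anode,cathode Optional explicit linear voxel index sets overriding
#'   the placed electrodes (used e.g. for point-like single-voxel sources in
#'   oracle comparisons).
#' @return List of class `"source_distribution"`: nodal load vector `f` (A),
#'   per-voxel `density` (A/m^3) at the source voxels, the voxel sets and
#'   current.
#' @export
build_source <- function(model, I_mA = NULL, anode = NULL, cathode = NULL) {
  stopifnot(inherits(model, "voxel_model"))
  if (is.null(anode) != is.null(cathode))
    stop("give both anode and cathode voxel sets, or neither")
  if (is.null(anode)) {
    if (is.null(model$electrodes)) stop("model has no placed electrodes")
    anode <- model$electrodes$anode
    cathode <- model$electrodes$cathode
    if (is.null(I_mA)) I_mA <- model$electrodes$montage$current_mA
  }
  if (is.null(I_mA)) I_mA <- 2
  if (!length(anode) || !length(cathode)) stop("empty electrode voxel set")
  if (length(intersect(anode, cathode))) stop("anode and cathode voxels overlap")
  d <- dim(model$labels)
  hm <- model$h / 1000
  I <- I_mA / 1000
  nn <- prod(d + 1L)
  f <- numeric(nn)
  if (I != 0) {
    per_a <- I / length(anode) / 8
    per_c <- -I / length(cathode) / 8
    na <- .voxel_corner_nodes(anode, d)
    nc <- .voxel_corner_nodes(cathode, d)
    for (k in 1:8) {
      fa <- tabulate(na[, k], nbins = nn)
      f <- f + per_a * fa
    }
    for (k in 1:8) {
      fc <- tabulate(nc[, k], nbins = nn)
      f <- f + per_c * fc
    }
    f <- f - sum(f) / sum(f != 0) * (f != 0)   # remove rounding residue
  }
  structure(list(
    f = f, I_mA = I_mA, anode = anode, cathode = cathode,
    density = c(anode = I / (length(anode) * hm^3),
                cathode = -I / (length(cathode) * hm^3)),
    dims = d
  ), class = "source_distribution")
}

# 8 corner node linear indices (1-based, node grid dims d+1) per voxel.
.voxel_corner_nodes <- function(vox, d) {
  ijk <- arrayInd(vox, d)
  mx <- d[1] + 1L; my <- d[2] + 1L
  out <- matrix(0L, length(vox), 8)
  k <- 0L
  for (az in 0:1) for (ay in 0:1) for (ax in 0:1) {
    k <- k + 1L
    out[, k] <- (ijk[, 1] + ax) + mx * (ijk[, 2] + ay - 1L) +
      mx * my * (ijk[, 3] + az - 1L)
  }
  out
}

#' Low-level FEM solve on an explicit conductivity volume
#'
#' Solves `div(sigma grad phi) = i` with homogeneous Neumann boundary
#' conditions on a voxel grid, given the per-voxel conductivity directly.
#' Most callers want [solve_potential()], which derives the conductivity from
#' a labelled model; this entry point exists for phantoms with arbitrary
#' per-layer conductivities (e.g. oracle comparisons).
#'
#' @param sigma 3-D numeric array of per-voxel conductivities (S/m, 0 = air).
#' @param f Nodal load vector (A), length `prod(dim(sigma) + 1)`.
#' @param h Voxel edge length in mm.
#' @param tol Relative-residual tolerance (default 1e-6).
#' @param maxit Maximum CG iterations (default 10000).
#' @param precond `"ic0"` (incomplete Cholesky, default) or `"jacobi"`.
#' @return List: `phi` (3-D nodal array, V, zero-mean gauge over the
#'   conducting domain), `iterations`, `relres` history, `converged`.
#' @export
fem_solve <- function(sigma, f, h, tol = 1e-6, maxit = 10000L,
                      precond = c("ic0", "jacobi")) {
  precond <- match.arg(precond)
  d <- dim(sigma)
  stopifnot(length(d) == 3)
  if (length(f) != prod(d + 1L)) stop("load vector length mismatch")
  bal <- sum(f)
  scale <- max(abs(f), 1e-300)
  if (abs(bal) > 1e-9 * scale * length(f))
    stop("unbalanced source: net current ", bal, " A")
  res <- .fem_solve_cpp(as.integer(d), as.numeric(sigma), as.numeric(f),
                        .kref(), h / 1000, tol, as.integer(maxit),
                        if (precond == "ic0") 1L else 0L)
  if (!res$converged && any(f != 0)) {
    stop(sprintf(
      "CG did not converge in %d iterations (final relative residual %.3g); %s",
      res$iterations, utils::tail(res$relres, 1),
      "residual history in the error condition"),
      call. = FALSE)
  }
  list(phi = array(res$phi, dim = d + 1L), iterations = res$iterations,
       relres = res$relres, converged = res$converged, nactive = res$nactive)
}

#' Solve the volume-conduction equation on a labelled model
#'
#' Assembles first-order (trilinear) cubical elements over all non-air voxels
#' with the per-label conductivities and solves the singular Neumann system by
#' preconditioned conjugate gradients, projecting out the constant mode each
#' iteration. The returned potential is zero-mean over the conducting domain.
#'
#' @param model A `voxel_model`.
#' @param sigma_table A [conductivity_table()].
#' @param source A [build_source()] result.
#' @inheritParams fem_solve
#' @return List of class `"potential_field"`: nodal `phi` array (V), `model`
#'   dims/h, gauge tag, convergence info.
#' @export
solve_potential <- function(model, sigma_table = conductivity_table(), source,
                            tol = 1e-6, maxit = 10000L,
                            precond = c("ic0", "jacobi")) {
  stopifnot(inherits(model, "voxel_model"),
            inherits(source, "source_distribution"))
  if (!identical(dim(model$labels), source$dims))
    stop("source was built for a different grid")
  sig <- sigma_volume(model, sigma_table)
  res <- fem_solve(sig, source$f, model$h, tol = tol, maxit = maxit,
                   precond = match.arg(precond))
  structure(list(phi = res$phi, h = model$h, origin = model$origin,
                 gauge = "zero-mean", iterations = res$iterations,
                 relres = res$relres, tol = tol), class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("Nodal potential on %s grid, h = %g mm (%s gauge)\n",
              paste(dim(x$phi), collapse = " x "), x$h, x$gauge))
  cat(sprintf("  CG: %d iterations, final relative residual %.3g\n",
              x$iterations, utils::tail(c(0, x$relres), 1)))
  invisible(x)
}

#' Electric field from a solved potential
#'
#' Evaluates `E = -grad(phi)` at every element center from the trilinear
#' shape-function gradients. Vector components are retained (the field
#' direction distinguishes anterior-posterior from posterior-anterior
#' stimulation); air elements are set to `NA`.
#'
#' @param phi A `potential_field` from [solve_potential()], or a plain nodal
#'   array (then `h`/`origin` must come from `model`).
#' @param model The `voxel_model` the potential was solved on.
#' @return List of class `"efield_sample"`: arrays `Ex`, `Ey`, `Ez` and
#'   magnitude `emag` (V/m) at element centers, node-recovered component
#'   arrays `Exn`, `Eyn`, `Ezn` (see Details), plus grid info.
#' @details For off-grid sampling the element-center components are first
#'   recovered to the nodes by averaging the adjacent elements' values
#'   (air-excluded), a standard gradient-recovery smoothing that removes most
#'   of the voxelization noise of the piecewise-trilinear potential near
#'   staircased tissue interfaces.
#' @export
compute_efield <- function(phi, model) {
  stopifnot(inherits(model, "voxel_model"))
  arr <- if (inherits(phi, "potential_field")) phi$phi else phi
  d <- dim(model$labels)
  if (!identical(dim(arr), d + 1L)) stop("potential grid does not match the model")
  E <- .efield_cpp(as.integer(d), as.numeric(arr), model$h / 1000)
  air <- model$labels == .TISSUE_CODES[["air"]]
  Ex <- array(E$Ex, d); Ey <- array(E$Ey, d); Ez <- array(E$Ez, d)
  Ex[air] <- NA_real_; Ey[air] <- NA_real_; Ez[air] <- NA_real_
  rec <- .recover_nodes(Ex, Ey, Ez)
  structure(list(Ex = Ex, Ey = Ey, Ez = Ez,
                 emag = sqrt(Ex^2 + Ey^2 + Ez^2),
                 Exn = rec$x, Eyn = rec$y, Ezn = rec$z,
                 h = model$h, origin = model$origin),
            class = "efield_sample")
}

# Average element-center component arrays to the nodes (NA-aware): each node
# takes the mean over its adjacent non-air elements.
.recover_nodes <- function(Ex, Ey, Ez) {
  d <- dim(Ex)
  dn <- d + 1L
  ok <- !is.na(Ex)
  W <- array(0, dn)
  one <- function(A) {
    S <- array(0, dn)
    Az <- A; Az[!ok] <- 0
    ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1)
      S[ix + cx, iy + cy, iz + cz] <- S[ix + cx, iy + cy, iz + cz] + Az
    S
  }
  ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1)
    W[ix + cx, iy + cy, iz + cz] <- W[ix + cx, iy + cy, iz + cz] + ok
  Sx <- one(Ex) / W; Sy <- one(Ey) / W; Sz <- one(Ez) / W
  Sx[W == 0] <- NA_real_; Sy[W == 0] <- NA_real_; Sz[W == 0] <- NA_real_
  list(x = Sx, y = Sy, z = Sz)
}

#' Discrete current-conservation report
#'
#' Two verification quantities for a solved system: (a) the maximum nodal
#' residual of the discrete weak form away from source nodes, and (b) the
#' total current crossing a closed voxel surface enclosing the anode
#' assembly, computed by flux summation of `sigma * E` against the gradient
#' of a nodal indicator function (a route independent of the CG iteration).
#' At a converged solve the enclosed-surface current should match the
#' injected current to well within 1%.
#'
#' @param model,sigma_table,phi,source The solved configuration.
#' @param pad Indicator box padding around the anode, in voxels.
#' @return List of class `"conservation_report"`: `I_enclosed_mA`,
#'   `I_injected_mA`, `rel_error`, `max_residual` (A).
#' @export
check_current_conservation <- function(model, sigma_table = conductivity_table(),
                                       phi, source, pad = 2L) {
  stopifnot(inherits(model, "voxel_model"),
            inherits(source, "source_distribution"))
  arr <- if (inherits(phi, "potential_field")) phi$phi else phi
  d <- dim(model$labels)
  hm <- model$h / 1000
  sig <- sigma_volume(model, sigma_table)

  # (a) nodal residual away from source nodes
  Af <- .fem_apply_cpp(as.integer(d), as.numeric(sig), as.numeric(arr),
                       .kref(), hm)
  resid <- Af - source$f
  src_nodes <- unique(as.vector(.voxel_corner_nodes(
    c(source$anode, source$cathode), d)))
  max_resid <- max(abs(resid[-src_nodes]), 0)

  # (b) flux through a closed surface enclosing the anode: the current leaving
  # the indicator box is the Galerkin bilinear form chi^T A phi = int(sigma
  # grad(phi) . grad(chi)), evaluated matrix-free through the element loop —
  # independent of the CG iteration that produced phi.
  flux <- function(vox) {
    ijk <- arrayInd(vox, d)
    lo <- pmax(apply(ijk, 2, min) - pad, 1L)
    hi <- pmin(apply(ijk, 2, max) + pad, d)
    chi <- array(0, d + 1L)
    chi[lo[1]:(hi[1] + 1L), lo[2]:(hi[2] + 1L), lo[3]:(hi[3] + 1L)] <- 1
    sum(chi * Af)
  }
  I_out <- flux(source$anode)
  I <- source$I_mA / 1000
  structure(list(
    I_enclosed_mA = I_out * 1000,
    I_injected_mA = source$I_mA,
    rel_error = if (I != 0) abs(I_out - I) / abs(I) else abs(I_out),
    max_residual = max_resid
  ), class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("Enclosed-surface current: %.6f mA (injected %.6f mA, rel. error %.3g)\n",
              x$I_enclosed_mA, x$I_injected_mA, x$rel_error))
  cat(sprintf("Max nodal residual away from sources: %.3g A\n", x$max_residual))
  invisible(x)
}

#' Simulate one montage on one head model
#'
#' The central forward simulation: places the electrode assemblies, builds
#' the balanced current source, solves the volume-conduction equation and
#' derives the electric field. Returns a classed object carrying everything
#' downstream modules need.
#'
#' @param model A `voxel_model` without electrodes.
#' @param m A [montage()] (or one-row montage data frame).
#' @param sigma_table A [conductivity_table()].
#' @param espec An [electrode_spec()].
#' @param tol,maxit,precond Solver settings, see [fem_solve()].
#' @return Object of class `"tdcs_sim"`: the electrode-bearing `model`, the
#'   `potential` field, the `efield`, the `montage`, and solver diagnostics.
#' @examples
#' \donttest{
#' m <- build_sphere_phantom(default_head_spec(), h = 4, check = "none")
#' sim <- simulate_montage(m, montage("FCz", "POz"))
#' summary(sim)
#' }
#' @export
simulate_montage <- function(model, m, sigma_table = conductivity_table(),
                             espec = electrode_spec(), tol = 1e-6,
                             maxit = 10000L, precond = "ic0") {
  placed <- place_electrodes(model, m, espec)
  src <- build_source(placed)
  pot <- solve_potential(placed, sigma_table, src, tol = tol, maxit = maxit,
                         precond = precond)
  ef <- compute_efield(pot, placed)
  structure(list(model = placed, potential = pot, efield = ef,
                 montage = placed$electrodes$montage, source = src,
                 sigma_table = sigma_table),
            class = "tdcs_sim")
}

#' @export
print.tdcs_sim <- function(x, ...) {
  m <- x$montage
  cat(sprintf("tDCS simulation: %s -> %s at %g mA on '%s' (h = %g mm)\n",
              m$anode, m$cathode, m$current_mA, x$model$meta$id, x$model$h))
  cat(sprintf("  CG %d iterations, relative residual %.3g\n",
              x$potential$iterations, utils::tail(c(0, x$potential$relres), 1)))
  invisible(x)
}

#' @export
summary.tdcs_sim <- function(object, ...) {
  em <- object$efield$emag
  gm <- object$model$labels == .TISSUE_CODES[["gray_matter"]]
  out <- list(
    montage = object$montage,
    h = object$model$h,
    iterations = object$potential$iterations,
    emag_gm = summary(em[gm]),
    emag_head = summary(em[!is.na(em)])
  )
  class(out) <- "summary.tdcs_sim"
  out
}

#' @export
print.summary.tdcs_sim <- function(x, ...) {
  m <- x$montage
  cat(sprintf("tDCS simulation %s -> %s, %g mA, h = %g mm (%d CG iterations)\n",
              m$anode, m$cathode, m$current_mA, x$h, x$iterations))
  cat("|E| in gray matter (V/m):\n"); print(x$emag_gm)
  cat("|E| over all tissue (V/m):\n"); print(x$emag_head)
  invisible(x)
}

# Trilinear interpolation of a 3-D array sampled at grid coordinates
# grid0 + h * (0:(n-1)) per axis. pts: matrix (n x 3) of world coordinates.
# NA corners get zero weight (renormalized); all-NA neighborhoods give NA.
.trilinear <- function(arr, pts, grid0, h) {
  d <- dim(arr)
  t1 <- (pts[, 1] - grid0[1]) / h
  t2 <- (pts[, 2] - grid0[2]) / h
  t3 <- (pts[, 3] - grid0[3]) / h
  i1 <- floor(t1); i2 <- floor(t2); i3 <- floor(t3)
  if (any(i1 < 0 | i1 > d[1] - 2 | i2 < 0 | i2 > d[2] - 2 |
          i3 < 0 | i3 > d[3] - 2))
    stop("query point outside the sampled grid")
  f1 <- t1 - i1; f2 <- t2 - i2; f3 <- t3 - i3
  val <- numeric(nrow(pts)); wsum <- numeric(nrow(pts))
  for (c3 in 0:1) for (c2 in 0:1) for (c1 in 0:1) {
    w <- (if (c1 == 1) f1 else 1 - f1) *
      (if (c2 == 1) f2 else 1 - f2) *
      (if (c3 == 1) f3 else 1 - f3)
    idx <- (i1 + c1 + 1L) + d[1] * (i2 + c2) + d[1] * d[2] * (i3 + c3)
    v <- arr[idx]
    ok <- !is.na(v)
    val[ok] <- val[ok] + w[ok] * v[ok]
    wsum[ok] <- wsum[ok] + w[ok]
  }
  out <- val / wsum
  out[wsum == 0] <- NA_real_
  out
}

# Interpolate the nodal potential at world points (node grid starts h/2
# before the first voxel center).
interp_potential <- function(phi, pts) {
  stopifnot(inherits(phi, "potential_field"))
  .trilinear(phi$phi, pts, phi$origin - phi$h / 2, phi$h)
}
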