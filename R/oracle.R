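#' Layered-sphere specification for the analytic oracle
#'
#' A concentric N-layer sphere with piecewise-constant conductivity and a
#' pair of point current electrodes, for which the potential has a closed
#' Legendre-series form. Used as the independent verification oracle for the
#' voxel FEM solver. The default geometry is a 4-layer head: brain 80 mm
#' (0.2 S/m), CSF 83 mm (1.8 S/m), skull 87 mm (0.008 S/m), scalp 92 mm
#' (0.08 S/m).
#'
#' @param radii Layer outer radii in mm, strictly increasing (innermost
#'   first); the last entry is the outer head radius.
#' @param sigma Conductivity per layer (S/m), all positive.
#' @param L Series truncation order (default 300).
#' @param tol Relative tail tolerance for the series convergence check.
#' @return List of class `"layered_sphere_spec"`.
#' @export
layered_sphere_spec <- function(radii = c(80, 83, 87, 92),
                                sigma = c(0.2, 1.8, 0.008, 0.08),
                                L = 300L, tol = 1e-6) {
  radii <- as.numeric(radii); sigma <- as.numeric(sigma)
  if (length(radii) != length(sigma)) stop("one conductivity per layer required")
  if (any(diff(radii) <= 0) || any(radii <= 0)) stop("radii must be strictly increasing")
  if (any(sigma <= 0)) stop("conductivities must be positive")
  if (L < 1) stop("L must be >= 1")
  structure(list(radii = radii, sigma = sigma, L = as.integer(L), tol = tol),
            class = "layered_sphere_spec")
}

# Radial expansion coefficients for a unit point source (+1 A) at radius b_m
# in a layered sphere. Layer j's radial factor is
#   f_l(r) = A_j (r/r_j)^l + B_j (r/r_in_j)^{-(l+1)} [+ particular term in
# the source layer when the source is interior], with the growing basis
# normalized at the layer's outer radius and the decaying basis at its inner
# radius so every matrix entry stays O(1) at high degree. Continuity of phi and of
# sigma * dphi/dr is imposed at each interface; regularity fixes B_1 = 0.
# A surface source (b_m == R) enters through the outer Neumann datum
# sigma dphi/dr = I (2l+1) / (4 pi R^2) per degree l; an interior source
# contributes the free-space particular solution
#   p_l(r) = I/(4 pi sigma_s) * r_<^l / r_>^{l+1}
# and the outer boundary stays homogeneous Neumann. The l = 0 (monopole)
# terms of a balanced source/sink pair at equal radii cancel exactly, so the
# expansion starts at l = 1.
.oracle_coeffs <- function(radii_m, sigma, b_m, L) {
  N <- length(radii_m)
  R <- radii_m[N]
  surface <- abs(b_m - R) < 1e-12
  if (!surface && (b_m <= 0 || b_m >= R))
    stop("source radius must be in (0, R] ")
  js <- if (surface) N else findInterval(b_m, radii_m, left.open = TRUE) + 1L
  Acoef <- matrix(0, L, N); Bcoef <- matrix(0, L, N)
  # unknown layout: A_1, then (A_j, B_j) for j = 2..N
  pos_A <- c(1, seq(2, by = 2, length.out = N - 1))
  pos_B <- c(NA, seq(3, by = 2, length.out = N - 1))
  I <- 1
  for (l in seq_len(L)) {
    M <- matrix(0, 2 * N - 1, 2 * N - 1)
    rhs <- numeric(2 * N - 1)
    p <- function(r) {           # particular term (interior source only)
      if (surface) return(0)
      if (r <= b_m) (r / b_m)^l / b_m else (b_m / r)^(l + 1) / b_m
    }
    dp <- function(r) {
      if (surface) return(0)
      if (r <= b_m) (l / r) * (r / b_m)^l / b_m
      else (-(l + 1) / r) * (b_m / r)^(l + 1) / b_m
    }
    pfac <- if (surface) 0 else I / (4 * pi * sigma[js])
    row <- 0L
    for (i in seq_len(N - 1)) {
      ri <- radii_m[i]
      tt <- ri / radii_m[i + 1]               # < 1
      si <- if (i > 1) (ri / radii_m[i - 1])^(-(l + 1)) else 0  # layer i B at r_i
      # continuity of phi at r_i (layer i+1's B basis is 1 there)
      row <- row + 1L
      M[row, pos_A[i]] <- 1
      if (i > 1) M[row, pos_B[i]] <- si
      M[row, pos_A[i + 1]] <- -tt^l
      M[row, pos_B[i + 1]] <- -1
      rhs[row] <- -pfac * (as.numeric(i == js) - as.numeric(i + 1 == js)) * p(ri)
      # continuity of sigma * dphi/dr at r_i
      row <- row + 1L
      M[row, pos_A[i]] <- sigma[i] * l / ri
      if (i > 1) M[row, pos_B[i]] <- -sigma[i] * (l + 1) / ri * si
      M[row, pos_A[i + 1]] <- -sigma[i + 1] * l / ri * tt^l
      M[row, pos_B[i + 1]] <- sigma[i + 1] * (l + 1) / ri
      rhs[row] <- -(sigma[i] * as.numeric(i == js) -
                      sigma[i + 1] * as.numeric(i + 1 == js)) * pfac * dp(ri)
    }
    # outer boundary at R
    row <- row + 1L
    M[row, pos_A[N]] <- sigma[N] * l / R
    if (N > 1)
      M[row, pos_B[N]] <- -sigma[N] * (l + 1) / R * (R / radii_m[N - 1])^(-(l + 1))
    rhs[row] <- if (surface) I * (2 * l + 1) / (4 * pi * R^2)
    else -sigma[N] * as.numeric(N == js) * pfac * dp(R)
    sol <- solve(M, rhs)
    Acoef[l, ] <- sol[pos_A]
    if (N > 1) Bcoef[l, 2:N] <- sol[pos_B[2:N]]
  }
  list(A = Acoef, B = Bcoef, js = js, surface = surface, b_m = b_m,
       pfac = if (surface) 0 else 1 / (4 * pi * sigma[js]))
}

# Evaluate the per-degree radial factor f_l (and optionally f_l') at radii
# r_m (vector, meters) for all l = 1..L. Returns list of L x n matrices.
.oracle_radial <- function(co, radii_m, L, r_m, deriv = FALSE) {
  N <- length(radii_m)
  layer <- findInterval(r_m, radii_m, left.open = TRUE) + 1L
  layer[layer > N] <- N
  n <- length(r_m)
  Fv <- matrix(0, L, n)
  Fd <- if (deriv) matrix(0, L, n) else NULL
  b <- co$b_m
  for (j in seq_len(N)) {
    sel <- which(layer == j)
    if (!length(sel)) next
    r <- r_m[sel]
    x <- r / radii_m[j]
    xin <- if (j > 1) r / radii_m[j - 1] else rep(1, length(r))
    for (l in seq_len(L)) {
      ra <- x^l
      rb <- xin^(-(l + 1))
      v <- co$A[l, j] * ra + (if (j > 1) co$B[l, j] * rb else 0)
      if (!co$surface && j == co$js) {
        q <- ifelse(r <= b, (r / b)^l / b, (b / r)^(l + 1) / b)
        v <- v + co$pfac * q
      }
      Fv[l, sel] <- v
      if (deriv) {
        dv <- co$A[l, j] * (l / r) * ra -
          (if (j > 1) co$B[l, j] * ((l + 1) / r) * rb else rep(0, length(r)))
        if (!co$surface && j == co$js) {
          dq <- ifelse(r <= b, (l / r) * (r / b)^l / b,
                       -((l + 1) / r) * (b / r)^(l + 1) / b)
          dv <- dv + co$pfac * dq
        }
        Fd[l, sel] <- dv
      }
    }
  }
  list(f = Fv, df = Fd)
}

.unitize <- function(v) v / sqrt(sum(v^2))

.oracle_check_points <- function(spec, pts, electrodes, source_radius) {
  R <- spec$radii[length(spec$radii)]
  r <- sqrt(rowSums(pts^2))
  if (any(r >= R)) stop("query points must lie strictly inside the outer radius")
  # guard the source singularities: within ~1 degree of arc of an electrode
  guard <- R * pi / 180
  for (k in 1:2) {
    epos <- source_radius * .unitize(electrodes[k, ])
    dd <- sqrt(rowSums(sweep(pts, 2, epos)^2))
    if (any(dd < guard)) stop("query point at an electrode singularity")
  }
  r
}

#' Closed-form potential in a layered sphere with point electrodes
#'
#' Legendre-polynomial series solution for a +I/-I point-electrode pair on
#' (or inside) an N-layer concentric sphere: per-degree radial coefficients
#' are matched by continuity of the potential and of the radial current
#' density at each interface, with the point-source Neumann datum on the
#' outer boundary (surface electrodes) or a free-space particular solution
#' (interior sources, used to mimic single-voxel FEM sources whose centers
#' sit just below the scalp surface). Both electrodes must sit at the same
#' radius so the monopole terms cancel. The series is summed to `spec$L` with
#' a tail-magnitude convergence check.
#'
#' @param spec A [layered_sphere_spec()].
#' @param points Numeric matrix (n x 3) of query points in mm, strictly
#'   inside the outer radius and away from the electrode singularities.
#' @param electrodes 2 x 3 matrix of electrode direction vectors (rows:
#'   anode, cathode; need not be normalized). Default: vertex and antipode.
#' @param source_radius Radius of both point sources in mm; default the outer
#'   radius (electrodes on the surface).
#' @param I_mA Injected current (default 2).
#' @return Numeric vector of potentials (V). The gauge is the natural one of
#'   the series (zero monopole); use differences or recenter before comparing
#'   with a zero-mean FEM solution.
#' @export
oracle_potential <- function(spec, points, electrodes = rbind(c(0, 0, 1), c(0, 0, -1)),
                             source_radius = NULL, I_mA = 2) {
  stopifnot(inherits(spec, "layered_sphere_spec"))
  points <- as.matrix(points)
  R <- spec$radii[length(spec$radii)]
  if (is.null(source_radius)) source_radius <- R
  r_mm <- .oracle_check_points(spec, points, electrodes, source_radius)
  radii_m <- spec$radii / 1000
  I_A <- I_mA / 1000
  co <- .oracle_coeffs(radii_m, spec$sigma, source_radius / 1000, spec$L)
  rad <- .oracle_radial(co, radii_m, spec$L, r_mm / 1000)
  ds <- .unitize(electrodes[1, ]); dk <- .unitize(electrodes[2, ])
  rhat <- points / r_mm
  us <- pmin(pmax(rhat %*% ds, -1), 1)
  uk <- pmin(pmax(rhat %*% dk, -1), 1)
  n <- nrow(points)
  P0s <- rep(1, n); P1s <- as.numeric(us)
  P0k <- rep(1, n); P1k <- as.numeric(uk)
  phi <- numeric(n)
  term_mag <- numeric(spec$L)
  for (l in seq_len(spec$L)) {
    dP <- P1s - P1k
    tl <- rad$f[l, ] * dP
    phi <- phi + tl
    term_mag[l] <- max(abs(rad$f[l, ])) * 2
    P2s <- ((2 * l + 1) * us * P1s - l * P0s) / (l + 1)
    P0s <- P1s; P1s <- as.numeric(P2s)
    P2k <- ((2 * l + 1) * uk * P1k - l * P0k) / (l + 1)
    P0k <- P1k; P1k <- as.numeric(P2k)
  }
  # cancellation-safe convergence check: tail of the term-magnitude series
  total <- sum(term_mag)
  tail_rel <- sum(term_mag[max(1, spec$L - 4):spec$L]) / max(total, .Machine$double.xmin)
  if (tail_rel > spec$tol)
    stop(sprintf(
      "Legendre series not converged at L = %d (relative tail %.2g); increase L",
      spec$L, tail_rel))
  I_A * phi
}

#' Closed-form electric field in a layered sphere
#'
#' Analytic gradient of the [oracle_potential()] series: `E = -grad(phi)`
#' from the term-wise radial derivatives and the Legendre derivative
#' recurrence.
#'
#' @inheritParams oracle_potential
#' @return Numeric matrix (n x 3) of field vectors in V/m.
#' @export
oracle_efield <- function(spec, points, electrodes = rbind(c(0, 0, 1), c(0, 0, -1)),
                          source_radius = NULL, I_mA = 2) {
  stopifnot(inherits(spec, "layered_sphere_spec"))
  points <- as.matrix(points)
  R <- spec$radii[length(spec$radii)]
  if (is.null(source_radius)) source_radius <- R
  r_mm <- .oracle_check_points(spec, points, electrodes, source_radius)
  radii_m <- spec$radii / 1000
  r_m <- r_mm / 1000
  I_A <- I_mA / 1000
  co <- .oracle_coeffs(radii_m, spec$sigma, source_radius / 1000, spec$L)
  rad <- .oracle_radial(co, radii_m, spec$L, r_m, deriv = TRUE)
  rhat <- points / r_mm
  grad <- matrix(0, nrow(points), 3)
  for (k in 1:2) {
    sgn <- if (k == 1) 1 else -1
    dk <- .unitize(electrodes[k, ])
    u <- as.numeric(pmin(pmax(rhat %*% dk, -1), 1))
    P0 <- rep(1, nrow(points)); P1 <- u
    Pl_m1 <- P0; Pl <- P1
    for (l in seq_len(spec$L)) {
      one_u2 <- pmax(1 - u^2, 1e-14)
      dPl <- l * (Pl_m1 - u * Pl) / one_u2
      at_pole <- (1 - u^2) < 1e-12
      if (any(at_pole))
        dPl[at_pole] <- sign(u[at_pole])^(l + 1) * l * (l + 1) / 2
      fl <- rad$f[l, ]; dfl <- rad$df[l, ]
      # grad(phi) = f' P_l rhat + f P_l' (dhat - u rhat) / r
      cmn <- fl * dPl / r_m
      grad <- grad + sgn * (
        (dfl * Pl - cmn * u) * rhat + cmn %o% dk
      )
      P2 <- ((2 * l + 1) * u * Pl - l * Pl_m1) / (l + 1)
      Pl_m1 <- Pl; Pl <- P2
    }
  }
  -I_A * grad
}

#' Compare the voxel FEM solution with the layered-sphere oracle
#'
#' Voxelizes the layered sphere, solves the FEM system with single-voxel
#' point sources placed antipodally on the vertical grid axis (so both
#' sources share a center radius and the oracle's monopole terms cancel),
#' and reports relative L2 and maximum errors of the potential and of |E| on
#' an evaluation shell, excluding angular caps around the electrodes.
#'
#' @param spec A [layered_sphere_spec()].
#' @param h Voxel size in mm.
#' @param shell_radius Evaluation shell radius in mm; default 1 mm below the
#'   innermost (gray-matter) interface.
#' @param n_points Number of quasi-uniform shell sample points.
#' @param exclude_deg Angular cap half-angle (degrees) excluded around each
#'   electrode axis.
#' @param tol,maxit Solver settings.
#' @param I_mA Injected current.
#' @return List of class `"oracle_comparison"`: `rel_l2_phi`, `rel_l2_emag`,
#'   `max_rel_phi`, `max_rel_emag`, solver iterations, grid and source info.
#' @export
compare_with_fem <- function(spec, h, shell_radius = NULL, n_points = 4000,
                             exclude_deg = 10, tol = 1e-6, maxit = 10000L,
                             I_mA = 2) {
  stopifnot(inherits(spec, "layered_sphere_spec"))
  R <- spec$radii[length(spec$radii)]
  if (is.null(shell_radius)) shell_radius <- spec$radii[1] - 1

  # voxelize (odd grid centered on the sphere)
  n <- ceiling(2 * (R + 2 * h) / h)
  if (n %% 2 == 0) n <- n + 1L
  n <- as.integer(n)
  ax <- (seq_len(n) - (n + 1) / 2) * h
  r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  idx <- findInterval(r, spec$radii, left.open = TRUE) + 1L
  sig <- array(0, dim = c(n, n, n))
  ins <- idx <= length(spec$radii) & r <= R
  sig[ins] <- spec$sigma[idx[ins]]

  # antipodal single-voxel sources on the z axis
  cc <- (n + 1L) %/% 2L
  k_top <- max(which(ax <= R & ax > 0 & sig[cc, cc, ] > 0))
  k_bot <- min(which(sig[cc, cc, ] > 0))
  vz <- function(k) cc + n * (cc - 1L) + n * n * (k - 1L)
  b <- ax[k_top]
  stopifnot(abs(ax[k_bot] + b) < 1e-9)     # symmetric by construction

  d <- c(n, n, n)
  I_A <- I_mA / 1000
  f <- numeric(prod(d + 1L))
  na <- .voxel_corner_nodes(vz(k_top), d)
  nc <- .voxel_corner_nodes(vz(k_bot), d)
  f[na] <- f[na] + I_A / 8
  f[nc] <- f[nc] - I_A / 8
  sol <- fem_solve(sig, f, h, tol = tol, maxit = maxit)

  # evaluation shell
  pts <- fibonacci_sphere(n_points) * shell_radius
  keep <- abs(pts[, 3] / shell_radius) < cos(exclude_deg * pi / 180)
  pts <- pts[keep, , drop = FALSE]

  phi_fem <- .trilinear(sol$phi, pts, c(ax[1] - h / 2, ax[1] - h / 2, ax[1] - h / 2), h)
  E <- .efield_cpp(as.integer(d), as.numeric(sol$phi), h / 1000)
  air <- sig == 0
  Exa <- array(E$Ex, d); Exa[air] <- NA
  Eya <- array(E$Ey, d); Eya[air] <- NA
  Eza <- array(E$Ez, d); Eza[air] <- NA
  rec <- .recover_nodes(Exa, Eya, Eza)     # same recovery as the pipeline
  g0n <- c(ax[1], ax[1], ax[1]) - h / 2
  ex <- .trilinear(rec$x, pts, g0n, h)
  ey <- .trilinear(rec$y, pts, g0n, h)
  ez <- .trilinear(rec$z, pts, g0n, h)
  emag_fem <- sqrt(ex^2 + ey^2 + ez^2)

  phi_or <- oracle_potential(spec, pts, source_radius = b, I_mA = I_mA)
  E_or <- oracle_efield(spec, pts, source_radius = b, I_mA = I_mA)
  emag_or <- sqrt(rowSums(E_or^2))

  phi_fem <- phi_fem - mean(phi_fem)
  phi_or <- phi_or - mean(phi_or)
  rel_l2 <- function(a, o) sqrt(sum((a - o)^2) / sum(o^2))
  out <- list(
    rel_l2_phi = rel_l2(phi_fem, phi_or),
    rel_l2_emag = rel_l2(emag_fem, emag_or),
    max_rel_phi = max(abs(phi_fem - phi_or)) / max(abs(phi_or)),
    max_rel_emag = max(abs(emag_fem - emag_or)) / max(abs(emag_or)),
    h = h, n_grid = n, iterations = sol$iterations,
    source_radius = b, shell_radius = shell_radius,
    n_points = nrow(pts)
  )
  class(out) <- "oracle_comparison"
  out
}

#' @export
print.oracle_comparison <- function(x, ...) {
  cat(sprintf("FEM vs layered-sphere oracle at h = %g mm (%d^3 grid, %d CG iterations)\n",
              x$h, x$n_grid, x$iterations))
  cat(sprintf("  shell r = %.1f mm, %d points, sources at r = %.2f mm\n",
              x$shell_radius, x$n_points, x$source_radius))
  cat(sprintf("  phi : rel L2 %.4f, max rel %.4f\n", x$rel_l2_phi, x$max_rel_phi))
  cat(sprintf("  |E| : rel L2 %.4f, max rel %.4f\n", x$rel_l2_emag, x$max_rel_emag))
  invisible(x)
}
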