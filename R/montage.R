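#' Sponge electrode specification
#'
#' Physical description of the stimulation electrodes: a rubber
#' current-injection sheet embedded mid-depth in a saline-soaked sponge. The
#' default footprint is 7 cm x 5 cm (35 cm^2), oriented with the long (7 cm)
#' edge perpendicular to the posterior-anterior direction, so the extent along
#' the midline arc is 5 cm. Sponge thickness is 5 mm on each side of the 1 mm
#' rubber sheet (11 mm assembly).
#'
#' @param length_mm Long edge (left-right), default 70.
#' @param width_mm Short edge (anterior-posterior), default 50.
#' @param sponge_mm Sponge thickness on each side of the rubber sheet.
#' @param rubber_mm Rubber sheet thickness, default 1.
#' @return List of class `"electrode_spec"`.
#' @export
electrode_spec <- function(length_mm = 70, width_mm = 50,
                           sponge_mm = 5, rubber_mm = 1) {
  stopifnot(length_mm > 0, width_mm > 0, sponge_mm > 0, rubber_mm > 0)
  structure(list(length_mm = length_mm, width_mm = width_mm,
                 sponge_mm = sponge_mm, rubber_mm = rubber_mm,
                 area_cm2 = length_mm * width_mm / 100,
                 total_mm = 2 * sponge_mm + rubber_mm),
            class = "electrode_spec")
}

#' Montage specification
#'
#' An ordered (anode, cathode) pair of scalp sites with the injected direct
#' current. The order carries the polarity: `montage("FCz", "POz")` drives
#' current anterior-to-posterior, the swapped pair posterior-to-anterior.
#'
#' @param anode,cathode Site names (see [midline_sites()]).
#' @param current_mA Injected current in mA, default 2.
#' @return List of class `"montage_spec"`.
#' @export
montage <- function(anode, cathode, current_mA = 2) {
  if (identical(anode, cathode)) stop("anode and cathode must differ")
  if (current_mA < 0) stop("current must be >= 0")
  structure(list(anode = anode, cathode = cathode, current_mA = current_mA),
            class = "montage_spec")
}

#' @export
print.montage_spec <- function(x, ...) {
  cat(sprintf("Montage %s (anode) -> %s (cathode), %g mA\n",
              x$anode, x$cathode, x$current_mA))
  invisible(x)
}

# Midline site names and their nasion-inion arc fractions (10-10 system).
.MIDLINE_FRACS <- c(Fpz = 0.10, Fz = 0.30, FCz = 0.40, Cz = 0.50,
                    CPz = 0.60, Pz = 0.70, POz = 0.80, Oz = 0.90, Iz = 1.00)

#' Midline 10-10 scalp sites on a head model
#'
#' Places the midline electrode sites (Fpz through Iz) at their fractions of
#' the nasion-inion scalp arc: the half great circle running from the anterior
#' equator point over the vertex to the posterior equator point. Adjacent
#' named sites are 10% of the arc apart; Cz (fraction 0.5) is the vertex. An
#' `extracephalic` return site is placed on the inferior pole of the model,
#' antipodal to Cz.
#'
#' @param model A `voxel_model` with an anterior axis in its metadata.
#' @return `data.frame` with columns `site`, `arc_frac`, `x`, `y`, `z`, the
#'   outward unit normal `nx, ny, nz`, and the posterior-pointing arc tangent
#'   `tx, ty, tz`. Coordinates lie on the outermost tissue sphere.
#' @export
midline_sites <- function(model) {
  stopifnot(inherits(model, "voxel_model"))
  R <- model$meta$outer_radius
  if (is.null(R) || !any(model$labels == .TISSUE_CODES[["air"]]))
    stop("model lacks an air/scalp boundary")
  ctr <- model$meta$spec$center
  fr <- .MIDLINE_FRACS
  th <- fr * pi                       # angle from nasion within the y-z plane
  pos <- cbind(0, cos(th), sin(th))   # +y anterior, +z superior
  tangent <- cbind(0, -sin(th), cos(th))
  # extracephalic: inferior pole, antipodal to Cz
  pos <- rbind(pos, c(0, 0, -1))
  tangent <- rbind(tangent, c(0, 1, 0))
  nrm <- pos
  out <- data.frame(
    site = c(names(fr), "extracephalic"),
    arc_frac = c(fr, NA_real_),
    x = ctr[1] + R * pos[, 1], y = ctr[2] + R * pos[, 2], z = ctr[3] + R * pos[, 3],
    nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
    tx = tangent[, 1], ty = tangent[, 2], tz = tangent[, 3],
    stringsAsFactors = FALSE
  )
  attr(out, "arc_length") <- model$meta$arc_length
  attr(out, "outer_radius") <- R
  out
}

# Scalp arc distance (mm) between two sites given the midline arc length.
.site_arc_dist <- function(a, b, arc_length) {
  fa <- .MIDLINE_FRACS[a]; fb <- .MIDLINE_FRACS[b]
  if (a == "extracephalic" || b == "extracephalic") return(Inf)
  abs(fa - fb) * arc_length
}

#' Do two electrode footprints overlap?
#'
#' Two 5 cm midline footprints intersect when the center-to-center scalp arc
#' distance is below the footprint extent along the arc. The extracephalic
#' site never overlaps a cephalic one. The relation is symmetric.
#'
#' @param a,b Site names.
#' @param e An [electrode_spec()].
#' @param arc_length Nasion-inion arc length in mm (default: the 92 mm
#'   default phantom's arc, `pi * 92`).
#' @return Logical.
#' @examples
#' electrodes_overlap("CPz", "Pz")   # TRUE: adjacent sites
#' electrodes_overlap("Cz", "POz")   # FALSE
#' @export
electrodes_overlap <- function(a, b, e = electrode_spec(),
                               arc_length = pi * 92) {
  for (s in c(a, b))
    if (!s %in% c(names(.MIDLINE_FRACS), "extracephalic"))
      stop("unknown site: ", s)
  unname(.site_arc_dist(a, b, arc_length) < e$width_mm)
}

#' Enumerate candidate midline montages
#'
#' Generates the candidate set for joint M1+SMA stimulation: the first
#' electrode at Fz, FCz, Cz, CPz or Pz crossed with a second electrode at an
#' extracephalic position, Iz, Fpz, POz or Pz, plus the POz-Fpz
#' configuration. Same-site and overlapping pairs are removed and unordered
#' duplicates collapsed, leaving 23 montages for the default geometry. Note
#' the asymmetry of the generating sets: POz appears as a first electrode
#' only in the POz-Fpz pair; this mirrors the conventional candidate table for this target pair, which
#' contains POz-Fpz but no POz-extracephalic row.
#'
#' @param e An [electrode_spec()].
#' @param arc_length Nasion-inion arc length in mm. The candidate set is
#'   invariant to head size across the plausible adult range (roughly 25-50
#'   cm arcs), since site spacing scales with the arc.
#' @param current_mA Injected current per montage (default 2).
#' @return `data.frame` with columns `anode`, `cathode`, `current_mA`, one
#'   row per montage, in conventional table order (grouped by second
#'   electrode: extracephalic, Iz, Fpz, POz, Pz).
#' @export
enumerate_candidates <- function(e = electrode_spec(), arc_length = pi * 92,
                                 current_mA = 2) {
  firsts <- c("Fz", "FCz", "Cz", "CPz", "Pz")
  seconds <- c("extracephalic", "Iz", "Fpz", "POz", "Pz")
  rows <- list()
  seen <- character()
  add <- function(a, b) {
    if (identical(a, b)) return()
    if (electrodes_overlap(a, b, e, arc_length)) return()
    key <- paste(sort(c(a, b)), collapse = "|")
    if (key %in% seen) return()
    seen <<- c(seen, key)
    rows[[length(rows) + 1L]] <<- data.frame(anode = a, cathode = b,
                                             stringsAsFactors = FALSE)
  }
  for (s in seconds) {
    for (f in firsts) add(f, s)
    if (s == "Fpz") add("POz", s)    # the one extra first-electrode site
  }
  out <- do.call(rbind, rows)
  out$current_mA <- current_mA
  rownames(out) <- NULL
  out
}

# Voxel index sets (linear indices) of one electrode assembly on the scalp
# sphere. The footprint is the tangent-plane rectangle at the site, extruded
# along the site normal; depth below/above the scalp is measured radially so
# the assembly conforms to the curved surface. The rubber sheet is the voxel
# layer whose radial depth band contains the mid-sponge depth.
.electrode_voxels <- function(model, site_row, e) {
  h <- model$h
  lab <- model$labels
  d <- dim(lab)
  ctr <- model$meta$spec$center
  R <- model$meta$outer_radius
  nhat <- c(site_row$nx, site_row$ny, site_row$nz)
  tap <- c(site_row$tx, site_row$ty, site_row$tz)
  tlr <- c(nhat[2] * tap[3] - nhat[3] * tap[2],
           nhat[3] * tap[1] - nhat[1] * tap[3],
           nhat[1] * tap[2] - nhat[2] * tap[1])
  spos <- c(site_row$x, site_row$y, site_row$z)

  air <- which(lab == .TISSUE_CODES[["air"]])
  ijk <- arrayInd(air, d)
  px <- model$origin[1] + (ijk[, 1] - 1) * h - ctr[1]
  py <- model$origin[2] + (ijk[, 2] - 1) * h - ctr[2]
  pz <- model$origin[3] + (ijk[, 3] - 1) * h - ctr[3]
  r <- sqrt(px^2 + py^2 + pz^2)
  depth <- r - R
  tot <- e$total_mm
  keep <- depth > 0 & depth <= tot
  if (!any(keep)) stop("no room for the electrode assembly: increase the grid margin")
  air <- air[keep]; px <- px[keep]; py <- py[keep]; pz <- pz[keep]
  depth <- depth[keep]
  rx <- px - (spos[1] - ctr[1]); ry <- py - (spos[2] - ctr[2]); rz <- pz - (spos[3] - ctr[3])
  u <- rx * tap[1] + ry * tap[2] + rz * tap[3]   # along the midline arc
  v <- rx * tlr[1] + ry * tlr[2] + rz * tlr[3]   # left-right
  hemi <- px * nhat[1] + py * nhat[2] + pz * nhat[3] > 0   # site hemisphere only
  foot <- hemi & abs(u) <= e$width_mm / 2 & abs(v) <= e$length_mm / 2
  air <- air[foot]; depth <- depth[foot]
  layer <- ceiling(depth / h)
  rubber_layer <- ceiling((e$sponge_mm + e$rubber_mm / 2) / h)
  rubber <- air[layer == rubber_layer]
  sponge <- air[layer != rubber_layer]
  if (!length(rubber)) stop("electrode rubber sheet captured no voxels; h too coarse")
  exp_vol <- e$length_mm * e$width_mm * tot
  if ((length(rubber) + length(sponge)) * h^3 < 0.8 * exp_vol)
    warning(sprintf("electrode at %s covers < 80%% of its nominal volume (air gap?)",
                    site_row$site))
  list(sponge = sponge, rubber = rubber)
}

#' Place a montage's electrode assemblies on a model
#'
#' Stamps the two sponge/rubber assemblies into the label volume and records
#' the anode and cathode rubber voxel sets for source construction. Swapping
#' anode and cathode yields identical geometry with swapped source labels.
#'
#' @param model A `voxel_model` (electrodes not yet placed).
#' @param m A [montage()] or a one-row montage `data.frame`.
#' @param e An [electrode_spec()].
#' @return The model with electrode voxels labelled `saline_sponge` /
#'   `rubber_sheet` and an `electrodes` field (`anode`, `cathode` linear voxel
#'   index sets, the montage, the spec).
#' @export
place_electrodes <- function(model, m, e = electrode_spec()) {
  stopifnot(inherits(model, "voxel_model"))
  if (is.data.frame(m)) m <- montage(m$anode[1], m$cathode[1], m$current_mA[1])
  if (!is.null(model$electrodes)) stop("model already carries electrodes")
  if (electrodes_overlap(m$anode, m$cathode, e, model$meta$arc_length))
    stop(sprintf("electrode footprints of %s and %s overlap", m$anode, m$cathode))
  sites <- midline_sites(model)
  ra <- sites[sites$site == m$anode, , drop = FALSE]
  rc <- sites[sites$site == m$cathode, , drop = FALSE]
  if (nrow(ra) != 1 || nrow(rc) != 1)
    stop("montage sites must be midline 10-10 sites or 'extracephalic'")
  va <- .electrode_voxels(model, ra, e)
  vc <- .electrode_voxels(model, rc, e)
  if (length(intersect(c(va$sponge, va$rubber), c(vc$sponge, vc$rubber))))
    stop(sprintf("electrode assemblies of %s and %s overlap after placement",
                 m$anode, m$cathode))
  lab <- model$labels
  lab[c(va$sponge, vc$sponge)] <- .TISSUE_CODES[["saline_sponge"]]
  lab[c(va$rubber, vc$rubber)] <- .TISSUE_CODES[["rubber_sheet"]]
  model$labels <- lab
  model$electrodes <- list(anode = va$rubber, cathode = vc$rubber,
                           anode_assembly = c(va$sponge, va$rubber),
                           cathode_assembly = c(vc$sponge, vc$rubber),
                           montage = m, spec = e)
  model
}
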