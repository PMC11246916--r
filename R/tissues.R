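# Integer label codes for the voxel models. Air is 0 and never enters the FEM
# domain; the electrode materials (sponge, rubber) get their own labels so a
# montage can be stamped into a model without losing the anatomy underneath.
.TISSUE_CODES <- c(
  air          = 0L,
  skin_fat     = 1L,
  muscle       = 2L,
  compact_bone = 3L,
  spongy_bone  = 4L,
  dura         = 5L,
  blood        = 6L,
  csf          = 7L,
  gray_matter  = 8L,
  white_matter = 9L,
  eye          = 10L,
  saline_sponge = 11L,
  rubber_sheet  = 12L
)

.SIGMA_DEFAULTS <- c(
  skin_fat     = 0.08,
  muscle       = 0.16,
  compact_bone = 0.008,
  spongy_bone  = 0.027,
  dura         = 0.16,
  blood        = 0.7,
  csf          = 1.8,
  gray_matter  = 0.2,
  white_matter = 0.14,
  eye          = 1.5,
  saline_sponge = 1.6,
  rubber_sheet  = 0.1
)

#' Tissue label codes
#'
#' Named integer codes used in voxel-model label arrays. `air` (0) marks
#' voxels outside the conducting domain.
#'
#' @return Named integer vector of label codes.
#' @export
tissue_codes <- function() .TISSUE_CODES

#' Tissue conductivity table
#'
#' Returns the electrical conductivity (S/m) assigned to each tissue
#' compartment. Defaults are standard literature values for the quasi-static
#' regime: gray matter 0.2, white matter 0.14, blood 0.7, compact bone 0.008,
#' spongy bone 0.027, dura 0.16, CSF 1.8, muscle 0.16, skin and fat (shared
#' label) 0.08, eye 1.5, and 1.6 for the saline-soaked electrode sponge. The
#' rubber current-injection sheet has no established value; with uniform
#' volumetric injection its conductivity has negligible influence on the
#' tissue field (see the sensitivity test suite) and defaults to 0.1 S/m.
#'
#' @param ... Named per-tissue overrides, e.g. `conductivity_table(csf = 2)`.
#'   Names must be tissue labels; values must be positive and finite.
#' @return Named numeric vector of class `"conductivity_table"`, one entry per
#'   non-air tissue label.
#' @examples
#' tab <- conductivity_table()
#' tab["csf"]            # 1.8 S/m
#' conductivity_table(compact_bone = 0.012)["compact_bone"]
#' @export
conductivity_table <- function(...) {
  tab <- .SIGMA_DEFAULTS
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("conductivity overrides must be named")
    bad <- setdiff(names(ov), names(tab))
    if (length(bad))
      stop("unknown tissue label(s): ", paste(bad, collapse = ", "))
    vals <- unlist(ov)
    if (any(!is.finite(vals)) || any(vals <= 0))
      stop("conductivities must be positive and finite")
    tab[names(ov)] <- vals
  }
  structure(tab, class = "conductivity_table")
}

#' Scale conductivities by per-tissue multipliers
#'
#' Used by the sensitivity analysis: multipliers apply to the named tissues
#' only and must be positive.
#'
#' @param table A [conductivity_table()].
#' @param multipliers Named numeric vector, e.g. `c(compact_bone = 0.5,
#'   spongy_bone = 0.5)`.
#' @return A new `conductivity_table`.
#' @export
scale_conductivity <- function(table, multipliers) {
  stopifnot(inherits(table, "conductivity_table"))
  if (!length(multipliers)) return(table)
  if (is.null(names(multipliers)) || any(!nzchar(names(multipliers))))
    stop("multipliers must be named by tissue")
  bad <- setdiff(names(multipliers), names(table))
  if (length(bad)) stop("unknown tissue label(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(multipliers)) || any(multipliers <= 0))
    stop("multipliers must be positive")
  table[names(multipliers)] <- table[names(multipliers)] * multipliers
  table
}

#' @export
print.conductivity_table <- function(x, ...) {
  cat("Tissue conductivities (S/m):\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

# Per-voxel conductivity volume from a label array; air -> 0.
sigma_volume <- function(model, table = conductivity_table()) {
  lab <- model$labels
  codes <- .TISSUE_CODES
  lut <- numeric(max(codes) + 1L)          # index = code + 1
  lut[codes[names(table)] + 1L] <- as.numeric(table)
  used <- sort(unique(as.integer(lab)))
  known <- c(codes[["air"]], codes[names(table)])
  if (!all(used %in% known))
    stop("label array contains codes with no conductivity assignment: ",
         paste(setdiff(used, known), collapse = ", "))
  array(lut[as.integer(lab) + 1L], dim = dim(lab))
}
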