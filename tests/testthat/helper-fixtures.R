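# Shared fixtures. Solves are cached per session so several test files can
# reuse the same simulation without re-running the solver.

.fix <- new.env(parent = emptyenv())

# A thick-layered phantom whose shells survive coarse grids: cheap machinery
# tests run on it at h = 8 mm (25^3 grid, millisecond solves).
thick_spec <- function() {
  sphere_layer_spec(c(80, 72, 60, 48, 32),
                    c("skin_fat", "compact_bone", "csf", "gray_matter",
                      "white_matter"))
}

thick_model <- function(h = 8) {
  key <- paste0("thick", h)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- build_sphere_phantom(thick_spec(), h, check = "none",
                                        id = paste0("thick", h))
  .fix[[key]]
}

default_model <- function(h = 4) {
  key <- paste0("default", h)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- build_sphere_phantom(default_head_spec(), h, check = "none",
                                        id = paste0("default", h))
  .fix[[key]]
}

cached_sim <- function(anode = "FCz", cathode = "POz", h = 4,
                       model = default_model(h), current = 2, tol = 1e-6) {
  key <- paste("sim", model$meta$id, anode, cathode, current, tol, sep = "|")
  if (is.null(.fix[[key]]))
    .fix[[key]] <- simulate_montage(model, montage(anode, cathode, current),
                                    tol = tol)
  .fix[[key]]
}

# The reference candidate-montage table: 23 rows, grouped by the second
# electrode (extracephalic, Iz, Fpz, POz, Pz), first electrode cycling
# Fz/FCz/Cz/CPz/Pz, with POz-Fpz as the only extra first-electrode pairing.
reference_montages <- function() {
  data.frame(
    anode = c("Fz", "FCz", "Cz", "CPz", "Pz",
              "Fz", "FCz", "Cz", "CPz", "Pz",
              "Fz", "FCz", "Cz", "CPz", "Pz", "POz",
              "Fz", "FCz", "Cz", "CPz",
              "Fz", "FCz", "Cz"),
    cathode = c(rep("extracephalic", 5), rep("Iz", 5), rep("Fpz", 6),
                rep("POz", 4), rep("Pz", 3)),
    stringsAsFactors = FALSE
  )
}
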