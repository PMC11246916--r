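#' Evaluate candidate montages over a model population
#'
#' Runs the full place-solve-map-average pipeline for every (model, montage)
#' pair and aggregates the four ROI means and their unweighted average across
#' models (mean and standard deviation) — the population-level montage table
#' that the optimization ranks. Per-pair results can be cached in an
#' environment and reused (e.g. as the baseline of a sensitivity analysis).
#'
#' @param models List of `voxel_model` objects (a phantom population).
#' @param montages Montage `data.frame` from [enumerate_candidates()] (or a
#'   subset of its rows).
#' @param rois ROI table, see [default_rois()].
#' @param sigma_table A [conductivity_table()].
#' @param espec An [electrode_spec()].
#' @param d,n_points Cortical sampling parameters.
#' @param tol,maxit Solver settings.
#' @param cache Optional environment for per-(model, montage) result reuse.
#' @param scenario Tag stored with cached entries (used by
#'   [sensitivity_analysis()]).
#' @param verbose Print per-solve progress.
#' @return Object of class `"montage_eval"`: `table` (per-montage population
#'   mean and SD of each ROI mean and of the four-ROI average), `avg` matrix
#'   (models x montages) of four-ROI averages, `roi` array (models x montages
#'   x ROIs), montage labels, model ids, and an `incomplete` flag per montage
#'   if any model's solve failed.
#' @export
evaluate_montages <- function(models, montages, rois = default_rois(),
                              sigma_table = conductivity_table(),
                              espec = electrode_spec(), d = 1,
                              n_points = 10000, tol = 1e-6, maxit = 10000L,
                              cache = NULL, scenario = "baseline",
                              verbose = FALSE) {
  stopifnot(length(models) >= 1, nrow(montages) >= 1)
  if (inherits(models, "voxel_model")) models <- list(models)
  nm <- nrow(montages)
  nmod <- length(models)
  labels <- paste(montages$anode, montages$cathode, sep = "-")
  roi_arr <- array(NA_real_, dim = c(nmod, nm, nrow(rois)),
                   dimnames = list(NULL, labels, rois$roi))
  avg <- matrix(NA_real_, nmod, nm, dimnames = list(NULL, labels))
  errors <- list()
  sig_key <- paste(signif(as.numeric(sigma_table), 10), collapse = ",")
  samples <- cortical_samples(models[[1]], d, n_points)
  for (i in seq_len(nmod)) {
    mod <- models[[i]]
    if (attr(samples, "radius") != mod$meta$gm_outer - d)
      samples <- cortical_samples(mod, d, n_points)
    for (j in seq_len(nm)) {
      key <- paste(mod$meta$id, labels[j], scenario, sig_key, sep = "|")
      res <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]] else NULL
      if (is.null(res)) {
        res <- tryCatch({
          sim <- simulate_montage(mod, montages[j, ], sigma_table, espec,
                                  tol = tol, maxit = maxit)
          roi_means(sim, rois, d = d, n_points = n_points, samples = samples)
        }, error = function(e) e)
        if (!is.null(cache) && !inherits(res, "error")) cache[[key]] <- res
      }
      if (inherits(res, "error")) {
        errors[[paste(mod$meta$id, labels[j])]] <- conditionMessage(res)
        next
      }
      roi_arr[i, j, ] <- res[rois$roi]
      avg[i, j] <- res[["average"]]
      if (verbose)
        message(sprintf("%s %s: average %.4f V/m", mod$meta$id, labels[j],
                        res[["average"]]))
    }
  }
  pop_mean <- function(m) colMeans(m)
  pop_sd <- function(m) if (nmod > 1) apply(m, 2, sd) else rep(0, ncol(m))
  tab <- data.frame(anode = montages$anode, cathode = montages$cathode,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(rois))) {
    mk <- matrix(roi_arr[, , k], nmod, nm)
    tab[[paste0(rois$roi[k], "_mean")]] <- pop_mean(mk)
    tab[[paste0(rois$roi[k], "_sd")]] <- pop_sd(mk)
  }
  tab$average_mean <- pop_mean(avg)
  tab$average_sd <- pop_sd(avg)
  tab$incomplete <- vapply(seq_len(nm), function(j) anyNA(avg[, j]), logical(1))
  structure(list(table = tab, avg = avg, roi = roi_arr,
                 montages = labels, model_ids = vapply(models, function(m) m$meta$id, ""),
                 rois = rois, scenario = scenario, errors = errors,
                 n_models = nmod),
            class = "montage_eval")
}

#' @export
print.montage_eval <- function(x, digits = 3, ...) {
  cat(sprintf("Montage evaluation: %d montages x %d models (scenario '%s')\n",
              length(x$montages), x$n_models, x$scenario))
  tb <- x$table
  show <- data.frame(montage = paste(tb$anode, tb$cathode, sep = "-"),
                     average = sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
                                       tb$average_mean, tb$average_sd))
  print(show, row.names = FALSE)
  if (length(x$errors)) cat(length(x$errors), "solve failure(s); montages flagged incomplete\n")
  invisible(x)
}

#' @export
summary.montage_eval <- function(object, ...) {
  rk <- rank_montages(object)
  opt <- per_model_optima(object)
  structure(list(ranked = rk, optima = opt, n_models = object$n_models),
            class = "summary.montage_eval")
}

#' @export
print.summary.montage_eval <- function(x, ...) {
  cat("Top montages by population mean of the four-ROI average |E|:\n")
  print(utils::head(x$ranked[, c("anode", "cathode", "average_mean", "average_sd")], 5),
        row.names = FALSE)
  cat("\nPer-model optimum counts:\n")
  print(x$optima[x$optima > 0])
  invisible(x)
}

#' @export
plot.montage_eval <- function(x, ...) {
  tb <- x$table[order(-x$table$average_mean), ]
  lab <- paste(tb$anode, tb$cathode, sep = "-")
  op <- par(mar = c(7, 4, 2, 1)); on.exit(par(op))
  bp <- barplot(tb$average_mean, names.arg = lab, las = 2,
                ylab = "mean four-ROI |E| (V/m)",
                ylim = c(0, max(tb$average_mean + tb$average_sd) * 1.1), ...)
  arrows(bp, tb$average_mean - tb$average_sd, bp,
         tb$average_mean + tb$average_sd, angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Rank montages by mean ROI-averaged field strength
#'
#' Sorts the evaluation table in descending order of the population mean of
#' the four-ROI average. Exact ties keep montage list order and are flagged.
#'
#' @param ev A `montage_eval`.
#' @return The evaluation table with a `rank` column, sorted; attribute
#'   `ties` marks tied groups.
#' @export
rank_montages <- function(ev) {
  stopifnot(inherits(ev, "montage_eval"))
  tb <- ev$table
  ord <- order(-tb$average_mean)
  out <- tb[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  dup <- duplicated(out$average_mean) | duplicated(out$average_mean, fromLast = TRUE)
  attr(out, "ties") <- any(dup)
  if (any(dup)) out$tied <- dup
  out
}

#' Per-model optimal montage counts
#'
#' For each model, the montage with the largest four-ROI average field; ties
#' go to the montage earlier in list order and are flagged. Counts sum to
#' the number of models.
#'
#' @param ev A `montage_eval`.
#' @return Named integer vector of counts per montage (list order), with a
#'   `ties` attribute listing models whose optimum was tied.
#' @export
per_model_optima <- function(ev) {
  stopifnot(inherits(ev, "montage_eval"))
  if (anyNA(ev$avg)) stop("evaluation incomplete: missing (model, montage) results")
  best <- apply(ev$avg, 1, which.max)
  ties <- which(apply(ev$avg, 1, function(r) sum(r == max(r)) > 1))
  counts <- tabulate(best, nbins = length(ev$montages))
  names(counts) <- ev$montages
  attr(counts, "ties") <- ties
  counts
}

#' Conductivity sensitivity scenarios
#'
#' The default scenario set perturbs one tissue group at a time: bone
#' conductivity (compact and spongy jointly) by +/-50% and CSF conductivity
#' by +/-10%, plus the unperturbed baseline.
#'
#' @return Named list of per-tissue multiplier vectors.
#' @export
default_scenarios <- function() {
  list(
    baseline = c(),
    bone_x0.5 = c(compact_bone = 0.5, spongy_bone = 0.5),
    bone_x1.5 = c(compact_bone = 1.5, spongy_bone = 1.5),
    csf_x0.9 = c(csf = 0.9),
    csf_x1.1 = c(csf = 1.1)
  )
}

#' Conductivity sensitivity analysis
#'
#' Re-evaluates every montage on every model under each scenario's perturbed
#' conductivity table and reports the per-scenario ranking and the set of
#' scenario-optimal montages (the robustness summary).
#'
#' @param models,montages,rois,espec,d,n_points,tol,maxit As in
#'   [evaluate_montages()].
#' @param scenarios Named list of multiplier vectors, see
#'   [default_scenarios()].
#' @param sigma_table Baseline [conductivity_table()].
#' @param baseline Optional precomputed baseline `montage_eval` to reuse.
#' @param verbose Print progress.
#' @return Object of class `"sensitivity_result"`: `evaluations` (one
#'   `montage_eval` per scenario), `optimal` (scenario -> best montage),
#'   `robust_set` (unique scenario optima).
#' @export
sensitivity_analysis <- function(models, montages, scenarios = default_scenarios(),
                                 rois = default_rois(),
                                 sigma_table = conductivity_table(),
                                 espec = electrode_spec(), d = 1,
                                 n_points = 10000, tol = 1e-6, maxit = 10000L,
                                 baseline = NULL, verbose = FALSE) {
  if (!length(scenarios)) stop("no scenarios given")
  for (s in scenarios)
    if (length(s) && any(s <= 0)) stop("scenario multipliers must be positive")
  evs <- vector("list", length(scenarios))
  names(evs) <- names(scenarios)
  for (nm in names(scenarios)) {
    if (nm == "baseline" && !is.null(baseline)) { evs[[nm]] <- baseline; next }
    tab <- if (length(scenarios[[nm]]))
      scale_conductivity(sigma_table, scenarios[[nm]]) else sigma_table
    evs[[nm]] <- evaluate_montages(models, montages, rois, tab, espec,
                                   d = d, n_points = n_points, tol = tol,
                                   maxit = maxit, scenario = nm,
                                   verbose = verbose)
  }
  optimal <- vapply(evs, function(e) {
    rk <- rank_montages(e)
    paste(rk$anode[1], rk$cathode[1], sep = "-")
  }, character(1))
  structure(list(evaluations = evs, optimal = optimal,
                 robust_set = unique(unname(optimal)),
                 scenarios = scenarios),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Conductivity sensitivity analysis\n")
  for (nm in names(x$optimal))
    cat(sprintf("  %-10s optimal montage: %s\n", nm, x$optimal[nm]))
  cat("Robust optimum set:", paste(x$robust_set, collapse = ", "), "\n")
  invisible(x)
}
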