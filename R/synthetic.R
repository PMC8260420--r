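# Synthetic acquisitions: noisy voxel spectra with known ground truth, water
# reference scans, region-typical voxel compositions and serum time courses.
# All randomness is driven by explicit seeds; the global RNG state is
# restored after every call.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Ground truth for a simulated acquisition
#'
#' @param concentrations Named nonnegative vector, metabolite label ->
#'   true concentration in basis amplitude units (1 unit = 1 mmol/L in the
#'   voxel under the default basis calibration).
#' @param water_signal_scale Integrated area of the unsuppressed water
#'   reference (arbitrary units, > 0).
#' @param noise_sd Standard deviation of the additive Gaussian noise per grid
#'   point (intensity units, >= 0).
#' @param seed Integer RNG seed.
#' @return An object of class `"ground_truth"`.
#' @export
ground_truth <- function(concentrations = c(Eth = 10, NAA = 12, Cr = 8, Cho = 2),
                         water_signal_scale = 85800, noise_sd = 0, seed = 1L) {
  if (is.null(names(concentrations)) || any(!nzchar(names(concentrations))))
    stop("'concentrations' must be a named vector")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(concentrations = concentrations,
                 water_signal_scale = water_signal_scale,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ground_truth")
}

#' A (possibly simulated) single-voxel spectrum
#'
#' @param grid ppm axis.
#' @param intensity Real absorption-mode intensities, same length as `grid`,
#'   finite.
#' @param params The [acq_params()] of the acquisition.
#' @param voxel_id Label, typically one of the four study regions.
#' @param is_water_reference Whether this is the unsuppressed water scan.
#' @return Object of class `"mrs_spectrum"`.
#' @export
mrs_spectrum <- function(grid, intensity, params, voxel_id = "user",
                         is_water_reference = FALSE) {
  if (length(intensity) != length(grid))
    stop("intensity length must equal grid length")
  if (!all(is.finite(intensity))) stop("intensity must be finite")
  structure(list(grid = as.numeric(grid), intensity = as.numeric(intensity),
                 params = params, voxel_id = voxel_id,
                 is_water_reference = isTRUE(is_water_reference)),
            class = "mrs_spectrum")
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("MRS spectrum [%s]%s: %d points, %.2f-%.2f ppm\n",
              x$voxel_id, if (x$is_water_reference) " (water reference)" else "",
              length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Simulate a metabolite spectrum from ground truth
#'
#' `intensity = basis %*% concentrations + N(0, noise_sd)`, reproducible for a
#' fixed `truth$seed`.
#'
#' @param truth A [ground_truth()]; every concentration label must exist in
#'   the basis.
#' @param basis A [basis_set()].
#' @param voxel_id Label carried on the result.
#' @return An [mrs_spectrum()].
#' @export
simulate_spectrum <- function(truth, basis, voxel_id = "user") {
  stopifnot(inherits(truth, "ground_truth"), inherits(basis, "basis_set"))
  unknown <- setdiff(names(truth$concentrations), basis$names)
  if (length(unknown))
    stop("unknown metabolite label(s) not in basis: ",
         paste(unknown, collapse = ", "))
  y <- as.numeric(basis$spectra[, names(truth$concentrations), drop = FALSE] %*%
                    truth$concentrations)
  if (truth$noise_sd > 0)
    y <- y + with_seed(truth$seed, stats::rnorm(length(y), 0, truth$noise_sd))
  mrs_spectrum(basis$params$grid, y, basis$params, voxel_id)
}

#' Simulate the unsuppressed water reference scan
#'
#' A single water resonance at `params$reference_ppm` whose integrated area
#' equals `truth$water_signal_scale`, plus the same additive noise model.
#'
#' @inheritParams simulate_spectrum
#' @param params An [acq_params()].
#' @export
simulate_water_reference <- function(truth, params, voxel_id = "user") {
  stopifnot(inherits(truth, "ground_truth"))
  if (truth$water_signal_scale <= 0) stop("'water_signal_scale' must be > 0")
  water <- default_resonances()$Water
  water$center_ppm <- params$reference_ppm
  y <- render_resonance(water, params,
                        amplitude = truth$water_signal_scale / water$n_protons)
  if (truth$noise_sd > 0)
    y <- y + with_seed(truth$seed + 1L,
                       stats::rnorm(length(y), 0, truth$noise_sd))
  mrs_spectrum(params$grid, y, params, voxel_id, is_water_reference = TRUE)
}

# Region-typical GM/CSF ranges calibrated to the packaged study fractions;
# WM takes the remainder. Voxel volumes are the study's (mL).
region_ranges <- function() {
  list(
    occipital_cortex = list(gm = c(0.40, 0.54), csf = c(0.03, 0.05), ml = 15.6),
    cerebellum       = list(gm = c(0.77, 0.89), csf = c(0.00, 0.04), ml = 8.0),
    frontal_cortex   = list(gm = c(0.11, 0.16), csf = c(0.08, 0.23), ml = 8.0),
    putamen          = list(gm = c(0.77, 0.91), csf = c(0.00, 0.02), ml = 7.5)
  )
}

#' Study regions
#' @export
study_regions <- function() names(region_ranges())

#' Draw a region-typical voxel composition
#'
#' GM and CSF fractions are drawn uniformly from ranges calibrated to the
#' packaged study voxels (e.g. cerebellar CSF at most 4%, frontal CSF 8-23%);
#' WM takes the remainder and the triplet is renormalized to sum to exactly 1.
#'
#' @param region One of [study_regions()].
#' @param seed Integer RNG seed.
#' @return A [voxel_composition()].
#' @export
sample_voxel_composition <- function(region, seed = 1L) {
  rr <- region_ranges()
  if (!region %in% names(rr))
    stop("unknown region '", region, "'; expected one of ",
         paste(names(rr), collapse = ", "))
  r <- rr[[region]]
  f <- with_seed(seed, {
    gm <- stats::runif(1, r$gm[1], r$gm[2])
    csf <- stats::runif(1, r$csf[1], r$csf[2])
    c(gm, 1 - gm - csf, csf)
  })
  f <- f / sum(f)
  voxel_composition(f[1], f[2], f[3], voxel_ml = r$ml, region = region)
}

#' Simulate a serum ethanol time course
#'
#' Piecewise-linear Widmark-style kinetics: linear rise from zero at t = 0 to
#' the peak at the end of the absorption window, then zero-order elimination
#' at `beta_gL_per_h`; concentrations are clamped at zero.
#'
#' @param pk A [pk_params()]; the peak equals
#'   `target_bac_gkg * serum_blood_factor` unless `peak_gL` is given.
#' @param times_min Nonnegative, strictly increasing sampling times (min).
#' @param subject Label.
#' @param peak_gL Optional explicit peak serum concentration (g/L).
#' @return A data.frame of class `"serum_series"` with columns
#'   `subject`, `time_min`, `conc_gL`.
#' @export
simulate_serum_series <- function(pk, times_min, subject = "V1",
                                  peak_gL = NULL) {
  stopifnot(inherits(pk, "pk_params"))
  if (any(times_min < 0)) stop("times must be >= 0")
  if (any(diff(times_min) <= 0)) stop("times must be strictly increasing")
  if (is.null(peak_gL)) peak_gL <- pk$target_bac_gkg * pk$serum_blood_factor
  t_abs <- pk$absorption_min
  conc <- ifelse(times_min <= t_abs,
                 peak_gL * times_min / t_abs,
                 peak_gL - pk$beta_gL_per_h * (times_min - t_abs) / 60)
  conc <- pmax(conc, 0)
  serum_series(subject, times_min, conc)
}

#' @rdname simulate_serum_series
#' @param conc_gL Serum concentrations (g/L, >= 0).
#' @param timepoint_labels Optional tags (e.g. T1..T5).
#' @export
serum_series <- function(subject, times_min, conc_gL, timepoint_labels = NULL) {
  if (any(diff(times_min) <= 0)) stop("times must be strictly increasing")
  if (any(conc_gL < 0)) stop("concentrations must be >= 0")
  out <- data.frame(subject = subject, time_min = as.numeric(times_min),
                    conc_gL = as.numeric(conc_gL),
                    stringsAsFactors = FALSE)
  if (!is.null(timepoint_labels)) out$timepoint <- timepoint_labels
  class(out) <- c("serum_series", "data.frame")
  out
}

#' Simulate one voxel end to end (spectrum + matched water reference)
#'
#' The scanner gain links the metabolite and water channels: with gain g the
#' metabolite amplitudes are `g * c_raw` (mmol per L voxel) and the water
#' reference area is `g * n_water * C_water_voxel * 1000`, where
#' `C_water_voxel` is the tissue-fraction-weighted water concentration
#' (mol/L). Feeding both into the quantification chain recovers the truth.
#'
#' @param norm_eth_gL True ethanol concentration normalized to voxel water
#'   (g per L water), the study's reporting unit.
#' @param comp A [voxel_composition()].
#' @param basis A [basis_set()] containing `Eth`.
#' @param other_mmol Raw concentrations for the background metabolites
#'   (mmol per L voxel).
#' @param noise_sd,seed Noise level and seed, as in [ground_truth()].
#' @param gain Scanner gain g (> 0); results are invariant to it.
#' @param constants A [water_constants()].
#' @return List with `spectrum`, `water_ref`, `truth` (the ground truth
#'   object), and `raw_mmol` (the implied raw ethanol concentration).
#' @export
simulate_voxel_case <- function(norm_eth_gL, comp, basis = default_basis(),
                                other_mmol = c(NAA = 12, Cr = 8, Cho = 2),
                                noise_sd = 0, seed = 1L, gain = 1,
                                constants = water_constants()) {
  stopifnot(inherits(comp, "voxel_composition"))
  if (gain <= 0) stop("'gain' must be > 0")
  wc <- water_content(comp, constants)
  raw_gL <- denormalize_from_water(norm_eth_gL, wc$percent)
  raw_mmol <- gL_to_mmol(raw_gL)
  n_water <- default_resonances()$Water$n_protons
  conc <- c(Eth = raw_mmol, other_mmol[setdiff(names(other_mmol), "Eth")])
  truth <- ground_truth(concentrations = gain * conc,
                        water_signal_scale = gain * n_water *
                          wc$mol_per_L * 1000,
                        noise_sd = noise_sd, seed = seed)
  list(spectrum = simulate_spectrum(truth, basis, voxel_id = comp$region),
       water_ref = simulate_water_reference(truth, basis$params,
                                            voxel_id = comp$region),
       truth = truth, raw_mmol = raw_mmol)
}
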