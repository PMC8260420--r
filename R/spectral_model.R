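# Forward spectral model: Lorentzian resonance rendering and basis sets.
#
# Conventions: the ppm axis increases left-to-right in storage (plotting
# reverses it, as usual in NMR). Every Lorentzian line is normalized to unit
# area over the analysis grid (analytic truncation correction), so a resonance
# rendered at unit amplitude integrates to exactly n_protons in
# intensity x ppm units. This makes "unit amplitude = 1 mmol/L-equivalent"
# an exact calibration on the grid and keeps rendered areas invariant under
# linewidth changes.

#' Define a resonance (chemical-shift multiplet)
#'
#' A resonance is a set of Lorentzian lines sharing one linewidth, centred at
#' `center_ppm` and offset by the multiplet structure (J-coupling pattern).
#'
#' @param center_ppm Chemical shift of the multiplet centre (ppm).
#' @param n_protons Number of protons contributing to the signal (>= 1).
#' @param multiplet Two-column matrix or data.frame with columns
#'   `offset_hz` (line offset from the centre, Hz) and `rel_intensity`
#'   (positive weights summing to 1). Default: a singlet.
#' @param linewidth_hz Full width at half maximum of each line (Hz, > 0).
#' @return An object of class `"resonance"`.
#' @examples
#' eth <- resonance(1.18, 3, multiplet_triplet(7.1))
#' @export
resonance <- function(center_ppm, n_protons,
                      multiplet = cbind(offset_hz = 0, rel_intensity = 1),
                      linewidth_hz = 4) {
  multiplet <- as.matrix(multiplet)
  if (ncol(multiplet) != 2L)
    stop("'multiplet' must have columns offset_hz and rel_intensity")
  colnames(multiplet) <- c("offset_hz", "rel_intensity")
  rel <- multiplet[, "rel_intensity"]
  if (any(rel <= 0))
    stop("multiplet relative intensities must be positive")
  if (abs(sum(rel) - 1) > 1e-9)
    stop("multiplet relative intensities must sum to 1 (got ",
         format(sum(rel)), ")")
  if (!is.numeric(linewidth_hz) || linewidth_hz <= 0)
    stop("'linewidth_hz' must be > 0")
  if (n_protons < 1 || n_protons != round(n_protons))
    stop("'n_protons' must be a positive integer")
  structure(
    list(center_ppm = as.numeric(center_ppm),
         n_protons = as.integer(n_protons),
         multiplet = multiplet,
         linewidth_hz = as.numeric(linewidth_hz)),
    class = "resonance")
}

#' @rdname resonance
#' @param j_hz Coupling constant in Hz.
#' @export
multiplet_triplet <- function(j_hz) {
  cbind(offset_hz = c(-j_hz, 0, j_hz), rel_intensity = c(1, 2, 1) / 4)
}

#' @rdname resonance
#' @export
multiplet_quartet <- function(j_hz) {
  cbind(offset_hz = c(-1.5, -0.5, 0.5, 1.5) * j_hz,
        rel_intensity = c(1, 3, 3, 1) / 8)
}

#' Default in vivo resonance library
#'
#' Literature 1H chemical shifts for the species modelled here: the ethanol
#' CH3 triplet (1.18 ppm, J = 7.1 Hz, 1:2:1), the N-acetyl aspartate (NAA)
#' CH3 singlet (2.01 ppm), total creatine (Cr, 3.03 ppm), choline-containing
#' compounds (Cho, 3.20 ppm, 9 equivalent protons) and water (4.70 ppm).
#' The ethanol CH2 quartet (3.65 ppm) is included but not part of the default
#' basis; at the echo times used here the CH3 triplet carries the
#' quantification.
#'
#' @param linewidth_hz Common linewidth applied to all resonances (Hz).
#' @return Named list of `resonance` objects.
#' @export
default_resonances <- function(linewidth_hz = 4) {
  list(
    Eth    = resonance(1.18, 3, multiplet_triplet(7.1), linewidth_hz),
    NAA    = resonance(2.01, 3, linewidth_hz = linewidth_hz),
    Cr     = resonance(3.03, 3, linewidth_hz = linewidth_hz),
    Cho    = resonance(3.20, 9, linewidth_hz = linewidth_hz),
    EthCH2 = resonance(3.65, 2, multiplet_quartet(7.1), linewidth_hz),
    Water  = resonance(4.70, 2, linewidth_hz = linewidth_hz)
  )
}

#' Acquisition parameters
#'
#' @param field_mhz Proton Larmor frequency in MHz (default 123.25, a 3 T
#'   system).
#' @param te_ms Echo time in ms (default 74, optimized for ethanol detection).
#' @param grid Strictly monotone ppm axis (default 0-5 ppm, 2048 points).
#' @param reference_ppm Carrier / water reference position (ppm).
#' @return An object of class `"acq_params"`.
#' @export
acq_params <- function(field_mhz = 123.25, te_ms = 74,
                       grid = seq(0, 5, length.out = 2048),
                       reference_ppm = 4.70) {
  if (field_mhz <= 0) stop("'field_mhz' must be > 0")
  if (te_ms <= 0) stop("'te_ms' must be > 0")
  d <- diff(grid)
  if (length(grid) < 2L || !(all(d > 0) || all(d < 0)))
    stop("'grid' must be strictly monotone")
  structure(
    list(field_mhz = field_mhz, te_ms = te_ms,
         grid = as.numeric(grid), reference_ppm = reference_ppm),
    class = "acq_params")
}

# Unit-area Lorentzian on the grid, truncation-corrected: the analytic mass of
# the line inside [min(grid), max(grid)] is rescaled to 1 so that numerical
# integrals of renders are calibrated regardless of where the line sits.
lorentzian_grid <- function(grid, center, fwhm) {
  hw <- fwhm / 2
  dens <- (hw / pi) / ((grid - center)^2 + hw^2)
  mass <- (atan((max(grid) - center) / hw) +
           atan((center - min(grid)) / hw)) / pi
  dens / mass
}

#' Render a resonance to an absorption-mode spectrum
#'
#' Sums unit-area Lorentzian lines at `center_ppm + offset_hz / field_mhz`,
#' weighted by the multiplet intensities and scaled by
#' `amplitude * n_protons`, so the integral of the returned vector over the
#' grid equals `amplitude * n_protons` (intensity x ppm units).
#'
#' @param res A [resonance()].
#' @param params An [acq_params()].
#' @param amplitude Scale factor; unit amplitude is the basis convention
#'   (1 mmol/L-equivalent before water scaling).
#' @return Numeric vector of intensities on `params$grid`.
#' @export
render_resonance <- function(res, params, amplitude = 1) {
  stopifnot(inherits(res, "resonance"), inherits(params, "acq_params"))
  grid <- params$grid
  fwhm_ppm <- res$linewidth_hz / params$field_mhz
  centers <- res$center_ppm + res$multiplet[, "offset_hz"] / params$field_mhz
  lo <- min(centers) - 3 * fwhm_ppm
  hi <- max(centers) + 3 * fwhm_ppm
  if (lo < min(grid) || hi > max(grid))
    stop("resonance at ", format(res$center_ppm),
         " ppm out of range: grid must cover +/- 3 linewidths [",
         format(lo), ", ", format(hi), "] ppm")
  y <- numeric(length(grid))
  for (k in seq_along(centers)) {
    y <- y + res$multiplet[k, "rel_intensity"] *
      lorentzian_grid(grid, centers[k], fwhm_ppm)
  }
  amplitude * res$n_protons * y
}

#' Build the default metabolite basis set
#'
#' Renders the selected resonances at unit amplitude on the acquisition grid.
#' The default columns are the species resolved in the in vivo spectra:
#' ethanol (CH3 triplet), NAA, Cr and Cho.
#'
#' @param params An [acq_params()]; the grid must span at least 0.5-4.2 ppm.
#' @param include Metabolite labels to include (subset of
#'   `names(resonances)`).
#' @param resonances Resonance library, default [default_resonances()].
#' @return An object of class `"basis_set"`: list with `names`, `spectra`
#'   (matrix, rows = grid points, columns = metabolites), `params`,
#'   `resonances`.
#' @export
default_basis <- function(params = acq_params(),
                          include = c("Eth", "NAA", "Cr", "Cho"),
                          resonances = default_resonances()) {
  if (min(params$grid) > 0.5 || max(params$grid) < 4.2)
    stop("grid too narrow: basis construction needs coverage of 0.5-4.2 ppm")
  missing_res <- setdiff(include, names(resonances))
  if (length(missing_res))
    stop("unknown resonance label(s): ", paste(missing_res, collapse = ", "))
  resonances <- resonances[include]
  spectra <- vapply(resonances, render_resonance, numeric(length(params$grid)),
                    params = params)
  basis_set(include, spectra, params, resonances)
}

#' @rdname default_basis
#' @param names Ordered metabolite labels.
#' @param spectra Matrix of unit-amplitude model spectra.
#' @export
basis_set <- function(names, spectra, params, resonances = NULL) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(names))
    stop("column count must equal label count")
  if (nrow(spectra) != length(params$grid))
    stop("spectra rows must match the acquisition grid")
  if (any(apply(spectra, 2, function(col) all(col <= 0))))
    stop("each basis column must have at least one strictly positive value")
  colnames(spectra) <- names
  structure(list(names = names, spectra = spectra, params = params,
                 resonances = resonances),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat("Metabolite basis set:", paste(x$names, collapse = ", "), "\n")
  cat(sprintf("  grid: %d points, %.2f-%.2f ppm; field %.2f MHz; TE %g ms\n",
              length(x$params$grid), min(x$params$grid), max(x$params$grid),
              x$params$field_mhz, x$params$te_ms))
  invisible(x)
}

# trapezoidal integral over the ppm grid (helper used throughout)
trapz_grid <- function(grid, y) {
  sum(diff(grid) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
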