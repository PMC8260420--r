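# Absolute quantification: internal water reference scaling, tissue-fraction
# water content, and normalization of ethanol to the voxel water volume
# fraction. No relaxation (T1/T2) correction is applied; a hook exists but
# defaults to the identity.

#' Ethanol molar mass (g/mol)
#' @export
ethanol_molar_mass <- 46.068

#' Compartment water constants
#'
#' Water concentration (mol/L) and water volume fraction (%) assumed for each
#' tissue compartment: 42.9 mol/L (78%) for gray matter, 35.8 mol/L (65%) for
#' white matter and 53.4 mol/L (97%) for cerebrospinal fluid. Both variants
#' are kept explicit: the percent weights drive the water-content
#' normalization, the molar weights drive the water-reference scaling.
#'
#' @param c_gm,c_wm,c_csf Water concentrations (mol/L).
#' @param w_gm,w_wm,w_csf Water volume fractions (%).
#' @return Object of class `"water_constants"`.
#' @export
water_constants <- function(c_gm = 42.9, c_wm = 35.8, c_csf = 53.4,
                            w_gm = 78, w_wm = 65, w_csf = 97) {
  structure(list(c_gm = c_gm, c_wm = c_wm, c_csf = c_csf,
                 w_gm = w_gm, w_wm = w_wm, w_csf = w_csf),
            class = "water_constants")
}

#' Voxel tissue composition
#'
#' @param f_gm,f_wm,f_csf Volume fractions in `[0, 1]`, summing to 1 within
#'   1e-9.
#' @param voxel_ml Voxel volume (mL, > 0).
#' @param region Label.
#' @return Object of class `"voxel_composition"`.
#' @export
voxel_composition <- function(f_gm, f_wm, f_csf, voxel_ml = 8,
                              region = "user") {
  f <- c(f_gm, f_wm, f_csf)
  if (any(f < -1e-12) || any(f > 1 + 1e-12))
    stop("tissue fractions must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9)
    stop("tissue fractions must sum to 1 (got ", format(sum(f)), ")")
  if (voxel_ml <= 0) stop("'voxel_ml' must be > 0")
  structure(list(f_gm = f_gm, f_wm = f_wm, f_csf = f_csf,
                 voxel_ml = voxel_ml, region = region),
            class = "voxel_composition")
}

#' Voxel water content from tissue fractions
#'
#' Fraction-weighted combination of the compartment constants, in both
#' conventions:
#' `percent = f_gm*w_gm + f_wm*w_wm + f_csf*w_csf` (the normalization
#' denominator) and `mol_per_L = f_gm*c_gm + f_wm*c_wm + f_csf*c_csf` (the
#' reference water concentration for absolute scaling).
#'
#' @param comp A [voxel_composition()].
#' @param constants A [water_constants()].
#' @return List with `percent` and `mol_per_L`.
#' @examples
#' water_content(voxel_composition(0.46, 0.50, 0.04))$percent  # 72.26 -> 72.3
#' @export
water_content <- function(comp, constants = water_constants()) {
  stopifnot(inherits(comp, "voxel_composition"))
  k <- constants
  list(percent = comp$f_gm * k$w_gm + comp$f_wm * k$w_wm + comp$f_csf * k$w_csf,
       mol_per_L = comp$f_gm * k$c_gm + comp$f_wm * k$c_wm +
         comp$f_csf * k$c_csf)
}

#' @rdname water_content
#' @param gm_pct,wm_pct,csf_pct Printed tissue percentages. Published
#'   segmentation tables round each percentage independently, so a row may
#'   not sum to exactly 100; the published water contents are weighted sums
#'   of the printed values, which this variant reproduces without
#'   renormalizing.
#' @export
water_content_from_pct <- function(gm_pct, wm_pct, csf_pct,
                                   constants = water_constants()) {
  k <- constants
  list(percent = (gm_pct * k$w_gm + wm_pct * k$w_wm + csf_pct * k$w_csf) / 100,
       mol_per_L = (gm_pct * k$c_gm + wm_pct * k$c_wm +
                      csf_pct * k$c_csf) / 100)
}

#' Round half away from zero
#'
#' The rounding used when mirroring the study tables (base `round()` rounds
#' half to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Internal-water-reference concentration
#'
#' `raw_mmol = (met_area / water_area) * (n_water / n_met) * C_water * 1000`,
#' with `C_water` the voxel's fraction-weighted water concentration (mol/L)
#' and the areas proton-weighted signal integrals. No relaxation correction
#' is applied (`relaxation_factor = 1`).
#'
#' @param met_area Proton-weighted metabolite signal area (same units as
#'   `water_area`).
#' @param water_area Water reference signal area (> 0).
#' @param n_met Protons contributing to the metabolite signal.
#' @param comp A [voxel_composition()].
#' @param constants A [water_constants()].
#' @param n_water Protons per water molecule.
#' @param relaxation_factor Multiplicative correction hook; identity by
#'   default.
#' @return Concentration in mmol per L of voxel.
#' @export
water_reference_conc <- function(met_area, water_area, n_met, comp,
                                 constants = water_constants(), n_water = 2,
                                 relaxation_factor = 1) {
  if (water_area <= 0) stop("'water_area' must be > 0")
  wc <- water_content(comp, constants)
  (met_area / water_area) * (n_water / n_met) * wc$mol_per_L * 1000 *
    relaxation_factor
}

#' Normalize a concentration to the voxel water volume fraction
#'
#' Ethanol distributes in the aqueous compartment only, so concentrations per
#' litre of voxel are converted to concentrations per litre of voxel water by
#' dividing by `wc_percent / 100`. [denormalize_from_water()] is the exact
#' inverse (multiply by the water content to recover per-voxel values).
#'
#' @param raw_gL Concentration per L of voxel (g/L).
#' @param wc_percent Voxel water content in percent, in (0, 100].
#' @return Concentration per L of voxel water (g/L).
#' @export
normalize_to_water <- function(raw_gL, wc_percent) {
  if (any(wc_percent <= 0)) stop("'wc_percent' must be > 0")
  raw_gL / (wc_percent / 100)
}

#' @rdname normalize_to_water
#' @param norm_gL Water-normalized concentration (g/L).
#' @export
denormalize_from_water <- function(norm_gL, wc_percent) {
  if (any(wc_percent <= 0)) stop("'wc_percent' must be > 0")
  norm_gL * (wc_percent / 100)
}

#' Convert ethanol concentrations between mmol/L and g/L
#'
#' @param c_mmol,c_gL Nonnegative concentrations.
#' @param molar_mass Molar mass in g/mol (default ethanol, 46.068).
#' @export
mmol_to_gL <- function(c_mmol, molar_mass = ethanol_molar_mass) {
  if (any(c_mmol < 0)) stop("concentration must be >= 0")
  c_mmol * molar_mass / 1000
}

#' @rdname mmol_to_gL
#' @export
gL_to_mmol <- function(c_gL, molar_mass = ethanol_molar_mass) {
  if (any(c_gL < 0)) stop("concentration must be >= 0")
  c_gL * 1000 / molar_mass
}

#' Quantify a fitted metabolite against the water reference
#'
#' Runs the full quantification chain for one voxel: fitted amplitude ->
#' proton-weighted area -> raw concentration (internal water reference) ->
#' g/L -> water-normalized g/L, carrying the CRLB from the fit.
#'
#' @param fit An [lcfit()] whose basis carries the resonance metadata.
#' @param water_area Water reference area from [water_area()].
#' @param comp A [voxel_composition()].
#' @param metabolite Label to quantify (default `"Eth"`).
#' @param constants A [water_constants()].
#' @param molar_mass g/mol used for the mass-unit conversion.
#' @return Object of class `"quant_result"`: `raw_conc_mmol`, `raw_gL`,
#'   `norm_conc_gL`, `wc_percent`, `crlb_percent`, plus labels.
#' @export
quantify_voxel <- function(fit, water_area, comp, metabolite = "Eth",
                           constants = water_constants(),
                           molar_mass = ethanol_molar_mass) {
  stopifnot(inherits(fit, "lcfit"))
  if (!metabolite %in% names(fit$amplitudes))
    stop("metabolite '", metabolite, "' not in fit")
  res <- fit$basis$resonances[[metabolite]]
  if (is.null(res))
    stop("basis carries no resonance metadata for '", metabolite, "'")
  met_area <- fit$amplitudes[[metabolite]] * res$n_protons
  raw_mmol <- water_reference_conc(met_area, water_area, res$n_protons,
                                   comp, constants)
  raw_gL <- mmol_to_gL(raw_mmol, molar_mass)
  wc <- water_content(comp, constants)
  structure(
    list(metabolite = metabolite, region = comp$region,
         raw_conc_mmol = raw_mmol, raw_gL = raw_gL,
         norm_conc_gL = normalize_to_water(raw_gL, wc$percent),
         wc_percent = wc$percent,
         crlb_percent = unname(fit$crlb_percent[metabolite])),
    class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("%s in %s: %.3f g/L (normalized to %.1f%% voxel water; raw %.3f g/L = %.2f mmol/L)",
              x$metabolite, x$region, x$norm_conc_gL, x$wc_percent,
              x$raw_gL, x$raw_conc_mmol))
  if (is.finite(x$crlb_percent %||% NA_real_))
    cat(sprintf("; CRLB %.1f%%", x$crlb_percent))
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
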