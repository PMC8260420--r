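# Widmark-model study-design calculations and the brain-versus-serum
# comparison. Serum g/L converts to whole-blood g/kg via the factor implied
# by the study's stated 0.99 g/L <-> 0.8 g/kg correspondence (0.99/0.8 =
# 1.2375, close to the conventional 1.236).

#' Pharmacokinetic and dosing parameters
#'
#' @param body_mass_kg Body mass (kg).
#' @param r_factor Widmark distribution factor (dimensionless; ~0.7 for men).
#' @param target_bac_gkg Target blood alcohol concentration (g/kg).
#' @param beta_gL_per_h Zero-order elimination slope (g/L per hour; classical
#'   range 0.1-0.2).
#' @param serum_blood_factor Divisor converting serum g/L to blood g/kg.
#' @param abv Beverage ethanol volume fraction (vodka: 0.40).
#' @param ethanol_density Ethanol density (g/mL).
#' @param resorption_deficit Fraction of the ingested dose that never reaches
#'   the blood, in `[0, 1)`.
#' @param absorption_min Duration of the linear absorption ramp (min).
#' @return Object of class `"pk_params"`.
#' @export
pk_params <- function(body_mass_kg = 70, r_factor = 0.7,
                      target_bac_gkg = 0.8, beta_gL_per_h = 0.15,
                      serum_blood_factor = 0.99 / 0.8, abv = 0.40,
                      ethanol_density = 0.789, resorption_deficit = 0.2,
                      absorption_min = 60) {
  vals <- c(body_mass_kg, r_factor, target_bac_gkg, beta_gL_per_h,
            serum_blood_factor, abv, ethanol_density, absorption_min)
  if (any(vals <= 0)) stop("all pk parameters must be positive")
  if (abv > 1) stop("'abv' must lie in (0, 1]")
  if (resorption_deficit < 0 || resorption_deficit >= 1)
    stop("'resorption_deficit' must lie in [0, 1)")
  structure(list(body_mass_kg = body_mass_kg, r_factor = r_factor,
                 target_bac_gkg = target_bac_gkg,
                 beta_gL_per_h = beta_gL_per_h,
                 serum_blood_factor = serum_blood_factor, abv = abv,
                 ethanol_density = ethanol_density,
                 resorption_deficit = resorption_deficit,
                 absorption_min = absorption_min),
            class = "pk_params")
}

#' Convert between serum and whole-blood ethanol concentrations
#'
#' `blood_gkg = serum_gL / serum_blood_factor`; the default factor 1.2375
#' maps 0.99 g/L serum to exactly 0.80 g/kg blood.
#'
#' @param serum_gL,blood_gkg Nonnegative concentrations.
#' @param factor Serum-to-blood divisor.
#' @export
blood_from_serum <- function(serum_gL, factor = 0.99 / 0.8) {
  if (any(serum_gL < 0)) stop("serum concentration must be >= 0")
  serum_gL / factor
}

#' @rdname blood_from_serum
#' @export
serum_from_blood <- function(blood_gkg, factor = 0.99 / 0.8) {
  if (any(blood_gkg < 0)) stop("blood concentration must be >= 0")
  blood_gkg * factor
}

#' Widmark dose of ethanol for a target blood alcohol concentration
#'
#' `grams = target_bac_gkg * body_mass_kg * r_factor / (1 - resorption_deficit)`.
#'
#' @param pk A [pk_params()].
#' @return Grams of ethanol to ingest.
#' @export
widmark_dose_grams <- function(pk) {
  stopifnot(inherits(pk, "pk_params"))
  pk$target_bac_gkg * pk$body_mass_kg * pk$r_factor /
    (1 - pk$resorption_deficit)
}

#' Beverage volume delivering a given ethanol mass
#'
#' @param grams Ethanol mass (g).
#' @param abv Ethanol volume fraction of the beverage.
#' @param ethanol_density g/mL.
#' @return Beverage volume in mL.
#' @export
dose_to_beverage_ml <- function(grams, abv = 0.40, ethanol_density = 0.789) {
  if (abv <= 0 || ethanol_density <= 0)
    stop("'abv' and 'ethanol_density' must be > 0")
  grams / (ethanol_density * abv)
}

#' Compare brain and serum ethanol matrices
#'
#' Summarizes each matrix per subject (max, min, range, coefficient of
#' variation), pairs each serum sample with the temporally nearest brain
#' measurement within `pair_tol_min`, and compares flatness of the two curves
#' via the ratio of their CVs. A degenerate pair of constant series gets CVs
#' of 0 and a flatness ratio of 1 by convention. No significance testing is
#' performed (n = 3 subjects).
#'
#' @param brain data.frame with columns `subject`, `time_min`, `conc_gL`
#'   (plus optional `region`, `cycle`).
#' @param serum data.frame with columns `subject`, `time_min`, `conc_gL`
#'   (plus optional `timepoint`).
#' @param pair_tol_min Maximum |time difference| for nearest-time pairing
#'   (min).
#' @return Object of class `"matrix_comparison"`: `summary` (per subject per
#'   matrix), `pairs` (nearest-time pairings with brain/serum ratio),
#'   `flatness` (CV ratios).
#' @export
compare_matrices <- function(brain, serum, pair_tol_min = 20) {
  need <- c("subject", "time_min", "conc_gL")
  if (!all(need %in% names(brain)) || !all(need %in% names(serum)))
    stop("brain and serum tables need columns subject, time_min, conc_gL")
  subjects <- intersect(unique(brain$subject), unique(serum$subject))
  if (!length(subjects)) stop("no common subjects")
  for (s in subjects) {
    bs <- brain[brain$subject == s, ]; ss <- serum[serum$subject == s, ]
    if (nrow(bs) < 2L || nrow(ss) < 2L)
      stop("need >= 2 timepoints per subject per matrix (subject ", s, ")")
    if (max(bs$time_min) < min(ss$time_min) ||
        max(ss$time_min) < min(bs$time_min))
      stop("unpairable series for subject ", s, ": no overlapping time span")
  }

  cv <- function(x) if (mean(x) == 0 || stats::sd(x) == 0) 0
                    else stats::sd(x) / mean(x)
  stat_row <- function(s, what, x)
    data.frame(subject = s, matrix = what, max = max(x), min = min(x),
               range = diff(range(x)), cv = cv(x))
  summ <- do.call(rbind, lapply(subjects, function(s) {
    rbind(stat_row(s, "brain", brain$conc_gL[brain$subject == s]),
          stat_row(s, "serum", serum$conc_gL[serum$subject == s]))
  }))

  pairs <- do.call(rbind, lapply(subjects, function(s) {
    bs <- brain[brain$subject == s, ]; ss <- serum[serum$subject == s, ]
    do.call(rbind, lapply(seq_len(nrow(ss)), function(i) {
      dt <- abs(bs$time_min - ss$time_min[i])
      j <- which.min(dt)
      if (dt[j] > pair_tol_min) return(NULL)
      data.frame(subject = s,
                 timepoint = if ("timepoint" %in% names(ss))
                   ss$timepoint[i] else NA_character_,
                 serum_time_min = ss$time_min[i],
                 brain_time_min = bs$time_min[j],
                 serum_gL = ss$conc_gL[i], brain_gL = bs$conc_gL[j],
                 brain_over_serum = if (ss$conc_gL[i] == 0 &&
                                        bs$conc_gL[j] == 0) 1
                   else bs$conc_gL[j] / ss$conc_gL[i])
    }))
  }))

  flat <- do.call(rbind, lapply(subjects, function(s) {
    cb <- summ$cv[summ$subject == s & summ$matrix == "brain"]
    cs <- summ$cv[summ$subject == s & summ$matrix == "serum"]
    data.frame(subject = s, cv_brain = cb, cv_serum = cs,
               cv_ratio_brain_over_serum = if (cb == 0 && cs == 0) 1
                 else cb / cs,
               brain_flatter = cb < cs | (cb == 0 & cs == 0))
  }))

  structure(list(summary = summ, pairs = pairs, flatness = flat,
                 pair_tol_min = pair_tol_min),
            class = "matrix_comparison")
}

#' @export
print.matrix_comparison <- function(x, ...) {
  cat("Brain vs serum ethanol comparison\n\nPer-subject summaries:\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("\nNearest-time pairings (tolerance %g min):\n", x$pair_tol_min))
  print(x$pairs, row.names = FALSE)
  cat("\nFlatness (coefficient of variation):\n")
  print(x$flatness, row.names = FALSE)
  invisible(x)
}
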