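# Accessors for the packaged drinking-study dataset: three male volunteers,
# serum ethanol at five timepoints (T1 = end of drinking through T5 ~ 160
# min later) and water-normalized brain ethanol from four voxels (occipital
# cortex, cerebellum, frontal cortex, putamen) over two measurement cycles,
# plus the segmented tissue fractions of every voxel.
#
# Brain measurement times are reconstructed from the protocol order and the
# ~7-min scan duration (serum times are the study's approximate T1..T5
# offsets); they matter only for nearest-time pairing.

study_file <- function(name) {
  path <- system.file("extdata", name, package = "ethanolMRS")
  if (!nzchar(path)) stop("packaged fixture '", name, "' not found")
  path
}

#' Packaged study ethanol concentrations
#'
#' All serum and water-normalized brain ethanol concentrations of the study,
#' in g/L, with subject, matrix, region, cycle, timepoint and approximate
#' time after the end of drinking.
#'
#' @return data.frame with columns `matrix`, `subject`, `cycle`, `region`,
#'   `timepoint`, `time_min`, `conc_gL`.
#' @export
study_concentrations <- function() {
  utils::read.csv(study_file("study_ethanol_concentrations.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname study_concentrations
#' @export
study_brain <- function() {
  x <- study_concentrations()
  x <- x[x$matrix == "brain", c("subject", "cycle", "region", "time_min",
                                "conc_gL")]
  rownames(x) <- NULL
  x
}

#' @rdname study_concentrations
#' @export
study_serum <- function() {
  x <- study_concentrations()
  x <- x[x$matrix == "serum", c("subject", "timepoint", "time_min",
                                "conc_gL")]
  rownames(x) <- NULL
  x
}

#' Packaged study voxel tissue fractions
#'
#' Gray matter, white matter and CSF percentages of every measurement voxel
#' (subject x cycle x region) from the anatomical segmentation, together
#' with the voxel water content (%) as published.
#'
#' @return data.frame with columns `subject`, `cycle`, `region`, `gm_pct`,
#'   `wm_pct`, `csf_pct`, `wc_pct`.
#' @export
study_voxels <- function() {
  utils::read.csv(study_file("study_voxel_fractions.csv"),
                  stringsAsFactors = FALSE)
}

#' Study participants
#'
#' Demographics and the actually administered vodka volumes (40 vol%).
#' The drinking volumes are observational fixture data: the study's exact
#' Widmark distribution factor and resorption deficit are not stated, so
#' they cannot be recomputed from the dose functions.
#'
#' @return data.frame with one row per volunteer.
#' @export
study_subjects <- function() {
  data.frame(subject = c("V1", "V2", "V3"),
             age_y = c(26, 29, 24),
             height_cm = c(173, 183, 185),
             body_mass_kg = c(62, 69, 82.5),
             beverage_L = c(0.15, 0.17, 0.20),
             stringsAsFactors = FALSE)
}

#' Voxel composition from a study table row
#'
#' Printed percentages are rounded independently and may sum to 99-101; they
#' are renormalized here so the composition satisfies the exact sum-to-one
#' invariant required for simulation. Table-mirroring water contents use
#' [water_content_from_pct()] on the printed values instead.
#'
#' @param row One row of [study_voxels()].
#' @return A [voxel_composition()].
#' @export
composition_from_row <- function(row) {
  ml <- region_ranges()[[row$region]]$ml
  f <- c(row$gm_pct, row$wm_pct, row$csf_pct)
  f <- f / sum(f)
  voxel_composition(f[1], f[2], f[3], voxel_ml = ml, region = row$region)
}
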