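# Plain-text serialization: spectra as ppm/intensity CSV with a JSON
# metadata sidecar; basis sets as a JSON header plus a CSV matrix; serum
# series and fit results as CSV/JSON. Numeric round trips are kept at full
# double precision (15 significant digits).

fmt_num <- function(x) format(x, digits = 15, scientific = TRUE, trim = TRUE)

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write / read a spectrum as CSV plus JSON sidecar
#'
#' The CSV holds `ppm,intensity`; the sidecar holds `voxel_id`,
#' `is_water_reference` and the acquisition parameters (grid excluded — it
#' lives in the CSV).
#'
#' @param spec An [mrs_spectrum()].
#' @param path CSV path; the sidecar replaces `.csv` with `.json`.
#' @return `write_spectrum`: the path, invisibly. `read_spectrum`: an
#'   [mrs_spectrum()].
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "mrs_spectrum"))
  utils::write.csv(data.frame(ppm = fmt_num(spec$grid),
                              intensity = fmt_num(spec$intensity)),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(voxel_id = spec$voxel_id,
               is_water_reference = spec$is_water_reference,
               params = list(field_mhz = spec$params$field_mhz,
                             te_ms = spec$params$te_ms,
                             reference_ppm = spec$params$reference_ppm))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  tab <- utils::read.csv(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  params <- acq_params(field_mhz = meta$params$field_mhz,
                       te_ms = meta$params$te_ms,
                       grid = tab$ppm,
                       reference_ppm = meta$params$reference_ppm)
  mrs_spectrum(tab$ppm, tab$intensity, params, voxel_id = meta$voxel_id,
               is_water_reference = meta$is_water_reference)
}

#' Write / read a basis set (JSON header + CSV matrix)
#'
#' The CSV has the ppm grid in the first column and one column per
#' metabolite; the JSON header carries labels, acquisition parameters and
#' the resonance definitions. The round trip is lossless to 1e-12.
#'
#' @param basis A [basis_set()].
#' @param path CSV path; header written next to it with `.json` extension.
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "basis_set"))
  tab <- data.frame(ppm = fmt_num(basis$params$grid))
  for (nm in basis$names) tab[[nm]] <- fmt_num(basis$spectra[, nm])
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  res <- lapply(basis$resonances, function(r) {
    if (is.null(r)) return(NULL)
    list(center_ppm = r$center_ppm, n_protons = r$n_protons,
         linewidth_hz = r$linewidth_hz,
         offset_hz = r$multiplet[, "offset_hz"],
         rel_intensity = r$multiplet[, "rel_intensity"])
  })
  hdr <- list(labels = basis$names,
              params = list(field_mhz = basis$params$field_mhz,
                            te_ms = basis$params$te_ms,
                            reference_ppm = basis$params$reference_ppm),
              resonances = res)
  jsonlite::write_json(hdr, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  tab <- utils::read.csv(path)
  hdr <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  params <- acq_params(field_mhz = hdr$params$field_mhz,
                       te_ms = hdr$params$te_ms,
                       grid = tab$ppm,
                       reference_ppm = hdr$params$reference_ppm)
  resonances <- lapply(hdr$resonances, function(r) {
    if (is.null(r$center_ppm)) return(NULL)
    resonance(r$center_ppm, r$n_protons,
              cbind(offset_hz = r$offset_hz, rel_intensity = r$rel_intensity),
              r$linewidth_hz)
  })
  basis_set(hdr$labels, as.matrix(tab[, hdr$labels, drop = FALSE]), params,
            resonances[hdr$labels])
}

#' Write / read a serum series CSV (`subject,time_min,serum_g_per_L`)
#'
#' @param series A [serum_series()] (or data.frame with those columns).
#' @param path CSV path.
#' @export
write_serum <- function(series, path) {
  out <- data.frame(subject = series$subject, time_min = series$time_min,
                    serum_g_per_L = series$conc_gL)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_serum
#' @export
read_serum <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(subject = tab$subject, time_min = tab$time_min,
                    conc_gL = tab$serum_g_per_L, stringsAsFactors = FALSE)
  class(out) <- c("serum_series", "data.frame")
  out
}

#' Serialize a fit result to JSON
#'
#' Records amplitudes, percent CRLBs, residual RMS, the noise estimate and
#' the active set — enough to audit a quantification without the spectra.
#'
#' @param fit An [lcfit()].
#' @param path JSON path.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "lcfit"))
  jsonlite::write_json(
    list(voxel_id = fit$voxel_id,
         amplitudes = as.list(fit$amplitudes),
         crlb_percent = as.list(fit$crlb_percent),
         active = as.list(fit$active),
         residual_rms = fit$residual_rms,
         noise_sd_est = fit$noise_sd_est,
         solver = "lawson-hanson nnls"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tissue-fraction table
#'
#' CSV with columns `subject,cycle,region,gm_pct,wm_pct,csf_pct` (percent
#' integers); fractions are derived downstream.
#'
#' @param path CSV path.
#' @export
read_fractions <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "cycle", "region", "gm_pct", "wm_pct", "csf_pct")
  if (!all(need %in% names(tab)))
    stop("fraction table needs columns ", paste(need, collapse = ", "))
  tab
}
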