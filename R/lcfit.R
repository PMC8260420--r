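# Linear-combination fit of metabolite basis spectra.
#
# The estimator minimizes ||y - B a||^2 subject to a >= 0 (Lawson-Hanson
# active set). Precision is reported as Cramer-Rao lower bounds computed on
# the active columns:
#   CRLB_i(%) = sqrt([(B'B)^-1]_ii) * sigma / a_i * 100.
# This is the core of programs like LCModel without their nuisance machinery
# (spline baseline, lineshape regularization, phase search); an optional
# low-order polynomial baseline can be co-fitted.

#' Fit a spectrum as a nonnegative linear combination of basis spectra
#'
#' @param spec An [mrs_spectrum()]. If its grid differs from the basis grid
#'   the spectrum is linearly resampled onto the basis grid; extrapolation is
#'   refused.
#' @param basis A [basis_set()] with at least one column.
#' @param noise_sd Known noise standard deviation; if `NULL` it is estimated
#'   from the signal-free window via [estimate_noise()].
#' @param baseline_degree `NULL` (no baseline, the default) or an integer
#'   0-2: degree of an unconstrained polynomial baseline co-fitted with the
#'   nonnegative amplitudes by alternating minimization.
#' @return An object of class `"lcfit"`: amplitudes, CRLBs (percent; `NA` for
#'   metabolites fitted at the zero boundary), residual RMS, the noise
#'   estimate and the inputs. Methods: `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `predict`, `plot`, `simulate`.
#' @examples
#' b <- default_basis()
#' tr <- ground_truth(c(Eth = 8, NAA = 12, Cr = 8, Cho = 2),
#'                    noise_sd = 30, seed = 42)
#' fit <- lcfit(simulate_spectrum(tr, b), b)
#' coef(fit)
#' @export
lcfit <- function(spec, basis, noise_sd = NULL, baseline_degree = NULL) {
  stopifnot(inherits(spec, "mrs_spectrum"), inherits(basis, "basis_set"))
  B <- basis$spectra
  if (ncol(B) < 1L) stop("basis must have at least one column")
  grid <- basis$params$grid
  y <- spec$intensity
  if (length(spec$grid) != length(grid) ||
      any(abs(spec$grid - grid) > 1e-9)) {
    if (min(grid) < min(spec$grid) - 1e-12 ||
        max(grid) > max(spec$grid) + 1e-12)
      stop("grid mismatch: basis grid extends beyond the spectrum; ",
           "refusing to extrapolate")
    y <- stats::approx(spec$grid, spec$intensity, xout = grid)$y
  }

  qrB <- qr(B)
  if (qrB$rank < ncol(B)) {
    cc <- stats::cor(B)
    pairs <- which(abs(cc) > 1 - 1e-8 & upper.tri(cc), arr.ind = TRUE)
    culprits <- unique(c(basis$names[pairs[, 1]], basis$names[pairs[, 2]]))
    stop("rank-deficient basis (collinear columns: ",
         paste(culprits, collapse = ", "), ")")
  }

  if (is.null(baseline_degree)) {
    sol <- pracma::lsqnonneg(B, y)
    a <- sol$x
    base_coef <- NULL
    base_vals <- 0
  } else {
    if (!baseline_degree %in% 0:2)
      stop("'baseline_degree' must be 0, 1 or 2")
    P <- stats::poly(grid, degree = max(baseline_degree, 1), simple = TRUE)
    P <- cbind(1, P[, seq_len(baseline_degree), drop = FALSE])
    a <- rep(0, ncol(B)); base_vals <- rep(0, length(y))
    for (it in 1:200) {
      a_new <- pracma::lsqnonneg(B, y - base_vals)$x
      base_coef <- qr.coef(qr(P), y - B %*% a_new)
      base_new <- as.numeric(P %*% base_coef)
      delta <- max(abs(a_new - a), abs(base_new - base_vals))
      a <- a_new; base_vals <- base_new
      if (delta < 1e-10) break
    }
  }
  names(a) <- basis$names
  fitted_vals <- as.numeric(B %*% a) + base_vals
  resid <- y - fitted_vals

  sigma <- if (is.null(noise_sd)) estimate_noise(spec) else noise_sd
  active <- a > 0

  fit <- structure(
    list(amplitudes = a, active = active,
         residual_rms = sqrt(mean(resid^2)),
         noise_sd_est = sigma,
         fitted = fitted_vals, residuals = resid,
         baseline_coef = base_coef,
         basis = basis, grid = grid, intensity = y,
         voxel_id = spec$voxel_id),
    class = "lcfit")
  fit$crlb_percent <- crlb(fit)
  fit
}

#' Cramer-Rao lower bounds for a linear-combination fit
#'
#' For the additive white-Gaussian model the Fisher information of the active
#' amplitudes is `(B'B) / sigma^2`, giving
#' `CRLB_i = sqrt([(B'B)^-1]_ii) * sigma / a_i * 100` percent. Metabolites
#' fitted at the zero boundary get `NA` (flagged, not numeric): a relative
#' bound on a zero amplitude is undefined.
#'
#' @param fit An [lcfit()] object.
#' @param noise_sd Noise SD to use; defaults to the fit's estimate.
#' @return Named vector of percent CRLBs (`NA` for inactive metabolites).
#' @export
crlb <- function(fit, noise_sd = NULL) {
  stopifnot(inherits(fit, "lcfit"))
  sigma <- if (is.null(noise_sd)) fit$noise_sd_est else noise_sd
  a <- fit$amplitudes
  out <- rep(NA_real_, length(a))
  names(out) <- names(a)
  act <- fit$active
  if (!any(act)) return(out)
  Ba <- fit$basis$spectra[, act, drop = FALSE]
  info <- crossprod(Ba)
  inv <- tryCatch(solve(info), error = function(e)
    stop("singular information matrix for active columns: ",
         paste(names(a)[act], collapse = ", ")))
  out[act] <- sqrt(diag(inv)) * sigma / a[act] * 100
  out
}

#' Estimate the noise standard deviation from a signal-free window
#'
#' Takes the intensities inside `window` (ppm), removes a linear trend and
#' returns their standard deviation. The default window 4.2-5.0 ppm is signal
#' free in water-suppressed spectra fitted with the default basis.
#'
#' @param spec An [mrs_spectrum()].
#' @param window Length-2 ppm range.
#' @return Estimated noise SD (intensity units).
#' @export
estimate_noise <- function(spec, window = c(4.2, 5.0)) {
  stopifnot(inherits(spec, "mrs_spectrum"))
  idx <- spec$grid >= min(window) & spec$grid <= max(window)
  if (sum(idx) < 10L)
    stop("signal-free window [", min(window), ", ", max(window),
         "] ppm absent from grid (", sum(idx), " points)")
  x <- spec$grid[idx]; y <- spec$intensity[idx]
  stats::sd(stats::lm.fit(cbind(1, x), y)$residuals)
}

#' @export
coef.lcfit <- function(object, ...) object$amplitudes

#' @export
fitted.lcfit <- function(object, ...) object$fitted

#' @export
residuals.lcfit <- function(object, ...) object$residuals

#' @export
print.lcfit <- function(x, ...) {
  cat("Linear-combination spectral fit")
  if (nzchar(x$voxel_id) && x$voxel_id != "user")
    cat(" [", x$voxel_id, "]", sep = "")
  cat("\n  amplitudes:\n")
  print(round(x$amplitudes, 4))
  cat(sprintf("  residual RMS %.4g; noise SD %.4g\n",
              x$residual_rms, x$noise_sd_est))
  invisible(x)
}

#' @export
summary.lcfit <- function(object, ...) {
  tab <- data.frame(metabolite = names(object$amplitudes),
                    amplitude = unname(object$amplitudes),
                    crlb_percent = unname(object$crlb_percent),
                    active = unname(object$active),
                    row.names = NULL)
  structure(list(table = tab, residual_rms = object$residual_rms,
                 noise_sd_est = object$noise_sd_est,
                 voxel_id = object$voxel_id),
            class = "summary.lcfit")
}

#' @export
print.summary.lcfit <- function(x, ...) {
  cat("Linear-combination spectral fit")
  if (nzchar(x$voxel_id) && x$voxel_id != "user")
    cat(" [", x$voxel_id, "]", sep = "")
  cat("\n")
  tab <- x$table
  tab$amplitude <- signif(tab$amplitude, 5)
  tab$crlb_percent <- signif(tab$crlb_percent, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("residual RMS: %.4g   estimated noise SD: %.4g\n",
              x$residual_rms, x$noise_sd_est))
  invisible(x)
}

#' @export
predict.lcfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  ppm <- if (is.data.frame(newdata)) newdata$ppm else as.numeric(newdata)
  stats::approx(object$grid, object$fitted, xout = ppm)$y
}

#' @export
plot.lcfit <- function(x, ...) {
  offset <- 1.1 * max(abs(x$residuals)) + 0.05 * diff(range(x$intensity))
  graphics::plot(x$grid, x$intensity, type = "l", col = "grey40",
                 xlim = rev(range(x$grid)), xlab = "chemical shift (ppm)",
                 ylab = "intensity",
                 ylim = range(c(x$intensity, x$fitted,
                                min(x$intensity) - 2.2 * offset)), ...)
  graphics::lines(x$grid, x$fitted, col = "red")
  graphics::lines(x$grid, x$residuals + min(x$intensity) - 2 * offset,
                  col = "grey60")
  graphics::legend("topleft", legend = c("data", "fit", "residual"),
                   col = c("grey40", "red", "grey60"), lty = 1, bty = "n")
  invisible(x)
}

#' Simulate replicate spectra from a fitted model
#'
#' Draws `nsim` spectra `B a + N(0, sigma)` using the fitted amplitudes and
#' the fit's noise estimate; the tool behind parametric Monte-Carlo checks of
#' the reported CRLBs.
#'
#' @param object An [lcfit()].
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Matrix (grid points x nsim).
#' @export
simulate.lcfit <- function(object, nsim = 1, seed = 1L, ...) {
  mu <- as.numeric(object$basis$spectra %*% object$amplitudes)
  with_seed(seed, {
    matrix(stats::rnorm(length(mu) * nsim, mean = mu,
                        sd = object$noise_sd_est),
           nrow = length(mu), ncol = nsim)
  })
}

#' Integrated area of the unsuppressed water reference
#'
#' Fits the reference scan with a single water basis column rendered on its
#' own grid and returns `amplitude * n_protons_water`, the proton-weighted
#' signal area used as the denominator of the internal-water-reference
#' quantification. Robust to the Lorentzian tails leaving the grid, unlike a
#' plain numerical integral.
#'
#' @param ref An [mrs_spectrum()] water reference.
#' @param params Acquisition parameters (default: the spectrum's own).
#' @return Water signal area (intensity x ppm units).
#' @export
water_area <- function(ref, params = ref$params) {
  stopifnot(inherits(ref, "mrs_spectrum"))
  water <- default_resonances()$Water
  water$center_ppm <- params$reference_ppm
  wb <- basis_set("Water",
                  matrix(render_resonance(water, params), ncol = 1),
                  params, list(Water = water))
  fit <- lcfit(ref, wb, noise_sd = 0)
  unname(fit$amplitudes["Water"] * water$n_protons)
}
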