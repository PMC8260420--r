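# Shared fixtures, built once per run. Everything is generated in code; the
# only stored data are the packaged study tables.

PARAMS <- acq_params()
BASIS <- default_basis(PARAMS)

# a mid-study occipital voxel
COMP_OCC <- voxel_composition(0.46, 0.50, 0.04, voxel_ml = 15.6,
                              region = "occipital_cortex")

# small dense design for brute-force oracles: three overlapping singlets on a
# coarse grid
small_basis <- function(linewidth_hz = 12) {
  p <- acq_params(grid = seq(0.5, 4.5, length.out = 120))
  res <- list(A = resonance(1.8, 1, linewidth_hz = linewidth_hz),
              B = resonance(2.1, 1, linewidth_hz = linewidth_hz),
              C = resonance(2.5, 1, linewidth_hz = linewidth_hz))
  spectra <- vapply(res, render_resonance, numeric(length(p$grid)),
                    params = p)
  basis_set(names(res), spectra, p, res)
}

# exhaustive active-set nonnegative least squares (independent oracle)
nnls_bruteforce <- function(B, y) {
  p <- ncol(B)
  best <- list(ssr = sum(y^2), x = rep(0, p))
  for (mask in 1:(2^p - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    xs <- qr.coef(qr(B[, idx, drop = FALSE]), y)
    if (any(xs < 0)) next
    r <- y - B[, idx, drop = FALSE] %*% xs
    if (sum(r^2) < best$ssr - 1e-12) {
      x <- rep(0, p); x[idx] <- xs
      best <- list(ssr = sum(r^2), x = x)
    }
  }
  best
}
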