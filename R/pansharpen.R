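#' Gram-Schmidt pan-sharpening
#'
#' Component-substitution fusion of a 4-band multispectral image (2 m)
#' with a co-registered panchromatic band (0.5 m):
#' \enumerate{
#'   \item simulate a low-resolution pan as the weighted mean of the four
#'     bands;
#'   \item Gram-Schmidt-orthogonalize `[sim_pan, blue, green, red, nir]`
#'     in that order using image-wide mean/covariance statistics;
#'   \item upsample the GS components to the pan grid with
#'     [resample_cubic()];
#'   \item replace the first component by the real pan, linearly matched
#'     to the mean and standard deviation of the *upsampled* simulated
#'     pan (so a pan identical to the upsampled simulated pan makes the
#'     substitution a no-op);
#'   \item invert the GS transform;
#'   \item clip to the radiometric range.
#' }
#' The fused image preserves the spectral statistics of the input bands
#' while injecting the pan band's spatial detail.
#'
#' @param ms 4-band [mb_raster()] at the coarse resolution.
#' @param pan 1-band [mb_raster()] at the fine resolution; must cover the
#'   same extent, with a cell size that divides the multispectral cell
#'   size by an integer factor.
#' @param weights simulated-pan band weights (non-negative, sum 1).
#' @param clip clip the output to `ms$dn_range` (default `TRUE`).
#' @return A 4-band [mb_raster()] on the pan grid.
#' @export
gram_schmidt_pansharpen <- function(ms, pan,
                                    weights = c(0.1, 0.3, 0.4, 0.2),
                                    clip = TRUE) {
  stopifnot(inherits(ms, "mb_raster"), inherits(pan, "mb_raster"),
            n_bands(ms) == 4L, n_bands(pan) == 1L)
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    stop("weights must be non-negative and sum to 1")
  }
  ratio <- ms$cell_size_m / pan$cell_size_m
  if (abs(ratio - round(ratio)) > 1e-9) stop("non-integer resolution ratio")
  dms <- dim(ms$bands); dp <- dim(pan$bands)
  if (dp[1] != dms[1] * ratio || dp[2] != dms[2] * ratio) {
    stop("extent mismatch between ms and pan")
  }

  nb <- 4L
  X <- matrix(ms$bands, ncol = nb)               # pixels x bands (2 m)
  sim_pan <- X %*% weights
  comps <- cbind(sim_pan, X)                     # order: sim_pan, b1..b4
  mu <- colMeans(comps)
  GS <- matrix(0, nrow(comps), nb + 1L)
  phi <- matrix(0, nb + 1L, nb + 1L)             # projection coefficients
  for (k in seq_len(nb + 1L)) {
    g <- comps[, k] - mu[k]
    if (k > 1L) for (j in seq_len(k - 1L)) {
      denom <- sum(GS[, j]^2)
      phi[k, j] <- if (denom > 0) sum((comps[, k] - mu[k]) * GS[, j]) / denom
                   else 0
      g <- g - phi[k, j] * GS[, j]
    }
    GS[, k] <- g
  }

  up <- function(v) {
    r <- mb_raster(matrix(v, dms[1], dms[2]), ms$cell_size_m,
                   origin = ms$origin, band_names = "c",
                   dn_range = c(-Inf, Inf))
    as.vector(resample_cubic(r, pan$cell_size_m)$bands[, , 1])
  }
  GS_hr <- matrix(0, dp[1] * dp[2], nb + 1L)
  for (k in 2:(nb + 1L)) GS_hr[, k] <- up(GS[, k])

  sim_pan_up <- up(sim_pan)
  p <- as.vector(pan$bands[, , 1])
  sd_p <- sd(p)
  gain <- if (sd_p > 0) sd(sim_pan_up) / sd_p else 1
  GS_hr[, 1] <- (p - mean(p)) * gain + mean(sim_pan_up) - mu[1]

  out <- array(0, c(dp[1], dp[2], nb))
  for (k in 2:(nb + 1L)) {
    v <- mu[k] + GS_hr[, k]
    for (j in seq_len(k - 1L)) v <- v + phi[k, j] * GS_hr[, j]
    if (clip) v <- pmin(ms$dn_range[2], pmax(ms$dn_range[1], v))
    out[, , k - 1L] <- v
  }
  mb_raster(out, cell_size_m = pan$cell_size_m, origin = pan$origin,
            band_names = ms$band_names, nodata = ms$nodata,
            dn_range = ms$dn_range)
}
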