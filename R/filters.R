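# Standalone background-field estimators: mask-aware Gaussian, first-order
# polynomial, solid-harmonic projection wrapper, and the dipole filter.

#' Mask-aware Gaussian background estimate
#'
#' Classic homodyne-style high-pass filtering: the background at each masked
#' voxel is the Gaussian-weighted mean of the field over the in-mask voxels
#' within the truncated kernel, with the weights renormalized over the mask so
#' that no signal leaks in from outside (normalized convolution). The residual
#' `field - background` enhances local, high-spatial-frequency variation, at
#' the cost of also suppressing genuine medium-scale contrast.
#'
#' @param field 3D numeric array (Hz).
#' @param mask Logical 3D array.
#' @param sigma Kernel standard deviation in voxels.
#' @param truncate Kernel cut-off in sigmas per axis (default 3; the kernel
#'   support is the cube of half-width `ceiling(truncate*sigma)` voxels).
#' @return List with `background` and `residual` 3D arrays (0 outside mask).
#' @export
gaussian_background <- function(field, mask, sigma, truncate = 3) {
  stopifnot(sigma > 0)
  mask <- check_mask(mask, field)
  R <- as.integer(ceiling(truncate * sigma))
  d <- dim(field)
  dp <- vapply(d + 2L * R, function(n) stats::nextn(n, c(2, 3, 5)), integer(1))
  off <- c(0L, 0L, 0L)  # corner placement; kernel indexed with wrap-around
  offs <- seq.int(-R, R)
  g1 <- exp(-offs^2 / (2 * sigma^2))
  kern <- lapply(dp, function(n) wrap_kernel_1d(g1, offs, n))
  Kf <- stats::fft(outer(outer(kern[[1]], kern[[2]]), kern[[3]]))
  m <- array(0, d); m[mask] <- 1
  conv <- function(x) Re(ifftn(stats::fft(pad_array(x, dp, off)) * Kf))
  num <- conv(field * m)
  den <- conv(m)
  bg <- array(0, d)
  sel <- which(mask)
  bgp <- crop_array(num, d, off)[sel] / crop_array(den, d, off)[sel]
  bg[sel] <- bgp
  res <- array(0, d)
  res[sel] <- field[sel] - bgp
  list(background = bg, residual = res)
}

#' First-order polynomial (plane) background fit
#'
#' Ordinary least-squares fit of `a + b*x + c*y + d*z` over the masked voxels,
#' in physical coordinates (mm) with origin at the mask center of mass. This
#' removes the constant frequency offset and linear shim-like gradients of the
#' main field; higher polynomial orders are deliberately not offered since they
#' do not correspond to a physical solution of the static field problem.
#'
#' @param field 3D numeric array (Hz).
#' @param mask Logical 3D array (must span at least 4 non-coplanar voxels).
#' @param grid A [voxel_grid()].
#' @return List with `coefficients` (intercept, x, y, z), `center` (origin of
#'   the fit frame), `background` and `residual` arrays.
#' @export
polf <- function(field, mask, grid) {
  mask <- check_mask(mask, field)
  idx <- which(mask, arr.ind = TRUE)
  center <- colMeans(index_coords(idx, grid))
  P <- index_coords(idx, grid, center)
  X <- cbind(1, P)
  colnames(X) <- c("intercept", "x", "y", "z")
  if (qr(X)$rank < 4L)
    stop("degenerate fit: masked voxels are coplanar, cannot fit a 3D plane")
  fit <- stats::lm.fit(X, field[mask])
  bg <- array(0, dim(field))
  bg[mask] <- fit$fitted.values
  res <- array(0, dim(field))
  res[mask] <- fit$residuals
  list(coefficients = stats::setNames(fit$coefficients,
                                      c("intercept", "x", "y", "z")),
       center = center, background = bg, residual = res)
}

#' Solid-harmonic background filter (orthonormalized-basis projection)
#'
#' Fits the masked field with solid spherical harmonics orthonormalized on the
#' mask and returns the fitted harmonic background. Captures smooth field
#' variation from any source outside the mask (which is harmonic inside it) up
#' to the given order; local, internally generated dipole fields are not
#' harmonic inside the mask and are largely retained.
#'
#' @param field 3D numeric array (Hz).
#' @param mask Logical 3D array.
#' @param grid A [voxel_grid()].
#' @param order Maximum harmonic order of the fit.
#' @param basis Optional precomputed [ssh_basis()] of order `>= order` on the
#'   same mask (reused across calls; building the basis dominates the cost).
#' @return List with `background`, `residual`, `coefficients`, and the
#'   `basis` used.
#' @export
sphinx_filter <- function(field, mask, grid, order, basis = NULL) {
  stopifnot(order >= 1)
  if (is.null(basis)) basis <- ssh_basis(mask, grid, order)
  pr <- ssh_project(field, basis, order = order)
  list(background = pr$background, residual = pr$residual,
       coefficients = pr$coefficients, basis = basis)
}

#' Spectral dipole kernel on a (padded) grid
#'
#' The unit magnetic dipole field `(3*cos^2(theta) - 1) / (4*pi*r^3)` has the
#' closed-form Fourier representation `D(k) = 1/3 - kz^2/|k|^2`, with `kz` the
#' frequency component along the main-field direction; `D(0)` is set to 0
#' (the mean field is not determined by susceptibility differences). Spatial
#' frequencies account for anisotropic voxel sizes.
#'
#' @param dim Integer triple: array dimensions of the (padded) volume.
#' @param grid A [voxel_grid()] supplying voxel size and field direction.
#' @return Object of class `dipole_kernel` with element `spectrum` (3D array,
#'   values in `[-2/3, 1/3]`).
#' @export
dipole_kernel <- function(dim, grid) {
  dim <- as.integer(dim)
  k <- lapply(1:3, function(a) fft_freq(dim[a]) / grid$voxel_size[a])
  b0 <- grid$b0_direction
  k2 <- outer(outer(k[[1]]^2, k[[2]]^2, `+`), k[[3]]^2, `+`)
  kb <- outer(outer(k[[1]] * b0[1], k[[2]] * b0[2], `+`), k[[3]] * b0[3], `+`)
  D <- 1 / 3 - kb^2 / k2
  D[k2 == 0] <- 0
  structure(list(dim = dim, spectrum = D, b0_direction = b0,
                 voxel_size = grid$voxel_size),
            class = "dipole_kernel")
}

#' Forward dipole field of a susceptibility distribution
#'
#' Convolves a susceptibility map (ppm) with the dipole kernel on a zero-padded
#' grid and converts to Hz at the grid's main field strength:
#' `b = hz_per_ppm(b_base) * IFFT(D * FFT(chi))`.
#'
#' @param chi 3D array of susceptibility in ppm.
#' @param grid A [voxel_grid()].
#' @param pad_fraction Zero padding per side as a fraction of each dimension
#'   (default 1/8).
#' @param kernel Optional precomputed [dipole_kernel()] matching the padded
#'   dimensions.
#' @return 3D array of field values in Hz, same dimensions as `chi`.
#' @export
forward_dipole_field <- function(chi, grid, pad_fraction = 1 / 8, kernel = NULL) {
  d <- dim(chi)
  dp <- d + 2L * as.integer(ceiling(d * pad_fraction))
  if (is.null(kernel)) kernel <- dipole_kernel(dp, grid)
  stopifnot(identical(kernel$dim, dp))
  bp <- Re(ifftn(kernel$spectrum * stats::fft(pad_array(chi, dp))))
  hz_per_ppm(grid$b_base) * crop_array(bp, d)
}

#' Dipole-filter configuration
#'
#' @param lambda Tikhonov regularization weight on the exterior
#'   pseudo-susceptibility (default 500). The objective is stated for fields
#'   in Hz and dimensionless susceptibility (ppm values / 1e6), where the
#'   dipole forward factor is `gamma/2pi * B_base` Hz; at that scale the
#'   default is a very mild penalty.
#' @param n_iter Number of conjugate-gradient iterations (default 50).
#' @param pad_fraction Zero padding per side as a fraction of the matrix size
#'   (default 1/8).
#' @param allow_pad_sources Allow pseudo-susceptibility in the zero-padded
#'   margin in addition to the measured-but-unmasked region (default TRUE).
#' @param interior `"hard"` (default) forces the pseudo-susceptibility to zero
#'   inside the mask by support restriction; `"penalty"` instead applies the
#'   Tikhonov weight only to in-mask values, leaving the support unrestricted.
#' @return Object of class `dipf_config`.
#' @export
dipf_config <- function(lambda = 500, n_iter = 50L, pad_fraction = 1 / 8,
                        allow_pad_sources = TRUE,
                        interior = c("hard", "penalty")) {
  stopifnot(lambda >= 0, n_iter >= 1, pad_fraction >= 0)
  structure(list(lambda = lambda, n_iter = as.integer(n_iter),
                 pad_fraction = pad_fraction,
                 allow_pad_sources = allow_pad_sources,
                 interior = match.arg(interior)),
            class = "dipf_config")
}

#' Dipole filter (projection onto dipole fields)
#'
#' Estimates an exterior pseudo-susceptibility `chi_ext` whose dipole-convolved
#' field best explains the measured field inside the mask,
#' `min ||m*(b - c*(chi_ext * d))||^2 + lambda*||chi_ext||^2`, and subtracts
#' that field. The minimization runs over dimensionless susceptibility with
#' `c = gamma/2pi * B_base` (the convention in which the default
#' `lambda = 500` is stated); the returned `chi_ext` is converted to ppm. The normal equations are solved by conjugate gradients with the
#' solution support restricted to voxels outside the mask (including the
#' zero-padded margin by default); the physics of the dipole convolution makes
#' this the background estimator of choice for fields from sources in and near
#' the measured volume.
#'
#' @param field 3D numeric array (Hz), finite inside the mask.
#' @param mask Logical 3D array: the fit domain (data term is evaluated here).
#' @param grid A [voxel_grid()].
#' @param config A [dipf_config()].
#' @param support Optional logical 3D array (original dimensions) giving the
#'   voxels allowed to carry pseudo-susceptibility; defaults to the complement
#'   of `mask`. Used by the local stage to restrict sources to excluded
#'   pockets inside the head.
#' @return Object of class `dipf_result`: `chi_ext` (ppm, original dims),
#'   `background`, `residual` (Hz, 0 outside mask), and `residual_history`
#'   (masked data-term L2 norm per iteration, including iteration 0).
#' @export
dipf <- function(field, mask, grid, config = dipf_config(), support = NULL) {
  mask <- check_mask(mask, field)
  if (any(!is.finite(field[mask]))) stop("non-finite field values inside mask")
  d <- dim(field)
  dp <- d + 2L * as.integer(ceiling(d * config$pad_fraction))
  off <- (dp - d) %/% 2L
  kern <- dipole_kernel(dp, grid)$spectrum
  cscale <- GAMMA_HZ_PER_T * grid$b_base  # Hz per unit (dimensionless) chi

  mp <- pad_array(array(as.numeric(mask), d), dp, off)
  if (is.null(support)) {
    sp <- 1 - mp
    if (!config$allow_pad_sources) {
      inside <- pad_array(array(1, d), dp, off)
      sp <- sp * inside
    }
  } else {
    stopifnot(identical(dim(support), d))
    sp <- pad_array(array(as.numeric(support), d), dp, off)
  }
  hard <- config$interior == "hard"
  if (!hard) sp <- array(1, dp)  # unrestricted support, penalty on mask
  wt2 <- if (hard) 1 else mp     # Tikhonov weight squared

  A <- function(x) mp * Re(ifftn(kern * stats::fft(x))) * cscale
  At <- function(y) sp * Re(ifftn(kern * stats::fft(mp * y))) * cscale
  bp <- pad_array(field, dp, off) * mp

  # CG on the normal equations (A'A + lambda*W'W) x = A'b, x supported on sp.
  rhs <- At(bp)
  x <- array(0, dp)
  Ax <- array(0, dp)
  r <- rhs
  p <- r
  rs <- sum(r^2)
  hist <- numeric(config$n_iter + 1L)
  hist[1] <- sqrt(sum(bp^2))
  for (i in seq_len(config$n_iter)) {
    Ap_f <- A(p)
    Np <- At(Ap_f) + config$lambda * (wt2 * p)
    alpha <- rs / sum(p * Np)
    if (!is.finite(alpha)) { hist <- hist[seq_len(i)]; break }
    x <- x + alpha * p
    Ax <- Ax + alpha * Ap_f
    r <- r - alpha * Np
    rs_new <- sum(r^2)
    hist[i + 1L] <- sqrt(sum((bp - Ax)^2))
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  if (hard) x <- sp * x

  bg_p <- Re(ifftn(kern * stats::fft(x))) * cscale
  bg <- array(0, d)
  sel <- which(mask)
  bgc <- crop_array(bg_p, d, off)
  bg[sel] <- bgc[sel]
  res <- array(0, d)
  res[sel] <- field[sel] - bg[sel]
  structure(list(chi_ext = crop_array(x, d, off) * 1e6, background = bg,
                 residual = res, residual_history = hist,
                 config = config),
            class = "dipf_result")
}

#' @export
print.dipf_result <- function(x, ...) {
  h <- x$residual_history
  cat(sprintf("<dipf_result> %d CG iterations, data residual %.4g -> %.4g Hz (L2)\n",
              length(h) - 1L, h[1], h[length(h)]))
  invisible(x)
}
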