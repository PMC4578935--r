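# Solid spherical harmonics and their orthonormalization on a masked domain.
#
# Background fields originate outside the volume of interest and therefore
# satisfy the Laplace equation inside it; regular solid harmonics r^l * Y_lm
# span exactly those fields. On an arbitrary masked domain the discrete
# harmonics lose their orthogonality, so they are re-orthonormalized by
# Gram-Schmidt with respect to the plain voxelwise inner product over the mask.

# (l, m) table in basis order: l ascending, m from -l to l.
lm_table <- function(order_max) {
  do.call(rbind, lapply(0:order_max, function(l)
    data.frame(l = l, m = seq(-l, l))))
}

# Real spherical harmonic factors for all m at fixed l, evaluated from
# associated Legendre functions (pracma::legendre, Condon-Shortley phase as in
# the MATLAB convention; the overall sign is immaterial because the basis is
# re-orthonormalized and only the projected background is used).
# Returns an n x (2l+1) matrix, columns m = -l..l.
real_ylm_block <- function(l, ct, phi) {
  n <- length(ct)
  if (l == 0L) return(matrix(sqrt(1 / (4 * pi)), n, 1))
  P <- pracma::legendre(l, ct)            # (l+1) x n, rows m = 0..l
  out <- matrix(0, n, 2 * l + 1)
  for (m in 0:l) {
    N <- sqrt((2 * l + 1) / (4 * pi) *
                exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
    if (m == 0L) {
      out[, l + 1] <- N * P[1, ]
    } else {
      base <- sqrt(2) * N * P[m + 1, ]
      out[, l + 1 + m] <- base * cos(m * phi)
      out[, l + 1 - m] <- base * sin(m * phi)
    }
  }
  out
}

# Evaluate all raw solid harmonics up to order_max at the given physical
# coordinates (n x 3, already centered); returns n x (order_max+1)^2 matrix.
solid_harmonic_matrix <- function(coords, order_max, radius_scale) {
  r <- sqrt(rowSums(coords^2))
  rn <- r / radius_scale
  ct <- ifelse(r > 0, coords[, 3] / r, 0)
  ct <- pmin(1, pmax(-1, ct))
  phi <- atan2(coords[, 2], coords[, 1])
  K <- (order_max + 1L)^2
  V <- matrix(0, nrow(coords), K)
  col <- 1L
  rl <- rep(1, length(r))
  for (l in 0:order_max) {
    if (l > 0) rl <- rl * rn
    Y <- real_ylm_block(l, ct, phi)
    V[, col:(col + 2L * l)] <- rl * Y
    col <- col + 2L * l + 1L
  }
  V
}

#' Real regular solid spherical harmonic on a voxel grid
#'
#' Evaluates `v_lm = N_lm * (r/radius_scale)^l * Y_lm(theta, phi)` (real
#' convention) at every voxel center, with coordinates relative to `center`.
#' These are harmonic polynomials: their Laplacian vanishes, which makes them
#' the natural model class for fields generated by sources outside the volume.
#'
#' @param l Order, `l >= 0`.
#' @param m Degree, `|m| <= l`.
#' @param grid A [voxel_grid()].
#' @param center Physical coordinates (mm) of the expansion center.
#' @param radius_scale Radius (mm) used to normalize `r`, keeping `r^l` well
#'   conditioned at high orders.
#' @return 3D numeric array.
#' @export
solid_harmonic <- function(l, m, grid, center = c(0, 0, 0), radius_scale = 1) {
  l <- as.integer(l); m <- as.integer(m)
  if (l < 0L || abs(m) > l) stop("need l >= 0 and |m| <= l")
  stopifnot(radius_scale > 0)
  ax <- grid_axes(grid, center)
  idx <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  V <- solid_harmonic_matrix(idx, l, radius_scale)
  array(V[, l^2 + l + m + 1L], grid$shape)
}

#' Orthonormalize a raw basis on a masked domain
#'
#' Gram-Schmidt orthonormalization of the raw basis vectors with respect to
#' the voxelwise inner product over the masked voxels, with one
#' re-orthogonalization pass for numerical stability on near-degenerate
#' domains. The first vector is simply normalized; each subsequent vector has
#' the projections onto all previously orthonormalized vectors subtracted and
#' is then normalized.
#'
#' @param raw_basis Either a list of 3D arrays or an `n_masked x K` matrix of
#'   masked-voxel values (columns are basis vectors).
#' @param mask Logical 3D array (required when `raw_basis` is a list of
#'   volumes; used to extract masked values).
#' @param lm Optional data frame with columns `l`, `m` naming each column,
#'   used in degenerate-basis error messages.
#' @return Matrix of orthonormal columns with attribute `gram_residual`, the
#'   maximum deviation of the Gram matrix from identity.
#' @export
orthonormalize <- function(raw_basis, mask = NULL, lm = NULL) {
  if (is.list(raw_basis)) {
    mask <- check_mask(mask, raw_basis[[1]])
    U <- vapply(raw_basis, function(v) v[mask], numeric(sum(mask)))
  } else {
    U <- as.matrix(raw_basis)
  }
  K <- ncol(U)
  for (j in seq_len(K)) {
    nrm0 <- sqrt(sum(U[, j]^2))
    if (j > 1L) {
      prev <- U[, seq_len(j - 1L), drop = FALSE]
      for (pass in 1:2)
        U[, j] <- U[, j] - prev %*% crossprod(prev, U[, j])
    }
    nrm <- sqrt(sum(U[, j]^2))
    if (nrm < 1e-10 * nrm0 || nrm0 == 0) {
      lab <- if (!is.null(lm)) sprintf(" (l = %d, m = %d)", lm$l[j], lm$m[j])
             else sprintf(" (column %d)", j)
      stop("degenerate basis: vector", lab,
           " lies in the span of earlier vectors on this mask")
    }
    U[, j] <- U[, j] / nrm
  }
  G <- crossprod(U)
  attr(U, "gram_residual") <- max(abs(G - diag(K)))
  U
}

#' Build an orthonormalized solid-harmonic basis on a mask
#'
#' Evaluates all real solid harmonics up to `order_max` at the masked voxels
#' and orthonormalizes them there. By default the expansion center is the mask
#' center of mass and the radius scale is the largest masked-voxel distance
#' from it, so that the normalized radius stays in `[0, 1]`.
#'
#' @param mask Logical 3D array.
#' @param grid A [voxel_grid()].
#' @param order_max Maximum harmonic order (capped at 15).
#' @param center,radius_scale Optional overrides of the expansion geometry.
#' @return Object of class `ssh_basis`: masked orthonormal vectors, the `(l,m)`
#'   table, mask indices, geometry, and the achieved `gram_residual`.
#' @export
ssh_basis <- function(mask, grid, order_max, center = NULL, radius_scale = NULL) {
  order_max <- as.integer(order_max)
  if (order_max < 0L || order_max > 15L)
    stop("order_max must be in 0..15")
  mask <- check_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (is.null(center)) center <- colMeans(index_coords(idx, grid))
  coords <- index_coords(idx, grid, center)
  if (is.null(radius_scale)) radius_scale <- max(sqrt(rowSums(coords^2)))
  if (radius_scale <= 0) radius_scale <- 1
  V <- solid_harmonic_matrix(coords, order_max, radius_scale)
  lm <- lm_table(order_max)
  U <- orthonormalize(V, lm = lm)
  structure(list(order_max = order_max, center = center,
                 radius_scale = radius_scale,
                 mask_idx = which(mask), dim = dim(mask),
                 vectors = U, lm = lm,
                 gram_residual = attr(U, "gram_residual")),
            class = "ssh_basis")
}

#' @export
print.ssh_basis <- function(x, ...) {
  cat(sprintf("<ssh_basis> order %d (%d vectors) on %d voxels, gram residual %.2e\n",
              x$order_max, ncol(x$vectors), length(x$mask_idx), x$gram_residual))
  invisible(x)
}

#' Project a field onto an orthonormalized solid-harmonic basis
#'
#' Computes the expansion coefficients `c_lm = <b | u_lm>` over the masked
#' voxels and the background field they reconstruct. Outside the mask the
#' background is 0.
#'
#' @param field 3D numeric array (Hz).
#' @param basis An [ssh_basis()].
#' @param order Optional order cutoff `<= basis$order_max`; uses the leading
#'   columns of the basis (the nesting is exact because orthonormalization
#'   proceeds in basis order).
#' @return List with `coefficients` (data frame `l`, `m`, `value`),
#'   `background` and `residual` (3D arrays).
#' @export
ssh_project <- function(field, basis, order = NULL) {
  stopifnot(inherits(basis, "ssh_basis"))
  if (!identical(dim(field), basis$dim))
    stop("field shape does not match basis mask shape")
  keep <- seq_len(ncol(basis$vectors))
  if (!is.null(order)) {
    if (order > basis$order_max) stop("order exceeds basis order_max")
    keep <- which(basis$lm$l <= order)
  }
  Vb <- basis$vectors[, keep, drop = FALSE]
  b <- field[basis$mask_idx]
  cf <- drop(crossprod(Vb, b))
  bg <- array(0, basis$dim)
  bg[basis$mask_idx] <- Vb %*% cf
  res <- array(0, basis$dim)
  res[basis$mask_idx] <- b - bg[basis$mask_idx]
  list(coefficients = cbind(basis$lm[keep, ], value = cf),
       background = bg, residual = res)
}
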