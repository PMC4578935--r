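#' @keywords internal
"_PACKAGE"

#' Proton gyromagnetic ratio over 2*pi, in Hz per tesla
#'
#' Conversion constant between field strength and precession frequency,
#' gamma/2pi = 42.577478518 MHz/T.
#' @export
GAMMA_HZ_PER_T <- 42.577478518e6

#' Field shift per ppm of susceptibility at a given main field
#'
#' A susceptibility offset of `chi` ppm in a main field of `b_base` tesla
#' shifts the Larmor frequency by `chi * hz_per_ppm(b_base)` Hz (before
#' geometry factors from the dipole kernel).
#'
#' @param b_base Main field strength in tesla.
#' @return Hz per ppm (scalar).
#' @export
hz_per_ppm <- function(b_base) GAMMA_HZ_PER_T * b_base * 1e-6

#' Voxel-grid geometry for field-map volumes
#'
#' Bundles the array shape, voxel size, main-field direction and strength
#' shared by all volumes in a processing run. The main field is along +z by
#' default.
#'
#' @param shape Integer triple `(nx, ny, nz)`.
#' @param voxel_size Voxel edge lengths in mm, length-3.
#' @param b0_direction Unit vector of the main-field direction.
#' @param b_base Main field strength in tesla (default 9.4).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, voxel_size = c(1, 1, 1),
                       b0_direction = c(0, 0, 1), b_base = 9.4) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  b0_direction <- as.numeric(b0_direction)
  stopifnot(length(b0_direction) == 3L)
  nrm <- sqrt(sum(b0_direction^2))
  if (abs(nrm - 1) > 1e-12) {
    if (nrm == 0) stop("b0_direction must be a non-zero vector")
    b0_direction <- b0_direction / nrm
  }
  structure(list(shape = shape, voxel_size = voxel_size,
                 b0_direction = b0_direction, b_base = b_base),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d, voxel %.3g x %.3g x %.3g mm, B = %.3g T along (%.2g, %.2g, %.2g)\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$b_base, x$b0_direction[1], x$b0_direction[2], x$b0_direction[3]))
  invisible(x)
}

# Physical coordinates (mm) of all voxels, 0-based index * voxel size,
# optionally shifted so that `center` maps to the origin.
grid_axes <- function(grid, center = c(0, 0, 0)) {
  lapply(1:3, function(a) {
    (seq_len(grid$shape[a]) - 1) * grid$voxel_size[a] - center[a]
  })
}

# n x 3 matrix of physical coordinates for the given voxel index matrix
# (as from which(..., arr.ind = TRUE)).
index_coords <- function(idx, grid, center = c(0, 0, 0)) {
  sweep(sweep(idx - 1, 2, grid$voxel_size, `*`), 2, center, `-`)
}

#' Center of mass of a mask, in physical coordinates (mm)
#'
#' @param mask Logical 3D array.
#' @param grid A [voxel_grid()].
#' @return Length-3 numeric vector.
#' @export
mask_center <- function(mask, grid) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  colMeans(index_coords(idx, grid))
}

check_mask <- function(mask, field = NULL) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (!any(mask)) stop("mask is empty (no TRUE voxel)")
  if (!is.null(field) && !identical(dim(field), dim(mask)))
    stop("field and mask shapes differ: ",
         paste(dim(field), collapse = "x"), " vs ",
         paste(dim(mask), collapse = "x"))
  mask
}
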