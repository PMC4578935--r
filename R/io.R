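# NIfTI input/output for field maps, masks and basis caches.

#' Read a 3D volume (and grid) from a NIfTI file
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param b_base,b0_direction Main-field parameters to attach to the grid
#'   (not stored in NIfTI headers).
#' @return List with `volume` (numeric array) and `grid` ([voxel_grid()] from
#'   the header pixel dimensions).
#' @export
read_field_nifti <- function(path, b_base = 9.4, b0_direction = c(0, 0, 1)) {
  img <- RNifti::readNifti(path)
  vol <- array(as.numeric(img), dim(img)[1:3])
  vs <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(vs)) || any(vs <= 0)) vs <- c(1, 1, 1)
  list(volume = vol,
       grid = voxel_grid(dim(vol), vs, b0_direction, b_base))
}

#' Read a binary mask from a NIfTI file
#'
#' Nonzero voxels are TRUE.
#' @param path NIfTI file.
#' @return Logical 3D array.
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) != 0, dim(img)[1:3])
}

#' Write a field volume to NIfTI
#'
#' @param volume 3D numeric array.
#' @param grid A [voxel_grid()] (supplies pixel dimensions).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_field_nifti <- function(volume, grid, path) {
  img <- RNifti::asNifti(volume,
                         reference = list(pixdim = c(-1, grid$voxel_size,
                                                     1, 1, 1, 1)),
                         datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a binary mask to NIfTI (uint8, values 0/1)
#'
#' @param mask Logical 3D array.
#' @param grid A [voxel_grid()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask_nifti <- function(mask, grid, path) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)),
                         reference = list(pixdim = c(-1, grid$voxel_size,
                                                     1, 1, 1, 1)),
                         datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Save an orthonormalized harmonic basis to a NIfTI + JSON cache
#'
#' The basis vectors are stored as one 4D NIfTI volume (0 outside the mask)
#' plus a JSON sidecar with the geometry and the achieved Gram residual.
#'
#' @param basis An [ssh_basis()].
#' @param grid A [voxel_grid()].
#' @param path Output NIfTI path; the sidecar is `path` with a `.json`
#'   extension appended.
#' @return Invisibly, the paths written.
#' @export
save_ssh_basis <- function(basis, grid, path) {
  K <- ncol(basis$vectors)
  vol4 <- array(0, c(basis$dim, K))
  step <- prod(basis$dim)
  for (k in seq_len(K))
    vol4[basis$mask_idx + (k - 1L) * step] <- basis$vectors[, k]
  img <- RNifti::asNifti(vol4, datatype = "double")
  RNifti::writeNifti(img, path)
  meta <- list(order_max = basis$order_max, center = basis$center,
               radius_scale = basis$radius_scale,
               gram_residual = basis$gram_residual,
               dim = basis$dim)
  jpath <- paste0(path, ".json")
  jsonlite::write_json(meta, jpath, auto_unbox = TRUE, digits = NA)
  invisible(c(nifti = jpath, json = jpath))
}

#' Load a harmonic basis saved by [save_ssh_basis()]
#'
#' @param path NIfTI path given to [save_ssh_basis()].
#' @return An [ssh_basis()] object.
#' @export
load_ssh_basis <- function(path) {
  vol4 <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- dim(vol4)[1:3]
  K <- dim(vol4)[4]
  mask_idx <- which(apply(vol4 != 0, c(1, 2, 3), any))
  step <- prod(d)
  U <- vapply(seq_len(K), function(k) vol4[mask_idx + (k - 1L) * step],
              numeric(length(mask_idx)))
  order_max <- as.integer(meta$order_max)
  structure(list(order_max = order_max, center = meta$center,
                 radius_scale = meta$radius_scale, mask_idx = mask_idx,
                 dim = as.integer(d), vectors = U, lm = lm_table(order_max),
                 gram_residual = meta$gram_residual),
            class = "ssh_basis")
}
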