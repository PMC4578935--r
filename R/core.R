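#' Field map (Hz) from unwrapped multi-echo phase
#'
#' Converts unwrapped gradient-echo phase volumes into an off-resonance field
#' map. The phase accumulates as `phi = 2*pi * b * TE`, so with several echoes
#' the per-voxel field is the ordinary least-squares slope of phase versus echo
#' time divided by `2*pi`; with a single echo it is `phi / (2*pi*TE)`. Any
#' constant phase offset shared by all echoes (receiver phase) drops out of the
#' regression.
#'
#' @param phases 4D array `(nx, ny, nz, n_echo)` of unwrapped phase in radians,
#'   or a 3D array for a single echo.
#' @param echo_times Echo times in seconds, strictly increasing, length equal
#'   to the number of echoes.
#' @param mask Logical 3D array; voxels outside are set to 0 in the output.
#' @return 3D array of field values in Hz.
#' @export
field_from_phase <- function(phases, echo_times, mask) {
  echo_times <- as.numeric(echo_times)
  ne <- length(echo_times)
  if (ne < 1L) stop("need at least one echo")
  if (ne > 1L && any(diff(echo_times) <= 0))
    stop("echo times must be strictly increasing")
  if (length(dim(phases)) == 3L) phases <- array(phases, c(dim(phases), 1L))
  if (dim(phases)[4] != ne)
    stop("number of phase volumes (", dim(phases)[4],
         ") does not match number of echo times (", ne, ")")
  d <- dim(phases)[1:3]
  mask <- check_mask(mask, array(0, d))
  if (ne == 1L) {
    b <- phases[, , , 1] / (2 * pi * echo_times)
  } else {
    tc <- echo_times - mean(echo_times)
    denom <- sum(tc^2)
    b <- array(0, d)
    for (e in seq_len(ne)) b <- b + phases[, , , e] * tc[e]
    b <- b / (denom * 2 * pi)
  }
  b[!mask] <- 0
  if (any(!is.finite(b[mask]))) stop("non-finite field values inside mask")
  b
}

#' Masked summary statistics of a field map
#'
#' Mean, standard deviation and histogram of the field restricted to the mask.
#' The standard deviation uses the population definition (divisor n), the
#' convention used throughout the filter-comparison statistics. Histogram bins
#' are fixed-width in Hz over the masked value range.
#'
#' @param field 3D numeric array (Hz).
#' @param mask Logical 3D array of the same shape.
#' @param n_bins Number of histogram bins (default 100).
#' @return A list of class `field_summary` with elements `mean`, `std`,
#'   `n_voxels`, and `histogram` (data frame `bin_left`, `bin_right`, `count`).
#' @export
masked_summary <- function(field, mask, n_bins = 100L) {
  mask <- check_mask(mask, field)
  v <- field[mask]
  n_bins <- max(1L, as.integer(n_bins))
  if (diff(range(v)) == 0) {
    edges <- v[1] + seq(-0.5, 0.5, length.out = n_bins + 1L)
  } else {
    edges <- seq(min(v), max(v), length.out = n_bins + 1L)
  }
  h <- graphics::hist(v, breaks = edges, plot = FALSE, include.lowest = TRUE)
  structure(list(mean = mean(v), std = sd_pop(v), n_voxels = length(v),
                 histogram = data.frame(bin_left = edges[-length(edges)],
                                        bin_right = edges[-1],
                                        count = h$counts)),
            class = "field_summary")
}

#' @export
print.field_summary <- function(x, ...) {
  cat(sprintf("<field_summary> n = %d voxels, mean = %.4g Hz, sd = %.4g Hz, %d bins\n",
              x$n_voxels, x$mean, x$std, nrow(x$histogram)))
  invisible(x)
}

#' Write a field summary to CSV (+ JSON header)
#'
#' The histogram goes to `csv_path` with columns `bin_left`, `bin_right`,
#' `count`; mean/std/n go to `json_path` (defaults to the CSV path with a
#' `.json` extension).
#'
#' @param summary A [masked_summary()] result.
#' @param csv_path Output CSV path.
#' @param json_path Output JSON path.
#' @return Invisibly, the paths written.
#' @export
write_summary <- function(summary, csv_path,
                          json_path = sub("\\.csv$", ".json", csv_path)) {
  utils::write.csv(summary$histogram, csv_path, row.names = FALSE)
  jsonlite::write_json(list(mean = summary$mean, std = summary$std,
                            n_voxels = summary$n_voxels),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}
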