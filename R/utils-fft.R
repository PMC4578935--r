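# FFT helpers shared by the Gaussian filter, the dipole forward model and the
# simulator. All convolutions are circular on a zero-padded grid.

ifftn <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Unnormalized DFT sample frequencies (cycles per sample), numpy-style order.
fft_freq <- function(n) {
  half <- floor((n - 1) / 2)
  c(0:half, seq.int(half - n + 1, -1)) / n
}

# Embed `x` into a zero array of dims `dim_to`, corner placement at `offset`
# (0-based). Default centers the original volume in the padded one.
pad_array <- function(x, dim_to, offset = NULL) {
  d <- dim(x)
  dim_to <- as.integer(dim_to)
  stopifnot(all(dim_to >= d))
  if (is.null(offset)) offset <- (dim_to - d) %/% 2L
  out <- array(0, dim_to)
  out[offset[1] + seq_len(d[1]),
      offset[2] + seq_len(d[2]),
      offset[3] + seq_len(d[3])] <- x
  out
}

crop_array <- function(x, dim_to, offset = NULL) {
  d <- dim(x)
  dim_to <- as.integer(dim_to)
  if (is.null(offset)) offset <- (d - dim_to) %/% 2L
  x[offset[1] + seq_len(dim_to[1]),
    offset[2] + seq_len(dim_to[2]),
    offset[3] + seq_len(dim_to[3]), drop = FALSE]
}

# 1D kernel placed with wrap-around so the kernel center sits at index 1.
wrap_kernel_1d <- function(values, offsets, n) {
  stopifnot(n >= length(values))
  v <- numeric(n)
  v[(offsets %% n) + 1] <- values
  v
}

# Shift a 3D array by integer vector `by` (zero fill). out[i] = x[i - by].
shift_array <- function(x, by, fill = FALSE) {
  d <- dim(x)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    b <- by[a]
    if (abs(b) >= d[a]) return(out)
    if (b >= 0) { src[[a]] <- seq_len(d[a] - b); dst[[a]] <- src[[a]] + b }
    else        { src[[a]] <- seq_len(d[a] + b) - b; dst[[a]] <- seq_len(d[a] + b) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

# Smooth zero-mean unit-std Gaussian random field via spectral low-pass of
# white noise; `corr_sigma` is the smoothing sigma in voxels.
smooth_random_field <- function(dim, corr_sigma) {
  w <- array(stats::rnorm(prod(dim)), dim)
  g <- lapply(dim, function(n) exp(-2 * (pi * fft_freq(n) * corr_sigma)^2))
  G <- outer(outer(g[[1]], g[[2]]), g[[3]])
  f <- Re(ifftn(stats::fft(w) * G))
  f <- f - mean(f)
  f / stats::sd(f)
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
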