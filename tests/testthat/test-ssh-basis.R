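laplacian7 <- function(v) {
  d <- dim(v)
  i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
  v[i + 1, j, k] + v[i - 1, j, k] + v[i, j + 1, k] + v[i, j - 1, k] +
    v[i, j, k + 1] + v[i, j, k - 1] - 6 * v[i, j, k]
}

test_that("low-order solid harmonics reduce to the known polynomials", {
  g <- voxel_grid(c(12, 12, 12))
  ctr <- c(5.5, 5.5, 5.5)
  v00 <- solid_harmonic(0, 0, g, ctr, 6)
  expect_equal(max(v00) - min(v00), 0)
  v10 <- solid_harmonic(1, 0, g, ctr, 6)
  co <- coord_arrays(c(12, 12, 12))
  expect_equal(cor(as.vector(v10), as.vector(co$z)), 1, tolerance = 1e-12)
  expect_error(solid_harmonic(2, 3, g, ctr, 6), "\\|m\\|")
})

test_that("solid harmonics are discretely harmonic in the interior", {
  g <- voxel_grid(c(16, 16, 16))
  ctr <- c(7.5, 7.5, 7.5)
  # the 7-point stencil is exact only to O(voxel^2): degree-4 harmonics
  # carry a genuine discretization term of that order
  for (l in 2:4) for (m in c(-l, 0, l - 1)) {
    v <- solid_harmonic(l, m, g, ctr, 8)
    tol <- if (l < 4) 1e-10 else 1e-3
    expect_lt(max(abs(laplacian7(v))), tol * max(abs(v)))
  }
})

test_that("orthonormalized basis satisfies the Gram identity on varied masks", {
  d <- c(18, 18, 18)
  g <- voxel_grid(d)
  masks <- list(sphere = sphere_mask(d, 7),
                ellipsoid = ellipsoid_mask(d, c(8, 6, 5)),
                holed = holed_mask(d, 7))
  for (nm in names(masks)) {
    B <- ssh_basis(masks[[nm]], g, 6)
    G <- crossprod(B$vectors)
    expect_lt(max(abs(G - diag(ncol(B$vectors)))), 1e-8)
    expect_equal(ncol(B$vectors), 49L)
    expect_lt(B$gram_residual, 1e-8)
  }
})

test_that("orthonormalization is idempotent up to sign", {
  d <- c(14, 14, 14)
  g <- voxel_grid(d)
  mask <- sphere_mask(d, 5)
  B <- ssh_basis(mask, g, 3)
  U2 <- orthonormalize(B$vectors)
  expect_lt(attr(U2, "gram_residual"), 1e-12)
  sgn <- sign(colSums(U2 * B$vectors))
  expect_equal(sweep(U2, 2, sgn, `*`), B$vectors,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("raw harmonics approach orthogonality on a finely sampled sphere", {
  # continuous solid harmonics are orthogonal over a ball; the raw discrete
  # Gram matrix should approach diagonal as sampling refines
  offdiag_level <- function(n) {
    d <- rep(n, 3)
    g <- voxel_grid(d, voxel_size = rep(16 / n, 3))
    mask <- array(TRUE, d)
    idx <- which(mask, arr.ind = TRUE)
    ctr <- colMeans(sweep(idx - 1, 2, g$voxel_size, `*`))
    co <- sweep(sweep(idx - 1, 2, g$voxel_size, `*`), 2, ctr)
    r <- sqrt(rowSums(co^2))
    sel <- r <= 7.5
    V <- mubafire:::solid_harmonic_matrix(co[sel, ], 3, 7.5)
    G <- crossprod(V)
    Gn <- G / sqrt(outer(diag(G), diag(G)))
    max(abs(Gn - diag(ncol(V))))
  }
  expect_lt(offdiag_level(48), offdiag_level(16))
  expect_lt(offdiag_level(48), 0.05)
})

test_that("projection is exact, linear and idempotent", {
  d <- c(16, 16, 16)
  g <- voxel_grid(d)
  mask <- ellipsoid_mask(d, c(7, 6, 5))
  B <- ssh_basis(mask, g, 4)

  # exact member of the basis
  f <- array(0, d)
  f[B$mask_idx] <- 3 * B$vectors[, 8]
  pr <- ssh_project(f, B)
  expect_equal(pr$coefficients$value[8], 3, tolerance = 1e-10)
  expect_lt(max(abs(pr$coefficients$value[-8])), 1e-10)
  expect_lt(max(abs(pr$residual)), 1e-10)

  # zero field
  expect_true(all(ssh_project(array(0, d), B)$coefficients$value == 0))

  # idempotence: projecting the background reproduces the coefficients
  set.seed(31)
  f2 <- array(rnorm(prod(d)), d)
  p1 <- ssh_project(f2, B)
  p2 <- ssh_project(p1$background, B)
  expect_equal(p2$coefficients$value, p1$coefficients$value,
               tolerance = 1e-10)
  # residual orthogonal to every basis vector
  ip <- crossprod(B$vectors, p1$residual[B$mask_idx])
  expect_lt(max(abs(ip)), 1e-8 * sqrt(sum(p1$residual^2)))
})

test_that("projection onto a spanning basis leaves only the noise", {
  set.seed(32)
  d <- c(20, 20, 20)
  g <- voxel_grid(d)
  mask <- sphere_mask(d, 8)
  B <- ssh_basis(mask, g, 4)
  # random harmonic combination within the model class + noise
  idx <- which(mask, arr.ind = TRUE)
  co <- com_coords(mask, g)
  V <- mubafire:::solid_harmonic_matrix(co, 4, max(sqrt(rowSums(co^2))))
  f <- array(0, d)
  f[mask] <- V %*% runif(ncol(V), -5, 5) + rnorm(nrow(V), sd = 0.3)
  pr <- ssh_project(f, B)
  expect_lt(sd_pop_t(pr$residual[mask]), 2 * 0.3)
  # cross-check against a direct least-squares oracle
  fit <- lm.fit(V, f[mask])
  expect_equal(sd_pop_t(pr$residual[mask]), sd_pop_t(fit$residuals),
               tolerance = 1e-6)
})

test_that("degenerate raw bases are rejected with the offending label", {
  d <- c(10, 10, 10)
  mask <- sphere_mask(d, 4)
  n <- sum(mask)
  set.seed(33)
  v1 <- rnorm(n)
  raw <- cbind(v1, 2 * v1)
  expect_error(orthonormalize(raw, lm = data.frame(l = c(0, 1), m = c(0, -1))),
               "l = 1, m = -1")
})

test_that("basis caches survive a NIfTI round trip", {
  d <- c(12, 12, 12)
  g <- voxel_grid(d)
  mask <- sphere_mask(d, 5)
  B <- ssh_basis(mask, g, 2)
  path <- tempfile(fileext = ".nii.gz")
  save_ssh_basis(B, g, path)
  B2 <- load_ssh_basis(path)
  expect_equal(B2$order_max, B$order_max)
  expect_equal(B2$mask_idx, B$mask_idx)
  expect_equal(B2$vectors, B$vectors, tolerance = 1e-8, ignore_attr = TRUE)
})
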