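# The multistage chain: plane fit, harmonic projection, dipole filter, and the
# optional local outlier-exclusion stage.

#' Multistage chain configuration
#'
#' @param sphinx_order Harmonic order of the in-chain solid-harmonic stage
#'   (default 4; the standalone filter typically uses order 10).
#' @param dipf A [dipf_config()] for the in-chain dipole filter.
#' @param local_enabled Run the local outlier stage after the chain
#'   (default FALSE).
#' @param n_sigma Threshold multiplier for the local stage: voxels with
#'   `|field| > n_sigma * sd(field)` are excluded (default 8; typical range
#'   5 to 15).
#' @param local_dipf A [dipf_config()] for the local-stage dipole filter.
#' @return Object of class `chain_config`.
#' @export
chain_config <- function(sphinx_order = 4L, dipf = dipf_config(),
                         local_enabled = FALSE, n_sigma = 8,
                         local_dipf = dipf_config()) {
  stopifnot(sphinx_order >= 1, n_sigma > 0)
  structure(list(sphinx_order = as.integer(sphinx_order), dipf = dipf,
                 local_enabled = local_enabled, n_sigma = n_sigma,
                 local_dipf = local_dipf),
            class = "chain_config")
}

#' Run the multistage background-removal chain
#'
#' Applies, in sequence: a first-order polynomial fit (constant offset and
#' linear gradients), solid-harmonic projection on the residual (smooth
#' harmonic background of any exterior origin), and the dipole filter on that
#' residual (remaining dipole fields of nearby exterior sources). Each stage
#' removes the component the next one would struggle with. If
#' `config$local_enabled`, the local outlier stage ([run_local()]) follows.
#'
#' @param field 3D numeric array (Hz).
#' @param mask Logical 3D array.
#' @param grid A [voxel_grid()].
#' @param config A [chain_config()].
#' @param basis Optional precomputed [ssh_basis()] (order `>= sphinx_order`)
#'   on `mask`, reused to avoid rebuilding.
#' @param verbose Print per-stage masked standard deviations.
#' @return Object of class `chain_result` with `corrected`,
#'   `stage_backgrounds` (named list: polf, sphinx, dipf, and local if run),
#'   `excluded_mask`, `refined_mask`, `sigma_log` (masked sd after each
#'   stage), and `config`.
#' @export
run_chain <- function(field, mask, grid, config = chain_config(),
                      basis = NULL, verbose = FALSE) {
  mask <- check_mask(mask, field)
  sel <- which(mask)
  sigma_log <- c(input = sd_pop(field[sel]))

  st1 <- polf(field, mask, grid)
  r1 <- st1$residual
  sigma_log["polf"] <- sd_pop(r1[sel])

  st2 <- sphinx_filter(r1, mask, grid, config$sphinx_order, basis = basis)
  r2 <- st2$residual
  sigma_log["sphinx"] <- sd_pop(r2[sel])

  st3 <- dipf(r2, mask, grid, config$dipf)
  r3 <- st3$residual
  sigma_log["dipf"] <- sd_pop(r3[sel])

  backgrounds <- list(polf = st1$background, sphinx = st2$background,
                      dipf = st3$background)
  excluded <- array(FALSE, dim(mask))
  refined <- mask
  corrected <- r3

  if (isTRUE(config$local_enabled)) {
    loc <- run_local(r3, mask, grid, config)
    backgrounds$local <- loc$background
    excluded <- loc$excluded_mask
    refined <- loc$refined_mask
    corrected <- loc$corrected
    sigma_log["local"] <- sd_pop(corrected[refined])
  }

  if (verbose) {
    for (nm in names(sigma_log))
      message(sprintf("  stage %-7s masked sd = %.4g Hz", nm, sigma_log[nm]))
  }
  structure(list(corrected = corrected, stage_backgrounds = backgrounds,
                 excluded_mask = excluded, refined_mask = refined,
                 sigma_log = sigma_log, config = config),
            class = "chain_result")
}

#' @export
print.chain_result <- function(x, ...) {
  cat("<chain_result> stages:", paste(names(x$stage_backgrounds), collapse = " -> "), "\n")
  cat("  masked sd (Hz):",
      paste(sprintf("%s %.3g", names(x$sigma_log), x$sigma_log), collapse = ", "), "\n")
  cat(sprintf("  excluded voxels: %d\n", sum(x$excluded_mask)))
  invisible(x)
}

#' Threshold a corrected field map for outlier voxels
#'
#' Flags masked voxels whose magnitude exceeds `xi = n_sigma * sd`, where `sd`
#' is the (population) standard deviation of the field inside the mask. Such
#' voxels typically carry erroneous field values (intra-voxel gradients near
#' air bubbles, unwrapping failures) rather than representative data.
#'
#' @param field 3D numeric array (Hz), typically already chain-corrected.
#' @param mask Logical 3D array.
#' @param n_sigma Threshold multiplier.
#' @return List with `bad` (logical array of flagged voxels) and `xi` (Hz).
#' @export
threshold_mask <- function(field, mask, n_sigma = 8) {
  mask <- check_mask(mask, field)
  xi <- n_sigma * sd_pop(field[mask])
  bad <- mask & (abs(field) > xi)
  list(bad = bad, xi = xi)
}

#' Connect diagonal neighbors and apply six-neighbor erosion margin
#'
#' Two-step refinement of an exclusion mask. Step 1 joins diagonally adjacent
#' flagged voxels into face-connected groups: for every pair of flagged voxels
#' differing by one step in exactly two axes (e.g. `[i,j,k]` and
#' `[i+1,j+1,k]`), the two face-bridging voxels (`[i+1,j,k]` and `[i,j+1,k]`)
#' are added; for three-axis diagonals the three single-axis bridges are
#' added. Step 2 adds every in-mask face neighbor (6-connectivity) of the
#' step-1 set, so that direct neighbors of flagged voxels — which potentially
#' contain disturbed field gradients — are excluded as well.
#'
#' @param bad Logical 3D array of flagged voxels (subset of `mask`).
#' @param mask Logical 3D array.
#' @return Logical 3D array: the refined exclusion set (subset of `mask`).
#' @export
connect_and_erode <- function(bad, mask) {
  stopifnot(identical(dim(bad), dim(mask)))
  if (any(bad & !mask)) stop("bad voxels must lie inside the mask")
  if (!any(bad)) return(array(FALSE, dim(mask)))
  ax <- diag(3)
  bridges <- array(FALSE, dim(bad))
  add_pairs <- function(dvec, bridge_dirs) {
    # voxels u with bad[u] & bad[u + dvec]; add u + each bridge dir
    pair_at <- bad & shift_array(bad, -dvec)
    if (!any(pair_at)) return()
    for (bd in bridge_dirs)
      bridges <<- bridges | shift_array(pair_at, bd)
  }
  signs <- c(1, -1)
  for (a in 1:2) for (b in (a + 1):3) if (b <= 3)
    for (s1 in signs) for (s2 in signs) {
      d <- s1 * ax[a, ] + s2 * ax[b, ]
      add_pairs(d, list(s1 * ax[a, ], s2 * ax[b, ]))
    }
  for (s1 in signs) for (s2 in signs) for (s3 in signs) {
    d <- c(s1, s2, s3)
    add_pairs(d, list(c(s1, 0, 0), c(0, s2, 0), c(0, 0, s3)))
  }
  step1 <- (bad | bridges)
  dil <- step1
  for (a in 1:3) for (s in signs)
    dil <- dil | shift_array(step1, s * ax[a, ])
  (step1 | dil) & mask
}

#' Local outlier-exclusion stage
#'
#' Operates on a chain-corrected field map: thresholds outlier voxels
#' ([threshold_mask()]), refines the exclusion set ([connect_and_erode()]),
#' then runs the dipole filter with the pseudo-susceptibility support
#' restricted to the excluded voxels and the fit domain restricted to the
#' remaining mask — so the spurious dipole-like field radiating from e.g. an
#' air bubble into the surrounding tissue is estimated and subtracted.
#' Excluded voxels are reported as missing (removed from the refined mask),
#' not inpainted, since they do not contain representative data.
#'
#' @param field 3D numeric array (Hz), already corrected by the earlier
#'   stages.
#' @param mask Logical 3D array (original fit mask).
#' @param grid A [voxel_grid()].
#' @param config A [chain_config()] (uses `n_sigma` and `local_dipf`).
#' @return List with `corrected` (on the refined mask), `background`,
#'   `excluded_mask`, `refined_mask`, `xi`, and `chi_local` (ppm, support on
#'   the exclusion set); `NULL` background if nothing was excluded.
#' @export
run_local <- function(field, mask, grid, config = chain_config()) {
  mask <- check_mask(mask, field)
  th <- threshold_mask(field, mask, config$n_sigma)
  if (!any(th$bad)) {
    return(list(corrected = field, background = array(0, dim(field)),
                excluded_mask = array(FALSE, dim(field)),
                refined_mask = mask, xi = th$xi, chi_local = NULL))
  }
  excl <- connect_and_erode(th$bad, mask)
  refined <- mask & !excl
  if (!any(refined))
    stop("degenerate input: exclusion set covers the entire mask")
  fit <- dipf(field, refined, grid, config$local_dipf, support = excl)
  corrected <- array(0, dim(field))
  corrected[refined] <- field[refined] - fit$background[refined]
  list(corrected = corrected, background = fit$background,
       excluded_mask = excl, refined_mask = refined, xi = th$xi,
       chi_local = fit$chi_ext)
}
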