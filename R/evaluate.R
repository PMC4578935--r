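# Quantitative evaluation: L1 deviation against the reference field, Monte
# Carlo study aggregation, parameter sweeps, and the L1-vs-sigma correlation.

#' Masked L1 deviation between a corrected field and a reference
#'
#' Mean absolute voxelwise difference over the mask,
#' `L1 = (1/n) * sum_mask |b_corr - b_ref|`, with the reference mean-removed
#' (it is defined as a mean-free contrast map). By default the corrected map
#' is mean-removed as well, since a constant offset is not determined by
#' background removal; `demean = "reference"` compares the corrected map as
#' is, retaining any constant offset in the score.
#'
#' @param corrected 3D numeric array (Hz).
#' @param reference 3D numeric array (Hz).
#' @param mask Logical 3D array.
#' @param demean `"both"` (default) or `"reference"`.
#' @return Scalar, Hz.
#' @export
l1_metric <- function(corrected, reference, mask,
                      demean = c("both", "reference")) {
  demean <- match.arg(demean)
  mask <- check_mask(mask, corrected)
  stopifnot(identical(dim(reference), dim(corrected)))
  a <- corrected[mask]; b <- reference[mask]
  if (demean == "both") a <- a - mean(a)
  mean(abs(a - (b - mean(b))))
}

#' Default filter set for comparison studies
#'
#' The four correctors compared throughout: mask-aware Gaussian filter,
#' standalone solid-harmonic projection, standalone dipole filter, and the
#' full multistage chain. Each element is a function
#' `(field, mask, grid, cache) -> corrected field`; `cache` is an environment
#' used to share the (expensive) harmonic basis across samples with identical
#' masks.
#'
#' @param gf_sigma Gaussian sigma in voxels (default 4; use ~2 at desk-small
#'   scale, i.e. the full-scale value scaled by the linear matrix ratio).
#' @param sphinx_order Order of the standalone harmonic filter (default 10).
#' @param dipf_cfg A [dipf_config()] for the standalone dipole filter.
#' @param chain_cfg A [chain_config()] for the multistage chain.
#' @return Named list of filter functions (`gf`, `sphinx`, `dipf`,
#'   `mubafire`).
#' @export
default_filter_set <- function(gf_sigma = 4, sphinx_order = 10L,
                               dipf_cfg = dipf_config(),
                               chain_cfg = chain_config()) {
  list(
    gf = function(field, mask, grid, cache)
      gaussian_background(field, mask, gf_sigma)$residual,
    sphinx = function(field, mask, grid, cache)
      sphinx_filter(field, mask, grid, sphinx_order,
                    basis = cached_basis(cache, mask, grid, sphinx_order))$residual,
    dipf = function(field, mask, grid, cache)
      dipf(field, mask, grid, dipf_cfg)$residual,
    mubafire = function(field, mask, grid, cache)
      run_chain(field, mask, grid, chain_cfg,
                basis = cached_basis(cache, mask, grid,
                                     chain_cfg$sphinx_order))$corrected
  )
}

# Basis cache: one basis per (order, mask identity) pair. Masks are compared
# with identical(); within a study all samples share the phantom mask, so the
# basis is built once.
cached_basis <- function(cache, mask, grid, order) {
  if (is.null(cache)) return(ssh_basis(mask, grid, order))
  key <- sprintf("order%d", order)
  hit <- cache[[key]]
  if (!is.null(hit) && identical(hit$mask, mask)) return(hit$basis)
  basis <- ssh_basis(mask, grid, order)
  cache[[key]] <- list(mask = mask, basis = basis)
  basis
}

#' Run a filter-comparison study over simulation samples
#'
#' Applies each filter to each sample's observed field, records the L1
#' deviation from the sample's reference field and the masked standard
#' deviation of the corrected map, and aggregates mean ± sd per filter —
#' the comparison-table layout of the validation study.
#'
#' @param samples List of [simulate_sample()] results (or a
#'   [simulate_study()] result).
#' @param filters Named list of filter functions, see [default_filter_set()].
#' @param verbose Print per-sample progress.
#' @return Object of class `study_report`: `summary` (data frame: filter,
#'   mean_l1, sd_l1, mean_sigma, sd_sigma, n), `records` (per sample x
#'   filter), and `reference` (mean/sd of the masked reference-field sd).
#' @export
run_study <- function(samples, filters = default_filter_set(),
                      verbose = FALSE) {
  if (!is.null(samples$samples)) samples <- samples$samples
  stopifnot(length(samples) >= 1L, length(filters) >= 1L,
            !is.null(names(filters)))
  cache <- new.env(parent = emptyenv())
  rec <- list()
  ref_sigma <- numeric(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    ref_sigma[i] <- sd_pop(s$b_ref[s$mask])
    for (f in names(filters)) {
      t0 <- proc.time()[3]
      corrected <- filters[[f]](s$b_obs, s$mask, s$grid, cache)
      dt <- proc.time()[3] - t0
      rec[[length(rec) + 1L]] <- data.frame(
        sample = i, seed = s$seed, filter = f,
        l1 = l1_metric(corrected, s$b_ref, s$mask),
        sigma = sd_pop(corrected[s$mask]),
        time_s = dt)
      if (verbose)
        message(sprintf("sample %d / %s: L1 = %.3f Hz, sigma = %.3f Hz (%.1fs)",
                        i, f, rec[[length(rec)]]$l1,
                        rec[[length(rec)]]$sigma, dt))
    }
  }
  records <- do.call(rbind, rec)
  agg <- lapply(names(filters), function(f) {
    r <- records[records$filter == f, ]
    data.frame(filter = f, mean_l1 = mean(r$l1), sd_l1 = sd_pop(r$l1),
               mean_sigma = mean(r$sigma), sd_sigma = sd_pop(r$sigma),
               n = nrow(r))
  })
  structure(list(summary = do.call(rbind, agg), records = records,
                 reference = data.frame(mean_sigma = mean(ref_sigma),
                                        sd_sigma = sd_pop(ref_sigma),
                                        n = length(ref_sigma))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, digits = 3, ...) {
  cat(sprintf("<study_report> n = %d samples\n", x$reference$n))
  s <- x$summary
  cat(sprintf("  %-10s %10s %10s %12s %12s\n",
              "filter", "mean L1", "sd L1", "mean sigma", "sd sigma"))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s %10.*f %10.*f %12.*f %12.*f\n", s$filter[i],
                digits, s$mean_l1[i], digits, s$sd_l1[i],
                digits, s$mean_sigma[i], digits, s$sd_sigma[i]))
  cat(sprintf("  %-10s %10s %10s %12.*f %12.*f\n", "reference", "(0)", "(0)",
              digits, x$reference$mean_sigma, digits, x$reference$sd_sigma))
  invisible(x)
}

#' Write a study report to CSV and JSON
#'
#' @param report A [run_study()] result.
#' @param csv_path Summary CSV path (per-sample records go to
#'   `*_records.csv`).
#' @param json_path JSON path (defaults next to the CSV).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(report, csv_path,
                               json_path = sub("\\.csv$", ".json", csv_path)) {
  utils::write.csv(report$summary, csv_path, row.names = FALSE)
  rec_path <- sub("\\.csv$", "_records.csv", csv_path)
  utils::write.csv(report$records, rec_path, row.names = FALSE)
  jsonlite::write_json(list(summary = report$summary,
                            reference = report$reference),
                       json_path, dataframe = "rows", digits = NA)
  invisible(c(csv = csv_path, records = rec_path, json = json_path))
}

#' Parameter sweep of harmonic order and dipole-filter iterations
#'
#' For each sample, evaluates the standalone harmonic filter at every order in
#' `sphinx_orders` (one basis built at the maximum order; lower orders use its
#' leading vectors, so the model classes are exactly nested), the standalone
#' dipole filter at every iteration count in `dipf_iters` (one conjugate-
#' gradient run with snapshots, identical to separate runs because CG is
#' deterministic), and optionally the full chain on the grid of both.
#' The error is the L1 deviation from the sample reference normalized by the
#' masked sd of the reference field.
#'
#' @param samples List of [simulate_sample()] results (or a
#'   [simulate_study()] result).
#' @param sphinx_orders Integer vector of harmonic orders.
#' @param dipf_iters Integer vector of CG iteration counts.
#' @param include_chain Also sweep the chain over
#'   `sphinx_orders x dipf_iters` (default FALSE).
#' @param dipf_cfg Base [dipf_config()] (lambda, padding) for the sweeps.
#' @return Data frame: `method`, `order`, `n_iter`, `sample`, `l1`,
#'   `norm_error`, `time_s`.
#' @export
parameter_sweep <- function(samples, sphinx_orders = 1:10,
                            dipf_iters = c(5L, 10L, 20L, 50L),
                            include_chain = FALSE,
                            dipf_cfg = dipf_config()) {
  if (!is.null(samples$samples)) samples <- samples$samples
  stopifnot(length(samples) >= 1L)
  cache <- new.env(parent = emptyenv())
  out <- list()
  add <- function(method, order, n_iter, sample, l1, ref_sd, dt)
    out[[length(out) + 1L]] <<- data.frame(
      method = method, order = order, n_iter = n_iter, sample = sample,
      l1 = l1, norm_error = l1 / ref_sd, time_s = dt)

  max_ord <- max(sphinx_orders)
  max_it <- max(dipf_iters)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    ref_sd <- sd_pop(s$b_ref[s$mask])
    basis <- cached_basis(cache, s$mask, s$grid, max_ord)
    for (o in sort(sphinx_orders)) {
      t0 <- proc.time()[3]
      res <- ssh_project(s$b_obs, basis, order = o)$residual
      add("sphinx", o, NA_integer_, i,
          l1_metric(res, s$b_ref, s$mask), ref_sd, proc.time()[3] - t0)
    }
    t0 <- proc.time()[3]
    snaps <- dipf_snapshots(s$b_obs, s$mask, s$grid,
                            dipf_cfg, iters = sort(dipf_iters))
    dt_all <- proc.time()[3] - t0
    for (k in seq_along(snaps))
      add("dipf", NA_integer_, sort(dipf_iters)[k], i,
          l1_metric(snaps[[k]], s$b_ref, s$mask), ref_sd, dt_all)
    if (include_chain) {
      for (o in sort(sphinx_orders)) {
        t0 <- proc.time()[3]
        r1 <- polf(s$b_obs, s$mask, s$grid)$residual
        r2 <- ssh_project(r1, basis, order = o)$residual
        csnaps <- dipf_snapshots(r2, s$mask, s$grid,
                                 dipf_cfg, iters = sort(dipf_iters))
        dt_all <- proc.time()[3] - t0
        for (k in seq_along(csnaps))
          add("mubafire", o, sort(dipf_iters)[k], i,
              l1_metric(csnaps[[k]], s$b_ref, s$mask), ref_sd, dt_all)
      }
    }
  }
  do.call(rbind, out)
}

# One CG run recording the masked residual field at the requested iteration
# counts; returns a named list of residual volumes. Same solver as dipf()
# (default exterior support); kept separate to keep the main solver lean.
dipf_snapshots <- function(field, mask, grid, config, iters) {
  config$n_iter <- max(iters)
  mask <- check_mask(mask, field)
  d <- dim(field)
  dp <- d + 2L * as.integer(ceiling(d * config$pad_fraction))
  off <- (dp - d) %/% 2L
  kern <- dipole_kernel(dp, grid)$spectrum
  cscale <- GAMMA_HZ_PER_T * grid$b_base  # dimensionless-chi convention
  mp <- pad_array(array(as.numeric(mask), d), dp, off)
  sp <- 1 - mp
  A <- function(x) mp * Re(ifftn(kern * stats::fft(x))) * cscale
  At <- function(y) sp * Re(ifftn(kern * stats::fft(mp * y))) * cscale
  bp <- pad_array(field, dp, off) * mp
  rhs <- At(bp)
  x <- array(0, dp); Ax <- array(0, dp)
  r <- rhs; p <- r; rs <- sum(r^2)
  sel <- which(mask)
  snaps <- list()
  for (i in seq_len(config$n_iter)) {
    Ap_f <- A(p)
    Np <- At(Ap_f) + config$lambda * p
    alpha <- rs / sum(p * Np)
    if (!is.finite(alpha)) break
    x <- x + alpha * p
    Ax <- Ax + alpha * Ap_f
    r <- r - alpha * Np
    rs_new <- sum(r^2)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    if (i %in% iters) {
      resv <- array(0, d)
      bgc <- crop_array(Ax, d, off)  # Ax = masked forward field of x
      resv[sel] <- field[sel] - bgc[sel]
      snaps[[as.character(i)]] <- resv
    }
  }
  snaps
}

#' Pearson correlation between per-record L1 deviation and masked sd
#'
#' Across samples and filters, a lower corrected-map standard deviation tends
#' to indicate a more accurate correction; this computes the Pearson
#' correlation over the study's per-sample records to quantify that link.
#'
#' @param report A [run_study()] result (needs >= 3 records).
#' @return Scalar correlation coefficient.
#' @export
correlation_l1_sigma <- function(report) {
  r <- report$records
  if (nrow(r) < 3L) stop("need at least 3 per-sample records")
  if (sd_pop(r$l1) == 0 || sd_pop(r$sigma) == 0)
    stop("undefined correlation: degenerate variance in records")
  stats::cor(r$l1, r$sigma)
}
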