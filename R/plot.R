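# ggplot2 views of study reports, sweep tables and field-map slices.

#' @importFrom rlang .data
NULL

#' Bar plot of a filter-comparison study
#'
#' Mean L1 deviation and mean masked sd per filter, with sd-over-samples
#' error bars; the reference-field sd is drawn as a dashed line in the sigma
#' panel.
#'
#' @param report A [run_study()] result.
#' @return A ggplot object.
#' @export
plot_study <- function(report) {
  s <- report$summary
  long <- rbind(
    data.frame(filter = s$filter, metric = "L1 deviation (Hz)",
               value = s$mean_l1, err = s$sd_l1),
    data.frame(filter = s$filter, metric = "masked sd (Hz)",
               value = s$mean_sigma, err = s$sd_sigma))
  refline <- data.frame(metric = "masked sd (Hz)",
                        y = report$reference$mean_sigma)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$filter, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$err,
                                        ymax = .data$value + .data$err),
                           width = 0.25) +
    ggplot2::geom_hline(data = refline, ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Background-removal comparison") +
    ggplot2::theme_minimal()
}

#' Error curves of a parameter sweep
#'
#' Normalized error versus harmonic order (harmonic filter) and versus
#' iteration count (dipole filter), averaged over samples.
#'
#' @param sweep A [parameter_sweep()] result.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  sp <- sweep[sweep$method == "sphinx", ]
  dp <- sweep[sweep$method == "dipf", ]
  sp_m <- stats::aggregate(norm_error ~ order, sp, mean)
  dp_m <- stats::aggregate(norm_error ~ n_iter, dp, mean)
  long <- rbind(
    data.frame(x = sp_m$order, y = sp_m$norm_error,
               panel = "harmonic order"),
    data.frame(x = dp_m$n_iter, y = dp_m$norm_error,
               panel = "CG iterations"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = "parameter", y = "normalized L1 error",
                  title = "Parameter sweep") +
    ggplot2::theme_minimal()
}

#' Raster view of an axial slice of a field map
#'
#' @param field 3D numeric array.
#' @param z Slice index (default middle).
#' @param mask Optional logical array; voxels outside are blanked.
#' @return A ggplot object.
#' @export
plot_slice <- function(field, z = NULL, mask = NULL) {
  d <- dim(field)
  if (is.null(z)) z <- (d[3] + 1L) %/% 2L
  sl <- field[, , z]
  if (!is.null(mask)) sl[!mask[, , z]] <- NA
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "Hz", title = sprintf("slice z = %d", z)) +
    ggplot2::theme_void()
}
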