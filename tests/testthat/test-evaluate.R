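brute_l1 <- function(corrected, reference, mask, demean_corrected = FALSE) {
  tot <- 0; n <- 0
  d <- dim(mask)
  cm <- if (demean_corrected) mean(corrected[mask]) else 0
  rm_ <- mean(reference[mask])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (mask[i, j, k]) {
      tot <- tot + abs((corrected[i, j, k] - cm) -
                       (reference[i, j, k] - rm_))
      n <- n + 1
    }
  tot / n
}

test_that("the L1 deviation metric matches a brute-force voxel loop", {
  set.seed(81)
  for (rep in 1:3) {
    d <- c(5, 6, 4)
    mask <- array(runif(prod(d)) > 0.4, d)
    mask[2, 2, 2] <- TRUE
    a <- array(rnorm(prod(d)), d)
    b <- array(rnorm(prod(d)), d)
    expect_equal(l1_metric(a, b, mask, demean = "reference"),
                 brute_l1(a, b, mask), tolerance = 1e-12)
    expect_equal(l1_metric(a, b, mask, demean = "both"),
                 brute_l1(a, b, mask, demean_corrected = TRUE),
                 tolerance = 1e-12)
  }

  # identical maps: zero deviation
  expect_equal(l1_metric(a, a, mask, demean = "both"), 0)
  # a constant offset vanishes when both maps are mean-adjusted
  expect_equal(l1_metric(a + 3, a, mask, demean = "both"), 0,
               tolerance = 1e-12)
  # hand-computed 3-voxel case
  m3 <- array(FALSE, c(3, 1, 1)); m3[] <- TRUE
  ca <- array(c(1, -2, 3), c(3, 1, 1))
  cb <- array(0, c(3, 1, 1))
  expect_equal(l1_metric(ca, cb, m3, demean = "both"),
               mean(abs(c(1, -2, 3) - mean(c(1, -2, 3)))))
  expect_error(l1_metric(ca, cb, array(FALSE, c(3, 1, 1))), "empty")
})

test_that("run_study aggregates per-filter records correctly", {
  samples <- make_tiny_samples(2)
  ident <- list(none = function(field, mask, grid, cache) field)
  rep1 <- run_study(samples[1], filters = ident)
  expect_equal(rep1$summary$mean_l1,
               l1_metric(samples[[1]]$b_obs, samples[[1]]$b_ref,
                         samples[[1]]$mask))
  expect_equal(rep1$summary$n, 1L)

  # duplicated sample: zero spread
  rep2 <- run_study(list(samples[[1]], samples[[1]]), filters = ident)
  expect_equal(rep2$summary$sd_l1, 0)
  expect_equal(rep2$summary$sd_sigma, 0)

  # aggregates are invariant under sample order
  rep_ab <- run_study(samples, filters = ident)
  rep_ba <- run_study(rev(samples), filters = ident)
  expect_equal(rep_ab$summary$mean_l1, rep_ba$summary$mean_l1,
               tolerance = 1e-12)
  expect_equal(rep_ab$reference$mean_sigma, rep_ba$reference$mean_sigma,
               tolerance = 1e-12)
})

test_that("correlation between L1 and sigma behaves as a Pearson coefficient", {
  rec <- data.frame(l1 = c(1, 2, 3, 4), sigma = c(2, 4, 6, 8))
  rep <- structure(list(records = rec), class = "study_report")
  expect_equal(correlation_l1_sigma(rep), 1)
  rep$records$sigma <- c(8, 6, 4, 2)
  expect_equal(correlation_l1_sigma(rep), -1)
  rep$records$sigma <- rep(1, 4)
  expect_error(correlation_l1_sigma(rep), "degenerate")
  rep$records <- rec[1:2, ]
  expect_error(correlation_l1_sigma(rep), "3")
})

test_that("a small parameter sweep produces a complete, sane table", {
  samples <- make_tiny_samples(1)
  tbl <- parameter_sweep(samples, sphinx_orders = c(1, 3),
                         dipf_iters = c(3L, 6L),
                         dipf_cfg = dipf_config(n_iter = 6))
  expect_setequal(unique(tbl$method), c("sphinx", "dipf"))
  expect_equal(sum(tbl$method == "sphinx"), 2L)
  expect_equal(sum(tbl$method == "dipf"), 2L)
  expect_true(all(is.finite(tbl$norm_error)))
  # sweep orders are nested projections: higher order cannot be worse in L2,
  # and here matches a direct standalone run
  s <- samples[[1]]
  direct <- sphinx_filter(s$b_obs, s$mask, s$grid, 3)$residual
  expect_equal(tbl$l1[tbl$method == "sphinx" & tbl$order == 3],
               l1_metric(direct, s$b_ref, s$mask), tolerance = 1e-8)
  # dipf snapshot at k iterations equals a fresh run with n_iter = k
  fresh <- dipf(s$b_obs, s$mask, s$grid, dipf_config(n_iter = 3))$residual
  expect_equal(tbl$l1[tbl$method == "dipf" & tbl$n_iter == 3],
               l1_metric(fresh, s$b_ref, s$mask), tolerance = 1e-10)
})

test_that("study reports export to CSV and JSON", {
  samples <- make_tiny_samples(1)
  rep <- run_study(samples,
                   filters = list(none = function(f, m, g, c) f))
  csv <- tempfile(fileext = ".csv")
  paths <- write_study_report(rep, csv)
  expect_true(all(file.exists(paths)))
  tab <- read.csv(paths["csv"])
  expect_equal(tab$mean_l1, rep$summary$mean_l1, tolerance = 1e-12)
})
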