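# Evaluation statistics: metrics, effect sizes, paired t, 1D SPM.

test_that("regression metrics match hand computations", {
  m <- regression_metrics(c(0, 1, 2), c(0, 1, 2))
  expect_equal(unlist(m), c(mae = 0, mse = 0, r2 = 1))

  m2 <- regression_metrics(c(0, 1, 2), c(0, 1, 3)) # SST = 2, SSE = 1
  expect_equal(m2$mae, 1 / 3)
  expect_equal(m2$mse, 1 / 3)
  expect_equal(m2$r2, 0.5)

  y <- c(2, 4, 9, 1)
  m3 <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(m3$r2, 0)

  expect_error(regression_metrics(rep(1, 5), rnorm(5)),
               class = "serveload_numeric_error")
  expect_error(regression_metrics(1:3, 1:4), class = "serveload_data_error")
})

test_that("pooled Cohen's d reproduces the consistent reference cells to 3 dp", {
  expect_equal(round(cohens_d_pooled(0.209, 0.047, 0.339, 0.009), 3), 3.842)

  ref <- reference_metrics()
  expect_equal(nrow(ref), 18)
  expect_equal(sum(ref$consistent), 16)
  for (i in which(ref$consistent)) {
    d <- cohens_d_pooled(ref$mean_gnn_gru[i], ref$sd_gnn_gru[i],
                         ref$mean_gru[i], ref$sd_gru[i])
    expect_equal(round(d, 3), ref$d_printed[i],
                 label = sprintf("%s/%s", ref$feature[i], ref$metric[i]))
  }
  # the two inconsistent cells really are inconsistent
  for (i in which(!ref$consistent)) {
    d <- cohens_d_pooled(ref$mean_gnn_gru[i], ref$sd_gnn_gru[i],
                         ref$mean_gru[i], ref$sd_gru[i])
    expect_gt(abs(round(d, 3) - ref$d_printed[i]), 0.5)
  }
})

test_that("Cohen's d is symmetric, scale invariant, and guards degeneracy", {
  expect_equal(cohens_d_pooled(1, 2, 3, 4), cohens_d_pooled(3, 4, 1, 2))
  expect_equal(cohens_d_pooled(10, 20, 30, 40), cohens_d_pooled(1, 2, 3, 4))
  expect_equal(cohens_d_pooled(5, 1, 5, 3), 0)
  expect_error(cohens_d_pooled(1, 0, 2, 0), class = "serveload_numeric_error")
})

test_that("paired t matches the reference implementation", {
  a <- c(12.1, 14.3, 11.8, 15.2, 13.3)
  b <- c(11.2, 13.1, 12.0, 14.1, 12.2)
  got <- paired_t(a, b)
  want <- t.test(a, b, paired = TRUE)
  expect_equal(got$t, unname(want$statistic), tolerance = 1e-9)
  expect_equal(got$p, want$p.value, tolerance = 1e-9)
  expect_equal(got$df, unname(want$parameter))
  expect_true(is.logical(got$normality_ok))

  same <- paired_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # near-constant nonzero difference: enormous t, vanishing p
  withr::local_seed(41)
  x <- rnorm(12)
  tiny <- paired_t(x + 5 + rnorm(12, sd = 1e-4), x)
  expect_lt(tiny$p, 1e-6)

  expect_error(paired_t(c(1, 2), c(3, 4)), class = "serveload_argument_error")
  # bit-exact constant nonzero difference: degenerate
  expect_error(paired_t(2:11, 1:10), class = "serveload_numeric_error")
})

# smooth Gaussian 1D noise with approximately known FWHM (in nodes),
# built by convolving white noise with a Gaussian kernel
smooth_noise <- function(m, q, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- ceiling(3 * sigma)
  kern <- dnorm(-half:half, sd = sigma)
  kern <- kern / sqrt(sum(kern^2)) # unit variance after convolution
  t(vapply(seq_len(m), function(i) {
    x <- rnorm(q + 2 * half)
    as.numeric(stats::filter(x, kern, sides = 2))[(half + 1):(half + q)]
  }, numeric(q)))
}

test_that("identical paired curves give an all-zero t field and no clusters", {
  withr::local_seed(42)
  Y <- smooth_noise(8, 101, 15)
  res <- spm_paired_t(Y, Y)
  expect_equal(res$t_field, numeric(101))
  expect_length(res$clusters, 0)
  expect_false(res$significant)
})

test_that("a large offset against small smooth noise lights the whole field", {
  withr::local_seed(43)
  Y_a <- smooth_noise(10, 101, 20)
  Y_b <- Y_a + 50 + smooth_noise(10, 101, 20) * 0.1
  res <- spm_paired_t(Y_a, Y_b)
  expect_length(res$clusters, 1)
  expect_equal(res$clusters[[1]]$start, 0)
  expect_equal(res$clusters[[1]]$end, 100)
  expect_lt(res$clusters[[1]]$p, 0.01)
  expect_true(res$significant)
})

test_that("the FWHM estimator recovers the generating smoothness", {
  withr::local_seed(44)
  for (fwhm in c(8, 15, 25)) {
    est <- mean(vapply(1:20, function(i) {
      R <- smooth_noise(12, 101, fwhm)
      serveload:::estimate_fwhm(sweep(R, 2, colMeans(R)))
    }, numeric(1)))
    expect_equal(est, fwhm, tolerance = 0.25 * fwhm)
  }
})

test_that("the RFT critical threshold rises as the field gets rougher", {
  crit <- vapply(c(30, 20, 10, 5, 2), function(fwhm) {
    serveload:::rft_threshold(df = 19, resels = 100 / fwhm, alpha = 0.05)
  }, numeric(1))
  expect_true(all(diff(crit) > 0))
})

test_that("RFT and permutation thresholds agree on smooth Gaussian nulls", {
  withr::local_seed(45)
  m <- 20
  fwhm <- 18
  # permutation thresholds over simulated null datasets
  perm_crit <- vapply(1:40, function(i) {
    D <- smooth_noise(m, 101, fwhm)
    spm_paired_t(D, matrix(0, m, 101), method = "perm", n_perm = 300,
                 seed = i)$critical_t
  }, numeric(1))
  rft_crit <- mean(vapply(1:40, function(i) {
    D <- smooth_noise(m, 101, fwhm)
    spm_paired_t(D, matrix(0, m, 101), method = "rft")$critical_t
  }, numeric(1)))
  band <- quantile(perm_crit, c(0.025, 0.975))
  expect_gt(rft_crit, band[1] - 0.15)
  expect_lt(rft_crit, band[2] + 0.15)
})

test_that("family-wise error under the global null stays near alpha", {
  withr::local_seed(46)
  m <- 20
  false_pos <- mean(vapply(1:500, function(i) {
    D <- smooth_noise(m, 101, 20)
    spm_paired_t(D, matrix(0, m, 101), method = "rft")$significant
  }, logical(1)))
  expect_lte(false_pos, 1.5 * 0.05)
})

test_that("spm results serialize to JSON", {
  withr::local_seed(47)
  Y_a <- smooth_noise(8, 101, 15)
  res <- spm_paired_t(Y_a, Y_a + 30 + smooth_noise(8, 101, 15))
  path <- withr::local_tempfile(fileext = ".json")
  write_spm_json(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$critical_t, res$critical_t)
  expect_length(back$t_field, 101)
  expect_error(spm_paired_t(Y_a[1:2, ], Y_a[1:2, ] + 1),
               class = "serveload_argument_error")
})
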