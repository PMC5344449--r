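test_that("dead-channel rule flags relative-RMS outliers only", {
  same <- matrix(1, 10, 100)
  expect_false(any(detect_dead_channels(same)$exclude))

  set.seed(4)
  x <- matrix(rnorm(98 * 500), 98)
  x[37, ] <- 20 * x[37, ]
  dd <- detect_dead_channels(x)          # default factor 10
  expect_equal(which(dd$exclude), 37L)

  expect_error(detect_dead_channels(matrix(1, 1, 10)), "2 channels")
})

test_that("wavelet detrending removes drift but not signal", {
  fs <- 1 / 0.027
  n <- 13333
  ramp <- seq(0, 5, length.out = n)
  for (wv in c("haar", "d4")) {
    out <- wavelet_detrend(ramp, fs = fs, wavelet = wv)
    expect_lt(max(abs(out)), 0.05 * diff(range(ramp)))
  }
  expect_equal(wavelet_detrend(rep(2.5, 4096), fs = fs),
               rep(0, 4096), tolerance = 1e-10)

  set.seed(8)
  wn <- rnorm(8192)
  out <- wavelet_detrend(wn, fs = fs)
  expect_gt(var(out) / var(wn), 0.90)    # < 10% variance removed
  expect_lt(abs(mean(out)), 0.05)

  ## a matrix input is detrended row-wise
  m <- rbind(ramp, ramp)
  expect_equal(dim(wavelet_detrend(m, fs = fs)), dim(m))
  expect_error(wavelet_detrend(1:3, level = 5), "shorter")
  expect_error(wavelet_detrend(1:3), "fs or level")
})

test_that("zero-phase low-pass has the designed pass/stop behavior", {
  fs <- 37
  tt <- seq(0, 360, by = 1 / fs)
  slow <- sin(2 * pi * 0.01 * tt)
  keep <- lowpass(slow, fs, 0.1)
  mid <- seq(round(length(tt) * 0.25), round(length(tt) * 0.75))
  expect_gt(max(abs(keep[mid])), 0.95)

  fast <- sin(2 * pi * 1 * tt)
  gone <- lowpass(fast, fs, 0.1)
  expect_lt(max(abs(gone[mid])), 0.05)

  dc <- rep(3, 1000)
  expect_equal(lowpass(dc, fs, 0.1), dc, tolerance = 1e-6)
  expect_error(lowpass(dc, fs, 20), "Nyquist")
})

test_that("PCA spatial filter removes global but spares local components", {
  set.seed(5)
  n_ch <- 30; n_t <- 2000
  g <- sin(2 * pi * 0.08 * seq_len(n_t) / 10)
  gains <- 1 + rnorm(n_ch, 0, 0.05)
  noise <- matrix(rnorm(n_ch * n_t, 0, 0.05), n_ch)
  X <- gains %o% g + noise
  pf <- pca_spatial_filter(X, k = 1)
  expect_equal(nrow(pf$removed), 1)
  removed_var <- 1 - colSums(t(pf$filtered^2)) / colSums(t(X^2))
  expect_true(all(removed_var > 0.90))

  ## orthogonal channel-localized signals survive k = 1 removal
  Y <- matrix(0, n_ch, n_t)
  Y[3, ] <- sin(2 * pi * seq_len(n_t) / 50)
  Y[9, ] <- cos(2 * pi * seq_len(n_t) / 80)
  Y <- Y + matrix(rnorm(n_ch * n_t, 0, 0.01), n_ch)
  pfy <- pca_spatial_filter(Y, k = 1)
  for (ch in c(3, 9)) {
    loss <- 1 - sqrt(sum(pfy$filtered[ch, ]^2) / sum(Y[ch, ]^2))
    expect_lt(loss, 0.10)
  }

  z <- pca_spatial_filter(matrix(0, 5, 50))
  expect_equal(z$filtered, matrix(0, 5, 50))
  expect_error(pca_spatial_filter(X, k = n_ch), "smaller")
})

test_that("PCA spatial filter is idempotent", {
  set.seed(6)
  X <- (1 + rnorm(20, 0, 0.05)) %o% rnorm(500) +
       matrix(rnorm(20 * 500, 0, 0.2), 20)
  f1 <- pca_spatial_filter(X, k = 1)
  ## projecting the same component out again changes nothing
  again <- f1$filtered - f1$spatial %*% (t(f1$spatial) %*% f1$filtered)
  expect_equal(again, f1$filtered, tolerance = 1e-10)
  expect_lt(max(abs(t(f1$spatial) %*% f1$filtered)),
            1e-8 * max(abs(X)))
})

test_that("downsampling keeps every factor-th sample", {
  x <- matrix(seq_len(40), 2, byrow = TRUE)
  expect_equal(unname(downsample(x, 1))[1, ], x[1, ], ignore_attr = TRUE)
  d <- downsample(x, 10)
  expect_equal(ncol(d), 2)
  expect_equal(d[1, ], c(1, 11), ignore_attr = TRUE)
  const <- downsample(rep(7, 100), 10)
  expect_true(all(const == 7))
  expect_error(downsample(x, 0), ">= 1")
  ## 27 ms acquisition downsampled 10-fold -> 270 ms effective period
  expect_equal(0.027 * 10, 0.27)
})

test_that("HRF residual RMS behaves like an OLS residual", {
  cfg <- tiny_config()
  sched <- generate_event_schedule(cfg, "gesture")
  ft <- seq(0, 359, by = 0.5)
  des <- build_design(sched, ft)
  inspan <- rbind(3 * des$X[, 1] + 2, -1 * des$X[, 2])
  expect_equal(hrf_residual_rms(inspan, des), c(0, 0), tolerance = 1e-9)
  expect_equal(hrf_residual_rms(matrix(0, 2, length(ft)), des), c(0, 0))
  set.seed(12)
  noisy <- matrix(rnorm(5 * length(ft)), 5)
  expect_equal(hrf_residual_rms(noisy, des), rep(1, 5), tolerance = 0.1)
})

test_that("the full preprocessing chain preserves a planted effect", {
  cfg <- sim_config(n_subjects = 1, seed = 21, noise_sd = 1,
                    response_sd = 0, dead_channels = 9L,
                    active_channels = data.frame(channel = c(5, 6),
                                                 condition = "gesture",
                                                 amplitude = 3))
  sub <- simulate_subject(cfg, 1, "gesture")
  prep <- preprocess_subject(sub$od)
  expect_equal(which(prep$dead$exclude), 9L)
  expect_equal(prep$sample_period, 0.27)
  expect_true(all(is.na(prep$series[9, ])))

  des <- build_design(sub$schedule, prep$frame_times)
  good <- which(!prep$dead$exclude)
  fit <- fit_glm(prep$series[good, , drop = FALSE], des)
  con <- rep(NA_real_, 98)
  con[good] <- contrast(fit, "G>C")$value
  ## planted 3 uM HbO -> -1 uM HbR -> +1 per condition on the negated
  ## deoxy signal; the G>C preset sums the two gesture conditions
  expect_equal(con[5], 2, tolerance = 0.25)
  expect_equal(con[6], 2, tolerance = 0.25)
  expect_lt(max(abs(con[-c(5, 6, 9)])), 0.5)
  expect_named(prep$provenance, c("config", "n_dead", "signal",
                                  "negate_hbr", "sample_period", "stages"))
})
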