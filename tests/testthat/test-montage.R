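test_that("default montage has the acquisition geometry of the study design", {
  lay <- default_montage()
  expect_equal(nrow(lay$emitters), 30)
  expect_equal(nrow(lay$detectors), 29)
  expect_equal(nrow(lay$channel_pairs), 98)
  sep <- channel_separations(lay)
  expect_true(all(abs(sep - 30) < 1))
  expect_setequal(rownames(lay$fiducials),
                  c("nasion", "inion", "Cz", "T3", "T4"))
})

test_that("channel coordinates are optode-pair midpoints", {
  lay <- list(emitters = rbind(E1 = c(0, 0, 0)),
              detectors = rbind(D1 = c(30, 0, 0)),
              channel_pairs = cbind(1L, 1L))
  expect_equal(unname(channels_from_optodes(lay)[1, ]), c(15, 0, 0))

  full <- default_montage()
  cc <- channels_from_optodes(full)
  expect_equal(nrow(cc), 98)
  p <- full$channel_pairs[7, ]
  expect_equal(unname(cc[7, ]),
               unname((full$emitters[p[1], ] + full$detectors[p[2], ]) / 2))

  ## permuting optode storage order (with pair indices remapped) leaves the
  ## channel coordinates unchanged
  pe <- sample(nrow(full$emitters)); pd <- sample(nrow(full$detectors))
  lay2 <- full
  lay2$emitters <- full$emitters[pe, ]
  lay2$detectors <- full$detectors[pd, ]
  lay2$channel_pairs <- cbind(order(pe)[full$channel_pairs[, 1]],
                              order(pd)[full$channel_pairs[, 2]])
  expect_equal(unname(channels_from_optodes(lay2)),
               unname(cc))

  bad <- full; bad$channel_pairs[1, 1] <- 99L
  expect_error(channels_from_optodes(bad), "non-existent")
})

test_that("fiducial transform recovers planted similarity motions", {
  tpl <- default_montage()$fiducials

  id <- fiducial_transform(tpl, tpl)
  expect_equal(id$rotation, diag(3), tolerance = 1e-10)
  expect_equal(id$scale, 1, tolerance = 1e-10)
  expect_lt(id$rms, 1e-9)

  th <- 30 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- sweep(tpl %*% t(R), 2, c(12, -5, 30), `+`)
  tr <- fiducial_transform(moved, tpl)
  expect_lt(tr$rms, 1e-9)
  expect_equal(apply_transform(tr, moved), tpl, tolerance = 1e-9,
               ignore_attr = TRUE)

  ## random similarity transforms recovered to < 1e-6
  set.seed(7)
  for (i in 1:20) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); ang <- runif(1, 0, pi)
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]),
               c(-ax[2], ax[1], 0))
    Rr <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    s <- runif(1, 0.8, 1.2); tv <- rnorm(3, 0, 40)
    moved <- sweep(s * tpl %*% t(Rr), 2, tv, `+`)
    tr <- fiducial_transform(moved, tpl)
    expect_lt(max(abs(apply_transform(tr, moved) - tpl)), 1e-6)
  }
})

test_that("noisy landmarks yield residual RMS near the noise level", {
  tpl <- default_montage()$fiducials
  set.seed(11)
  rms <- replicate(200, {
    noisy <- tpl + matrix(rnorm(length(tpl), 0, 2), nrow(tpl))
    fiducial_transform(noisy, tpl)$rms
  })
  ## the similarity fit absorbs 7 of the 15 coordinate dof; the expected
  ## per-landmark Euclidean residual is sigma * sqrt(3 * 8 / 15) ~ 2.53
  expect_gt(mean(rms), 2.0)
  expect_lt(mean(rms), 3.1)
})

test_that("coplanar landmarks are rejected", {
  flat <- cbind(rnorm(5), rnorm(5), 0)
  expect_error(fiducial_transform(flat, flat + 1), "coplanar|degenerate")
})

test_that("median-coordinate registration behaves as an interpolator", {
  co <- channels_from_optodes(default_montage())
  vals <- lapply(1:3, function(s) as.numeric(seq_len(nrow(co))))
  reg <- register_to_median(rep(list(co), 3), vals)
  expect_equal(unname(reg$median_coords), unname(co))
  expect_equal(unname(reg$values[1, ]), vals[[1]])

  ## component-wise median definition
  cset <- list(rbind(c(0, 0, 0)), rbind(c(2, 0, 0)), rbind(c(10, 0, 0)))
  reg2 <- register_to_median(cset, list(1, 1, 1), k = 1)
  expect_equal(unname(reg2$median_coords[1, ]), c(2, 0, 0))

  ## a 1 mm uniform displacement leaves values near nearest-channel values
  co2 <- co; co2[] <- co2 + 1 / sqrt(3)
  v <- rnorm(nrow(co))
  reg3 <- register_to_median(list(co, co2), list(v, v))
  expect_equal(unname(reg3$values[2, ]), v, tolerance = 0.15)

  expect_error(register_to_median(list(co), list(rep(NA_real_, nrow(co)))),
               "usable")
})

test_that("channel-to-volume interpolation is a partition of unity", {
  co <- channels_from_optodes(default_montage())
  grid <- channel_support_grid(co)
  v <- channels_to_volume(rep(3.5, nrow(co)), co, grid)
  expect_equal(v, rep(3.5, length(grid$index)), tolerance = 1e-12)

  ## single nonzero channel: values decay with distance from it along the
  ## path toward a neighbouring channel (where the weight normalization is
  ## shared between the two)
  pair <- rbind(c(0, 0, 0), c(30, 0, 0))
  g2 <- channel_support_grid(pair, voxel_size = 2)
  v1 <- channels_to_volume(c(1, 0), pair, g2)
  online <- which(g2$coords[, 2] == 0 & g2$coords[, 3] == 0 &
                  g2$coords[, 1] >= 0 & g2$coords[, 1] <= 30)
  online <- online[order(g2$coords[online, 1])]
  expect_true(all(diff(v1[online]) <= 0))
  expect_true(any(diff(v1[online]) < 0))
  expect_equal(v1[online][1], 1)

  ## fwhm -> 0 limit: nearest channel's value (checked away from exact ties)
  vals <- rnorm(nrow(co))
  v0 <- channels_to_volume(vals, co, grid, kernel_fwhm = 0)
  dmat <- apply(grid$coords, 1, function(p) colSums((t(co) - p)^2))
  nearest <- apply(dmat, 2, which.min)
  gap <- apply(dmat, 2, function(d) diff(sort(d)[1:2]))
  untied <- gap > 1e-6
  expect_equal(v0[untied], vals[nearest[untied]])

  ## linearity in the channel values
  a <- rnorm(nrow(co)); b <- rnorm(nrow(co))
  expect_equal(channels_to_volume(2 * a - 3 * b, co, grid),
               2 * channels_to_volume(a, co, grid) -
               3 * channels_to_volume(b, co, grid), tolerance = 1e-10)
})

test_that("mask voxels all lie within the support distance of a channel", {
  co <- channels_from_optodes(default_montage())
  grid <- channel_support_grid(co, voxel_size = 4, mask_distance = 20)
  dmin <- apply(grid$coords, 1, function(p)
    sqrt(min(colSums((t(co) - p)^2))))
  expect_lte(max(dmin), 20)
})

test_that("polhemus digitizer text round-trips", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# digitizer export", "nasion: 0.0 84.1 -45.2",
               "Cz 0 -14 98"), f)
  m <- read_polhemus(f)
  expect_equal(rownames(m), c("nasion", "Cz"))
  expect_equal(unname(m["nasion", ]), c(0, 84.1, -45.2))
})
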