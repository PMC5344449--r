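test_that("group t-map is the one-sample t across subjects", {
  set.seed(2)
  V <- matrix(rnorm(20 * 50, 0.3), 20)
  tm <- group_t_map(V)
  expect_equal(tm$df, 19)
  expect_equal(tm$t[1],
               mean(V[, 1]) / (sd(V[, 1]) / sqrt(20)), tolerance = 1e-12)
  expect_equal(tm$p[1], pt(tm$t[1], 19, lower.tail = FALSE))

  ## zero-variance voxels are masked with a warning
  Vd <- V; Vd[, 3] <- 1
  expect_warning(tmd <- group_t_map(Vd), "zero-variance")
  expect_true(is.na(tmd$t[3]))
  expect_error(group_t_map(V[1, , drop = FALSE]), "2 subjects")
})

test_that("mean group t tracks the noncentral expectation", {
  set.seed(3)
  reps <- 500
  tvals <- vapply(seq_len(reps), function(i) {
    v <- rnorm(31, 0.5, 1)
    mean(v) / (sd(v) / sqrt(31))
  }, numeric(1))
  tm <- group_t_map(matrix(rnorm(31 * reps, 0.5, 1), 31))
  expect_equal(mean(tm$t), 0.5 * sqrt(31), tolerance = 0.1)
  expect_equal(mean(tvals), mean(tm$t), tolerance = 0.15)
})

test_that("clustering respects the connectivity scheme", {
  grid <- volume_grid(c(6, 6, 6), voxel_size = 1)
  ## component A: 5 voxels in a row; component B: 3 voxels, joined to A only
  ## corner-to-corner (diagonally)
  A <- cbind(1:5, 2, 2)
  B <- cbind(6, 3, 3); B <- rbind(B, c(6, 4, 3), c(6, 5, 3))
  lin <- function(ijk) ijk[, 1] + 6 * (ijk[, 2] - 1) + 36 * (ijk[, 3] - 1)
  tv <- rep(0, length(grid$index))
  tv[c(lin(A), lin(B))] <- 10
  tm <- toy_tmap(tv, grid)

  for (conn in c(6, 18)) {
    cl <- threshold_and_cluster(tm, grid, p_thresh = 0.001,
                                connectivity = conn, cluster_threshold = 4)
    expect_equal(sort(cl$size), c(3, 5))
    expect_equal(sum(cl$significant), 1)
  }
  cl26 <- threshold_and_cluster(tm, grid, p_thresh = 0.001,
                                connectivity = 26, cluster_threshold = 4)
  expect_equal(cl26$size, 8)

  ## agreement with the independent flood-fill oracle on random volumes
  set.seed(10)
  for (i in 1:10) {
    tv <- rnorm(length(grid$index), 1.5)
    tm <- toy_tmap(tv, grid, df = 10)
    for (conn in c(6, 18, 26)) {
      cl <- threshold_and_cluster(tm, grid, p_thresh = 0.05,
                                  connectivity = conn)
      mask <- array(tm$p < 0.05, grid$dim)
      expect_equal(sort(cl$size, decreasing = TRUE),
                   as.integer(flood_fill_sizes(mask, conn)))
    }
  }

  empty <- toy_tmap(rep(0, length(grid$index)), grid)
  expect_equal(nrow(threshold_and_cluster(empty, grid)), 0)
})

test_that("cluster peaks lie inside their clusters", {
  grid <- volume_grid(c(8, 8, 8), voxel_size = 2, origin = c(-8, -8, -8))
  set.seed(19)
  tv <- rnorm(length(grid$index), 1)
  tm <- toy_tmap(tv, grid, df = 20)
  cl <- threshold_and_cluster(tm, grid, p_thresh = 0.10)
  for (i in seq_len(nrow(cl))) {
    pk <- c(cl$peak_x[i], cl$peak_y[i], cl$peak_z[i])
    hit <- which(grid$coords[, 1] == pk[1] & grid$coords[, 2] == pk[2] &
                 grid$coords[, 3] == pk[3])
    expect_length(hit, 1)
    expect_equal(tm$t[hit], cl$peak_t[i])
  }
  expect_true(all(diff(cl$size) <= 0))
})

test_that("sign-flip FPR table is monotone and symmetric under the null", {
  co <- channels_from_optodes(default_montage())
  grid <- channel_support_grid(co)
  set.seed(6)
  V <- channels_to_volume(matrix(rnorm(12 * 98), 12), co, grid)
  f <- signflip_mc(V, grid, n_perm = 120, seed = 2)
  ## monotone non-increasing along rows and columns (within MC error)
  eps <- 0.05
  expect_true(all(diff(f$fpr) <= eps))              # down a column
  expect_true(all(t(diff(t(f$fpr))) <= eps))        # along a row
  expect_true(all(f$fpr >= 0 & f$fpr <= 1))

  ## the sign-flip t distribution at a voxel is centered on zero
  perm_means <- replicate(300, mean(sample(c(-1, 1), 12, TRUE) * V[, 500]))
  expect_lt(abs(mean(perm_means)), 3 * sd(perm_means) / sqrt(300))
  expect_error(signflip_mc(V, grid, n_perm = 0), "n_perm")
})

test_that("channel-wise t flags effects at the nominal level", {
  set.seed(7)
  null <- matrix(rnorm(31 * 200), 31)
  st <- channelwise_t(null)
  expect_equal(mean(st$flagged), 0.05, tolerance = 0.035)
  expect_true(all(st$n == 31))

  zero <- matrix(0, 10, 4)
  expect_false(any(channelwise_t(zero)$flagged))

  ## missing channels change per-channel n
  miss <- null; miss[1:5, 7] <- NA
  expect_equal(channelwise_t(miss)$n[7], 26)

  ## empirical power matches the noncentral-t closed form
  reps <- 200
  eff <- matrix(rnorm(31 * reps, 0.5, 1), 31)
  power_emp <- mean(channelwise_t(eff)$flagged)
  power_th <- pt(qt(0.95, 30), 30, ncp = 0.5 * sqrt(31),
                 lower.tail = FALSE)
  expect_equal(power_emp, power_th, tolerance = 0.05)
})

test_that("dual criterion separates significant from active findings", {
  co <- channels_from_optodes(default_montage())
  grid <- channel_support_grid(co)
  adjacency <- grid_adjacency(grid, 18)

  ## strong localized effect in 5 channels across 31 subjects
  target <- order(colSums((t(co) - c(80, -20, -5))^2))[1:5]
  set.seed(8)
  contrasts <- matrix(rnorm(31 * 98, 0, 1), 31)
  contrasts[, target] <- contrasts[, target] + 1.5
  res <- run_group_analysis(contrasts, co, grid = grid)
  expect_true(any(res$findings$label == "significant"))
  sig <- res$findings[res$findings$label == "significant", ]
  hit_channels <- as.integer(unlist(strsplit(sig$channels, ",")))
  expect_true(length(intersect(hit_channels, target)) >= 1)

  ## flagged channel without a surviving cluster stays "active"
  st <- data.frame(channel = 1:98, n = 31, t = 1, p = 0.5, flagged = FALSE)
  st$flagged[13] <- TRUE; st$p[13] <- 0.01
  tm <- toy_tmap(rep(0, length(grid$index)), grid, df = 30)
  tm$grid <- grid
  cl <- threshold_and_cluster(tm, grid, adjacency = adjacency)
  f <- dual_criterion(cl, st, co, tm, grid, adjacency = adjacency)
  expect_equal(f$label, "active")
  expect_equal(f$channels, "13")

  ## nothing anywhere -> empty findings
  st$flagged[13] <- FALSE
  f0 <- dual_criterion(cl, st, co, tm, grid, adjacency = adjacency)
  expect_equal(nrow(f0), 0)
})

test_that("overlap fraction counts voxels in the reference mask", {
  a <- c(rep(TRUE, 10), rep(FALSE, 90))
  b <- rep(TRUE, 100)
  expect_equal(overlap_fraction(a, b), 1)
  expect_equal(overlap_fraction(a, !a), 0)
  bb <- rep(FALSE, 100); bb[1:23] <- TRUE
  aa <- rep(TRUE, 100)
  expect_equal(overlap_fraction(aa, bb), 0.23)
  expect_error(overlap_fraction(rep(FALSE, 10), rep(TRUE, 10)), "empty")
  expect_error(overlap_fraction(a, b[1:50]), "same grid")
})
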