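# Independent brute-force oracles, written without reference to the package's
# own clustering/permutation code paths.

# 3-D connected components by stack-based flood fill on a logical array.
# Returns cluster sizes (sorted decreasing).
flood_fill_sizes <- function(mask3d, connectivity = 18) {
  dims <- dim(mask3d)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nrm <- rowSums(abs(off))
  off <- switch(as.character(connectivity),
                "6" = off[nrm == 1, , drop = FALSE],
                "18" = off[nrm >= 1 & nrm <= 2, , drop = FALSE],
                "26" = off[nrm >= 1, , drop = FALSE])
  visited <- array(FALSE, dims)
  sizes <- integer(0)
  todo <- which(mask3d, arr.ind = TRUE)
  for (r in seq_len(nrow(todo))) {
    start <- todo[r, ]
    if (visited[start[1], start[2], start[3]]) next
    stack <- list(start)
    visited[start[1], start[2], start[3]] <- TRUE
    size <- 0L
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (k in seq_len(nrow(off))) {
        nb <- v + off[k, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (!mask3d[nb[1], nb[2], nb[3]]) next
        if (visited[nb[1], nb[2], nb[3]]) next
        visited[nb[1], nb[2], nb[3]] <- TRUE
        stack[[length(stack) + 1]] <- nb
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}

# Exact familywise false-positive proportions of the sign-flip cluster
# procedure by enumeration of all 2^n sign assignments on a full-box grid.
exhaustive_signflip_fpr <- function(V, dims, cluster_sizes, p_thresholds,
                                    connectivity = 18) {
  n <- nrow(V)
  df <- n - 1
  t_crit <- qt(p_thresholds, df = df, lower.tail = FALSE)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  hits <- matrix(0, length(cluster_sizes), length(p_thresholds))
  for (r in seq_len(nrow(signs))) {
    Vs <- signs[r, ] * V
    m <- colMeans(Vs)
    s <- apply(Vs, 2, sd)
    tval <- m / (s / sqrt(n))
    for (j in seq_along(p_thresholds)) {
      supra <- array(is.finite(tval) & tval > t_crit[j], dims)
      sizes <- flood_fill_sizes(supra, connectivity)
      mx <- if (length(sizes) > 0) sizes[1] else 0L
      hits[, j] <- hits[, j] + as.integer(mx >= cluster_sizes)
    }
  }
  hits / nrow(signs)
}

# construct a volume_map by hand for clustering tests
toy_tmap <- function(tvals, grid, df = 10) {
  structure(list(t = tvals,
                 p = pt(tvals, df = df, lower.tail = FALSE),
                 n = df + 1, df = df, grid = grid),
            class = "volume_map")
}

# tiny simulation config for fast unit tests
tiny_config <- function(...) {
  args <- list(n_subjects = 2, seed = 42, n_channels = 4,
               systemic = list(cardiac = c(amp = 0, freq = 1.1),
                               resp = c(amp = 0, freq = 0.25),
                               mayer = c(amp = 0, freq = 0.095),
                               drift_amp = 0),
               noise_sd = 0, response_sd = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}
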