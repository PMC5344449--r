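#' One-sample group t-map over subject volumes
#'
#' Voxel-wise one-sample t statistic across subjects with `df = n - 1` and a
#' one-tailed (upper) p-value. Voxels with zero between-subject variance are
#' masked out (`NA`) with a warning.
#'
#' @param volumes n_subjects x n_voxels matrix of subject contrast volumes
#'   on a shared grid's mask.
#' @param grid the `volume_grid` the columns refer to (kept as metadata).
#' @return a `volume_map`: `t`, `p` (one-tailed), `n`, `df`, `grid`.
#' @export
group_t_map <- function(volumes, grid = NULL) {
  V <- as.matrix(volumes)
  n <- nrow(V)
  if (n < 2) stop("need at least 2 subjects")
  m <- colMeans(V)
  s <- sqrt((colSums(V^2) - n * m^2) / (n - 1))
  tval <- m / (s / sqrt(n))
  degenerate <- s == 0
  if (any(degenerate)) {
    tval[degenerate] <- NA_real_
    warning(sprintf("%d zero-variance voxels masked", sum(degenerate)))
  }
  p <- stats::pt(tval, df = n - 1, lower.tail = FALSE)
  structure(list(t = tval, p = p, n = n, df = n - 1, grid = grid),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  cat(sprintf("volume_map: %d voxels, df = %d, max t = %.3f\n",
              length(x$t), x$df, max(x$t, na.rm = TRUE)))
  invisible(x)
}

## cluster sizes (and memberships) of suprathreshold voxels under a
## precomputed mask adjacency
cluster_components <- function(supra, adjacency) {
  idx <- which(supra)
  if (length(idx) == 0)
    return(list(sizes = integer(0), membership = integer(0), voxels = idx))
  keep <- supra[adjacency[, 1]] & supra[adjacency[, 2]]
  remap <- integer(length(supra))
  remap[idx] <- seq_along(idx)
  g <- igraph::graph_from_edgelist(
    cbind(remap[adjacency[keep, 1]], remap[adjacency[keep, 2]]),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  list(sizes = as.integer(comp$csize), membership = comp$membership,
       voxels = idx)
}

#' Threshold a t-map and extract connected clusters
#'
#' Suprathreshold voxels (one-tailed `p < p_thresh`) are partitioned into
#' connected components under 6-, 18- or 26-connectivity; each cluster's
#' size, peak voxel and peak statistic are tabulated, and clusters at least
#' `cluster_threshold` voxels large are flagged significant.
#'
#' @param tmap a `volume_map`.
#' @param grid the `volume_grid` (defaults to the map's own).
#' @param p_thresh uncorrected one-tailed voxel threshold.
#' @param connectivity 6, 18 or 26.
#' @param cluster_threshold cluster-extent significance threshold (voxels).
#' @param adjacency optional precomputed [grid_adjacency()] edge matrix.
#' @return data frame (`cluster_table`): `cluster`, `size`, `peak_x/y/z`
#'   (mm), `peak_t`, `peak_p`, `significant`.
#' @export
threshold_and_cluster <- function(tmap, grid = tmap$grid, p_thresh = 0.001,
                                  connectivity = 18, cluster_threshold = 70,
                                  adjacency = NULL) {
  stopifnot(p_thresh > 0, p_thresh < 1)
  if (is.null(grid)) stop("no volume_grid available")
  if (is.null(adjacency)) adjacency <- grid_adjacency(grid, connectivity)
  supra <- !is.na(tmap$p) & tmap$p < p_thresh
  cc <- cluster_components(supra, adjacency)
  if (length(cc$sizes) == 0) {
    out <- data.frame(cluster = integer(0), size = integer(0),
                      peak_x = numeric(0), peak_y = numeric(0),
                      peak_z = numeric(0), peak_t = numeric(0),
                      peak_p = numeric(0), significant = logical(0))
    class(out) <- c("cluster_table", "data.frame")
    return(out)
  }
  ord <- order(cc$sizes, decreasing = TRUE)
  rows <- lapply(seq_along(ord), function(i) {
    members <- cc$voxels[cc$membership == ord[i]]
    pk <- members[which.max(tmap$t[members])]
    data.frame(cluster = i, size = cc$sizes[ord[i]],
               peak_x = grid$coords[pk, 1], peak_y = grid$coords[pk, 2],
               peak_z = grid$coords[pk, 3], peak_t = tmap$t[pk],
               peak_p = tmap$p[pk],
               significant = cc$sizes[ord[i]] >= cluster_threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Sign-flip Monte Carlo calibration of cluster-extent thresholds
#'
#' Estimates familywise false-positive proportions of the cluster procedure:
#' on each of `n_perm` permutations every subject's volume is independently
#' multiplied by +1 or -1 (valid under a symmetric null, where the expected
#' group result is no activity), the one-tailed group t-map is recomputed,
#' and for every (cluster size, voxel p threshold) cell the permutation
#' counts as a false positive if any connected cluster of at least that size
#' survives that threshold. With `exhaustive = TRUE` all `2^n` sign
#' assignments are enumerated instead of sampled.
#'
#' @param volumes n_subjects x n_voxels matrix of contrast volumes.
#' @param grid the shared `volume_grid`.
#' @param n_perm number of permutations.
#' @param cluster_sizes cluster-extent thresholds (rows of the output).
#' @param p_thresholds uncorrected voxel p thresholds (columns).
#' @param connectivity cluster connectivity (6/18/26).
#' @param seed RNG seed for the sign draws.
#' @param flip `"independent"` (each subject flipped with probability 1/2)
#'   or `"fixed_count"` (a uniformly drawn subset of half the subjects,
#'   rounded down, is flipped).
#' @param exhaustive enumerate all sign assignments (small n only).
#' @return an `fpr_table`: `fpr` matrix (sizes x thresholds of false-positive
#'   proportions), `max_cluster` (per-permutation max cluster size per
#'   threshold), `n_perm`, `seed`.
#' @export
signflip_mc <- function(volumes, grid, n_perm = 1000,
                        cluster_sizes = c(10, 30, 50, 70),
                        p_thresholds = c(0.05, 0.01, 0.001, 0.0001),
                        connectivity = 18, seed = 1,
                        flip = c("independent", "fixed_count"),
                        exhaustive = FALSE) {
  flip <- match.arg(flip)
  V <- as.matrix(volumes)
  n <- nrow(V)
  if (n < 2) stop("need at least 2 subjects")
  if (n_perm < 1) stop("n_perm must be >= 1")
  df <- n - 1
  t_crit <- stats::qt(p_thresholds, df = df, lower.tail = FALSE)
  adjacency <- grid_adjacency(grid, connectivity)
  ## sign flips leave sum(V^2) per voxel unchanged
  ss <- colSums(V^2)

  signs <- if (exhaustive) {
    if (n > 14) stop("exhaustive enumeration limited to n <= 14")
    m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    n_perm <- nrow(m)
    m
  } else with_seed(seed, {
    if (flip == "independent")
      matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    else t(vapply(seq_len(n_perm), function(i) {
      s <- rep(1, n); s[sample.int(n, n %/% 2)] <- -1; s
    }, numeric(n)))
  })

  max_cluster <- matrix(0L, n_perm, length(p_thresholds))
  chunk <- 100L
  for (start in seq(1, n_perm, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n_perm)
    M <- (signs[rows, , drop = FALSE] %*% V) / n      # permuted means
    for (r in seq_along(rows)) {
      m <- M[r, ]
      s <- sqrt(pmax(ss - n * m^2, 0) / df)
      tval <- ifelse(s > 0, m / (s / sqrt(n)), NA_real_)
      for (j in seq_along(p_thresholds)) {
        supra <- !is.na(tval) & tval > t_crit[j]
        if (!any(supra)) next
        sizes <- cluster_components(supra, adjacency)$sizes
        max_cluster[rows[r], j] <- max(sizes)
      }
    }
  }

  fpr <- vapply(seq_along(p_thresholds), function(j)
    vapply(cluster_sizes, function(k) mean(max_cluster[, j] >= k),
           numeric(1)),
    numeric(length(cluster_sizes)))
  fpr <- matrix(fpr, length(cluster_sizes), length(p_thresholds),
                dimnames = list(paste0("size>=", cluster_sizes),
                                paste0("p<", p_thresholds)))
  structure(list(fpr = fpr, cluster_sizes = cluster_sizes,
                 p_thresholds = p_thresholds, max_cluster = max_cluster,
                 n_perm = n_perm, seed = if (exhaustive) NA_integer_ else seed,
                 connectivity = connectivity, exhaustive = exhaustive),
            class = "fpr_table")
}

#' @export
print.fpr_table <- function(x, digits = 4, ...) {
  cat(sprintf("fpr_table: %d permutations%s\n", x$n_perm,
              if (x$exhaustive) " (exhaustive)" else ""))
  print(round(x$fpr, digits))
  invisible(x)
}

#' Channel-wise one-sample t statistics
#'
#' One-sample, one-tailed t per channel across subjects (after registration
#' to the median channel coordinates), with per-channel `n` accounting for
#' missing (dead) channels. Channels with `p < alpha` are flagged.
#'
#' @param contrasts n_subjects x n_channels matrix; `NA` for unusable
#'   channels.
#' @param alpha channel-wise significance level.
#' @return data frame: `channel`, `n`, `t`, `p`, `flagged`.
#' @export
channelwise_t <- function(contrasts, alpha = 0.05) {
  V <- as.matrix(contrasts)
  n_ch <- ncol(V)
  res <- lapply(seq_len(n_ch), function(ch) {
    v <- V[, ch]; v <- v[is.finite(v)]
    n <- length(v)
    if (n < 2 || stats::sd(v) == 0)
      return(data.frame(channel = ch, n = n, t = NA_real_, p = NA_real_,
                        flagged = FALSE))
    tval <- mean(v) / (stats::sd(v) / sqrt(n))
    p <- stats::pt(tval, df = n - 1, lower.tail = FALSE)
    data.frame(channel = ch, n = n, t = tval, p = p, flagged = p < alpha)
  })
  out <- do.call(rbind, res)
  if (!is.null(colnames(V))) out$label <- colnames(V)
  out
}

#' Dual voxel/channel significance criterion
#'
#' A finding is labelled `"significant"` only when its voxel cluster meets
#' the corrected criterion (one-tailed p below the voxel threshold with
#' extent at least the calibrated cluster threshold) *and* at least one
#' spatially corresponding channel (within `radius` mm of a cluster member
#' voxel) is channel-wise significant. Channel-level hits whose clusters
#' fail the extent criterion are demoted to `"active"`.
#'
#' @param clusters a `cluster_table` from [threshold_and_cluster()].
#' @param channel_stats output of [channelwise_t()].
#' @param channel_coords n_channels x 3 channel coordinates (mm).
#' @param tmap the `volume_map` the clusters came from (for member lookup).
#' @param grid the `volume_grid`.
#' @param p_thresh,connectivity,adjacency clustering parameters, as used to
#'   build `clusters`.
#' @param radius channel-to-cluster correspondence radius (mm).
#' @return data frame of findings: cluster id, size, peak location/statistic,
#'   matched channel count, `label` in `{"significant", "active"}`. Flagged
#'   channels outside any cluster are appended as channel-only `"active"`
#'   rows with `cluster = NA`.
#' @export
dual_criterion <- function(clusters, channel_stats, channel_coords, tmap,
                           grid = tmap$grid, p_thresh = 0.001,
                           connectivity = 18, radius = 20,
                           adjacency = NULL) {
  if (is.null(adjacency)) adjacency <- grid_adjacency(grid, connectivity)
  supra <- !is.na(tmap$p) & tmap$p < p_thresh
  cc <- cluster_components(supra, adjacency)
  flagged <- channel_stats$channel[channel_stats$flagged %in% TRUE]
  cc_sizes_order <- order(cc$sizes, decreasing = TRUE)

  findings <- list()
  used_channels <- integer(0)
  for (i in seq_len(nrow(clusters))) {
    members <- cc$voxels[cc$membership == cc_sizes_order[clusters$cluster[i]]]
    mcoords <- grid$coords[members, , drop = FALSE]
    near <- vapply(flagged, function(ch) {
      d2 <- rowSums(sweep(mcoords, 2, channel_coords[ch, ])^2)
      any(d2 <= radius^2)
    }, logical(1))
    matched <- flagged[near]
    used_channels <- union(used_channels, matched)
    label <- if (clusters$significant[i] && length(matched) > 0)
      "significant" else "active"
    findings[[length(findings) + 1]] <-
      data.frame(cluster = clusters$cluster[i], size = clusters$size[i],
                 peak_x = clusters$peak_x[i], peak_y = clusters$peak_y[i],
                 peak_z = clusters$peak_z[i], peak_t = clusters$peak_t[i],
                 n_channels = length(matched),
                 channels = paste(matched, collapse = ","), label = label)
  }
  lone <- setdiff(flagged, used_channels)
  for (ch in lone)
    findings[[length(findings) + 1]] <-
      data.frame(cluster = NA_integer_, size = NA_integer_,
                 peak_x = channel_coords[ch, 1],
                 peak_y = channel_coords[ch, 2],
                 peak_z = channel_coords[ch, 3],
                 peak_t = channel_stats$t[channel_stats$channel == ch],
                 n_channels = 1L, channels = as.character(ch),
                 label = "active")
  if (length(findings) == 0)
    return(data.frame(cluster = integer(0), size = integer(0),
                      peak_x = numeric(0), peak_y = numeric(0),
                      peak_z = numeric(0), peak_t = numeric(0),
                      n_channels = integer(0), channels = character(0),
                      label = character(0)))
  out <- do.call(rbind, findings)
  rownames(out) <- NULL
  out
}

#' Fraction of one mask lying inside another
#'
#' `|A intersect B| / |A|` over a shared grid — e.g. the fraction of a
#' cluster's active voxels falling inside an independent meta-analytic mask.
#'
#' @param maskA,maskB logical vectors (or arrays) on the same grid.
#' @return fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(maskA, maskB) {
  a <- as.logical(maskA); b <- as.logical(maskB)
  if (length(a) != length(b)) stop("masks are not on the same grid")
  if (sum(a) == 0) stop("mask A is empty")
  sum(a & b) / sum(a)
}
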