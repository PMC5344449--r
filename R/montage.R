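#' Default 98-channel probe montage
#'
#' Builds a stylized whole-head montage with 30 emitters and 29 detectors
#' arranged at nominal 30 mm spacing, yielding 98 emitter-detector channels
#' covering frontal, temporal and parietal scalp. The layout is a synthetic
#' stand-in for a custom LABNIRS-style cap: a 5 x 11 checkerboard band wrapped
#' around a cylindrical head model (radius 88 mm, centered near the MNI
#' origin) plus a 2 x 2 vertex patch. Within the band, horizontal neighbours
#' are separated by a 29.9 mm chord and vertical neighbours by exactly 30 mm.
#'
#' @param radius head-cylinder radius in mm.
#' @param center xy-center of the head cylinder in MNI mm.
#' @return A `probe_layout` object: lists `emitters` and `detectors` of
#'   labelled 3-D positions (matrices, mm), a 98 x 2 `channel_pairs` matrix of
#'   (emitter, detector) indices, and `fiducials` (nasion, inion, Cz, T3, T4).
#' @export
default_montage <- function(radius = 88, center = c(0, -15)) {
  ## 5 x 11 band: rows are heights, columns azimuths centered on +y (anterior)
  step <- 30
  dtheta <- step / radius                    # arc step along the band
  ncol_band <- 11L; nrow_band <- 5L
  theta <- (seq_len(ncol_band) - (ncol_band + 1) / 2) * dtheta
  z_rows <- seq(-30, by = step, length.out = nrow_band)
  band <- expand.grid(row = seq_len(nrow_band), col = seq_len(ncol_band))
  band_xyz <- cbind(
    x = center[1] + radius * sin(theta[band$col]),
    y = center[2] + radius * cos(theta[band$col]),
    z = z_rows[band$row])
  band_parity <- (band$row + band$col) %% 2L  # checkerboard emitter/detector

  ## 2 x 2 vertex patch, 30 mm spacing
  patch_xyz <- cbind(x = c(-15, 15, -15, 15),
                     y = center[2] + c(-15, -15, 15, 15),
                     z = 108)
  patch_parity <- c(0L, 1L, 1L, 0L)

  xyz <- rbind(band_xyz, patch_xyz)
  parity <- c(band_parity, patch_parity)
  is_emitter <- parity == 0L                 # 28 + 2 emitters, 27 + 2 detectors

  emitters <- xyz[is_emitter, , drop = FALSE]
  detectors <- xyz[!is_emitter, , drop = FALSE]
  rownames(emitters) <- paste0("E", seq_len(nrow(emitters)))
  rownames(detectors) <- paste0("D", seq_len(nrow(detectors)))

  ## channels: all band-grid nearest-neighbour pairs + the 4 patch edges
  node_id <- integer(nrow(xyz))
  node_id[is_emitter] <- seq_len(sum(is_emitter))
  node_id[!is_emitter] <- seq_len(sum(!is_emitter))

  band_index <- matrix(seq_len(nrow_band * ncol_band), nrow_band, ncol_band)
  pairs <- rbind(
    cbind(as.vector(band_index[, -ncol_band]), as.vector(band_index[, -1])),
    cbind(as.vector(band_index[-nrow_band, ]), as.vector(band_index[-1, ])))
  n_band <- nrow_band * ncol_band
  pairs <- rbind(pairs,
                 n_band + cbind(c(1L, 1L, 2L, 3L), c(2L, 3L, 4L, 4L)))

  ## orient every pair as (emitter, detector)
  flip <- parity[pairs[, 1]] == 1L
  pairs[flip, ] <- pairs[flip, c(2, 1)]
  channel_pairs <- cbind(emitter = node_id[pairs[, 1]],
                         detector = node_id[pairs[, 2]])

  fiducials <- rbind(nasion = c(0, 84, -45),
                     inion  = c(0, -110, -30),
                     Cz     = c(0, -14, 98),
                     T3     = c(-82, -16, -50),
                     T4     = c(82, -16, -50))
  colnames(fiducials) <- c("x", "y", "z")

  structure(list(emitters = emitters, detectors = detectors,
                 channel_pairs = channel_pairs, fiducials = fiducials),
            class = "probe_layout")
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf("probe_layout: %d emitters, %d detectors, %d channels\n",
              nrow(x$emitters), nrow(x$detectors), nrow(x$channel_pairs)))
  invisible(x)
}

#' Channel coordinates from optode positions
#'
#' Each channel is located at the midpoint of its emitter and detector.
#'
#' @param layout a `probe_layout`.
#' @return n_channels x 3 matrix of coordinates (mm), rows `CH1..CHn`.
#' @export
channels_from_optodes <- function(layout) {
  p <- layout$channel_pairs
  if (any(p[, 1] > nrow(layout$emitters)) || any(p[, 2] > nrow(layout$detectors)))
    stop("channel pair references a non-existent optode")
  xyz <- (layout$emitters[p[, 1], , drop = FALSE] +
          layout$detectors[p[, 2], , drop = FALSE]) / 2
  rownames(xyz) <- paste0("CH", seq_len(nrow(xyz)))
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

#' Emitter-detector separations
#' @param layout a `probe_layout`.
#' @return numeric vector of channel source-detector distances (mm).
#' @export
channel_separations <- function(layout) {
  p <- layout$channel_pairs
  d <- layout$emitters[p[, 1], , drop = FALSE] -
       layout$detectors[p[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Fiducial-based similarity transform to template space
#'
#' Least-squares similarity (rotation + isotropic scale + translation) mapping
#' subject landmarks onto template landmarks, solved in closed form by the
#' SVD (Kabsch/Umeyama). Used to carry digitized optode positions into MNI
#' space from the nasion/inion/Cz/T3/T4 landmark set.
#'
#' @param subject_fiducials n x 3 matrix of digitized landmarks (mm).
#' @param template_fiducials n x 3 matrix of the same landmarks in MNI (mm).
#' @return list with `rotation` (3 x 3), `scale`, `translation` (length 3),
#'   `affine` (4 x 4 homogeneous matrix) and `rms` landmark residual (mm).
#' @export
fiducial_transform <- function(subject_fiducials, template_fiducials) {
  A <- as.matrix(subject_fiducials); B <- as.matrix(template_fiducials)
  stopifnot(nrow(A) == nrow(B), ncol(A) == 3, ncol(B) == 3)
  if (nrow(A) < 4) stop("need at least 4 landmark pairs")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (qr(A0)$rank < 3)
    stop("landmarks are coplanar or degenerate; similarity fit is singular")
  S <- crossprod(A0, B0)
  sv <- svd(S)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  scale <- sum(diag(D) * sv$d) / sum(A0^2)
  t0 <- cb - scale * as.vector(R %*% ca)
  fitted <- sweep(scale * A %*% t(R), 2, t0, `+`)
  rms <- sqrt(mean(rowSums((fitted - B)^2)))
  affine <- rbind(cbind(scale * R, t0), c(0, 0, 0, 1))
  list(rotation = R, scale = scale, translation = t0, affine = affine,
       rms = rms)
}

#' Apply a fiducial transform to coordinates
#' @param transform result of [fiducial_transform()].
#' @param xyz n x 3 coordinate matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, xyz) {
  xyz <- as.matrix(xyz)
  sweep(transform$scale * xyz %*% t(transform$rotation), 2,
        transform$translation, `+`)
}

#' Register per-subject channel values to the median channel coordinates
#'
#' Computes the component-wise median of each channel's MNI coordinate across
#' subjects, then interpolates every subject's channel values at those median
#' locations by inverse-distance weighting over the subject's `k` nearest
#' channels. Subjects whose montage already sits at the median coordinates are
#' returned unchanged (a channel at zero distance dominates the weights).
#'
#' @param coords_per_subject list of n_channels x 3 coordinate matrices.
#' @param values_per_subject list (or matrix rows) of per-channel values;
#'   `NA` marks unusable (e.g. dead) channels.
#' @param k number of nearest channels in the interpolation stencil.
#' @return list with `median_coords` (n_channels x 3) and `values`
#'   (n_subjects x n_channels matrix of registered values).
#' @export
register_to_median <- function(coords_per_subject, values_per_subject, k = 4) {
  n_sub <- length(coords_per_subject)
  stopifnot(n_sub >= 1)
  if (is.matrix(values_per_subject))
    values_per_subject <- lapply(seq_len(nrow(values_per_subject)),
                                 function(i) values_per_subject[i, ])
  stopifnot(length(values_per_subject) == n_sub)
  n_ch <- nrow(coords_per_subject[[1]])
  arr <- simplify2array(coords_per_subject)       # n_ch x 3 x n_sub
  median_coords <- apply(arr, c(1, 2), stats::median)
  dimnames(median_coords) <- dimnames(coords_per_subject[[1]])

  out <- matrix(NA_real_, n_sub, n_ch)
  for (s in seq_len(n_sub)) {
    co <- coords_per_subject[[s]]
    v <- values_per_subject[[s]]
    usable <- which(is.finite(v))
    if (length(usable) < k)
      stop(sprintf("subject %d has fewer than k=%d usable channels", s, k))
    for (ch in seq_len(n_ch)) {
      d2 <- rowSums(sweep(co[usable, , drop = FALSE], 2,
                          median_coords[ch, ])^2)
      nn <- usable[order(d2)[seq_len(k)]]
      dn <- sqrt(sort(d2)[seq_len(k)])
      if (dn[1] < 1e-9) { out[s, ch] <- v[nn[1]]; next }
      w <- 1 / dn
      out[s, ch] <- sum(w * v[nn]) / sum(w)
    }
  }
  colnames(out) <- rownames(coords_per_subject[[1]])
  list(median_coords = median_coords, values = out)
}

#' Volume grid supported by a channel montage
#'
#' Defines a regular isotropic voxel grid (MNI mm) whose mask is the set of
#' voxels within `mask_distance` of at least one channel — the scalp shell an
#' fNIRS montage is actually sensitive to.
#'
#' @param channel_coords n_channels x 3 matrix of channel MNI coordinates.
#' @param voxel_size isotropic voxel edge in mm.
#' @param mask_distance channel-support radius in mm.
#' @return a `volume_grid`: `origin`, `voxel_size`, `dim`, logical `mask`
#'   (array), `coords` (n_mask x 3 voxel centers), `index` (linear indices of
#'   mask voxels).
#' @export
channel_support_grid <- function(channel_coords, voxel_size = 4,
                                 mask_distance = 20) {
  cc <- as.matrix(channel_coords)
  lo <- floor((apply(cc, 2, min) - mask_distance) / voxel_size) * voxel_size
  hi <- ceiling((apply(cc, 2, max) + mask_distance) / voxel_size) * voxel_size
  ax <- lapply(1:3, function(i) seq(lo[i], hi[i], by = voxel_size))
  dims <- vapply(ax, length, 1L)
  vox <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  ## squared distance from every voxel to its nearest channel
  d2min <- rep(Inf, nrow(vox))
  for (ch in seq_len(nrow(cc))) {
    d2 <- (vox[, 1] - cc[ch, 1])^2 + (vox[, 2] - cc[ch, 2])^2 +
          (vox[, 3] - cc[ch, 3])^2
    d2min <- pmin(d2min, d2)
  }
  keep <- d2min <= mask_distance^2
  mask <- array(keep, dim = dims)
  structure(list(origin = lo, voxel_size = voxel_size, dim = dims,
                 mask = mask, coords = vox[keep, , drop = FALSE],
                 index = which(keep)),
            class = "volume_grid")
}

#' Volume grid from explicit dimensions
#'
#' Low-level constructor used for toy volumes in calibration checks; the mask
#' defaults to the full box.
#'
#' @param dim integer length-3 grid dimensions.
#' @param voxel_size voxel edge in mm.
#' @param origin coordinate of the first voxel center (mm).
#' @param mask optional logical array of `dim`.
#' @return a `volume_grid`.
#' @export
volume_grid <- function(dim, voxel_size = 4, origin = c(0, 0, 0),
                        mask = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3)
  if (is.null(mask)) mask <- array(TRUE, dim = dim)
  ax <- lapply(1:3, function(i) origin[i] + (seq_len(dim[i]) - 1) * voxel_size)
  vox <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  keep <- as.vector(mask)
  structure(list(origin = origin, voxel_size = voxel_size, dim = dim,
                 mask = mask, coords = vox[keep, , drop = FALSE],
                 index = which(keep)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %s @ %g mm, %d voxels in mask\n",
              paste(x$dim, collapse = " x "), x$voxel_size, length(x$index)))
  invisible(x)
}

#' Neighbour edges of mask voxels under a connectivity scheme
#'
#' @param grid a `volume_grid`.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
#' @return 2-column matrix of mask-voxel indices (1..n_mask), each undirected
#'   neighbour pair listed once.
#' @export
grid_adjacency <- function(grid, connectivity = 18) {
  connectivity <- match.arg(as.character(connectivity), c("6", "18", "26"))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nrm <- rowSums(abs(off))
  off <- switch(connectivity,
                "6"  = off[nrm == 1, , drop = FALSE],
                "18" = off[nrm >= 1 & nrm <= 2, , drop = FALSE],
                "26" = off[nrm >= 1, , drop = FALSE])
  ## keep one direction per pair (lexicographically positive offsets)
  pos <- off[, 3] > 0 | (off[, 3] == 0 & (off[, 2] > 0 |
           (off[, 2] == 0 & off[, 1] > 0)))
  off <- off[pos, , drop = FALSE]

  dims <- grid$dim
  pos_in_mask <- integer(prod(dims))            # 0 = outside mask
  pos_in_mask[grid$index] <- seq_along(grid$index)
  idx0 <- grid$index - 1L
  i <- idx0 %% dims[1]
  j <- (idx0 %/% dims[1]) %% dims[2]
  kk <- idx0 %/% (dims[1] * dims[2])

  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(off))) {
    ni <- i + off[r, 1]; nj <- j + off[r, 2]; nk <- kk + off[r, 3]
    ok <- ni >= 0 & ni < dims[1] & nj >= 0 & nj < dims[2] &
          nk >= 0 & nk < dims[3]
    nidx <- ni[ok] + dims[1] * (nj[ok] + dims[2] * nk[ok]) + 1L
    nb <- pos_in_mask[nidx]
    hit <- nb > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nb[hit])
  }
  cbind(from = from, to = to)
}

#' Interpolate channel values onto a volume grid
#'
#' Voxel values are Gaussian-kernel weighted averages of the channel values
#' within the support radius; the weights are normalized per voxel (partition
#' of unity), so a spatially constant channel pattern maps to a constant
#' volume. As `kernel_fwhm` tends to zero each voxel tends to its nearest
#' channel's value.
#'
#' @param channel_values numeric vector (or n_subjects x n_channels matrix).
#' @param channel_coords n_channels x 3 coordinate matrix (mm).
#' @param grid a `volume_grid`.
#' @param kernel_fwhm Gaussian kernel full width at half maximum (mm).
#' @param support_distance kernel support radius (mm); defaults to the grid's
#'   mask distance convention (20 mm).
#' @return numeric vector over mask voxels (or n_subjects x n_mask matrix).
#' @export
channels_to_volume <- function(channel_values, channel_coords, grid,
                               kernel_fwhm = 15, support_distance = 20) {
  W <- interpolation_weights(channel_coords, grid, kernel_fwhm,
                             support_distance)
  if (is.matrix(channel_values)) channel_values %*% W
  else as.vector(channel_values %*% W)
}

#' Channel-to-voxel interpolation weight matrix
#'
#' @inheritParams channels_to_volume
#' @return n_channels x n_mask matrix with columns summing to 1.
#' @export
interpolation_weights <- function(channel_coords, grid, kernel_fwhm = 15,
                                  support_distance = 20) {
  cc <- as.matrix(channel_coords)
  vox <- grid$coords
  sigma <- kernel_fwhm / (2 * sqrt(2 * log(2)))
  D2 <- outer(rowSums(cc^2), rep(1, nrow(vox))) +
        outer(rep(1, nrow(cc)), rowSums(vox^2)) - 2 * cc %*% t(vox)
  D2[D2 < 0] <- 0
  W <- if (kernel_fwhm <= 0) {
    ## nearest-channel limit
    w <- matrix(0, nrow(cc), nrow(vox))
    w[cbind(max.col(-t(D2), ties.method = "first"), seq_len(nrow(vox)))] <- 1
    w
  } else exp(-D2 / (2 * sigma^2))
  W[D2 > support_distance^2] <- 0
  cs <- colSums(W)
  if (any(cs == 0))
    stop("mask voxel with empty channel support; increase support_distance")
  sweep(W, 2, cs, `/`)
}

#' Read Polhemus-style digitizer text
#'
#' Parses plain-text digitizer output with one `label x y z` record per line
#' (whitespace- or colon-delimited, coordinates in mm).
#'
#' @param path file path.
#' @return named matrix of positions (rows = labels).
#' @export
read_polhemus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(gsub(":", " ", lines), "\\s+")
  labs <- vapply(parts, `[`, "", 1)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(xyz)) stop("malformed digitizer line")
  rownames(xyz) <- labs
  colnames(xyz) <- c("x", "y", "z")
  xyz
}
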