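#' Preprocessing configuration
#'
#' @param dead_rms_factor a channel is rejected when the RMS of its raw trace
#'   exceeds this multiple of the across-channel mean RMS.
#' @param lowpass_cutoff low-pass corner frequency (Hz).
#' @param wavelet `"haar"` or `"d4"` (Daubechies-4) for baseline detrending.
#' @param detrend_cutoff highest frequency treated as baseline drift (Hz);
#'   sets the decomposition level of the wavelet detrend.
#' @param pca_mode `"remove_top_k"` or `"uniformity_threshold"` selection of
#'   global spatial components.
#' @param pca_k number of components removed under `remove_top_k`.
#' @param pca_uniformity_threshold spatial-uniformity score (0-1) above which
#'   a component is treated as global.
#' @param downsample_factor integer decimation factor applied after the
#'   low-pass (which doubles as the anti-alias filter).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(dead_rms_factor = 10, lowpass_cutoff = 0.1,
                              wavelet = c("d4", "haar"),
                              detrend_cutoff = 0.01,
                              pca_mode = c("remove_top_k",
                                           "uniformity_threshold"),
                              pca_k = 1, pca_uniformity_threshold = 0.7,
                              downsample_factor = 10) {
  stopifnot(dead_rms_factor > 1, lowpass_cutoff > 0, downsample_factor >= 1,
            pca_k >= 0)
  structure(list(dead_rms_factor = dead_rms_factor,
                 lowpass_cutoff = lowpass_cutoff,
                 wavelet = match.arg(wavelet),
                 detrend_cutoff = detrend_cutoff,
                 pca_mode = match.arg(pca_mode), pca_k = pca_k,
                 pca_uniformity_threshold = pca_uniformity_threshold,
                 downsample_factor = as.integer(downsample_factor)),
            class = "preprocess_config")
}

#' Detect dead channels by the relative-RMS rule
#'
#' A channel is excluded when the root mean square of its raw trace is more
#' than `factor` times the mean RMS over all channels of that recording.
#'
#' @param raw channels x time matrix (a single trace per channel; for
#'   multi-wavelength arrays pass e.g. the wavelength-collapsed trace) or an
#'   `od_recording` (RMS pooled over wavelengths).
#' @param factor exclusion multiple of the mean RMS.
#' @return list `exclude` (logical mask), `rms` (per-channel RMS),
#'   `mean_rms`.
#' @export
detect_dead_channels <- function(raw, factor = 10) {
  if (inherits(raw, "od_recording")) raw <- wavelength_rms(raw)
  raw <- as.matrix(raw)
  if (nrow(raw) < 2) stop("need at least 2 channels")
  rms <- sqrt(rowMeans(raw^2))
  mean_rms <- mean(rms)
  exclude <- rms > factor * mean_rms
  if (all(exclude)) stop("all channels excluded by the RMS rule")
  list(exclude = exclude, rms = rms, mean_rms = mean_rms)
}

## channels x time trace pooled over wavelengths (root mean square)
wavelength_rms <- function(od) {
  d <- dim(od$od)
  acc <- matrix(0, d[1], d[3])
  for (j in seq_len(d[2])) acc <- acc + od$od[, j, ]^2
  sqrt(acc / d[2])
}

## ---- minimal periodized DWT (Haar / Daubechies-4) -------------------------
## Implemented in-package for baseline detrending: decompose, zero the
## approximation at the target level, reconstruct.

wavelet_filters <- function(name) {
  h <- switch(name,
    haar = c(1, 1) / sqrt(2),
    d4 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) /
         (4 * sqrt(2)),
    stop("unknown wavelet ", name))
  g <- rev(h) * (-1)^(seq_along(h) - 1)  # quadrature mirror high-pass
  list(h = h, g = g)
}

dwt_step <- function(x, f) {
  n <- length(x); L <- length(f$h)
  idx <- outer(seq(1, n, by = 2) - 1, seq_len(L) - 1, `+`) %% n + 1
  xm <- matrix(x[idx], ncol = L)
  list(a = as.vector(xm %*% f$h), d = as.vector(xm %*% f$g))
}

idwt_step <- function(a, d, f) {
  n <- 2 * length(a); L <- length(f$h)
  x <- numeric(n)
  pos <- seq(1, n, by = 2)
  for (k in seq_len(L)) {
    tgt <- (pos + k - 2) %% n + 1
    x[tgt] <- x[tgt] + a * f$h[k] + d * f$g[k]
  }
  x
}

#' Remove slow baseline drift by wavelet decomposition
#'
#' Removes the least-squares line (itself baseline), then decomposes each
#' channel with a periodized orthogonal DWT, zeroes the approximation
#' coefficients at the chosen level (everything slower than roughly
#' `fs / 2^(level+1)` Hz), and reconstructs. Line removal keeps the
#' periodized boundary continuous so the wavelet's edge effects stay local.
#' The series is reflection-padded to the next power of two before the
#' transform.
#'
#' @param series numeric vector or channels x time matrix.
#' @param fs sampling rate (Hz); required when `level` is not given.
#' @param level decomposition depth; by default the smallest level whose
#'   approximation band lies below `detrend_cutoff`.
#' @param detrend_cutoff highest frequency regarded as drift (Hz).
#' @param wavelet `"d4"` or `"haar"`.
#' @return detrended series of the input's shape (approximately zero mean).
#' @export
wavelet_detrend <- function(series, fs = NULL, level = NULL,
                            detrend_cutoff = 0.01, wavelet = "d4") {
  if (is.matrix(series))
    return(t(apply(series, 1, wavelet_detrend, fs = fs, level = level,
                   detrend_cutoff = detrend_cutoff, wavelet = wavelet)))
  x <- as.numeric(series)
  n <- length(x)
  if (is.null(level)) {
    if (is.null(fs)) stop("give either fs or level")
    level <- max(1L, ceiling(log2(fs / (2 * detrend_cutoff)) - 1))
  }
  f <- wavelet_filters(wavelet)
  n_pad <- 2^ceiling(log2(n))
  if (n_pad < 2^level) stop("series shorter than 2^level")
  ## least-squares line is slow baseline; removing it also keeps the
  ## periodized signal continuous at the wrap-around
  i <- seq_len(n) - (n + 1) / 2
  x <- x - mean(x) - i * sum(i * x) / sum(i^2)
  pad <- c(x, rev(x)[seq_len(n_pad - n)])

  a <- pad; details <- vector("list", level)
  for (l in seq_len(level)) {
    st <- dwt_step(a, f)
    a <- st$a
    details[[l]] <- st$d
  }
  a <- numeric(length(a))                     # drop the baseline band
  for (l in rev(seq_len(level)))
    a <- idwt_step(a, details[[l]], f)
  a[seq_len(n)]
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`filtfilt`), so the
#' hemodynamic response suffers no phase/latency distortion. The series is
#' mean-centered and reflection-padded by several filter time constants
#' before filtering to suppress edge transients (a DC series passes through
#' unchanged).
#'
#' @param series numeric vector or channels x time matrix.
#' @param fs sampling rate (Hz).
#' @param cutoff corner frequency (Hz); must be below Nyquist.
#' @param order filter order (before the forward-backward pass).
#' @return filtered series of the input's shape.
#' @export
lowpass <- function(series, fs, cutoff = 0.1, order = 4) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  one <- function(v) {
    n <- length(v)
    m <- mean(v)
    v <- v - m
    pad <- min(n - 1, ceiling(3 * fs / cutoff))
    vp <- c(2 * v[1] - v[pad:2], v, 2 * v[n] - v[(n - 1):(n - pad)])
    out <- signal::filtfilt(bf, vp)
    out[pad + seq_len(n)] + m
  }
  if (is.matrix(series)) t(apply(series, 1, one)) else one(series)
}

#' Remove global components with a PCA spatial filter
#'
#' Systemic physiology (cardiac, respiratory, Mayer waves, blood-pressure
#' drift) appears as spatially global variance shared across channels. The
#' spatial principal components of the channel covariance are computed and
#' those designated global are projected out of the data. A component counts
#' as global only when its spatial uniformity score
#' `|mean(v)| * sqrt(n_channels)` (1 for perfectly uniform loadings, ~0.1
#' for a random direction) exceeds the threshold; `remove_top_k` takes the
#' `k` largest-variance such components, `uniformity_threshold` takes all of
#' them. The gate ensures a spatially localized response — however large —
#' is never mistaken for systemic physiology.
#'
#' @param series channels x time matrix.
#' @param mode `"remove_top_k"` or `"uniformity_threshold"`.
#' @param k maximum number of components removed under `remove_top_k`.
#' @param uniformity_threshold spatial-uniformity score above which a
#'   component is eligible for removal.
#' @return list `filtered` (channels x time), `removed` (component time
#'   courses, components x time), `spatial` (channels x components loading
#'   matrix), `uniformity` (score per component).
#' @export
pca_spatial_filter <- function(series, mode = c("remove_top_k",
                                                "uniformity_threshold"),
                               k = 1, uniformity_threshold = 0.7) {
  mode <- match.arg(mode)
  X <- as.matrix(series)                      # channels x time
  n_ch <- nrow(X)
  if (mode == "remove_top_k" && k >= n_ch)
    stop("k must be smaller than the number of channels")
  if (all(X == 0))
    return(list(filtered = X, removed = matrix(0, 0, ncol(X)),
                spatial = matrix(0, n_ch, 0), uniformity = numeric(0)))
  sv <- svd(t(X))                             # time x channels
  V <- sv$v                                   # spatial components (channels)
  uniformity <- abs(colMeans(V)) * sqrt(n_ch)
  global <- which(uniformity > uniformity_threshold)
  sel <- if (mode == "remove_top_k") utils::head(global, k) else global
  if (length(sel) == 0)
    return(list(filtered = X, removed = matrix(0, 0, ncol(X)),
                spatial = V[, 0, drop = FALSE], uniformity = uniformity))
  Vs <- V[, sel, drop = FALSE]
  removed_tc <- t(Vs) %*% X                   # component time courses
  filtered <- X - Vs %*% removed_tc
  list(filtered = filtered, removed = removed_tc, spatial = Vs,
       uniformity = uniformity)
}

#' Decimate a series
#'
#' Keeps every `factor`-th sample; assumes anti-alias filtering (the 0.1 Hz
#' low-pass) has already been applied.
#'
#' @param series numeric vector or channels x time matrix.
#' @param factor integer decimation factor.
#' @return decimated series; attribute `factor`.
#' @export
downsample <- function(series, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  out <- if (is.matrix(series))
    series[, seq(1, ncol(series), by = factor), drop = FALSE]
  else series[seq(1, length(series), by = factor)]
  attr(out, "factor") <- factor
  out
}

#' Residual RMS after HRF deconvolution (QC metric)
#'
#' Regresses each channel on the HRF-convolved design and reports the root
#' mean square of the residual — a per-channel goodness-of-fit quality
#' metric, not a signal transformation.
#'
#' @param series channels x frames matrix.
#' @param design a `design_matrix`.
#' @return numeric vector of residual RMS per channel.
#' @export
hrf_residual_rms <- function(series, design) {
  series <- as.matrix(series)
  X <- design$X
  if (ncol(series) != nrow(X)) stop("series frame count does not match design")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  res <- t(qr.resid(qrX, t(series)))
  sqrt(rowMeans(res^2))
}

#' Run the standard preprocessing chain on one subject
#'
#' Fixed stage order: dead-channel QC on the raw optical densities, MBLL
#' conversion, wavelet detrend, zero-phase 0.1 Hz low-pass, PCA spatial
#' filter, 10-fold downsampling. Dead channels are carried through as `NA`
#' rows and excluded from the PCA. A provenance list records the
#' configuration and per-stage summaries.
#'
#' @param od an `od_recording` (channels x wavelengths x time).
#' @param config a `preprocess_config`.
#' @param ext extinction table for the MBLL step.
#' @param signal chromophore retained for analysis (default deoxyhemoglobin).
#' @param negate_hbr flip the sign of the HbR series so that activation
#'   (an HbR decrease) maps to positive effects.
#' @return list `series` (channels x frames analysis matrix, `NA` rows for
#'   dead channels), `frame_times`, `sample_period`, `dead` (QC result),
#'   `hemo` (full `hemo_series` post-filtering), `removed` (PCA component
#'   time courses), `provenance`.
#' @export
preprocess_subject <- function(od, config = preprocess_config(),
                               ext = extinction_table(),
                               signal = c("hbr", "hbo"), negate_hbr = TRUE) {
  signal <- match.arg(signal)
  fs <- 1 / od$sample_period

  dead <- detect_dead_channels(od, factor = config$dead_rms_factor)

  hemo <- mbll_invert(od, ext)
  x <- if (signal == "hbr" && negate_hbr) -hemo$hbr else hemo[[signal]]
  good <- which(!dead$exclude)

  xg <- x[good, , drop = FALSE]
  xg <- wavelet_detrend(xg, fs = fs, detrend_cutoff = config$detrend_cutoff,
                        wavelet = config$wavelet)
  xg <- lowpass(xg, fs = fs, cutoff = config$lowpass_cutoff)
  pf <- pca_spatial_filter(xg, mode = config$pca_mode, k = config$pca_k,
                           uniformity_threshold =
                             config$pca_uniformity_threshold)
  xg <- downsample(pf$filtered, config$downsample_factor)

  out <- matrix(NA_real_, nrow(x), ncol(xg))
  out[good, ] <- xg
  sp <- od$sample_period * config$downsample_factor
  frame_times <- (seq_len(ncol(out)) - 1) * sp
  provenance <- list(config = unclass(config), n_dead = sum(dead$exclude),
                     signal = signal, negate_hbr = negate_hbr,
                     sample_period = sp,
                     stages = c("dead_qc", "mbll", "wavelet_detrend",
                                "lowpass", "pca_filter", "downsample"))
  list(series = out, frame_times = frame_times, sample_period = sp,
       dead = dead, hemo = hemo, removed = pf$removed,
       provenance = provenance)
}
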