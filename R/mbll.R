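#' Molar extinction coefficients for HbO/HbR
#'
#' Bundled tabulation of hemoglobin molar extinction coefficients
#' (Gratzer/Kollias compilation as distributed by OMLC), interpolated at the
#' requested wavelengths and converted from cm^-1/M to per-(uM*mm), the unit
#' convention used throughout: with concentration changes in uM and an
#' effective pathlength in mm, `OD = eps * conc * pathlength`. The
#' differential pathlength factor is folded into the reported units, so
#' concentrations are relative (uM-equivalent), not absolute.
#'
#' 805 nm sits near the isosbestic point where the HbO and HbR coefficients
#' nearly coincide.
#'
#' @param wavelengths wavelengths in nm (default the LABNIRS triplet).
#' @return an `extinction_table`: `wavelengths`, and an `eps` matrix with
#'   rows HbO, HbR (per uM per mm).
#' @export
extinction_table <- function(wavelengths = c(780, 805, 830)) {
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  ## Gratzer/Kollias values, cm^-1/M, on a coarse NIR support grid
  tab_nm <- c(750, 760, 770, 780, 790, 800, 805, 810, 820, 830, 840, 850)
  tab_hbo <- c(518, 586, 650, 710, 756, 816, 844, 864, 916, 974, 1022, 1058)
  tab_hbr <- c(1405, 1548, 1311, 1075, 952, 842, 810, 782, 744, 693, 673, 692)
  if (any(wavelengths < min(tab_nm) | wavelengths > max(tab_nm)))
    stop("wavelength outside bundled extinction range (750-850 nm)")
  cmM_to_uMmm <- 1e-7                       # cm^-1 M^-1 -> mm^-1 uM^-1
  eps <- rbind(
    HbO = stats::approx(tab_nm, tab_hbo, wavelengths)$y,
    HbR = stats::approx(tab_nm, tab_hbr, wavelengths)$y) * cmM_to_uMmm
  colnames(eps) <- paste0(wavelengths, "nm")
  if (length(wavelengths) >= 2) {
    cn <- kappa(eps, exact = TRUE)
    if (!is.finite(cn)) stop("extinction matrix is rank deficient")
  }
  structure(list(wavelengths = wavelengths, eps = eps),
            class = "extinction_table")
}

#' Optical density changes from raw intensity
#'
#' `dOD(t) = -log10(I(t) / mean(I[baseline]))` per channel and wavelength.
#' Non-positive intensities are flagged and produce `NA` samples with a QC
#' warning rather than aborting, matching how acquisition dropouts are
#' handled upstream of dead-channel rejection.
#'
#' @param intensity channels x wavelengths x time array (or channels x time
#'   matrix for a single wavelength) of raw detector intensities.
#' @param baseline integer sample window used for the reference intensity
#'   (default the whole recording).
#' @param sample_period sampling interval in seconds.
#' @return an `od_recording`: `od` array with the input's shape,
#'   `sample_period`, `baseline`, and `flagged` (channel/wavelength pairs with
#'   non-positive samples).
#' @export
od_from_intensity <- function(intensity, baseline = NULL,
                              sample_period = 0.027) {
  if (is.matrix(intensity))
    intensity <- array(intensity, dim = c(nrow(intensity), 1, ncol(intensity)))
  d <- dim(intensity)
  if (is.null(baseline)) baseline <- seq_len(d[3])
  bad <- intensity <= 0
  if (any(bad)) {
    intensity[bad] <- NA_real_
    idx <- unique(which(bad, arr.ind = TRUE)[, 1:2, drop = FALSE])
    warning(sprintf("%d channel/wavelength traces contain non-positive samples",
                    nrow(idx)))
  } else idx <- matrix(integer(0), 0, 2)
  iref <- apply(intensity[, , baseline, drop = FALSE], c(1, 2), mean,
                na.rm = TRUE)
  if (any(!is.finite(iref) | iref <= 0))
    stop("baseline window has non-positive mean intensity")
  od <- -log10(sweep(intensity, c(1, 2), iref, `/`))
  structure(list(od = od, sample_period = sample_period, baseline = baseline,
                 flagged = idx),
            class = "od_recording")
}

#' Concentration changes via the modified Beer-Lambert law
#'
#' Solves, independently at every channel and time point, the linear MBLL
#' system `dOD(lambda) = pathlength * [eps_HbO(lambda) dHbO +
#' eps_HbR(lambda) dHbR]` for the chromophore concentration changes by least
#' squares over the measured wavelengths (with 3 wavelengths and 2
#' chromophores this is the normal-equations solution).
#'
#' @param od an `od_recording` or a channels x wavelengths x time array.
#' @param ext an `extinction_table` covering the recorded wavelengths.
#' @param pathlength effective optical pathlength in mm (default 1: pathlength
#'   folded into the relative concentration units).
#' @param sample_period sampling interval (s), used when `od` is a bare array.
#' @return a `hemo_series`: channels x time matrices `hbo` and `hbr`
#'   (uM-equivalent), plus `sample_period`.
#' @export
mbll_invert <- function(od, ext = extinction_table(), pathlength = 1,
                        sample_period = 0.027) {
  if (inherits(od, "od_recording")) {
    sample_period <- od$sample_period
    od <- od$od
  }
  d <- dim(od)
  if (length(d) != 3) stop("od must be channels x wavelengths x time")
  if (d[2] != length(ext$wavelengths))
    stop("wavelength count does not match extinction table")
  if (d[2] < 2) stop("need at least 2 wavelengths to separate HbO and HbR")
  E <- t(ext$eps) * pathlength              # n_lambda x 2
  pinv <- solve(crossprod(E), t(E))         # 2 x n_lambda
  n_ch <- d[1]; n_t <- d[3]
  hbo <- matrix(NA_real_, n_ch, n_t)
  hbr <- matrix(NA_real_, n_ch, n_t)
  for (ch in seq_len(n_ch)) {
    conc <- pinv %*% od[ch, , ]             # 2 x time
    hbo[ch, ] <- conc[1, ]
    hbr[ch, ] <- conc[2, ]
  }
  hemo_series(hbo, hbr, sample_period)
}

#' Construct a hemodynamic time-series container
#'
#' @param hbo,hbr channels x time matrices of concentration changes
#'   (uM-equivalent).
#' @param sample_period sampling interval in seconds.
#' @return a `hemo_series` object.
#' @export
hemo_series <- function(hbo, hbr, sample_period) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  stopifnot(identical(dim(hbo), dim(hbr)), sample_period > 0)
  structure(list(hbo = hbo, hbr = hbr, sample_period = sample_period),
            class = "hemo_series")
}

#' @export
print.hemo_series <- function(x, ...) {
  cat(sprintf("hemo_series: %d channels x %d samples @ %g s\n",
              nrow(x$hbo), ncol(x$hbo), x$sample_period))
  invisible(x)
}

#' Forward optical model: concentrations to optical density
#'
#' Inverse companion of [mbll_invert()]: projects chromophore concentration
#' changes back to multi-wavelength optical-density changes,
#' `dOD(lambda, t) = [eps_HbO(lambda) dHbO(t) + eps_HbR(lambda) dHbR(t)] *
#' pathlength`. Used by the synthetic-data generator so that the full
#' optics-to-inference pipeline can be exercised against known ground truth.
#'
#' @param hemo a `hemo_series`.
#' @param ext an `extinction_table`.
#' @param pathlength effective pathlength in mm.
#' @return an `od_recording` with channels x wavelengths x time `od`.
#' @export
forward_mbll <- function(hemo, ext = extinction_table(), pathlength = 1) {
  E <- t(ext$eps) * pathlength              # n_lambda x 2
  n_ch <- nrow(hemo$hbo); n_t <- ncol(hemo$hbo); n_l <- nrow(E)
  od <- array(NA_real_, dim = c(n_ch, n_l, n_t))
  for (ch in seq_len(n_ch))
    od[ch, , ] <- E %*% rbind(hemo$hbo[ch, ], hemo$hbr[ch, ])
  structure(list(od = od, sample_period = hemo$sample_period,
                 baseline = NULL, flagged = matrix(integer(0), 0, 2)),
            class = "od_recording")
}
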