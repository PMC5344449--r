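#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities parameterized by their modes: the
#' response peaks at `peak_delay` seconds and the undershoot at
#' `undershoot_delay` seconds, with the undershoot scaled by
#' `1/peak_undershoot_ratio`. The kernel is normalized to unit peak so that a
#' regression coefficient is expressed in the signal's own units.
#'
#' @param dt sampling interval (s).
#' @param peak_delay time-to-peak of the positive lobe (s).
#' @param undershoot_delay time-to-trough of the undershoot (s).
#' @param peak_dispersion,undershoot_dispersion gamma scale parameters (s).
#' @param peak_undershoot_ratio peak:undershoot amplitude ratio.
#' @param length_out kernel duration (s).
#' @return numeric kernel sampled at `dt`, first sample at t = 0.
#' @export
canonical_hrf <- function(dt, peak_delay = 6, undershoot_delay = 16,
                          peak_dispersion = 1, undershoot_dispersion = 1,
                          peak_undershoot_ratio = 6, length_out = 32) {
  stopifnot(dt > 0, peak_delay > 0, undershoot_delay > peak_delay,
            peak_dispersion > 0, undershoot_dispersion > 0,
            peak_undershoot_ratio > 0)
  t <- seq(0, length_out, by = dt)
  ## gamma with scale s and mode m has shape m/s + 1
  g <- function(t, mode, scale)
    stats::dgamma(t, shape = mode / scale + 1, scale = scale)
  h <- g(t, peak_delay, peak_dispersion) -
       g(t, undershoot_delay, undershoot_dispersion) / peak_undershoot_ratio
  h / max(h)
}

#' HRF-convolved design matrix from an event schedule
#'
#' One boxcar regressor per (task, congruency) condition present in the
#' schedule — oddball trials contribute to their own congruency — convolved
#' with the canonical HRF on a fine internal grid and sampled at the frame
#' times of the (possibly downsampled) series, plus a constant column.
#' Condition columns are scaled so that an isolated trial's response peaks at
#' 1; a regression coefficient is therefore the peak single-trial response in
#' the signal's own units, and a zero-duration (stick) event reproduces the
#' unit-peak HRF exactly.
#'
#' @param schedule an `event_schedule` (see [generate_event_schedule()]) or
#'   any data frame with `onset`, `task`, `congruency` columns.
#' @param frame_times numeric vector of frame acquisition times (s).
#' @param trial_duration event boxcar duration (s); the stimulus epoch.
#' @param hrf_args list of overrides passed to [canonical_hrf()].
#' @param oddballs `"own"` (default: oddballs keep their own congruency) or
#'   `"exclude"` (dropped from the design).
#' @return a `design_matrix`: numeric matrix `X` (frames x regressors),
#'   `frame_times`, `condition_cols` (names of non-constant columns).
#' @export
build_design <- function(schedule, frame_times, trial_duration = 1.5,
                         hrf_args = list(), oddballs = c("own", "exclude")) {
  oddballs <- match.arg(oddballs)
  ev <- as.data.frame(schedule)
  if (oddballs == "exclude" && "is_oddball" %in% names(ev))
    ev <- ev[!ev$is_oddball, , drop = FALSE]
  stopifnot(length(frame_times) >= 2)
  if (nrow(ev) > 0 && any(ev$onset > max(frame_times)))
    stop("event onset beyond the last frame")

  dt <- 0.05                                   # fine grid for convolution
  t_hi <- seq(0, max(frame_times) + trial_duration + 32, by = dt)
  hrf <- do.call(canonical_hrf, c(list(dt = dt), hrf_args))

  ## peak of one isolated trial's response; unit-peak scaling of the columns
  n_box <- max(1L, round(trial_duration / dt))
  trial_peak <- max(stats::convolve(c(rep(1, n_box),
                                      numeric(length(hrf) + n_box)),
                                    rev(hrf), type = "open"))

  cols <- list()
  if (nrow(ev) > 0) {
    cond <- interaction(ev$task, ev$congruency, sep = ":", drop = TRUE)
    for (cn in levels(cond)) {
      onsets <- ev$onset[cond == cn]
      box <- numeric(length(t_hi))
      for (o in onsets)
        box[t_hi >= o & t_hi < o + trial_duration] <- 1
      conv <- stats::convolve(box, rev(hrf),
                              type = "open")[seq_along(t_hi)] / trial_peak
      cols[[cn]] <- stats::approx(t_hi, conv, xout = frame_times,
                                  rule = 2)$y
    }
  }
  X <- cbind(do.call(cbind, cols), constant = 1)
  colnames(X) <- c(names(cols), "constant")
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient")
  structure(list(X = X, frame_times = frame_times,
                 condition_cols = names(cols)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d frames x %d regressors (%s)\n",
              nrow(x$X), ncol(x$X), paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

#' Per-channel ordinary least squares fit
#'
#' Fits every channel's series on the HRF-convolved design by OLS, returning
#' effect estimates, residual variance and degrees of freedom — the
#' first-level beta map for one subject.
#'
#' @param series channels x frames numeric matrix, or a `hemo_series` (the
#'   `signal` chromophore is used).
#' @param design a `design_matrix` whose frames match the series.
#' @param signal which chromophore to analyze when `series` is a
#'   `hemo_series`; deoxyhemoglobin is the default analysis signal as it is
#'   less contaminated by systemic physiology.
#' @return a `beta_map`: `beta` (channels x regressors), `sigma2` (residual
#'   variance per channel), `df`, `design` reference.
#' @export
fit_glm <- function(series, design, signal = c("hbr", "hbo")) {
  if (inherits(series, "hemo_series")) {
    signal <- match.arg(signal)
    series <- series[[signal]]
  }
  series <- as.matrix(series)
  X <- design$X
  if (ncol(series) != nrow(X))
    stop("series frame count does not match design")
  if (anyNA(series)) stop("series contains NA; run QC/preprocessing first")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  beta <- t(qr.coef(qrX, t(series)))           # channels x regressors
  fitted <- beta %*% t(X)
  res <- series - fitted
  df <- nrow(X) - qrX$rank
  if (df <= 0) stop("no residual degrees of freedom")
  sigma2 <- rowSums(res^2) / df
  colnames(beta) <- colnames(X)
  structure(list(beta = beta, sigma2 = sigma2, df = df,
                 XtXinv = chol2inv(qr.R(qrX)), design = design),
            class = "beta_map")
}

#' Named contrast weight vectors
#'
#' Presets over the four task-by-congruency regressors:
#' `"I>C"` — incongruent minus congruent, summed across the gesture and color
#' tasks; `"G>C"` — gesture minus color, summed across congruencies. Columns
#' absent from the fitted design (e.g. a single-task run) receive their
#' weight only if present.
#'
#' @param beta a `beta_map`.
#' @param preset `"I>C"` or `"G>C"`.
#' @return named numeric weight vector over the design's regressors.
#' @export
contrast_weights <- function(beta, preset = c("I>C", "G>C")) {
  preset <- match.arg(preset)
  cols <- colnames(beta$beta)
  w <- stats::setNames(numeric(length(cols)), cols)
  tk <- sub(":.*$", "", cols)
  cg <- sub("^.*:", "", cols)
  cond <- cols != "constant"
  if (preset == "I>C") {
    w[cond & cg == "incongruent"] <- 1
    w[cond & cg == "congruent"] <- -1
  } else {
    w[cond & tk == "gesture"] <- 1
    w[cond & tk == "color"] <- -1
  }
  w
}

#' Linear contrast of GLM effects
#'
#' @param beta a `beta_map`.
#' @param weights named numeric vector over regressors, or a preset name
#'   accepted by [contrast_weights()].
#' @return list with `value` (per-channel contrast), `variance` (its OLS
#'   sampling variance per channel), `df`, `weights`.
#' @export
contrast <- function(beta, weights) {
  if (is.character(weights) && length(weights) == 1)
    weights <- contrast_weights(beta, weights)
  cols <- colnames(beta$beta)
  if (is.null(names(weights))) {
    if (length(weights) != length(cols))
      stop("unnamed weight vector must match regressor count")
    names(weights) <- cols
  }
  if (!all(names(weights) %in% cols))
    stop("unknown regressor in contrast weights: ",
         paste(setdiff(names(weights), cols), collapse = ", "))
  w <- stats::setNames(numeric(length(cols)), cols)
  w[names(weights)] <- weights
  value <- as.vector(beta$beta %*% w)
  variance <- beta$sigma2 * as.numeric(t(w) %*% beta$XtXinv %*% w)
  list(value = value, variance = variance, df = beta$df, weights = w)
}
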