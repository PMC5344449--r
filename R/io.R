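#' Write a BIDS-style events table
#'
#' Columns `onset`, `duration`, `trial_type` (`task:congruency`),
#' `is_oddball`, `block`, tab-separated.
#'
#' @param schedule an `event_schedule`.
#' @param path output file.
#' @param duration stimulus duration (s).
#' @export
write_events_tsv <- function(schedule, path, duration = 1.5) {
  df <- data.frame(onset = schedule$onset, duration = duration,
                   trial_type = paste(schedule$task, schedule$congruency,
                                      sep = ":"),
                   is_oddball = schedule$is_oddball,
                   block = schedule$block_index)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events table
#' @param path events TSV.
#' @return an `event_schedule`-compatible data frame.
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path)
  parts <- strsplit(df$trial_type, ":", fixed = TRUE)
  out <- data.frame(onset = df$onset,
                    task = vapply(parts, `[`, "", 1),
                    congruency = vapply(parts, `[`, "", 2),
                    is_oddball = as.logical(df$is_oddball),
                    block_index = df$block)
  class(out) <- c("event_schedule", "data.frame")
  out
}

#' Write a multichannel recording as plain-text matrices
#'
#' Portable plain-text serialization of a channels x wavelengths x time
#' optical-density recording: one TSV matrix per wavelength
#' (`<stem>_od_<wl>.tsv`, channels in rows) plus a JSON sidecar with the
#' sampling metadata.
#'
#' @param od an `od_recording`.
#' @param stem output path stem.
#' @param wavelengths wavelengths (nm) used in file naming.
#' @return character vector of written paths.
#' @export
write_od_tsv <- function(od, stem, wavelengths = c(780, 805, 830)) {
  d <- dim(od$od)
  stopifnot(d[2] == length(wavelengths))
  paths <- character(0)
  for (j in seq_len(d[2])) {
    p <- sprintf("%s_od_%d.tsv", stem, wavelengths[j])
    utils::write.table(od$od[, j, ], p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  side <- sprintf("%s_od.json", stem)
  jsonlite::write_json(list(sample_period = od$sample_period,
                            wavelengths = wavelengths,
                            n_channels = d[1], n_samples = d[3]),
                       side, auto_unbox = TRUE, digits = NA)
  c(paths, side)
}

#' Read a recording written by [write_od_tsv()]
#' @param stem path stem used at write time.
#' @return an `od_recording`.
#' @export
read_od_tsv <- function(stem) {
  meta <- jsonlite::read_json(sprintf("%s_od.json", stem),
                              simplifyVector = TRUE)
  od <- array(NA_real_, c(meta$n_channels, length(meta$wavelengths),
                          meta$n_samples))
  for (j in seq_along(meta$wavelengths)) {
    p <- sprintf("%s_od_%d.tsv", stem, meta$wavelengths[j])
    od[, j, ] <- as.matrix(utils::read.delim(p, header = FALSE))
  }
  structure(list(od = od, sample_period = meta$sample_period,
                 baseline = NULL, flagged = matrix(integer(0), 0, 2)),
            class = "od_recording")
}

#' Write concentration series in long format
#'
#' Tidy TSV with columns `channel`, `time`, `chromophore`, `value`.
#'
#' @param hemo a `hemo_series`.
#' @param path output file.
#' @export
write_hemo_tsv <- function(hemo, path) {
  n_ch <- nrow(hemo$hbo); n_t <- ncol(hemo$hbo)
  tt <- (seq_len(n_t) - 1) * hemo$sample_period
  df <- data.frame(
    channel = rep(rep(seq_len(n_ch), each = n_t), 2),
    time = rep(rep(tt, n_ch), 2),
    chromophore = rep(c("HbO", "HbR"), each = n_ch * n_t),
    value = c(as.vector(t(hemo$hbo)), as.vector(t(hemo$hbr))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write channel coordinates as TSV
#' @param coords n x 3 labelled coordinate matrix (mm).
#' @param path output file.
#' @export
write_channel_coords <- function(coords, path) {
  df <- data.frame(channel = rownames(coords), coords)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a volume map as NIfTI
#'
#' Serializes mask-restricted voxel values back into their full 3-D box and
#' writes an MNI/RAS-mm NIfTI volume (requires the `RNifti` package).
#'
#' @param values numeric vector over the grid's mask voxels.
#' @param grid a `volume_grid`.
#' @param path output `.nii`/`.nii.gz` file.
#' @param background value outside the mask.
#' @export
write_volume_nifti <- function(values, grid, path, background = 0) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required to write NIfTI volumes")
  vol <- array(background, dim = grid$dim)
  vol[grid$index] <- values
  vs <- grid$voxel_size
  xform <- rbind(c(vs, 0, 0, grid$origin[1]),
                 c(0, vs, 0, grid$origin[2]),
                 c(0, 0, vs, grid$origin[3]),
                 c(0, 0, 0, 1))
  img <- RNifti::asNifti(vol)
  RNifti::qform(img) <- structure(xform, code = 4L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
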