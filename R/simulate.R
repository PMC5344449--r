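#' Simulation configuration for a conflict-paradigm fNIRS study
#'
#' Collects the study-design constants of the block paradigm (twelve 15 s
#' task blocks alternating with 15 s rest, four trials per block at an ISI of
#' 3.75 s, one oddball per block), the acquisition constants (98 channels,
#' 27 ms sampling, three wavelengths), the forward hemodynamic model
#' (HRF-convolved condition effects in designated channels, global systemic
#' oscillations, slow drift, white noise, dead channels, an HbR response that
#' is a scaled mirror of the HbO response), and the behavioral reaction-time
#' model.
#'
#' @param n_subjects number of simulated participants.
#' @param seed integer seed; fully determines all generated outputs.
#' @param sample_period acquisition sampling interval (s).
#' @param n_blocks task blocks per run.
#' @param block_duration,rest_duration block and rest lengths (s).
#' @param isi inter-stimulus interval within a block (s).
#' @param trials_per_block trials per task block.
#' @param tasks character vector of tasks simulated per subject.
#' @param n_channels number of acquisition channels.
#' @param active_channels data frame with columns `channel`, `condition`,
#'   `amplitude` designating ground-truth effects (uM-equivalent HbO
#'   amplitude). `condition` may be a task (`"gesture"`), a congruency
#'   (`"incongruent"`), a `task:congruency` pair, or `"all"`.
#' @param systemic list of global-component parameters: `cardiac`, `resp`,
#'   `mayer` as `c(amp =, freq =)` (uM-equivalent, Hz) and `drift_amp`
#'   (uM-equivalent peak-scale slow drift).
#' @param noise_sd white measurement noise SD per channel (uM-equivalent).
#' @param response_sd between-subject SD of the per-channel, per-condition
#'   HbO response amplitude (uM-equivalent), drawn independently for every
#'   channel and condition of each subject and added to the nominal
#'   amplitudes. This is the individual-differences variance component that
#'   makes group-level t statistics realistic; with it at zero every subject
#'   responds identically and group t values are bounded only by
#'   measurement noise.
#' @param dead_channels channel indices rendered as broken
#'   (high-amplitude garbage traces).
#' @param hbr_to_hbo_ratio scaling of the noiseless HbR response relative to
#'   HbO; negative (default -1/3), since deoxyhemoglobin falls when
#'   oxyhemoglobin rises and its response is typically smaller.
#' @param rt_params per-task reaction-time model: lognormal trial RTs with
#'   congruent mean `mean` (s), incongruency delay `delta` (s), within-subject
#'   trial SD `sd_trial`, between-subject SD `sd_subject`, and response
#'   `accuracy`.
#' @param trial_duration stimulus epoch length used for the forward
#'   regressors (s).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects = 31, seed = 1, sample_period = 0.027,
                       n_blocks = 12, block_duration = 15, rest_duration = 15,
                       isi = 3.75, trials_per_block = 4,
                       tasks = c("gesture", "color"), n_channels = 98,
                       active_channels = NULL,
                       systemic = list(cardiac = c(amp = 0.2, freq = 1.1),
                                       resp = c(amp = 0.3, freq = 0.25),
                                       mayer = c(amp = 0.4, freq = 0.095),
                                       drift_amp = 0.5),
                       noise_sd = 1, response_sd = 1,
                       dead_channels = integer(0),
                       hbr_to_hbo_ratio = -1/3,
                       rt_params = list(
                         gesture = list(mean = 1.365, delta = 0.040,
                                        sd_trial = 0.25, sd_subject = 0.15,
                                        accuracy = 0.982),
                         color = list(mean = 0.658, delta = 0.106,
                                      sd_trial = 0.20, sd_subject = 0.15,
                                      accuracy = 0.987)),
                       trial_duration = 1.5) {
  if (trials_per_block * isi > block_duration)
    stop("trials_per_block * isi exceeds block_duration")
  stopifnot(n_blocks %% 2 == 0, sample_period > 0, noise_sd >= 0,
            n_channels >= 1)
  if (is.null(active_channels))
    active_channels <- data.frame(channel = integer(0),
                                  condition = character(0),
                                  amplitude = numeric(0))
  structure(list(n_subjects = n_subjects, seed = seed,
                 sample_period = sample_period, n_blocks = n_blocks,
                 block_duration = block_duration,
                 rest_duration = rest_duration, isi = isi,
                 trials_per_block = trials_per_block, tasks = tasks,
                 n_channels = n_channels, active_channels = active_channels,
                 systemic = systemic, noise_sd = noise_sd,
                 response_sd = response_sd,
                 dead_channels = dead_channels,
                 hbr_to_hbo_ratio = hbr_to_hbo_ratio, rt_params = rt_params,
                 trial_duration = trial_duration,
                 run_length = n_blocks * (block_duration + rest_duration)),
            class = "sim_config")
}

## evaluate code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  ge <- globalenv()
  old <- if (exists(".Random.seed", envir = ge, inherits = FALSE))
    get(".Random.seed", envir = ge) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = ge, inherits = FALSE))
        rm(".Random.seed", envir = ge)
    } else assign(".Random.seed", old, envir = ge)
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

#' Generate a block/trial event schedule
#'
#' Produces the trial timing of one run: `n_blocks` alternating task/rest
#' blocks, `trials_per_block` trials per block at the configured ISI, half the
#' blocks congruent-dominant and half incongruent-dominant (random order),
#' and exactly one oddball trial per block — a trial of the opposite
#' congruency at a uniformly random slot, breaking repetition effects.
#' Gesture trials carry randomized nuisance attributes (actor gender, gesture
#' type) that have no hemodynamic effect.
#'
#' @param config a `sim_config`.
#' @param task task id, one of `config$tasks`.
#' @param seed optional seed override (default `config$seed`).
#' @return an `event_schedule` data frame: `onset`, `task`, `congruency`,
#'   `is_oddball`, `block_index`, `block_dominance`, `actor_gender`,
#'   `gesture_type`; attribute `run_length` (s).
#' @export
generate_event_schedule <- function(config, task = config$tasks[1],
                                    seed = config$seed) {
  task <- match.arg(task, config$tasks)
  with_seed(seed, {
    nb <- config$n_blocks; tpb <- config$trials_per_block
    dominance <- sample(rep(c("congruent-dominant", "incongruent-dominant"),
                            each = nb / 2))
    oddball_slot <- sample.int(tpb, nb, replace = TRUE)
    block_onset <- (seq_len(nb) - 1) * (config$block_duration +
                                        config$rest_duration)
    trials <- do.call(rbind, lapply(seq_len(nb), function(b) {
      dom <- sub("-dominant", "", dominance[b])
      opp <- if (dom == "congruent") "incongruent" else "congruent"
      congr <- rep(dom, tpb)
      congr[oddball_slot[b]] <- opp
      data.frame(onset = block_onset[b] + (seq_len(tpb) - 1) * config$isi,
                 task = task, congruency = congr,
                 is_oddball = seq_len(tpb) == oddball_slot[b],
                 block_index = b, block_dominance = dominance[b])
    }))
    n <- nrow(trials)
    trials$actor_gender <- if (task == "gesture")
      sample(c("female", "male"), n, replace = TRUE) else NA_character_
    trials$gesture_type <- if (task == "gesture")
      sample(c("head", "hand"), n, replace = TRUE) else NA_character_
    attr(trials, "run_length") <- config$run_length
    class(trials) <- c("event_schedule", "data.frame")
    trials
  })
}

## match active_channels condition strings against design condition columns
condition_amplitudes <- function(config, condition_cols) {
  amp <- matrix(0, config$n_channels, length(condition_cols),
                dimnames = list(NULL, condition_cols))
  ac <- config$active_channels
  for (i in seq_len(nrow(ac))) {
    cond <- ac$condition[i]
    hit <- if (cond == "all") rep(TRUE, length(condition_cols))
    else condition_cols == cond |
      sub(":.*$", "", condition_cols) == cond |
      sub("^.*:", "", condition_cols) == cond
    amp[ac$channel[i], hit] <- amp[ac$channel[i], hit] + ac$amplitude[i]
  }
  amp
}

#' Ground-truth hemodynamic series for a schedule
#'
#' Forward model for one subject's run: per channel,
#' `HbO = sum(condition regressor (*) HRF) * amplitude + drift + systemic +
#' noise`, where the amplitudes are the configured nominal effects plus the
#' subject's between-subject response deviations (`response_sd`), the
#' systemic cardiac/respiratory/Mayer oscillations are shared across
#' channels with per-channel gains near 1 (global components — the target of
#' the PCA spatial filter), and the drift is a slow random channel-specific
#' baseline. `HbR` is `hbr_to_hbo_ratio` times the noiseless HbO component
#' plus independent noise of the same SD.
#'
#' @param schedule an `event_schedule`.
#' @param config a `sim_config`.
#' @param seed optional seed override.
#' @return a `hemo_series` with attributes `truth` (channels x condition
#'   amplitude matrix) and `frame_times`.
#' @export
generate_hemo_truth <- function(schedule, config, seed = config$seed) {
  run <- attr(schedule, "run_length")
  if (any(schedule$onset >= run)) stop("schedule onset beyond run length")
  with_seed(seed, {
    tt <- seq(0, run - config$sample_period, by = config$sample_period)
    n_t <- length(tt); n_ch <- config$n_channels

    des <- build_design(schedule, tt, trial_duration = config$trial_duration)
    cond_cols <- des$condition_cols
    amp <- condition_amplitudes(config, cond_cols)
    ## realized amplitudes: nominal effect + between-subject response
    ## variability, independent per channel and condition
    amp_real <- amp + matrix(stats::rnorm(length(amp), 0,
                                          config$response_sd),
                             nrow(amp), ncol(amp))
    task_sig <- if (length(cond_cols) > 0)
      amp_real %*% t(des$X[, cond_cols, drop = FALSE])
    else matrix(0, n_ch, n_t)

    sy <- config$systemic
    systemic <- matrix(0, n_ch, n_t)
    for (nm in c("cardiac", "resp", "mayer")) {
      p <- sy[[nm]]
      if (is.null(p) || p[["amp"]] == 0) next
      g <- p[["amp"]] * sin(2 * pi * p[["freq"]] * tt + stats::runif(1, 0, 2 * pi))
      gain <- 1 + stats::rnorm(n_ch, 0, 0.1)
      systemic <- systemic + gain %o% g
    }
    drift <- matrix(0, n_ch, n_t)
    if (!is.null(sy$drift_amp) && sy$drift_amp > 0) {
      slope <- stats::rnorm(n_ch, 0, sy$drift_amp)
      phase <- stats::runif(n_ch, 0, 2 * pi)
      amp2 <- stats::rnorm(n_ch, 0, sy$drift_amp / 2)
      drift <- slope %o% (tt / run) +
               (amp2 %o% rep(1, n_t)) *
               sin(rep(1, n_ch) %o% (2 * pi * tt / run) +
                   phase %o% rep(1, n_t))
    }
    clean_hbo <- task_sig + systemic + drift
    hbo <- clean_hbo + matrix(stats::rnorm(n_ch * n_t, 0, config$noise_sd),
                              n_ch, n_t)
    hbr <- config$hbr_to_hbo_ratio * clean_hbo +
           matrix(stats::rnorm(n_ch * n_t, 0, config$noise_sd), n_ch, n_t)

    for (dc in config$dead_channels) {
      scale <- 50 * max(config$noise_sd, 1)
      hbo[dc, ] <- stats::rnorm(n_t, 0, scale)
      hbr[dc, ] <- stats::rnorm(n_t, 0, scale)
    }

    out <- hemo_series(hbo, hbr, config$sample_period)
    attr(out, "truth") <- amp                 # nominal (seed-independent)
    attr(out, "realized") <- amp_real         # this subject's amplitudes
    attr(out, "frame_times") <- tt
    out
  })
}

#' Behavioral trials with a congruency interference effect
#'
#' Draws per-trial reaction times from a lognormal distribution (positive,
#' right-skewed) whose mean is the task's congruent mean plus `delta` for
#' incongruent trials, shifted by a subject-specific offset; correctness is
#' Bernoulli at the task's accuracy.
#'
#' @param schedule an `event_schedule`.
#' @param config a `sim_config`.
#' @param subject subject id recorded in the output.
#' @param seed optional seed override.
#' @return data frame `subject`, `task`, `congruency`, `is_oddball`, `onset`,
#'   `rt` (s), `correct`.
#' @export
generate_rt_trials <- function(schedule, config, subject = 1L,
                               seed = config$seed) {
  task <- schedule$task[1]
  p <- config$rt_params[[task]]
  if (is.null(p)) stop("no rt_params for task ", task)
  stopifnot(p$sd_trial > 0, p$sd_subject >= 0)
  with_seed(seed, {
    shift <- stats::rnorm(1, 0, p$sd_subject)
    m <- p$mean + shift + ifelse(schedule$congruency == "incongruent",
                                 p$delta, 0)
    m <- pmax(m, 0.05)
    s2 <- log(1 + (p$sd_trial / m)^2)
    rt <- stats::rlnorm(nrow(schedule), meanlog = log(m) - s2 / 2,
                        sdlog = sqrt(s2))
    data.frame(subject = subject, task = task,
               congruency = schedule$congruency,
               is_oddball = schedule$is_oddball, onset = schedule$onset,
               rt = rt,
               correct = stats::runif(nrow(schedule)) < p$accuracy)
  })
}

#' Simulate one subject's run end to end
#'
#' Schedule, ground-truth hemodynamics, forward optics and behavior for one
#' subject and task, with a subject-specific seed derived deterministically
#' from the configuration seed.
#'
#' @param config a `sim_config`.
#' @param subject subject index (drives the derived seed).
#' @param task task id.
#' @param ext extinction table for the forward optical model.
#' @param pathlength effective pathlength (mm).
#' @return list `schedule`, `hemo` (with `truth` attribute), `od`
#'   (`od_recording`), `behavior`, `seed`.
#' @export
simulate_subject <- function(config, subject = 1L, task = config$tasks[1],
                             ext = extinction_table(), pathlength = 1) {
  seed <- subject_seed(config$seed, subject, task)
  schedule <- generate_event_schedule(config, task, seed = seed)
  hemo <- generate_hemo_truth(schedule, config, seed = seed + 1L)
  od <- forward_mbll(hemo, ext, pathlength)
  behavior <- generate_rt_trials(schedule, config, subject = subject,
                                 seed = seed + 2L)
  list(schedule = schedule, hemo = hemo, od = od, behavior = behavior,
       seed = seed)
}

## deterministic per-subject/task seed stream, kept within 32-bit range
subject_seed <- function(seed, subject, task) {
  toff <- 1013L * (utf8ToInt(substr(task, 1, 1))[1] %% 26L)
  as.integer((as.double(seed) * 7919 + subject * 104729 + toff) %%
             .Machine$integer.max)
}

#' Simulate the behavioral arm of a study
#'
#' @param config a `sim_config`.
#' @param tasks tasks to include.
#' @return long data frame of trials across subjects and tasks.
#' @export
simulate_behavior <- function(config, tasks = config$tasks) {
  do.call(rbind, lapply(seq_len(config$n_subjects), function(s) {
    do.call(rbind, lapply(tasks, function(tk) {
      seed <- subject_seed(config$seed, s, tk)
      sched <- generate_event_schedule(config, tk, seed = seed)
      generate_rt_trials(sched, config, subject = s, seed = seed + 2L)
    }))
  }))
}
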