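#' Gesture stimulus onset from rater annotations
#'
#' Independent raters mark, per stimulus video, the time at which the
#' gesture's meaning becomes resolvable; the median of the rater values is
#' taken as that video's stimulus onset (with four raters, the midpoint of
#' the two central values).
#'
#' @param rater_times numeric vector of rater annotations for one video (s),
#'   or a list of such vectors (one per video).
#' @return onset in seconds (vector when a list is given).
#' @export
gesture_onset <- function(rater_times) {
  if (is.list(rater_times))
    return(vapply(rater_times, gesture_onset, numeric(1)))
  if (length(rater_times) == 0) stop("no rater annotations")
  stats::median(rater_times)
}

#' Reaction-time summary with subject-then-group aggregation
#'
#' Condition means are computed per subject first; the group mean and SEM
#' (SD across subjects divided by sqrt(n)) are then taken over the subject
#' means — the aggregation under which group-level paired tests are valid.
#'
#' @param trials data frame with `subject`, `rt` (s) and the grouping
#'   columns; non-responses (`NA` rt) are dropped.
#' @param grouping character vector of condition columns (default
#'   `c("task", "congruency")`).
#' @param exclude_errors drop incorrect-response trials (needs a `correct`
#'   column); off by default.
#' @param exclude_oddballs drop oddball trials; off by default (oddballs
#'   belong to their own congruency).
#' @return an `rt_stats` list: `summary` data frame (grouping columns,
#'   `mean_ms`, `sem_ms`, `n_subjects`) and `subject_means` (subject x
#'   condition data frame, seconds).
#' @export
rt_summary <- function(trials, grouping = c("task", "congruency"),
                       exclude_errors = FALSE, exclude_oddballs = FALSE) {
  tr <- trials[!is.na(trials$rt), , drop = FALSE]
  if (exclude_errors) tr <- tr[tr$correct, , drop = FALSE]
  if (exclude_oddballs) tr <- tr[!tr$is_oddball, , drop = FALSE]
  if (nrow(tr) == 0) stop("no responded trials")
  key <- interaction(tr[grouping], sep = ":", drop = TRUE)
  subj_means <- stats::aggregate(rt ~ subject + key, data =
                                   data.frame(subject = tr$subject, key = key,
                                              rt = tr$rt), FUN = mean)
  summ <- do.call(rbind, lapply(levels(subj_means$key), function(k) {
    v <- subj_means$rt[subj_means$key == k]
    data.frame(condition = k, mean_ms = 1000 * mean(v),
               sem_ms = if (length(v) > 1)
                 1000 * stats::sd(v) / sqrt(length(v)) else NA_real_,
               n_subjects = length(v))
  }))
  structure(list(summary = summ, subject_means = subj_means),
            class = "rt_stats")
}

#' @export
print.rt_stats <- function(x, ...) {
  print(transform(x$summary, mean_ms = round(mean_ms, 1),
                  sem_ms = round(sem_ms, 1)))
  invisible(x)
}

#' One-tailed paired t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` for paired differences `d = a - b`,
#' with the upper-tail p-value at `df = n - 1` (alternative: `a > b`).
#' Identical inputs (all differences exactly zero) give `t = 0, p = 0.5`;
#' zero variance around a nonzero mean is an error.
#'
#' @param a,b per-subject paired values.
#' @return list `t`, `p`, `df`, `mean_diff`.
#' @export
paired_t_one_tailed <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p = 0.5, df = length(d) - 1, mean_diff = 0))
    stop("zero variance of paired differences")
  }
  n <- length(d)
  tval <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = tval, p = stats::pt(tval, df = n - 1, lower.tail = FALSE),
       df = n - 1, mean_diff = mean(d))
}

#' Paired subject means for two conditions
#'
#' Helper extracting aligned per-subject mean vectors for a condition pair,
#' ready for [paired_t_one_tailed()].
#'
#' @param trials behavioral trial data frame.
#' @param grouping condition columns.
#' @param cond_a,cond_b condition labels (joined by `:` when several
#'   grouping columns are used).
#' @return list of numeric vectors `a`, `b` aligned by subject.
#' @export
paired_condition_means <- function(trials, grouping, cond_a, cond_b) {
  st <- rt_summary(trials, grouping)$subject_means
  wa <- st[st$key == cond_a, ]
  wb <- st[st$key == cond_b, ]
  common <- intersect(wa$subject, wb$subject)
  list(a = wa$rt[match(common, wa$subject)],
       b = wb$rt[match(common, wb$subject)], subjects = common)
}

#' Response accuracy per task
#'
#' @param trials data frame with `task` and logical `correct`.
#' @return named numeric vector, percent correct per task.
#' @export
accuracy <- function(trials) {
  if (nrow(trials) == 0) stop("no trials")
  if (is.null(trials$correct)) stop("no correctness flags")
  tasks <- unique(trials$task)
  vapply(stats::setNames(tasks, tasks), function(tk) {
    sel <- trials$task == tk
    100 * mean(trials$correct[sel])
  }, numeric(1))
}

#' Full behavioral analysis of a trial table
#'
#' Condition RT summaries, accuracy, and the standard one-tailed paired
#' contrasts: incongruent vs congruent within each task, gesture vs color,
#' and incongruent vs congruent pooled over tasks.
#'
#' @param trials behavioral trial data frame (`subject`, `task`,
#'   `congruency`, `rt`, `correct`).
#' @return list `rt` (an `rt_stats`), `accuracy`, `tests` (data frame of
#'   paired one-tailed tests: `contrast`, `t`, `p`, `df`, `mean_diff_ms`).
#' @export
analyze_behavior <- function(trials) {
  rt <- rt_summary(trials)
  tests <- list()
  for (tk in unique(trials$task)) {
    pm <- paired_condition_means(trials, c("task", "congruency"),
                                 paste0(tk, ":incongruent"),
                                 paste0(tk, ":congruent"))
    tt <- paired_t_one_tailed(pm$a, pm$b)
    tests[[length(tests) + 1]] <-
      data.frame(contrast = paste0(tk, ": incongruent > congruent"),
                 t = tt$t, p = tt$p, df = tt$df,
                 mean_diff_ms = 1000 * tt$mean_diff)
  }
  if (all(c("gesture", "color") %in% trials$task)) {
    pm <- paired_condition_means(trials, "task", "gesture", "color")
    tt <- paired_t_one_tailed(pm$a, pm$b)
    tests[[length(tests) + 1]] <-
      data.frame(contrast = "gesture > color", t = tt$t, p = tt$p,
                 df = tt$df, mean_diff_ms = 1000 * tt$mean_diff)
  }
  pm <- paired_condition_means(trials, "congruency", "incongruent",
                               "congruent")
  tt <- paired_t_one_tailed(pm$a, pm$b)
  tests[[length(tests) + 1]] <-
    data.frame(contrast = "incongruent > congruent (all tasks)", t = tt$t,
               p = tt$p, df = tt$df, mean_diff_ms = 1000 * tt$mean_diff)
  list(rt = rt, accuracy = accuracy(trials), tests = do.call(rbind, tests))
}
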