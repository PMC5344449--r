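test_that("event schedules realize the block paradigm", {
  cfg <- sim_config()
  sched <- generate_event_schedule(cfg, "gesture")
  expect_s3_class(sched, "event_schedule")
  expect_equal(nrow(sched), 48)
  expect_equal(attr(sched, "run_length"), 360)

  ## one oddball per block, opposite in congruency to its block's dominance
  for (b in unique(sched$block_index)) {
    blk <- sched[sched$block_index == b, ]
    expect_equal(sum(blk$is_oddball), 1)
    dom <- sub("-dominant", "", blk$block_dominance[1])
    expect_equal(sum(blk$congruency == dom), 3)
    expect_true(all(blk$congruency[blk$is_oddball] != dom))
  }
  expect_equal(sum(grepl("^congruent", sched$block_dominance)) / 4, 6)

  expect_identical(generate_event_schedule(cfg, "gesture", seed = 5),
                   generate_event_schedule(cfg, "gesture", seed = 5))
  expect_error(sim_config(isi = 4), "exceeds block_duration")
})

test_that("schedule invariants hold across 1000 random seeds", {
  cfg <- sim_config()
  ok <- vapply(1:1000, function(s) {
    sched <- generate_event_schedule(cfg, "color", seed = s)
    per_block <- tapply(sched$is_oddball, sched$block_index, sum)
    nrow(sched) == 48 &&
      all(per_block == 1) &&
      all(sched$onset >= 0 & sched$onset < 360) &&
      sum(grepl("^congruent", sched$block_dominance)) == 24
  }, logical(1))
  expect_true(all(ok))
  ## oddball position is uniform over the four slots
  slots <- vapply(1:400, function(s) {
    sched <- generate_event_schedule(cfg, "color", seed = s)
    which(sched$is_oddball[sched$block_index == 1])
  }, integer(1))
  expect_gt(chisq.test(tabulate(slots, 4))$p.value, 0.001)
})

test_that("hemodynamic forward model is null when everything is off", {
  cfg <- tiny_config()
  sched <- generate_event_schedule(cfg, "gesture")
  hemo <- generate_hemo_truth(sched, cfg)
  expect_equal(max(abs(hemo$hbo)), 0)
  expect_equal(max(abs(hemo$hbr)), 0)
})

test_that("a planted amplitude is recovered exactly by OLS on clean data", {
  cfg <- tiny_config(active_channels = data.frame(
    channel = 2, condition = "gesture:incongruent", amplitude = 1.7))
  sched <- generate_event_schedule(cfg, "gesture")
  hemo <- generate_hemo_truth(sched, cfg)
  des <- build_design(sched, attr(hemo, "frame_times"),
                      trial_duration = cfg$trial_duration)
  fit <- fit_glm(hemo$hbo, des)
  expect_equal(unname(fit$beta[2, "gesture:incongruent"]), 1.7,
               tolerance = 1e-6)
  expect_equal(unname(fit$beta[1, "gesture:incongruent"]), 0,
               tolerance = 1e-8)
  ## HbR mirrors the noiseless HbO response at the configured ratio
  fitr <- fit_glm(hemo$hbr, des)
  expect_equal(unname(fitr$beta[2, "gesture:incongruent"]), -1.7 / 3,
               tolerance = 1e-6)
})

test_that("noise realizations differ across seeds but truth does not", {
  cfg <- tiny_config(noise_sd = 0.5,
                     active_channels = data.frame(
                       channel = 1, condition = "all", amplitude = 2))
  sched <- generate_event_schedule(cfg, "gesture")
  h1 <- generate_hemo_truth(sched, cfg, seed = 10)
  h2 <- generate_hemo_truth(sched, cfg, seed = 20)
  expect_false(isTRUE(all.equal(h1$hbo, h2$hbo)))
  expect_identical(attr(h1, "truth"), attr(h2, "truth"))
  expect_identical(generate_hemo_truth(sched, cfg, seed = 10)$hbo, h1$hbo)
})

test_that("dead channels are rendered as high-amplitude garbage", {
  cfg <- tiny_config(noise_sd = 0.3, dead_channels = 3L)
  sched <- generate_event_schedule(cfg, "gesture")
  hemo <- generate_hemo_truth(sched, cfg)
  rms <- sqrt(rowMeans(hemo$hbo^2))
  expect_gt(rms[3] / mean(rms[-3]), 10)
})

test_that("reaction times carry the configured interference effect", {
  cfg0 <- sim_config(rt_params = list(gesture = list(
    mean = 1, delta = 0, sd_trial = 0.2, sd_subject = 0, accuracy = 1)))
  sched <- generate_event_schedule(cfg0, "gesture")
  ## delta = 0: no systematic congruency difference
  set.seed(2)
  diffs <- vapply(1:300, function(s) {
    tr <- generate_rt_trials(sched, cfg0, seed = s)
    mean(tr$rt[tr$congruency == "incongruent"]) -
      mean(tr$rt[tr$congruency == "congruent"])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.01)

  ## planted 100 ms delta, 48 trials x 31 subjects: one-tailed paired t
  ## rejects at p < 0.01 in nearly all replicates
  cfgp <- sim_config(n_subjects = 31, rt_params = list(gesture = list(
    mean = 1, delta = 0.1, sd_trial = 0.05, sd_subject = 0.1,
    accuracy = 1)), tasks = "gesture")
  rejections <- vapply(1:100, function(rep) {
    cfgp$seed <- 5000 + rep
    trials <- simulate_behavior(cfgp)
    pm <- paired_condition_means(trials, "congruency", "incongruent",
                                 "congruent")
    paired_t_one_tailed(pm$a, pm$b)$p < 0.01
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
})

test_that("response accuracy matches its generating probability", {
  cfg <- sim_config(seed = 77, rt_params = list(gesture = list(
    mean = 1, delta = 0.04, sd_trial = 0.2, sd_subject = 0.1,
    accuracy = 0.98)), tasks = "gesture", n_subjects = 31)
  trials <- simulate_behavior(cfg)
  n <- nrow(trials)
  ci <- qbinom(c(0.005, 0.995), n, 0.98) / n
  expect_gte(mean(trials$correct), ci[1])
  expect_lte(mean(trials$correct), ci[2])
})

test_that("subject simulation is deterministic in the configured seed", {
  cfg <- sim_config(n_subjects = 1, n_channels = 3, seed = 9,
                    noise_sd = 0.2)
  s1 <- simulate_subject(cfg, 1, "color")
  s2 <- simulate_subject(cfg, 1, "color")
  expect_identical(s1$od$od, s2$od$od)
  expect_identical(s1$behavior$rt, s2$behavior$rt)
})
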