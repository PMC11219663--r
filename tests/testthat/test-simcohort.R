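test_that("config validation enforces the study-condition invariants", {
  expect_error(sim_config(record_hours = 12), "record_hours")
  expect_error(sim_config(prevalence_ih = 1.2), "prevalences")
  expect_error(sim_config(ih_onset_hours_range = c(5, 10)), "after hour 6")
  expect_error(sim_config(sample_period_s = 0), "sample_period_s")
  expect_error(sim_config(ih_duration_min_range = c(4, 30)), "ih_duration")
  # scalar group parameters broadcast to all three groups
  cfg <- sim_config(prx_coupling = 0.9)
  expect_equal(unname(cfg$prx_coupling), rep(0.9, 3))
})

test_that("outcome prevalences are matched in expectation", {
  cfg <- sim_config(n_patients = 1000, seed = 3)
  gt <- sim_ground_truth(cfg)
  expect_lt(abs(mean(gt$is_ih) - 0.623), 0.05)
  expect_lt(abs(mean(gt$is_sih[gt$is_ih]) - 30 / 43), 0.07)
  expect_true(all(gt$is_ih[gt$is_sih])) # sih implies ih
  # planted durations respect the outcome classes
  expect_true(all(gt$duration_min[gt$is_ih & !gt$is_sih] > 5))
  expect_true(all(gt$duration_min[gt$is_ih & !gt$is_sih] < 60))
  expect_true(all(gt$duration_min[gt$is_sih] > 60))
  expect_true(all(gt$onset_hours[gt$is_ih] > 6))

  gt0 <- sim_ground_truth(sim_config(n_patients = 50, prevalence_ih = 0, seed = 4))
  expect_false(any(gt0$is_ih))
})

test_that("baseline covariates shift in the published directions", {
  gt <- sim_ground_truth(sim_config(n_patients = 600, seed = 8))
  expect_gt(mean(gt$age[gt$is_ih]), mean(gt$age[!gt$is_ih]))
  expect_lt(mean(gt$gcs[gt$is_ih]), mean(gt$gcs[!gt$is_ih]))
  expect_true(all(gt$gcs >= 3 & gt$gcs <= 15))
  expect_lt(abs(mean(gt$sex) - 2 / 3), 0.06)
})

test_that("cohorts are byte-identical across runs and generation order", {
  cfg <- sim_config(n_patients = 6, seed = 11)
  a <- suppressWarnings(sim_cohort(cfg))
  b <- suppressWarnings(sim_cohort(cfg))
  expect_identical(a, b)
  # per-patient substreams: regenerating one patient alone gives the same series
  solo <- suppressWarnings(sim_patient(cfg, a$patient_id[4], a[4, ]))
  expect_identical(solo, a$recording[[4]])
})

test_that("planted episodes appear only after hour 6 and are found downstream", {
  cfg <- sim_config(n_patients = 1, seed = 21)
  out <- list(is_ih = TRUE, is_sih = FALSE, onset_hours = 10, duration_min = 8)
  rec <- suppressWarnings(sim_patient(cfg, "pos", out))
  es <- resample_epochs(rec)
  ep <- detect_episodes(es$icp[es$t_mid_s > 6 * 3600], 22, 5)
  expect_equal(nrow(ep), 1)
  onset_h <- (ep$start_epoch[1] - 1) * 12 / 3600 + 6
  expect_lt(abs(onset_h - 10), 12 / 3600 + 1e-9)

  neg <- suppressWarnings(sim_patient(cfg, "neg", list(is_ih = FALSE, is_sih = FALSE)))
  esn <- resample_epochs(neg)
  expect_equal(nrow(detect_episodes(esn$icp[esn$t_mid_s > 6 * 3600], 22, 5)), 0)

  expect_error(
    sim_patient(cfg, "bad", list(is_ih = TRUE, is_sih = FALSE,
                                 onset_hours = 5, duration_min = 10)),
    "after hour 6")
  expect_error(
    sim_patient(cfg, "bad", list(is_ih = FALSE, is_sih = TRUE)),
    "is_sih implies is_ih")
})

test_that("simulated patients never trigger the early-persistent-IH exclusion", {
  cfg <- sim_config(n_patients = 12, seed = 31)
  cohort <- suppressWarnings(sim_cohort(cfg))
  out <- apply_inclusion_filters(cohort)
  expect_true(all(out$included))
})

test_that("strong ICP-MAP coupling produces high PRx downstream", {
  vals <- vapply(1:20, function(i) {
    cfg <- sim_config(n_patients = 1, prx_coupling = 0.9, seed = 500 + i)
    rec <- suppressWarnings(sim_patient(cfg, "A", list(is_ih = FALSE, is_sih = FALSE)))
    es <- smooth_epochs(resample_epochs(rec))
    window_mean(prx(extract_window(es, 0, 6)))
  }, numeric(1))
  expect_gt(mean(vals), 0.5)
})
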