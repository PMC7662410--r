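test_that("generate_nn_series: zero modulation gives a constant series", {
  nn <- generate_nn_series(60, 800, 0, 0, 0.1, 0.25, 0, seed = 1)
  expect_true(all(abs(nn$nn_ms - 800) < 1e-9))
  expect_gte(max(nn$beat_times_s), 60)
  expect_true(all(diff(nn$beat_times_s) > 0))
})

test_that("generate_nn_series validates its inputs", {
  expect_error(generate_nn_series(-1, 800), class = "anspm_invalid_argument")
  expect_error(generate_nn_series(60, 0), class = "anspm_invalid_argument")
  # modulation amplitude that could push an interval to zero
  expect_error(generate_nn_series(60, 800, 300, 150, 0.1, 0.25, 0),
               class = "anspm_invalid_argument")
  # band frequencies outside their bands
  expect_error(generate_nn_series(60, 800, 10, 10, 0.2, 0.25, 0),
               class = "anspm_invalid_argument")
  expect_error(generate_nn_series(60, 800, 10, 10, 0.1, 0.5, 0),
               class = "anspm_invalid_argument")
})

test_that("spectral content of generated series lands in the injected band", {
  nn_hf <- generate_nn_series(300, 800, 0, 30, 0.1, 0.25, 0, seed = 1)
  fd <- frequency_domain_indices(nn_hf)
  expect_gt(fd$hf_norm, 80)
  nn_lf <- generate_nn_series(300, 800, 30, 0, 0.1, 0.25, 0, seed = 1)
  fd2 <- frequency_domain_indices(nn_lf)
  expect_gt(fd2$lf_norm, fd2$hf_norm)
  expect_gt(fd2$lf_norm, 80)
})

test_that("generate_ecg places a peak at each beat time", {
  nn <- nn_series(c(1, 2, 3))
  ecg <- generate_ecg(nn, 1000, 1, 0)
  for (t in c(1, 2, 3)) {
    w <- round((t - 0.05) * 1000):round((t + 0.05) * 1000)
    t_max <- (w[which.max(ecg$x[w])] - 1) / 1000
    expect_lt(abs(t_max - t), 0.010)
  }
  expect_gte(length(ecg$x) / ecg$fs_hz, max(nn$beat_times_s) + 1)
})

test_that("generate_ecg rejects empty beat lists and low sampling rates", {
  expect_error(generate_ecg(list(beat_times_s = numeric(0))),
               class = "anspm_invalid_argument")
  expect_error(generate_ecg(nn_series(c(1, 2)), fs_hz = 50),
               class = "anspm_invalid_argument")
})

test_that("generate_eda: flat, event, and drift cases", {
  flat <- generate_eda(60, 2.0, 0, NULL, 1000, 0)
  expect_true(all(abs(flat$x - 2.0) < 1e-12))

  ev <- scr_events(c(5, 15, 25, 35, 45), 0.5)
  eda <- generate_eda(60, 2.0, 0, ev, 1000, 0)
  expect_equal(detect_scrs(eda)$ns_scr, 5)

  drift <- generate_eda(60, 2.0, 1.0, NULL, 1000, 0)
  scl <- extract_scl(drift)
  expect_equal(scl$mean_scl, mean(drift$x), tolerance = 0.01)
})

test_that("generate_eda rejects invalid events", {
  expect_error(generate_eda(60, 2, 0, scr_events(5, -1)),
               class = "anspm_invalid_argument")
  expect_error(generate_eda(60, 2, 0, scr_events(70, 0.5)),
               class = "anspm_invalid_argument")
  expect_error(generate_eda(60, 2, 0, scr_events(5, 0.5, rise_s = 3, decay_s = 1)),
               class = "anspm_invalid_argument")
  # events driving conductance non-positive
  expect_error(generate_eda(60, 0.1, -60, NULL, 100, 0),
               class = "anspm_invalid_argument")
})

test_that("identical seeds give bit-identical outputs", {
  a <- generate_nn_series(120, 800, 20, 20, 0.1, 0.25, 15, seed = 9)
  b <- generate_nn_series(120, 800, 20, 20, 0.1, 0.25, 15, seed = 9)
  expect_identical(a, b)
  e1 <- generate_eda(30, 2, 0.5, scr_events(10, 0.3), 100, 0.01, seed = 4)
  e2 <- generate_eda(30, 2, 0.5, scr_events(10, 0.3), 100, 0.01, seed = 4)
  expect_identical(e1, e2)
  g1 <- generate_ecg(a, 250, 1, 0.05, seed = 5)
  g2 <- generate_ecg(a, 250, 1, 0.05, seed = 5)
  expect_identical(g1, g2)
})

test_that("generated latent scores are near unit variance for n >= 500", {
  truth <- latent_ground_truth(1, c(0.6, -0.5, 0.4), 0, 800, seed = 3)
  tab <- generate_indicator_table(truth)
  # with loadings 1 and zero noise the MV equals its latent score
  for (mv in c("lf", "hf", "lf_hf", "recall_score")) {
    expect_lt(abs(var(tab[[mv]]) - 1), 0.1)
  }
})

test_that("generate_indicator_table validates ground truth", {
  expect_error(latent_ground_truth(1.2, c(0.5, 0.2, 0.1)),
               class = "anspm_invalid_argument")
  expect_error(latent_ground_truth(1, c(0.5, 0.2, 0.1), noise_sd = -1),
               class = "anspm_invalid_argument")
  expect_error(latent_ground_truth(1, c(0.5, 0.2, 0.1), n_subjects = 2),
               class = "anspm_invalid_argument")
  expect_error(latent_ground_truth(1, c(0.9, 0.9, 0.4)),
               class = "anspm_invalid_argument")
})

test_that("channel CSV round-trip preserves signal and schedule", {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tmp, paste0(tmp, ".json"))), add = TRUE)
  ch <- generate_eda(10, 2, 0, NULL, 50, 0)
  write_channel_csv(ch, tmp, schedule = default_schedule())
  back <- read_channel_csv(tmp)
  expect_equal(back$channel$x, ch$x, tolerance = 1e-12)
  expect_equal(back$channel$fs_hz, 50)
  expect_s3_class(back$schedule, "stimulus_schedule")
  expect_equal(nrow(back$schedule), 7)
})
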