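test_that("detect_r_peaks recovers noiseless synthetic beats", {
  nn <- generate_nn_series(60, 800, 0, 0, 0.1, 0.25, 0, seed = 1)
  ecg <- generate_ecg(nn, 1000, 1, 0)
  pk <- detect_r_peaks(ecg)
  expect_true(abs(length(pk) - 75) <= 2)  # ~75 beats in 60 s at 800 ms
  err <- vapply(nn$beat_times_s[nn$beat_times_s <= max(pk) + 0.4],
                function(t) min(abs(pk - t)), numeric(1))
  expect_true(all(err <= 0.010))
  expect_true(all(diff(pk) >= 0.2))  # refractory
})

test_that("detect_r_peaks errors on flat or too-short signals", {
  expect_error(detect_r_peaks(rep(0, 10000), 1000), class = "anspm_no_beats")
  expect_error(detect_r_peaks(rnorm(500), 1000), class = "anspm_signal_error")
  expect_error(detect_r_peaks(rnorm(10000), 50), class = "anspm_invalid_argument")
})

test_that("detect_r_peaks is robust to 10% noise (Monte Carlo, 20 seeds)", {
  nn <- generate_nn_series(60, 800, 10, 10, 0.1, 0.25, 5, seed = 2)
  sens <- prec <- numeric(20)
  for (s in 1:20) {
    ecg <- generate_ecg(nn, 500, 1, 0.1, seed = s)
    pk <- detect_r_peaks(ecg)
    truth <- nn$beat_times_s
    d_truth <- vapply(truth, function(t) min(abs(pk - t)), numeric(1))
    d_det <- vapply(pk, function(t) min(abs(truth - t)), numeric(1))
    sens[s] <- mean(d_truth <= 0.05)
    prec[s] <- mean(d_det <= 0.05)
  }
  expect_gte(mean(sens), 0.98)
  expect_gte(mean(prec), 0.98)
})

test_that("build_nn_series flags ectopic-adjacent intervals", {
  nn <- build_nn_series(c(0, 0.8, 1.6, 2.4))
  expect_equal(nn$nn_ms, c(800, 800, 800))
  expect_false(any(nn$excluded))

  # a 300 ms interval: it and the interval after the ectopic beat are out
  nn2 <- build_nn_series(c(0, 0.8, 1.1, 1.9), ectopic_rel_threshold = 0.2)
  expect_equal(nn2$nn_ms, c(800, 300, 800))
  expect_equal(nn2$excluded, c(FALSE, TRUE, TRUE))

  expect_error(build_nn_series(c(0, 0.8)), class = "anspm_invalid_argument")
})

test_that("time-domain indices match hand computations", {
  expect_equal(time_domain_indices(nn_series_from_nn(c(800, 800, 800))),
               list(avnn = 800, sdnn = 0, rmssd = 0, pnn50 = 0))
  td <- time_domain_indices(nn_series_from_nn(c(800, 810, 790, 820)))
  expect_equal(td$avnn, 805)
  expect_equal(td$rmssd, sqrt((10^2 + 20^2 + 30^2) / 3), tolerance = 1e-12)
  expect_equal(td$pnn50, 0)
  td2 <- time_domain_indices(nn_series_from_nn(c(700, 800, 760, 900)))
  expect_equal(td2$pnn50, 2 / 3)
})

test_that("time-domain indices match the brute-force oracle on 100 random series", {
  set.seed(11)
  for (i in 1:100) {
    nn_ms <- runif(sample(5:60, 1), 500, 1200)
    got <- time_domain_indices(nn_series_from_nn(nn_ms))
    want <- oracle_time_domain(nn_ms)
    for (k in names(want)) {
      expect_equal(got[[k]], want[[k]], tolerance = 1e-9)
    }
  }
})

test_that("time-domain indices skip excluded intervals", {
  nn <- build_nn_series(c(0, 0.8, 1.1, 1.9, 2.7, 3.5, 4.3))
  td <- time_domain_indices(nn)
  expect_equal(td$avnn, 800)
  expect_equal(td$sdnn, 0)
})

test_that("frequency-domain indices separate the LF and HF bands", {
  hf_only <- generate_nn_series(300, 800, 0, 30, 0.1, 0.25, 0, seed = 1)
  fd <- frequency_domain_indices(hf_only)
  expect_gt(fd$hf_norm, 80)
  expect_lt(fd$lf_hf, 0.25)

  lf_only <- generate_nn_series(300, 800, 30, 0, 0.1, 0.25, 0, seed = 1)
  fd2 <- frequency_domain_indices(lf_only)
  expect_gt(fd2$lf_norm, 80)
  expect_gt(fd2$lf_hf, 4)

  both <- generate_nn_series(300, 800, 30, 30, 0.1, 0.25, 0, seed = 1)
  fd3 <- frequency_domain_indices(both)
  expect_equal(fd3$lf_hf, 1, tolerance = 0.25)
})

test_that("frequency-domain indices respect their preconditions", {
  short <- generate_nn_series(30, 800, 0, 20, 0.1, 0.25, 0, seed = 1)
  expect_error(frequency_domain_indices(short), class = "anspm_invalid_argument")
  flat <- generate_nn_series(120, 800, 0, 0, 0.1, 0.25, 0, seed = 1)
  expect_error(frequency_domain_indices(flat), class = "anspm_invalid_argument")
})

test_that("indices are scale-equivariant and band ratio amplitude-invariant", {
  set.seed(21)
  nn_ms <- runif(40, 600, 1000)
  base <- time_domain_indices(nn_series_from_nn(nn_ms))
  scaled <- time_domain_indices(nn_series_from_nn(3 * nn_ms))
  expect_equal(scaled$avnn, 3 * base$avnn, tolerance = 1e-12)
  expect_equal(scaled$sdnn, 3 * base$sdnn, tolerance = 1e-12)
  expect_equal(scaled$rmssd, 3 * base$rmssd, tolerance = 1e-12)

  small <- generate_nn_series(300, 800, 10, 20, 0.1, 0.25, 0, seed = 2)
  big <- generate_nn_series(300, 800, 20, 40, 0.1, 0.25, 0, seed = 2)
  r1 <- frequency_domain_indices(small)$lf_hf
  r2 <- frequency_domain_indices(big)$lf_hf
  expect_equal(r1, r2, tolerance = 0.05)
})

test_that("lf_norm + hf_norm never exceeds 100", {
  for (s in 1:5) {
    nn <- generate_nn_series(180, 800, 15, 25, 0.1, 0.3, 8, seed = s)
    fd <- frequency_domain_indices(nn)
    expect_lte(fd$lf_norm + fd$hf_norm, 100 + 1e-9)
  }
})
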