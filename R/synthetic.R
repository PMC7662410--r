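# Synthetic-data module: biosignals and indicator tables with known ground
# truth, so every downstream stage (peak detection, HRV/EDA features, path
# model) can be tested round-trip without access to subject recordings.

#' Generate an NN-interval series with controllable spectral content
#'
#' Beat-to-beat intervals are a mean RR plus additive sinusoidal
#' modulation in the LF and HF heart-rate-variability bands plus white
#' jitter. The additive-sinusoid model is deliberately simple: it has an
#' analytic spectral oracle (all modulation power sits at the two chosen
#' frequencies), which is what the frequency-domain index tests rely on.
#'
#' @param duration_s length of the series in seconds (> 0).
#' @param mean_rr_ms mean NN interval, milliseconds.
#' @param lf_amp_ms amplitude of the low-frequency modulation (ms).
#' @param hf_amp_ms amplitude of the high-frequency modulation (ms).
#' @param lf_freq_hz LF modulation frequency; must lie in (0.04, 0.15) Hz.
#' @param hf_freq_hz HF modulation frequency; must lie in (0.15, 0.4) Hz.
#' @param jitter_sd_ms standard deviation of white interval jitter (ms).
#' @param seed integer seed; identical seeds give identical series.
#' @return an `nn_series` object: `beat_times_s`, `nn_ms`, `excluded` flags.
#' @examples
#' nn <- generate_nn_series(60, 800, 0, 0, 0.1, 0.25, 0, seed = 1)
#' all(nn$nn_ms == 800)
#' @export
generate_nn_series <- function(duration_s, mean_rr_ms,
                               lf_amp_ms = 0, hf_amp_ms = 0,
                               lf_freq_hz = 0.1, hf_freq_hz = 0.25,
                               jitter_sd_ms = 0, seed = NULL) {
  assert_scalar_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  assert_scalar_number(mean_rr_ms, "mean_rr_ms", lower = 0, strict_lower = TRUE)
  assert_scalar_number(lf_amp_ms, "lf_amp_ms", lower = 0)
  assert_scalar_number(hf_amp_ms, "hf_amp_ms", lower = 0)
  assert_scalar_number(jitter_sd_ms, "jitter_sd_ms", lower = 0)
  if (mean_rr_ms <= 2 * (lf_amp_ms + hf_amp_ms)) {
    stop_anspm("modulation amplitudes too large for mean_rr_ms (intervals could hit zero)",
               class = "anspm_invalid_argument")
  }
  if (lf_freq_hz <= 0.04 || lf_freq_hz >= 0.15) {
    stop_anspm("lf_freq_hz must lie inside the LF band (0.04, 0.15) Hz",
               class = "anspm_invalid_argument")
  }
  if (hf_freq_hz <= 0.15 || hf_freq_hz >= 0.4) {
    stop_anspm("hf_freq_hz must lie inside the HF band (0.15, 0.4) Hz",
               class = "anspm_invalid_argument")
  }
  with_seed(seed, {
    n_max <- ceiling(duration_s * 1000 / mean_rr_ms * 2) + 10L
    jitter <- if (jitter_sd_ms > 0) stats::rnorm(n_max, 0, jitter_sd_ms) else numeric(n_max)
    t <- 0
    times <- numeric(n_max + 1L)
    k <- 1L
    while (t < duration_s && k <= n_max) {
      nn <- mean_rr_ms +
        lf_amp_ms * sin(2 * pi * lf_freq_hz * t) +
        hf_amp_ms * sin(2 * pi * hf_freq_hz * t) +
        jitter[k]
      if (nn <= 0) {
        stop_anspm("generated a non-positive interval; reduce modulation or jitter",
                   class = "anspm_invalid_argument")
      }
      t <- t + nn / 1000
      k <- k + 1L
      times[k] <- t
    }
    beat_times <- times[seq_len(k)]
    nn_series(beat_times)
  })
}

#' Synthesize an ECG trace from a beat-time series
#'
#' One template QRS complex (a biphasic Mexican-hat wavelet, ~40 ms wide)
#' is placed at each beat time on a flat baseline, plus optional white
#' noise. Morphology beyond a detectable R-peak is out of scope.
#'
#' @param nn an `nn_series` (or any object with `$beat_times_s`).
#' @param fs_hz sampling rate in Hz; must be >= 100 for the R-peak
#'   localization contract to hold.
#' @param amplitude_mv R-peak amplitude in millivolts.
#' @param noise_sd_mv white-noise standard deviation in millivolts.
#' @param seed integer seed for the noise stream.
#' @return a `raw_channel` object: `x` (mV), `fs_hz`, `units = "mV"`.
#' @export
generate_ecg <- function(nn, fs_hz = 1000, amplitude_mv = 1,
                         noise_sd_mv = 0, seed = NULL) {
  beats <- nn$beat_times_s
  if (is.null(beats) || length(beats) == 0L) {
    stop_anspm("nn series has no beats", class = "anspm_invalid_argument")
  }
  assert_scalar_number(fs_hz, "fs_hz", lower = 100)
  assert_scalar_number(noise_sd_mv, "noise_sd_mv", lower = 0)
  n <- ceiling((max(beats) + 1) * fs_hz)
  t_half <- 0.02                                   # QRS half-width, seconds
  kt <- seq(-3 * t_half, 3 * t_half, by = 1 / fs_hz)
  u <- kt / t_half
  kernel <- amplitude_mv * (1 - u^2) * exp(-u^2 / 2)  # Mexican hat
  x <- numeric(n)
  centers <- round(beats * fs_hz) + 1L
  half <- (length(kernel) - 1L) %/% 2L
  for (c0 in centers) {
    lo <- c0 - half; hi <- c0 + half
    klo <- max(1L, 1L + (1L - lo)); khi <- length(kernel) - max(0L, hi - n)
    lo <- max(1L, lo); hi <- min(n, hi)
    if (lo <= hi) x[lo:hi] <- x[lo:hi] + kernel[klo:khi]
  }
  if (noise_sd_mv > 0) {
    x <- x + with_seed(seed, stats::rnorm(n, 0, noise_sd_mv))
  }
  raw_channel(x, fs_hz, units = "mV")
}

#' Synthesize an EDA trace with tonic drift and discrete SCR events
#'
#' The tonic part is a level plus linear drift; each skin conductance
#' response (SCR) is a bi-exponential (Bateman-type) waveform
#' `a * (exp(-t/decay) - exp(-t/rise))`, peak-normalized to its stated
#' amplitude — the standard sudomotor impulse-response shape.
#'
#' @param duration_s trace length in seconds.
#' @param scl_level_us tonic skin conductance level, microsiemens (> 0).
#' @param drift_us_per_min linear tonic drift, microsiemens per minute.
#' @param scr_events data.frame (or list of lists) with columns
#'   `onset_s`, `amplitude_us`, `rise_s`, `decay_s`.
#' @param fs_hz sampling rate in Hz.
#' @param noise_sd_us white-noise standard deviation, microsiemens.
#' @param seed integer seed for the noise stream.
#' @return a `raw_channel` object: `x` (microsiemens), `fs_hz`, `units = "uS"`.
#' @export
generate_eda <- function(duration_s, scl_level_us, drift_us_per_min = 0,
                         scr_events = NULL, fs_hz = 1000,
                         noise_sd_us = 0, seed = NULL) {
  assert_scalar_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  assert_scalar_number(scl_level_us, "scl_level_us", lower = 0, strict_lower = TRUE)
  assert_scalar_number(noise_sd_us, "noise_sd_us", lower = 0)
  n <- ceiling(duration_s * fs_hz)
  t <- seq_len(n) / fs_hz
  x <- scl_level_us + drift_us_per_min / 60 * t
  events <- normalize_scr_events(scr_events)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$amplitude_us <= 0) {
      stop_anspm("SCR amplitudes must be > 0", class = "anspm_invalid_argument")
    }
    if (ev$onset_s < 0 || ev$onset_s >= duration_s) {
      stop_anspm("SCR onset outside the trace", class = "anspm_invalid_argument")
    }
    if (ev$rise_s >= ev$decay_s) {
      stop_anspm("SCR rise time must be shorter than decay time",
                 class = "anspm_invalid_argument")
    }
    tau <- t - ev$onset_s
    w <- ifelse(tau > 0, exp(-tau / ev$decay_s) - exp(-tau / ev$rise_s), 0)
    tp <- ev$rise_s * ev$decay_s / (ev$decay_s - ev$rise_s) *
      log(ev$decay_s / ev$rise_s)
    peak <- exp(-tp / ev$decay_s) - exp(-tp / ev$rise_s)
    x <- x + ev$amplitude_us * w / peak
  }
  if (noise_sd_us > 0) {
    x <- x + with_seed(seed, stats::rnorm(n, 0, noise_sd_us))
  }
  if (any(x <= 0)) {
    stop_anspm("generated conductance is not positive everywhere",
               class = "anspm_invalid_argument")
  }
  raw_channel(x, fs_hz, units = "uS")
}

normalize_scr_events <- function(scr_events) {
  if (is.null(scr_events) || (is.data.frame(scr_events) && nrow(scr_events) == 0L)) {
    return(data.frame(onset_s = numeric(0), amplitude_us = numeric(0),
                      rise_s = numeric(0), decay_s = numeric(0)))
  }
  if (!is.data.frame(scr_events)) {
    scr_events <- do.call(rbind, lapply(scr_events, as.data.frame))
  }
  need <- c("onset_s", "amplitude_us", "rise_s", "decay_s")
  if (!all(need %in% names(scr_events))) {
    stop_anspm("scr_events needs columns: ", paste(need, collapse = ", "),
               class = "anspm_invalid_argument")
  }
  scr_events[need]
}

#' Helper to build SCR event tables
#' @param onset_s onsets in seconds.
#' @param amplitude_us amplitudes in microsiemens.
#' @param rise_s rise time constants (default 0.75 s).
#' @param decay_s decay time constants (default 3 s).
#' @return a data.frame usable as `scr_events` in [generate_eda()].
#' @export
scr_events <- function(onset_s, amplitude_us, rise_s = 0.75, decay_s = 3) {
  data.frame(onset_s = onset_s, amplitude_us = amplitude_us,
             rise_s = rise_s, decay_s = decay_s)
}

# ---------------------------------------------------------------------------
# Indicator-table ground truth

#' Ground truth for simulating indicator tables
#'
#' Describes the population the generator draws from: reflective loadings
#' for the nine physiological manifest variables plus the recall score,
#' per-indicator noise, and the three standardized structural path
#' coefficients (Sympathetic -> ANS, Vagal -> ANS, ANS -> Recall).
#'
#' @param loadings named numeric vector in `[-1, 1]`, one entry per manifest
#'   variable of the model spec (see [default_path_model()]).
#' @param path_coefficients numeric length-3 vector
#'   `(Sympathetic->ANS, Vagal->ANS, ANS->Recall)`.
#' @param noise_sd named numeric vector (>= 0) of indicator noise standard
#'   deviations; a single value is recycled.
#' @param n_subjects number of rows to simulate (>= 3).
#' @param seed integer seed.
#' @return a `latent_ground_truth` list.
#' @export
latent_ground_truth <- function(loadings, path_coefficients, noise_sd = 0,
                                n_subjects = 100L, seed = 1L) {
  if (any(abs(loadings) > 1)) {
    stop_anspm("|loadings| must be <= 1", class = "anspm_invalid_argument")
  }
  if (any(noise_sd < 0)) {
    stop_anspm("noise_sd must be >= 0", class = "anspm_invalid_argument")
  }
  if (length(path_coefficients) != 3L) {
    stop_anspm("path_coefficients must have length 3 ",
               "(Sympathetic->ANS, Vagal->ANS, ANS->Recall)",
               class = "anspm_invalid_argument")
  }
  if (n_subjects < 3L) {
    stop_anspm("n_subjects must be >= 3", class = "anspm_invalid_argument")
  }
  b <- path_coefficients
  if (b[1]^2 + b[2]^2 > 1 || b[3]^2 > 1) {
    stop_anspm("path coefficients imply negative disturbance variance; ",
               "need b1^2 + b2^2 <= 1 and b3^2 <= 1",
               class = "anspm_invalid_argument")
  }
  structure(list(loadings = loadings, path_coefficients = b,
                 noise_sd = noise_sd, n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed)),
            class = "latent_ground_truth")
}

#' Simulate an indicator table from latent ground truth
#'
#' Exogenous latent scores (Sympathetic, Vagal) are independent standard
#' normal; each endogenous latent variable is the weighted sum of its
#' predecessors plus a disturbance whose variance is set to
#' `1 - explained variance`, so every latent variable is exactly
#' unit-variance and the path coefficients read as standardized
#' coefficients. Manifest variables are `loading * LV + N(0, noise_sd)`.
#'
#' @param truth a [latent_ground_truth()].
#' @param path_spec a [path_model_spec()]; default [default_path_model()].
#' @return an indicator table data.frame: the nine physiological manifest
#'   variables, `recall_score`, and `gender` (`"F"`/`"M"`, balanced).
#' @export
generate_indicator_table <- function(truth, path_spec = default_path_model()) {
  stopifnot(inherits(truth, "latent_ground_truth"))
  validate_path_model(path_spec)
  mvs <- unlist(path_spec$blocks, use.names = FALSE)
  loadings <- rep_len_named(truth$loadings, mvs, "loadings")
  noise_sd <- rep_len_named(truth$noise_sd, mvs, "noise_sd")
  b <- truth$path_coefficients
  n <- truth$n_subjects
  with_seed(truth$seed, {
    symp <- stats::rnorm(n)
    vagal <- stats::rnorm(n)
    ans <- b[1] * symp + b[2] * vagal +
      stats::rnorm(n, 0, sqrt(max(0, 1 - b[1]^2 - b[2]^2)))
    recall <- b[3] * ans + stats::rnorm(n, 0, sqrt(max(0, 1 - b[3]^2)))
    lv <- cbind(Sympathetic = symp, Vagal = vagal, ANS = ans, Recall = recall)
    out <- matrix(NA_real_, n, length(mvs), dimnames = list(NULL, mvs))
    for (block in names(path_spec$blocks)) {
      for (mv in path_spec$blocks[[block]]) {
        eps <- if (noise_sd[mv] > 0) stats::rnorm(n, 0, noise_sd[mv]) else 0
        out[, mv] <- loadings[mv] * lv[, block] + eps
      }
    }
    tab <- as.data.frame(out)
    tab$gender <- rep(c("F", "M"), length.out = n)[sample.int(n)]
    tab
  })
}

rep_len_named <- function(x, names_out, what) {
  if (is.null(names(x))) {
    if (length(x) == 1L) x <- rep(x, length(names_out))
    if (length(x) != length(names_out)) {
      stop_anspm(what, " must be named, scalar, or match the number of MVs",
                 class = "anspm_invalid_argument")
    }
    names(x) <- names_out
  }
  missing <- setdiff(names_out, names(x))
  if (length(missing)) {
    stop_anspm(what, " missing entries for: ", paste(missing, collapse = ", "),
               class = "anspm_invalid_argument")
  }
  x[names_out]
}

# ---------------------------------------------------------------------------
# Raw channel container + CSV/JSON sidecar I/O

#' Raw signal channel
#' @param x numeric samples.
#' @param fs_hz sampling rate.
#' @param units unit string (e.g. `"mV"`, `"uS"`).
#' @return a `raw_channel` list.
#' @export
raw_channel <- function(x, fs_hz, units = "") {
  structure(list(x = as.numeric(x), fs_hz = fs_hz, units = units),
            class = "raw_channel")
}

#' @export
print.raw_channel <- function(x, ...) {
  cat(sprintf("<raw_channel> %d samples @ %g Hz [%s], %.1f s\n",
              length(x$x), x$fs_hz, x$units, length(x$x) / x$fs_hz))
  invisible(x)
}

#' Write a raw channel as two-column CSV plus a JSON sidecar
#'
#' @param channel a [raw_channel()].
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @param schedule optional [stimulus_schedule()] stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_channel_csv <- function(channel, path, schedule = NULL) {
  t <- seq_along(channel$x) / channel$fs_hz
  utils::write.csv(data.frame(time_s = t, value = channel$x),
                   path, row.names = FALSE)
  meta <- list(fs_hz = channel$fs_hz, units = channel$units)
  if (!is.null(schedule)) meta$schedule <- as.data.frame(schedule)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raw channel written by [write_channel_csv()]
#' @param path CSV path with a `<path>.json` sidecar next to it.
#' @return a list: `channel` ([raw_channel()]) and `schedule` (or NULL).
#' @export
read_channel_csv <- function(path) {
  dat <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sched <- NULL
  if (!is.null(meta$schedule)) {
    s <- meta$schedule
    sched <- stimulus_schedule(s$label, s$emotion, s$start_s, s$duration_s)
  }
  list(channel = raw_channel(dat$value, meta$fs_hz, meta$units),
       schedule = sched)
}
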