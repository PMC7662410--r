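# ECG / heart-rate-variability module: R-peak detection, NN-interval series
# with ectopic-beat exclusion, and the time- and frequency-domain indices
# used as manifest variables of the path model.

#' NN-interval series
#'
#' Beat times plus the normal-to-normal intervals between retained
#' (non-ectopic) beats. `nn_ms[i]` is the interval ending at
#' `beat_times_s[i + 1]`; `excluded[i]` marks intervals contaminated by an
#' ectopic beat, which all index computations skip.
#'
#' @param beat_times_s strictly increasing beat times, seconds.
#' @param excluded logical per-interval exclusion flags (default none).
#' @return an `nn_series` object.
#' @export
nn_series <- function(beat_times_s, excluded = NULL) {
  if (length(beat_times_s) < 2L) {
    stop_anspm("need at least 2 beats to form an interval",
               class = "anspm_invalid_argument")
  }
  if (any(diff(beat_times_s) <= 0)) {
    stop_anspm("beat times must be strictly increasing",
               class = "anspm_invalid_argument")
  }
  nn_ms <- diff(beat_times_s) * 1000
  if (is.null(excluded)) excluded <- rep(FALSE, length(nn_ms))
  stopifnot(length(excluded) == length(nn_ms))
  structure(list(beat_times_s = beat_times_s, nn_ms = nn_ms,
                 excluded = excluded),
            class = "nn_series")
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("<nn_series> %d beats, %d intervals (%d excluded), mean NN %.1f ms\n",
              length(x$beat_times_s), length(x$nn_ms), sum(x$excluded),
              mean(x$nn_ms[!x$excluded])))
  invisible(x)
}

#' Detect R-peaks in an ECG trace
#'
#' Pan-Tompkins-style energy detector: zero-phase 5-15 Hz band-pass,
#' derivative, squaring, 150 ms moving-window integration, adaptive
#' threshold on the integrated energy, then R-wave localization as the
#' raw-signal maximum near each energy peak. A 200 ms refractory period is
#' enforced throughout.
#'
#' @param ecg numeric samples in mV, or a [raw_channel()].
#' @param fs_hz sampling rate in Hz (>= 100); taken from the channel if
#'   `ecg` is a [raw_channel()].
#' @return numeric vector of beat times in seconds (time 0 = first sample).
#' @export
detect_r_peaks <- function(ecg, fs_hz = NULL) {
  if (inherits(ecg, "raw_channel")) {
    if (is.null(fs_hz)) fs_hz <- ecg$fs_hz
    ecg <- ecg$x
  }
  if (is.null(fs_hz) || fs_hz < 100) {
    stop_anspm("fs_hz must be >= 100 for reliable R-peak localization",
               class = "anspm_invalid_argument")
  }
  if (length(ecg) < 2 * fs_hz) {
    stop_anspm("signal too short (< 2 s)", class = "anspm_signal_error")
  }
  if (stats::sd(ecg) == 0) {
    stop_anspm("no beats detected: flat signal", class = "anspm_no_beats")
  }
  refractory <- as.integer(round(0.2 * fs_hz))
  bp <- bandpass_zerophase(ecg, fs_hz, 5, 15, order = 2L)
  energy <- (c(0, diff(bp)) * fs_hz)^2
  win <- as.integer(round(0.15 * fs_hz))
  cs <- cumsum(c(0, energy))
  n <- length(energy)
  lo <- pmax(0L, seq_len(n) - win)
  integ <- (cs[seq_len(n) + 1L] - cs[lo + 1L]) / (seq_len(n) - lo)
  cand <- find_peaks(integ, threshold = .Machine$double.eps,
                     min_separation = refractory)
  if (length(cand) == 0L) {
    stop_anspm("no beats detected", class = "anspm_no_beats")
  }
  h <- integ[cand]
  thr <- 0.3 * stats::quantile(h, 0.90, names = FALSE)
  cand <- cand[h > thr]
  if (length(cand) == 0L) {
    stop_anspm("no beats detected", class = "anspm_no_beats")
  }
  # localize the R wave: raw-signal maximum within +/- 100 ms of each
  # energy peak (integration window skews energy peaks rightward)
  half <- as.integer(round(0.1 * fs_hz))
  peaks <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(length(ecg), i + half)
    lo + which.max(ecg[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  if (length(peaks) > 1L) {  # re-enforce refractory after relocation
    keep <- c(TRUE, diff(peaks) >= refractory)
    while (!all(keep)) {
      drop <- which(!keep)[1]
      if (ecg[peaks[drop]] > ecg[peaks[drop - 1L]]) {
        peaks <- peaks[-(drop - 1L)]
      } else {
        peaks <- peaks[-drop]
      }
      keep <- c(TRUE, diff(peaks) >= refractory)
    }
  }
  (peaks - 1L) / fs_hz
}

#' Build an NN-interval series with ectopic exclusion
#'
#' Intervals deviating from a running 5-interval median by more than
#' `ectopic_rel_threshold` (relative) mark their terminating beat as
#' ectopic; every interval adjacent to an ectopic beat is excluded, since
#' both intervals touching a non-sinus beat are corrupted.
#'
#' @param beat_times_s strictly increasing beat times, seconds (>= 3 beats).
#' @param ectopic_rel_threshold relative deviation triggering exclusion
#'   (default 0.2).
#' @return an [nn_series()] with exclusion flags set.
#' @export
build_nn_series <- function(beat_times_s, ectopic_rel_threshold = 0.2) {
  if (length(beat_times_s) < 3L) {
    stop_anspm("need at least 3 beats", class = "anspm_invalid_argument")
  }
  nn <- diff(beat_times_s) * 1000
  if (any(nn <= 0)) {
    stop_anspm("beat times must be strictly increasing",
               class = "anspm_invalid_argument")
  }
  m <- length(nn)
  ref <- if (m >= 5L) {
    stats::runmed(nn, 5L, endrule = "median")
  } else {
    rep(stats::median(nn), m)
  }
  deviant <- abs(nn - ref) / ref > ectopic_rel_threshold
  # interval i ends at beat i+1; if that beat is ectopic, interval i+1
  # (starting there) is corrupted too
  excluded <- deviant | c(FALSE, deviant[-m])
  nn_series(beat_times_s, excluded = excluded)
}

retained_nn <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  nn$nn_ms[!nn$excluded]
}

#' Time-domain HRV indices
#'
#' Computed on retained intervals only. Successive differences are taken
#' between interval pairs that are adjacent in the original series and
#' both retained. `pnn50` is the proportion (in `[0, 1]`) of absolute
#' successive differences strictly greater than 50 ms; `sdnn` uses the
#' sample (n-1) standard deviation.
#'
#' @param nn an [nn_series()].
#' @return named list: `avnn`, `sdnn`, `rmssd` (ms), `pnn50` (proportion).
#' @examples
#' nn <- nn_series(c(0, 0.8, 1.61, 2.4, 3.22))
#' time_domain_indices(nn)
#' @export
time_domain_indices <- function(nn) {
  keep <- !nn$excluded
  x <- nn$nn_ms[keep]
  if (length(x) < 2L) {
    stop_anspm("need at least 2 retained intervals", class = "anspm_invalid_argument")
  }
  # successive differences only across adjacent retained pairs
  adj <- which(keep[-length(keep)] & keep[-1L])
  d <- nn$nn_ms[adj + 1L] - nn$nn_ms[adj]
  if (length(d) == 0L) {
    stop_anspm("no adjacent retained interval pairs", class = "anspm_invalid_argument")
  }
  list(
    avnn = mean(x),
    sdnn = stats::sd(x),
    rmssd = sqrt(mean(d^2)),
    pnn50 = mean(abs(d) > 50)
  )
}

#' Frequency-domain HRV indices
#'
#' The retained NN tachogram (interval vs. time of its terminating beat) is
#' cubic-spline interpolated onto a uniform grid at `resample_hz`,
#' linearly detrended, Hann-tapered and turned into a one-sided
#' periodogram. Band powers are integrated over VLF (0.003-0.04 Hz),
#' LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz). Normalized powers follow
#' `lf_norm = LF / (total - VLF) * 100` with the denominator taken as all
#' power above 0.04 Hz (i.e. total minus VLF and anything slower), so
#' `lf_norm + hf_norm <= 100` always holds. `lf_hf` is the ratio of
#' absolute band powers in ms^2.
#'
#' On 60 s epochs the spectral resolution is ~0.017 Hz, so the VLF
#' estimate is marked unreliable (`vlf_reliable = FALSE`) whenever the
#' epoch is shorter than 1 / 0.003 s; normalization still follows the
#' definition above.
#'
#' @param nn an [nn_series()].
#' @param resample_hz uniform resampling rate for the tachogram (default 4).
#' @return named list: `lf_norm`, `hf_norm` (percent), `lf_hf`
#'   (dimensionless), plus diagnostic absolute powers `lf_power`,
#'   `hf_power`, `vlf_power` (ms^2) and `vlf_reliable`.
#' @export
frequency_domain_indices <- function(nn, resample_hz = 4) {
  keep <- !nn$excluded
  t_end <- nn$beat_times_s[-1L][keep]
  x <- nn$nn_ms[keep]
  # a nominal 60 s epoch yields a tachogram spanning slightly less than
  # 60 s (first and last beats sit inside the epoch), so allow ~5 s slack
  if (length(x) < 4L || (max(t_end) - min(t_end)) < 55 - 1e-9) {
    stop_anspm("epoch must cover at least ~60 s of retained intervals",
               class = "anspm_invalid_argument")
  }
  grid <- seq(min(t_end), max(t_end), by = 1 / resample_hz)
  xs <- stats::spline(t_end, x, xout = grid, method = "fmm")$y
  ps <- periodogram_psd(xs, resample_hz)
  band_power <- function(flo, fhi) {
    sum(ps$psd[ps$freq_hz > flo & ps$freq_hz <= fhi]) * ps$df
  }
  vlf <- band_power(0.003, 0.04)
  lf <- band_power(0.04, 0.15)
  hf <- band_power(0.15, 0.4)
  total_above_vlf <- band_power(0.04, Inf)
  if (total_above_vlf <= .Machine$double.eps) {
    stop_anspm("spectral power numerically zero; indices undefined",
               class = "anspm_invalid_argument")
  }
  if (hf <= .Machine$double.eps) {
    stop_anspm("HF power numerically zero; lf_hf undefined",
               class = "anspm_invalid_argument")
  }
  list(
    lf_norm = lf / total_above_vlf * 100,
    hf_norm = hf / total_above_vlf * 100,
    lf_hf = lf / hf,
    lf_power = lf, hf_power = hf, vlf_power = vlf,
    vlf_reliable = (max(t_end) - min(t_end)) >= 1 / 0.003
  )
}

#' All HRV indices of one epoch
#'
#' Convenience wrapper combining [time_domain_indices()] and
#' [frequency_domain_indices()].
#'
#' @inheritParams frequency_domain_indices
#' @return one-row data.frame with columns `avnn`, `sdnn`, `rmssd`,
#'   `pnn50`, `lf`, `hf`, `lf_hf` (where `lf`/`hf` are the normalized
#'   percent powers used as manifest variables).
#' @export
hrv_indices <- function(nn, resample_hz = 4) {
  td <- time_domain_indices(nn)
  fd <- frequency_domain_indices(nn, resample_hz)
  data.frame(avnn = td$avnn, sdnn = td$sdnn, rmssd = td$rmssd,
             pnn50 = td$pnn50, lf = fd$lf_norm, hf = fd$hf_norm,
             lf_hf = fd$lf_hf)
}
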