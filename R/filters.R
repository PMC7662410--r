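# Minimal DSP toolbox used by the ECG and EDA feature extractors.
#
# Filtering is done in the frequency domain with the squared-magnitude
# response of a Butterworth design applied to a reflect-padded signal.
# Multiplying by a real, even frequency response is exactly zero-phase
# (the forward-backward "filtfilt" idea without edge transients), which
# matters here because epoch means must not be biased by filter delay.

#' Zero-phase low-pass filter
#'
#' @param x numeric signal.
#' @param fs_hz sampling rate in Hz.
#' @param cutoff_hz -3 dB cut-off frequency in Hz.
#' @param order Butterworth order of the underlying magnitude response.
#' @return filtered signal, same length as `x`.
#' @keywords internal
lowpass_zerophase <- function(x, fs_hz, cutoff_hz, order = 4L) {
  freq_filter_zerophase(x, fs_hz, function(f) {
    1 / (1 + (f / cutoff_hz)^(2L * order))
  })
}

#' Zero-phase band-pass filter (Butterworth magnitude response)
#' @keywords internal
bandpass_zerophase <- function(x, fs_hz, low_hz, high_hz, order = 2L) {
  freq_filter_zerophase(x, fs_hz, function(f) {
    hp <- ifelse(f == 0, 0, 1 / (1 + (low_hz / pmax(f, .Machine$double.eps))^(2L * order)))
    lp <- 1 / (1 + (f / high_hz)^(2L * order))
    hp * lp
  })
}

# Apply a real frequency-response gain |H(f)| to x, with reflect padding.
freq_filter_zerophase <- function(x, fs_hz, gain_fun) {
  n <- length(x)
  if (n < 4L) return(x)
  pad <- min(n - 1L, as.integer(round(3 * fs_hz)))  # 3 s of context each side
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  np <- length(xp)
  f <- seq(0, np - 1L) / np * fs_hz
  f <- pmin(f, fs_hz - f)  # two-sided -> folded frequency axis
  g <- gain_fun(f)
  y <- Re(stats::fft(stats::fft(xp) * g, inverse = TRUE)) / np
  y[(pad + 1L):(pad + n)]
}

#' Decimate a signal to a lower sampling rate with anti-alias filtering
#'
#' @param x numeric signal sampled at `fs_hz`.
#' @param fs_hz original sampling rate.
#' @param target_hz desired output rate; `fs_hz` must be an integer multiple.
#' @return list with `x` (decimated signal) and `fs_hz` (= target_hz).
#' @keywords internal
decimate_to <- function(x, fs_hz, target_hz) {
  if (fs_hz < target_hz) {
    stop_anspm("cannot decimate from ", fs_hz, " Hz to ", target_hz, " Hz",
               class = "anspm_invalid_argument")
  }
  factor <- fs_hz / target_hz
  if (abs(factor - round(factor)) > 1e-9) {
    stop_anspm("sampling rate ", fs_hz, " is not an integer multiple of ",
               target_hz, class = "anspm_invalid_argument")
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(list(x = x, fs_hz = target_hz))
  xf <- lowpass_zerophase(x, fs_hz, cutoff_hz = 0.4 * target_hz, order = 8L)
  list(x = xf[seq(1L, length(xf), by = factor)], fs_hz = target_hz)
}

# Triangular (Bartlett) window of length n, endpoints at zero.
bartlett_window <- function(n) {
  stopifnot(n >= 2L)
  k <- seq(0L, n - 1L)
  1 - abs((k - (n - 1) / 2) / ((n - 1) / 2))
}

# Indices of local maxima of x strictly above `threshold`, with at least
# `min_separation` samples between retained peaks (taller peak wins).
find_peaks <- function(x, threshold = -Inf, min_separation = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  core <- x[2:(n - 1L)]
  idx <- which(core > x[1:(n - 2L)] & core >= x[3:n] & core > threshold) + 1L
  if (length(idx) <= 1L || min_separation <= 1L) return(idx)
  # greedy pruning: keep tallest, drop neighbours closer than min_separation
  ord <- idx[order(x[idx], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_separation)) kept <- c(kept, i)
  }
  sort(kept)
}

# One-segment periodogram with a Hann taper on a detrended series.
# Returns frequencies (Hz) and one-sided PSD scaled so that
# sum(psd) * df == variance contributed by each band (units^2).
periodogram_psd <- function(x, fs_hz) {
  n <- length(x)
  x <- stats::residuals(stats::lm.fit(cbind(1, seq_len(n)), x))  # linear detrend
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1L) / (n - 1L))       # Hann
  xw <- x * w
  u <- sum(w^2)                      # window power normalisation
  sp <- abs(stats::fft(xw))^2 / (u * fs_hz)
  nh <- floor(n / 2)
  psd <- sp[2:(nh + 1L)] * 2        # one-sided, drop DC
  f <- seq_len(nh) * fs_hz / n
  list(freq_hz = f, psd = psd, df = fs_hz / n)
}
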