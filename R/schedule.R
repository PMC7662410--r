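#' Stimulus schedule
#'
#' An ordered, non-overlapping set of epochs (a baseline period followed by
#' advertisement spots), each tagged with the emotion it predominantly
#' conveys. All times are in seconds from the start of the recording.
#'
#' @param labels character vector of epoch labels.
#' @param emotions character vector; each one of `"baseline"`, `"rational"`,
#'   `"disgust"`, `"anger"`, `"surprise"`, `"sadness"`.
#' @param start_s numeric vector of epoch onsets (seconds).
#' @param duration_s numeric vector of epoch durations (seconds, > 0).
#' @return a `stimulus_schedule` object (a data.frame with one row per epoch).
#' @examples
#' sched <- default_schedule()
#' nrow(sched)        # 7 epochs: baseline + six spots
#' @export
stimulus_schedule <- function(labels, emotions, start_s, duration_s) {
  n <- length(labels)
  if (length(emotions) != n || length(start_s) != n || length(duration_s) != n) {
    stop_anspm("schedule fields must have equal length", class = "anspm_invalid_argument")
  }
  allowed <- c("baseline", "rational", "disgust", "anger", "surprise", "sadness")
  if (!all(emotions %in% allowed)) {
    stop_anspm("unknown emotion label; allowed: ", paste(allowed, collapse = ", "),
               class = "anspm_invalid_argument")
  }
  if (any(duration_s <= 0)) {
    stop_anspm("epoch durations must be > 0", class = "anspm_invalid_argument")
  }
  ord <- order(start_s)
  labels <- labels[ord]; emotions <- emotions[ord]
  start_s <- start_s[ord]; duration_s <- duration_s[ord]
  if (n > 1L && any(start_s[-1L] < (start_s + duration_s)[-n] - 1e-9)) {
    stop_anspm("epochs overlap", class = "anspm_invalid_argument")
  }
  structure(
    data.frame(label = labels, emotion = emotions,
               start_s = start_s, duration_s = duration_s,
               stringsAsFactors = FALSE),
    class = c("stimulus_schedule", "data.frame")
  )
}

#' Default stimulus schedule: 1 min baseline plus six 1 min spots
#'
#' Spot order: rational (traffic speed), disgust (cocaine use), anger
#' (child abuse), surprise (alcohol and driving), sadness (road
#' distractions), rational (addiction treatments).
#'
#' @param spot_duration_s spot length in seconds (default 60).
#' @param baseline_duration_s baseline length in seconds (default 60).
#' @return a [stimulus_schedule()].
#' @export
default_schedule <- function(spot_duration_s = 60, baseline_duration_s = 60) {
  emotions <- c("baseline", "rational", "disgust", "anger",
                "surprise", "sadness", "rational")
  labels <- c("baseline", paste0("spot", 1:6))
  starts <- c(0, baseline_duration_s + spot_duration_s * 0:5)
  durs <- c(baseline_duration_s, rep(spot_duration_s, 6L))
  stimulus_schedule(labels, emotions, starts, durs)
}

schedule_total_duration <- function(schedule) {
  max(schedule$start_s + schedule$duration_s)
}
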