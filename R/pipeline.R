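# End-to-end study pipeline: epoch segmentation, feature extraction,
# indicator-table assembly, per-spot PLS-PM fits with bootstrap
# significance, gender permutation comparison, and report generation.

#' Slice a recording into stimulus epochs
#'
#' @param channel a [raw_channel()].
#' @param schedule a [stimulus_schedule()].
#' @return named list of [raw_channel()] slices, one per epoch, boundaries
#'   sample-accurate at the channel's sampling rate.
#' @export
segment_epochs <- function(channel, schedule) {
  stopifnot(inherits(channel, "raw_channel"),
            inherits(schedule, "stimulus_schedule"))
  fs <- channel$fs_hz
  n <- length(channel$x)
  need <- schedule_total_duration(schedule)
  if (n < floor(need * fs)) {
    stop_anspm(sprintf("recording (%.1f s) shorter than schedule (%.1f s)",
                       n / fs, need), class = "anspm_coverage_error")
  }
  out <- lapply(seq_len(nrow(schedule)), function(i) {
    lo <- floor(schedule$start_s[i] * fs) + 1L
    hi <- floor((schedule$start_s[i] + schedule$duration_s[i]) * fs)
    raw_channel(channel$x[lo:hi], fs, channel$units)
  })
  names(out) <- schedule$label
  out
}

#' Assemble the subject-by-spot indicator table
#'
#' Joins per subject-spot HRV indices, EDA features, recall scores and
#' gender into the table consumed by [fit_plspm()]. Subjects missing any
#' spot in any input are dropped entirely (mirroring a per-subject quality
#' exclusion); the dropped ids are attached as attribute
#' `dropped_subjects` and reported via a message.
#'
#' @param hrv data.frame: `subject_id`, `spot`, `avnn`, `sdnn`, `rmssd`,
#'   `pnn50`, `lf`, `hf`, `lf_hf`.
#' @param eda data.frame: `subject_id`, `spot`, `mean_scl`, `ns_scr`.
#' @param recall data.frame: `subject_id`, `spot`, `recall_score` (a
#'   `spot` column is optional; without it the score is recycled across
#'   spots).
#' @param gender data.frame: `subject_id`, `gender`.
#' @return data.frame with exactly the 11 model columns `lf`, `sdnn`,
#'   `ns_scr`, `mean_scl`, `hf`, `pnn50`, `rmssd`, `lf_hf`, `avnn`,
#'   `recall_score`, `gender`; row keys (subject, spot) are attached as
#'   attribute `keys`.
#' @export
assemble_indicator_table <- function(hrv, eda, recall, gender) {
  for (d in list(hrv, eda)) {
    if (anyDuplicated(d[c("subject_id", "spot")])) {
      stop_anspm("duplicate subject x spot keys", class = "anspm_key_error")
    }
  }
  if (!("spot" %in% names(recall))) {
    recall <- merge(unique(hrv[c("subject_id", "spot")]), recall,
                    by = "subject_id")
  }
  if (anyDuplicated(recall[c("subject_id", "spot")])) {
    stop_anspm("duplicate subject x spot keys in recall", class = "anspm_key_error")
  }
  tab <- merge(hrv, eda, by = c("subject_id", "spot"))
  tab <- merge(tab, recall, by = c("subject_id", "spot"))
  tab <- merge(tab, gender, by = "subject_id")
  n_spots <- length(unique(c(hrv$spot, eda$spot, recall$spot)))
  counts <- table(tab$subject_id)
  complete <- names(counts)[counts == n_spots]
  all_ids <- unique(c(hrv$subject_id, eda$subject_id,
                      recall$subject_id, gender$subject_id))
  dropped <- setdiff(all_ids, complete)
  if (length(dropped)) {
    message("dropping ", length(dropped),
            " subject(s) with incomplete epochs: ",
            paste(dropped, collapse = ", "))
  }
  tab <- tab[tab$subject_id %in% complete, , drop = FALSE]
  tab <- tab[order(tab$subject_id, tab$spot), , drop = FALSE]
  cols <- c("lf", "sdnn", "ns_scr", "mean_scl", "hf", "pnn50", "rmssd",
            "lf_hf", "avnn", "recall_score", "gender")
  missing_cols <- setdiff(cols, names(tab))
  if (length(missing_cols)) {
    stop_anspm("inputs lack columns: ", paste(missing_cols, collapse = ", "),
               class = "anspm_key_error")
  }
  out <- tab[, cols]
  rownames(out) <- NULL
  attr(out, "keys") <- data.frame(subject_id = tab$subject_id,
                                  spot = tab$spot)
  attr(out, "dropped_subjects") <- dropped
  out
}

#' Study configuration
#'
#' @param synthetic list describing the simulated study. `mode = "table"`
#'   draws indicator tables directly from latent ground truth
#'   (`loadings`, `path_coefficients`, `noise_sd`); `mode = "signals"`
#'   synthesizes raw ECG/EDA per subject and runs the full feature
#'   pipeline. Common field: `n_subjects`.
#' @param schedule a [stimulus_schedule()] (default [default_schedule()]).
#' @param model a [path_model_spec()] (default [default_path_model()]).
#' @param scoring a [scoring_scheme()] (default [default_recall_scheme()]);
#'   used in `"signals"` mode to score simulated questionnaires.
#' @param n_spots number of advertisement spots the model run expects;
#'   must equal the schedule's non-baseline epoch count (default 6).
#' @param analysis list of analysis options: `scheme`, `tol`, `n_boot`,
#'   `n_perm`, `alpha`, `seed`.
#' @return a `study_config` object.
#' @export
study_config <- function(synthetic = list(mode = "table", n_subjects = 50),
                         schedule = default_schedule(),
                         model = default_path_model(),
                         scoring = default_recall_scheme(),
                         n_spots = 6L,
                         analysis = list()) {
  defaults <- list(scheme = "path", tol = 1e-7, n_boot = 500L,
                   n_perm = 999L, alpha = 0.05, seed = 1L)
  analysis <- utils::modifyList(defaults, analysis)
  spots <- sum(schedule$emotion != "baseline")
  if (spots != n_spots) {
    stop_anspm("schedule has ", spots, " spots but the model run expects ",
               n_spots, class = "anspm_config_error")
  }
  if (is.null(analysis$seed)) {
    stop_anspm("a seed is required (stochastic stages enabled)",
               class = "anspm_config_error")
  }
  if (is.null(synthetic$mode) ||
      !synthetic$mode %in% c("table", "signals")) {
    stop_anspm("synthetic$mode must be 'table' or 'signals'",
               class = "anspm_config_error")
  }
  structure(list(synthetic = synthetic, schedule = schedule, model = model,
                 scoring = scoring, n_spots = n_spots, analysis = analysis),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Recognized top-level keys: `synthetic` (mode, n_subjects, loadings,
#' path_coefficients, noise_sd, ...), `n_spots`, `analysis`
#' (scheme, tol, n_boot, n_perm, alpha, seed), and optionally `schedule`
#' (list with label/emotion/start_s/duration_s vectors).
#'
#' @param path YAML file path.
#' @return a [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  sched <- if (!is.null(y$schedule)) {
    stimulus_schedule(y$schedule$label, y$schedule$emotion,
                      y$schedule$start_s, y$schedule$duration_s)
  } else default_schedule()
  args <- list(schedule = sched)
  if (!is.null(y$synthetic)) args$synthetic <- y$synthetic
  if (!is.null(y$n_spots)) args$n_spots <- y$n_spots
  if (!is.null(y$analysis)) args$analysis <- y$analysis
  do.call(study_config, args)
}

# --------------------------------------------------------------------------
# Simulated raw recordings for one subject (signals mode)

# Physiologically plausible resting defaults: RR ~ 850 ms (~70 bpm), LF and
# HF modulation ~25 ms each, 10 ms white jitter; SCL ~5 uS with mild drift
# and a handful of SCRs per minute during emotional content.
simulate_subject_recording <- function(schedule, seed,
                                       mean_rr_ms = 850, lf_amp_ms = 25,
                                       hf_amp_ms = 25, jitter_sd_ms = 10,
                                       fs_hz = 250,
                                       scl_level_us = 5,
                                       drift_us_per_min = 0.2,
                                       scr_rate_per_min = 3,
                                       scr_amp_us = 0.4,
                                       ecg_noise_mv = 0.02,
                                       eda_noise_us = 0.005) {
  total <- schedule_total_duration(schedule)
  beats <- numeric(0)
  t0 <- 0
  for (i in seq_len(nrow(schedule))) {
    ep <- schedule[i, ]
    # modest emotion-dependent autonomic shifts (user-configurable world,
    # not calibrated to any study): emotional spots damp HF, boost LF
    emo <- ep$emotion
    lf <- lf_amp_ms * if (emo %in% c("anger", "disgust", "surprise")) 1.3 else 1
    hf <- hf_amp_ms * if (emo %in% c("baseline", "rational")) 1.2 else 0.8
    nn <- generate_nn_series(ep$duration_s, mean_rr_ms, lf, hf,
                             0.1, 0.25, jitter_sd_ms,
                             seed = derive_seed(seed, 10L + i))
    beats <- c(beats, nn$beat_times_s[nn$beat_times_s <= ep$duration_s] +
                 ep$start_s)
    t0 <- ep$start_s + ep$duration_s
  }
  beats <- sort(unique(beats))
  beats <- beats[c(TRUE, diff(beats) > 0.3)]  # drop boundary collisions
  ecg <- generate_ecg(list(beat_times_s = beats), fs_hz, 1, ecg_noise_mv,
                      seed = derive_seed(seed, 1L))
  # SCR events: homogeneous within epochs, rate raised on emotional spots
  onsets <- numeric(0)
  amps <- numeric(0)
  ev_seed <- derive_seed(seed, 2L)
  with_seed(ev_seed, {
    for (i in seq_len(nrow(schedule))) {
      ep <- schedule[i, ]
      rate <- scr_rate_per_min *
        if (ep$emotion %in% c("baseline", "rational")) 0.6 else 1.2
      k <- stats::rpois(1, rate * ep$duration_s / 60)
      if (k > 0) {
        o <- sort(stats::runif(k, ep$start_s + 1, ep$start_s + ep$duration_s - 5))
        o <- o[c(TRUE, diff(o) > 2)]  # enforce separability
        onsets <- c(onsets, o)
        amps <- c(amps, scr_amp_us * stats::rlnorm(length(o), 0, 0.3))
      }
    }
  })
  eda <- generate_eda(total, scl_level_us, drift_us_per_min,
                      if (length(onsets)) scr_events(onsets, amps) else NULL,
                      fs_hz = 100, noise_sd_us = eda_noise_us,
                      seed = derive_seed(seed, 3L))
  list(ecg = ecg, eda = eda)
}

#' Extract per-epoch features from one subject's recording
#'
#' @param ecg,eda [raw_channel()] objects covering the full schedule.
#' @param schedule a [stimulus_schedule()].
#' @return data.frame with one row per epoch: `spot`, `emotion`, the HRV
#'   indices and the EDA features.
#' @export
features_from_recording <- function(ecg, eda, schedule) {
  ecg_ep <- segment_epochs(ecg, schedule)
  eda_ep <- segment_epochs(eda, schedule)
  rows <- lapply(seq_len(nrow(schedule)), function(i) {
    lab <- schedule$label[i]
    beats <- detect_r_peaks(ecg_ep[[lab]])
    nn <- build_nn_series(beats)
    h <- hrv_indices(nn)
    e <- eda_features(eda_ep[[lab]])
    cbind(data.frame(spot = lab, emotion = schedule$emotion[i],
                     stringsAsFactors = FALSE), h, e)
  })
  do.call(rbind, rows)
}

# Simulated questionnaire: each item answered correctly with probability
# p_correct, scored with the study's scoring scheme.
simulate_recall_scores <- function(subject_ids, spots, scheme, seed,
                                   p_correct = 0.4) {
  items <- scheme$items
  with_seed(seed, {
    rows <- expand.grid(subject_id = subject_ids, spot = spots,
                        stringsAsFactors = FALSE)
    rows$recall_score <- vapply(seq_len(nrow(rows)), function(k) {
      correct <- stats::runif(nrow(items)) < p_correct
      ans <- ifelse(correct, items$correct_answer, "wrong")
      score_questionnaire(data.frame(item_id = items$item_id, answer = ans,
                                     stringsAsFactors = FALSE),
                          scheme)$score
    }, numeric(1))
    rows
  })
}

#' Run a full study end-to-end
#'
#' Executes: synthetic data generation (indicator tables, or raw signals
#' followed by segmentation, feature extraction and recall scoring), then
#' one independent sign-aligned PLS-PM fit per advertisement spot with
#' bootstrap significance, and a gender permutation comparison per spot.
#' Fully deterministic given the configuration seed. No multiple-testing
#' correction is applied across spots or edges; the report says so.
#'
#' @param config a [study_config()].
#' @return a `study_report` list: `spots` (per-spot results: path
#'   coefficients with bootstrap CIs, R-squared, GoF, gender comparison,
#'   recall summaries), `baseline` (signals mode only), `provenance`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  an <- config$analysis
  seed <- as.integer(an$seed)
  sched <- config$schedule
  spots <- sched[sched$emotion != "baseline", , drop = FALSE]
  syn <- config$synthetic
  n_sub <- as.integer(syn$n_subjects %||% 50L)

  if (syn$mode == "table") {
    loadings <- unlist(syn$loadings %||% 0.8)
    b_true <- as.numeric(unlist(syn$path_coefficients %||% c(0.4, -0.55, 0.3)))
    noise_sd <- unlist(syn$noise_sd %||% 0.5)
    gender_master <- with_seed(derive_seed(seed, 7L),
                               sample(rep(c("F", "M"), length.out = n_sub)))
    tables <- lapply(seq_len(nrow(spots)), function(i) {
      truth <- latent_ground_truth(loadings, b_true, noise_sd, n_sub,
                                   seed = derive_seed(seed, 100L + i))
      tab <- generate_indicator_table(truth, config$model)
      tab$gender <- gender_master
      tab
    })
    baseline_features <- NULL
  } else {
    per_subject <- lapply(seq_len(n_sub), function(s) {
      rec <- simulate_subject_recording(sched, derive_seed(seed, 5000L + s))
      feats <- features_from_recording(rec$ecg, rec$eda, sched)
      feats$subject_id <- sprintf("S%02d", s)
      feats
    })
    feats <- do.call(rbind, per_subject)
    recall <- simulate_recall_scores(unique(feats$subject_id), spots$label,
                                     config$scoring, derive_seed(seed, 8L))
    gender <- data.frame(subject_id = sprintf("S%02d", seq_len(n_sub)),
                         gender = rep(c("F", "M"), length.out = n_sub))
    baseline_features <- feats[feats$emotion == "baseline",
                               setdiff(names(feats), "emotion")]
    feats_spots <- feats[feats$emotion != "baseline", ]
    hrv <- feats_spots[c("subject_id", "spot", "avnn", "sdnn", "rmssd",
                         "pnn50", "lf", "hf", "lf_hf")]
    eda <- feats_spots[c("subject_id", "spot", "mean_scl", "ns_scr")]
    full <- assemble_indicator_table(hrv, eda, recall, gender)
    keys <- attr(full, "keys")
    tables <- lapply(spots$label, function(lab) {
      full[keys$spot == lab, , drop = FALSE]
    })
  }

  spot_results <- lapply(seq_len(nrow(spots)), function(i) {
    tab <- tables[[i]]
    fit <- fit_plspm(tab, config$model, scheme = an$scheme,
                     tol = an$tol)
    boot <- bootstrap_paths(tab, config$model, n_boot = an$n_boot,
                            seed = derive_seed(seed, 200L + i),
                            alpha = an$alpha, scheme = an$scheme)
    perm <- permutation_group_test(tab, config$model, group = tab$gender,
                                   n_perm = an$n_perm,
                                   seed = derive_seed(seed, 300L + i),
                                   scheme = an$scheme)
    recall_summary <- stats::aggregate(
      recall_score ~ gender, data = tab,
      FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
    list(
      spot = spots$label[i],
      emotion = spots$emotion[i],
      n = nrow(tab),
      paths = boot[, c("from", "to", "beta", "se", "ci_lo", "ci_hi",
                       "significant")],
      r_squared = as.list(fit$r_squared),
      gof = fit$gof,
      converged = fit$converged,
      flipped = fit$flipped,
      gender_comparison = perm$edges,
      recall_mean = mean(tab$recall_score),
      recall_by_gender = data.frame(
        gender = recall_summary$gender,
        mean = recall_summary$recall_score[, "mean"],
        sd = recall_summary$recall_score[, "sd"])
    )
  })
  names(spot_results) <- spots$label

  provenance <- list(
    package_version = as.character(utils::packageVersion("anspm")),
    seed = seed,
    mode = syn$mode,
    n_subjects = n_sub,
    analysis = an,
    note = paste("No multiple-testing correction is applied across the",
                 "spots or structural edges.")
  )
  structure(list(spots = spot_results, baseline = baseline_features,
                 provenance = provenance),
            class = "study_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a study report to disk
#'
#' Writes `report.json` (the full report) and per-spot CSV summaries of
#' path coefficients and gender comparisons. Output is deterministic:
#' rerunning an identical configuration reproduces the JSON byte for
#' byte.
#'
#' @param report a `study_report` from [run_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  paths <- do.call(rbind, lapply(report$spots, function(s) {
    cbind(data.frame(spot = s$spot, emotion = s$emotion), s$paths,
          row.names = NULL)
  }))
  utils::write.csv(paths, file.path(dir, "path_coefficients.csv"),
                   row.names = FALSE)
  gender <- do.call(rbind, lapply(report$spots, function(s) {
    cbind(data.frame(spot = s$spot), s$gender_comparison, row.names = NULL)
  }))
  utils::write.csv(gender, file.path(dir, "gender_comparison.csv"),
                   row.names = FALSE)
  fitstats <- do.call(rbind, lapply(report$spots, function(s) {
    data.frame(spot = s$spot, emotion = s$emotion, n = s$n,
               gof = s$gof,
               r2_ANS = s$r_squared$ANS %||% NA_real_,
               r2_Recall = s$r_squared$Recall %||% NA_real_,
               recall_mean = s$recall_mean)
  }))
  utils::write.csv(fitstats, file.path(dir, "fit_summary.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d spots, mode '%s', seed %d\n",
              length(x$spots), x$provenance$mode, x$provenance$seed))
  for (s in x$spots) {
    cat(sprintf("  %s (%s): GoF %.3f, R2[ANS] %.3f, R2[Recall] %.3f, recall mean %.2f\n",
                s$spot, s$emotion, s$gof,
                s$r_squared$ANS %||% NA, s$r_squared$Recall %||% NA,
                s$recall_mean))
  }
  invisible(x)
}
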