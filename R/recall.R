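# Recall-questionnaire scoring: each item carries a point budget that is
# fully awarded on a correct answer; the total ranges from 0 (no recall)
# to 15 (perfect recall).

#' Scoring scheme for the recall questionnaire
#'
#' @param items data.frame with columns `item_id`, `kind` (one of
#'   `"spontaneous_message"`, `"emotion_match"`, `"suggested_yesno"`,
#'   `"suggested_message"`), `max_points` (>= 0) and `correct_answer`.
#'   For multi-select items (`suggested_message`), `correct_answer` is a
#'   `;`-separated set of correct options.
#' @return a `scoring_scheme` object. Max points must sum to 15.
#' @export
scoring_scheme <- function(items) {
  need <- c("item_id", "kind", "max_points", "correct_answer")
  if (!is.data.frame(items) || !all(need %in% names(items))) {
    stop_anspm("items needs columns: ", paste(need, collapse = ", "),
               class = "anspm_invalid_argument")
  }
  kinds <- c("spontaneous_message", "emotion_match",
             "suggested_yesno", "suggested_message")
  if (!all(items$kind %in% kinds)) {
    stop_anspm("unknown item kind; allowed: ", paste(kinds, collapse = ", "),
               class = "anspm_invalid_argument")
  }
  if (any(items$max_points < 0)) {
    stop_anspm("max_points must be >= 0", class = "anspm_invalid_argument")
  }
  if (abs(sum(items$max_points) - 15) > 1e-9) {
    stop_anspm("max_points must sum to 15 (got ", sum(items$max_points), ")",
               class = "anspm_invalid_scheme")
  }
  if (anyDuplicated(items$item_id)) {
    stop_anspm("duplicate item_id", class = "anspm_invalid_argument")
  }
  structure(list(items = items), class = "scoring_scheme")
}

#' Default recall scoring scheme
#'
#' The item-level point allocation of the original questionnaire is not
#' public, so the shipped default spreads the 15 points equally across 10
#' items (1.5 points each): six spontaneous-message items (one per spot),
#' one emotion-match item, two suggested yes/no items and one
#' suggested-message multi-select item. Whether spontaneous and suggested
#' sections should carry equal weight is a modeling choice; weights are
#' fully configurable via [scoring_scheme()].
#'
#' @return a [scoring_scheme()].
#' @export
default_recall_scheme <- function() {
  items <- data.frame(
    item_id = c(paste0("spont_spot", 1:6),
                "emotion_overall", "sugg_yes1", "sugg_yes2", "sugg_multi"),
    kind = c(rep("spontaneous_message", 6L), "emotion_match",
             "suggested_yesno", "suggested_yesno", "suggested_message"),
    max_points = rep(1.5, 10L),
    correct_answer = c(rep("correct", 7L), "yes", "yes", "msg1;msg2;msg3"),
    stringsAsFactors = FALSE
  )
  scoring_scheme(items)
}

#' Score one subject's questionnaire responses
#'
#' Single-answer items award `max_points` when the answer matches the key
#' and 0 otherwise. Multi-select items (`suggested_message`) award
#' proportional credit: `max_points * (correct selections - incorrect
#' selections) / n correct options`, floored at 0. Missing responses score
#' 0 and are reported in `missing_items`.
#'
#' @param responses data.frame with columns `item_id` and `answer`; for
#'   multi-select items `answer` is a `;`-separated selection set.
#' @param scheme a [scoring_scheme()].
#' @param subject_id optional identifier carried into the result.
#' @return a `recall_score` list: `subject_id`, `score` in `[0, 15]`,
#'   `per_item` data.frame, `missing_items`.
#' @export
score_questionnaire <- function(responses, scheme = default_recall_scheme(),
                                subject_id = NA) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  items <- scheme$items
  if (nrow(responses) > 0) {
    unknown <- setdiff(responses$item_id, items$item_id)
    if (length(unknown)) {
      stop_anspm("unknown item_id in responses: ", paste(unknown, collapse = ", "),
                 class = "anspm_invalid_argument")
    }
    if (anyDuplicated(responses$item_id)) {
      stop_anspm("duplicate item_id in responses", class = "anspm_invalid_argument")
    }
  }
  ans <- stats::setNames(as.character(responses$answer), responses$item_id)
  pts <- numeric(nrow(items))
  for (i in seq_len(nrow(items))) {
    it <- items[i, ]
    a <- unname(ans[it$item_id])
    if (is.na(a) || !nzchar(a)) { pts[i] <- 0; next }
    if (it$kind == "suggested_message") {
      key <- strsplit(it$correct_answer, ";", fixed = TRUE)[[1]]
      sel <- strsplit(a, ";", fixed = TRUE)[[1]]
      hit <- sum(sel %in% key)
      miss <- sum(!(sel %in% key))
      pts[i] <- it$max_points * max(0, (hit - miss) / length(key))
    } else {
      pts[i] <- if (identical(a, it$correct_answer)) it$max_points else 0
    }
  }
  missing_items <- items$item_id[!(items$item_id %in% names(ans)) |
                                   is.na(ans[items$item_id])]
  structure(list(
    subject_id = subject_id,
    score = sum(pts),
    per_item = data.frame(item_id = items$item_id, points = pts,
                          stringsAsFactors = FALSE),
    missing_items = missing_items
  ), class = "recall_score")
}

#' Score a long-format response table for many subjects
#'
#' @param responses data.frame with columns `subject_id`, `item_id`, `answer`.
#' @param scheme a [scoring_scheme()].
#' @return data.frame with one row per subject: `subject_id`, `recall_score`.
#' @export
score_response_table <- function(responses, scheme = default_recall_scheme()) {
  ids <- unique(responses$subject_id)
  scores <- vapply(ids, function(sid) {
    score_questionnaire(responses[responses$subject_id == sid,
                                  c("item_id", "answer")],
                        scheme, subject_id = sid)$score
  }, numeric(1))
  data.frame(subject_id = ids, recall_score = scores)
}
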