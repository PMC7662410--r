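all_correct_responses <- function(scheme) {
  data.frame(item_id = scheme$items$item_id,
             answer = scheme$items$correct_answer,
             stringsAsFactors = FALSE)
}

test_that("perfect and null recall hit the scale endpoints", {
  scheme <- default_recall_scheme()
  expect_equal(score_questionnaire(all_correct_responses(scheme), scheme)$score, 15)
  wrong <- data.frame(item_id = scheme$items$item_id, answer = "nope")
  expect_equal(score_questionnaire(wrong, scheme)$score, 0)
  blank <- data.frame(item_id = character(0), answer = character(0))
  res <- score_questionnaire(blank, scheme)
  expect_equal(res$score, 0)
  expect_setequal(res$missing_items, scheme$items$item_id)
})

test_that("half of equally weighted items correct scores 7.5", {
  scheme <- default_recall_scheme()
  resp <- all_correct_responses(scheme)
  resp$answer[6:10] <- "nope"
  expect_equal(score_questionnaire(resp, scheme)$score, 7.5)
})

test_that("multi-select items award proportional credit, floored at zero", {
  items <- data.frame(
    item_id = c("m", "pad"), kind = c("suggested_message", "suggested_yesno"),
    max_points = c(9, 6), correct_answer = c("a;b;c", "yes"))
  scheme <- scoring_scheme(items)
  sc <- function(ans) {
    score_questionnaire(data.frame(item_id = "m", answer = ans), scheme)$score
  }
  expect_equal(sc("a;b;c"), 9)
  expect_equal(sc("a;b"), 6)
  expect_equal(sc("a;zzz"), 0)        # one right minus one wrong
  expect_equal(sc("zzz;qqq"), 0)      # floored at zero
  expect_equal(sc("a;b;c;zzz"), 6)    # 3 right - 1 wrong of 3
})

test_that("schemes must budget exactly 15 points", {
  items <- data.frame(item_id = "x", kind = "suggested_yesno",
                      max_points = 10, correct_answer = "yes")
  expect_error(scoring_scheme(items), class = "anspm_invalid_scheme")
  expect_error(scoring_scheme(data.frame(item_id = "x", kind = "nope",
                                         max_points = 15, correct_answer = "y")),
               class = "anspm_invalid_argument")
})

test_that("unknown or duplicate items in responses are rejected", {
  scheme <- default_recall_scheme()
  expect_error(score_questionnaire(data.frame(item_id = "ghost", answer = "x"),
                                   scheme),
               class = "anspm_invalid_argument")
  dup <- data.frame(item_id = rep("sugg_yes1", 2), answer = "yes")
  expect_error(score_questionnaire(dup, scheme),
               class = "anspm_invalid_argument")
})

test_that("flipping any single answer to correct never decreases the score", {
  scheme <- default_recall_scheme()
  set.seed(5)
  for (rep in 1:10) {
    resp <- all_correct_responses(scheme)
    wrong_mask <- runif(nrow(resp)) < 0.5
    resp$answer[wrong_mask] <- "nope"
    base <- score_questionnaire(resp, scheme)$score
    fix <- which(wrong_mask)
    if (!length(fix)) next
    i <- sample(fix, 1)
    resp$answer[i] <- scheme$items$correct_answer[i]
    expect_gte(score_questionnaire(resp, scheme)$score, base)
  }
})

test_that("item order does not affect the total", {
  scheme <- default_recall_scheme()
  resp <- all_correct_responses(scheme)
  resp$answer[c(2, 4, 9)] <- "nope"
  shuffled <- resp[sample(nrow(resp)), ]
  expect_equal(score_questionnaire(shuffled, scheme)$score,
               score_questionnaire(resp, scheme)$score)
})

test_that("score_response_table scores many subjects at once", {
  scheme <- default_recall_scheme()
  good <- all_correct_responses(scheme); good$subject_id <- "s1"
  bad <- good; bad$subject_id <- "s2"; bad$answer <- "nope"
  out <- score_response_table(rbind(good, bad), scheme)
  expect_equal(out$recall_score[match(c("s1", "s2"), out$subject_id)], c(15, 0))
})
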