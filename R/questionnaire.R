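# s-EMBU-C questionnaire scoring, validity filtering, normalization and
# parenting-style typing.
#
# The short-form questionnaire has 21 items on a four-point Likert scale
# ("never occurs" ... "always occurs"), split over three dimensions:
# Rejection (6 items), Emotional Warmth (7 items), Overprotection (8 items).
# Each dimension's score is the mean of its item ratings, so scores live on
# the 1-4 scale.

#' Likert labels of the four-point response scale
#' @return Character vector of the four response labels, in increasing order.
#' @export
likert_labels <- function() {
  c("never occurs", "occasionally occurs", "often occurs", "always occurs")
}

#' Default scoring key for the 21-item questionnaire
#'
#' Maps item columns `r1..r6`, `e1..e7`, `o1..o8` to the dimensions
#' rejection, warmth (emotional warmth) and overprotection, in questionnaire
#' order. The published item list is not part of this package, so the key is
#' configurable: supply your own via [read_scoring_key()]. A `reverse` flag
#' is supported (reverse-scored items are recoded as `5 - rating`) but no
#' item in the default key is reversed.
#'
#' @return A tibble with columns `item`, `dimension`, `reverse`.
#' @export
default_scoring_key <- function() {
  tibble::tibble(
    item = c(paste0("r", 1:6), paste0("e", 1:7), paste0("o", 1:8)),
    dimension = rep(dimension_names(), times = c(6L, 7L, 8L)),
    reverse = FALSE
  )
}

#' Read a scoring key from YAML
#'
#' The YAML maps each item column name either to a dimension name or to a
#' mapping with fields `dimension` and (optionally) `reverse`.
#'
#' @param path Path to a YAML file.
#' @return A tibble with columns `item`, `dimension`, `reverse`.
#' @export
read_scoring_key <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) stopf("scoring key '%s' is empty", path)
  rows <- lapply(names(raw), function(item) {
    entry <- raw[[item]]
    if (is.character(entry)) {
      tibble::tibble(item = item, dimension = entry, reverse = FALSE)
    } else {
      tibble::tibble(item = item,
                     dimension = entry$dimension,
                     reverse = isTRUE(entry$reverse))
    }
  })
  key <- dplyr::bind_rows(rows)
  validate_scoring_key(key)
  key
}

validate_scoring_key <- function(key) {
  bad <- setdiff(unique(key$dimension), dimension_names())
  if (length(bad) > 0)
    stopf("unknown dimension(s) in scoring key: %s", paste(bad, collapse = ", "))
  counts <- table(factor(key$dimension, levels = dimension_names()))
  expected <- c(rejection = 6L, warmth = 7L, overprotection = 8L)
  if (!all(counts == expected))
    stopf("scoring key must have 6/7/8 items for rejection/warmth/overprotection, got %s",
          paste(counts, collapse = "/"))
  invisible(key)
}

#' Score one questionnaire response
#'
#' Each dimension score is the arithmetic mean of that dimension's item
#' ratings, so scores are on the 1-4 scale of the response options.
#'
#' @param ratings Named numeric vector (or single-row data frame) of item
#'   ratings in 1..4, named by the item columns of `key`.
#' @param key Scoring key, see [default_scoring_key()].
#' @return Named numeric vector `c(s_r, s_e, s_o)`.
#' @export
#' @examples
#' ratings <- stats::setNames(rep(2, 21), default_scoring_key()$item)
#' score_questionnaire(ratings)
score_questionnaire <- function(ratings, key = default_scoring_key()) {
  if (is.data.frame(ratings)) {
    stopifnot(nrow(ratings) == 1)
    ratings <- unlist(ratings[, intersect(names(ratings), key$item), drop = FALSE])
  }
  validate_scoring_key(key)
  missing <- setdiff(key$item, names(ratings))
  if (length(missing) > 0)
    stopf("missing item rating(s): %s", paste(missing, collapse = ", "))
  vals <- ratings[key$item]
  bad <- key$item[!(vals %in% 1:4)]
  if (length(bad) > 0)
    stopf("rating outside 1..4 for item(s): %s", paste(bad, collapse = ", "))
  vals <- ifelse(key$reverse, 5 - vals, vals)
  out <- tapply(vals, factor(key$dimension, levels = dimension_names()), mean)
  c(s_r = unname(out["rejection"]), s_e = unname(out["warmth"]),
    s_o = unname(out["overprotection"]))
}

#' Score a table of questionnaire responses
#'
#' @param responses Data frame with one row per participant, a `user_id`
#'   column and the item columns of `key`.
#' @inheritParams score_questionnaire
#' @return Tibble with columns `user_id`, `s_r`, `s_e`, `s_o`.
#' @export
score_questionnaires <- function(responses, key = default_scoring_key()) {
  validate_scoring_key(key)
  scores <- t(vapply(seq_len(nrow(responses)), function(i) {
    score_questionnaire(responses[i, , drop = FALSE], key)
  }, numeric(3)))
  tibble::tibble(user_id = responses$user_id,
                 s_r = scores[, 1], s_e = scores[, 2], s_o = scores[, 3])
}

#' Check the instructed-response (polygraph) item
#'
#' Participants are instructed to answer "occasionally occurs" for the father
#' and "always occurs" for the mother; any other combination (or a missing
#' answer) marks a careless responder.
#'
#' @param father,mother Character labels of the two polygraph answers
#'   (vectorized).
#' @return Logical vector, `TRUE` only for the instructed combination.
#' @export
check_polygraph <- function(father, mother) {
  ok <- !is.na(father) & !is.na(mother) &
    father == "occasionally occurs" & mother == "always occurs"
  unname(ok)
}

#' Normalize a 1-4 scale score to [-1, 1]
#'
#' Applies `y = (s - 2.5) / 1.5`, mapping the 1-4 questionnaire scale onto
#' the symmetric interval used by the assessment model's tanh output.
#'
#' @param s Numeric score(s) in [1, 4].
#' @return Normalized score(s) in [-1, 1].
#' @seealso [denormalize_score()]
#' @export
normalize_score <- function(s) {
  if (any(!is.finite(s)) || any(s < 1 | s > 4))
    stopf("scores must lie in [1, 4]")
  (s - 2.5) / 1.5
}

#' Map a normalized score back to the 1-4 scale
#' @param y Normalized score(s) in [-1, 1].
#' @return Score(s) in [1, 4].
#' @export
denormalize_score <- function(y) {
  if (any(!is.finite(y)) || any(y < -1 | y > 1))
    stopf("normalized scores must lie in [-1, 1]")
  y * 1.5 + 2.5
}

#' Classify a score triple into a parenting-style type
#'
#' Uses the three strict-inequality rules on the dimension scores:
#' * positive: `s_e > s_r + 1` and `s_e > s_o + 1`
#' * mixed: `|s_e - s_r| < 1` and `|s_e - s_o| < 1`
#' * negative: `s_e + 1 < s_r` and `s_e + 1 < s_o`
#'
#' The three regions are mutually exclusive; a triple satisfying none of them
#' (including boundary cases where a gap equals exactly 1) is classified
#' `"other"`.
#'
#' @param s_r,s_e,s_o Numeric vectors of dimension scores in [1, 4].
#' @return Factor with levels positive, mixed, negative, other.
#' @export
classify_style <- function(s_r, s_e, s_o) {
  positive <- (s_e > s_r + 1) & (s_e > s_o + 1)
  mixed <- (abs(s_e - s_r) < 1) & (abs(s_e - s_o) < 1)
  negative <- (s_e + 1 < s_r) & (s_e + 1 < s_o)
  out <- rep("other", length(s_e))
  out[positive] <- "positive"
  out[mixed] <- "mixed"
  out[negative] <- "negative"
  factor(out, levels = style_levels())
}

#' @rdname classify_style
#' @export
style_levels <- function() c("positive", "mixed", "negative", "other")

#' Filter participants by the validity rules
#'
#' A participant is kept when all three rules hold, evaluated in this order:
#' 1. the polygraph item is answered as instructed;
#' 2. the follower count is between 5 and 5,000 (inclusive);
#' 3. strictly more than 10 original posts fall inside the window.
#'
#' A rejected participant is reported with the first failing rule.
#'
#' @param users Data frame with columns `user_id`, `followers`,
#'   `polygraph_father`, `polygraph_mother`.
#' @param posts Data frame with columns `user_id`, `timestamp` (Date or
#'   coercible), `is_original`.
#' @param window Length-2 vector (start, end) of the activity window; posts
#'   with `start <= timestamp <= end` count.
#' @return List with elements `kept` (the retained rows of `users`) and
#'   `rejections` (tibble `user_id`, `reason`).
#' @export
filter_participants <- function(users, posts, window) {
  if (nrow(users) == 0)
    return(list(kept = users, rejections = tibble::tibble(user_id = character(),
                                                          reason = character())))
  window <- as.Date(window)
  stopifnot(length(window) == 2)
  ts <- as.Date(posts$timestamp)
  in_window <- posts$is_original & ts >= window[1] & ts <= window[2]
  n_orig <- tapply(in_window, posts$user_id, sum)

  reason <- rep(NA_character_, nrow(users))
  poly_ok <- check_polygraph(users$polygraph_father, users$polygraph_mother)
  reason[!poly_ok] <- "polygraph"
  foll_ok <- users$followers >= 5 & users$followers <= 5000
  reason[is.na(reason) & !foll_ok] <- "follower-bound"
  counts <- n_orig[as.character(users$user_id)]
  counts[is.na(counts)] <- 0
  reason[is.na(reason) & counts <= 10] <- "activity"

  list(kept = users[is.na(reason), , drop = FALSE],
       rejections = tibble::tibble(user_id = users$user_id[!is.na(reason)],
                                   reason = reason[!is.na(reason)]))
}

#' Summarize a scored dataset
#'
#' Reports per-type counts and percentages (denominator: the total of the
#' four groups, one-decimal half-up rounding), per-dimension mean scores and
#' gender counts per type. When the caller supplies `n_reported` (a claimed
#' total that may disagree with the grouped total), the discrepancy is kept
#' visible in the summary rather than silently reconciled.
#'
#' @param scored Data frame with columns `s_r`, `s_e`, `s_o`, `gender`, and
#'   optionally `style` (computed from the scores when absent).
#' @param n_reported Optional externally reported participant total.
#' @return An object of class `style_summary`.
#' @export
summarize_dataset <- function(scored, n_reported = NULL) {
  if (is.null(scored) || nrow(scored) == 0) stopf("cannot summarize an empty dataset")
  if (is.null(scored$style))
    scored$style <- classify_style(scored$s_r, scored$s_e, scored$s_o)
  scored$style <- factor(scored$style, levels = style_levels())
  counts <- as.integer(table(scored$style))
  total <- sum(counts)
  summary_tbl <- tibble::tibble(
    style = style_levels(),
    n = counts,
    pct = round_half_up(100 * counts / total, 1)
  )
  gender_tbl <- as_tibble(as.data.frame(table(style = scored$style,
                                              gender = scored$gender),
                                        stringsAsFactors = FALSE))
  names(gender_tbl)[3] <- "n"
  out <- list(
    counts = summary_tbl,
    dimension_means = c(s_r = mean(scored$s_r), s_e = mean(scored$s_e),
                        s_o = mean(scored$s_o)),
    gender_counts = gender_tbl,
    n_grouped = total,
    n_reported = n_reported %||% total,
    discrepancy = (n_reported %||% total) - total
  )
  class(out) <- "style_summary"
  out
}

#' @export
print.style_summary <- function(x, ...) {
  cat("Parenting-style dataset summary\n")
  cat(sprintf("  users grouped: %d (reported: %d%s)\n", x$n_grouped, x$n_reported,
              if (x$discrepancy != 0)
                sprintf("; %d unaccounted for", x$discrepancy) else ""))
  for (i in seq_len(nrow(x$counts)))
    cat(sprintf("  %-9s %5d (%.1f%%)\n", x$counts$style[i], x$counts$n[i],
                x$counts$pct[i]))
  cat(sprintf("  mean scores: s_r=%.2f s_e=%.2f s_o=%.2f\n",
              x$dimension_means[1], x$dimension_means[2], x$dimension_means[3]))
  invisible(x)
}

#' Read a questionnaire CSV
#'
#' Expects one row per participant with columns `user_id`, `gender`, `age`,
#' `followers`, `polygraph_father`, `polygraph_mother` and the 21 item
#' columns of the scoring key.
#'
#' @param path CSV path.
#' @return Tibble of responses.
#' @export
read_questionnaire_csv <- function(path) {
  as_tibble(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE))
}
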