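# Questionnaire scoring, validity filtering, normalization and style typing.

test_that("dimension scores are item means on the 1-4 scale", {
  key <- default_scoring_key()
  expect_equal(unname(table(key$dimension)[c("rejection", "warmth", "overprotection")]),
               c(6L, 7L, 8L), ignore_attr = TRUE)

  all_one <- setNames(rep(1, 21), key$item)
  expect_equal(score_questionnaire(all_one),
               c(s_r = 1, s_e = 1, s_o = 1))

  mixed <- setNames(c(1, 2, 1, 2, 1, 2, rep(3, 7), rep(4, 8)), key$item)
  expect_equal(score_questionnaire(mixed),
               c(s_r = 1.5, s_e = 3, s_o = 4))

  # reverse flag recodes as 5 - rating
  rkey <- key
  rkey$reverse[1] <- TRUE
  rev_scored <- score_questionnaire(all_one, rkey)
  expect_equal(unname(rev_scored["s_r"]), (4 + 5 * 1) / 6)
})

test_that("incomplete or out-of-range responses fail with the item named", {
  key <- default_scoring_key()
  ratings <- setNames(rep(2, 21), key$item)
  expect_error(score_questionnaire(ratings[-8]), "e2")
  bad <- ratings
  bad["o3"] <- 5
  expect_error(score_questionnaire(bad), "o3")
  bad["o3"] <- 0
  expect_error(score_questionnaire(bad), "o3")
})

test_that("scoring keys round-trip through YAML and are validated", {
  key <- default_scoring_key()
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(paste0(key$item, ": ", key$dimension), path)
  expect_equal(read_scoring_key(path)$dimension, key$dimension)

  writeLines(c("a1: rejection", "a2: warmth"), path)
  expect_error(read_scoring_key(path), "6/7/8")
  writeLines("a1: nonsense", path)
  expect_error(read_scoring_key(path), "unknown dimension")
})

test_that("polygraph check accepts only the instructed combination", {
  expect_true(check_polygraph("occasionally occurs", "always occurs"))
  expect_false(check_polygraph("always occurs", "occasionally occurs"))
  expect_false(check_polygraph("never occurs", "always occurs"))
  expect_false(check_polygraph(NA, "always occurs"))
  expect_equal(check_polygraph(c("occasionally occurs", "often occurs"),
                               c("always occurs", "always occurs")),
               c(TRUE, FALSE))
})

test_that("normalization maps [1,4] onto [-1,1] and round-trips", {
  expect_equal(normalize_score(2.5), 0)
  expect_equal(normalize_score(4), 1)
  expect_equal(normalize_score(1), -1)
  expect_error(normalize_score(0.9), "1, 4")
  expect_error(denormalize_score(1.2), "-1, 1")

  s <- runif(200, 1, 4)
  y <- normalize_score(s)
  expect_true(all(y >= -1 & y <= 1))
  expect_equal(denormalize_score(y), s, tolerance = 1e-12)
  expect_equal(denormalize_score(normalize_score(3.17)), 3.17,
               tolerance = 1e-12)
})

test_that("style typing follows the strict-inequality rules", {
  expect_equal(as.character(classify_style(1.5, 3.5, 2.0)), "positive")
  expect_equal(as.character(classify_style(2.0, 2.5, 2.5)), "mixed")
  expect_equal(as.character(classify_style(3.5, 1.5, 3.0)), "negative")
  expect_equal(as.character(classify_style(1.0, 2.5, 3.5)), "other")
  # a gap of exactly 1 satisfies no strict inequality
  expect_equal(as.character(classify_style(2.0, 3.0, 1.5)), "other")
})

test_that("the three typed regions are mutually exclusive on a dense grid", {
  g <- seq(1, 4, by = 0.1)
  grid <- expand.grid(s_r = g, s_e = g, s_o = g)
  pos <- (grid$s_e > grid$s_r + 1) & (grid$s_e > grid$s_o + 1)
  mix <- (abs(grid$s_e - grid$s_r) < 1) & (abs(grid$s_e - grid$s_o) < 1)
  neg <- (grid$s_e + 1 < grid$s_r) & (grid$s_e + 1 < grid$s_o)
  expect_true(all(pos + mix + neg <= 1))
  labelled <- classify_style(grid$s_r, grid$s_e, grid$s_o)
  expect_equal(as.character(labelled),
               ifelse(pos, "positive",
                      ifelse(mix, "mixed", ifelse(neg, "negative", "other"))))
})

make_filter_users <- function(...) {
  defaults <- list(user_id = "u1", followers = 100,
                   polygraph_father = "occasionally occurs",
                   polygraph_mother = "always occurs")
  args <- utils::modifyList(defaults, list(...))
  tibble::as_tibble(args)
}

make_filter_posts <- function(uid, n_orig, n_repost = 0) {
  tibble::tibble(user_id = uid,
                 timestamp = as.Date("2022-01-01") + seq_len(n_orig + n_repost),
                 is_original = rep(c(TRUE, FALSE), c(n_orig, n_repost)))
}

test_that("participant filtering applies the three rules in order", {
  window <- as.Date(c("2021-11-01", "2022-10-31"))

  res <- filter_participants(make_filter_users(followers = 4),
                             make_filter_posts("u1", 20), window)
  expect_equal(res$rejections$reason, "follower-bound")

  # exactly 10 original posts is not "more than 10"
  res <- filter_participants(make_filter_users(),
                             make_filter_posts("u1", 10, n_repost = 30), window)
  expect_equal(res$rejections$reason, "activity")

  # boundary pass: inclusive follower bounds, 11 originals
  res <- filter_participants(make_filter_users(followers = 5000),
                             make_filter_posts("u1", 11), window)
  expect_equal(nrow(res$kept), 1)
  expect_equal(nrow(res$rejections), 0)

  # polygraph failure masks later rules
  res <- filter_participants(
    make_filter_users(followers = 4, polygraph_father = "always occurs"),
    make_filter_posts("u1", 3), window)
  expect_equal(res$rejections$reason, "polygraph")

  # originals outside the window do not count
  res <- filter_participants(
    make_filter_users(),
    tibble::tibble(user_id = "u1", timestamp = as.Date("2020-01-01") + 1:20,
                   is_original = TRUE), window)
  expect_equal(res$rejections$reason, "activity")

  empty <- filter_participants(make_filter_users()[0, ],
                               make_filter_posts("u1", 1)[0, ], window)
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$rejections), 0)
})

test_that("filtering kept users again changes nothing", {
  users <- dplyr::bind_rows(
    make_filter_users(user_id = "a"),
    make_filter_users(user_id = "b", followers = 2),
    make_filter_users(user_id = "c", polygraph_mother = "never occurs"))
  posts <- dplyr::bind_rows(make_filter_posts("a", 30),
                            make_filter_posts("b", 30),
                            make_filter_posts("c", 30))
  window <- as.Date(c("2021-11-01", "2022-10-31"))
  once <- filter_participants(users, posts, window)
  twice <- filter_participants(once$kept, posts, window)
  expect_equal(twice$kept, once$kept)
  expect_equal(nrow(twice$rejections), 0)
})

test_that("dataset summary reproduces the published group arithmetic", {
  # representative score triples for each type, replicated at the published
  # group counts 379/162/16/14
  protos <- data.frame(
    s_r = c(1.5, 2.5, 3.0, 1.0), s_e = c(3.5, 2.5, 1.5, 2.5),
    s_o = c(2.0, 2.5, 3.0, 3.5))
  counts <- c(379, 162, 16, 14)
  scored <- protos[rep(1:4, counts), ]
  scored$gender <- rep(c("male", "female"), length.out = nrow(scored))
  sm <- summarize_dataset(scored, n_reported = 575)
  expect_equal(sm$counts$n, counts)
  expect_equal(sm$counts$pct, c(66.4, 28.4, 2.8, 2.5))
  expect_equal(sm$n_grouped, 571)
  expect_equal(sm$discrepancy, 4)

  # uniform case and degenerate cases
  four <- summarize_dataset(protos[rep(1:4, each = 1), ][, 1:3] |>
                              transform(gender = "female"))
  expect_equal(four$counts$pct, rep(25, 4))

  allpos <- summarize_dataset(data.frame(s_r = 1.2, s_e = 3.8, s_o = 1.4,
                                         gender = "male")[rep(1, 5), ])
  expect_equal(allpos$counts$pct[1], 100)
  expect_error(summarize_dataset(protos[0, ]), "empty")
})

test_that("summary percentages sum to 100 within rounding slack", {
  for (seed in 1:5) {
    scored <- with(list(), {
      set.seed(seed)
      data.frame(s_r = runif(200, 1, 4), s_e = runif(200, 1, 4),
                 s_o = runif(200, 1, 4),
                 gender = sample(c("male", "female"), 200, TRUE))
    })
    sm <- summarize_dataset(scored)
    expect_lt(abs(sum(sm$counts$pct) - 100), 0.2)
  }
})
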