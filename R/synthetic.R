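# Synthetic corpus generator. Emulates the statistical structure the
# assessment method relies on: each user carries latent parenting-dimension
# scores whose style type drives category-specific word usage, diluted by
# abundant noise posts (daily trivia) and occasional quotation posts written
# under another style's word distribution. Everything is reproducible from
# one seed.

#' Canonical category names of the two lexicons
#'
#' The topic lexicon's 11 categories and the affect lexicon's 7 emotion
#' categories used throughout the analyses.
#' @return Character vector of category names.
#' @export
topic_category_names <- function() {
  c("social", "family", "friend", "health", "work", "leisure", "money",
    "religion", "death", "psychology", "love")
}

#' @rdname topic_category_names
#' @export
emotion_category_names <- function() {
  c("happy", "like", "surprise", "angry", "sad", "fear", "hate")
}

# Default emission rates (percent of tokens) per style type, shaped like the
# published per-type mean proportions: the positive type leads on social /
# family / friend / work / leisure / money / psychology words, the mixed
# type on religion, the negative type on health / death / love and the
# negative emotions sad / fear / hate. The "other" type (no rule applies)
# uses the mixed type's rates.
default_topic_rates <- function() {
  m <- rbind(
    positive = c(5.64, 0.56, 0.26, 0.73, 4.20, 4.56, 1.78, 0.30, 0.17, 1.73, 0.09),
    mixed    = c(5.09, 0.39, 0.14, 0.64, 4.12, 4.01, 1.53, 0.32, 0.24, 1.65, 0.10),
    negative = c(5.12, 0.49, 0.13, 0.87, 3.80, 2.37, 0.90, 0.27, 0.38, 1.70, 0.14)
  )
  m <- rbind(m, other = m["mixed", ])
  colnames(m) <- topic_category_names()
  m
}

# Emotion rates are gender-stratified: under the negative type female users
# express markedly more sad / fear / hate than male users.
default_emotion_rates <- function() {
  male <- rbind(
    positive = c(7.53, 3.52, 0.06, 0.24, 0.23, 0.05, 0.72),
    mixed    = c(6.24, 4.39, 0.09, 0.13, 0.28, 0.11, 0.89),
    negative = c(6.81, 1.92, 0.07, 0.09, 0.12, 0.01, 0.36)
  )
  female <- rbind(
    positive = c(6.11, 3.93, 0.09, 0.17, 0.38, 0.09, 0.90),
    mixed    = c(5.33, 3.92, 0.06, 0.24, 0.50, 0.14, 0.92),
    negative = c(4.00, 3.91, 0.07, 0.19, 0.64, 0.15, 1.35)
  )
  male <- rbind(male, other = male["mixed", ])
  female <- rbind(female, other = female["mixed", ])
  colnames(male) <- colnames(female) <- emotion_category_names()
  list(male = male, female = female)
}

#' Specification of a synthetic corpus
#'
#' Defaults mirror the study conditions: 575 users, style mixture
#' 379/162/16/14 (positive/mixed/negative/other), 193.5 posts per user on
#' average (min 10, max 1987), male fraction 281/575, posts within the
#' 2019-11-01..2022-10-31 window, and per-style emission rates shaped like
#' the published topic/emotion proportion tables (with the gender
#' stratification of the emotion rates). Noise posts (daily trivia drawing
#' only filler vocabulary) occur with probability 0.5; quotation posts
#' (written under a different style's rates) with probability 0.05.
#'
#' @param n_users Number of users.
#' @param style_weights Named mixture weights over
#'   positive/mixed/negative/other (must sum to 1).
#' @param posts_mean,posts_min,posts_max Posts-per-user distribution
#'   (lognormal, clamped).
#' @param posts_sdlog Log-scale standard deviation of the posts-per-user
#'   distribution (0.9 reproduces a 10..~2000 range at the default mean).
#' @param tokens_per_post Mean tokens per post.
#' @param words_per_category Toy vocabulary size per lexicon category.
#' @param n_filler Filler (out-of-lexicon) vocabulary size.
#' @param noise_prob Probability a post is pure noise.
#' @param quote_prob Probability a non-noise post quotes another style.
#' @param male_frac Probability a user is male.
#' @param topic_rates 4 x 11 matrix of percent rates (styles x topics).
#' @param emotion_rates List `male`/`female` of 4 x 7 percent-rate matrices.
#' @param window Length-2 Date vector of the posting window.
#' @param seed Seed determining the whole corpus.
#' @return Object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_users = 575L,
                        style_weights = c(positive = 379, mixed = 162,
                                          negative = 16, other = 14) / 571,
                        posts_mean = 193.5, posts_min = 10L, posts_max = 1987L,
                        posts_sdlog = 0.9, tokens_per_post = 40,
                        words_per_category = 25L,
                        n_filler = 400L, noise_prob = 0.5, quote_prob = 0.05,
                        male_frac = 281 / 575,
                        topic_rates = default_topic_rates(),
                        emotion_rates = default_emotion_rates(),
                        window = as.Date(c("2019-11-01", "2022-10-31")),
                        seed = 1L) {
  if (abs(sum(style_weights) - 1) > 1e-9)
    stopf("style weights must sum to 1")
  if (!all(names(style_weights) == style_levels()))
    stopf("style weights must be named positive/mixed/negative/other")
  rates_ok <- all(topic_rates >= 0 & topic_rates <= 100) &&
    all(emotion_rates$male >= 0 & emotion_rates$male <= 100) &&
    all(emotion_rates$female >= 0 & emotion_rates$female <= 100)
  if (!rates_ok) stopf("emission rates must be percentages in [0, 100]")
  if (words_per_category < 1 || n_filler < 1) stopf("vocabulary sizes must be >= 1")
  if (posts_min < 1 || posts_max < posts_min) stopf("invalid posts-per-user bounds")
  structure(list(n_users = as.integer(n_users), style_weights = style_weights,
                 posts_mean = posts_mean, posts_min = as.integer(posts_min),
                 posts_max = as.integer(posts_max), posts_sdlog = posts_sdlog,
                 tokens_per_post = tokens_per_post,
                 words_per_category = as.integer(words_per_category),
                 n_filler = as.integer(n_filler), noise_prob = noise_prob,
                 quote_prob = quote_prob, male_frac = male_frac,
                 topic_rates = topic_rates, emotion_rates = emotion_rates,
                 window = as.Date(window), seed = as.integer(seed)),
            class = "corpus_spec")
}

#' @export
print.corpus_spec <- function(x, ...) {
  cat(sprintf("<corpus_spec: %d users, ~%.0f posts/user, seed %d>\n",
              x$n_users, x$posts_mean, x$seed))
  invisible(x)
}

# Toy vocabularies mimic the morphology real lexicons expose to a subword
# encoder: words within a category share the category stem (as Chinese
# affect words share characters) plus a distinct random letter suffix, and
# filler words are unrelated random strings with no common stem. Must be
# called under an established RNG seed.
random_strings <- function(n, len) {
  out <- replicate(n, paste(sample(letters, len, replace = TRUE),
                            collapse = ""))
  while (anyDuplicated(out)) {
    dup <- duplicated(out)
    out[dup] <- replicate(sum(dup), paste(sample(letters, len, replace = TRUE),
                                          collapse = ""))
  }
  out
}

toy_vocab <- function(categories, words_per_category) {
  stats::setNames(lapply(categories, function(cat) {
    paste0(cat, random_strings(words_per_category, 3L))
  }), categories)
}

# Scores are sampled uniformly from the style type's feasible sub-region of
# [1,4]^3, then snapped to the item-mean grid (multiples of 1/6, 1/7, 1/8)
# so a questionnaire with integer ratings can reproduce them exactly; the
# snap is re-checked against the type and resampled on the rare boundary
# crossing.
sample_scores <- function(style) {
  repeat {
    s <- runif(3, 1, 4)
    s <- c(round(s[1] * 6) / 6, round(s[2] * 7) / 7, round(s[3] * 8) / 8)
    s <- pmin(pmax(s, 1), 4)
    if (as.character(classify_style(s[1], s[2], s[3])) == style) return(s)
  }
}

# Integer 1-4 item ratings whose mean is exactly the (grid-snapped) score.
allocate_items <- function(score, k) {
  total <- round(score * k)
  base <- total %/% k
  extra <- total %% k
  if (base == 4) { base <- 3; extra <- k } # score exactly 4
  ratings <- c(rep(base + 1L, extra), rep(base, k - extra))
  sample(ratings)
}

#' Generate a synthetic corpus
#'
#' See [corpus_spec()] for the generating mechanism. Each user receives a
#' style type from the mixture, latent scores uniform in that type's score
#' region, a questionnaire whose item means reproduce the scores exactly,
#' and a post history: noise posts draw only filler tokens; quotation posts
#' draw another style's (and a random gender's) rates; ordinary posts draw
#' category tokens at the user's style- and gender-specific percent rates.
#'
#' @param spec A [corpus_spec()].
#' @return List with `users` (tibble of attributes, true scores and style),
#'   `questionnaires`, `posts` (tibble `user_id`, `text`, `timestamp`,
#'   `is_original`), `topic_lexicon`, `emotion_lexicon`, `spec`.
#' @export
generate_corpus <- function(spec = corpus_spec()) {
  cat_names <- c(topic_category_names(), emotion_category_names())
  days <- seq(spec$window[1], spec$window[2], by = "day")
  meanlog <- log(spec$posts_mean) - spec$posts_sdlog^2 / 2

  with_seed(spec$seed, {
    topics <- toy_vocab(topic_category_names(), spec$words_per_category)
    emotions <- toy_vocab(emotion_category_names(), spec$words_per_category)
    filler <- random_strings(spec$n_filler, 7L)
    vocab <- c(topics, emotions)
    users <- vector("list", spec$n_users)
    quests <- vector("list", spec$n_users)
    posts <- vector("list", spec$n_users)
    styles <- sample(style_levels(), spec$n_users, replace = TRUE,
                     prob = spec$style_weights)
    genders <- sample(c("male", "female"), spec$n_users, replace = TRUE,
                      prob = c(spec$male_frac, 1 - spec$male_frac))

    for (i in seq_len(spec$n_users)) {
      uid <- sprintf("u%04d", i)
      style <- styles[i]
      gender <- genders[i]
      s <- sample_scores(style)
      items <- c(allocate_items(s[1], 6L), allocate_items(s[2], 7L),
                 allocate_items(s[3], 8L))
      names(items) <- default_scoring_key()$item

      n_posts <- max(spec$posts_min,
                     min(spec$posts_max, round(rlnorm(1, meanlog, spec$posts_sdlog))))
      stamps <- sort(sample(days, n_posts, replace = TRUE))
      is_noise <- runif(n_posts) < spec$noise_prob
      is_quote <- !is_noise & runif(n_posts) < spec$quote_prob
      texts <- character(n_posts)
      for (j in seq_len(n_posts)) {
        n_tok <- rpois(1, spec$tokens_per_post - 1) + 1L
        if (is_noise[j]) {
          texts[j] <- paste(sample(filler, n_tok, replace = TRUE),
                            collapse = " ")
          next
        }
        eff_style <- style
        eff_gender <- gender
        if (is_quote[j]) {
          eff_style <- sample(setdiff(style_levels(), style), 1)
          eff_gender <- sample(c("male", "female"), 1)
        }
        p_cat <- c(spec$topic_rates[eff_style, ],
                   spec$emotion_rates[[eff_gender]][eff_style, ]) / 100
        cats <- sample(c(cat_names, "filler"), n_tok, replace = TRUE,
                       prob = c(p_cat, 1 - sum(p_cat)))
        texts[j] <- paste(vapply(cats, function(cc) {
          if (cc == "filler") sample(filler, 1) else sample(vocab[[cc]], 1)
        }, character(1)), collapse = " ")
      }

      users[[i]] <- tibble::tibble(
        user_id = uid, gender = gender,
        age = min(51L, max(14L, as.integer(round(rnorm(1, 24, 5.8))))),
        followers = as.integer(round(exp(runif(1, log(5), log(5000))))),
        s_r = s[1], s_e = s[2], s_o = s[3], style = style
      )
      quests[[i]] <- dplyr::bind_cols(
        tibble::tibble(user_id = uid, gender = gender,
                       polygraph_father = "occasionally occurs",
                       polygraph_mother = "always occurs"),
        as_tibble(as.list(items))
      )
      posts[[i]] <- tibble::tibble(user_id = uid, text = texts,
                                   timestamp = stamps,
                                   is_original = !is_quote)
    }

    list(users = dplyr::bind_rows(users),
         questionnaires = dplyr::bind_rows(quests),
         posts = dplyr::bind_rows(posts),
         topic_lexicon = lexicon(topics, name = "toy-topics"),
         emotion_lexicon = lexicon(emotions, name = "toy-emotions"),
         spec = spec)
  })
}

#' Write a fixture corpus to disk
#'
#' `tiny` (12 users, <= 20 posts each) suits unit tests; `small` (300
#' users, 100-120 posts each — an active-user profile, so every sequence
#' saturates the assessment model's 100-post truncation) suits integration
#' runs and the recovery studies. Writes
#' `corpus.jsonl`, `labels.csv`, `questionnaire.csv`, `topics.tsv` and
#' `emotions.tsv` into `dir`. Regeneration with the same seed is
#' byte-identical.
#'
#' @param scale `"tiny"` or `"small"`.
#' @param dir Output directory (created if needed).
#' @param seed Corpus seed.
#' @return Invisibly, a list with the generated corpus and the file paths.
#' @export
make_fixture <- function(scale = c("tiny", "small"), dir = tempfile("fixture"),
                         seed = 1L) {
  scale <- match.arg(scale)
  spec <- switch(scale,
    tiny = corpus_spec(n_users = 12L, posts_mean = 15, posts_min = 10L,
                       posts_max = 20L, seed = seed),
    small = corpus_spec(n_users = 300L, posts_mean = 110, posts_min = 100L,
                        posts_max = 120L, posts_sdlog = 0.3, seed = seed)
  )
  corpus <- generate_corpus(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    corpus = file.path(dir, "corpus.jsonl"),
    labels = file.path(dir, "labels.csv"),
    questionnaire = file.path(dir, "questionnaire.csv"),
    topics = file.path(dir, "topics.tsv"),
    emotions = file.path(dir, "emotions.tsv")
  )
  write_corpus_jsonl(corpus$posts, paths$corpus)
  write.csv(corpus$users, paths$labels, row.names = FALSE)
  write.csv(corpus$questionnaires, paths$questionnaire, row.names = FALSE)
  write_lexicon_tsv(corpus$topic_lexicon, paths$topics)
  write_lexicon_tsv(corpus$emotion_lexicon, paths$emotions)
  invisible(list(corpus = corpus, paths = paths, spec = spec))
}
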