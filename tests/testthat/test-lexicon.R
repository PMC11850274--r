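# Lexicon loading, proportion profiles, group comparisons and the six
# correlation word sets.

test_that("TSV and JSON lexicons load with deduplication", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("happy\t佳", "happy\t笑", "sad\t哭"), path)
  lex <- read_lexicon(path)
  expect_equal(vapply(lex$categories, length, 1L), c(happy = 2L, sad = 1L))

  writeLines(c("happy\ta", "happy\ta", "happy\tb"), path)
  expect_equal(length(read_lexicon(path)$categories$happy), 2)

  writeLines(character(0), path)
  expect_error(read_lexicon(path), "empty")

  jpath <- withr::local_tempfile(fileext = ".json")
  writeLines('{"x": ["a", "b"], "y": ["c"]}', jpath)
  jlex <- read_lexicon(jpath)
  expect_equal(vapply(jlex$categories, length, 1L), c(x = 2L, y = 1L))

  expect_error(read_lexicon(withr::local_tempfile(fileext = ".xyz")),
               "format")
})

test_that("lexicons round-trip through TSV", {
  lex <- toy_lexicon()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon_tsv(lex, path)
  back <- read_lexicon(path)
  expect_equal(back$categories, lex$categories)
})

test_that("category proportions count matches per category over all tokens", {
  lex <- lexicon(list(X = "A"), name = "t")
  expect_equal(unname(category_proportions(c("A A", "B"), lex)),
               100 * 2 / 3, tolerance = 1e-12)

  lex2 <- lexicon(list(X = "A", Y = c("A", "B")), name = "t")
  p <- category_proportions("A B", lex2)
  expect_equal(unname(p), c(50, 100))

  none <- category_proportions("q r s", lex2)
  expect_equal(unname(none), c(0, 0))

  expect_error(category_proportions(c("", "  "), lex2), "tokens")
})

test_that("proportions are invariant to post order and concatenation", {
  lex <- toy_lexicon()
  posts <- c("aa bb cc", "dd dd aa", "ee ff", "bb bb bb")
  p1 <- category_proportions(posts, lex)
  p2 <- category_proportions(rev(posts), lex)
  p3 <- category_proportions(paste(posts, collapse = " "), lex)
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("per-post averaging is a distinct, documented alternative", {
  lex <- lexicon(list(X = "A"), name = "t")
  # pooled: 3 of 4 tokens; per-post: mean(100, 50)
  expect_equal(unname(category_proportions(c("A A", "A B"), lex)), 75)
  expect_equal(unname(category_proportions(c("A A", "A B"), lex,
                                           per_post = TRUE)), 75)
  expect_equal(unname(category_proportions(c("A", "A B B B"), lex,
                                           per_post = TRUE)),
               mean(c(100, 25)))
})

test_that("group comparison matches the closed-form pooled t", {
  cmp <- compare_groups(c(2, 4), c(1, 3))
  expect_equal(cmp$t, ref_pooled_t(c(2, 4), c(1, 3)), tolerance = 1e-10)

  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(sample(2:9, 1))
    b <- rnorm(sample(2:9, 1), mean = runif(1, -1, 1))
    cmp <- compare_groups(a, b)
    expect_equal(cmp$t, ref_pooled_t(a, b), tolerance = 1e-10)
    expect_equal(cmp$p, ref_pooled_t_p(a, b), tolerance = 1e-10)
    expect_equal(cmp$diff, mean(a) - mean(b))
  }
})

test_that("group comparison handles degenerate inputs as documented", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  const <- compare_groups(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_equal(const$t, -Inf)
  expect_equal(const$p, 0)
  expect_equal(const$signif, "***")

  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("Welch variant differs from pooled under unequal variances", {
  a <- c(1, 2, 3, 4, 10)
  b <- c(2.2, 2.3, 2.4)
  pooled <- compare_groups(a, b, var_equal = TRUE)
  welch <- compare_groups(a, b, var_equal = FALSE)
  expect_equal(welch$t, unname(t.test(a, b)$statistic))
  expect_false(isTRUE(all.equal(pooled$p, welch$p)))
})

test_that("group tables flag the per-category maximum and test it", {
  set.seed(3)
  n <- 40
  profiles <- tibble::tibble(
    user_id = paste0("u", 1:(2 * n)),
    sad = c(rnorm(n, 5), rnorm(n, 1)),
    happy = c(rnorm(n, 2), rnorm(n, 6))
  )
  group <- rep(c("neg", "pos"), each = n)
  tabs <- group_tables(profiles, group)
  expect_equal(tabs$max_tests$top_group[tabs$max_tests$category == "sad"], "neg")
  expect_equal(tabs$max_tests$top_group[tabs$max_tests$category == "happy"], "pos")
  expect_true(all(tabs$max_tests$p < 0.001))
  expect_equal(sort(tabs$means$n), c(n, n))

  expect_error(group_tables(profiles, rep("one", 2 * n)), "2 non-empty")

  gender <- rep(c("male", "female"), n)
  tabs2 <- group_tables(profiles, group, gender = gender)
  expect_true(all(c("group", "category", "male_minus_female", "t", "p") %in%
                    names(tabs2$gender_tests)))
})

test_that("word sets are unions of their mapped categories", {
  topic <- lexicon(list(a = c("t1", "t2", "t3"), b = c("t4", "t5")),
                   name = "topics")
  emo <- lexicon(list(c = c("e1", "e2"), d = c("e2", "e3")), name = "emo")
  bundle <- build_word_sets(topic, emo,
                            mapping = list(T_p = c("a", "b"), E_p = "c",
                                           T_m = "a", E_m = "d",
                                           T_n = "b", E_n = c("c", "d")))
  expect_equal(unname(bundle$sizes),
               c(5L, 2L, 3L, 2L, 2L, 3L)) # overlap e2 collapses in E_n
  expect_error(build_word_sets(topic, emo,
                               mapping = list(T_p = "zz", E_p = "c",
                                              T_m = "a", E_m = "d",
                                              T_n = "b", E_n = "c")),
               "zz")
})

test_that("the default mapping reproduces the published emotion set sizes", {
  sizes <- c(happy = 1967, like = 11108, surprise = 228, angry = 388,
             sad = 2314, fear = 1179, hate = 10282)
  emo <- lexicon(lapply(names(sizes), function(cat) {
    sprintf("%s%05d", cat, seq_len(sizes[[cat]]))
  }) |> setNames(names(sizes)), name = "affect")
  topic <- lexicon(setNames(lapply(topic_category_names(), function(cat) {
    paste0(cat, "_w")
  }), topic_category_names()), name = "topics")
  bundle <- build_word_sets(topic, emo)
  expect_equal(bundle$sizes[["E_p"]], 1967 + 388)    # happy + angry: 2355
  expect_equal(bundle$sizes[["E_m"]], 11108 + 228)   # like + surprise: 11336
  expect_equal(bundle$sizes[["E_n"]], 2314 + 1179 + 10282) # 13775
})

test_that("set representations are means, permutation-invariant and bounded", {
  fake_embedder <- function(words) {
    t(vapply(words, function(w) c(nchar(w), utf8ToInt(substr(w, 1, 1))),
             numeric(2)))
  }
  expect_equal(set_representation("ab", fake_embedder),
               c(2, utf8ToInt("a")))
  expect_equal(set_representation(c("a", "abc"), fake_embedder),
               c(2, utf8ToInt("a")))
  expect_error(set_representation(character(0), fake_embedder), "empty")

  enc <- encoder_spec(d_e = 8, d_w = 8, seed = 3)
  we <- word_embedder(enc)
  words <- c("alpha", "beta", "gamma", "delta")
  r1 <- set_representation(words, we)
  r2 <- set_representation(sample(words), we)
  expect_equal(r1, r2)
  M <- we(words)
  expect_true(all(r1 >= apply(M, 2, min) - 1e-12))
  expect_true(all(r1 <= apply(M, 2, max) + 1e-12))
})

test_that("bundle representations concatenate in the documented set order", {
  setup <- toy_setup()
  b <- setup$bundle
  expect_equal(names(b$sets), c("T_p", "E_p", "T_m", "E_m", "T_n", "E_n"))
  expect_equal(b$rep_vector,
               unlist(b$representations[names(b$sets)], use.names = FALSE))
  expect_equal(length(b$rep_vector), 6 * setup$enc$d_w)
})
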