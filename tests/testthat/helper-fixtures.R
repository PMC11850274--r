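# Shared fixtures, generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

tiny_corpus <- function(seed = 42L) {
  key <- paste0("tiny-", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_corpus(
      corpus_spec(n_users = 12L, posts_mean = 15, posts_min = 10L,
                  posts_max = 20L, seed = seed))
  }
  .fixture_cache[[key]]
}

# Small widths for model tests: everything shaped but cheap.
toy_setup <- function(seed = 42L, d_e = 16L, d_h = 8L, d_w = 4L, d_u = 6L) {
  corpus <- tiny_corpus(seed)
  enc <- encoder_spec(d_e = d_e, d_w = d_w, seed = 5L)
  seqs <- prepare_sequences(corpus$posts, enc, max_posts = 10L)
  bundle <- bundle_representations(
    build_word_sets(corpus$topic_lexicon, corpus$emotion_lexicon),
    word_embedder(enc))
  config <- model_config(d_e = d_e, d_h = d_h, d_w = d_w, d_u = d_u,
                         seed = 11L)
  list(corpus = corpus, enc = enc, seqs = seqs, bundle = bundle,
       config = config)
}

toy_lexicon <- function() {
  lexicon(list(X = c("aa", "bb"), Y = c("bb", "cc", "dd")), name = "toy")
}

random_ratings <- function() {
  setNames(sample(1:4, 21, replace = TRUE), default_scoring_key()$item)
}
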