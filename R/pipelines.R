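# End-to-end pipelines wiring the modules into the two subtasks:
# correlation exploration (dataset summary + proportion tables + group
# tests) and assessment (train, evaluate, attention case study, optional
# ablation). Both are deterministic from one global seed.

#' Subtask 1: correlation exploration
#'
#' Computes the dataset summary (style counts, percentages, mean scores),
#' per-user lexicon profiles, and the group-level proportion tables with
#' significance tests, stratified by style and gender. When `out_dir` is
#' given, the tables are written as CSV files.
#'
#' @param posts Corpus tibble (`user_id`, `text`, `timestamp`,
#'   `is_original`) or path to a JSONL corpus.
#' @param labels Tibble with `user_id`, `gender`, `s_r`, `s_e`, `s_o` (a
#'   `style` column is computed if absent) or path to a labels CSV.
#' @param topic_lex,emotion_lex [lexicon()] objects or file paths.
#' @param out_dir Optional output directory for the CSV reports.
#' @param tokenizer See [tokenize_whitespace()].
#' @return List with `summary`, `topic_tables`, `emotion_tables` (each a
#'   [group_tables()] result) and `profiles`.
#' @export
run_correlation_analysis <- function(posts, labels, topic_lex, emotion_lex,
                                     out_dir = NULL,
                                     tokenizer = tokenize_whitespace) {
  if (is.character(posts)) posts <- read_corpus_jsonl(posts)
  if (is.character(labels)) labels <- as_tibble(read.csv(labels))
  if (is.character(topic_lex)) topic_lex <- read_lexicon(topic_lex)
  if (is.character(emotion_lex)) emotion_lex <- read_lexicon(emotion_lex)
  if (is.null(labels$style))
    labels$style <- classify_style(labels$s_r, labels$s_e, labels$s_o)

  summary <- summarize_dataset(labels)
  topic_profiles <- user_profiles(posts, topic_lex, tokenizer)
  emo_profiles <- user_profiles(posts, emotion_lex, tokenizer)
  idx <- match(topic_profiles$user_id, labels$user_id)
  style <- as.character(labels$style)[idx]
  gender <- labels$gender[idx]

  topic_tables <- group_tables(topic_profiles, style)
  emotion_tables <- group_tables(emo_profiles, style, gender = gender)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(summary$counts, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
    write.csv(topic_tables$means, file.path(out_dir, "topic_means.csv"),
              row.names = FALSE)
    write.csv(topic_tables$max_tests, file.path(out_dir, "topic_tests.csv"),
              row.names = FALSE)
    write.csv(emotion_tables$means, file.path(out_dir, "emotion_means.csv"),
              row.names = FALSE)
    write.csv(emotion_tables$gender_means,
              file.path(out_dir, "emotion_gender_means.csv"), row.names = FALSE)
    write.csv(emotion_tables$gender_tests,
              file.path(out_dir, "emotion_gender_tests.csv"), row.names = FALSE)
  }
  invisible(list(summary = summary, topic_tables = topic_tables,
                 emotion_tables = emotion_tables,
                 profiles = list(topic = topic_profiles, emotion = emo_profiles)))
}

#' Subtask 2: assessment pipeline
#'
#' Splits the users, embeds the truncated post sequences, builds the six
#' word-set representations, trains the assessment model, evaluates it on
#' the test set, and extracts the attention report of the first test user.
#' Optional: the ablation study over the attention and injection layers.
#'
#' @inheritParams run_correlation_analysis
#' @param enc An [encoder_spec()].
#' @param config A [model_config()] (its `d_e`/`d_w` must match `enc`).
#' @param train_cfg A [train_config()].
#' @param seed Global seed; the split, initialisation and batch-order seeds
#'   are derived from it.
#' @param ablate Also run the ablation study.
#' @param out_dir Optional output directory (history, evaluation, attention
#'   case study, checkpoint).
#' @return List with `model`, `report`, `attention_case`, `split`, and
#'   `ablation` when requested.
#' @export
run_assessment_pipeline <- function(posts, labels, topic_lex, emotion_lex,
                                    enc = encoder_spec(),
                                    config = model_config(),
                                    train_cfg = train_config(),
                                    seed = 1L, ablate = FALSE, out_dir = NULL) {
  if (is.character(posts)) posts <- read_corpus_jsonl(posts)
  if (is.character(labels)) labels <- as_tibble(read.csv(labels))
  if (is.character(topic_lex)) topic_lex <- read_lexicon(topic_lex)
  if (is.character(emotion_lex)) emotion_lex <- read_lexicon(emotion_lex)
  if (config$d_e != enc$d_e)
    stopf("model d_e (%d) does not match encoder d_e (%d)", config$d_e, enc$d_e)

  ids <- intersect(unique(posts$user_id), labels$user_id)
  split <- split_dataset(ids, seed = derive_seed(seed, "split"))
  seqs <- prepare_sequences(posts[posts$user_id %in% ids, ], enc,
                            max_posts = train_cfg$max_posts)
  bundle <- bundle_representations(build_word_sets(topic_lex, emotion_lex),
                                   word_embedder(enc))
  config$seed <- derive_seed(seed, "init")
  train_cfg$seed <- derive_seed(seed, "train")

  y <- list(train = label_matrix(labels, split$train),
            val = label_matrix(labels, split$val),
            test = label_matrix(labels, split$test))
  model <- train_model(seqs[split$train], y$train, seqs[split$val], y$val,
                       config, train_cfg, reps = bundle)
  report <- evaluate_model(model, seqs[split$test], y$test, reps = bundle)

  case_id <- split$test[1]
  case_posts <- truncate_last_k(posts[posts$user_id == case_id, ],
                                train_cfg$max_posts)
  case_trace <- forward(seqs[[case_id]], model$params, config, reps = bundle)
  attention_case <- attention_report(case_posts$text, case_trace)

  out <- list(model = model, report = report, attention_case = attention_case,
              split = split, bundle = bundle)
  if (ablate) {
    out$ablation <- ablation_study(seqs[split$train], y$train,
                                   seqs[split$val], y$val, seqs[split$test],
                                   y$test, config, train_cfg, reps = bundle)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(model$history, file.path(out_dir, "history.csv"),
              row.names = FALSE)
    write.csv(report$metrics, file.path(out_dir, "evaluation.csv"),
              row.names = FALSE)
    write.csv(attention_case, file.path(out_dir, "attention_case.csv"),
              row.names = FALSE)
    if (ablate)
      write.csv(out$ablation$report, file.path(out_dir, "ablation.csv"),
                row.names = FALSE)
    save_checkpoint(model, file.path(out_dir, "checkpoint.rds"))
  }
  invisible(out)
}

#' Assess one user's parenting style from posts
#'
#' Runs a trained model on a single user's post history and returns the
#' predicted scores denormalized to the 1-4 questionnaire scale.
#'
#' @param model A [train_model()] result.
#' @param posts Tibble of the user's posts (`text`, `timestamp`).
#' @param reps Word-set representations used at training time.
#' @param enc The [encoder_spec()] used at training time.
#' @param max_posts Truncation applied before embedding.
#' @return Named numeric vector `c(s_r, s_e, s_o)` in [1, 4].
#' @export
assess_user <- function(model, posts, reps, enc = encoder_spec(),
                        max_posts = 100L) {
  p <- truncate_last_k(posts, max_posts)
  emb <- embed_posts(p$text, enc)
  tr <- forward(emb, model$params, model$config, reps = reps)
  predicted_scores(tr)
}
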