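# Training loop (Adam on MSE over the normalized score triple), dataset
# splitting, evaluation metrics, the two classic baselines and the ablation
# study driver.

#' Training configuration
#'
#' Defaults follow the published schedule: batch size 64, learning rate
#' 1e-4, 30 epochs, each user truncated to the last 100 posts.
#'
#' @param batch_size Users per gradient step.
#' @param learning_rate Adam step size.
#' @param epochs Training epochs; the best-validation epoch is kept.
#' @param max_posts Per-user truncation (most recent posts).
#' @param clip_norm Global gradient-norm clipping threshold (standard
#'   stabiliser for backpropagation through long recurrent sequences).
#' @param seed Seed for batch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, learning_rate = 1e-4, epochs = 30L,
                         max_posts = 100L, clip_norm = 1, seed = 1L) {
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 1, max_posts >= 1,
            clip_norm > 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 max_posts = as.integer(max_posts), clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "train_config")
}

clip_gradients <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(total) && total > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / total))
  grads
}

#' Split users into train/validation/test sets
#'
#' Default fractions mirror a 475/50/50 split of 575 users, scaled to the
#' corpus size. The split is disjoint and reproducible from the seed.
#'
#' @param user_ids Vector of user identifiers.
#' @param sizes Optional integer vector `c(train, val, test)`; overrides
#'   `fractions`. Must not exceed the number of users.
#' @param fractions Length-3 fractions used when `sizes` is `NULL`; they are
#'   scaled so the three sets cover all users.
#' @param seed RNG seed.
#' @return List of id vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(user_ids, sizes = NULL,
                          fractions = c(475, 50, 50) / 575, seed = 1L) {
  n <- length(user_ids)
  if (is.null(sizes)) {
    fractions <- fractions / sum(fractions)
    sizes <- floor(fractions * n)
    rem <- n - sum(sizes)
    if (rem > 0) {
      top <- order(fractions * n - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[top] <- sizes[top] + 1
    }
  }
  sizes <- as.integer(sizes)
  stopifnot(length(sizes) == 3)
  if (sum(sizes) > n)
    stopf("split sizes (%d) exceed the number of users (%d)", sum(sizes), n)
  with_seed(seed, {
    perm <- sample(user_ids, n)
    list(train = perm[seq_len(sizes[1])],
         val = perm[sizes[1] + seq_len(sizes[2])],
         test = perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
  })
}

#' Embed every user's truncated post sequence
#'
#' @param posts Corpus tibble (`user_id`, `text`, `timestamp`).
#' @param spec An [encoder_spec()].
#' @param max_posts Truncation: keep each user's most recent posts.
#' @param pad_to Optional fixed length: sequences shorter than this are
#'   zero-padded at the end. Padding keeps the sum-pooled attention output
#'   on a common scale across users with different post counts (the LSTM
#'   state decays over the zero inputs, so padded steps contribute little).
#' @return Named list of embedding matrices, one per user.
#' @export
prepare_sequences <- function(posts, spec = encoder_spec(), max_posts = 100L,
                              pad_to = NULL) {
  ids <- unique(posts$user_id)
  out <- lapply(ids, function(uid) {
    p <- truncate_last_k(posts[posts$user_id == uid, , drop = FALSE], max_posts)
    emb <- embed_posts(p$text, spec)
    if (!is.null(pad_to) && nrow(emb) < pad_to)
      emb <- rbind(emb, matrix(0, pad_to - nrow(emb), ncol(emb)))
    emb
  })
  names(out) <- ids
  out
}

#' Normalized label matrix for a set of users
#'
#' @param labels Tibble with `user_id`, `s_r`, `s_e`, `s_o` on the 1-4
#'   scale.
#' @param ids User ids selecting and ordering the rows.
#' @return Numeric matrix (users x 3) of normalized scores in [-1, 1].
#' @export
label_matrix <- function(labels, ids) {
  idx <- match(ids, labels$user_id)
  if (anyNA(idx))
    stopf("missing labels for user(s): %s",
          paste(head(ids[is.na(idx)], 5), collapse = ", "))
  m <- cbind(normalize_score(labels$s_r[idx]), normalize_score(labels$s_e[idx]),
             normalize_score(labels$s_o[idx]))
  rownames(m) <- ids
  colnames(m) <- dimension_names()
  m
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the assessment model
#'
#' Minimises the MSE between the predicted and questionnaire-derived
#' normalized score triples with Adam, and returns the parameters of the
#' epoch with the lowest validation MSE. Fully reproducible from the model
#' seed (initialisation) and training seed (batch order).
#'
#' @param train_seqs,val_seqs Named lists of per-user embedding matrices
#'   (see [prepare_sequences()]).
#' @param train_y,val_y Matching normalized label matrices (users x 3), see
#'   [label_matrix()].
#' @param config A [model_config()].
#' @param train_cfg A [train_config()].
#' @param reps Word-set representations ([bundle_representations()] result
#'   or numeric vector); ignored under the `no_injection` ablation.
#' @return Object of class `style_model`: `params`, `history` (tibble
#'   `epoch`, `train_loss`, `val_mse`), `best_epoch`, `config`.
#' @export
train_model <- function(train_seqs, train_y, val_seqs, val_y, config,
                        train_cfg = train_config(), reps = NULL) {
  if (length(train_seqs) == 0) stopf("empty training set")
  stopifnot(nrow(train_y) == length(train_seqs))
  rv <- rep_vector_for(config, reps)
  no_att <- config$ablation == "no_attention"
  no_inj <- config$ablation == "no_injection"
  params <- unclass(init_params(config))
  # start the output bias at the training-label mean (through the final
  # tanh), so the step budget is spent on signal rather than the intercept
  mu <- pmin(pmax(colMeans(train_y), -0.999), 0.999)
  params$fc2_b <- atanh(mu)
  state <- adam_init(params)
  best <- params
  best_val <- Inf
  best_epoch <- 0L
  history <- vector("list", train_cfg$epochs)
  n <- length(train_seqs)

  with_seed(train_cfg$seed, {
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
      ep_loss <- 0
      for (idx in batches) {
        res <- cpp_batch_loss_grad(train_seqs[idx],
                                   train_y[idx, , drop = FALSE], rv, params,
                                   no_att, no_inj)
        if (!is.finite(res$loss))
          stopf("training diverged at epoch %d (non-finite loss); lower the learning rate",
                epoch)
        ep_loss <- ep_loss + res$loss * length(idx)
        grads <- clip_gradients(res$grads, train_cfg$clip_norm %||% 1)
        upd <- adam_step(params, grads, state, train_cfg$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      pred <- cpp_predict_batch(val_seqs, rv, params, no_att, no_inj)
      val_mse <- mean((pred - val_y)^2)
      history[[epoch]] <- tibble::tibble(epoch = epoch,
                                         train_loss = ep_loss / n,
                                         val_mse = val_mse)
      if (val_mse < best_val) {
        best_val <- val_mse
        best <- params
        best_epoch <- epoch
      }
    }
  })

  structure(list(params = structure(best, class = "model_params"),
                 history = dplyr::bind_rows(history),
                 best_epoch = best_epoch, config = config),
            class = "style_model")
}

#' @export
print.style_model <- function(x, ...) {
  cat(sprintf("<style_model %s: best epoch %d/%d, val MSE %.4f>\n",
              x$config$ablation, x$best_epoch, nrow(x$history),
              min(x$history$val_mse)))
  invisible(x)
}

#' Predict normalized scores for a set of users
#'
#' @param model A [train_model()] result (or a bare parameter list, in
#'   which case `config` must be given).
#' @param seqs Named list of embedding matrices.
#' @param reps Word-set representations (as in [train_model()]).
#' @param config Required when `model` is a bare parameter list.
#' @return Matrix (users x 3) of normalized predictions, named rows.
#' @export
predict_scores <- function(model, seqs, reps = NULL, config = NULL) {
  if (inherits(model, "style_model")) {
    config <- model$config
    params <- model$params
  } else {
    if (is.null(config)) stopf("config required with bare parameters")
    params <- model
  }
  rv <- rep_vector_for(config, reps)
  pred <- cpp_predict_batch(seqs, rv, unclass(params),
                            config$ablation == "no_attention",
                            config$ablation == "no_injection")
  rownames(pred) <- names(seqs)
  colnames(pred) <- dimension_names()
  pred
}

#' Evaluation metrics for score predictions
#'
#' Per-dimension `MSE = (1/N) sum (y - y')^2` and `MAE = (1/N) sum |y - y'|`
#' on the normalized scale, plus their averages over the three dimensions.
#' The raw-scale (1-4) equivalents are included as extra columns (the
#' normalization is affine, so raw errors are the normalized ones scaled by
#' 1.5 for MAE and 1.5^2 for MSE).
#'
#' @param pred,y Numeric matrices (users x 3) of normalized predictions and
#'   labels.
#' @return Object of class `eval_report`: `metrics` tibble (`dimension`,
#'   `mse`, `mae`, `mse_raw`, `mae_raw`) with an `average` row, and `n`.
#' @export
eval_metrics <- function(pred, y) {
  stopifnot(is.matrix(pred), is.matrix(y), all(dim(pred) == dim(y)),
            ncol(pred) == 3)
  if (nrow(y) == 0) stopf("empty evaluation set")
  err <- pred - y
  mse <- unname(colMeans(err^2))
  mae <- unname(colMeans(abs(err)))
  metrics <- tibble::tibble(
    dimension = c(dimension_names(), "average"),
    mse = c(mse, mean(mse)),
    mae = c(mae, mean(mae))
  )
  metrics$mse_raw <- metrics$mse * 1.5^2
  metrics$mae_raw <- metrics$mae * 1.5
  structure(list(metrics = metrics, n = nrow(y)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d users (normalized scale):\n", x$n))
  for (i in seq_len(nrow(x$metrics)))
    cat(sprintf("  %-14s MSE %.4f  MAE %.4f\n", x$metrics$dimension[i],
                x$metrics$mse[i], x$metrics$mae[i]))
  invisible(x)
}

#' Evaluate a trained model on a labelled test set
#'
#' @inheritParams predict_scores
#' @param y Normalized label matrix for `seqs` (same order).
#' @return An [eval_metrics()] report.
#' @export
evaluate_model <- function(model, seqs, y, reps = NULL, config = NULL) {
  if (length(seqs) == 0) stopf("empty evaluation set")
  eval_metrics(predict_scores(model, seqs, reps = reps, config = config), y)
}

# ---- baselines ---------------------------------------------------------

merge_user_docs <- function(posts, ids) {
  vapply(ids, function(uid) paste(posts$text[posts$user_id == uid],
                                  collapse = " "), character(1))
}

tfidf_fit <- function(docs, tokenizer) {
  toks <- tokenizer(docs)
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  if (length(vocab) == 0) stopf("empty vocabulary")
  df <- numeric(length(vocab))
  names(df) <- vocab
  for (tk in toks) {
    u <- unique(tk)
    df[u[u %in% vocab]] <- df[u[u %in% vocab]] + 1
  }
  idf <- log((1 + length(docs)) / (1 + df)) + 1
  list(vocab = vocab, idf = idf, tokenizer = tokenizer)
}

tfidf_transform <- function(fit, docs) {
  toks <- fit$tokenizer(docs)
  m <- matrix(0, length(docs), length(fit$vocab),
              dimnames = list(NULL, fit$vocab))
  for (i in seq_along(toks)) {
    tk <- toks[[i]][toks[[i]] %in% fit$vocab]
    if (length(tk) == 0) next
    counts <- table(tk)
    m[i, names(counts)] <- as.numeric(counts) * fit$idf[names(counts)]
    nrm <- sqrt(sum(m[i, ]^2))
    if (nrm > 0) m[i, ] <- m[i, ] / nrm
  }
  m
}

#' TF-IDF + ridge regression baseline
#'
#' Merges each user's posts into one document, extracts an L2-normalised
#' TF-IDF vector (smoothed idf, vocabulary from the fitting set) and fits
#' one ridge regression per dimension on the train+validation users; the
#' report is computed on the test users.
#'
#' @param posts Corpus tibble (`user_id`, `text`).
#' @param labels Tibble `user_id`, `s_r`, `s_e`, `s_o` (1-4 scale).
#' @param split A [split_dataset()] result.
#' @param tokenizer See [tokenize_whitespace()].
#' @param lambda Ridge penalty.
#' @return An [eval_metrics()] report.
#' @export
baseline_tfidf_regression <- function(posts, labels, split,
                                      tokenizer = tokenize_whitespace,
                                      lambda = 0.1) {
  fit_ids <- c(split$train, split$val)
  if (length(fit_ids) < 2) stopf("need at least 2 training users")
  x_fit <- tfidf_transform(fit <- tfidf_fit(merge_user_docs(posts, fit_ids),
                                            tokenizer),
                           merge_user_docs(posts, fit_ids))
  x_test <- tfidf_transform(fit, merge_user_docs(posts, split$test))
  y_fit <- label_matrix(labels, fit_ids)
  y_test <- label_matrix(labels, split$test)
  pred <- vapply(1:3, function(k) {
    gm <- glmnet::glmnet(x_fit, y_fit[, k], alpha = 0, lambda = lambda,
                         standardize = FALSE)
    as.numeric(glmnet::predict.glmnet(gm, x_test))
  }, numeric(nrow(x_test)))
  if (nrow(x_test) == 1) pred <- matrix(pred, nrow = 1)
  eval_metrics(pred, y_test)
}

#' Handcrafted features + gradient-boosted trees baseline
#'
#' Represents each user by the 18 lexicon-category proportions (11 topic +
#' 7 emotion categories) and fits one boosted-trees regressor per dimension
#' on the train+validation users.
#'
#' @inheritParams baseline_tfidf_regression
#' @param topic_lex,emotion_lex [lexicon()] objects providing the 18
#'   categories.
#' @param nrounds,max_depth,eta Boosting hyper-parameters.
#' @return An [eval_metrics()] report.
#' @export
baseline_handcrafted_ensemble <- function(posts, labels, split, topic_lex,
                                          emotion_lex,
                                          tokenizer = tokenize_whitespace,
                                          nrounds = 100L, max_depth = 3L,
                                          eta = 0.1) {
  if (length(topic_lex$categories) + length(emotion_lex$categories) != 18)
    stopf("expected 11 topic + 7 emotion categories (18 features), got %d + %d",
          length(topic_lex$categories), length(emotion_lex$categories))
  fit_ids <- c(split$train, split$val)
  feats <- function(ids) {
    p1 <- user_profiles(posts[posts$user_id %in% ids, ], topic_lex, tokenizer)
    p2 <- user_profiles(posts[posts$user_id %in% ids, ], emotion_lex, tokenizer)
    m <- cbind(as.matrix(p1[match(ids, p1$user_id), -1]),
               as.matrix(p2[match(ids, p2$user_id), -1]))
    rownames(m) <- ids
    m
  }
  x_fit <- feats(fit_ids)
  x_test <- feats(split$test)
  y_fit <- label_matrix(labels, fit_ids)
  y_test <- label_matrix(labels, split$test)
  pred <- vapply(1:3, function(k) {
    bst <- xgboost::xgboost(x_fit, y_fit[, k], nrounds = nrounds,
                            max_depth = max_depth, learning_rate = eta,
                            objective = "reg:squarederror", verbosity = 0,
                            nthreads = 1)
    stats::predict(bst, x_test)
  }, numeric(nrow(x_test)))
  if (nrow(x_test) == 1) pred <- matrix(pred, nrow = 1)
  eval_metrics(pred, y_test)
}

#' Ablation study
#'
#' Trains the full model and both ablation variants under identical seeds
#' and configuration, and reports per-dimension and average test MSE with
#' deltas against the full model.
#'
#' @inheritParams train_model
#' @param test_seqs,test_y Test sequences and normalized labels.
#' @return List with `report` (tibble `variant` x `dimension`, `mse`,
#'   `delta_mse`) and `models` (the three trained models).
#' @export
ablation_study <- function(train_seqs, train_y, val_seqs, val_y, test_seqs,
                           test_y, config, train_cfg = train_config(),
                           reps = NULL) {
  variants <- c("full", "no_attention", "no_injection")
  models <- lapply(variants, function(v) {
    cfg <- config
    if (v != "full") cfg <- make_ablation(cfg, v)
    train_model(train_seqs, train_y, val_seqs, val_y, cfg, train_cfg,
                reps = reps)
  })
  names(models) <- variants
  reports <- lapply(models, evaluate_model, seqs = test_seqs, y = test_y,
                    reps = reps)
  full_mse <- reports$full$metrics$mse
  report <- dplyr::bind_rows(lapply(variants, function(v) {
    m <- reports[[v]]$metrics
    tibble::tibble(variant = v, dimension = m$dimension, mse = m$mse,
                   delta_mse = m$mse - full_mse)
  }))
  list(report = report, models = models)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS archive holding the configuration and the
#' named parameter blocks.
#' @param model A [train_model()] result.
#' @param path File path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, params = unclass(model$params),
               best_epoch = model$best_epoch), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  structure(list(params = structure(ck$params, class = "model_params"),
                 history = NULL, best_epoch = ck$best_epoch,
                 config = ck$config),
            class = "style_model")
}
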