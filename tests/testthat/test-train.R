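# Splitting, metrics, training loop, baselines and the ablation driver.

test_that("splits are disjoint, covering and seed-reproducible", {
  ids <- paste0("u", 1:575)
  sp <- split_dataset(ids, sizes = c(475, 50, 50), seed = 4)
  expect_equal(lengths(sp), c(train = 475L, val = 50L, test = 50L))
  expect_equal(sort(unlist(sp)), sort(ids), ignore_attr = TRUE)
  expect_identical(split_dataset(ids, sizes = c(475, 50, 50), seed = 4), sp)
  expect_false(identical(split_dataset(ids, sizes = c(475, 50, 50), seed = 5),
                         sp))

  # default fractions scale to the corpus and always cover it
  for (n in c(23, 100, 300)) {
    spn <- split_dataset(paste0("v", 1:n), seed = 1)
    expect_equal(length(unlist(spn)), n)
    expect_equal(anyDuplicated(unlist(spn)), 0)
  }
  expect_error(split_dataset(paste0("u", 1:10), sizes = c(10, 1, 1)),
               "exceed")
})

test_that("evaluation metrics match their definitions exactly", {
  y <- matrix(c(0.5, -0.2, 0.9, -1, 0, 1), 2, 3, byrow = TRUE)
  perfect <- eval_metrics(y, y)
  expect_equal(perfect$metrics$mse, rep(0, 4))
  expect_equal(perfect$metrics$mae, rep(0, 4))
  expect_equal(perfect$n, 2)

  one <- eval_metrics(matrix(0, 1, 3), matrix(1, 1, 3))
  expect_equal(one$metrics$mse, rep(1, 4))
  expect_equal(one$metrics$mae, rep(1, 4))

  set.seed(5)
  pred <- matrix(runif(30, -1, 1), 10, 3)
  lab <- matrix(runif(30, -1, 1), 10, 3)
  rep_ <- eval_metrics(pred, lab)
  for (k in 1:3) {
    expect_equal(rep_$metrics$mse[k], sum((pred[, k] - lab[, k])^2) / 10,
                 tolerance = 1e-12)
    expect_equal(rep_$metrics$mae[k], sum(abs(pred[, k] - lab[, k])) / 10,
                 tolerance = 1e-12)
  }
  expect_equal(rep_$metrics$mse[4], mean(rep_$metrics$mse[1:3]))
  expect_equal(rep_$metrics$mae[4], mean(rep_$metrics$mae[1:3]))
  # raw-scale errors are affine rescalings
  expect_equal(rep_$metrics$mse_raw, rep_$metrics$mse * 2.25)
  expect_equal(rep_$metrics$mae_raw, rep_$metrics$mae * 1.5)

  # constant-zero predictor equals the mean of squares
  zero <- eval_metrics(matrix(0, 10, 3), lab)
  expect_equal(zero$metrics$mse[1:3], colMeans(lab^2), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(eval_metrics(lab[0, , drop = FALSE], lab[0, , drop = FALSE]),
               "empty")
})

test_that("label matrices are normalized and ordered by the id vector", {
  labels <- tibble::tibble(user_id = c("a", "b"), s_r = c(1, 4),
                           s_e = c(2.5, 1), s_o = c(4, 2.5))
  m <- label_matrix(labels, c("b", "a"))
  expect_equal(m["b", ], c(rejection = 1, warmth = -1, overprotection = 0))
  expect_equal(m["a", ], c(rejection = -1, warmth = 0, overprotection = 1))
  expect_error(label_matrix(labels, c("a", "zz")), "zz")
})

test_that("the model can overfit a single user and training is seeded", {
  setup <- toy_setup()
  uid <- names(setup$seqs)[1]
  y <- label_matrix(setup$corpus$users, names(setup$seqs))
  tc <- train_config(batch_size = 1, learning_rate = 0.02, epochs = 40,
                     max_posts = 10, seed = 3)
  m <- train_model(setup$seqs[uid], y[uid, , drop = FALSE],
                   setup$seqs[uid], y[uid, , drop = FALSE],
                   setup$config, tc, reps = setup$bundle)
  expect_lt(tail(m$history$train_loss, 1), m$history$train_loss[1])
  expect_lt(min(m$history$val_mse), 0.05)

  m2 <- train_model(setup$seqs[uid], y[uid, , drop = FALSE],
                    setup$seqs[uid], y[uid, , drop = FALSE],
                    setup$config, tc, reps = setup$bundle)
  expect_identical(m$history, m2$history)
  expect_identical(m$params, m2$params)

  expect_error(train_model(list(), y[0, , drop = FALSE], setup$seqs[uid],
                           y[uid, , drop = FALSE], setup$config, tc),
               "empty")
})

test_that("best-validation checkpointing returns the best epoch's parameters", {
  setup <- toy_setup()
  ids <- names(setup$seqs)
  y <- label_matrix(setup$corpus$users, ids)
  tc <- train_config(batch_size = 4, learning_rate = 0.05, epochs = 8,
                     max_posts = 10, seed = 6)
  m <- train_model(setup$seqs[ids[1:8]], y[ids[1:8], ],
                   setup$seqs[ids[9:10]], y[ids[9:10], ],
                   setup$config, tc, reps = setup$bundle)
  expect_equal(m$best_epoch, which.min(m$history$val_mse))
  rep_ <- evaluate_model(m, setup$seqs[ids[9:10]], y[ids[9:10], ],
                         reps = setup$bundle)
  expect_equal(rep_$metrics$mse[4], min(m$history$val_mse), tolerance = 1e-10)
})

test_that("checkpoints round-trip through disk", {
  setup <- toy_setup()
  ids <- names(setup$seqs)
  y <- label_matrix(setup$corpus$users, ids)
  tc <- train_config(batch_size = 4, learning_rate = 0.02, epochs = 2,
                     max_posts = 10, seed = 6)
  m <- train_model(setup$seqs[ids[1:8]], y[ids[1:8], ],
                   setup$seqs[ids[9:10]], y[ids[9:10], ],
                   setup$config, tc, reps = setup$bundle)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_equal(predict_scores(back, setup$seqs[ids[11:12]], reps = setup$bundle),
               predict_scores(m, setup$seqs[ids[11:12]], reps = setup$bundle))
})

test_that("TF-IDF + ridge baseline fits a separable toy corpus", {
  # users whose vocabulary encodes their (normalized) label
  set.seed(9)
  n <- 30
  labels <- tibble::tibble(user_id = paste0("u", 1:n),
                           s_r = rep(c(1, 4), length.out = n),
                           s_e = rep(c(4, 1), length.out = n),
                           s_o = rep(c(1, 4), length.out = n))
  posts <- tibble::tibble(
    user_id = labels$user_id,
    text = ifelse(labels$s_r == 1, "low low calm", "high high angry"),
    timestamp = as.Date("2022-01-01"))
  split <- list(train = labels$user_id[1:20], val = labels$user_id[21:24],
                test = labels$user_id[25:30])
  rep_ <- baseline_tfidf_regression(posts, labels, split, lambda = 1e-4)
  expect_lt(rep_$metrics$mse[4], 0.01)
  expect_equal(rep_$n, 6)
})

test_that("handcrafted-feature baseline uses the 18 category proportions", {
  corpus <- tiny_corpus()
  labels <- corpus$users
  split <- split_dataset(labels$user_id, sizes = c(8, 2, 2), seed = 2)
  rep_ <- baseline_handcrafted_ensemble(corpus$posts, labels, split,
                                        corpus$topic_lexicon,
                                        corpus$emotion_lexicon, nrounds = 5)
  expect_s3_class(rep_, "eval_report")
  expect_equal(rep_$n, 2)
  expect_equal(nrow(rep_$metrics), 4)

  bad_lex <- lexicon(list(only = "w"), name = "bad")
  expect_error(baseline_handcrafted_ensemble(corpus$posts, labels, split,
                                             bad_lex, corpus$emotion_lexicon),
               "18")
})

test_that("ablation study trains three variants under identical seeds", {
  setup <- toy_setup()
  ids <- names(setup$seqs)
  y <- label_matrix(setup$corpus$users, ids)
  tc <- train_config(batch_size = 4, learning_rate = 0.02, epochs = 2,
                     max_posts = 10, seed = 5)
  st <- ablation_study(setup$seqs[ids[1:8]], y[ids[1:8], ],
                       setup$seqs[ids[9:10]], y[ids[9:10], ],
                       setup$seqs[ids[11:12]], y[ids[11:12], ],
                       setup$config, tc, reps = setup$bundle)
  expect_equal(nrow(st$report), 12) # 3 variants x 4 dimensions
  expect_setequal(unique(st$report$variant),
                  c("full", "no_attention", "no_injection"))
  expect_equal(st$report$delta_mse[st$report$variant == "full"], rep(0, 4))
  expect_equal(st$report$mse[st$report$variant == "no_injection"] -
                 st$report$mse[st$report$variant == "full"],
               st$report$delta_mse[st$report$variant == "no_injection"])
})
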