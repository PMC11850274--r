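# The assessment network: two stacked LSTM layers over the post-embedding
# sequence, tanh attention pooling, correlation injection (concatenation of
# the six word-set representations), and a two-layer tanh head emitting
# three normalized parenting scores in (-1, 1).

#' Model configuration
#'
#' @param d_e Input (post-embedding) width.
#' @param d_h LSTM hidden width (default 300).
#' @param d_w Width of each injected word-set representation (default 300;
#'   with `d_h = 300` the concatenated head input is `300 + 6*300 = 2100`
#'   wide).
#' @param d_u Head hidden width (default 128).
#' @param ablation `"full"`, `"no_attention"` (attention pooling replaced by
#'   the mean over hidden states) or `"no_injection"` (head consumes the
#'   pooled vector only).
#' @param seed Seed for parameter initialisation.
#' @return An object of class `model_config`.
#' @export
model_config <- function(d_e = 384L, d_h = 300L, d_w = 300L, d_u = 128L,
                         ablation = c("full", "no_attention", "no_injection"),
                         seed = 1L) {
  ablation <- match.arg(ablation)
  stopifnot(d_e >= 1, d_h >= 1, d_w >= 1, d_u >= 1)
  structure(list(d_e = as.integer(d_e), d_h = as.integer(d_h),
                 d_w = as.integer(d_w), d_u = as.integer(d_u),
                 ablation = ablation, seed = as.integer(seed)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config %s: d_e=%d d_h=%d d_w=%d d_u=%d concat=%d seed=%d>\n",
              x$ablation, x$d_e, x$d_h, x$d_w, x$d_u, concat_width(x), x$seed))
  invisible(x)
}

#' Width of the head input under a configuration
#'
#' `d_h + 6*d_w` when the injection layer is active, `d_h` otherwise.
#' @param config A [model_config()].
#' @return Integer width.
#' @export
concat_width <- function(config) {
  if (config$ablation == "no_injection") config$d_h
  else config$d_h + 6L * config$d_w
}

#' Initialise model parameters
#'
#' Weights are drawn uniformly in +/- 1/sqrt(fan-in); biases start at zero
#' except the LSTM forget-gate biases, which start at 1 so that early cell
#' states are carried forward, and the attention bias, which starts at 0.5
#' so that pooling begins close to sum-pooling rather than annihilating the
#' hidden sequence. Identical seeds give identical parameters.
#'
#' @param config A [model_config()].
#' @return Named list of parameter arrays (class `model_params`).
#' @export
init_params <- function(config) {
  H <- config$d_h
  cw <- concat_width(config)
  with_seed(config$seed, {
    u <- function(nr, nc) {
      lim <- 1 / sqrt(nr)
      matrix(runif(nr * nc, -lim, lim), nr, nc)
    }
    lstm_bias <- function() {
      b <- numeric(4 * H)
      b[(H + 1):(2 * H)] <- 1 # forget gate
      b
    }
    p <- list(
      lstm1_Wx = u(config$d_e, 4 * H), lstm1_Wh = u(H, 4 * H), lstm1_b = lstm_bias(),
      lstm2_Wx = u(H, 4 * H), lstm2_Wh = u(H, 4 * H), lstm2_b = lstm_bias(),
      att_W = u(H, 1), att_b = 0.5,
      fc1_W = u(cw, config$d_u), fc1_b = numeric(config$d_u),
      fc2_W = u(config$d_u, 3), fc2_b = numeric(3)
    )
    class(p) <- "model_params"
    p
  })
}

rep_vector_for <- function(config, reps) {
  if (config$ablation == "no_injection") return(numeric(0))
  if (is.null(reps))
    stopf("injection stage: word-set representations are required unless the no_injection ablation is used")
  if (inherits(reps, "word_set_bundle")) reps <- reps$rep_vector
  if (is.null(reps) || length(reps) != 6 * config$d_w)
    stopf("injection stage: expected a representation vector of length 6*d_w = %d, got %d",
          6 * config$d_w, length(reps))
  as.numeric(reps)
}

#' Forward pass
#'
#' Runs the full network on one user's embedded post sequence and returns
#' every intermediate quantity.
#'
#' @param emb Numeric matrix (posts x `d_e`), one row per post in
#'   chronological order.
#' @param params Parameters from [init_params()] or [train_model()].
#' @param config The matching [model_config()].
#' @param reps Word-set representations: a bundle from
#'   [bundle_representations()] or the concatenated numeric vector (length
#'   `6*d_w`). Ignored under the `no_injection` ablation.
#' @return Object of class `forward_trace`: `H` (hidden sequence), `att`
#'   (raw tanh attention scores), `pooled`, `concat`, `head_hidden`, and
#'   `scores` (normalized triple in (-1,1), named s_r/s_e/s_o).
#' @export
forward <- function(emb, params, config, reps = NULL) {
  if (!is.matrix(emb)) emb <- matrix(emb, nrow = 1)
  if (ncol(emb) != config$d_e)
    stopf("embedding stage: input width %d does not match d_e = %d",
          ncol(emb), config$d_e)
  rv <- rep_vector_for(config, reps)
  tr <- cpp_forward(emb, rv, unclass(params),
                    no_attention = config$ablation == "no_attention",
                    no_injection = config$ablation == "no_injection")
  tr$att <- as.numeric(tr$att)
  tr$scores <- stats::setNames(as.numeric(tr$scores), c("s_r", "s_e", "s_o"))
  tr$config <- config
  class(tr) <- "forward_trace"
  tr
}

#' @export
print.forward_trace <- function(x, ...) {
  cat(sprintf("<forward_trace: n=%d posts, scores s_r=%.3f s_e=%.3f s_o=%.3f>\n",
              nrow(x$H), x$scores[1], x$scores[2], x$scores[3]))
  invisible(x)
}

#' Predicted parenting scores on the 1-4 scale
#'
#' Denormalizes a trace's (-1,1) output back to the questionnaire scale.
#' @param trace A [forward()] result.
#' @return Named numeric vector `c(s_r, s_e, s_o)` in [1, 4].
#' @export
predicted_scores <- function(trace) {
  denormalize_score(trace$scores)
}

#' Ablation variants of a configuration
#'
#' `no_attention` replaces attention pooling by the mean over hidden states;
#' `no_injection` drops the word-set representations so the head consumes
#' the pooled vector alone.
#'
#' @param config A [model_config()].
#' @param which `"no_attention"` or `"no_injection"`.
#' @return The modified configuration.
#' @export
make_ablation <- function(config, which) {
  if (!is.character(which) || length(which) != 1 ||
      !which %in% c("no_attention", "no_injection"))
    stopf("ablation must name a variant: 'no_attention' or 'no_injection'")
  config$ablation <- which
  config
}

#' Attention report for a post sequence
#'
#' Pairs each post with its raw attention score and a softmax-normalized
#' display weight (non-negative, summing to 1), ranked by weight
#' descending. The raw scores are tanh activations in (-1, 1); the softmax
#' is a reporting convention, not part of the model.
#'
#' @param posts Character vector (or data frame with `text`) of the posts
#'   the trace was computed on, in the same order.
#' @param trace The matching [forward()] trace.
#' @return Tibble with `rank`, `text`, `score` (raw) and `weight`
#'   (softmax), sorted by rank.
#' @export
attention_report <- function(posts, trace) {
  if (is.data.frame(posts)) posts <- posts$text
  e <- trace$att
  if (length(posts) != length(e))
    stopf("post list length (%d) does not match trace length (%d)",
          length(posts), length(e))
  w <- exp(e - max(e))
  w <- w / sum(w)
  ord <- order(w, decreasing = TRUE)
  tibble::tibble(rank = seq_along(e), text = posts[ord], score = e[ord],
                 weight = w[ord])
}
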