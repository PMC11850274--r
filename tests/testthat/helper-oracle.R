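# Independent reference implementations used as oracles. These re-derive
# the quantities from their definitions with plain R loops and stay
# deliberately separate from the package's computation paths.

ref_sigmoid <- function(x) 1 / (1 + exp(-x))

# One LSTM layer, step by step from the cell equations.
ref_lstm_layer <- function(X, Wx, Wh, b) {
  n <- nrow(X)
  H <- nrow(Wh)
  h <- rep(0, H)
  cc <- rep(0, H)
  out <- matrix(0, n, H)
  for (t in seq_len(n)) {
    a <- as.numeric(X[t, , drop = FALSE] %*% Wx) + as.numeric(h %*% Wh) + b
    i <- ref_sigmoid(a[1:H])
    f <- ref_sigmoid(a[H + 1:H])
    g <- tanh(a[2 * H + 1:H])
    o <- ref_sigmoid(a[3 * H + 1:H])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    out[t, ] <- h
  }
  out
}

# Brute-force composition of the network equations: stacked LSTMs, tanh
# attention scores, pooled H' = att' H, concat with the six set
# representations, two tanh head layers.
ref_forward <- function(emb, reps, p, ablation = "full") {
  H1 <- ref_lstm_layer(emb, p$lstm1_Wx, p$lstm1_Wh, p$lstm1_b)
  H2 <- ref_lstm_layer(H1, p$lstm2_Wx, p$lstm2_Wh, p$lstm2_b)
  n <- nrow(H2)
  if (ablation == "no_attention") {
    att <- rep(1 / n, n)
    Hp <- colMeans(H2)
  } else {
    att <- as.numeric(tanh(H2 %*% p$att_W + p$att_b))
    Hp <- as.numeric(t(att) %*% H2)
  }
  C <- if (ablation == "no_injection") Hp else c(Hp, reps)
  U <- tanh(as.numeric(C %*% p$fc1_W) + p$fc1_b)
  scores <- tanh(as.numeric(U %*% p$fc2_W) + p$fc2_b)
  list(H = H2, att = att, pooled = Hp, concat = C, scores = scores)
}

# Closed-form pooled-variance two-sample t statistic.
ref_pooled_t <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

ref_pooled_t_p <- function(a, b) {
  tt <- ref_pooled_t(a, b)
  2 * pt(-abs(tt), df = length(a) + length(b) - 2)
}
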