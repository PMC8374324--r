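# Shared fixtures, built in code at test time.

# a small white-noise recording at the pipeline's native rate
noise_recording <- function(n = 12000, seed = 42, label = "normal") {
  set.seed(seed)
  pcg_recording(rnorm(n, sd = 0.1), 2000, label = label,
                recording_id = paste0("noise", seed))
}

# tiny labeled synthetic dataset shared across scoring tests
tiny_dataset <- function(n_normal = 12, n_abnormal = 6, seed = 11) {
  generate_dataset(n_normal, n_abnormal, seed = seed)$dataset
}

# brute-force O(N*M) density oracle: double loop over samples and dimensions
density_oracle <- function(Z) {
  N <- nrow(Z); M <- ncol(Z)
  C <- numeric(M)
  for (i in seq_len(M)) C[i] <- (max(Z[, i]) + min(Z[, i])) / 2
  total <- 0
  for (j in seq_len(N)) {
    s <- 0
    for (i in seq_len(M)) s <- s + (Z[j, i] - C[i])^2
    total <- total + sqrt(s)
  }
  total / N
}

# all-pairs Mann-Whitney AUC oracle with ties counted one half
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == "abnormal"]
  neg <- scores[labels == "normal"]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# textbook central-moment oracles
skew_oracle <- function(x) {
  m <- sum(x) / length(x)
  m2 <- sum((x - m)^2) / length(x)
  m3 <- sum((x - m)^3) / length(x)
  m3 / m2^(3 / 2)
}
kurt_oracle <- function(x) {
  m <- sum(x) / length(x)
  m2 <- sum((x - m)^2) / length(x)
  m4 <- sum((x - m)^4) / length(x)
  m4 / m2^2 - 3
}
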