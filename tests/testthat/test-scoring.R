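test_that("super-frame and recording scores follow their closed forms", {
  x <- rep(0, 70); xh <- rep(1, 70)
  expect_equal(superframe_score(x, xh), 1)
  expect_equal(superframe_score(x, x), 0)
  expect_equal(superframe_score(x, xh), superframe_score(xh, x))
  expect_error(superframe_score(1:3, 1:4), "identical shape")

  expect_equal(recording_score(c(1, 2, 3)), 2)
  expect_equal(recording_score(rep(0.7, 9)), 0.7)
  expect_error(recording_score(numeric(0)), "no super-frame")
  # the 1/(N-4) form over N-4 scores is just the mean, order-free
  set.seed(2)
  a <- runif(18)
  expect_equal(recording_score(a), sum(a) / 18)
  expect_equal(recording_score(sample(a)), recording_score(a))
})

test_that("roc_auc matches the all-pairs Mann-Whitney oracle", {
  # worked tie case: one tied normal/abnormal pair counts one half
  expect_equal(roc_auc(c(0.1, 0.2, 0.2, 0.4),
                       c("normal", "normal", "abnormal", "abnormal")), 0.875)
  # perfect separation and label complement
  s <- c(1, 2, 3, 10, 11)
  l <- c(rep("normal", 3), rep("abnormal", 2))
  expect_equal(roc_auc(s, l), 1)
  l_swap <- ifelse(l == "normal", "abnormal", "normal")
  expect_equal(roc_auc(s, l_swap), 0)

  set.seed(31)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    labels <- c("normal", "abnormal",
                sample(c("normal", "abnormal"), n - 2, replace = TRUE))
    scores <- sample(round(runif(n), sample(1:3, 1)))  # rounding forces ties
    auc <- roc_auc(scores, labels)
    expect_equal(auc, auc_oracle(scores, labels), tolerance = 1e-12)
    # label complement symmetry
    expect_equal(roc_auc(scores, ifelse(labels == "normal", "abnormal", "normal")),
                 1 - auc, tolerance = 1e-12)
    # invariance under a strictly monotone transform
    expect_equal(roc_auc(exp(3 * scores), labels), auc, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, rep("normal", 3)), "undefined")
})

test_that("split keeps all abnormals for testing and is seeded", {
  dd <- generate_dataset(100, 30, seed = 2)
  sp <- split_normals(dd$dataset, 0.9, seed = 5)
  train_labs <- dataset_labels(sp$train)
  test_labs <- dataset_labels(sp$test)
  expect_equal(sum(train_labs == "normal"), 90)
  expect_equal(sum(train_labs == "abnormal"), 0)
  expect_equal(sum(test_labs == "normal"), 10)
  expect_equal(sum(test_labs == "abnormal"), 30)
  expect_length(intersect(names(sp$train), names(sp$test)), 0)
  sp2 <- split_normals(dd$dataset, 0.9, seed = 5)
  expect_identical(names(sp$train), names(sp2$train))
  sp3 <- split_normals(dd$dataset, 0.9, seed = 6)
  expect_false(identical(names(sp$train), names(sp3$train)))
})

test_that("delta ratio reproduces the published worked examples", {
  expect_equal(delta_ratio(0.825, 0.798), 0.034)
  expect_equal(delta_ratio(0.944, 0.616), 0.532)
  expect_equal(delta_ratio(0.7, 0.7), 0)
  expect_equal(delta_ratio(0.5, 0.4, digits = NULL), 0.25)
  expect_error(delta_ratio(0.5, 0), "positive")
  expect_error(delta_ratio(0.4, 0.5), ">=")
})

test_that("delta table helper appends delta and the secondary beta ratio", {
  tab <- data.frame(model = c("BVAE", "DBAE"), subset = c("a", "e"),
                    best_auc = c(0.825, 0.928), worst_auc = c(0.798, 0.918),
                    best_beta = c(0.01, 0.1), worst_beta = c(1, 1))
  out <- delta_from_auc_table(tab)
  expect_equal(out$delta, c(0.034, 0.011))
  expect_equal(out$beta_ratio, c(0.01 / 1 - 1, 0.1 / 1 - 1))
})

test_that("score_recordings aggregates per-super-frame scores per recording", {
  dd <- tiny_dataset()
  sf <- preprocess_dataset(dd)
  fit <- pcg_ae(do.call(rbind, sf[dataset_labels(dd) == "normal"]),
                "dbae", beta = 0.1, epochs = 3, seed = 1)
  tab <- score_recordings(fit, sf, labels = dataset_labels(dd))
  expect_equal(nrow(tab), length(dd))
  expect_true(all(tab$n_superframes == 18))
  per <- attr(tab, "superframe_scores")
  expect_equal(tab$score, unname(vapply(per, mean, numeric(1))))
  expect_true(all(unlist(per) >= 0))
})

test_that("beta sweep produces one evaluation per beta with tie-aware best", {
  dd <- tiny_dataset(n_normal = 14, n_abnormal = 6)
  sw <- beta_sweep(dd, "dbae", betas = c(0.1, 10), seed = 4, epochs = 3)
  expect_equal(nrow(sw$results), 2)
  expect_true(sw$auc_best >= sw$auc_worst)
  expect_equal(sw$delta, delta_ratio(sw$auc_best, sw$auc_worst))
  expect_true(all(sw$results$n_test_abnormal == 6))
  # reproducibility of the whole sweep table
  sw2 <- beta_sweep(dd, "dbae", betas = c(0.1, 10), seed = 4, epochs = 3)
  expect_identical(sw$results, sw2$results)
})
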