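#' Anomaly score of a single super-frame
#'
#' Mean squared error between a super-frame and its reconstruction over all
#' elements; higher values mean the model reconstructs the frame worse, i.e.
#' the frame looks less like the normal data the model was trained on.
#'
#' @param x,x_hat Numeric vectors/matrices of identical shape.
#' @return Nonnegative scalar.
#' @export
superframe_score <- function(x, x_hat) {
  if (!identical(dim(x), dim(x_hat)) || length(x) != length(x_hat)) {
    stop("x and x_hat must have identical shape")
  }
  mean((as.numeric(x) - as.numeric(x_hat))^2)
}

#' Overall anomaly score of a recording
#'
#' The per-recording score is the arithmetic mean of its per-super-frame
#' scores; for a recording with `N` Mel frames there are `N - 4` super-frames,
#' so this is `a = 1/(N-4) * sum(a_i)`.
#'
#' @param a_list Numeric vector of per-super-frame scores.
#' @return Scalar mean score.
#' @export
recording_score <- function(a_list) {
  if (length(a_list) < 1) stop("no super-frame scores supplied")
  mean(a_list)
}

#' Score every recording of a dataset with a fitted model
#'
#' @param model A fitted [pcg_ae()].
#' @param superframes Named list of super-frame matrices (from
#'   [preprocess_dataset()]).
#' @param labels Optional character vector of labels matching
#'   `superframes` (taken from names-matched dataset if supplied).
#' @param domains Optional character vector of domain tags.
#' @return Data frame (one row per recording): `recording_id`, `label`,
#'   `domain_id`, `n_superframes`, `score`.  The per-super-frame score
#'   vectors are attached as attribute `"superframe_scores"`.
#' @export
score_recordings <- function(model, superframes, labels = NULL, domains = NULL) {
  stopifnot(inherits(model, "pcg_ae"), is.list(superframes))
  ids <- names(superframes)
  if (is.null(ids)) ids <- sprintf("rec%03d", seq_along(superframes))
  per_sf <- lapply(superframes, function(x) predict(model, x, type = "score"))
  out <- data.frame(
    recording_id = ids,
    label = if (is.null(labels)) NA_character_ else labels,
    domain_id = if (is.null(domains)) NA_character_ else domains,
    n_superframes = vapply(per_sf, length, integer(1)),
    score = vapply(per_sf, recording_score, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "superframe_scores") <- per_sf
  out
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC of anomaly scores with `"abnormal"` as the positive class and higher
#' scores meaning more anomalous.  Computed with average ranks, which equals
#' the all-pairs Mann-Whitney statistic with ties counted one half — no
#' score threshold is ever chosen.
#'
#' @param scores Numeric vector of anomaly scores.
#' @param labels Character/factor vector in `{"normal", "abnormal"}`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c("normal", "abnormal")))
  pos <- labels == "abnormal"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: need at least one normal and one abnormal recording")
  }
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Split a dataset into training normals and a mixed test set
#'
#' Training uses a random `train_fraction` of the normal recordings only;
#' the held-out normals plus all abnormal recordings form the test set.  The
#' split is at recording level (super-frames of one recording never straddle
#' the split) and fully determined by `seed`.
#'
#' @param dataset A [pcg_dataset()].
#' @param train_fraction Fraction of normals used for training (default 0.9).
#' @param seed Integer seed for the shuffle.
#' @return List with `pcg_dataset`s `train` and `test`.
#' @export
split_normals <- function(dataset, train_fraction = 0.9, seed = 1) {
  stopifnot(inherits(dataset, "pcg_dataset"),
            train_fraction > 0, train_fraction < 1)
  labs <- dataset_labels(dataset)
  normal_idx <- which(labs == "normal")
  if (!length(normal_idx)) stop("no normal recordings to train on")
  n_train <- floor(length(normal_idx) * train_fraction)
  if (n_train < 1) stop("train_fraction leaves no training recordings")
  if (n_train == length(normal_idx)) n_train <- length(normal_idx) - 1L
  perm <- with_preserved_rng(seed, sample(normal_idx))
  train_idx <- sort(perm[seq_len(n_train)])
  test_idx <- sort(c(setdiff(normal_idx, train_idx), which(labs == "abnormal")))
  list(train = pcg_dataset(unclass(dataset)[train_idx]),
       test = pcg_dataset(unclass(dataset)[test_idx]))
}

# run expr under a given seed without clobbering the caller's RNG state
with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Sensitivity ratio between best and worst beta settings
#'
#' `delta = auc_best / auc_worst - 1`: the relative AUC gained by moving
#' from the worst-performing to the best-performing beta on the same data.
#' Zero means beta does not matter; large values mean performance depends
#' strongly on tuning beta.
#'
#' @param auc_best,auc_worst AUC values with `0 < auc_worst <= auc_best`.
#' @param digits Rounding applied to the result (3 matches the reference
#'   tables); `NULL` for no rounding.
#' @return Scalar ratio.
#' @export
delta_ratio <- function(auc_best, auc_worst, digits = 3) {
  if (any(auc_worst <= 0)) stop("auc_worst must be positive")
  if (any(auc_best < auc_worst)) stop("auc_best must be >= auc_worst")
  d <- auc_best / auc_worst - 1
  if (!is.null(digits)) d <- round(d, digits)
  d
}

#' Delta sensitivity table from published best/worst AUCs
#'
#' Applies [delta_ratio()] row-wise to a table of best/worst AUC values,
#' e.g. the bundled `reference_auc.csv` of published benchmark results, so
#' the beta-sensitivity arithmetic can be checked without any training.
#'
#' @param auc_table Data frame with columns `model`, `subset`, `best_auc`,
#'   `worst_auc` (and optionally `best_beta`, `worst_beta`).
#' @return The table with `delta` (3 dp) and, when betas are present,
#'   `beta_ratio` (the literal best/worst beta ratio minus one, a secondary
#'   diagnostic) appended.
#' @export
delta_from_auc_table <- function(auc_table) {
  stopifnot(all(c("model", "subset", "best_auc", "worst_auc") %in%
                  names(auc_table)))
  auc_table$delta <- delta_ratio(auc_table$best_auc, auc_table$worst_auc)
  if (all(c("best_beta", "worst_beta") %in% names(auc_table))) {
    auc_table$beta_ratio <- auc_table$best_beta / auc_table$worst_beta - 1
  }
  auc_table
}

#' Train/evaluate one model family across a grid of beta values
#'
#' Implements the evaluation protocol: split the normals 90/10 at recording
#' level, train one model per beta on the training normals' super-frames,
#' score the mixed test set by mean reconstruction error and compare with
#' ROC/AUC.  The same split and the same model seed are used for every beta
#' so the sweep isolates the effect of beta.
#'
#' @param dataset A labeled [pcg_dataset()].
#' @param kind Model family passed to [pcg_ae()].
#' @param betas Beta grid (default `c(0.01, 0.1, 1, 10, 100)`).
#' @param seed Master seed (split and model training derive from it).
#' @param train_fraction Fraction of normals used for training.
#' @param epochs,batch_size,lr,latent_dim,hidden Passed to [pcg_ae()].
#' @return Object of class `pcg_sweep`: list with `results` (data frame:
#'   `model_kind`, `beta`, `n_train`, `n_test_normal`, `n_test_abnormal`,
#'   `auc`, `final_density`), `best_beta`, `worst_beta`, `auc_best`,
#'   `auc_worst`, `delta`, `models` (fitted `pcg_ae` per beta), and
#'   `score_tables` (per-recording scores per beta).  Ties in AUC resolve
#'   toward the smaller beta.
#' @export
beta_sweep <- function(dataset, kind = c("dbae", "dbvae", "bvae"),
                       betas = c(0.01, 0.1, 1, 10, 100), seed = 1,
                       train_fraction = 0.9, epochs = 300, batch_size = 256,
                       lr = 2e-3, latent_dim = 8, hidden = c(128, 64)) {
  kind <- match.arg(kind)
  betas <- sort(betas)
  sp <- split_normals(dataset, train_fraction, seed = seed)
  train_sf <- preprocess_dataset(sp$train)
  test_sf <- preprocess_dataset(sp$test)
  test_labels <- dataset_labels(sp$test)
  test_domains <- vapply(sp$test, `[[`, character(1), "domain_id")
  x_train <- do.call(rbind, train_sf)

  models <- list(); tables <- list()
  res <- data.frame()
  for (b in betas) {
    fit <- pcg_ae(x_train, kind = kind, beta = b, latent_dim = latent_dim,
                  hidden = hidden, epochs = epochs, batch_size = batch_size,
                  lr = lr, seed = seed)
    tab <- score_recordings(fit, test_sf, labels = test_labels,
                            domains = test_domains)
    auc <- roc_auc(tab$score, tab$label)
    key <- format(b)
    models[[key]] <- fit
    tables[[key]] <- tab
    res <- rbind(res, data.frame(
      model_kind = kind, beta = b, n_train = length(sp$train),
      n_test_normal = sum(test_labels == "normal"),
      n_test_abnormal = sum(test_labels == "abnormal"),
      auc = auc,
      final_density = fit$history$density[nrow(fit$history)]))
  }
  # ties toward the smaller beta: betas ascend, so first max/min wins
  best_i <- which.max(res$auc)
  worst_i <- which.min(res$auc)
  structure(list(
    results = res,
    best_beta = res$beta[best_i], worst_beta = res$beta[worst_i],
    auc_best = res$auc[best_i], auc_worst = res$auc[worst_i],
    delta = delta_ratio(res$auc[best_i], res$auc[worst_i]),
    models = models, score_tables = tables,
    split_seed = seed, kind = kind
  ), class = "pcg_sweep")
}

#' @export
print.pcg_sweep <- function(x, ...) {
  cat(sprintf("<pcg_sweep:%s> %d beta settings, seed %d\n",
              x$kind, nrow(x$results), x$split_seed))
  print(x$results[, c("beta", "auc", "final_density")],
        row.names = FALSE, digits = 4)
  cat(sprintf("best beta %g (AUC %.3f), worst beta %g (AUC %.3f), delta %.3f\n",
              x$best_beta, x$auc_best, x$worst_beta, x$auc_worst, x$delta))
  invisible(x)
}
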