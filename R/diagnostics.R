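#' Sample skewness (biased central moments)
#'
#' `g1 = m3 / m2^(3/2)` with `m_k` the 1/N central moments.  Zero for any
#' symmetric sample; used to judge how Gaussian-like a latent dimension is.
#'
#' @param values Numeric vector with at least 3 values and nonzero variance.
#' @return Scalar skewness.
#' @export
moment_skewness <- function(values) {
  check_moment_input(values, 3)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 <= 0) stop("degenerate (zero-variance) input: skewness undefined")
  mean((values - m)^3) / m2^1.5
}

#' Sample excess kurtosis (biased central moments)
#'
#' `g2 = m4 / m2^2 - 3`; the `-3` makes a Gaussian score 0.  Bounded below
#' by -2.  Large positive values indicate a heavy-tailed / sharply peaked
#' latent distribution.
#'
#' @param values Numeric vector with at least 4 values and nonzero variance.
#' @return Scalar excess kurtosis (>= -2).
#' @export
moment_kurtosis <- function(values) {
  check_moment_input(values, 4)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 <= 0) stop("degenerate (zero-variance) input: kurtosis undefined")
  mean((values - m)^4) / m2^2 - 3
}

check_moment_input <- function(values, n_min) {
  if (length(values) < n_min) {
    stop("need at least ", n_min, " values, got ", length(values))
  }
  if (!all(is.finite(values))) stop("non-finite values in moment input")
}

#' Latent-space moment diagnostics of a fitted model
#'
#' Encodes super-frames from normal recordings with the deterministic
#' encoder (means, no sampling), computes skewness and excess kurtosis per
#' latent dimension, and summarizes them as mean +/- sd across dimensions.
#' Constant (degenerate) latent dimensions are excluded from the summary
#' with a warning.
#'
#' @param model A fitted [pcg_ae()], or `NULL` to summarize a raw latent
#'   matrix passed as `superframes` (e.g. a Gaussian reference batch).
#' @param superframes Super-frame matrix / list of matrices (encoded through
#'   the model), or a latent matrix when `model` is `NULL`.
#' @return Object of class `pcg_moments`: `skewness`, `kurtosis`
#'   (per-dimension vectors, `NA` where degenerate), `skewness_mean`,
#'   `skewness_sd`, `kurtosis_mean`, `kurtosis_sd`, `latent_mean`,
#'   `density`, `n_samples`, `n_dims_used`.
#' @export
latent_moments <- function(model, superframes) {
  Z <- if (is.null(model)) {
    as.matrix(if (is.list(superframes)) do.call(rbind, superframes) else superframes)
  } else {
    predict(model, superframes, type = "latent")
  }
  if (nrow(Z) < 4) stop("need at least 4 latent samples for moment estimates")
  m2 <- apply(Z, 2, function(v) mean((v - mean(v))^2))
  degenerate <- m2 < 1e-12
  if (any(degenerate)) {
    warning(sum(degenerate), " degenerate latent dimension(s) excluded from ",
            "the moment summary")
  }
  g1 <- rep(NA_real_, ncol(Z))
  g2 <- rep(NA_real_, ncol(Z))
  for (i in which(!degenerate)) {
    g1[i] <- moment_skewness(Z[, i])
    g2[i] <- moment_kurtosis(Z[, i])
  }
  used <- !degenerate
  structure(list(
    skewness = g1, kurtosis = g2,
    skewness_mean = mean(g1[used]), skewness_sd = stats::sd(g1[used]),
    kurtosis_mean = mean(g2[used]), kurtosis_sd = stats::sd(g2[used]),
    latent_mean = colMeans(Z), density = latent_density(Z),
    n_samples = nrow(Z), n_dims_used = sum(used)
  ), class = "pcg_moments")
}

#' @export
print.pcg_moments <- function(x, ...) {
  cat(sprintf("<pcg_moments> %d samples, %d latent dimension(s)\n",
              x$n_samples, x$n_dims_used))
  cat(sprintf("skewness  %.3f (+/- %.3f)\n", x$skewness_mean,
              ifelse(is.na(x$skewness_sd), 0, x$skewness_sd)))
  cat(sprintf("kurtosis  %.3f (+/- %.3f)\n", x$kurtosis_mean,
              ifelse(is.na(x$kurtosis_sd), 0, x$kurtosis_sd)))
  cat(sprintf("density   %.4f\n", x$density))
  invisible(x)
}

#' Moment diagnostics table across a set of fitted models
#'
#' One row per model (plus an `N(0,1)` reference row computed on seeded
#' Gaussian draws), each summarizing the latent skewness/kurtosis of the
#' normal super-frames — the latent-Gaussianity comparison across model
#' families.
#'
#' @param models Named list of fitted [pcg_ae()] models.
#' @param superframes Normal-recording super-frames to encode (matrix or
#'   list of matrices).
#' @param reference_n Rows of the synthetic `N(0,1)` reference batch.
#' @param seed Seed for the reference batch.
#' @return Data frame with columns `model`, `beta`, `skewness_mean`,
#'   `skewness_sd`, `kurtosis_mean`, `kurtosis_sd`, `density`, `n_samples`.
#' @export
moments_table <- function(models, superframes, reference_n = 10000, seed = 1) {
  stopifnot(length(models) >= 1)
  ref_dim <- models[[1]]$config$latent_dim
  Zref <- with_preserved_rng(seed,
    matrix(stats::rnorm(reference_n * ref_dim), reference_n, ref_dim))
  rows <- list(summ_row("N(0,1)", NA_real_, latent_moments(NULL, Zref)))
  nms <- names(models)
  if (is.null(nms)) nms <- vapply(models, `[[`, character(1), "kind")
  for (i in seq_along(models)) {
    m <- models[[i]]
    rows[[i + 1]] <- summ_row(nms[i], m$beta, latent_moments(m, superframes))
  }
  do.call(rbind, rows)
}

summ_row <- function(name, beta, mom) {
  data.frame(model = name, beta = beta,
             skewness_mean = mom$skewness_mean, skewness_sd = mom$skewness_sd,
             kurtosis_mean = mom$kurtosis_mean, kurtosis_sd = mom$kurtosis_sd,
             density = mom$density, n_samples = mom$n_samples,
             stringsAsFactors = FALSE)
}
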