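#' Fit a density-regularized auto-encoder to heart-sound super-frames
#'
#' Trains one of four fully-connected auto-encoder variants on flattened
#' super-frames (rows of `x`), using only normal recordings (the
#' unsupervised contract):
#'
#' \describe{
#'   \item{`dbae`}{deterministic encoder, loss `L = L_r + beta * D` where
#'     `L_r` is the element-wise mean squared reconstruction error and `D`
#'     the latent dispersion of [latent_density()] computed on the current
#'     mini-batch.}
#'   \item{`dbvae`}{variational encoder with Gaussian reparameterization;
#'     same `L_r + beta * D` loss, with `D` measured on the sampled latent
#'     vectors (what the decoder actually sees).}
#'   \item{`bvae`}{the beta-VAE baseline: `L = L_r + beta * KL(q || N(0, I))`.}
#'   \item{`ae`}{plain auto-encoder (no latent penalty); identical to
#'     `dbae` with `beta = 0` and used as its ablation reference.}
#' }
#'
#' The encoder is a ReLU stack `input -> hidden -> latent` (variational kinds
#' emit `2 * latent_dim` outputs, split into mean and log-variance); the
#' decoder mirrors it.  Optimization is Adam on shuffled mini-batches.  All
#' randomness (initialization, shuffling, reparameterization draws) comes
#' from one stream seeded with `seed`, so identical calls are bit-reproducible.
#'
#' @param x Numeric matrix of super-frames (samples x features, typically
#'   `n x 70`), or a list of such matrices (one per recording) which is
#'   row-bound.
#' @param kind Model family; see Details.
#' @param beta Nonnegative weight of the latent penalty (dispersion or KL).
#' @param latent_dim Latent dimensionality (default 8).
#' @param hidden Encoder hidden layer sizes (decoder mirrors them).
#' @param epochs,batch_size,lr Adam training schedule.
#' @param seed Integer seed controlling all randomness of the fit.
#' @param verbose Print per-epoch losses.
#' @return An object of class `pcg_ae` with elements `kind`, `beta`,
#'   `params` (encoder/decoder weights), `config`, and `history` (per-epoch
#'   loss breakdown: `recon`, `density`, `kl`, `total`).
#' @examples
#' x <- matrix(rnorm(200 * 70), 200, 70)
#' fit <- pcg_ae(x, kind = "dbae", beta = 1, epochs = 3, seed = 1)
#' scores <- predict(fit, x, type = "score")
#' @export
pcg_ae <- function(x, kind = c("dbae", "dbvae", "bvae", "ae"), beta = 1,
                   latent_dim = 8, hidden = c(128, 64), epochs = 300,
                   batch_size = 256, lr = 2e-3, seed = 1, verbose = FALSE) {
  kind <- match.arg(kind)
  if (is.list(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  if (nrow(x) < 1) stop("no training super-frames supplied")
  if (!all(is.finite(x))) stop("training data contains non-finite values")
  stopifnot(beta >= 0, latent_dim >= 1, epochs >= 1, batch_size >= 1)
  if (kind == "ae") beta <- 0
  input_dim <- ncol(x)
  n <- nrow(x)
  variational <- kind %in% c("bvae", "dbvae")
  enc_out <- if (variational) 2L * latent_dim else latent_dim

  set.seed(seed)
  enc <- init_stack(c(input_dim, hidden, enc_out))
  dec <- init_stack(c(latent_dim, rev(hidden), input_dim))
  n_enc <- length(enc)
  params <- c(enc, dec)
  state <- list(m = adam_init(params), v = adam_init(params))
  t_step <- 0L

  history <- data.frame(epoch = seq_len(epochs), recon = NA_real_,
                        density = NA_real_, kl = NA_real_, total = NA_real_)

  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    ep_loss <- c(recon = 0, density = 0, kl = 0, total = 0)
    for (s in starts) {
      idx <- perm[s:min(s + batch_size - 1, n)]
      Xb <- x[idx, , drop = FALSE]
      B <- nrow(Xb)

      ef <- stack_forward(params[seq_len(n_enc)], Xb)
      if (variational) {
        mu <- ef$out[, seq_len(latent_dim), drop = FALSE]
        lv <- ef$out[, latent_dim + seq_len(latent_dim), drop = FALSE]
        eps <- matrix(stats::rnorm(B * latent_dim), B, latent_dim)
        sd_z <- exp(lv / 2)
        z <- mu + sd_z * eps
      } else {
        z <- ef$out
      }

      df <- stack_forward(params[n_enc + seq_along(dec)], z)
      xhat <- df$out

      recon <- mean((xhat - Xb)^2)
      d_xhat <- 2 * (xhat - Xb) / length(Xb)
      db <- stack_backward(params[n_enc + seq_along(dec)], df$cache, d_xhat)
      dz <- db$dX

      dens <- 0; kl <- 0
      if (kind %in% c("dbae", "dbvae", "ae")) {
        dg <- density_with_grad(z)
        dens <- dg$value
        if (beta > 0) dz <- dz + beta * dg$grad
      }
      if (variational) {
        dmu <- dz
        dlv <- dz * (0.5 * sd_z * eps)
        if (kind == "bvae") {
          kl <- mean(0.5 * rowSums(mu^2 + exp(lv) - 1 - lv))
          dmu <- dmu + beta * mu / B
          dlv <- dlv + beta * 0.5 * (exp(lv) - 1) / B
        }
        d_enc_out <- cbind(dmu, dlv)
      } else {
        d_enc_out <- dz
      }
      eb <- stack_backward(params[seq_len(n_enc)], ef$cache, d_enc_out)

      total <- recon + beta * if (kind == "bvae") kl else dens
      if (!is.finite(total)) {
        stop("non-finite training loss at epoch ", ep,
             " (recon=", signif(recon, 4), ", penalty diverged); ",
             "reduce lr or beta")
      }

      grads <- c(eb$grads, db$grads)
      t_step <- t_step + 1L
      upd <- adam_step(params, grads, state, t_step, lr = lr)
      params <- upd$params
      state <- upd$state

      w <- B / n
      ep_loss <- ep_loss + w * c(recon, dens, kl, total)
    }
    history[ep, -1] <- ep_loss
    if (verbose) {
      message(sprintf("epoch %3d  recon %.5f  density %.5f  kl %.5f  total %.5f",
                      ep, ep_loss[1], ep_loss[2], ep_loss[3], ep_loss[4]))
    }
  }

  new_pcg_ae(
    enc = params[seq_len(n_enc)], dec = params[n_enc + seq_along(dec)],
    kind = kind,
    config = list(kind = kind, beta = beta, input_dim = input_dim,
                  latent_dim = latent_dim, hidden = hidden, epochs = epochs,
                  batch_size = batch_size, lr = lr, seed = seed,
                  n_train = n),
    history = history
  )
}

# low-level constructor; also used by tests to build hand-crafted networks
new_pcg_ae <- function(enc, dec, kind, config, history = NULL) {
  structure(list(kind = kind, beta = config$beta, params = list(enc = enc, dec = dec),
                 config = config, history = history),
            class = "pcg_ae")
}

#' Gaussian reparameterization draw
#'
#' `z = mu + exp(log_var / 2) * eps` with `eps ~ N(0, I)` drawn from R's
#' current RNG stream (seed with [set.seed()] for reproducibility).  Used at
#' train time by the variational kinds; inference decodes from `mu` directly.
#'
#' @param mu,log_var Matrices (samples x latent dims) of the same shape.
#' @return Matrix of latent draws, same shape as `mu`.
#' @export
reparameterize <- function(mu, log_var) {
  mu <- as.matrix(mu); log_var <- as.matrix(log_var)
  stopifnot(all(dim(mu) == dim(log_var)))
  eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  mu + exp(log_var / 2) * eps
}

encode_raw <- function(object, x) {
  x <- as.matrix(x)
  if (ncol(x) != object$config$input_dim) {
    stop("input has ", ncol(x), " features; model expects ",
         object$config$input_dim)
  }
  stack_forward(object$params$enc, x)$out
}

#' @rdname pcg_ae
#' @param object A fitted `pcg_ae`.
#' @param newdata Super-frame matrix (or list of matrices).
#' @param type `"reconstruction"` (decoded super-frames), `"latent"`
#'   (deterministic encoder means), or `"score"` (per-super-frame mean
#'   squared reconstruction error).  Inference never samples, so all types
#'   are deterministic.
#' @param ... Unused.
#' @export
predict.pcg_ae <- function(object, newdata,
                           type = c("reconstruction", "latent", "score"), ...) {
  type <- match.arg(type)
  if (is.list(newdata)) newdata <- do.call(rbind, newdata)
  E <- encode_raw(object, newdata)
  ld <- object$config$latent_dim
  z <- if (object$kind %in% c("bvae", "dbvae")) E[, seq_len(ld), drop = FALSE] else E
  if (type == "latent") return(z)
  xhat <- stack_forward(object$params$dec, z)$out
  if (type == "reconstruction") return(xhat)
  rowMeans((as.matrix(newdata) - xhat)^2)
}

#' @export
residuals.pcg_ae <- function(object, newdata, ...) {
  if (missing(newdata)) stop("supply newdata: the fit does not store training data")
  if (is.list(newdata)) newdata <- do.call(rbind, newdata)
  as.matrix(newdata) - predict(object, newdata, type = "reconstruction")
}

#' @export
coef.pcg_ae <- function(object, ...) object$params

#' @export
print.pcg_ae <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<pcg_ae:%s> beta=%g  %d -> [%s] -> %d latent, %d epochs, seed %d\n",
              x$kind, x$beta, cfg$input_dim,
              paste(cfg$hidden, collapse = ","), cfg$latent_dim,
              cfg$epochs, cfg$seed))
  if (!is.null(x$history)) {
    fin <- x$history[nrow(x$history), ]
    cat(sprintf("final loss: total %.5f (recon %.5f, density %.5f, kl %.5f)\n",
                fin$total, fin$recon, fin$density, fin$kl))
  }
  invisible(x)
}

#' @export
summary.pcg_ae <- function(object, ...) {
  structure(list(kind = object$kind, config = object$config,
                 history = object$history), class = "summary.pcg_ae")
}

#' @export
print.summary.pcg_ae <- function(x, ...) {
  cat(sprintf("Density-regularized auto-encoder (%s), beta = %g\n",
              x$kind, x$config$beta))
  cat(sprintf("trained on %d super-frames of dim %d, %d epochs, batch %d, lr %g\n",
              x$config$n_train, x$config$input_dim, x$config$epochs,
              x$config$batch_size, x$config$lr))
  if (!is.null(x$history)) {
    show <- x$history[unique(round(seq(1, nrow(x$history), length.out = 6))), ]
    print(show, row.names = FALSE, digits = 5)
  }
  invisible(x)
}

#' @export
plot.pcg_ae <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  graphics::matplot(h$epoch, cbind(h$total, h$recon), type = "l", lty = 1,
                    col = c("black", "steelblue"), xlab = "epoch",
                    ylab = "loss", main = paste0(x$kind, ", beta=", x$beta), ...)
  graphics::legend("topright", legend = c("total", "reconstruction"),
                   col = c("black", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' Loss breakdown of the density-based models
#'
#' `total = recon + beta * D` with `recon` the element-wise mean squared
#' error and `D` the latent dispersion ([latent_density()]) of the batch.
#'
#' @param x,x_hat Input and reconstruction matrices of identical shape.
#' @param z Latent batch (samples x dims).
#' @param beta Penalty weight.
#' @return List of class `loss_breakdown`: `recon`, `density`, `kl` (0),
#'   `beta`, `total`.
#' @export
loss_density_ae <- function(x, x_hat, z, beta) {
  x <- as.matrix(x); x_hat <- as.matrix(x_hat)
  stopifnot(all(dim(x) == dim(x_hat)), beta >= 0)
  recon <- mean((x - x_hat)^2)
  dens <- latent_density(z)
  structure(list(recon = recon, density = dens, kl = 0, beta = beta,
                 total = recon + beta * dens), class = "loss_breakdown")
}

#' Loss breakdown of the beta-VAE baseline
#'
#' `total = recon + beta * KL` where `KL` is the mean (over samples) closed
#' form divergence of the diagonal Gaussian posterior from `N(0, I)`:
#' `0.5 * sum_d (mu_d^2 + sigma_d^2 - 1 - log sigma_d^2)`.
#'
#' @inheritParams loss_density_ae
#' @param mu,log_var Posterior means and log-variances (samples x dims).
#' @return List of class `loss_breakdown`: `recon`, `density` (0), `kl`,
#'   `beta`, `total`.
#' @export
loss_beta_vae <- function(x, x_hat, mu, log_var, beta) {
  x <- as.matrix(x); x_hat <- as.matrix(x_hat)
  mu <- as.matrix(mu); log_var <- as.matrix(log_var)
  stopifnot(all(dim(x) == dim(x_hat)), all(dim(mu) == dim(log_var)), beta >= 0)
  recon <- mean((x - x_hat)^2)
  kl <- mean(0.5 * rowSums(mu^2 + exp(log_var) - 1 - log_var))
  structure(list(recon = recon, density = 0, kl = kl, beta = beta,
                 total = recon + beta * kl), class = "loss_breakdown")
}
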