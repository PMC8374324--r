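#' Latent-batch centroid (per-dimension midrange)
#'
#' The centroid of a latent batch is the midrange of each dimension,
#' `c_i = (max_j z_ij + min_j z_ij) / 2` — deliberately not the mean: it is
#' anchored by the edge samples of the batch.
#'
#' @param Z Numeric matrix, one row per sample, one column per latent
#'   dimension (a vector is treated as a single sample).
#' @return Numeric vector of length `ncol(Z)`.
#' @export
latent_centroid <- function(Z) {
  Z <- as_latent_matrix(Z)
  (apply(Z, 2, max) + apply(Z, 2, min)) / 2
}

#' Latent-batch density measure
#'
#' Mean Euclidean distance of the samples to the midrange centroid,
#' `D = (1/N) * sum_j ||Z_j - C||_2`.  Despite the name this is a dispersion:
#' smaller values mean a tighter (denser) latent cloud, and the training loss
#' adds `beta * D` so minimizing it shrinks the cloud toward the centroid.
#'
#' @inheritParams latent_centroid
#' @return Nonnegative scalar; 0 iff all samples coincide.
#' @export
latent_density <- function(Z) {
  Z <- as_latent_matrix(Z)
  C <- latent_centroid(Z)
  mean(sqrt(rowSums(sweep(Z, 2, C)^2)))
}

as_latent_matrix <- function(Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  if (nrow(Z) < 1) stop("empty latent batch")
  if (!all(is.finite(Z))) stop("latent batch contains non-finite values")
  Z
}

# Value and subgradient of the density measure w.r.t. the latent batch.
# The centroid depends on the per-dimension argmax/argmin samples; their
# subgradient contribution is 1/2 each (both halves land on the same sample
# for a constant dimension).  Used by the training loop; verified against
# numerical differentiation in the tests.
density_with_grad <- function(Z) {
  N <- nrow(Z)
  mx <- apply(Z, 2, which.max)
  mn <- apply(Z, 2, which.min)
  C <- (Z[cbind(mx, seq_len(ncol(Z)))] + Z[cbind(mn, seq_len(ncol(Z)))]) / 2
  diffs <- sweep(Z, 2, C)
  norms <- sqrt(rowSums(diffs^2))
  U <- diffs / ifelse(norms > 0, norms, 1)  # unit vectors; 0 rows stay 0
  U[norms == 0, ] <- 0
  D <- mean(norms)
  grad <- U / N
  ubar <- colMeans(U)                       # dD/dC = -ubar
  for (i in seq_len(ncol(Z))) {
    grad[mx[i], i] <- grad[mx[i], i] - ubar[i] / 2
    grad[mn[i], i] <- grad[mn[i], i] - ubar[i] / 2
  }
  list(value = D, grad = grad)
}
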