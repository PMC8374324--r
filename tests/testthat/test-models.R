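make_train_x <- function(n = 200, seed = 21) {
  set.seed(seed)
  matrix(rnorm(n * 70), n, 70)
}

test_that("training runs, records history, and is bit-reproducible", {
  x <- make_train_x()
  fit <- pcg_ae(x, "dbae", beta = 0.5, epochs = 5, seed = 3)
  expect_s3_class(fit, "pcg_ae")
  expect_equal(nrow(fit$history), 5)
  expect_true(all(is.finite(as.matrix(fit$history))))
  # total = recon + beta * density at every logged epoch
  expect_equal(fit$history$total,
               fit$history$recon + 0.5 * fit$history$density,
               tolerance = 1e-10)
  refit <- pcg_ae(x, "dbae", beta = 0.5, epochs = 5, seed = 3)
  expect_identical(coef(fit), coef(refit))
  expect_identical(fit$history, refit$history)
})

test_that("bvae history satisfies total = recon + beta * kl", {
  x <- make_train_x(150)
  fit <- pcg_ae(x, "bvae", beta = 2, epochs = 4, seed = 8)
  expect_equal(fit$history$total,
               fit$history$recon + 2 * fit$history$kl, tolerance = 1e-10)
  expect_true(all(fit$history$kl >= 0))
  # variational encoder emits deterministic (mu, log-var): latent type is
  # reproducible without touching the RNG
  z1 <- predict(fit, x[1:7, ], type = "latent")
  z2 <- predict(fit, x[1:7, ], type = "latent")
  expect_identical(z1, z2)
  expect_equal(dim(z1), c(7, 8))
})

test_that("dbae with beta = 0 reproduces the plain auto-encoder exactly", {
  x <- make_train_x(120)
  a <- pcg_ae(x, "dbae", beta = 0, epochs = 6, seed = 5)
  b <- pcg_ae(x, "ae", epochs = 6, seed = 5)
  expect_identical(coef(a), coef(b))
  expect_identical(a$history[c("recon", "density", "kl", "total")],
                   b$history[c("recon", "density", "kl", "total")])
  # and with beta = 0 the total is the reconstruction loss alone
  expect_equal(a$history$total, a$history$recon)
})

test_that("reparameterization draws have the right law and degenerate limit", {
  mu <- matrix(c(1, -2), 1)
  # sigma -> 0 collapses onto the mean
  z <- reparameterize(mu, matrix(-60, 1, 2))
  expect_equal(z, mu, tolerance = 1e-10)
  # seeded draws are identical across runs
  set.seed(10); z1 <- reparameterize(mu, matrix(0.3, 1, 2))
  set.seed(10); z2 <- reparameterize(mu, matrix(0.3, 1, 2))
  expect_identical(z1, z2)
  # Monte-Carlo: mean within 3 standard errors, sd matches exp(lv/2)
  set.seed(11)
  lv <- 0.4
  draws <- reparameterize(matrix(1.5, 1e5, 1), matrix(lv, 1e5, 1))
  se <- exp(lv / 2) / sqrt(1e5)
  expect_lt(abs(mean(draws) - 1.5), 3 * se)
  expect_equal(sd(draws), exp(lv / 2), tolerance = 0.02)
})

test_that("loss breakdowns match hand-worked values", {
  x <- matrix(0, 3, 4)
  xh <- matrix(1, 3, 4)
  z <- rbind(c(0, 0), c(2, 0), c(1, 3))
  lb <- loss_density_ae(x, xh, z, beta = 2)
  # recon = 1 exactly; density via the midrange centroid (1, 1.5)
  d_hand <- mean(c(sqrt(1 + 2.25), sqrt(1 + 2.25), sqrt(0 + 2.25)))
  expect_equal(lb$recon, 1)
  expect_equal(lb$density, d_hand)
  expect_equal(lb$total, 1 + 2 * d_hand)

  # beta-VAE: mu = 0, sigma = 1 gives zero KL; mu = 1, sigma = 1 gives 1/2
  lb0 <- loss_beta_vae(x, x, matrix(0, 3, 1), matrix(0, 3, 1), beta = 1)
  expect_equal(lb0$kl, 0)
  expect_equal(lb0$total, 0)
  lb1 <- loss_beta_vae(x, xh, matrix(1, 3, 1), matrix(0, 3, 1), beta = 3)
  expect_equal(lb1$kl, 0.5)
  expect_equal(lb1$total, 1 + 1.5)
  # perfect model with a collapsed latent batch: total exactly zero
  expect_equal(loss_density_ae(x, x, matrix(1, 3, 2), beta = 5)$total, 0)
})

test_that("an identity-constructed network reconstructs its input exactly", {
  # encoder 4 -> ReLU([x; -x]) -> 4, decoder mirrors it: x = h+ - h-
  d <- 4
  enc <- list(
    list(W = cbind(diag(d), -diag(d)), b = numeric(2 * d)),
    list(W = rbind(diag(d), -diag(d)), b = numeric(d))
  )
  dec <- list(
    list(W = cbind(diag(d), -diag(d)), b = numeric(2 * d)),
    list(W = rbind(diag(d), -diag(d)), b = numeric(d))
  )
  mdl <- pcgdense:::new_pcg_ae(enc, dec, "dbae",
                               config = list(beta = 0, input_dim = d,
                                             latent_dim = d, hidden = 2 * d))
  set.seed(2)
  x <- matrix(rnorm(20), 5, d)
  expect_equal(predict(mdl, x, type = "reconstruction"), x, tolerance = 1e-12)
  expect_equal(predict(mdl, x, type = "score"), rep(0, 5), tolerance = 1e-20)
  expect_equal(unname(residuals(mdl, x)), matrix(0, 5, d), tolerance = 1e-12)
})

test_that("encoder/decoder enforce the input dimension contract", {
  fit <- pcg_ae(make_train_x(50), "dbae", epochs = 2, seed = 1)
  expect_error(predict(fit, matrix(0, 3, 69)), "expects")
})

test_that("the density penalty actually produces gradients and shrinks D", {
  x <- make_train_x(300, seed = 33)
  fit_lo <- pcg_ae(x, "dbae", beta = 0, epochs = 20, seed = 2)
  fit_hi <- pcg_ae(x, "dbae", beta = 100, epochs = 20, seed = 2)
  d_lo <- tail(fit_lo$history$density, 1)
  d_hi <- tail(fit_hi$history$density, 1)
  expect_lt(d_hi, d_lo / 2)
})

test_that("training loss decreases on structured synthetic data", {
  dd <- generate_dataset(10, 0, seed = 5)
  x <- do.call(rbind, preprocess_dataset(dd$dataset))
  fit <- pcg_ae(x, "dbae", beta = 0.1, epochs = 30, seed = 1)
  sm <- stats::filter(fit$history$total, rep(1 / 5, 5), sides = 1)
  expect_lt(tail(stats::na.omit(sm), 1), sm[5])
})
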