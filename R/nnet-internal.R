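# Minimal fully-connected network machinery with hand-written
# backpropagation and Adam, used by pcg_ae().  Batches are row-major:
# X is B x d_in, weights W are d_in x d_out, so a layer is X %*% W + b.

relu <- function(x) pmax(x, 0)

glorot_init <- function(d_in, d_out) {
  lim <- sqrt(6 / (d_in + d_out))
  matrix(stats::runif(d_in * d_out, -lim, lim), d_in, d_out)
}

# params: list of list(W, b) for a plain ReLU stack with linear final layer
init_stack <- function(dims) {
  lapply(seq_len(length(dims) - 1), function(i) {
    list(W = glorot_init(dims[i], dims[i + 1]),
         b = numeric(dims[i + 1]))
  })
}

# forward pass; returns list(out, cache) where cache holds pre-activations
# and inputs per layer for backprop.  Hidden layers ReLU, last layer linear.
stack_forward <- function(params, X) {
  n <- length(params)
  cache <- vector("list", n)
  A <- X
  for (i in seq_len(n)) {
    Zi <- A %*% params[[i]]$W
    Zi <- sweep(Zi, 2, params[[i]]$b, "+")
    cache[[i]] <- list(input = A, pre = Zi)
    A <- if (i < n) relu(Zi) else Zi
  }
  list(out = A, cache = cache)
}

# backprop through the stack given dL/d(output); returns list(grads, dX)
stack_backward <- function(params, cache, d_out) {
  n <- length(params)
  grads <- vector("list", n)
  delta <- d_out
  for (i in rev(seq_len(n))) {
    if (i < n) delta <- delta * (cache[[i]]$pre > 0)
    grads[[i]] <- list(W = crossprod(cache[[i]]$input, delta),
                       b = colSums(delta))
    delta <- delta %*% t(params[[i]]$W)
  }
  list(grads = grads, dX = delta)
}

adam_init <- function(params) {
  rapply(params, function(p) p * 0, how = "replace")
}

# one Adam update over a nested params/grads structure (in-place semantics
# via return value); t is the 1-based step count for bias correction
adam_step <- function(params, grads, state, t, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[i]][[nm]] / (1 - beta1^t)
      vhat <- state$v[[i]][[nm]] / (1 - beta2^t)
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}
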