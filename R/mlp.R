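# Small multi-layer perceptron regressor: two tanh hidden layers, linear
# output, squared loss with L2 penalty on the weights, trained full-batch
# with BFGS and analytic gradients. Mirrors the common scikit-learn
# MLPRegressor parameterization (loss = mean(err^2)/2 + alpha/(2n)*||W||^2,
# biases unpenalized; 'lbfgs'-style full-batch quasi-Newton optimization).

.mlp_unpack <- function(par, p, h1, h2) {
  i <- 0
  W1 <- matrix(par[i + seq_len(p * h1)], p, h1); i <- i + p * h1
  b1 <- par[i + seq_len(h1)]; i <- i + h1
  W2 <- matrix(par[i + seq_len(h1 * h2)], h1, h2); i <- i + h1 * h2
  b2 <- par[i + seq_len(h2)]; i <- i + h2
  W3 <- matrix(par[i + seq_len(h2)], h2, 1); i <- i + h2
  b3 <- par[i + 1]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3)
}

.mlp_forward <- function(w, x) {
  a1 <- tanh(sweep(x %*% w$W1, 2, w$b1, "+"))
  a2 <- tanh(sweep(a1 %*% w$W2, 2, w$b2, "+"))
  pred <- drop(a2 %*% w$W3) + w$b3
  list(a1 = a1, a2 = a2, pred = pred)
}

.mlp_fit <- function(x, y, hidden = c(20L, 2L), alpha = 20,
                     maxit = 4000L, tol = 1e-5, seed = 10L) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  h1 <- hidden[1]; h2 <- hidden[2]

  glorot <- function(fan_in, fan_out, n_w) {
    lim <- sqrt(6 / (fan_in + fan_out))
    stats::runif(n_w, -lim, lim)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  par0 <- c(glorot(p, h1, p * h1), rep(0, h1),
            glorot(h1, h2, h1 * h2), rep(0, h2),
            glorot(h2, 1, h2), 0)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  obj <- function(par) {
    w <- .mlp_unpack(par, p, h1, h2)
    f <- .mlp_forward(w, x)
    err <- f$pred - y
    mean(err^2) / 2 +
      alpha / (2 * n) * (sum(w$W1^2) + sum(w$W2^2) + sum(w$W3^2))
  }
  grad <- function(par) {
    w <- .mlp_unpack(par, p, h1, h2)
    f <- .mlp_forward(w, x)
    err <- (f$pred - y) / n                     # d(loss)/d(pred)
    d3 <- matrix(err, ncol = 1)
    gW3 <- t(f$a2) %*% d3 + (alpha / n) * w$W3
    gb3 <- sum(d3)
    d2 <- (d3 %*% t(w$W3)) * (1 - f$a2^2)
    gW2 <- t(f$a1) %*% d2 + (alpha / n) * w$W2
    gb2 <- colSums(d2)
    d1 <- (d2 %*% t(w$W2)) * (1 - f$a1^2)
    gW1 <- t(x) %*% d1 + (alpha / n) * w$W1
    gb1 <- colSums(d1)
    c(as.vector(gW1), gb1, as.vector(gW2), gb2, as.vector(gW3), gb3)
  }
  opt <- stats::optim(par0, obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = tol))
  structure(list(weights = .mlp_unpack(opt$par, p, h1, h2),
                 hidden = hidden, alpha = alpha,
                 converged = opt$convergence == 0, value = opt$value),
            class = "fc_mlp")
}

.mlp_predict <- function(object, x) {
  .mlp_forward(object$weights, as.matrix(x))$pred
}
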