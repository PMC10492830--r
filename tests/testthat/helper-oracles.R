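# Independent oracles used across the test suite. These deliberately avoid
# the package's own code paths.

# Finite-width ReLU network gradient kernel: Monte-Carlo estimate of the
# NTK as the expected inner product of parameter gradients of a finite
# network, averaged over random initializations. Parameterization: h^0 = x,
# h^l = sqrt(2/m) relu(W^l h^{l-1}) with W^l entries N(0, 1), output
# f = v' h^L with v entries N(0, 1). For depth 1 the expectation equals
# the infinite-width kernel exactly; for deeper nets the bias is O(1/m).
ntk_finite_width_oracle <- function(x, z, depth, offset = FALSE,
                                    width = 4096L, draws = 100L,
                                    seed = 1L) {
  if (offset) {
    x <- c(x, 1)
    z <- c(z, 1)
  }
  set.seed(seed)
  vals <- vapply(seq_len(draws), function(i) {
    Ws <- vector("list", depth)
    Ws[[1L]] <- matrix(rnorm(width * length(x)), width, length(x))
    if (depth > 1L) {
      for (l in 2:depth) Ws[[l]] <- matrix(rnorm(width * width), width, width)
    }
    v <- rnorm(width)
    grad_dot <- function(a, b) {
      # forward pass for both inputs
      fwd <- function(u) {
        hs <- vector("list", depth + 1L)
        gs <- vector("list", depth)
        hs[[1L]] <- u
        for (l in seq_len(depth)) {
          gs[[l]] <- as.vector(Ws[[l]] %*% hs[[l]])
          hs[[l + 1L]] <- sqrt(2 / width) * pmax(gs[[l]], 0)
        }
        list(hs = hs, gs = gs)
      }
      fa <- fwd(a); fb <- fwd(b)
      # gradient wrt v
      total <- sum(fa$hs[[depth + 1L]] * fb$hs[[depth + 1L]])
      # backprop: delta = df/dg^l
      da <- sqrt(2 / width) * v * (fa$gs[[depth]] > 0)
      db <- sqrt(2 / width) * v * (fb$gs[[depth]] > 0)
      for (l in depth:1) {
        # contribution of W^l: outer(delta, h^{l-1}) for each input
        total <- total + sum(da * db) * sum(fa$hs[[l]] * fb$hs[[l]])
        if (l > 1L) {
          da <- sqrt(2 / width) * as.vector(crossprod(Ws[[l]], da)) *
            (fa$gs[[l - 1L]] > 0)
          db <- sqrt(2 / width) * as.vector(crossprod(Ws[[l]], db)) *
            (fb$gs[[l - 1L]] > 0)
        }
      }
      total
    }
    grad_dot(x, z)
  }, numeric(1))
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(draws))
}

# naive per-entry metric oracles
mean_r2_loop <- function(pred, truth) {
  vals <- numeric(0)
  for (i in seq_len(nrow(truth))) {
    ybar <- mean(truth[i, ])
    ss_tot <- sum((truth[i, ] - ybar)^2)
    if (ss_tot > 0) {
      vals <- c(vals, 1 - sum((pred[i, ] - truth[i, ])^2) / ss_tot)
    }
  }
  mean(vals)
}

mean_cosine_loop <- function(pred, truth, groups) {
  vals <- numeric(0)
  for (i in seq_len(nrow(truth))) {
    idx <- which(groups == groups[i])
    mu <- colMeans(truth[idx, , drop = FALSE])
    p <- pred[i, ] - mu
    y <- truth[i, ] - mu
    if (sum(p^2) > 0 && sum(y^2) > 0) {
      vals <- c(vals, sum(p * y) / sqrt(sum(p^2) * sum(y^2)))
    }
  }
  mean(vals)
}

# gradient descent on ||Y - W X||_F^2 (columns are samples) from an
# arbitrary initialization; converges to the minimum-norm-residual
# solution W0 + (Y - W0 X) X^+ for small enough steps
gd_least_squares <- function(X, Y, W0, steps = 1e5, lr = NULL) {
  if (is.null(lr)) lr <- 0.9 / max(eigen(X %*% t(X), only.values = TRUE,
                                         symmetric = TRUE)$values)
  W <- W0
  for (i in seq_len(steps)) {
    W <- W + lr * (Y - W %*% X) %*% t(X)
  }
  W
}

rand_matrix <- function(r, c, sd = 1) matrix(rnorm(r * c, sd = sd), r, c)

# a model whose predictions are a fixed matrix, whatever the inputs
perfect_model <- function(out) structure(list(out = out),
                                         class = "fixed_output_model")
predict.fixed_output_model <- function(object, newdata, ...) object$out
registerS3method("predict", "fixed_output_model", predict.fixed_output_model,
                 envir = asNamespace("stats"))
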