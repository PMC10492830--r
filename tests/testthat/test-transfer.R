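make_linear_source <- function(d, c_s, seed = 1) {
  set.seed(seed)
  linear_model(rand_matrix(c_s, d))
}

test_that("projection with a realizable linear target has zero residual", {
  src <- make_linear_source(6, 4)
  set.seed(2)
  Xt <- rand_matrix(10, 6)
  M <- rand_matrix(3, 4)
  Yt <- predict(src, Xt) %*% t(M)
  tm <- fit_projected(src, Xt, Yt, head_spec = "linear", ridge = 0)
  expect_equal(predict(tm, Xt), Yt, tolerance = 1e-8)
})

test_that("projection from a scalar source equals 1-feature least squares", {
  src <- make_linear_source(5, 1)
  set.seed(3)
  Xt <- rand_matrix(20, 5)
  Yt <- rand_matrix(20, 2)
  tm <- fit_projected(src, Xt, Yt, head_spec = "linear", ridge = 0)
  p <- predict(src, Xt)
  beta <- solve(crossprod(p), crossprod(p, Yt))   # direct 1-feature LS
  expect_equal(predict(tm, Xt), p %*% beta, tolerance = 1e-8)
})

test_that("single-sample projection interpolates the target label", {
  src <- make_linear_source(4, 3)
  Xt <- rand_matrix(1, 4)
  Yt <- matrix(c(2, -1), 1, 2)
  tm <- fit_projected(src, Xt, Yt, head_spec = laplace_kernel(5), ridge = 0)
  expect_equal(predict(tm, Xt), Yt, tolerance = 1e-8)
})

test_that("translation from a zero source is the baseline predictor", {
  src <- linear_model(matrix(0, 2, 5))
  set.seed(4)
  Xt <- rand_matrix(12, 5); Yt <- rand_matrix(12, 2)
  Xnew <- rand_matrix(6, 5)
  tm <- fit_translated(src, Xt, Yt, head_spec = laplace_kernel(5), ridge = 0)
  base <- fit_kernel(laplace_kernel(5), Xt, Yt, ridge = 0)
  expect_equal(predict(tm, Xnew), predict(base, Xnew), tolerance = 1e-8)
})

test_that("translation of an already-interpolating source is a no-op on train", {
  set.seed(5)
  Xt <- rand_matrix(8, 4); Yt <- rand_matrix(8, 2)
  src <- fit_kernel(laplace_kernel(5), Xt, Yt, ridge = 0)
  tm <- fit_translated(src, Xt, Yt, head_spec = laplace_kernel(5), ridge = 0)
  expect_equal(predict(tm, Xt), Yt, tolerance = 1e-7)
  # the head predicts ~0 on the training points
  expect_lt(max(abs(predict(tm$head, Xt))), 1e-7)
})

test_that("translation residual identity holds exactly", {
  src <- make_linear_source(5, 2, seed = 6)
  set.seed(6)
  Xt <- rand_matrix(10, 5); Yt <- rand_matrix(10, 2)
  Xnew <- rand_matrix(7, 5)
  tm <- fit_translated(src, Xt, Yt, head_spec = ntk_kernel(1), ridge = 0.1)
  expect_equal(predict(tm, Xnew) - predict(src, Xnew),
               predict(tm$head, Xnew))
})

test_that("linear translation equals gradient descent from source weights", {
  set.seed(7)
  for (rep in 1:3) {
    d <- 8; n_t <- 4
    Ws <- rand_matrix(2, d)
    src <- linear_model(Ws)
    Xt <- rand_matrix(n_t, d); Yt <- rand_matrix(n_t, 2)
    tm <- fit_translated(src, Xt, Yt, head_spec = "linear", ridge = 0)
    W_tr <- Ws + tm$head$weights
    W_gd <- gd_least_squares(t(Xt), t(Yt), Ws, steps = 3e4)
    expect_equal(W_tr, W_gd, tolerance = 1e-6)
  }
})

test_that("translation demands matching label dimensions", {
  src <- make_linear_source(5, 3)
  expect_error(fit_translated(src, rand_matrix(4, 5), rand_matrix(4, 2)),
               "projected or combined")
})

test_that("combined operator reduces to projection without the feature block", {
  src <- make_linear_source(6, 3, seed = 8)
  set.seed(8)
  Xt <- rand_matrix(9, 6); Yt <- rand_matrix(9, 2)
  Xnew <- rand_matrix(5, 6)
  both <- fit_projected_translated(src, Xt, Yt, head_spec = laplace_kernel(5),
                                   ridge = 0.1, blocks = "source")
  proj <- fit_projected(src, Xt, Yt, head_spec = laplace_kernel(5),
                        ridge = 0.1)
  expect_equal(predict(both, Xnew), predict(proj, Xnew), tolerance = 1e-10)
})

test_that("an additive combined head reproduces translation", {
  # restricting the combined head to f([p | x]) = p + g(x) is translation:
  # fitting g on the residuals and adding the source block back must equal
  # fit_translated exactly
  src <- make_linear_source(5, 2, seed = 9)
  set.seed(9)
  Xt <- rand_matrix(8, 5); Yt <- rand_matrix(8, 2)
  Xnew <- rand_matrix(6, 5)
  P <- predict(src, Xt)
  g <- fit_kernel(laplace_kernel(4), Xt, Yt - P, ridge = 0)
  additive <- predict(src, Xnew) + predict(g, Xnew)
  tm <- fit_translated(src, Xt, Yt, head_spec = laplace_kernel(4), ridge = 0)
  expect_equal(additive, predict(tm, Xnew), tolerance = 1e-10)
})

test_that("linear projected transfer equals the theory-module estimator", {
  set.seed(10)
  d <- 10; n_s <- 6; n_t <- 4; c_s <- 3; c_t <- 2
  Xs <- rand_matrix(d, n_s); ws <- rand_matrix(c_s, d)
  Xt <- rand_matrix(d, n_t); wt <- rand_matrix(c_t, d)
  ys <- ws %*% Xs; yt <- wt %*% Xt
  src <- min_norm_linear(Xs, ys)
  tm <- fit_projected(src, t(Xt), t(yt), head_spec = "linear", ridge = 0)
  ws_hat <- ys %*% pinv(Xs)
  w_proj <- (yt %*% pinv(ws_hat %*% Xt)) %*% ws_hat
  Xnew <- rand_matrix(5, d)
  expect_equal(predict(tm, Xnew), Xnew %*% t(w_proj), tolerance = 1e-8)
  # translated analogue
  src2 <- min_norm_linear(Xs, wt %*% Xs)  # c_s = c_t source
  tm2 <- fit_translated(src2, t(Xt), t(yt), head_spec = "linear", ridge = 0)
  ws_hat2 <- (wt %*% Xs) %*% pinv(Xs)
  w_tr <- ws_hat2 + (yt - ws_hat2 %*% Xt) %*% pinv(Xt)
  expect_equal(predict(tm2, Xnew), Xnew %*% t(w_tr), tolerance = 1e-8)
})

test_that("constant source outputs trigger the degeneracy warning", {
  src <- linear_model(matrix(0, 2, 4))
  expect_warning(fit_projected(src, rand_matrix(5, 4), rand_matrix(5, 2),
                               head_spec = "linear"),
                 "constant")
})

test_that("classification accuracy decodes argmax correctly", {
  Y <- one_hot(c(1, 2, 3, 1), 3)
  X <- rand_matrix(4, 2)
  expect_equal(evaluate_classification(perfect_model(Y), X, Y), 1.0)
  expect_equal(evaluate_classification(perfect_model(-one_hot(c(1, 2), 2)),
                                       rand_matrix(2, 2), one_hot(c(1, 2), 2)),
               0.0)
})

test_that("random guessing scores at chance on 3 classes", {
  set.seed(11)
  n <- 1e4
  Y <- one_hot(sample.int(3, n, replace = TRUE), 3)
  P <- rand_matrix(n, 3)
  acc <- mean(max.col(P, ties.method = "first") ==
                max.col(Y, ties.method = "first"))
  model <- perfect_model(P)
  expect_equal(evaluate_classification(model, rand_matrix(n, 2), Y), acc)
  expect_lt(abs(acc - 1 / 3), 0.02)
})

test_that("empty inputs to evaluate_classification are rejected", {
  m <- make_linear_source(3, 2)
  expect_error(evaluate_classification(m, matrix(numeric(0), 0, 3),
                                       matrix(numeric(0), 0, 2)),
               "at least one")
})
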