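test_that("epsilon_similarity measures mass outside the source row space", {
  set.seed(1)
  # full-row-rank source: projector is the identity, epsilon is 0
  ws_full <- rand_matrix(4, 4)
  expect_equal(epsilon_similarity(rand_matrix(2, 4), ws_full), 0,
               tolerance = 1e-20)
  # target factoring through the source: epsilon is 0
  ws <- rand_matrix(3, 8)
  wt <- rand_matrix(2, 3) %*% ws
  expect_equal(epsilon_similarity(wt, ws), 0, tolerance = 1e-16)
  # orthogonal unit rows: all target mass is outside
  expect_equal(epsilon_similarity(matrix(c(0, 1), 1, 2),
                                  matrix(c(1, 0), 1, 2)), 1)
})

test_that("baseline risk law matches its closed form and the MC oracle", {
  expect_equal(risk_baseline(10, 10, 1), 0)
  expect_equal(risk_baseline(10, 5, 1), 0.5)
  expect_error(risk_baseline(10, 11, 1), "n_t <= d")
  w <- gen_weights_with_epsilon(20, 3, 3, 0.2, sqrt(2), seed = 2)
  task <- linear_transfer_task(20, 0, 7, w$omega_s, w$omega_t)
  mc <- mc_risk(task, "baseline", trials = 5000, seed = 3)
  expect_lt(abs(mc$mean - risk_baseline(20, 7, 2)), 3 * mc$se)
})

test_that("projected risk formula reproduces the hand-evaluated case", {
  rb <- risk_projected(d = 4, n_s = 4, n_t = 2, c_s = 2, norm_wt_sq = 1,
                       epsilon = 0)
  expect_equal(rb$C1, 0)
  expect_equal(rb$C2, 1)
  expect_equal(rb$K1, 7 / 9)
  expect_equal(rb$risk, 7 / 18)
  # perfect-transfer limit
  expect_equal(risk_projected(6, 6, 6, 6, 1, 0)$risk, 0)
  expect_error(risk_projected(2, 1, 1, 1, 1), "at least 3")
})

test_that("the literal projected estimator recovers the target map exactly
           when the source is fully determined and n_t >= c_s", {
  # with n_s = d the source fit is exact; with epsilon = 0 and a square or
  # wide head system the projection head interpolates, so the composed
  # estimator equals omega_t on every trial — the closed-form projected
  # risk is not attained by this estimator in this regime
  w <- gen_weights_with_epsilon(8, 3, 3, 0, 1, seed = 4)
  task <- linear_transfer_task(8, 8, 3, w$omega_s, w$omega_t)
  mc <- mc_risk(task, "projected", trials = 200, seed = 5)
  expect_lt(mc$mean, 1e-16)
})

test_that("translated risk formula matches endpoints and the MC oracle", {
  # exact recovery: identical tasks and a fully determined source
  expect_equal(risk_translated(12, 12, 6, 0, 1), 0)
  # no source data: exactly the baseline
  expect_equal(risk_translated(12, 0, 6, 0.5, 1), risk_baseline(12, 6, 1))
  # closed form vs simulation
  set.seed(6)
  wt <- rand_matrix(3, 16); wt <- wt / sqrt(sum(wt^2))
  delta <- rand_matrix(3, 16); delta <- delta * sqrt(0.5 / sum(delta^2))
  ws <- wt + delta
  task <- linear_transfer_task(16, 12, 6, ws, wt)
  mc <- mc_risk(task, "translated", trials = 20000, seed = 7)
  closed <- risk_translated(16, 12, 6, sum((ws - wt)^2), sum(wt^2))
  expect_lt(abs(mc$mean - closed), 3 * mc$se)
})

test_that("translated risk interpolates baseline and exact-source risks", {
  d <- 10; n_t <- 4; nd <- 0.3; nw <- 1.2
  A <- nd / nw
  for (n_s in c(0, 3, 7, 10)) {
    expected <- (n_s / d) * A * risk_baseline(d, n_t, nw) +
      (1 - n_s / d) * risk_baseline(d, n_t, nw)
    expect_equal(risk_translated(d, n_s, n_t, nd, nw), expected)
  }
})

test_that("mc_risk is reproducible and exact in degenerate regimes", {
  w <- gen_weights_with_epsilon(8, 2, 2, 0.1, 1, seed = 8)
  task <- linear_transfer_task(8, 4, 8, w$omega_s, w$omega_t)
  a <- mc_risk(task, "baseline", trials = 50, seed = 9)
  b <- mc_risk(task, "baseline", trials = 50, seed = 9)
  expect_identical(a, b)
  # full interpolation: zero risk on every trial
  expect_lt(a$mean, 1e-20)
  # translated with identical tasks and n_s = d: zero risk
  task2 <- linear_transfer_task(8, 8, 3, w$omega_t, w$omega_t)
  expect_lt(mc_risk(task2, "translated", trials = 50, seed = 10)$mean, 1e-20)
  # source estimator needs matching label dimensions
  task3 <- linear_transfer_task(8, 4, 3, rand_matrix(2, 8), rand_matrix(3, 8))
  expect_error(mc_risk(task3, "translated"), "c_s = c_t")
})

test_that("asymptotic risk reduces to the printed special cases", {
  # S = 1, C = 0: the squared-baseline law
  for (Tv in c(0.1, 0.4, 0.9)) {
    expect_equal(projected_risk_limit(1, Tv, 0, 0, 1), (1 - Tv)^2)
  }
  # no target samples: full risk regardless of epsilon = 0 transfer
  expect_equal(projected_risk_limit(1, 0, 0.5, 0, 1), 1)
  # S = 1 general form
  S <- 1; Tv <- 0.3; C <- 0.4; eps <- 0.2
  expect_equal(projected_risk_limit(S, Tv, C, eps, 1),
               (1 - Tv + Tv * C) * (1 - Tv) + eps * Tv * (2 - Tv))
  expect_error(projected_risk_limit(1.2, 0, 0), "\\[0, 1\\]")
})

test_that("finite-d projected risk converges to the asymptotic form", {
  d <- 2000
  for (Tv in c(0.1, 0.3)) for (C in c(0.05, 0.25)) for (eps in c(0, 0.25)) {
    fin <- risk_projected(d, d, round(Tv * d), round(C * d), 1, eps)$risk
    lim <- projected_risk_limit(1, Tv, C, eps, 1)
    expect_lt(abs(fin - lim) / lim, 0.01)
  }
})

test_that("asymptotic risk is monotone in S when the similarity bound holds", {
  S_grid <- seq(0.1, 1, by = 0.1)
  for (C in c(0, 0.3, 0.8)) {
    vals <- sapply(S_grid, projected_risk_limit, T = 0.2, C = C,
                   epsilon = 0, norm_wt_sq = 1)
    expect_true(all(diff(vals) <= 1e-12))
    expect_true(projected_risk_limit_parts(0.5, 0.2, C, 0, 1)$monotone_in_S)
  }
})

test_that("adding source classes can help or hurt depending on the regime", {
  C_grid <- seq(0.05, 0.95, by = 0.1)
  # 2S - 1 - ST < 0: risk decreases with C
  S <- 0.4; Tv <- 0.2
  expect_true(projected_risk_limit_parts(S, Tv, 0.5)$C_decreases_risk)
  vals <- sapply(C_grid, function(C) projected_risk_limit(S, Tv, C, 0, 1))
  expect_true(all(diff(vals) <= 1e-12))
  # 2S - 1 - ST > 0: a regime where increasing C increases risk exists
  S <- 1; Tv <- 0.2
  expect_false(projected_risk_limit_parts(S, Tv, 0.5)$C_decreases_risk)
  vals <- sapply(C_grid, function(C) projected_risk_limit(S, Tv, C, 0, 1))
  expect_true(any(diff(vals) > 0))
})
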