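test_that("gen_weights_with_epsilon hits its targets to high precision", {
  for (eps in c(0, 0.3, 1)) {
    w <- gen_weights_with_epsilon(16, 4, 3, eps_target = eps, norm_wt = 1,
                                  seed = 1)
    expect_equal(epsilon_similarity(w$omega_t, w$omega_s), eps,
                 tolerance = 1e-8)
    expect_equal(sum(w$omega_t^2), 1, tolerance = 1e-8)
    # orthonormal source rows
    expect_equal(tcrossprod(w$omega_s), diag(4), tolerance = 1e-10)
  }
  # boundary: all mass off the row space
  w <- gen_weights_with_epsilon(10, 3, 2, eps_target = 4, norm_wt = 2,
                                seed = 2)
  expect_equal(epsilon_similarity(w$omega_t, w$omega_s), 4, tolerance = 1e-8)
  expect_error(gen_weights_with_epsilon(10, 3, 2, eps_target = 1.5,
                                        norm_wt = 1), "norm_wt")
  expect_error(gen_weights_with_epsilon(4, 4, 2, 0.1), "smaller")
})

test_that("isotropic linear draws are reproducible with exact labels", {
  w <- gen_weights_with_epsilon(6, 2, 2, 0.1, 1, seed = 3)
  task <- linear_transfer_task(6, 4, 3, w$omega_s, w$omega_t)
  a <- gen_isotropic_linear(task, seed = 4)
  b <- gen_isotropic_linear(task, seed = 4)
  expect_identical(a, b)
  expect_equal(dim(a$X_s), c(6L, 4L))
  expect_identical(a$y_s, w$omega_s %*% a$X_s)
  expect_identical(a$y_t, w$omega_t %*% a$X_t)
})

test_that("isotropic draws have identity covariance at large samples", {
  w <- gen_weights_with_epsilon(4, 2, 2, 0, 1, seed = 5)
  task <- linear_transfer_task(4, 4, 4, w$omega_s, w$omega_t)
  set.seed(6)
  X <- matrix(rnorm(4 * 1e5), 4, 1e5)   # the generator's sampling law
  S <- tcrossprod(X) / 1e5
  expect_lt(max(abs(S - diag(4))), 0.02)
})

test_that("clustered classification degenerates correctly at zero spread", {
  data <- gen_clustered_classification(n_source_classes = 6,
                                       n_target_classes = 3, d = 10,
                                       cluster_sd = 0, n_s = 60, n_t = 30,
                                       n_test = 30, seed = 7)
  # 1-nearest-center classification is perfect on both tasks
  pred_src <- apply(data$source$X, 1, function(x) {
    which.min(colSums((t(data$centers) - x)^2))
  })
  expect_equal(pred_src, data$source$class)
  # target samples sit exactly on centers mapped to their class
  pred_tgt <- apply(data$target$X, 1, function(x) {
    which.min(colSums((t(data$centers) - x)^2))
  })
  map_of <- function(src) which(vapply(data$class_map, function(s) src %in% s,
                                       TRUE))
  expect_equal(vapply(pred_tgt, map_of, 1L), data$target$class)
})

test_that("clustered classification respects shape and balance contracts", {
  data <- gen_clustered_classification(seed = 8)
  expect_equal(dim(data$source$X), c(2000L, 30L))
  expect_equal(colSums(data$source$Y), rep(100, 20), ignore_attr = TRUE)
  expect_equal(colSums(data$target$Y), rep(10, 5), ignore_attr = TRUE)
  expect_equal(rowSums(data$source$Y), rep(1, 2000))
  # unit-sphere centers
  expect_equal(rowSums(data$centers^2), rep(1, 20), tolerance = 1e-12)
  expect_error(gen_clustered_classification(n_s = 5), "at least")
})

test_that("a bijective class map makes the target a relabeled source task", {
  data <- gen_clustered_classification(n_source_classes = 4,
                                       n_target_classes = 4,
                                       class_map = as.list(1:4), d = 6,
                                       cluster_sd = 0, n_s = 20, n_t = 20,
                                       n_test = 4, seed = 9)
  # with zero spread, target samples lie on the centers of their own class
  expect_equal(data$target$X, data$centers[data$target$class, ],
               tolerance = 1e-12)
})

test_that("drug screen generator obeys its structural contracts", {
  sim <- drug_screen_sim(n_cell_lines = 6, n_drugs = 20, n_genes = 12,
                         fp_bits = 16, rank = 3, noise_sd = 0, seed = 10)
  screen <- gen_drug_screen(sim, held_out_cells = 2, held_out_drugs = 5)
  # reproducibility
  screen2 <- gen_drug_screen(sim, held_out_cells = 2, held_out_drugs = 5)
  expect_identical(screen, screen2)
  # source covers 4 cells x 15 seen drugs
  expect_equal(nrow(screen$source$X), 60L)
  expect_length(screen$targets, 2L)
  expect_equal(nrow(screen$targets[[1]]$seen$X), 15L)
  expect_equal(nrow(screen$targets[[1]]$unseen$X), 5L)
  # fingerprints are a function of drug identity, shared across cells
  fp_cols <- 13:28
  src <- screen$source
  for (drug in unique(src$drug)[1:5]) {
    rows <- which(src$drug == drug)
    expect_true(all(apply(src$X[rows, fp_cols, drop = FALSE], 2,
                          function(col) length(unique(col)) == 1L)))
  }
  # the feature row starts with the cell's control expression
  expect_equal(src$X[1, 1:12], screen$controls[src$cell[1], ],
               ignore_attr = TRUE)
})

test_that("noiseless rank-1 screens give rank-1 expression differences", {
  sim <- drug_screen_sim(n_cell_lines = 4, n_drugs = 10, n_genes = 8,
                         fp_bits = 8, rank = 1, noise_sd = 0, seed = 11)
  screen <- gen_drug_screen(sim, held_out_cells = 1, held_out_drugs = 2)
  src <- screen$source
  rows <- which(src$cell == src$cell[1])
  D <- sweep(src$Y[rows, ], 2, src$Y[rows[1], ])
  sv <- svd(D)$d
  expect_lt(sv[2] / sv[1], 1e-10)
})

test_that("held-out counts must leave data for the source task", {
  sim <- drug_screen_sim(n_cell_lines = 3, n_drugs = 5)
  expect_error(gen_drug_screen(sim, held_out_cells = 3, held_out_drugs = 1),
               "below the totals")
  expect_error(drug_screen_sim(rank = 100), "rank")
})
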