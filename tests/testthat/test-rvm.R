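test_that("kernel matrices satisfy the basic kernel identities", {
  X <- matrix(stats::rnorm(12), 4, 3)
  K <- kernel_matrix(X, X, list(type = "rbf", gamma = 1.3))
  expect_equal(diag(K[, 1:4]), rep(1, 4))              # k(x, x) = 1
  expect_equal(K[, 1:4], t(K[, 1:4]), tolerance = 1e-12)
  expect_equal(K[, 5], rep(1, 4))                      # bias column
  U <- rbind(c(1, 0), c(0, 1))
  KL <- kernel_matrix(U, U, list(type = "linear"))
  expect_identical(KL[1, 2], 0)
  expect_error(kernel_matrix(X, X, list(type = "rbf", gamma = -1)), "positive")
})

test_that("predicted probabilities follow the sigmoid contracts", {
  blobs <- make_blobs(30L)
  model <- train_binary(blobs$X, blobs$t)
  # zero weights give exactly 0.5
  m0 <- model
  m0$weights <- rep(0, length(model$weights))
  expect_equal(predict_proba(m0, blobs$X[1:5, ]), rep(0.5, 5))
  # probabilities in (0, 1); negating w complements them
  p <- predict_proba(model, blobs$X)
  expect_true(all(p > 0 & p < 1))
  mneg <- model
  mneg$weights <- -model$weights
  expect_equal(predict_proba(mneg, blobs$X), 1 - p, tolerance = 1e-12)
})

test_that("the Newton inner loop reaches a stationary point", {
  blobs <- make_blobs(40L)
  Phi <- kernel_matrix(blobs$X, blobs$X, list(type = "rbf", gamma = 2))
  alpha <- rep(1, ncol(Phi))
  fit <- newton_weight_update(rep(0, ncol(Phi)), alpha, Phi, blobs$t)
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-6)
  # symmetric balanced data keeps the bias at zero
  Xs <- rbind(c(-1, 0), c(1, 0))
  Phis <- kernel_matrix(Xs, Xs, list(type = "linear"))
  fs <- newton_weight_update(c(0, 0, 0), rep(1, 3), Phis, c(0, 1))
  expect_lt(abs(fs$w[3]), 1e-9)
})

test_that("Newton matches a brute-force optimizer on a tiny problem", {
  # 2 points, 2 basis functions (one kernel column + bias)
  Phi <- cbind(c(0.2, 0.9), 1)
  t <- c(0, 1)
  alpha <- c(0.7, 1.3)
  fit <- newton_weight_update(c(0, 0), alpha, Phi, t)
  obj <- function(w) {
    a <- drop(Phi %*% w)
    sum(ifelse(t == 1, log1p(exp(-a)), log1p(exp(a)))) + 0.5 * sum(alpha * w^2)
  }
  ref <- stats::optim(c(0, 0), obj, method = "BFGS",
                      control = list(reltol = 1e-14))
  expect_equal(fit$w, ref$par, tolerance = 1e-6)
})

test_that("the MacKay update prunes fully-constrained weights", {
  # gamma_i = 0 (Sigma_ii = 1/alpha_i) forces alpha to the prune threshold
  a <- update_hyperparameters(w = c(0.5), alpha = c(2),
                              Sigma = matrix(1 / 2), prune_threshold = 1e12)
  expect_identical(a, 1e12)
  expect_identical(update_hyperparameters(0, 1, matrix(0.1)), 1e12)
  # a well-determined weight gets alpha = gamma / w^2
  a2 <- update_hyperparameters(w = 2, alpha = 1, Sigma = matrix(0.25))
  expect_equal(a2, 0.75 / 4)
})

test_that("the alpha fixed point matches the exact marginal likelihood (quadrature)", {
  # single-basis toy: maximize p(t | alpha) = int p(t | w) N(w | 0, 1/alpha) dw
  phi <- c(1.2, -0.8, 1.5, -1.1)
  t <- c(1, 0, 1, 0)
  marginal <- function(alpha) {
    stats::integrate(function(w) {
      vapply(w, function(wi) {
        a <- phi * wi
        lik <- prod(ifelse(t == 1, 1 / (1 + exp(-a)), 1 / (1 + exp(a))))
        lik * stats::dnorm(wi, 0, 1 / sqrt(alpha))
      }, numeric(1))
    }, -20, 20)$value
  }
  best_alpha <- stats::optimize(function(a) -log(marginal(a)),
                                c(0.01, 50))$minimum
  # run the alternating scheme on the same single-basis design
  Phi <- matrix(phi, ncol = 1)
  alpha <- 1
  w <- 0
  for (i in 1:200) {
    fit <- newton_weight_update(w, alpha, Phi, t)
    w <- fit$w
    alpha_new <- update_hyperparameters(w, alpha, fit$Sigma)
    if (abs(alpha_new - alpha) < 1e-10) break
    alpha <- alpha_new
  }
  # Laplace-approximate evidence maximization tracks the exact optimum
  expect_equal(alpha, best_alpha, tolerance = 0.15)
})

test_that("training on separable blobs is accurate, sparse and deterministic", {
  blobs <- make_blobs(100L)
  m1 <- train_binary(blobs$X, blobs$t)
  p <- predict_proba(m1, blobs$X)
  expect_gte(mean((p > 0.5) == blobs$t), 0.99)
  expect_lte(nrow(m1$relevance_vectors), 0.10 * nrow(blobs$X))
  expect_lt(nrow(m1$relevance_vectors), nrow(blobs$X))
  expect_lt(m1$grad_norm, 1e-6)
  m2 <- train_binary(blobs$X, blobs$t)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$rv_index, m2$rv_index)
  expect_error(train_binary(blobs$X, rep(1, nrow(blobs$X))), "both classes")
})

test_that("multiclass classification recovers five disjoint blobs", {
  withr::with_seed(21L, {
    centers <- matrix(c(0, 0, 6, 0, 0, 6, 6, 6, 3, 12), 5, 2, byrow = TRUE)
    X <- do.call(rbind, lapply(1:5, function(k)
      sweep(matrix(stats::rnorm(2 * 40, sd = 0.5), 40, 2), 2, centers[k, ], `+`)))
  })
  labels <- rep(TISSUE_CLASSES, each = 40)
  idx_tr <- rep(c(TRUE, TRUE, TRUE, FALSE), 50)
  model <- train_multiclass(X[idx_tr, ], labels[idx_tr])
  pred <- rvm_classify(model, X[!idx_tr, ])
  expect_gte(mean(pred$class == labels[!idx_tr]), 0.95)
  expect_true(all(pred$probs > 0 & pred$probs < 1))
  # invariance to submodel training order
  model_rev <- train_multiclass(X[idx_tr, ], labels[idx_tr],
                                classes = rev(TISSUE_CLASSES))
  pred_rev <- rvm_classify(model_rev, X[!idx_tr, ])
  expect_identical(pred$class, pred_rev$class)
})

test_that("predicted probabilities are roughly calibrated on symmetric data", {
  blobs <- make_blobs(100L, sep = 2, seed = 9L)
  m <- train_binary(blobs$X, blobs$t)
  p <- predict_proba(m, blobs$X)
  # mean class-membership probability tracks the empirical hit rate per class
  expect_lt(abs(mean(p[blobs$t == 1]) - mean(p[blobs$t == 1] > 0.5)), 0.1)
  expect_lt(abs(mean(1 - p[blobs$t == 0]) - mean(p[blobs$t == 0] <= 0.5)), 0.1)
})

test_that("models survive JSON serialization", {
  blobs <- make_blobs(40L)
  m <- train_binary(blobs$X, blobs$t)
  path <- withr::local_tempfile(fileext = ".json")
  write_rvm_model(m, path)
  back <- read_rvm_model(path)
  expect_equal(predict_proba(back, blobs$X), predict_proba(m, blobs$X),
               tolerance = 1e-9)
  labels <- ifelse(blobs$t == 1, "adipose", "dense_collagen")
  mm <- train_multiclass(blobs$X, labels)
  write_rvm_model(mm, path)
  backm <- read_rvm_model(path)
  expect_identical(rvm_classify(backm, blobs$X)$class,
                   rvm_classify(mm, blobs$X)$class)
})
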