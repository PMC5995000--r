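# Sparse Bayesian (relevance vector machine) classification.
#
# Binary model: p(c = 1 | x) = sigmoid(sum_i w_i * phi_i(x)) with a
# zero-mean Gaussian prior N(w_i | 0, 1/alpha_i) on every weight.  Training
# alternates (a) a Newton/IRLS inner loop to the posterior mode of the
# penalized Bernoulli log-likelihood and (b) MacKay evidence updates
# alpha_i <- gamma_i / w_i^2, gamma_i = 1 - alpha_i * Sigma_ii, pruning
# basis functions whose alpha diverges.  Most weights are driven to zero;
# the training points behind the surviving basis functions are the
# relevance vectors.

sigmoid <- function(a) 1 / (1 + exp(-a))

#' Kernel design matrix
#'
#' `Phi[n, i] = k(X_n, Y_i)` with a constant bias column appended. Kernels:
#' `rbf` `exp(-||x - y||^2 / (2 * gamma^2))` and `linear` `<x, y>`.
#'
#' @param X Matrix of input vectors (rows).
#' @param Y Matrix of basis/relevance vectors (rows).
#' @param kernel List with `type` ("rbf" or "linear") and, for rbf, width
#'   `gamma` (> 0).
#' @return `nrow(X)` x `(nrow(Y) + 1)` matrix; the last column is the bias.
#' @export
kernel_matrix <- function(X, Y, kernel = list(type = "rbf", gamma = 1)) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(ncol(X) == ncol(Y))
  K <- switch(kernel$type,
    rbf = {
      if (!isTRUE(kernel$gamma > 0)) stop("rbf gamma must be positive")
      d2 <- outer(rowSums(X^2), rep(1, nrow(Y))) +
            outer(rep(1, nrow(X)), rowSums(Y^2)) - 2 * tcrossprod(X, Y)
      exp(-pmax(d2, 0) / (2 * kernel$gamma^2))
    },
    linear = tcrossprod(X, Y),
    stop("unknown kernel type: ", kernel$type))
  cbind(K, 1)
}

# median pairwise distance heuristic for the rbf width
median_heuristic <- function(X) {
  n <- nrow(X)
  idx <- if (n > 200) sample.int(n, 200) else seq_len(n)
  d <- stats::dist(X[idx, , drop = FALSE])
  g <- stats::median(d)
  if (!isTRUE(g > 0)) 1 else g
}

# penalized negative log-likelihood (up to const)
rvm_objective <- function(w, alpha, Phi, t) {
  a <- drop(Phi %*% w)
  # numerically safe -log lik of Bernoulli with logits a
  nll <- sum(ifelse(t == 1, log1p(exp(-a)), log1p(exp(a))))
  nll + 0.5 * sum(alpha * w^2)
}

#' One Newton (IRLS) solve for the posterior mode of the weights
#'
#' Minimizes the penalized negative Bernoulli log-likelihood
#' `E(w) = -log p(t | w) + w' A w / 2`, `A = diag(alpha)`, by damped Newton
#' steps `w <- w - H^{-1} grad` with `grad = A w - Phi'(t - sigma(Phi w))`
#' and `H = Phi' B Phi + A`, `B = diag(sigma_n (1 - sigma_n))`.
#'
#' @param w Starting weights.
#' @param alpha Prior precisions (> 0).
#' @param Phi Design matrix.
#' @param t 0/1 targets.
#' @param tol Convergence threshold on the gradient norm.
#' @param max_iter Maximum Newton iterations.
#' @return List `w`, `Sigma` (inverse Hessian at the mode), `grad_norm`,
#'   `converged`, `n_iter`.
#' @export
newton_weight_update <- function(w, alpha, Phi, t, tol = 1e-6, max_iter = 100L) {
  A <- alpha
  for (it in seq_len(max_iter)) {
    a <- drop(Phi %*% w)
    s <- sigmoid(a)
    grad <- A * w - drop(crossprod(Phi, t - s))
    if (!all(is.finite(grad))) stop("non-finite gradient at Newton iteration ", it)
    gnorm <- sqrt(sum(grad^2))
    if (gnorm < tol) {
      H <- crossprod(Phi * (s * (1 - s)), Phi) + diag(A, length(A))
      return(list(w = w, Sigma = chol2inv(chol(H)), grad_norm = gnorm,
                  converged = TRUE, n_iter = it - 1L))
    }
    B <- s * (1 - s)
    H <- crossprod(Phi * B, Phi) + diag(A, length(A))
    step <- drop(chol2inv(chol(H)) %*% grad)
    # damped: halve until the penalized objective does not increase
    obj0 <- rvm_objective(w, A, Phi, t)
    eta <- 1
    repeat {
      w_new <- w - eta * step
      if (rvm_objective(w_new, A, Phi, t) <= obj0 + 1e-12 || eta < 1e-8) break
      eta <- eta / 2
    }
    w <- w_new
  }
  a <- drop(Phi %*% w); s <- sigmoid(a)
  H <- crossprod(Phi * (s * (1 - s)), Phi) + diag(A, length(A))
  grad <- A * w - drop(crossprod(Phi, t - s))
  list(w = w, Sigma = chol2inv(chol(H)), grad_norm = sqrt(sum(grad^2)),
       converged = FALSE, n_iter = max_iter)
}

#' MacKay evidence update of the hyperparameters
#'
#' `alpha_i <- gamma_i / w_i^2` with `gamma_i = 1 - alpha_i * Sigma_ii`,
#' the fixed-point update that maximizes the marginal likelihood in the
#' Gaussian (Laplace) approximation. A weight pinned at zero (or a
#' nonpositive gamma) sends its alpha to the pruning threshold.
#'
#' @param w Weights at the posterior mode.
#' @param alpha Current precisions.
#' @param Sigma Posterior covariance (inverse Hessian) at the mode.
#' @param prune_threshold Alpha above which a basis function is pruned.
#' @return Numeric vector of updated alphas (capped at `prune_threshold`).
#' @export
update_hyperparameters <- function(w, alpha, Sigma, prune_threshold = 1e12) {
  gamma_i <- 1 - alpha * diag(Sigma)
  out <- numeric(length(w))
  for (i in seq_along(w)) {
    out[i] <- if (w[i] == 0 || gamma_i[i] <= 0) prune_threshold
              else min(gamma_i[i] / w[i]^2, prune_threshold)
  }
  out
}

#' Train a binary relevance vector machine
#'
#' Features are standardized (training statistics only); the design matrix
#' has one kernel basis per training point plus a bias. Outer iterations
#' alternate the Newton mode-finder and the MacKay alpha update, pruning
#' basis functions whose alpha reaches the threshold (the bias is never
#' pruned), until the weight change falls below `tol`.
#'
#' @param X Feature matrix (rows = samples).
#' @param t 0/1 vector (or logical) of class membership.
#' @param kernel Kernel spec as in [kernel_matrix()]; `NULL` = rbf with the
#'   median-pairwise-distance width.
#' @param max_outer,tol Outer-loop budget and `||delta w||` tolerance.
#' @param prune_threshold Alpha pruning threshold.
#' @return An `rvm_binary` model: `relevance_vectors` (standardized),
#'   `weights`, `alphas`, `kernel`, `center`/`scale`, `rv_index` (indices
#'   into the training set), `bias`, `converged`, `n_iterations`.
#' @export
train_binary <- function(X, t, kernel = NULL, max_outer = 500L, tol = 1e-4,
                         prune_threshold = 1e12) {
  X <- as.matrix(X); t <- as.numeric(t)
  stopifnot(nrow(X) == length(t), all(t %in% c(0, 1)))
  if (length(unique(t)) < 2) stop("both classes must be present for training")
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd); scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  if (is.null(kernel)) kernel <- list(type = "rbf", gamma = median_heuristic(Xs))

  N <- nrow(Xs)
  Phi_full <- kernel_matrix(Xs, Xs, kernel)      # N x (N + 1); last = bias
  active <- seq_len(N + 1L)                      # index N + 1 is the bias
  alpha <- rep(1, N + 1L)
  w <- rep(0, N + 1L)
  converged <- FALSE
  iters <- 0L
  for (outer in seq_len(max_outer)) {
    iters <- outer
    nw <- newton_weight_update(w[active], alpha[active],
                               Phi_full[, active, drop = FALSE], t)
    w_old_active <- w[active]
    w[active] <- nw$w
    alpha[active] <- update_hyperparameters(nw$w, alpha[active], nw$Sigma,
                                            prune_threshold)
    drop_idx <- active[alpha[active] >= prune_threshold & active != (N + 1L)]
    delta <- sqrt(sum((w[active] - w_old_active)^2))
    if (length(drop_idx)) {
      w[drop_idx] <- 0
      active <- setdiff(active, drop_idx)
    }
    if (delta < tol && !length(drop_idx)) { converged <- TRUE; break }
  }
  rv_index <- setdiff(active, N + 1L)
  structure(list(
    relevance_vectors = Xs[rv_index, , drop = FALSE],
    rv_index = rv_index,
    weights = w[active],                        # rv weights then bias
    alphas = alpha[active],
    kernel = kernel, center = center, scale = scale,
    converged = converged, n_iterations = iters,
    grad_norm = nw$grad_norm),
    class = "rvm_binary")
}

#' Predict class-1 probability from a binary RVM
#'
#' `sigmoid(K(x, relevance vectors) w + bias weight)`.
#'
#' @param model An `rvm_binary`.
#' @param X Feature matrix (rows = samples) on the original scale.
#' @return Vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$center)) stop("feature dimension mismatch")
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  nrv <- nrow(model$relevance_vectors)
  if (nrv > 0) {
    Phi <- kernel_matrix(Xs, model$relevance_vectors, model$kernel)
  } else {
    Phi <- matrix(1, nrow(Xs), 1)
  }
  sigmoid(drop(Phi %*% model$weights))
}

#' Train a one-vs-rest multiclass RVM
#'
#' One binary submodel per class present in the labels; prediction takes
#' the class with the highest submodel probability (ties broken in
#' alphabetical class order).
#'
#' @param X Feature matrix.
#' @param labels Character vector of class labels.
#' @param classes Class vocabulary (default [TISSUE_CLASSES]); classes
#'   absent from `labels` are skipped with a warning.
#' @param ... Passed to [train_binary()].
#' @return An `rvm_multiclass`: named list `models`, `classes`.
#' @export
train_multiclass <- function(X, labels, classes = TISSUE_CLASSES, ...) {
  present <- classes[classes %in% unique(labels)]
  if (length(present) < 2) stop("need at least 2 classes present")
  if (length(present) < length(classes))
    warning("classes absent from training data: ",
            paste(setdiff(classes, present), collapse = ", "))
  models <- lapply(present, function(cl) train_binary(X, labels == cl, ...))
  names(models) <- present
  structure(list(models = models, classes = present), class = "rvm_multiclass")
}

#' Classify samples with a multiclass RVM
#'
#' @param model An `rvm_multiclass`.
#' @param X Feature matrix (rows = samples).
#' @return List: `class` (character vector) and `probs` (samples x classes
#'   matrix of one-vs-rest probabilities).
#' @export
rvm_classify <- function(model, X) {
  X <- as.matrix(X)
  probs <- vapply(model$models, function(m) predict_proba(m, X),
                  numeric(nrow(X)))
  probs <- matrix(probs, nrow = nrow(X),
                  dimnames = list(NULL, model$classes))
  ord <- order(model$classes)  # alphabetical tie-break
  cls <- apply(probs[, ord, drop = FALSE], 1, function(p)
    model$classes[ord][which.max(p)])
  list(class = cls, probs = probs)
}

#' Serialize / restore an RVM model as JSON
#'
#' @param model An `rvm_binary` or `rvm_multiclass`.
#' @param path JSON file path.
#' @return `read_rvm_model()` returns the model object.
#' @export
write_rvm_model <- function(model, path) {
  ser_bin <- function(m) list(
    relevance_vectors = m$relevance_vectors, rv_index = m$rv_index,
    weights = m$weights, alphas = m$alphas, kernel = m$kernel,
    center = m$center, scale = m$scale, converged = m$converged,
    n_iterations = m$n_iterations)
  obj <- if (inherits(model, "rvm_binary")) {
    list(type = "binary", model = ser_bin(model))
  } else {
    list(type = "multiclass", classes = model$classes,
         models = lapply(model$models, ser_bin))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rvm_model
#' @export
read_rvm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_bin <- function(m) {
    m$relevance_vectors <- as.matrix(m$relevance_vectors)
    if (nrow(m$relevance_vectors) == 0)
      m$relevance_vectors <- matrix(0, 0, length(m$center))
    m$kernel <- as.list(m$kernel)
    structure(m, class = "rvm_binary")
  }
  if (identical(obj$type, "binary")) return(de_bin(obj$model))
  models <- lapply(obj$models, de_bin)
  structure(list(models = models, classes = obj$classes),
            class = "rvm_multiclass")
}
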