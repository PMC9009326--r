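# Classifier registry. Every spec is deterministic given (data, hyperparameters,
# seed) and emits scores in [0, 1]. The registry replaces the original study's
# sweep over 45 WEKA classifiers with a representative set; the harness
# (cross-validation, selection, training, thresholding) is the contract.

#' Construct a classifier spec
#'
#' @param name registry name.
#' @param fit function(X, y, seed) -> model internals (X a numeric matrix,
#'   y a 0/1 vector).
#' @param predict function(fit, X) -> scores in `[0, 1]`.
#' @param hyper named list of hyperparameters (recorded, passed via closure).
#' @param scale_equivariant whether decisions are invariant under a common
#'   positive rescaling of all features.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(name, fit, predict, hyper = list(),
                            scale_equivariant = FALSE) {
  structure(list(name = name, fit = fit, predict = predict, hyper = hyper,
                 scale_equivariant = scale_equivariant),
            class = "classifier_spec")
}

## ---- ridge-regularized logistic regression (IRLS) -------------------------

# Penalizes every coefficient (including the intercept) with lambda/2 * b^2,
# which keeps pure-label fits finite. Deterministic; no RNG.
ridge_logistic_fit <- function(X, y, lambda = 1e-2, maxit = 100L, tol = 1e-10) {
  X1 <- cbind(intercept = 1, X)
  p <- ncol(X1)
  beta <- rep(0, p)
  obj <- function(b) {
    eta <- drop(X1 %*% b)
    # -loglik + penalty, numerically stable log(1+exp)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + lambda / 2 * sum(b^2)
  }
  f_old <- obj(beta)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X1, mu - y)) + lambda * beta
    H <- crossprod(X1 * w, X1) + diag(lambda, p)
    step <- solve(H, grad)
    # step-halving line search on the penalized deviance
    alpha <- 1
    repeat {
      beta_new <- beta - alpha * step
      f_new <- obj(beta_new)
      if (f_new <= f_old + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    f_old <- f_new
    if (delta < tol) break
  }
  list(beta = beta, lambda = lambda, feature_names = colnames(X))
}

ridge_logistic_predict <- function(fit, X) {
  stats::plogis(drop(cbind(1, X) %*% fit$beta))
}

## ---- information-gain binary tree -----------------------------------------

binary_entropy <- function(p) {
  ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))
}

# Best single split over all features; candidate thresholds are midpoints
# between consecutive distinct sorted values. Ties broken by lowest feature
# index, then lowest threshold (deterministic).
best_split <- function(X, y, min_leaf) {
  n <- length(y)
  h_parent <- binary_entropy(mean(y))
  best <- NULL
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j], method = "radix")
    xs <- X[ord, j]
    ys <- y[ord]
    cum_pos <- cumsum(ys)
    cuts <- which(diff(xs) > 0)              # split after position i
    cuts <- cuts[cuts >= min_leaf & (n - cuts) >= min_leaf]
    if (!length(cuts)) next
    n_l <- cuts
    n_r <- n - cuts
    p_l <- cum_pos[cuts] / n_l
    p_r <- (cum_pos[n] - cum_pos[cuts]) / n_r
    gain <- h_parent - (n_l * binary_entropy(p_l) + n_r * binary_entropy(p_r)) / n
    k <- which.max(gain)
    if (gain[k] > 1e-12 && (is.null(best) || gain[k] > best$gain + 1e-15)) {
      best <- list(feature = j, threshold = (xs[cuts[k]] + xs[cuts[k] + 1L]) / 2,
                   gain = gain[k])
    }
  }
  best
}

grow_tree <- function(X, y, depth, max_depth, min_leaf, leaf_fit) {
  pure <- length(unique(y)) == 1L
  if (depth >= max_depth || pure || length(y) < 2L * min_leaf) {
    return(list(type = "leaf", n = length(y), model = leaf_fit(X, y)))
  }
  sp <- best_split(X, y, min_leaf)
  if (is.null(sp)) {
    return(list(type = "leaf", n = length(y), model = leaf_fit(X, y)))
  }
  left <- X[, sp$feature] <= sp$threshold
  list(type = "split", feature = sp$feature, threshold = sp$threshold,
       left = grow_tree(X[left, , drop = FALSE], y[left], depth + 1L,
                        max_depth, min_leaf, leaf_fit),
       right = grow_tree(X[!left, , drop = FALSE], y[!left], depth + 1L,
                         max_depth, min_leaf, leaf_fit))
}

tree_predict <- function(node, X, leaf_predict) {
  n <- nrow(X)
  out <- numeric(n)
  recurse <- function(node, idx) {
    if (!length(idx)) return()
    if (node$type == "leaf") {
      out[idx] <<- leaf_predict(node$model, X[idx, , drop = FALSE])
    } else {
      left <- X[idx, node$feature] <= node$threshold
      recurse(node$left, idx[left])
      recurse(node$right, idx[!left])
    }
  }
  recurse(node, seq_len(n))
  out
}

#' Fit a logistic model tree
#'
#' A binary decision tree over the feature vector, with splits chosen by
#' information gain, and a ridge-regularized logistic regression (over all
#' features) fitted at each leaf; an instance is scored by its leaf's
#' logistic output. `max_depth = 0` degenerates to plain logistic regression.
#' Pure leaves yield scores strictly inside (0, 1) because the ridge penalty
#' keeps the leaf fit finite.
#'
#' @param X numeric matrix of features.
#' @param y 0/1 labels.
#' @param max_depth maximum split depth (0 = single leaf).
#' @param min_leaf minimum instances per child; must be >= 2.
#' @param lambda ridge penalty of the leaf fits.
#' @return an `lmt_fit` list usable with [lmt_predict()].
#' @export
lmt_fit <- function(X, y, max_depth = 3L, min_leaf = 15L, lambda = 1e-2) {
  if (min_leaf < 2) stop("min_leaf must be >= 2")
  node <- grow_tree(as.matrix(X), y, 0L, max_depth, min_leaf,
                    leaf_fit = function(Xl, yl) ridge_logistic_fit(Xl, yl, lambda))
  structure(list(tree = node, max_depth = max_depth, min_leaf = min_leaf,
                 lambda = lambda), class = "lmt_fit")
}

#' @rdname lmt_fit
#' @param fit an `lmt_fit`.
#' @export
lmt_predict <- function(fit, X) {
  tree_predict(fit$tree, as.matrix(X), ridge_logistic_predict)
}

## ---- baselines ------------------------------------------------------------

dtree_fit <- function(X, y, max_depth = 5L, min_leaf = 5L) {
  # Laplace-smoothed leaf frequency keeps scores in (0, 1)
  grow_tree(as.matrix(X), y, 0L, max_depth, min_leaf,
            leaf_fit = function(Xl, yl) (sum(yl) + 1) / (length(yl) + 2))
}

dtree_predict <- function(fit, X) {
  tree_predict(fit, as.matrix(X), function(model, Xl) rep(model, nrow(Xl)))
}

gaussian_nb_fit <- function(X, y) {
  X <- as.matrix(X)
  fit_class <- function(cls) {
    Xi <- X[y == cls, , drop = FALSE]
    list(mean = colMeans(Xi), sd = pmax(apply(Xi, 2, stats::sd), 1e-6),
         prior = nrow(Xi) / nrow(X))
  }
  list(pos = fit_class(1), neg = fit_class(0))
}

gaussian_nb_predict <- function(fit, X) {
  X <- as.matrix(X)
  loglik <- function(cls) {
    ll <- log(cls$prior)
    for (j in seq_len(ncol(X))) {
      ll <- ll + stats::dnorm(X[, j], cls$mean[j], cls$sd[j], log = TRUE)
    }
    ll
  }
  lp <- loglik(fit$pos)
  ln <- loglik(fit$neg)
  1 / (1 + exp(pmin(ln - lp, 700)))
}

knn_fit <- function(X, y, k = 5L) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), y = y,
       center = ctr, scale = scl, k = min(k, nrow(X)))
}

knn_predict <- function(fit, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, fit$center), 2, fit$scale, "/")
  apply(Xs, 1L, function(row) {
    d2 <- colSums((t(fit$X) - row)^2)
    nn <- order(d2, method = "radix")[seq_len(fit$k)]
    mean(fit$y[nn])
  })
}

## ---- registry -------------------------------------------------------------

#' The default classifier registry
#'
#' Ships logistic regression (ridge, IRLS), a logistic model tree, a decision
#' tree, Gaussian naive Bayes and k-nearest-neighbors. Registry order is the
#' deterministic tie-break order in [select_best()].
#'
#' @param lmt_max_depth,lmt_min_leaf,lambda,tree_max_depth,tree_min_leaf,knn_k
#'   hyperparameters of the registered specs.
#' @return named list of [classifier_spec()] objects.
#' @export
default_registry <- function(lmt_max_depth = 3L, lmt_min_leaf = 15L,
                             lambda = 1e-2, tree_max_depth = 5L,
                             tree_min_leaf = 5L, knn_k = 5L) {
  specs <- list(
    classifier_spec("logistic",
      fit = function(X, y, seed) ridge_logistic_fit(X, y, lambda),
      predict = ridge_logistic_predict,
      hyper = list(lambda = lambda)),
    classifier_spec("lmt",
      fit = function(X, y, seed) lmt_fit(X, y, lmt_max_depth, lmt_min_leaf, lambda),
      predict = lmt_predict,
      hyper = list(max_depth = lmt_max_depth, min_leaf = lmt_min_leaf,
                   lambda = lambda)),
    classifier_spec("decision_tree",
      fit = function(X, y, seed) dtree_fit(X, y, tree_max_depth, tree_min_leaf),
      predict = dtree_predict,
      hyper = list(max_depth = tree_max_depth, min_leaf = tree_min_leaf),
      scale_equivariant = TRUE),
    classifier_spec("naive_bayes",
      fit = function(X, y, seed) gaussian_nb_fit(X, y),
      predict = gaussian_nb_predict),
    classifier_spec("knn",
      fit = function(X, y, seed) knn_fit(X, y, knn_k),
      predict = knn_predict,
      hyper = list(k = knn_k),
      scale_equivariant = TRUE)
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}
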