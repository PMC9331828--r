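#' Classification learners for the screening benchmark
#'
#' Four model families over the per-patient feature matrix, implemented in
#' the package so that tree internals (split features, thresholds, depths,
#' leaf values) stay inspectable for importance ranking and decision-cut
#' extraction:
#'
#' * [fit_gradient_boost()]: gradient boosted regression trees under
#'   logistic loss, second-order (Newton) leaf weights, sparsity-aware
#'   splits (missing values learn a default direction per node);
#' * [fit_adaboost()]: discrete adaptive boosting of shallow trees;
#' * [fit_kernel_machine()]: regularized least-squares kernel classifier
#'   (linear, polynomial and radial kernels; best kernel kept by internal
#'   validation);
#' * [fit_relu_net()]: fully connected network with rectified-linear
#'   activations trained by adaptive-momentum stochastic gradient descent
#'   (Adam) on the cross-entropy loss.
#'
#' Trees consume raw feature values so that extracted cuts stay in
#' canonical laboratory units; the kernel machine and the network use
#' median imputation, missingness indicators and train-half z-scoring.
#'
#' @name ml_learners
NULL

# ---------------------------------------------------------------------------
# Regression tree with Newton-style gains (shared by both boosters)
#
# Nodes are rows of a data.frame: node id, feature (name, NA for leaves),
# threshold, default_left (where missing values go), left/right child ids,
# value (leaf weight), depth, cover (sum of hessians).
# Split convention: x <= threshold goes left, x > threshold goes right.

grow_tree <- function(X, g, h, max_depth = 3L, min_child_weight = 1e-3,
                      lambda = 1, min_gain = 1e-8,
                      feature_subset = seq_len(ncol(X))) {
  nodes <- list()
  new_id <- function() length(nodes) + 1L

  leaf_value <- function(gs, hs) -gs / (hs + lambda)
  score <- function(gs, hs) gs * gs / (hs + lambda)

  build <- function(idx, depth) {
    id <- new_id()
    nodes[[id]] <<- list(node = id, feature = NA_character_,
                         threshold = NA_real_, default_left = NA,
                         left = NA_integer_, right = NA_integer_,
                         value = leaf_value(sum(g[idx]), sum(h[idx])),
                         depth = depth, cover = sum(h[idx]))
    if (depth >= max_depth || length(idx) < 2L) return(id)

    G <- sum(g[idx]); H <- sum(h[idx])
    base <- score(G, H)
    best <- list(gain = min_gain)
    for (j in feature_subset) {
      x <- X[idx, j]
      obs <- which(!is.na(x))
      if (length(obs) < 2L) next
      xo <- x[obs]
      ord <- order(xo, method = "radix")
      xs <- xo[ord]
      gs <- cumsum(g[idx][obs][ord])
      hs <- cumsum(h[idx][obs][ord])
      Gm <- G - gs[length(gs)]          # gradient mass of missing rows
      Hm <- H - hs[length(hs)]
      # candidate split after each position where the value changes
      cut_at <- which(diff(xs) > 0)
      if (!length(cut_at)) next
      GL <- gs[cut_at]; HL <- hs[cut_at]
      for (miss_left in c(TRUE, FALSE)) {
        gl <- GL + if (miss_left) Gm else 0
        hl <- HL + if (miss_left) Hm else 0
        gr <- G - gl; hr <- H - hl
        ok <- hl >= min_child_weight & hr >= min_child_weight
        if (!any(ok)) next
        gains <- ifelse(ok, score(gl, hl) + score(gr, hr) - base, -Inf)
        b <- which.max(gains)
        if (gains[b] > best$gain) {
          best <- list(gain = gains[b], feature = j,
                       threshold = (xs[cut_at[b]] + xs[cut_at[b] + 1L]) / 2,
                       default_left = miss_left)
        }
      }
    }
    if (is.null(best$feature)) return(id)

    x <- X[idx, best$feature]
    go_left <- ifelse(is.na(x), best$default_left, x <= best$threshold)
    lid <- build(idx[go_left], depth + 1L)
    rid <- build(idx[!go_left], depth + 1L)
    nodes[[id]]$feature <<- colnames(X)[best$feature]
    nodes[[id]]$threshold <<- best$threshold
    nodes[[id]]$default_left <<- best$default_left
    nodes[[id]]$left <<- lid
    nodes[[id]]$right <<- rid
    nodes[[id]]$value <<- NA_real_
    id
  }
  build(seq_len(nrow(X)), 0L)
  data.table::rbindlist(nodes)
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  node <- rep(1L, n)
  out <- numeric(n)
  repeat {
    is_leaf <- is.na(tree$feature[node])
    if (all(is_leaf)) break
    act <- which(!is_leaf)
    nd <- node[act]
    feat <- tree$feature[nd]
    xs <- X[cbind(act, match(feat, colnames(X)))]
    go_left <- ifelse(is.na(xs), tree$default_left[nd],
                      xs <= tree$threshold[nd])
    node[act] <- ifelse(go_left, tree$left[nd], tree$right[nd])
  }
  out <- tree$value[node]
  out
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# per-tree feature subsets for column subsampling (at least 1 feature each)
.column_subsets <- function(p, n_trees, colsample, seed) {
  k <- max(1L, round(colsample * p))
  if (k >= p) return(rep(list(seq_len(p)), n_trees))
  .with_seed(seed, function()
    lapply(seq_len(n_trees), function(i) sort(sample.int(p, k))))
}

# run fn under a local seed, restoring the caller's RNG state afterwards
.with_seed <- function(seed, fn) {
  if (!exists(".Random.seed", envir = globalenv()))
    runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}

# ---------------------------------------------------------------------------

#' Gradient boosted trees (logistic loss)
#'
#' @param X Numeric feature matrix (NAs allowed; trees learn a default
#'   direction for them).
#' @param y Binary 0/1 labels.
#' @param n_trees Number of boosting rounds. Default 100.
#' @param max_depth Tree depth. Default 3.
#' @param learning_rate Shrinkage. Default 0.3 (the reference boosted-tree
#'   implementation's default step size).
#' @param lambda L2 regularization of leaf weights. Default 1.
#' @param min_child_weight Minimum hessian mass per child. Default 1
#'   (reference default); suppresses noise-fitting splits that isolate a
#'   handful of samples.
#' @param colsample Fraction of features offered to each tree (sampled per
#'   tree, seeded); decorrelates trees and spreads importance across
#'   correlated strong features. Default 0.7.
#' @param seed Seed for the per-tree column subsampling.
#' @return An `fcs_gb` model (list of node tables + metadata) with a
#'   `predict` method returning probabilities.
#' @export
fit_gradient_boost <- function(X, y, n_trees = 100L, max_depth = 3L,
                               learning_rate = 0.3, lambda = 1,
                               min_child_weight = 1, colsample = 0.7,
                               seed = 0L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  F0 <- log(p0 / (1 - p0))
  Fhat <- rep(F0, nrow(X))
  subsets <- .column_subsets(ncol(X), n_trees, colsample, seed)
  trees <- vector("list", n_trees)
  for (m in seq_len(n_trees)) {
    p <- sigmoid(Fhat)
    g <- p - y
    h <- pmax(p * (1 - p), 1e-10)
    tr <- grow_tree(X, g, h, max_depth, min_child_weight, lambda,
                    feature_subset = subsets[[m]])
    trees[[m]] <- tr
    Fhat <- Fhat + learning_rate * predict_tree(tr, X)
  }
  structure(list(trees = trees, base_score = F0,
                 learning_rate = learning_rate,
                 features = colnames(X), kind = "gradient_boost"),
            class = "fcs_gb")
}

#' @export
predict.fcs_gb <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  Fhat <- rep(object$base_score, nrow(X))
  for (tr in object$trees)
    Fhat <- Fhat + object$learning_rate * predict_tree(tr, X)
  sigmoid(Fhat)
}

#' Discrete AdaBoost over shallow trees
#'
#' Base learners are depth-limited regression trees fitted to the weighted
#' sign targets; each round reweights misclassified samples by
#' `exp(alpha)` with `alpha = log((1 - err) / err) / 2`.
#'
#' @inheritParams fit_gradient_boost
#' @param max_depth Base-learner depth. Default 2.
#' @return An `fcs_ada` model; `predict` returns probabilities
#'   (`sigmoid(2 * margin)`).
#' @export
fit_adaboost <- function(X, y, n_trees = 50L, max_depth = 2L,
                         colsample = 0.7, seed = 0L) {
  X <- as.matrix(X)
  yt <- ifelse(as.numeric(y) > 0.5, 1, -1)
  n <- nrow(X)
  w <- rep(1 / n, n)
  subsets <- .column_subsets(ncol(X), n_trees, colsample, seed)
  trees <- list(); alphas <- numeric(0)
  for (m in seq_len(n_trees)) {
    # weighted least-squares fit of the +/-1 targets: g = -w * yt, h = w
    tr <- grow_tree(X, -w * yt, w, max_depth,
                    min_child_weight = 1e-9, lambda = 1e-9,
                    feature_subset = subsets[[m]])
    pred <- sign(predict_tree(tr, X))
    pred[pred == 0] <- 1
    err <- sum(w[pred != yt])
    if (err >= 0.5) break
    if (err < 1e-12) {
      trees[[length(trees) + 1L]] <- tr
      alphas <- c(alphas, 6)            # capped weight for a perfect learner
      break
    }
    alpha <- 0.5 * log((1 - err) / err)
    trees[[length(trees) + 1L]] <- tr
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * yt * pred)
    w <- w / sum(w)
  }
  structure(list(trees = trees, alphas = alphas, features = colnames(X),
                 kind = "adaboost"),
            class = "fcs_ada")
}

#' @export
predict.fcs_ada <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  margin <- numeric(nrow(X))
  for (i in seq_along(object$trees))
    margin <- margin +
      object$alphas[i] * sign(predict_tree(object$trees[[i]], X))
  sigmoid(2 * margin)
}

# ---------------------------------------------------------------------------
# imputation + standardization shared by the kernel machine and the network

.impute_fit <- function(X) {
  X <- as.matrix(X)
  med <- apply(X, 2, function(col) {
    m <- stats::median(col, na.rm = TRUE)
    if (is.na(m)) 0 else m
  })
  has_na <- colSums(is.na(X)) > 0
  list(medians = med, indicator_cols = colnames(X)[has_na])
}

.impute_apply <- function(imp, X) {
  X <- as.matrix(X)
  if (length(imp$indicator_cols)) {
    ind <- matrix(0, nrow(X), length(imp$indicator_cols),
                  dimnames = list(NULL, paste0(imp$indicator_cols,
                                               "_missing")))
    for (k in seq_along(imp$indicator_cols))
      ind[, k] <- as.numeric(is.na(X[, imp$indicator_cols[k]]))
  } else {
    ind <- matrix(numeric(0), nrow(X), 0)
  }
  for (j in colnames(X)) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- imp$medians[[j]]
  }
  cbind(X, ind)
}

.scale_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

.scale_apply <- function(sc, X) sweep(sweep(X, 2, sc$center), 2, sc$scale,
                                      "/")

.kernel_matrix <- function(kind, A, B, gamma, degree = 3) {
  switch(kind,
         linear = A %*% t(B),
         poly = (1 + gamma * (A %*% t(B)))^degree,
         rbf = {
           an <- rowSums(A^2); bn <- rowSums(B^2)
           d2 <- outer(an, bn, "+") - 2 * (A %*% t(B))
           exp(-gamma * pmax(d2, 0))
         })
}

#' Regularized least-squares kernel machine
#'
#' Solves `(K + lambda I) alpha = y~` with `y~ = +/-1` and scores new
#' samples by `K(new, train) alpha`. Linear, polynomial (degree 3) and
#' radial kernels are fitted; the kernel (and ridge penalty) with the best
#' AUC on an internal 70/30 validation split of the training data is kept
#' and refitted on the full training set.
#'
#' @inheritParams fit_gradient_boost
#' @param kernels Candidate kernels.
#' @param lambdas Candidate ridge penalties.
#' @param seed Seed for the internal validation split.
#' @return An `fcs_svm` model; `predict` returns `sigmoid(score)`.
#' @export
fit_kernel_machine <- function(X, y, kernels = c("linear", "poly", "rbf"),
                               lambdas = c(0.01, 0.1, 1), seed = 0L) {
  imp <- .impute_fit(X)
  Xi <- .impute_apply(imp, X)
  sc <- .scale_fit(Xi)
  Xs <- .scale_apply(sc, Xi)
  yt <- ifelse(as.numeric(y) > 0.5, 1, -1)
  n <- nrow(Xs)
  gamma <- 1 / ncol(Xs)

  fit_on <- function(A, yy, kind, lambda) {
    K <- .kernel_matrix(kind, A, A, gamma)
    alpha <- solve(K + diag(lambda, nrow(A)), yy)
    list(kind = kind, lambda = lambda, alpha = alpha, A = A)
  }
  score_on <- function(model, B)
    drop(.kernel_matrix(model$kind, B, model$A, gamma) %*% model$alpha)

  best <- NULL
  if (n >= 8 && min(sum(yt > 0), sum(yt < 0)) >= 2) {
    val <- .with_seed(seed, function() {
      pos <- which(yt > 0); neg <- which(yt < 0)
      c(sample(pos, max(1, floor(0.3 * length(pos)))),
        sample(neg, max(1, floor(0.3 * length(neg)))))
    })
    tr <- setdiff(seq_len(n), val)
    best_auc <- -Inf
    for (kind in kernels) for (lambda in lambdas) {
      m <- fit_on(Xs[tr, , drop = FALSE], yt[tr], kind, lambda)
      s <- score_on(m, Xs[val, , drop = FALSE])
      auc <- tryCatch(evaluate_scores(s, as.numeric(yt[val] > 0))$auc,
                      error = function(e) NA_real_)
      if (is.finite(auc) && auc > best_auc) {
        best_auc <- auc
        best <- list(kind = kind, lambda = lambda)
      }
    }
  }
  if (is.null(best)) best <- list(kind = kernels[1], lambda = lambdas[1])
  model <- fit_on(Xs, yt, best$kind, best$lambda)
  structure(list(model = model, imputer = imp, scaler = sc, gamma = gamma,
                 kernel = best$kind, lambda = best$lambda,
                 features = colnames(as.matrix(X)), kind = "svm"),
            class = "fcs_svm")
}

#' @export
predict.fcs_svm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  Xs <- .scale_apply(object$scaler, .impute_apply(object$imputer, X))
  s <- drop(.kernel_matrix(object$model$kind, Xs, object$model$A,
                           object$gamma) %*% object$model$alpha)
  sigmoid(s)
}

#' Fully connected rectified-linear network
#'
#' Two hidden ReLU layers trained with Adam on the binary cross-entropy;
#' He-initialized weights, full-batch updates (the benchmark training sets
#' are small).
#'
#' @inheritParams fit_gradient_boost
#' @param hidden Hidden layer widths. Default `c(32, 16)`.
#' @param epochs Training epochs. Default 150.
#' @param learning_rate Adam step size. Default 0.01.
#' @param seed Seed for weight initialization.
#' @return An `fcs_relu` model; `predict` returns probabilities.
#' @export
fit_relu_net <- function(X, y, hidden = c(32, 16), epochs = 150L,
                         learning_rate = 0.01, seed = 0L) {
  imp <- .impute_fit(X)
  Xs0 <- .impute_apply(imp, X)
  sc <- .scale_fit(Xs0)
  A0 <- .scale_apply(sc, Xs0)
  y <- as.numeric(y)
  n <- nrow(A0)

  sizes <- c(ncol(A0), hidden, 1L)
  L <- length(sizes) - 1L
  W <- .with_seed(seed, function() lapply(seq_len(L), function(l)
    matrix(rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1])))
  b <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  for (t in seq_len(epochs)) {
    # forward
    As <- vector("list", L + 1L); As[[1]] <- A0
    Zs <- vector("list", L)
    for (l in seq_len(L)) {
      Z <- sweep(As[[l]] %*% W[[l]], 2, b[[l]], "+")
      Zs[[l]] <- Z
      As[[l + 1]] <- if (l < L) pmax(Z, 0) else sigmoid(Z)
    }
    p <- drop(As[[L + 1]])
    # backward (cross-entropy + sigmoid output -> delta = p - y)
    delta <- matrix((p - y) / n, n, 1)
    for (l in rev(seq_len(L))) {
      gW <- t(As[[l]]) %*% delta
      gb_ <- colSums(delta)
      if (l > 1)
        delta <- (delta %*% t(W[[l]])) * (Zs[[l - 1]] > 0)
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb_
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb_^2
      mhW <- mW[[l]] / (1 - beta1^t); vhW <- vW[[l]] / (1 - beta2^t)
      mhb <- mb[[l]] / (1 - beta1^t); vhb <- vb[[l]] / (1 - beta2^t)
      W[[l]] <- W[[l]] - learning_rate * mhW / (sqrt(vhW) + eps)
      b[[l]] <- b[[l]] - learning_rate * mhb / (sqrt(vhb) + eps)
    }
  }
  structure(list(W = W, b = b, imputer = imp, scaler = sc,
                 features = colnames(as.matrix(X)), kind = "relu_net"),
            class = "fcs_relu")
}

#' @export
predict.fcs_relu <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  A <- .scale_apply(object$scaler, .impute_apply(object$imputer, X))
  L <- length(object$W)
  for (l in seq_len(L)) {
    A <- sweep(A %*% object$W[[l]], 2, object$b[[l]], "+")
    if (l < L) A <- pmax(A, 0)
  }
  drop(sigmoid(A))
}
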