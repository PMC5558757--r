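# Heterogeneous node classifiers for the omnivariate tree. Common contract:
# fit on (matrix, binary 0/1 labels), predict class and a score in [0, 1]
# with predict(x) == (score(x) >= 0.5), deterministic given a seed.

.NODE_FAMILIES <- c("univariate_tree", "neural_net", "random_forest",
                    "multinomial_logistic")

#' Discrete hyperparameter grids of the node-classifier families
#'
#' Versioned grids searched by the genetic algorithm: C4.5-style pruning
#' confidence, neural-net hidden units, forest size and features-per-split,
#' logistic ridge penalty.
#'
#' @return Named list of per-family grids.
#' @export
node_family_grids <- function() {
  list(
    univariate_tree = list(confidence = c(0.1, 0.25, 0.5)),
    neural_net = list(hidden = c(5L, 10L, 20L, 40L)),
    random_forest = list(n_trees = c(50L, 100L, 200L, 500L),
                         mtry = c("sqrt", "log2", "all")),
    multinomial_logistic = list(ridge = c(1e-4, 1e-2, 1))
  )
}

.resolve_mtry <- function(mtry, p) {
  switch(mtry,
         sqrt = max(1L, ceiling(sqrt(p))),
         log2 = max(1L, ceiling(log2(p))),
         all = p,
         stop("unknown mtry rule: ", mtry))
}

#' Fit one node classifier
#'
#' @param family One of `"univariate_tree"`, `"neural_net"`,
#'   `"random_forest"`, `"multinomial_logistic"`.
#' @param hyperparams Named list drawn from [node_family_grids()].
#' @param X Numeric feature matrix.
#' @param y Binary labels (0/1).
#' @param seed Integer seed controlling all randomness of the fit.
#' @return Object of class `pas_node_model`.
#' @export
fit_node_classifier <- function(family, hyperparams, X, y, seed = 1L) {
  stopifnot(family %in% .NODE_FAMILIES, is.matrix(X),
            length(y) == nrow(X), all(y %in% c(0, 1)))
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  if (min(n1, length(y) - n1) < 2L) {
    # degenerate training set (a class absent or near-absent): constant
    # majority classifier
    m <- list(family = "constant",
              label = as.integer(n1 >= length(y) - n1))
    class(m) <- c("pas_node_constant", "pas_node_model")
    return(m)
  }
  m <- switch(family,
    univariate_tree = .fit_c45(X, y, hyperparams$confidence, seed),
    neural_net = .fit_mlp(X, y, hyperparams$hidden, seed),
    random_forest = .fit_forest(X, y, hyperparams$n_trees,
                                hyperparams$mtry, seed),
    multinomial_logistic = .fit_ridge_logistic(X, y, hyperparams$ridge))
  m$family <- family
  m$hyperparams <- hyperparams
  cls <- switch(family,
                univariate_tree = "pas_node_c45",
                neural_net = "pas_node_mlp",
                random_forest = "pas_node_forest",
                multinomial_logistic = "pas_node_logistic")
  class(m) <- c(cls, "pas_node_model")
  m
}

#' Score samples with a node classifier
#'
#' @param model A [fit_node_classifier()] result.
#' @param X Feature matrix.
#' @return Scores in `[0, 1]` (probability-like for class 1).
#' @export
predict_node_score <- function(model, X) {
  stopifnot(inherits(model, "pas_node_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  switch(class(model)[1],
         pas_node_constant = rep(as.numeric(model$label), nrow(X)),
         pas_node_c45 = .cpp_tree_prob(model$tree, X),
         pas_node_mlp = {
           pr <- model$params
           H <- tanh(sweep(X %*% pr$W1, 2, pr$b1, "+"))
           drop(1 / (1 + exp(-(drop(H %*% pr$w2) + pr$b2))))
         },
         pas_node_forest = .cpp_forest_prob(model$trees, X),
         pas_node_logistic = drop(stats::predict(
           model$fit, newx = X, type = "response", s = model$ridge)),
         stop("unknown node model class"))
}

#' Predict classes with a node classifier
#'
#' Equals `predict_node_score(model, X) >= 0.5`.
#'
#' @inheritParams predict_node_score
#' @return Integer vector of 0/1 predictions.
#' @export
predict_node <- function(model, X) {
  as.integer(predict_node_score(model, X) >= 0.5)
}

# ---- C4.5-style univariate tree: entropy splits + pessimistic pruning ----

.fit_c45 <- function(X, y, confidence, seed) {
  tree <- .cpp_tree_fit(X, y, max_depth = 20L, min_split = 4L,
                        min_leaf = 2L, mtry = ncol(X), min_gain = 0,
                        seed = as.integer(seed))
  tree <- .prune_c45(tree, confidence)
  list(tree = tree, confidence = confidence)
}

# pessimistic (upper-confidence-bound) error pruning a la C4.5: collapse a
# subtree when the node's own error upper bound does not exceed the summed
# bounds of its leaves. Smaller confidence -> more pruning.
.prune_c45 <- function(tree, confidence) {
  z <- qnorm(1 - confidence)
  ub <- function(err, n) {
    if (n == 0) return(0)
    f <- err / n
    (f + z^2 / (2 * n) + z * sqrt(f * (1 - f) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n)
  }
  feature <- tree$feature
  node_err <- pmin(tree$npos, tree$n - tree$npos)
  walk <- function(i) {  # returns estimated subtree errors for node i+? (1-based idx)
    if (feature[i + 1L] < 0) return(tree$n[i + 1L] * ub(node_err[i + 1L],
                                                        tree$n[i + 1L]))
    sub <- walk(tree$left[i + 1L]) + walk(tree$right[i + 1L])
    own <- tree$n[i + 1L] * ub(node_err[i + 1L], tree$n[i + 1L])
    if (own <= sub + 1e-9) {
      feature[i + 1L] <<- -1L
      return(own)
    }
    sub
  }
  walk(0L)
  tree$feature <- feature
  tree
}

# ---- single-hidden-layer neural network trained with L-BFGS ----

.fit_mlp <- function(X, y, hidden, seed, decay = 1e-3, maxit = 60L) {
  p <- ncol(X); h <- as.integer(hidden); n <- nrow(X)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  theta0 <- runif(p * h + h + h + 1, -0.5, 0.5) / sqrt(p)
  unpack <- function(th) {
    W1 <- matrix(th[1:(p * h)], p, h)
    b1 <- th[p * h + 1:h]
    w2 <- th[p * h + h + 1:h]
    b2 <- th[p * h + 2 * h + 1]
    list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  }
  fwd <- function(pr, X) {
    H <- tanh(sweep(X %*% pr$W1, 2, pr$b1, "+"))
    z <- drop(H %*% pr$w2) + pr$b2
    list(H = H, prob = 1 / (1 + exp(-z)))
  }
  fn <- function(th) {
    pr <- unpack(th)
    f <- fwd(pr, X)
    eps <- 1e-12
    -mean(y * log(f$prob + eps) + (1 - y) * log(1 - f$prob + eps)) +
      decay * (sum(pr$W1^2) + sum(pr$w2^2))
  }
  gr <- function(th) {
    pr <- unpack(th)
    f <- fwd(pr, X)
    dz <- (f$prob - y) / n
    gw2 <- drop(crossprod(f$H, dz)) + 2 * decay * pr$w2
    gb2 <- sum(dz)
    dH <- outer(dz, pr$w2) * (1 - f$H^2)
    gW1 <- crossprod(X, dH) + 2 * decay * pr$W1
    gb1 <- colSums(dH)
    c(as.vector(gW1), gb1, gw2, gb2)
  }
  fit <- optim(theta0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit))
  list(params = unpack(fit$par), hidden = h)
}

# ---- bagged random forest over entropy-split trees ----

.fit_forest <- function(X, y, n_trees, mtry, seed) {
  m <- .resolve_mtry(mtry, ncol(X))
  trees <- .cpp_forest_fit(X, y, n_trees = as.integer(n_trees),
                           max_depth = 10L, min_split = 5L, min_leaf = 2L,
                           mtry = m, seed = as.integer(seed))
  list(trees = trees, n_trees = n_trees, mtry = mtry)
}

# ---- ridge-penalized logistic regression (binary case of multinomial) ----

.fit_ridge_logistic <- function(X, y, ridge) {
  # small routed nodes trip glmnet's "fewer than 8 observations" advisory;
  # class counts >= 2 are already guaranteed by the caller
  fit <- suppressWarnings(
    glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                   alpha = 0, lambda = ridge, standardize = TRUE))
  list(fit = fit, ridge = ridge)
}

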