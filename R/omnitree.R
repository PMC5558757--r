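# The omnivariate decision tree: a complete binary tree of configurable
# depth whose internal slots each hold a heterogeneous classifier; routing
# follows each node's predicted class (predicted 0 -> left, 1 -> right).

#' Omnivariate tree configuration
#'
#' @param max_depth Depth of the complete binary tree skeleton (default 3,
#'   i.e. 7 internal slots); leaves sit at `max_depth`.
#' @param min_node_size Minimum routed training samples for a slot to stay
#'   internal (default 30).
#' @return List of class `omni_tree_config`.
#' @export
omni_tree_config <- function(max_depth = 3L, min_node_size = 30L) {
  stopifnot(max_depth >= 1L, min_node_size >= 1L)
  structure(list(max_depth = as.integer(max_depth),
                 min_node_size = as.integer(min_node_size)),
            class = "omni_tree_config")
}

.n_slots <- function(config) 2L^config$max_depth - 1L

.mix_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 2654435761 + as.numeric(salt) * 40503) %%
               2147483647)
}

# majority label with the spec's tie rule: more samples wins; tie -> the
# parent's majority; root tie -> class 1
.majority <- function(y, parent_label) {
  n1 <- sum(y == 1L)
  n0 <- length(y) - n1
  if (n1 > n0) 1L else if (n0 > n1) 0L else parent_label
}

#' Fit an omnivariate decision tree
#'
#' The root classifier is trained on all data; each internal node's
#' classifier is fitted on exactly the samples routed to it by its ancestors
#' (samples predicted class 0 go left, class 1 go right). A slot becomes a
#' leaf when the genome prunes it, its routed data is pure, its size is below
#' `min_node_size`, or it sits at `max_depth`. Leaf label is the majority of
#' its routed training data (ties resolved toward the parent majority, then
#' class 1); leaf score is the fraction of positive training samples routed
#' there.
#'
#' @param X Numeric feature matrix (training rows).
#' @param y Binary labels (1 = true PAS).
#' @param genome A GA genome (integer vector, see [random_genome()]); decoded
#'   against `config`.
#' @param config An [omni_tree_config()].
#' @param seed Integer seed; fixes every node fit.
#' @return Object of class `omni_tree`.
#' @export
fit_tree <- function(X, y, genome, config = omni_tree_config(), seed = 1L) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  y <- as.integer(y)
  if (!nrow(X)) stop("fit_tree: empty training set")
  stopifnot(all(y %in% c(0L, 1L)))
  spec <- decode_genome(genome, config)

  grow <- function(slot, rows, depth, parent_label) {
    ys <- y[rows]
    lab <- .majority(ys, parent_label)
    score <- if (length(rows)) mean(ys) else
      as.numeric(parent_label)
    pruned <- slot <= length(spec) && spec[[slot]]$prune
    pure <- length(unique(ys)) < 2L
    if (depth >= config$max_depth || pruned || pure ||
        length(rows) < config$min_node_size) {
      return(list(type = "leaf", label = lab, score = score,
                  n = length(rows)))
    }
    sp <- spec[[slot]]
    model <- fit_node_classifier(sp$family, sp$hyperparams,
                                 X[rows, , drop = FALSE], ys,
                                 seed = .mix_seed(seed, slot))
    pred <- predict_node(model, X[rows, , drop = FALSE])
    left <- grow(2L * slot, rows[pred == 0L], depth + 1L, lab)
    right <- grow(2L * slot + 1L, rows[pred == 1L], depth + 1L, lab)
    list(type = "internal", slot = slot, model = model,
         family = sp$family, hyperparams = sp$hyperparams,
         left = left, right = right, n = length(rows))
  }
  root <- grow(1L, seq_along(y), 0L, 1L)
  structure(list(root = root, config = config, genome = genome,
                 n_features = ncol(X), seed = seed),
            class = "omni_tree")
}

.route <- function(tree, X, what) {
  out <- numeric(nrow(X))
  walk <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (node$type == "leaf") {
      out[idx] <<- if (what == "label") node$label else node$score
      return(invisible())
    }
    pred <- predict_node(node$model, X[idx, , drop = FALSE])
    walk(node$left, idx[pred == 0L])
    walk(node$right, idx[pred == 1L])
  }
  walk(tree$root, seq_len(nrow(X)))
  out
}

#' Predict classes with a fitted omnivariate tree
#'
#' Traverses from the root following each internal node's predicted class and
#' returns the reached leaf's label.
#'
#' @param tree A fitted [fit_tree()].
#' @param X Feature matrix (or a single row vector).
#' @return Integer 0/1 predictions.
#' @export
predict_tree <- function(tree, X) {
  stopifnot(inherits(tree, "omni_tree"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != tree$n_features) {
    stop("predict_tree: expected ", tree$n_features, " features, got ",
         ncol(X))
  }
  as.integer(.route(tree, X, "label"))
}

#' Score samples with a fitted omnivariate tree
#'
#' Returns the fraction of positive (true-PAS) training samples at the
#' reached leaf, in `[0, 1]`.
#'
#' @inheritParams predict_tree
#' @return Numeric scores.
#' @export
predict_score_tree <- function(tree, X) {
  stopifnot(inherits(tree, "omni_tree"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != tree$n_features) {
    stop("predict_score_tree: expected ", tree$n_features, " features, got ",
         ncol(X))
  }
  .route(tree, X, "score")
}
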