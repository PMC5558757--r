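# Training/evaluation protocol: stratified 5-fold CV with a 15% validation
# holdout, training-only feature fitting and normalization, weak-variant
# pooling, and error metrics.

#' Stratified k-fold cross-validation splits with validation holdout
#'
#' Partitions records into `k` label-stratified folds. Within each fold the
#' remaining `k - 1` folds form the training portion, from which a stratified
#' `val_frac` fraction (floor per class) is reserved as the validation set
#' used for model optimisation; the test fold is used only for the final
#' assessment.
#'
#' @param records A `pas_dataset` (or any data.frame with `id` and `label`).
#' @param k Number of folds (default 5).
#' @param val_frac Validation fraction of the training portion (default
#'   0.15).
#' @param seed Integer seed; splits are deterministic per seed.
#' @return Object of class `cv_split`: `fold` (per-record fold id, aligned
#'   with `records`), `folds` (list of per-fold `train`/`validation`/`test`
#'   id vectors), `k`, `val_frac`, `seed`.
#' @export
make_cv_splits <- function(records, k = 5L, val_frac = 0.15, seed = 1L) {
  stopifnot(is.data.frame(records), !is.null(records$label),
            !is.null(records$id), !anyDuplicated(records$id))
  k <- as.integer(k)
  labs <- records$label
  counts <- table(labs)
  if (any(counts < k)) {
    stop("make_cv_splits: every class needs at least k = ", k,
         " records (got ", paste(names(counts), counts, sep = ":",
                                 collapse = ", "), ")")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(nrow(records))
  for (lv in names(counts)) {
    idx <- which(labs == lv)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds <- lapply(seq_len(k), function(f) {
    test <- which(fold == f)
    train_all <- which(fold != f)
    val <- integer()
    for (lv in names(counts)) {
      cls <- train_all[labs[train_all] == lv]
      n_val <- floor(val_frac * length(cls))
      if (n_val > 0) val <- c(val, sample(cls, n_val))
    }
    val <- sort(val)
    list(train = records$id[setdiff(train_all, val)],
         validation = records$id[val],
         test = records$id[test])
  })
  structure(list(fold = fold, folds = folds, k = k, val_frac = val_frac,
                 seed = seed),
            class = "cv_split")
}

#' Pool PAS-weak variants into a target variant's training set
#'
#' For a PAS-weak target variant, the pooled training set of a fold is the
#' target's training portion for that fold (the 80% outside the test fold,
#' validation holdout included) together with all records of the other nine
#' weak variants. Validation and test sets contain only target-variant
#' records; no pooled record shares an id with the target's test records.
#'
#' @param target_variant A PAS-weak hexamer.
#' @param fold Fold number (1-based).
#' @param datasets Named list of the 10 weak `pas_dataset`s (names =
#'   variants).
#' @param split A [make_cv_splits()] of the target variant's dataset.
#' @return List: `records` (pooled training `pas_dataset`, validation rows
#'   included), `validation_ids`, `test_ids`.
#' @export
pool_weak_training <- function(target_variant, fold, datasets, split) {
  if (classify_variant(target_variant) != "weak") {
    stop("pool_weak_training: pooling is defined only for PAS-weak ",
         "variants (got '", target_variant, "')")
  }
  stopifnot(inherits(split, "cv_split"), target_variant %in% names(datasets))
  f <- split$folds[[fold]]
  target <- datasets[[target_variant]]
  target_train <- target[target$id %in% c(f$train, f$validation), ,
                         drop = FALSE]
  others <- datasets[setdiff(names(datasets), target_variant)]
  pooled <- rbind(target_train,
                  do.call(rbind, lapply(others, as.data.frame)))
  if (any(pooled$id %in% f$test)) {
    stop("pool_weak_training: pooled record shares an id with the target ",
         "test set")
  }
  list(records = pas_dataset(pooled), validation_ids = f$validation,
       test_ids = f$test)
}

#' Classification error metrics
#'
#' `error_rate = 1 - (TP + TN) / (TP + TN + FP + FN)`;
#' `fpr = FP / (FP + TN)`; `fnr = FN / (FN + TP)`.
#'
#' @param TP,TN,FP,FN Confusion counts (non-negative).
#' @return `error_rate()` the rate in `[0, 1]`; `eval_report()` a full
#'   report object.
#' @export
error_rate <- function(TP, TN, FP, FN) {
  total <- TP + TN + FP + FN
  if (any(c(TP, TN, FP, FN) < 0)) stop("error_rate: negative counts")
  if (total == 0) stop("error_rate: zero total")
  1 - (TP + TN) / total
}

#' @rdname error_rate
#' @export
fpr <- function(TP, TN, FP, FN) if (FP + TN == 0) NA_real_ else FP / (FP + TN)

#' @rdname error_rate
#' @export
fnr <- function(TP, TN, FP, FN) if (FN + TP == 0) NA_real_ else FN / (FN + TP)

#' @rdname error_rate
#' @param truth,pred 0/1 vectors (1 = true PAS) from which to count the
#'   confusion matrix.
#' @export
eval_report <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  TP <- sum(truth == 1 & pred == 1)
  TN <- sum(truth == 0 & pred == 0)
  FP <- sum(truth == 0 & pred == 1)
  FN <- sum(truth == 1 & pred == 0)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 error_rate = error_rate(TP, TN, FP, FN),
                 fpr = fpr(TP, TN, FP, FN), fnr = fnr(TP, TN, FP, FN)),
            class = "pas_eval_report")
}

#' Size-weighted average
#'
#' `sum(size_i * value_i) / sum(size_i)`, the "Average" row of per-variant
#' result tables.
#'
#' @param values Numeric vector (e.g. per-variant error rates).
#' @param sizes Positive weights of the same length.
#' @return The weighted mean.
#' @export
weighted_average <- function(values, sizes) {
  if (length(values) != length(sizes)) {
    stop("weighted_average: mismatched lengths")
  }
  if (any(sizes <= 0)) stop("weighted_average: sizes must be positive")
  sum(sizes * values) / sum(sizes)
}

# fit feature model + normalization on training rows only, return normalized
# matrices for arbitrary id subsets
.prepare_fold <- function(records, train_ids, pseudocount = 1) {
  train <- records[records$id %in% train_ids, , drop = FALSE]
  fm <- fit_feature_model(pas_dataset(train), pseudocount = pseudocount)
  Xtr <- extract_features(train$seq, fm)
  norm <- suppressWarnings(fit_normalization(Xtr))
  list(feature_model = fm, norm = norm,
       matrix_for = function(ids) {
         d <- records[match(ids, records$id), , drop = FALSE]
         list(X = apply_normalization(extract_features(d$seq, fm), norm),
              y = as.integer(d$label == "true_pas"), ids = d$id)
       })
}

#' Run the full cross-validated experiment
#'
#' For each variant dataset and each fold: fits the training-dependent
#' feature components and normalization on that fold's training rows only,
#' evolves the GA on the train/validation split, and evaluates the selected
#' tree once on the test fold. Confusion counts are pooled over folds
#' (micro-average). Under `protocol = "weak-pooled"` the training set of each
#' weak variant is expanded with all records of the other nine weak variants.
#'
#' @param datasets Named list of `pas_dataset`s (names = variants), or a
#'   single `pas_dataset`.
#' @param protocol `"per-variant"` or `"weak-pooled"`.
#' @param ga_cfg A [ga_config()].
#' @param tree_cfg An [omni_tree_config()].
#' @param k,val_frac Cross-validation dimensions.
#' @param seed Integer seed for splits (GA uses `ga_cfg$seed` mixed per
#'   fold).
#' @return List of class `pas_experiment`: `per_variant` (named list of
#'   `pas_eval_report`), `weighted_error` (size-weighted average error),
#'   `sizes`.
#' @export
run_experiment <- function(datasets, protocol = c("per-variant",
                                                  "weak-pooled"),
                           ga_cfg = ga_config(), tree_cfg = omni_tree_config(),
                           k = 5L, val_frac = 0.15, seed = 1L) {
  protocol <- match.arg(protocol)
  if (inherits(datasets, "pas_dataset")) {
    datasets <- setNames(list(datasets), unique(datasets$variant))
  }
  reports <- list()
  for (variant in names(datasets)) {
    ds <- pas_dataset(datasets[[variant]])
    split <- make_cv_splits(ds, k = k, val_frac = val_frac,
                            seed = .mix_seed(seed, match(variant,
                                                         names(datasets))))
    truth_all <- integer()
    pred_all <- integer()
    for (f in seq_len(k)) {
      fd <- split$folds[[f]]
      if (protocol == "weak-pooled" &&
          classify_variant(variant) == "weak" && length(datasets) > 1L) {
        weak_sets <- datasets[classify_variant(names(datasets)) == "weak"]
        pool <- pool_weak_training(variant, f, weak_sets, split)
        records <- rbind(as.data.frame(pool$records),
                         as.data.frame(ds[ds$id %in% fd$test, ,
                                          drop = FALSE]))
        records <- pas_dataset(records[!duplicated(records$id), ,
                                       drop = FALSE])
        train_ids <- setdiff(pool$records$id, pool$validation_ids)
      } else {
        records <- ds
        train_ids <- fd$train
      }
      prep <- .prepare_fold(records, train_ids)
      tr <- prep$matrix_for(train_ids)
      va <- prep$matrix_for(fd$validation)
      te <- prep$matrix_for(fd$test)
      cfg <- ga_cfg
      cfg$seed <- .mix_seed(ga_cfg$seed, f)
      res <- evolve(list(X = tr$X, y = tr$y), list(X = va$X, y = va$y),
                    cfg, tree_cfg)
      pred <- predict_tree(res$best_tree, te$X)
      truth_all <- c(truth_all, te$y)
      pred_all <- c(pred_all, pred)
    }
    reports[[variant]] <- eval_report(truth_all, pred_all)
  }
  sizes <- vapply(datasets, nrow, integer(1))
  structure(list(per_variant = reports,
                 weighted_error = weighted_average(
                   vapply(reports, function(r) r$error_rate, numeric(1)),
                   sizes),
                 sizes = sizes, protocol = protocol),
            class = "pas_experiment")
}

#' Format an experiment as a per-variant table
#'
#' Mirrors the published result-table layout: variant, size, error %, FPR %,
#' FNR %, and a size-weighted average row.
#'
#' @param x A `pas_experiment`.
#' @return A data.frame.
#' @export
experiment_table <- function(x) {
  stopifnot(inherits(x, "pas_experiment"))
  rows <- data.frame(
    variant = names(x$per_variant),
    size = as.integer(x$sizes),
    error_pct = vapply(x$per_variant,
                       function(r) 100 * r$error_rate, numeric(1)),
    fpr_pct = vapply(x$per_variant, function(r) 100 * r$fpr, numeric(1)),
    fnr_pct = vapply(x$per_variant, function(r) 100 * r$fnr, numeric(1)),
    row.names = NULL)
  rbind(rows, data.frame(variant = "Average", size = sum(rows$size),
                         error_pct = 100 * x$weighted_error,
                         fpr_pct = weighted_average(rows$fpr_pct, rows$size),
                         fnr_pct = weighted_average(rows$fnr_pct,
                                                    rows$size)))
}
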