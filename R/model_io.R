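# Versioned model container: feature model + normalization + selected tree,
# with registry-version checks at prediction time.

.MODEL_VERSION <- "1.0"

#' Train a full PAS recognition model
#'
#' Holds out a stratified `val_frac` of the records as the validation set,
#' fits the training-dependent feature components and normalization on the
#' remaining training rows, evolves the GA on train/validation, and returns
#' the selected tree bundled with everything needed to score new sequences.
#'
#' @param records A `pas_dataset` with both classes.
#' @param ga_cfg A [ga_config()].
#' @param tree_cfg An [omni_tree_config()].
#' @param val_frac Validation fraction (default 0.15).
#' @param seed Integer seed (splits; the GA uses `ga_cfg$seed`).
#' @return Object of class `pas_model`.
#' @export
train_pas_model <- function(records, ga_cfg = ga_config(),
                            tree_cfg = omni_tree_config(),
                            val_frac = 0.15, seed = 1L) {
  records <- pas_dataset(records)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  val <- integer()
  for (lv in unique(records$label)) {
    cls <- which(records$label == lv)
    n_val <- floor(val_frac * length(cls))
    if (n_val > 0) val <- c(val, sample(cls, n_val))
  }
  train <- records[setdiff(seq_len(nrow(records)), val), , drop = FALSE]
  validation <- records[sort(val), , drop = FALSE]
  fm <- fit_feature_model(train)
  Xtr <- extract_features(train$seq, fm)
  norm <- suppressWarnings(fit_normalization(Xtr))
  Xtr <- apply_normalization(Xtr, norm)
  Xva <- apply_normalization(extract_features(validation$seq, fm), norm)
  res <- evolve(list(X = Xtr, y = as.integer(train$label == "true_pas")),
                list(X = Xva,
                     y = as.integer(validation$label == "true_pas")),
                ga_cfg, tree_cfg)
  structure(list(version = .MODEL_VERSION,
                 registry_version = fm$registry_version,
                 feature_model = fm, norm = norm, tree = res$best_tree,
                 genome = res$best_genome,
                 validation_error = res$best_fitness,
                 ga_history = res$history, ga_cfg = ga_cfg,
                 tree_cfg = tree_cfg, seed = seed),
            class = "pas_model")
}

#' Score sequences with a trained model
#'
#' @param model A [train_pas_model()] result (or one loaded with
#'   [load_model()]).
#' @param seqs Character vector of 206-nt sequences, or a `pas_dataset`.
#' @param registry_version Expected feature-registry version; a mismatch
#'   with the model is an error.
#' @return data.frame with `id`, `score` (leaf true-PAS fraction) and
#'   predicted `label`.
#' @export
predict_pas <- function(model, seqs, registry_version = NULL) {
  stopifnot(inherits(model, "pas_model"))
  if (!is.null(registry_version) &&
      !identical(registry_version, model$registry_version)) {
    stop("predict_pas: model registry_version '", model$registry_version,
         "' does not match requested '", registry_version, "'")
  }
  ids <- if (inherits(seqs, "pas_dataset")) seqs$id else
    if (!is.null(names(seqs))) names(seqs) else
      sprintf("seq_%05d", seq_along(seqs))
  X <- apply_normalization(extract_features(seqs, model$feature_model),
                           model$norm)
  score <- predict_score_tree(model$tree, X)
  pred <- predict_tree(model$tree, X)
  data.frame(id = ids, score = score,
             label = ifelse(pred == 1L, "true_pas", "pseudo_pas"),
             stringsAsFactors = FALSE)
}

#' Save / load a model container
#'
#' @param model A `pas_model`.
#' @param path File path (RDS container).
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   validated model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pas_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pas_model") ||
      !identical(model$version, .MODEL_VERSION)) {
    stop("load_model: '", path, "' is not a compatible model container")
  }
  model
}

#' Write a feature table as TSV
#'
#' Header = registry names; first columns are `id`, `variant`, `label`.
#'
#' @param ds A `pas_dataset`.
#' @param model A fitted [fit_feature_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ds, model, path) {
  ds <- pas_dataset(ds)
  X <- extract_features(ds$seq, model)
  out <- cbind(data.frame(id = ds$id, variant = ds$variant,
                          label = ds$label, stringsAsFactors = FALSE),
               as.data.frame(X))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
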