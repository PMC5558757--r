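# Min-max normalization to (-1, 1), fitted on training rows only and applied
# unchanged to validation/test rows (which may therefore exceed the range).

#' Fit normalization parameters on training features
#'
#' Records per-feature `min` and `max` from the training matrix. Constant
#' features (`max == min`) are flagged with a warning; they normalize to 0.
#'
#' @param train_features Numeric matrix of training rows (named columns).
#' @return Object of class `pas_norm_params`.
#' @export
fit_normalization <- function(train_features) {
  stopifnot(is.matrix(train_features), nrow(train_features) >= 1)
  mx <- apply(train_features, 2, max)
  mn <- apply(train_features, 2, min)
  const <- mx == mn
  if (any(const)) {
    warning("fit_normalization: ", sum(const),
            " constant feature(s) will normalize to 0: ",
            paste(head(names(which(const)), 5), collapse = ", "))
  }
  structure(list(min = mn, max = mx, constant = const,
                 names = colnames(train_features)),
            class = "pas_norm_params")
}

#' Apply fitted normalization
#'
#' `norm_i = (x_i - (max_i + min_i)/2) / ((max_i - min_i)/2)`; training
#' columns land in `[-1, 1]`, other rows may exceed it. Constant features
#' map to 0.
#'
#' @param x Numeric matrix (or single row vector) with the training columns.
#' @param params A [fit_normalization()] object.
#' @return Normalized matrix of the same shape.
#' @export
apply_normalization <- function(x, params) {
  stopifnot(inherits(params, "pas_norm_params"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (!is.null(colnames(x)) && !identical(colnames(x), params$names)) {
    x <- x[, params$names, drop = FALSE]
  }
  centre <- (params$max + params$min) / 2
  halfspan <- (params$max - params$min) / 2
  halfspan[params$constant] <- 1  # guarded division; numerator is 0 there
  out <- sweep(sweep(x, 2, centre), 2, halfspan, "/")
  out[, params$constant] <- 0
  out
}
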