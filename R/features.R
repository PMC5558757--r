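# The 218-value feature encoding: dinucleotide weight-matrix scores,
# positional information gain, top-position nucleotide frequencies,
# structural-profile window averages, and compositional descriptors.

.NT <- c("A", "C", "G", "T")
.DINUC <- sort(as.vector(outer(.NT, .NT, paste0)))   # AA..TT lexicographic
.REGISTRY_VERSION <- "1.0"

# n x L integer code matrix (A=1, C=2, G=3, T=4) from character sequences
.code_matrix <- function(seqs) {
  seqs <- toupper(as.character(seqs))
  if (any(grepl("[^ACGT]", seqs))) {
    stop("sequences must be over {A,C,G,T} (N not allowed here)")
  }
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must all have the same length")
  m <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)), .NT),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  m
}

# dinucleotide codes 1..16 at start positions 1..L-1
.dinuc_codes <- function(code_mat) {
  L <- ncol(code_mat)
  4L * (code_mat[, 1:(L - 1L), drop = FALSE] - 1L) +
    code_mat[, 2:L, drop = FALSE]
}

.trinuc_codes <- function(code_mat) {
  L <- ncol(code_mat)
  16L * (code_mat[, 1:(L - 2L), drop = FALSE] - 1L) +
    4L * (code_mat[, 2:(L - 1L), drop = FALSE] - 1L) +
    code_mat[, 3:L, drop = FALSE]
}

#' Fit a position-specific dinucleotide weight matrix
#'
#' For training sequences of common length `L`, estimates the probability of
#' each of the 16 dinucleotides at each of the `L - 1` start positions:
#' `p_ij = (count_ij + pseudocount) / (n + 16 * pseudocount)`. One matrix is
#' fitted per class (true PAS / pseudo-PAS) by calling this on each class's
#' training sequences. Background probabilities default to the uniform 1/16.
#'
#' @param train_seqs Character vector of equal-length DNA sequences.
#' @param pseudocount Laplace smoothing constant (default 1).
#' @return Object of class `weight_matrix_2mer` with fields `p`
#'   (16 x L-1, rows in fixed lexicographic order AA..TT), `Pb`, `L`,
#'   `pseudocount`.
#' @export
fit_weight_matrix <- function(train_seqs, pseudocount = 1) {
  if (!length(train_seqs)) stop("fit_weight_matrix: empty training set")
  cm <- .code_matrix(train_seqs)
  L <- ncol(cm)
  if (L < 2L) stop("fit_weight_matrix: sequences shorter than 2 nt")
  D <- .dinuc_codes(cm)
  n <- nrow(D)
  counts <- vapply(seq_len(ncol(D)), function(j) tabulate(D[, j], 16L),
                   integer(16))
  p <- (counts + pseudocount) / (n + 16 * pseudocount)
  dimnames(p) <- list(.DINUC, NULL)
  structure(list(p = p, Pb = setNames(rep(1 / 16, 16), .DINUC), L = L,
                 pseudocount = pseudocount),
            class = "weight_matrix_2mer")
}

#' Score a sequence against a dinucleotide weight matrix
#'
#' Default (`mode = "matched"`) sums, over dinucleotide start positions,
#' `log2(p[r(j), j] / Pb[r(j)])` for the dinucleotide `r(j)` observed at
#' position `j`. `mode = "literal"` adds the constant contribution of the 15
#' unmatched rows per position (`log2(1 / Pb_i)` each, i.e. `+60 * (L - 1)`
#' bits with uniform background), which shifts both class scores equally and
#' changes no decision.
#'
#' @param seq A DNA sequence (or character vector of them) of length `wm$L`.
#' @param wm A fitted [fit_weight_matrix()] object.
#' @param mode `"matched"` (default) or `"literal"`.
#' @return Numeric score(s).
#' @export
score_2mer <- function(seq, wm, mode = c("matched", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(wm, "weight_matrix_2mer"))
  cm <- .code_matrix(seq)
  if (ncol(cm) != wm$L) {
    stop("score_2mer: sequence length ", ncol(cm), " != matrix L = ", wm$L)
  }
  D <- .dinuc_codes(cm)
  if (any(wm$p == 0)) {
    # only an error if a zero cell is actually hit
    hit <- vapply(seq_len(ncol(D)),
                  function(j) any(wm$p[cbind(D[, j], j)] == 0), logical(1))
    if (any(hit)) {
      stop("score_2mer: observed dinucleotide has probability 0; refit the ",
           "weight matrix with pseudocount > 0")
    }
  }
  lp <- log2(wm$p / wm$Pb[1])  # uniform background
  s <- numeric(nrow(D))
  for (j in seq_len(ncol(D))) s <- s + lp[cbind(D[, j], j)]
  if (mode == "literal") {
    s <- s + 15 * log2(16) * ncol(D)
  }
  s
}

#' Two-class positional entropy
#'
#' `E = -(c1/(c1+c2)) log2(c1/(c1+c2)) - (c2/(c1+c2)) log2(c2/(c1+c2))` with
#' `0 log2 0 := 0`. The same formula computes the per-nucleotide entropy
#' `E(P, X)` (from occurrence counts of nucleotide X at position P in the two
#' classes) and the class-prior entropy `E(P)` (from class totals).
#'
#' @param c1,c2 Non-negative counts (vectorized); a pair that is both zero is
#'   an error.
#' @return Entropy in bits, in `[0, 1]`.
#' @export
positional_entropy <- function(c1, c2) {
  if (any(c1 < 0 | c2 < 0)) stop("positional_entropy: negative counts")
  if (any(c1 + c2 == 0)) {
    stop("positional_entropy: undefined for c1 = c2 = 0")
  }
  .entropy2(c1, c2)
}

# entropy that silently returns 0 for an empty pair (profile internals)
.entropy2 <- function(c1, c2) {
  tot <- c1 + c2
  p <- ifelse(tot > 0, c1 / tot, 0)
  term <- function(x) ifelse(x > 0, -x * log2(x), 0)
  ifelse(tot > 0, term(p) + term(1 - p), 0)
}

#' Fit a positional information-gain profile
#'
#' For every window position outside the hexamer (positions 101-106, 1-based,
#' are excluded: the hexamer is identical in both classes by construction),
#' tabulates nucleotide occurrences in true-PAS (`c1`) and pseudo-PAS (`c2`)
#' training sequences, computes per-nucleotide entropies `E(P, X)`, the
#' class-prior entropy `E(P)`, and the information gain. The default
#' `mode = "weighted"` uses the mutual-information form
#' `Gain(P) = E(P) - sum_X w_X E(P, X)` with `w_X` the fraction of training
#' sequences carrying X at P (non-negative by construction);
#' `mode = "literal"` uses the unweighted sum and may go negative.
#'
#' Also stores the pseudocount-smoothed per-position class log-ratio
#' `log2(f_true(X, P) / f_pseudo(X, P))` that drives [gain_score()].
#'
#' @param seqs Character vector of 206-nt sequences (or a `pas_dataset`,
#'   in which case `labels` is taken from it).
#' @param labels Vector with values `"true_pas"`/`"pseudo_pas"` (or logical,
#'   `TRUE` = true PAS).
#' @param mode `"weighted"` (default) or `"literal"`.
#' @param pseudocount Smoothing for the class log-ratio.
#' @return Object of class `gain_profile`.
#' @export
fit_gain_profile <- function(seqs, labels = NULL,
                             mode = c("weighted", "literal"),
                             pseudocount = 1) {
  mode <- match.arg(mode)
  if (inherits(seqs, "pas_dataset")) {
    labels <- seqs$label
    seqs <- seqs$seq
  }
  if (is.logical(labels)) labels <- ifelse(labels, "true_pas", "pseudo_pas")
  is_true <- labels == "true_pas"
  if (!any(is_true) || all(is_true)) {
    stop("fit_gain_profile: both classes must be present")
  }
  cm <- .code_matrix(seqs)
  L <- ncol(cm)
  count_by_pos <- function(m) {
    vapply(seq_len(ncol(m)), function(j) tabulate(m[, j], 4L), integer(4))
  }
  ct <- count_by_pos(cm[is_true, , drop = FALSE])
  cp <- count_by_pos(cm[!is_true, , drop = FALSE])
  dimnames(ct) <- dimnames(cp) <- list(.NT, NULL)
  n1 <- sum(is_true)
  n2 <- sum(!is_true)
  E_PX <- .entropy2(ct, cp)
  E_P <- rep(positional_entropy(n1, n2), L)
  w <- (ct + cp) / (n1 + n2)
  gain <- if (mode == "weighted") E_P - colSums(w * E_PX)
          else E_P - colSums(E_PX)
  hex <- .HEX_FROM:.HEX_TO
  if (L >= .HEX_TO) gain[hex] <- NA_real_
  log_ratio <- log2(((ct + pseudocount) / (n1 + 4 * pseudocount)) /
                      ((cp + pseudocount) / (n2 + 4 * pseudocount)))
  structure(list(counts_true = ct, counts_pseudo = cp, n_true = n1,
                 n_pseudo = n2, E_PX = E_PX, E_P = E_P, gain = gain,
                 log_ratio = log_ratio, mode = mode,
                 pseudocount = pseudocount, L = L),
            class = "gain_profile")
}

#' Gain-weighted class log-ratio score of a sequence
#'
#' `score = sum_P gain(P) * log2(f_true(seq[P], P) / f_pseudo(seq[P], P))`
#' over non-hexamer positions. High scores suggest a functional PAS, low
#' scores a pseudo-PAS; the score is 0 for any sequence when no position is
#' informative.
#'
#' @param seq DNA sequence(s) of the profile's length.
#' @param profile A fitted [fit_gain_profile()].
#' @return Numeric score(s).
#' @export
gain_score <- function(seq, profile) {
  stopifnot(inherits(profile, "gain_profile"))
  cm <- .code_matrix(seq)
  if (ncol(cm) != profile$L) stop("gain_score: sequence length mismatch")
  pos <- which(!is.na(profile$gain))
  s <- numeric(nrow(cm))
  for (p in pos) {
    s <- s + profile$gain[p] * profile$log_ratio[cbind(cm[, p], p)]
  }
  s
}

#' Select the most discriminative flank positions by information gain
#'
#' Picks the `n_up` highest-gain positions in the upstream flank (window
#' positions 1-100, 1-based) and the `n_down` highest in the downstream flank
#' (positions 107-206). Ties break toward the smaller position index.
#'
#' @param profile A fitted [fit_gain_profile()].
#' @param n_up,n_down Number of positions per flank (default 20 each).
#' @return List with integer vectors `up` and `down` (1-based window
#'   positions, each sorted by descending gain).
#' @export
select_top_positions <- function(profile, n_up = 20, n_down = 20) {
  stopifnot(inherits(profile, "gain_profile"))
  g <- profile$gain
  up <- 1:.FLANK_LEN
  down <- (.HEX_TO + 1L):profile$L
  if (n_up > length(up) || n_down > length(down)) {
    stop("select_top_positions: n exceeds available flank positions")
  }
  pick <- function(idx, n) {
    o <- idx[order(-g[idx], idx)]
    o[seq_len(n)]
  }
  list(up = pick(up, n_up), down = pick(down, n_down))
}

#' Nucleotide frequencies at the selected top positions
#'
#' @param seq DNA sequence(s), length 206.
#' @param positions Output of [select_top_positions()].
#' @return For a single sequence, a named numeric vector of 8 values:
#'   frequency of A, C, G, T among the downstream positions, then among the
#'   upstream positions (each 4-tuple sums to 1). For several sequences, a
#'   matrix with those columns.
#' @export
top_position_frequencies <- function(seq, positions) {
  cm <- .code_matrix(seq)
  if (any(unlist(positions) < 1L | unlist(positions) > ncol(cm))) {
    stop("top_position_frequencies: position out of range")
  }
  freq4 <- function(cols) {
    sub <- cm[, cols, drop = FALSE]
    matrix(vapply(1:4, function(k) rowMeans(sub == k), numeric(nrow(cm))),
           nrow = nrow(cm))
  }
  out <- cbind(freq4(positions$down), freq4(positions$up))
  colnames(out) <- c(paste0("topfreq_down_", .NT), paste0("topfreq_up_", .NT))
  if (nrow(out) == 1L) out[1, ] else out
}

#' Bundled DNA structural conversion scales
#'
#' Reads a table of di-/tri-nucleotide physicochemical scales (columns
#' `scale`, `k`, `kmer`, `value`; `#` comment lines ignored). The packaged
#' default bundles 16 scales; its values are synthetic stand-ins for the
#' published tables (see the file header) and can be replaced with literature
#' tables of the same shape.
#'
#' @param path Optional path to an alternative scale table.
#' @return Named list of `structural_scale` objects (`name`, `k`, `table`
#'   mapping each of the `4^k` k-mers to a value).
#' @export
load_structural_scales <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "structural_scales.synthetic.tsv",
                        package = "pastree")
  }
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$scale), function(d) {
    k <- unique(d$k)
    stopifnot(length(k) == 1L, k %in% c(2L, 3L))
    if (nrow(d) != 4^k || anyDuplicated(d$kmer)) {
      stop("load_structural_scales: scale '", d$scale[1], "' must cover all ",
           4^k, " ", k, "-mers exactly once")
    }
    structure(list(name = d$scale[1], k = k,
                   table = setNames(d$value, d$kmer)),
              class = "structural_scale")
  })
  out[unique(tab$scale)]
}

#' Numeric structural profile of a DNA sequence
#'
#' Re-encodes a sequence via a k-mer conversion table: element `t` of the
#' result is `scale$table[seq[t..t+k-1]]`, giving `L - k + 1` values. In the
#' feature registry this is applied per 100-nt flank so no value spans the
#' hexamer or the flank junction; applied to the concatenated 200-nt flanks
#' it yields the `199`-value dinucleotide profile.
#'
#' @param seq An N-free DNA sequence.
#' @param scale A `structural_scale`.
#' @return Numeric vector of length `nchar(seq) - scale$k + 1`.
#' @export
structural_profile <- function(seq, scale) {
  stopifnot(inherits(scale, "structural_scale"))
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < scale$k) stop("structural_profile: sequence shorter than k")
  starts <- 1:(L - scale$k + 1L)
  kmers <- substring(seq, starts, starts + scale$k - 1L)
  v <- scale$table[kmers]
  if (anyNA(v)) {
    stop("structural_profile: k-mer '", kmers[which(is.na(v))[1]],
         "' absent from scale '", scale$name, "'")
  }
  unname(v)
}

#' Average a structural profile over 25-nt sub-sequences
#'
#' Each flank is divided into four 25-nt sub-sequences; the mean of the
#' profile values whose k-mer start position lies in each sub-sequence is one
#' feature, giving 4 upstream + 4 downstream = 8 features per scale, ordered
#' upstream 5'->3' then downstream 5'->3'.
#'
#' @param profiles List with per-flank numeric profiles `up` and `down`
#'   (as from [structural_profile()] on each 100-nt flank).
#' @param window Sub-sequence width (default 25 nt).
#' @return Named numeric vector of 8 values.
#' @export
window_average <- function(profiles, window = 25L) {
  stopifnot(is.list(profiles), !is.null(profiles$up), !is.null(profiles$down))
  one <- function(v, side) {
    w <- pmin(ceiling(seq_along(v) / window), 4L)
    m <- vapply(1:4, function(i) mean(v[w == i]), numeric(1))
    setNames(m, paste0(side, "_w", 1:4))
  }
  c(one(profiles$up, "up"), one(profiles$down, "down"))
}

#' The 218-name feature registry
#'
#' Fixed, versioned ordering of the feature vector: 2 weight-matrix scores,
#' 1 information-gain score, 8 top-position frequencies, 16 scales x 8
#' structural window averages, 8 flank mononucleotide frequencies, 32 flank
#' dinucleotide frequencies, 24 in-frame codon-position frequencies (frames
#' anchored at the hexamer edge), and 15 whole-window descriptors.
#'
#' @param scale_names Character vector of the 16 structural-scale names.
#' @return Character vector of 218 unique feature names.
#' @export
feature_registry <- function(scale_names) {
  stopifnot(length(scale_names) == 16L)
  nm <- c(
    "score_pas", "score_pseudo",
    "gain_score",
    paste0("topfreq_down_", .NT), paste0("topfreq_up_", .NT),
    as.vector(t(outer(scale_names, c(paste0("up_w", 1:4),
                                     paste0("down_w", 1:4)),
                      function(s, w) paste0("struct_", s, "_", w)))),
    paste0("mono_up_", .NT), paste0("mono_down_", .NT),
    paste0("di_up_", .DINUC), paste0("di_down_", .DINUC),
    as.vector(t(outer(paste0("codon_", c("up", "down")),
                      as.vector(t(outer(paste0("f", 1:3, "_"), .NT,
                                        paste0))),
                      paste, sep = "_"))),
    paste0("flank_", .NT),
    "gc_content", "at_content", "gc_skew", "at_skew",
    "mono_entropy", "di_entropy", "cpg_oe", "purine_fraction",
    "run_a", "run_t", "run_max")
  stopifnot(length(nm) == 218L, !anyDuplicated(nm))
  nm
}

#' Fit the training-dependent feature components
#'
#' Fits, on training data only: the two class dinucleotide weight matrices,
#' the positional information-gain profile, and the top-position selection;
#' bundles the structural scales and the registry version.
#'
#' @param train A `pas_dataset` (both classes present).
#' @param pseudocount Laplace smoothing for matrices and log-ratios.
#' @param n_top Positions per flank for the top-position features.
#' @param scales Structural scales (default: bundled set of 16).
#' @param gain_mode `"weighted"` or `"literal"`.
#' @return Object of class `pas_feature_model`.
#' @export
fit_feature_model <- function(train, pseudocount = 1, n_top = 20,
                              scales = load_structural_scales(),
                              gain_mode = "weighted") {
  train <- pas_dataset(train)
  is_true <- train$label == "true_pas"
  if (!any(is_true) || all(is_true)) {
    stop("fit_feature_model: training data must contain both classes")
  }
  wm_true <- fit_weight_matrix(train$seq[is_true], pseudocount)
  wm_pseudo <- fit_weight_matrix(train$seq[!is_true], pseudocount)
  gp <- fit_gain_profile(train$seq, train$label, mode = gain_mode,
                         pseudocount = pseudocount)
  top <- select_top_positions(gp, n_top, n_top)
  structure(list(registry_version = .REGISTRY_VERSION,
                 registry = feature_registry(names(scales)),
                 wm_true = wm_true, wm_pseudo = wm_pseudo,
                 gain_profile = gp, top_positions = top, scales = scales,
                 pseudocount = pseudocount),
            class = "pas_feature_model")
}

# longest run of a given character (or of any single character when
# char = NULL) within a string, not spanning outside it
.longest_run <- function(s, char = NULL) {
  r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
  keep <- if (is.null(char)) rep(TRUE, length(r$values)) else r$values == char
  if (!any(keep)) 0L else max(r$lengths[keep])
}

#' Extract the 218-value feature vector
#'
#' Deterministically maps each 206-nt sequence to the registry's 218 named
#' values using the fitted training-dependent components. Sequences
#' containing N are rejected.
#'
#' @param seqs Character vector of 206-nt sequences, or a `pas_dataset`.
#' @param model A fitted [fit_feature_model()].
#' @return Numeric matrix, one row per sequence, 218 named columns.
#' @export
extract_features <- function(seqs, model) {
  stopifnot(inherits(model, "pas_feature_model"))
  if (inherits(seqs, "pas_dataset")) seqs <- seqs$seq
  cm <- .code_matrix(seqs)
  if (ncol(cm) != .WINDOW_LEN) {
    stop("extract_features: sequences must be ", .WINDOW_LEN, " nt")
  }
  n <- nrow(cm)
  D <- .dinuc_codes(cm)
  up_cols <- 1:.FLANK_LEN
  down_cols <- (.HEX_TO + 1L):.WINDOW_LEN
  Dup <- D[, 1:(.FLANK_LEN - 1L), drop = FALSE]
  Ddown <- D[, (.HEX_TO + 1L):(.WINDOW_LEN - 1L), drop = FALSE]

  out <- matrix(NA_real_, n, length(model$registry),
                dimnames = list(NULL, model$registry))
  out[, "score_pas"] <- score_2mer(seqs, model$wm_true)
  out[, "score_pseudo"] <- score_2mer(seqs, model$wm_pseudo)
  out[, "gain_score"] <- gain_score(seqs, model$gain_profile)

  tf <- top_position_frequencies(seqs, model$top_positions)
  if (is.null(dim(tf))) tf <- matrix(tf, nrow = 1,
                                     dimnames = list(NULL, names(tf)))
  out[, colnames(tf)] <- tf

  # structural window averages, computed per flank
  T3 <- NULL
  for (sc in model$scales) {
    val <- sc$table[if (sc$k == 2) .DINUC else
      sort(names(sc$table))]  # lexicographic lookup vector
    if (sc$k == 2) {
      Vu <- matrix(val[Dup], n)
      Vd <- matrix(val[Ddown], n)
    } else {
      if (is.null(T3)) T3 <- .trinuc_codes(cm)
      Tu <- T3[, 1:(.FLANK_LEN - 2L), drop = FALSE]
      Td <- T3[, (.HEX_TO + 1L):(.WINDOW_LEN - 2L), drop = FALSE]
      Vu <- matrix(val[Tu], n)
      Vd <- matrix(val[Td], n)
    }
    wmeans <- function(V) {
      w <- pmin(ceiling(seq_len(ncol(V)) / 25L), 4L)
      matrix(vapply(1:4, function(i) rowMeans(V[, w == i, drop = FALSE]),
                    numeric(n)), nrow = n)
    }
    block <- cbind(wmeans(Vu), wmeans(Vd))
    colnames(block) <- paste0("struct_", sc$name, "_",
                              c(paste0("up_w", 1:4), paste0("down_w", 1:4)))
    out[, colnames(block)] <- block
  }

  freq4 <- function(cols) {
    matrix(vapply(1:4, function(k) rowMeans(cm[, cols, drop = FALSE] == k),
                  numeric(n)), nrow = n)
  }
  out[, paste0("mono_up_", .NT)] <- freq4(up_cols)
  out[, paste0("mono_down_", .NT)] <- freq4(down_cols)

  freq16 <- function(Dm) {
    matrix(vapply(1:16, function(k) rowMeans(Dm == k), numeric(n)),
           nrow = n)
  }
  out[, paste0("di_up_", .DINUC)] <- freq16(Dup)
  out[, paste0("di_down_", .DINUC)] <- freq16(Ddown)

  # in-frame codon-position frequencies, frames anchored at the hexamer edge
  up_frame <- ((.FLANK_LEN - up_cols) %% 3L) + 1L          # frame 1 adjoins hexamer
  down_frame <- ((down_cols - (.HEX_TO + 1L)) %% 3L) + 1L
  for (f in 1:3) {
    out[, paste0("codon_up_f", f, "_", .NT)] <-
      freq4(up_cols[up_frame == f])
    out[, paste0("codon_down_f", f, "_", .NT)] <-
      freq4(down_cols[down_frame == f])
  }

  # whole-window descriptors over the 200 flank nt (hexamer excluded)
  flank_cols <- c(up_cols, down_cols)
  fl <- freq4(flank_cols)
  out[, paste0("flank_", .NT)] <- fl
  fA <- fl[, 1]; fC <- fl[, 2]; fG <- fl[, 3]; fT <- fl[, 4]
  out[, "gc_content"] <- fG + fC
  out[, "at_content"] <- fA + fT
  out[, "gc_skew"] <- ifelse(fG + fC > 0, (fG - fC) / (fG + fC), 0)
  out[, "at_skew"] <- ifelse(fA + fT > 0, (fA - fT) / (fA + fT), 0)
  ent <- function(p) {
    q <- p
    q[q == 0] <- 1  # 0 log 0 = 0
    -rowSums(matrix(p * log2(q), nrow = n))
  }
  out[, "mono_entropy"] <- ent(fl)
  Dflank <- cbind(Dup, Ddown)
  difreq <- freq16(Dflank)
  out[, "di_entropy"] <- ent(difreq)
  fCG <- difreq[, match("CG", .DINUC)]
  out[, "cpg_oe"] <- ifelse(fC * fG > 0, fCG / (fC * fG), 0)
  out[, "purine_fraction"] <- fA + fG
  ups <- substr(seqs, 1L, .FLANK_LEN)
  dns <- substr(seqs, .HEX_TO + 1L, .WINDOW_LEN)
  out[, "run_a"] <- pmax(vapply(ups, .longest_run, 0L, char = "A"),
                         vapply(dns, .longest_run, 0L, char = "A"))
  out[, "run_t"] <- pmax(vapply(ups, .longest_run, 0L, char = "T"),
                         vapply(dns, .longest_run, 0L, char = "T"))
  out[, "run_max"] <- pmax(vapply(ups, .longest_run, 0L),
                           vapply(dns, .longest_run, 0L))
  out
}
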