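# Synthetic PAS/pseudo-PAS generator: per-position nucleotide profiles with
# a planted hexamer, a controllable positional signal and known ground truth
# (the enrichment band), so every pipeline stage is testable offline.

# downstream-element band: k-mer offsets +16..+41 after the hexamer end,
# i.e. 1-based window positions 122..147 (documented ground truth for
# position-recovery tests)
.DSE_BAND <- 122:147
.USE_BAND <- 76:100   # upstream element band adjoining the hexamer

#' Default synthetic nucleotide profiles
#'
#' Builds per-position nucleotide probabilities for a true-PAS class and a
#' pseudo-PAS class over the 200 flank positions (the hexamer, window
#' positions 101-106, is planted verbatim). The pseudo class is a mildly A/T
#' rich position-independent background. At `signal_strength = 1` the
#' `"strong"` template carries a pronounced T/GT-rich downstream element
#' band (window positions 122-147) and a T/C-rich upstream element band
#' (positions 76-100); the `"weak"` template instead spreads A enrichment
#' over the whole downstream flank and has a more variable (block-wise)
#' upstream composition. `signal_strength` in `[0, 1]` linearly interpolates
#' the true-class profile between the pseudo background (0: classes
#' exchangeable) and the template (1).
#'
#' @param kind `"strong"` or `"weak"`.
#' @param signal_strength Scalar in `[0, 1]`.
#' @param variant Planted hexamer (defaults: AATAAA for strong, AAGAAA for
#'   weak).
#' @return Object of class `synthetic_profile` with 4 x 206 probability
#'   matrices `p_true`/`p_pseudo` (hexamer columns `NA`), the `variant`,
#'   `signal_strength`, and the ground-truth `dse_band` positions.
#' @export
default_profiles <- function(kind = c("strong", "weak"), signal_strength,
                             variant = NULL) {
  kind <- match.arg(kind)
  stopifnot(signal_strength >= 0, signal_strength <= 1)
  if (is.null(variant)) variant <- if (kind == "strong") "AATAAA" else
    "AAGAAA"
  if (classify_variant(variant) == "unknown") {
    stop("default_profiles: '", variant, "' is not a recognised PAS variant")
  }
  L <- .WINDOW_LEN
  bg <- c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)
  p_pseudo <- matrix(bg, 4, L, dimnames = list(.NT, NULL))
  template <- matrix(c(A = 0.32, C = 0.18, G = 0.18, T = 0.32), 4, L,
                     dimnames = list(.NT, NULL))
  if (kind == "strong") {
    template[, .DSE_BAND] <- c(0.15, 0.10, 0.25, 0.50)   # T/GT-rich DSE
    template[, .USE_BAND] <- c(0.15, 0.25, 0.10, 0.50)   # T/C-rich USE
  } else {
    down <- (.HEX_TO + 1L):L
    template[, down] <- c(0.45, 0.15, 0.15, 0.25)        # A-rich downstream
    template[, .DSE_BAND] <- c(0.35, 0.10, 0.15, 0.40)   # milder T band
    template[, 1:50] <- c(0.25, 0.30, 0.20, 0.25)        # variable upstream
    template[, 51:100] <- c(0.35, 0.15, 0.20, 0.30)
  }
  p_true <- (1 - signal_strength) * p_pseudo + signal_strength * template
  hex <- .HEX_FROM:.HEX_TO
  p_true[, hex] <- NA_real_
  p_pseudo[, hex] <- NA_real_
  structure(list(variant = toupper(variant), p_true = p_true,
                 p_pseudo = p_pseudo, signal_strength = signal_strength,
                 kind = kind, dse_band = .DSE_BAND, use_band = .USE_BAND),
            class = "synthetic_profile")
}

.check_profile <- function(profile) {
  stopifnot(inherits(profile, "synthetic_profile"))
  for (m in list(profile$p_true, profile$p_pseudo)) {
    flank <- m[, setdiff(seq_len(ncol(m)), .HEX_FROM:.HEX_TO)]
    if (any(flank < 0) || any(abs(colSums(flank) - 1) > 1e-9)) {
      stop("synthetic profile: each position's probabilities must be a ",
           "distribution")
    }
  }
}

#' Generate a labeled synthetic variant dataset
#'
#' Draws flank nucleotides independently per position from the class profile
#' and plants the variant hexamer at window positions 101-106 (1-based) in
#' both classes. Deterministic for a fixed seed.
#'
#' @param profile A [default_profiles()] object (or hand-built profile of
#'   the same shape).
#' @param n_true,n_pseudo Class sizes.
#' @param seed Integer seed.
#' @return A balanced-checkable `variant_dataset` with
#'   `source = "synthetic"`.
#' @export
generate_dataset <- function(profile, n_true, n_pseudo, seed = 1L) {
  .check_profile(profile)
  stopifnot(n_true >= 0, n_pseudo >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  gen <- function(n, pm) {
    if (n == 0) return(character())
    m <- matrix("", n, .WINDOW_LEN)
    hex <- strsplit(profile$variant, "", fixed = TRUE)[[1]]
    for (p in seq_len(.WINDOW_LEN)) {
      if (p >= .HEX_FROM && p <= .HEX_TO) {
        m[, p] <- hex[p - .HEX_FROM + 1L]
      } else {
        m[, p] <- sample(.NT, n, replace = TRUE, prob = pm[, p])
      }
    }
    apply(m, 1, paste0, collapse = "")
  }
  true_seqs <- gen(n_true, profile$p_true)
  pseudo_seqs <- gen(n_pseudo, profile$p_pseudo)
  df <- data.frame(
    id = c(sprintf("true_%05d", seq_len(n_true)),
           sprintf("pseudo_%05d", seq_len(n_pseudo))),
    seq = c(true_seqs, pseudo_seqs),
    variant = profile$variant,
    label = rep(c("true_pas", "pseudo_pas"), c(n_true, n_pseudo)),
    source = "synthetic", stringsAsFactors = FALSE)
  variant_dataset(df)
}
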