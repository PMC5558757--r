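#' The 12 most common human PAS hexamer variants
#'
#' `AATAAA` and `ATTAAA` form the PAS-strong category; the ten rarer variants
#' form PAS-weak.
#'
#' @format Character vector of length 12.
#' @export
PAS_VARIANTS <- c("AATAAA", "ATTAAA", "AAGAAA", "AAAAAG", "AATACA", "TATAAA",
                  "ACTAAA", "AGTAAA", "GATAAA", "AATATA", "CATAAA", "AATAGA")

#' @rdname PAS_VARIANTS
#' @export
PAS_STRONG <- c("AATAAA", "ATTAAA")

#' @rdname PAS_VARIANTS
#' @export
PAS_WEAK <- setdiff(PAS_VARIANTS, PAS_STRONG)

#' Categorize a PAS hexamer as strong, weak or unknown
#'
#' @param hexamer Character vector of 6-letter DNA strings.
#' @return Character vector with values `"strong"`, `"weak"` or `"unknown"`.
#' @examples
#' classify_variant("AATAAA")  # "strong"
#' classify_variant("GATAAA")  # "weak"
#' @export
classify_variant <- function(hexamer) {
  hexamer <- toupper(as.character(hexamer))
  bad <- nchar(hexamer) != 6L
  if (any(bad)) {
    stop("classify_variant: hexamer must be a 6-letter string, got '",
         hexamer[bad][1], "'")
  }
  out <- rep("unknown", length(hexamer))
  out[hexamer %in% PAS_STRONG] <- "strong"
  out[hexamer %in% PAS_WEAK] <- "weak"
  out
}

# window geometry shared across the package (0-based conventions in docs;
# R-side code uses 1-based indexing internally)
.WINDOW_LEN <- 206L
.FLANK_LEN <- 100L
.HEX_FROM <- 101L   # 1-based start of hexamer within the window
.HEX_TO <- 106L
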