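# Sequence I/O: FASTA round-trip, PAS window extraction from a genome,
# polyA GTF parsing, pseudo-PAS sampling, BED export.

#' Construct a PAS dataset
#'
#' A PAS dataset is a `data.frame` (class `pas_dataset`) with one row per
#' 206-nt window: columns `id`, `seq`, `variant`, `label`
#' (`"true_pas"`/`"pseudo_pas"`), `chrom`, `strand`, `hexamer_start`
#' (0-based genomic coordinate of the leftmost hexamer base, or `NA`) and
#' `source` (`"benchmark"`, `"gencode"` or `"synthetic"`).
#'
#' Invariants enforced: every `seq` is 206 nt over `{A,C,G,T}` and carries its
#' `variant` at window positions 100-105 (0-based).
#'
#' @param df A data.frame with the columns above (missing provenance columns
#'   are filled with `NA`).
#' @return The validated `pas_dataset`.
#' @export
pas_dataset <- function(df) {
  stopifnot(is.data.frame(df))
  for (col in c("chrom", "strand", "hexamer_start", "source")) {
    if (is.null(df[[col]])) df[[col]] <- NA
  }
  if (is.null(df$id)) df$id <- sprintf("seq_%05d", seq_len(nrow(df)))
  need <- c("id", "seq", "variant", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pas_dataset: missing columns: ",
                         paste(miss, collapse = ", "))
  df$seq <- toupper(df$seq)
  df$variant <- toupper(df$variant)
  if (nrow(df)) {
    if (any(nchar(df$seq) != .WINDOW_LEN)) {
      stop("pas_dataset: all sequences must be ", .WINDOW_LEN, " nt")
    }
    if (any(grepl("[^ACGT]", df$seq))) {
      stop("pas_dataset: sequences must be over {A,C,G,T}")
    }
    hex <- substr(df$seq, .HEX_FROM, .HEX_TO)
    if (any(hex != df$variant)) {
      stop("pas_dataset: hexamer at window positions 100-105 must equal ",
           "the variant (first offending id: ",
           df$id[which(hex != df$variant)[1]], ")")
    }
    if (any(!df$label %in% c("true_pas", "pseudo_pas"))) {
      stop("pas_dataset: label must be 'true_pas' or 'pseudo_pas'")
    }
  }
  df <- df[, c(need, "chrom", "strand", "hexamer_start", "source"),
           drop = FALSE]
  class(df) <- c("pas_dataset", "data.frame")
  df
}

#' Build a single-variant dataset
#'
#' Wraps [pas_dataset()] and additionally checks that all records share one
#' hexamer variant; attaches `n_true`/`n_pseudo` counts as attributes.
#'
#' @param df A data.frame of records (see [pas_dataset()]).
#' @param balanced If `TRUE`, require `n_true == n_pseudo` as in the benchmark
#'   construction protocol.
#' @return A `pas_dataset` with attributes `variant`, `n_true`, `n_pseudo`.
#' @export
variant_dataset <- function(df, balanced = FALSE) {
  ds <- pas_dataset(df)
  v <- unique(ds$variant)
  if (length(v) != 1L) {
    stop("variant_dataset: records span multiple variants: ",
         paste(v, collapse = ", "))
  }
  n_true <- sum(ds$label == "true_pas")
  n_pseudo <- sum(ds$label == "pseudo_pas")
  if (balanced && n_true != n_pseudo) {
    stop("variant_dataset: protocol requires n_true == n_pseudo (got ",
         n_true, " vs ", n_pseudo, ")")
  }
  attr(ds, "variant") <- v
  attr(ds, "n_true") <- n_true
  attr(ds, "n_pseudo") <- n_pseudo
  ds
}

#' Read a FASTA file
#'
#' Light line-level validation (so format errors carry a line number) followed
#' by Biostrings parsing. Sequences are uppercased; order is preserved.
#'
#' @param path Path to a FASTA file over `{A,C,G,T,N}` (case-insensitive).
#' @return Named character vector of sequences (names = full header text
#'   after `>`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("read_fasta: empty FASTA file: ", path)
  first <- nonblank[1]
  if (!startsWith(lines[first], ">")) {
    stop("read_fasta: line ", first, ": expected FASTA header starting ",
         "with '>'")
  }
  bad <- nonblank[!startsWith(lines[nonblank], ">") &
                    grepl("[^ACGTNacgtn]", lines[nonblank])]
  if (length(bad)) {
    stop("read_fasta: line ", bad[1], ": sequence contains characters ",
         "outside {A,C,G,T,N}")
  }
  ss <- Biostrings::readBStringSet(path)
  if (anyDuplicated(names(ss)) == 0 && any(!nzchar(names(ss)))) {
    stop("read_fasta: empty FASTA header")
  }
  setNames(toupper(as.character(ss)), names(ss))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (names become headers).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("write_fasta: all sequences must be named")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Extract a 206-nt PAS window from a genome
#'
#' Returns the sense-strand window: 100 nt upstream, the 6-nt hexamer, 100 nt
#' downstream, in transcript orientation. `hexamer_start` is the 0-based
#' genomic coordinate of the leftmost hexamer base on the reference strand
#' (half-open convention), for both strands; for `strand = "-"` the genomic
#' segment is reverse-complemented so the hexamer reads in transcript
#' orientation at window positions 100-105.
#'
#' @param genome Named character vector (or list) mapping chromosome name to
#'   sequence.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param hexamer_start 0-based coordinate of the leftmost hexamer base.
#' @param allow_n Keep windows containing `N` (default rejects them: the
#'   feature formulas are defined over `{A,C,G,T}`).
#' @return The 206-nt window string.
#' @export
extract_pas_window <- function(genome, chrom, strand, hexamer_start,
                               allow_n = FALSE) {
  if (!chrom %in% names(genome)) {
    stop("extract_pas_window: unknown chromosome '", chrom, "'")
  }
  cs <- genome[[chrom]]
  len <- nchar(cs)
  if (!strand %in% c("+", "-")) stop("extract_pas_window: bad strand")
  start0 <- hexamer_start - .FLANK_LEN          # 0-based window start
  end0 <- hexamer_start + 6L + .FLANK_LEN       # 0-based half-open end
  if (start0 < 0L || end0 > len) {
    stop("extract_pas_window: window [", start0, ", ", end0,
         ") overruns contig '", chrom, "' of length ", len)
  }
  seg <- toupper(substr(cs, start0 + 1L, end0))
  if (strand == "-") seg <- .revcomp(seg)
  hex <- substr(seg, .HEX_FROM, .HEX_TO)
  if (grepl("N", hex, fixed = TRUE)) {
    stop("extract_pas_window: hexamer contains N at ", chrom, ":",
         hexamer_start)
  }
  if (!allow_n && grepl("[^ACGT]", seg)) {
    stop("extract_pas_window: window contains non-ACGT bases at ", chrom,
         ":", hexamer_start, " (set allow_n = TRUE to keep)")
  }
  seg
}

#' Parse polyA features from a GENCODE-style GTF
#'
#' GTF coordinates (1-based, inclusive) are converted to the package's
#' internal 0-based half-open convention on read.
#'
#' @param path GTF file path.
#' @param feature_kind Feature (column 3) to keep; default `"polyA_signal"`,
#'   the hexamer annotation itself.
#' @return `data.frame` with columns `chrom`, `strand`, `start`, `end`
#'   (0-based half-open). Empty (with a warning) when no line matches.
#' @export
parse_polya_gtf <- function(path, feature_kind = "polyA_signal") {
  if (!file.exists(path)) stop("parse_polya_gtf: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(nzchar(lines) & !startsWith(lines, "#"))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) {
      stop("parse_polya_gtf: line ", i, ": expected >= 8 tab-separated ",
           "fields, got ", length(f))
    }
    if (is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5])))) {
      stop("parse_polya_gtf: line ", i, ": non-numeric start/end")
    }
  }
  if (!length(body)) {
    warning("parse_polya_gtf: no feature lines in ", path)
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer()))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  keep <- as.character(gr$type) == feature_kind
  if (!any(keep)) {
    warning("parse_polya_gtf: no '", feature_kind, "' features in ", path)
  }
  gr <- gr[keep]
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr) - 1L,  # to 0-based half-open
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE)
}

# all eligible hexamer occurrences of `variant` on a chromosome sequence;
# returns data.frame(strand, hexamer_start) with full 100-nt flanks and no N
# anywhere in the window
.pseudo_candidates <- function(chrom_seq, variant, both_strands = TRUE) {
  cs <- toupper(chrom_seq)
  subject <- Biostrings::DNAString(cs)
  hits <- function(pattern, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject)
    st <- BiocGenerics::start(m) - 1L   # 0-based leftmost
    if (!length(st)) return(NULL)
    data.frame(strand = strand, hexamer_start = st)
  }
  cand <- hits(variant, "+")
  if (both_strands) cand <- rbind(cand, hits(.revcomp(variant), "-"))
  if (is.null(cand) || !nrow(cand)) {
    return(data.frame(strand = character(), hexamer_start = integer()))
  }
  len <- nchar(cs)
  ok <- cand$hexamer_start >= .FLANK_LEN &
    cand$hexamer_start + 6L + .FLANK_LEN <= len
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand)) {
    win <- substr(rep(cs, nrow(cand)),
                  cand$hexamer_start - .FLANK_LEN + 1L,
                  cand$hexamer_start + 6L + .FLANK_LEN)
    cand <- cand[!grepl("[^ACGT]", win), , drop = FALSE]
  }
  cand[order(cand$hexamer_start, cand$strand), , drop = FALSE]
}

#' Sample pseudo-PAS windows from a chromosome
#'
#' Scans both strands (by default) for occurrences of the variant hexamer with
#' full 100-nt N-free flanks, drops any occurrence whose hexamer coordinates
#' intersect the exclusion intervals (positional comparison, strand ignored),
#' then samples `n` without replacement. Deterministic for fixed seed and
#' inputs.
#'
#' @param chrom_seq Chromosome sequence (character scalar).
#' @param variant PAS hexamer to search for.
#' @param exclude `data.frame` with 0-based half-open `start`/`end` columns of
#'   true-PAS hexamer intervals to exclude (may be empty or `NULL`).
#' @param n Number of windows to sample.
#' @param seed Integer seed.
#' @param chrom Chromosome name recorded in the output.
#' @param both_strands Scan the minus strand too.
#' @return A `pas_dataset` of `n` pseudo-PAS records.
#' @export
sample_pseudo_pas <- function(chrom_seq, variant, exclude = NULL, n, seed,
                              chrom = "chr21", both_strands = TRUE) {
  variant <- toupper(variant)
  cand <- .pseudo_candidates(chrom_seq, variant, both_strands)
  if (!is.null(exclude) && nrow(cand) && NROW(exclude)) {
    q <- IRanges::IRanges(start = cand$hexamer_start + 1L, width = 6L)
    s <- IRanges::IRanges(start = exclude$start + 1L,
                          end = exclude$end)
    hit <- IRanges::overlapsAny(q, s)
    cand <- cand[!hit, , drop = FALSE]
  }
  if (nrow(cand) < n) {
    stop("sample_pseudo_pas: requested ", n, " windows but only ",
         nrow(cand), " eligible candidates")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  take <- sort(sample.int(nrow(cand), n))
  cand <- cand[take, , drop = FALSE]
  genome <- setNames(list(chrom_seq), chrom)
  seqs <- vapply(seq_len(nrow(cand)), function(i) {
    extract_pas_window(genome, chrom, cand$strand[i], cand$hexamer_start[i])
  }, character(1))
  pas_dataset(data.frame(
    id = sprintf("pseudo_%s_%s_%d", chrom, cand$strand, cand$hexamer_start),
    seq = seqs, variant = variant, label = "pseudo_pas", chrom = chrom,
    strand = cand$strand, hexamer_start = cand$hexamer_start,
    source = "benchmark", stringsAsFactors = FALSE))
}

# save/restore global RNG state so seeded helpers do not clobber callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Export PAS windows as BED6
#'
#' One line per record with genomic provenance: 0-based half-open window
#' coordinates, name = variant, score = 0, strand.
#'
#' @param ds A `pas_dataset` whose records carry `chrom`/`strand`/
#'   `hexamer_start`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ds, path) {
  ds <- pas_dataset(ds)
  if (any(is.na(ds$chrom) | is.na(ds$hexamer_start))) {
    stop("write_bed: records lack genomic provenance")
  }
  start <- ds$hexamer_start - .FLANK_LEN
  end <- ds$hexamer_start + 6L + .FLANK_LEN
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     ds$chrom, start, end, ds$variant, ds$strand), path)
  invisible(path)
}
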