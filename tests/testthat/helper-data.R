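# Shared fixtures, built in code. Expensive ones are memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# random ACGT string(s)
rand_seq <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
           collapse = "")
  }, character(1))
}

# a 206-nt window with a given hexamer planted at positions 101-106
toy_window <- function(variant = "AATAAA", seed = 1) {
  set.seed(seed)
  paste0(rand_seq(1, 100), variant, rand_seq(1, 100))
}

rand_pas_windows <- function(n, variant = "AATAAA", seed = 7) {
  set.seed(seed)
  paste0(rand_seq(n, 100), variant, rand_seq(n, 100))
}

# small strong-signal dataset + fitted feature model, reused across files
strong_ds <- function() memo("strong_ds", {
  generate_dataset(default_profiles("strong", 1), 120, 120, seed = 42)
})

strong_fm <- function() memo("strong_fm", fit_feature_model(strong_ds()))

strong_X <- function() memo("strong_X", {
  extract_features(strong_ds(), strong_fm())
})

# toy genome: one contig that is exactly one valid window plus padding
toy_genome <- function() {
  core <- paste0(strrep("A", 100), "AATAAA", strrep("C", 100))
  list(chrA = core,
       chrB = paste0(strrep("G", 20), core, strrep("T", 20)))
}

write_toy_gtf <- function(path, lines) {
  writeLines(lines, path)
  path
}

bench_table <- function() {
  read.delim(system.file("extdata", "benchmark_table.tsv",
                         package = "pastree"))
}
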