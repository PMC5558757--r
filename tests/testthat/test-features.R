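# features: weight matrices, entropies, gain, structural profiles, the 218
# registry, and normalization — each checked against brute-force oracles.

test_that("fit_weight_matrix counts dinucleotides per position", {
  wm <- fit_weight_matrix("AAA", pseudocount = 0)
  expect_equal(unname(wm$p["AA", 1]), 1)
  expect_equal(unname(wm$p["AA", 2]), 1)
  expect_equal(sum(wm$p), 2)

  wm2 <- fit_weight_matrix(c("AC", "AG"), pseudocount = 0)
  expect_equal(unname(wm2$p["AC", 1]), 0.5)
  expect_equal(unname(wm2$p["AG", 1]), 0.5)

  # column-sum oracle on random input with smoothing
  seqs <- rand_seq(100, 30, seed = 2)
  wm3 <- fit_weight_matrix(seqs, pseudocount = 1)
  expect_equal(colSums(wm3$p), rep(1, 29), tolerance = 1e-9)
  expect_true(all(wm3$p > 0))
  expect_error(fit_weight_matrix(character()), "empty")
  expect_error(fit_weight_matrix(c("AC", "ACG")), "same length")
})

test_that("score_2mer matches hand evaluation and brute force", {
  # uniform matrix scores 0 everywhere
  wmu <- fit_weight_matrix(rand_seq(1, 10, seed = 1))
  wmu$p[] <- 1 / 16
  expect_equal(score_2mer(rand_seq(1, 10, seed = 3), wmu), 0)

  # hand example: L = 3, p[AA, ] = 0.5, seq AAA -> 2 * log2(8) = 6
  wm <- fit_weight_matrix("AAA")
  wm$p[] <- 1 / 30
  wm$p["AA", ] <- 0.5
  expect_equal(score_2mer("AAA", wm), 6)
  # literal mode adds the constant 15 * log2(16) per position
  expect_equal(score_2mer("AAA", wm, mode = "literal"), 6 + 15 * 4 * 2)

  # additivity + brute-force oracle on 100 random instances
  set.seed(4)
  train <- rand_seq(30, 12)
  wmr <- fit_weight_matrix(train, pseudocount = 1)
  for (s in rand_seq(100, 12)) {
    di <- substring(s, 1:11, 2:12)
    oracle <- sum(log2(vapply(1:11, function(j) wmr$p[di[j], j], 0) /
                         (1 / 16)))
    expect_equal(score_2mer(s, wmr), oracle, tolerance = 1e-9)
  }
  # zero probability with pseudocount = 0 errors toward smoothing
  wm0 <- fit_weight_matrix(c("AAAA", "AAAA"), pseudocount = 0)
  expect_error(score_2mer("ACGT", wm0), "pseudocount")
})

test_that("positional_entropy matches the closed form", {
  expect_equal(positional_entropy(5, 5), 1)
  expect_equal(positional_entropy(0, 7), 0)
  expect_equal(positional_entropy(3, 1), 0.811278, tolerance = 1e-6)
  # brute-force oracle over 100 random count pairs
  set.seed(9)
  for (i in 1:100) {
    c1 <- sample(0:50, 1); c2 <- sample(0:50, 1)
    if (c1 + c2 == 0) c1 <- 1
    p <- c1 / (c1 + c2)
    oracle <- sum(ifelse(c(p, 1 - p) > 0,
                         -c(p, 1 - p) * log2(c(p, 1 - p)), 0))
    expect_equal(positional_entropy(c1, c2), oracle, tolerance = 1e-9)
  }
  expect_error(positional_entropy(0, 0), "undefined")
})

test_that("gain profile: zero for identical classes, 1 for perfect split", {
  # identical class-conditional distributions, balanced -> weighted gain 0
  seqs <- rand_seq(40, 206, seed = 6)
  seqs <- paste0(substr(seqs, 1, 100), "AATAAA", substr(seqs, 107, 206))
  gp0 <- fit_gain_profile(c(seqs, seqs),
                          rep(c("true_pas", "pseudo_pas"), each = 40))
  expect_equal(max(gp0$gain, na.rm = TRUE), 0, tolerance = 1e-12)

  # perfect split at one position
  tr <- paste0("A", substr(seqs, 2, 206))[1:20]
  ps <- paste0("T", substr(seqs, 2, 206))[21:40]
  gp1 <- fit_gain_profile(c(tr, ps), rep(c("true_pas", "pseudo_pas"),
                                         each = 20))
  expect_equal(gp1$gain[1], 1)
  # weighted gain is mutual information: non-negative everywhere
  expect_true(all(gp1$gain >= -1e-12, na.rm = TRUE))
  # hexamer positions excluded
  expect_true(all(is.na(gp1$gain[101:106])))
  expect_error(fit_gain_profile(tr, rep("true_pas", 20)), "both classes")
})

test_that("weighted gain matches a brute-force oracle; argmax recovered", {
  set.seed(13)
  n <- 100
  base <- rand_seq(2 * n, 206)
  base <- paste0(substr(base, 1, 100), "AATAAA", substr(base, 107, 206))
  # plant an informative position: true-PAS strongly prefers G at 150
  planted <- 150
  tr <- base[1:n]
  idx <- runif(n) < 0.9
  substr(tr[idx], planted, planted) <- "G"
  ps <- base[(n + 1):(2 * n)]
  substr(ps, planted, planted) <- sample(c("A", "T"), n, replace = TRUE)
  labels <- rep(c("true_pas", "pseudo_pas"), each = n)
  gp <- fit_gain_profile(c(tr, ps), labels)
  expect_identical(which.max(gp$gain), as.integer(planted))

  # brute-force oracle at 20 random positions
  cmat <- do.call(rbind, strsplit(c(tr, ps), ""))
  is_true <- labels == "true_pas"
  for (p in sample(setdiff(1:206, 101:106), 20)) {
    EP <- positional_entropy(n, n)
    acc <- 0
    for (x in c("A", "C", "G", "T")) {
      c1 <- sum(cmat[is_true, p] == x)
      c2 <- sum(cmat[!is_true, p] == x)
      if (c1 + c2 > 0) {
        acc <- acc + (c1 + c2) / (2 * n) * positional_entropy(c1, c2)
      }
    }
    expect_equal(gp$gain[p], EP - acc, tolerance = 1e-9)
  }
  # literal mode reproduces the printed (unweighted) sum
  gpl <- fit_gain_profile(c(tr, ps), labels, mode = "literal")
  p0 <- setdiff(1:206, 101:106)[1]
  acc <- 0
  for (x in c("A", "C", "G", "T")) {
    c1 <- sum(cmat[is_true, p0] == x)
    c2 <- sum(cmat[!is_true, p0] == x)
    if (c1 + c2 > 0) acc <- acc + positional_entropy(c1, c2)
  }
  expect_equal(gpl$gain[p0], positional_entropy(n, n) - acc,
               tolerance = 1e-9)
})

test_that("gain_score separates classes and is zero for a flat profile", {
  ds <- strong_ds()
  gp <- fit_gain_profile(ds)
  flat <- gp
  flat$gain[!is.na(flat$gain)] <- 0
  expect_equal(gain_score(ds$seq[1], flat), 0)
  # held-out Monte-Carlo check against the generator's ground truth
  held <- generate_dataset(default_profiles("strong", 1), 200, 200,
                           seed = 77)
  sc <- gain_score(held$seq, gp)
  expect_gt(mean(sc[held$label == "true_pas"]),
            mean(sc[held$label == "pseudo_pas"]))
})

test_that("select_top_positions obeys tie-breaks and a full-sort oracle", {
  ds <- strong_ds()
  gp <- fit_gain_profile(ds)
  # spike
  gp1 <- gp
  gp1$gain[!is.na(gp1$gain)] <- 0
  gp1$gain[37] <- 0.5
  expect_identical(select_top_positions(gp1, n_up = 1)$up, 37L)
  # all equal -> smallest indices
  gp2 <- gp
  gp2$gain[!is.na(gp2$gain)] <- 0.25
  expect_identical(select_top_positions(gp2, n_up = 2)$up, c(1L, 2L))
  expect_identical(select_top_positions(gp2, n_down = 3)$down,
                   c(107L, 108L, 109L))
  # random profile matches brute-force sort
  set.seed(21)
  gp3 <- gp
  gp3$gain[1:100] <- runif(100)
  gp3$gain[107:206] <- runif(100)
  top <- select_top_positions(gp3, 20, 20)
  oracle_up <- order(-gp3$gain[1:100], 1:100)[1:20]
  oracle_down <- (107:206)[order(-gp3$gain[107:206], 1:100)[1:20]]
  expect_identical(top$up, as.integer(oracle_up))
  expect_identical(top$down, as.integer(oracle_down))
  expect_error(select_top_positions(gp, n_up = 101), "exceeds")
})

test_that("top_position_frequencies counts correctly", {
  s <- paste0(strrep("A", 100), "AATAAA", strrep("A", 100))
  pos <- list(up = 1:20, down = 107:126)
  tf <- top_position_frequencies(s, pos)
  expect_equal(unname(tf[c("topfreq_down_A", "topfreq_up_A")]), c(1, 1))
  expect_equal(sum(tf[1:4]), 1)
  expect_equal(sum(tf[5:8]), 1)
  # 10 A + 10 T upstream
  s2 <- paste0(strrep("A", 10), strrep("T", 10), strrep("C", 80),
               "AATAAA", strrep("G", 100))
  tf2 <- top_position_frequencies(s2, pos)
  expect_equal(unname(tf2[c("topfreq_up_A", "topfreq_up_T")]), c(0.5, 0.5))
  # counting oracle on a random case
  s3 <- toy_window(seed = 12)
  set.seed(3)
  pos3 <- list(up = sort(sample(1:100, 20)),
               down = sort(sample(107:206, 20)))
  tf3 <- top_position_frequencies(s3, pos3)
  ch <- strsplit(s3, "")[[1]]
  for (i in seq_along(c("A", "C", "G", "T"))) {
    nt <- c("A", "C", "G", "T")[i]
    expect_equal(unname(tf3[paste0("topfreq_down_", nt)]),
                 mean(ch[pos3$down] == nt))
    expect_equal(unname(tf3[paste0("topfreq_up_", nt)]),
                 mean(ch[pos3$up] == nt))
  }
  expect_error(top_position_frequencies(s3, list(up = 0:19, down = pos3$down)),
               "out of range")
})

test_that("structural profiles and window averages match slicing oracles", {
  scales <- load_structural_scales()
  expect_length(scales, 16L)
  expect_setequal(vapply(scales, `[[`, 0L, "k"), c(2L, 3L))

  const <- scales[[1]]
  const$table[] <- 3.5
  flank <- rand_seq(1, 100, seed = 5)
  expect_equal(structural_profile(flank, const), rep(3.5, 99))
  # k = 2 on a 100-nt flank -> 99 values; on 200 nt -> 199
  di <- scales[[which(vapply(scales, `[[`, 0L, "k") == 2)[1]]]
  expect_length(structural_profile(flank, di), 99L)
  expect_length(structural_profile(strrep("ACGT", 50), di), 199L)
  # alternating lookup pattern
  alt <- di
  alt$table[] <- 0
  alt$table["AC"] <- 1
  alt$table["CA"] <- 2
  expect_equal(structural_profile(strrep("AC", 5), alt),
               rep(c(1, 2), length.out = 9))

  # window averages: constant in -> constant out, 8 values
  wa <- window_average(list(up = rep(2, 99), down = rep(2, 99)))
  expect_length(wa, 8L)
  expect_equal(unname(wa), rep(2, 8))
  # linear profile vs explicit slices (k = 2 and k = 3 geometries)
  for (len in c(99, 98)) {
    v <- seq_len(len) / 10
    wa2 <- window_average(list(up = v, down = rev(v)))
    slices <- list(1:25, 26:50, 51:75, 76:len)
    expect_equal(unname(wa2),
                 c(vapply(slices, function(s) mean(v[s]), 0),
                   vapply(slices, function(s) mean(rev(v)[s]), 0)),
                 tolerance = 1e-12)
  }
})

test_that("the registry emits exactly 218 stable, finite features", {
  X <- strong_X()
  expect_identical(ncol(X), 218L)
  expect_true(all(is.finite(X)))
  expect_false(anyDuplicated(colnames(X)) > 0)
  # registry sub-block audit: 128 structural + 2 + 1 + 8 + 79 compositional
  nm <- colnames(X)
  expect_identical(sum(startsWith(nm, "struct_")), 128L)
  expect_identical(sum(nm %in% c("score_pas", "score_pseudo")), 2L)
  expect_identical(sum(nm == "gain_score"), 1L)
  expect_identical(sum(startsWith(nm, "topfreq_")), 8L)
  expect_identical(218L - 128L - 2L - 1L - 8L, 79L)
  # determinism
  X2 <- extract_features(strong_ds()$seq[1:5], strong_fm())
  expect_identical(X2, X[1:5, ])
  # N rejected
  bad <- paste0("N", substr(strong_ds()$seq[1], 2, 206))
  expect_error(extract_features(bad, strong_fm()), "\\{A,C,G,T\\}")
})

test_that("compositional blocks sum to one and match direct counting", {
  X <- strong_X()
  for (block in list(paste0("mono_up_", c("A", "C", "G", "T")),
                     paste0("mono_down_", c("A", "C", "G", "T")),
                     paste0("flank_", c("A", "C", "G", "T")))) {
    expect_equal(unname(rowSums(X[, block])), rep(1, nrow(X)),
                 tolerance = 1e-9)
  }
  di_up <- grep("^di_up_", colnames(X), value = TRUE)
  di_down <- grep("^di_down_", colnames(X), value = TRUE)
  expect_length(di_up, 16L)
  expect_equal(unname(rowSums(X[, di_up])), rep(1, nrow(X)),
               tolerance = 1e-9)
  expect_equal(unname(rowSums(X[, di_down])), rep(1, nrow(X)),
               tolerance = 1e-9)
  # codon-frame 4-tuples sum to 1
  for (f in 1:3) {
    for (side in c("up", "down")) {
      blk <- paste0("codon_", side, "_f", f, "_", c("A", "C", "G", "T"))
      expect_equal(unname(rowSums(X[, blk])), rep(1, nrow(X)),
                   tolerance = 1e-9)
    }
  }
  # direct-count oracle on one sequence
  s <- strong_ds()$seq[7]
  up <- strsplit(substr(s, 1, 100), "")[[1]]
  expect_equal(unname(X[7, "mono_up_G"]), mean(up == "G"))
  dn <- substr(s, 107, 206)
  dn_di <- substring(dn, 1:99, 2:100)
  expect_equal(unname(X[7, "di_down_TT"]), mean(dn_di == "TT"))
  # longest run oracle
  runs <- function(x, ch) {
    r <- rle(strsplit(x, "")[[1]])
    m <- r$lengths[r$values == ch]
    if (length(m)) max(m) else 0
  }
  expect_equal(unname(X[7, "run_a"]),
               max(runs(substr(s, 1, 100), "A"), runs(dn, "A")))
})

test_that("PAS-score margin separates held-out synthetic classes", {
  fm <- strong_fm()
  held <- generate_dataset(default_profiles("strong", 1), 150, 150,
                           seed = 99)
  Xh <- extract_features(held, fm)
  margin <- Xh[, "score_pas"] - Xh[, "score_pseudo"]
  expect_gt(mean(margin[held$label == "true_pas"]),
            mean(margin[held$label == "pseudo_pas"]))
})

test_that("normalization maps training extremes to [-1, 1] midpoint to 0", {
  X <- matrix(c(0, 5, 10, 2, 2, 2), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  expect_warning(np <- fit_normalization(X), "constant")
  Xn <- apply_normalization(X, np)
  expect_equal(unname(Xn[, "a"]), c(-1, 0, 1))
  expect_equal(unname(Xn[, "b"]), c(0, 0, 0))
  # brute-force oracle on random matrices, plus out-of-range test rows
  set.seed(17)
  for (i in 1:20) {
    M <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, letters[1:5]))
    np2 <- fit_normalization(M)
    Mn <- apply_normalization(M, np2)
    oracle <- sapply(1:5, function(j) {
      (M[, j] - (max(M[, j]) + min(M[, j])) / 2) /
        ((max(M[, j]) - min(M[, j])) / 2)
    })
    expect_equal(unname(Mn), oracle, tolerance = 1e-12)
    expect_true(all(Mn >= -1 - 1e-12 & Mn <= 1 + 1e-12))
    out <- apply_normalization(M[1, ] + 100, np2)
    expect_true(all(out > 1))
  }
})
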