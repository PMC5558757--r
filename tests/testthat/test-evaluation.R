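# CV splits, weak pooling, metrics, and the experiment driver

toy_records <- function(n_true = 50, n_pseudo = 50, variant = "AATAAA",
                        seed = 1, prefix = "r") {
  ds <- generate_dataset(default_profiles(
    if (classify_variant(variant) == "strong") "strong" else "weak",
    0.5, variant = variant), n_true, n_pseudo, seed = seed)
  ds$id <- paste0(prefix, "_", ds$id)
  pas_dataset(ds)
}

test_that("make_cv_splits partitions, stratifies and sizes the holdout", {
  rec <- toy_records(50, 50, seed = 2)
  sp <- make_cv_splits(rec, k = 5, val_frac = 0.15, seed = 3)
  # each test fold has 20 records; union is the dataset with no duplicates
  test_ids <- unlist(lapply(sp$folds, `[[`, "test"))
  expect_identical(sort(test_ids), sort(rec$id))
  for (f in sp$folds) {
    expect_length(f$test, 20L)
    # validation = floor(0.15 * 40) per class = 6 + 6
    expect_length(f$validation, 12L)
    expect_length(intersect(f$train, f$test), 0L)
    expect_length(intersect(f$validation, f$test), 0L)
    expect_length(intersect(f$train, f$validation), 0L)
    # stratification of the test fold
    labs <- rec$label[match(f$test, rec$id)]
    expect_identical(sum(labs == "true_pas"), 10L)
  }
  # determinism
  sp2 <- make_cv_splits(rec, k = 5, val_frac = 0.15, seed = 3)
  expect_identical(sp, sp2)
  expect_error(make_cv_splits(rec[c(1:4, 51:54), ], k = 5), "at least k")
})

test_that("pool_weak_training follows the pooled-fold construction", {
  # toy arithmetic: target 10 records (8 train / 2 test), nine others x 5
  target <- toy_records(5, 5, variant = "AAGAAA", seed = 4, prefix = "t")
  others <- setdiff(PAS_WEAK, "AAGAAA")
  datasets <- c(list(AAGAAA = target),
                setNames(lapply(seq_along(others), function(i)
                  toy_records(3, 2, variant = others[i], seed = 10 + i,
                              prefix = paste0("o", i))), others))
  sp <- make_cv_splits(target, k = 5, val_frac = 0, seed = 1)
  pool <- pool_weak_training("AAGAAA", 1, datasets, sp)
  expect_identical(nrow(pool$records), 8L + 9L * 5L)  # 53
  expect_length(intersect(pool$records$id, pool$test_ids), 0L)
  # test ids are target-variant records only
  expect_true(all(pool$test_ids %in% target$id))
  expect_error(pool_weak_training("AATAAA", 1, datasets, sp),
               "PAS-weak")
})

test_that("pooled size arithmetic reproduces the published-table case", {
  # With the published per-variant sizes, the AAGAAA pooled training set is
  # its 80% fold-training portion (1000) plus all records of the other nine
  # weak variants (5900) = 6900.
  b <- bench_table()
  weak <- b[b$variant %in% PAS_WEAK, ]
  target_size <- weak$size[weak$variant == "AAGAAA"]
  expect_identical(target_size, 1250L)
  others_total <- sum(weak$size) - target_size
  expect_identical(others_total, 5900L)
  expect_identical(0.8 * target_size + others_total, 6900)
  # same number from the pooling routine on synthetic stand-in datasets of
  # the published sizes (scaled 1:5 to keep runtime down: every class count
  # stays integral and the target stays divisible by k, so the pooled size
  # is exactly 6900 / 5 = 1380)
  datasets <- setNames(lapply(seq_len(nrow(weak)), function(i) {
    n <- weak$size[i] / 5
    toy_records(n / 2, n / 2, variant = weak$variant[i], seed = i,
                prefix = paste0("v", i))
  }), weak$variant)
  sp <- make_cv_splits(datasets$AAGAAA, k = 5, val_frac = 0, seed = 2)
  pool <- pool_weak_training("AAGAAA", 3, datasets, sp)
  expect_identical(nrow(pool$records), 1380L)
})

test_that("error metrics match their formulas", {
  expect_equal(error_rate(10, 10, 0, 0), 0)
  expect_equal(error_rate(0, 0, 10, 10), 1)
  expect_equal(error_rate(8, 6, 4, 2), 0.3)
  # error + accuracy = 1 exactly, on 100 random confusion matrices
  set.seed(6)
  for (i in 1:100) {
    cm <- sample(0:30, 4, replace = TRUE)
    if (sum(cm) == 0) cm[1] <- 1
    er <- error_rate(cm[1], cm[2], cm[3], cm[4])
    acc <- (cm[1] + cm[2]) / sum(cm)
    expect_identical(er + acc, 1)
  }
  expect_error(error_rate(0, 0, 0, 0), "zero total")
  r <- eval_report(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_identical(r$TP, 1L)
  expect_identical(r$FN, 1L)
  expect_identical(r$FP, 1L)
  expect_equal(r$fpr, 0.5)
  expect_equal(r$fnr, 0.5)
})

test_that("weighted_average matches the published-table oracle", {
  expect_equal(weighted_average(c(2, 4), c(1, 1)), 3)       # plain mean
  expect_equal(weighted_average(5, 7), 5)                   # identity
  b <- bench_table()
  expect_equal(round(weighted_average(b$dps_error, b$size), 2), 19.25)
  # bounded by min and max of inputs
  set.seed(8)
  for (i in 1:50) {
    v <- runif(6); s <- runif(6, 1, 10)
    w <- weighted_average(v, s)
    expect_gte(w, min(v))
    expect_lte(w, max(v))
  }
  expect_error(weighted_average(1:3, 1:2), "mismatch")
})

test_that("fold preparation is leak-free: test rows never touch fitting", {
  rec <- toy_records(40, 40, seed = 5)
  sp <- make_cv_splits(rec, k = 4, val_frac = 0.15, seed = 1)
  f <- sp$folds[[1]]
  fit_fingerprint <- function(records) {
    train <- records[records$id %in% f$train, ]
    fm <- fit_feature_model(pas_dataset(train))
    nm <- suppressWarnings(fit_normalization(
      extract_features(train$seq, fm)))
    list(wm = fm$wm_true$p, gain = fm$gain_profile$gain,
         top = fm$top_positions, min = nm$min, max = nm$max)
  }
  base <- fit_fingerprint(rec)
  # mutate every test-fold sequence; fitted components must be identical
  mutated <- rec
  ti <- mutated$id %in% f$test
  mutated$seq[ti] <- paste0(strrep("G", 100), mutated$variant[ti],
                            strrep("C", 100))
  expect_identical(fit_fingerprint(mutated), base)
})

test_that("run_experiment is deterministic and near-chance on null data", {
  # label-permuted (signal_strength = 0) data: error about 0.5
  ds <- generate_dataset(default_profiles("strong", 0), 60, 60, seed = 12)
  cheap <- ga_config(population_size = 4, generations = 1, seed = 5)
  tcfg <- omni_tree_config(max_depth = 1, min_node_size = 20)
  e1 <- run_experiment(ds, "per-variant", cheap, tcfg, k = 3, seed = 2)
  e2 <- run_experiment(ds, "per-variant", cheap, tcfg, k = 3, seed = 2)
  expect_identical(experiment_table(e1), experiment_table(e2))
  expect_gt(e1$weighted_error, 0.3)
  expect_lt(e1$weighted_error, 0.7)
  tab <- experiment_table(e1)
  expect_identical(tab$variant, c("AATAAA", "Average"))
})
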