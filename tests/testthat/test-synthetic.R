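test_that("the outlier mechanism puts one feature outside the training range", {
  cfg <- synthetic_config(n_features = 8, n_normal = 100, n_anomalous = 40,
                          anomaly_mechanism = "outlier",
                          anomaly_magnitude = 0.5, seed = 11)
  sp <- generate_synthetic(cfg)
  feats <- setdiff(names(sp$train_normal), "class")
  Xtr <- as.matrix(sp$train_normal[feats])
  lo <- apply(Xtr, 2, min)
  hi <- apply(Xtr, 2, max)
  Xa <- as.matrix(sp$test_anomalous[feats])
  out_of_range <- t(Xa) < lo | t(Xa) > hi
  expect_true(all(colSums(out_of_range) >= 1))
})

test_that("zero magnitude outliers stay within the training range", {
  cfg <- synthetic_config(n_features = 8, n_normal = 100, n_anomalous = 40,
                          anomaly_mechanism = "outlier",
                          anomaly_magnitude = 0, seed = 11)
  sp <- generate_synthetic(cfg)
  feats <- setdiff(names(sp$train_normal), "class")
  m <- fit_mapper(sp$train_normal, label = "class")
  # the planted feature sits exactly on the range boundary, so anomalous
  # samples are indistinguishable from fresh normal draws by range counts
  cn <- cfadetect:::rare_signal_counts(m, as.matrix(sp$test_normal[feats]), 0)
  ca <- cfadetect:::rare_signal_counts(m, as.matrix(sp$test_anomalous[feats]), 0)
  expect_lt(abs(mean(ca) - mean(cn)), 0.35)
})

test_that("broken combinations preserve marginals while decorrelating pairs", {
  cfg <- synthetic_config(n_features = 10, n_normal = 600, n_anomalous = 600,
                          anomaly_mechanism = "broken_combination",
                          rho = 0.9, seed = 13)
  sp <- generate_synthetic(cfg)
  feats <- setdiff(names(sp$train_normal), "class")
  Xn <- as.matrix(dplyr::bind_rows(sp$train_normal, sp$test_normal)[feats])
  Xa <- as.matrix(sp$test_anomalous[feats])
  # marginals agree (two-sample KS on every feature)
  for (j in seq_len(ncol(Xn))) {
    ks <- suppressWarnings(stats::ks.test(Xn[, j], Xa[, j]))
    expect_lt(unname(ks$statistic), 0.12)
  }
  # pair correlation strong in the normal data, near zero after decoupling
  for (k in seq_len(nrow(cfg$correlated_pairs))) {
    a <- cfg$correlated_pairs[k, 1]
    b <- cfg$correlated_pairs[k, 2]
    expect_gt(cor(Xn[, a], Xn[, b], method = "spearman"), 0.7)
    expect_lt(abs(cor(Xa[, a], Xa[, b], method = "spearman")), 0.2)
  }
})

test_that("excess absence shifts several features into their tails at once", {
  cfg <- synthetic_config(n_features = 12, n_normal = 400, n_anomalous = 100,
                          anomaly_mechanism = "excess_absence", seed = 17)
  sp <- generate_synthetic(cfg)
  feats <- setdiff(names(sp$train_normal), "class")
  m <- fit_mapper(sp$train_normal, label = "class")
  in_tail <- function(X) {
    Fm <- cfadetect:::mapper_cdf(m, as.matrix(X[feats]))
    rowSums(Fm < 0.03 | Fm > 0.97)
  }
  # anomalous samples carry clearly more simultaneous tail features
  expect_gt(mean(in_tail(sp$test_anomalous)), mean(in_tail(sp$test_normal)) + 1.5)
})

test_that("generation is seed-deterministic and splits are disjoint", {
  cfg <- synthetic_config(n_features = 6, n_normal = 50, n_anomalous = 20,
                          seed = 3)
  a <- generate_synthetic(cfg)
  b <- generate_synthetic(cfg)
  expect_identical(a$train_normal, b$train_normal)
  expect_identical(a$test_anomalous, b$test_anomalous)
  expect_equal(nrow(a$train_normal) + nrow(a$test_normal), cfg$n_normal)
  expect_error(synthetic_config(n_features = 4, correlated_pairs = list(c(1, 9))),
               "exceeds")
})
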