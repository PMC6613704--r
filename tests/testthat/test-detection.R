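# one small trained repertoire shared across the detection tests
local_rep <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) {
      base <- tiny_population(n_features = 10, C = 10, seed = 21)
      tp <- training_params("AIS", W_tau = 1000, T_S = 100, t_max = 300,
                            tau_target = 150, seed = 21)
      rep <- build_repertoire(base$pop, base$split$train_normal, tp,
                              N_pop = 2, label = "class")
      fx <<- list(split = base$split, mapper = base$mapper, rep = rep)
    }
    fx
  }
})

test_that("detection parameters are validated", {
  expect_error(detection_params(tau_A = 1), "at least 2")
  expect_error(detection_params(f = 0), "f must")
  expect_error(detection_params(fpr = 1), "fpr")
  expect_equal(detection_params()$tau_A, 5L)
  expect_equal(detection_params()$tau_act, 5L)
  expect_equal(detection_params(tau_A = 8)$tau_act, 8L)
})

test_that("monitoring yields survival counts bounded by the anergy time", {
  fx <- local_rep()
  dp <- detection_params(W_d = 800, tau_A = 5, seed = 1)
  x <- as.numeric(as.matrix(fx$split$test_normal[1, 1:10]))
  set.seed(1)
  cc <- monitor(fx$rep, x, dp)
  expect_equal(dim(cc$c_p), c(10, 6))
  for (i in 1:10) expect_true(all(diff(cc$c_p[i, ]) <= 0))
  expect_true(all(cc$c_p[, 1] >= cc$c_p[, 6]))
  expect_true(any(cc$c_p[, 1] > 0))
})

test_that("calibration thresholds follow the descending-quantile convention", {
  fx <- local_rep()
  dp <- detection_params(W_d = 600, tau_A = 5, f = 0.1, seed = 2)
  th <- calibrate(fx$rep, fx$split$train_normal[1:10, ], dp, label = "class")
  expect_equal(th$N_c, 10)
  # f = 0.1, N_c = 10 -> x = 1 -> threshold is the per-presenter maximum
  expect_equal(th$n_tilde, apply(th$c_tilde, 2, max))
  dp1 <- detection_params(W_d = 600, tau_A = 5, f = 1, seed = 2)
  th1 <- calibrate(fx$rep, fx$split$train_normal[1:10, ], dp1, label = "class")
  expect_equal(th1$n_tilde, apply(th1$c_tilde, 2, min))
  expect_true(all(th$n_tilde >= 0 & th$n_tilde <= 1))
  expect_error(calibrate(fx$rep, fx$split$train_normal[0, ], dp,
                         label = "class"), "empty")
})

test_that("the response is the positive part sum of threshold exceedances", {
  expect_equal(response(c(0.5, 0.2), c(0.3, 0.4)), 0.2)
  expect_equal(response(c(0.1, 0.2), c(0.3, 0.4)), 0)
  # nondecreasing in every survival fraction
  base <- response(c(0.5, 0.5), c(0.3, 0.3))
  expect_gte(response(c(0.6, 0.5), c(0.3, 0.3)), base)
  expect_error(response(c(0.1, 0.2, 0.3), c(0.1, 0.2)), "different presenter")
})

test_that("tpr_at_fpr uses the x-th largest normal response, strictly", {
  expect_equal(tpr_at_fpr(1:10, c(11, 12, 5), fpr = 0.1), 2 / 3)
  expect_equal(tpr_at_fpr(1:10, c(1, 2), fpr = 0.1), 0)
  expect_equal(tpr_at_fpr(rep(1, 5), rep(1, 5), fpr = 0.2), 0) # ties not above
  expect_error(tpr_at_fpr(numeric(0), 1), "non-empty")
  # exchangeable responses give TPR about equal to FPR
  set.seed(5)
  r <- rnorm(400)
  expect_lt(abs(tpr_at_fpr(r[1:200], r[201:400], 0.2) - 0.2), 0.1)
})

test_that("roc curves are monotone with the right boundaries", {
  set.seed(6)
  rn <- rnorm(100)
  ra <- rnorm(100, mean = 2)
  roc <- roc_curve(rn, ra, fpr_grid = seq(0.05, 1, by = 0.05))
  expect_true(all(diff(roc$tpr) >= 0))
  sep <- roc_curve(1:50, 101:150, fpr_grid = c(0.1, 0.5, 1))
  expect_true(all(sep$tpr == 1))
  # FPR = 1: anomalous responses strictly above the minimum normal response
  expect_equal(tpr_at_fpr(c(0, 1, 2), c(0.5, -1), fpr = 1), 0.5)
})

test_that("rare-signal counting baselines behave by construction", {
  fx <- local_rep()
  sp <- fx$split
  bl <- baseline_rare_count(fx$mapper, sp, tail = 0)
  # normal test samples can exceed the training range only occasionally
  expect_lt(mean(bl$normal_counts), 2)
  # an injected out-of-range value raises the count by at least one
  sp2 <- sp
  feats <- setdiff(names(sp$test_anomalous), "class")
  sp2$test_anomalous[1, feats[3]] <- max(fx$mapper$x_max) + 10
  bl2 <- baseline_rare_count(fx$mapper, sp2, tail = 0)
  expect_gte(bl2$anomalous_counts[1], max(1, bl$anomalous_counts[1]))
  expect_true(bl$tpr >= 0 && bl$tpr <= 1)

  # IList-based counting with v_max = 0 sees no rare signal in-range
  set.seed(31)
  pop0 <- build_population(fx$mapper, C = 10, v_max = 0)
  rep0 <- list(population = pop0, ilists = list(pop0$ranks), N_pop = 1,
               params = training_params("AIS"))
  class(rep0) <- "cfa_repertoire"
  bl0 <- baseline_ilists_rare_count(rep0, sp)
  in_range <- bl0$normal_counts[cfadetect:::rare_signal_counts(
    fx$mapper, as.matrix(sp$test_normal[feats]), 0) == 0]
  expect_true(all(in_range == 0))
})
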