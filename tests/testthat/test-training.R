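test_that("negative-selection education permutes only the educable region", {
  ilist <- letters[1:8]
  set.seed(1)
  out <- educate_is(ilist, n_frozen = 3)
  expect_setequal(out[1:5], letters[1:5])
  expect_identical(out[6:8], letters[6:8])
  # over many calls every educable token reaches rank 1 about equally often
  set.seed(2)
  tops <- table(replicate(600, educate_is(letters[1:6])[1]))
  expect_gt(stats::chisq.test(tops)$p.value, 0.001)
})

test_that("targeted-swap education pushes the partner token strictly down", {
  expect_identical(educate_ais(c("a", "b", "c", "d"), "b", p = 4),
                   c("a", "d", "c", "b"))
  # involution: swapping the displaced token back restores the list
  once <- educate_ais(letters[1:6], "b", p = 5)
  expect_identical(educate_ais(once, once[2], p = 5), letters[1:6])
  set.seed(3)
  for (k in 1:20) {
    il <- sample(letters[1:8])
    tok <- il[sample.int(7, 1)] # not the last rank
    out <- educate_ais(il, tok)
    expect_gt(match(tok, out), match(tok, il))
    expect_setequal(out, il)
  }
  # degenerate cases: last educable rank or frozen token leave the list alone
  expect_identical(educate_ais(letters[1:4], "d"), letters[1:4])
  expect_identical(educate_ais(letters[1:6], "e", n_frozen = 2), letters[1:6])
  expect_error(educate_ais(letters[1:4], "z"), "not present")
})

test_that("training produces a nonincreasing threshold trace and intact ILists", {
  fx <- tiny_population(n_features = 10, C = 10, seed = 4)
  tp <- training_params("AIS", W_tau = 500, T_S = 50, t_max = 100,
                        tau_target = 120, seed = 4)
  tr <- train_population(fx$pop, fx$split$train_normal, tp, label = "class")
  expect_true(all(diff(tr$trace$tau_n) <= 0))
  expect_true(all(tr$trace$n_subs >= 0))
  # tau_n only updates in windows without substitutions
  drops <- which(diff(tr$trace$tau_n) < 0) + 1L
  expect_true(all(tr$trace$n_subs[drops] == 0))
  # ILists remain permutations; frozen tokens never moved
  pop2 <- tr$population
  for (j in 1:pop2$N) {
    expect_setequal(pop2$ranks[j, ], seq_len(2 * pop2$C))
    froz <- which(pop2$frozen[j, ])
    expect_identical(pop2$ranks[j, froz], fx$pop$ranks[j, froz])
  }
})

test_that("iterations_to_threshold reads the trace correctly", {
  fx <- tiny_population(n_features = 10, C = 10, seed = 4)
  tp <- training_params("AIS", W_tau = 500, T_S = 50, t_max = 100,
                        tau_target = 120, seed = 4)
  tr <- train_population(fx$pop, fx$split$train_normal, tp, label = "class")
  expect_equal(iterations_to_threshold(tr, tau_target = 120),
               tr$iterations_to_target)
  expect_identical(iterations_to_threshold(tr, tau_target = 500), 0)
  expect_identical(iterations_to_threshold(tr, tau_target = 0), Inf)
  # monotone trace: unique crossing at the first window at or below target
  mid <- tr$trace$tau_n[ceiling(nrow(tr$trace) / 2)]
  k <- which(tr$trace$tau_n <= mid)[1]
  expect_equal(iterations_to_threshold(tr, mid), tr$trace$iterations[k])
})

test_that("AIS training demotes same-subtype tokens from the top ranks", {
  fx <- tiny_population(n_features = 20, C = 14, seed = 9)
  top_same <- function(p, k = 5) {
    mean(vapply(seq_len(p$N), function(j) {
      same <- rep(p$subtype[p$conn[j, ]] == p$digit[j], each = 2)
      sum(same[p$ranks[j, ] <= k])
    }, numeric(1)))
  }
  before <- top_same(fx$pop)
  tp <- training_params("AIS", W_tau = 1000, T_S = 100, t_max = 400,
                        tau_target = 100, seed = 9)
  tr <- train_population(fx$pop, fx$split$train_normal, tp, label = "class")
  expect_lt(top_same(tr$population), before)
})

test_that("repertoires share connectivity but educate independently", {
  fx <- tiny_population(n_features = 10, C = 10, seed = 10)
  tp <- training_params("AIS", W_tau = 500, T_S = 50, t_max = 50,
                        tau_target = 150, seed = 10)
  rep <- build_repertoire(fx$pop, fx$split$train_normal, tp, N_pop = 3,
                          label = "class")
  expect_length(rep$ilists, 3)
  expect_identical(rep$population$conn, fx$pop$conn)
  expect_false(identical(rep$ilists[[1]], rep$ilists[[2]]))
  expect_false(identical(rep$ilists[[2]], rep$ilists[[3]]))
  # degenerate repertoire of one population
  rep1 <- build_repertoire(fx$pop, fx$split$train_normal, tp, N_pop = 1,
                           label = "class")
  expect_length(rep1$ilists, 1)
  # reproducible under the same seed
  rep_b <- build_repertoire(fx$pop, fx$split$train_normal, tp, N_pop = 3,
                            label = "class")
  expect_identical(rep$ilists, rep_b$ilists)
})
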