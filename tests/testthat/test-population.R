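test_that("build_population assembles balanced agents, ILists and frozen sets", {
  fx <- tiny_population(n_features = 40, C = 20, seed = 2)
  pop <- fx$pop
  expect_equal(pop$N, 40)
  expect_equal(sum(pop$subtype == 1), 20)
  expect_equal(sum(pop$digit == 1), 20)
  expect_equal(dim(pop$ranks), c(40, 40))
  # every IList is a permutation of its 2C token ranks
  for (j in 1:pop$N) expect_setequal(pop$ranks[j, ], 1:40)
  # frozen tokens are r-tokens of opposite-subtype presenters, on bottom ranks
  for (j in 1:pop$N) {
    froz <- which(pop$frozen[j, ])
    expect_true(all(froz %% 2 == 0))
    expect_setequal(pop$ranks[j, froz], (pop$n_educ[j] + 1):40)
  }
  # about half the connections are opposite-subtype
  expect_equal(mean(2 * pop$C - pop$n_educ), 10, tolerance = 0.3)
  expect_error(build_population(fx$mapper, C = 41), "cannot exceed")
})

test_that("populations are reproducible and full connectivity is allowed", {
  fx <- tiny_population(n_features = 10, C = 10, seed = 5)
  set.seed(5)
  pop2 <- build_population(fx$mapper, C = 10, v_max = 0.05, seed = 5)
  expect_identical(fx$pop$conn, pop2$conn)
  expect_identical(fx$pop$ranks, pop2$ranks)
  expect_true(all(table(as.vector(pop2$conn)) == 10)) # every presenter covered
})

test_that("rank_of reads presenter digits and detector tokens", {
  fx <- tiny_population(n_features = 10, C = 10, seed = 5)
  pop <- fx$pop
  i1 <- which(pop$subtype == 1)[1]
  expect_identical(rank_of(pop, "presenter", i1, 1), 1L)
  expect_identical(rank_of(pop, "presenter", i1, 2), 2L)
  pres <- pop$conn[3, 4]
  tok <- paste0("f_", pres)
  expect_identical(rank_of(pop, "detector", 3, tok), pop$ranks[3, 2 * 4 - 1])
  expect_error(rank_of(pop, "detector", 3, "f_999"), "connectivity")
})

test_that("decide matches the rule oracle on the exhaustive 2x2 sweep", {
  pres_configs <- expand.grid(rep(list(1:2), 4))
  det_rows <- list(c(1L, 2L), c(2L, 1L))
  states <- enumerate_states(2)
  for (r in seq_len(nrow(pres_configs))) {
    pres_pref <- matrix(as.integer(pres_configs[r, ]), 2, 2)
    for (d1 in 1:2) for (d2 in 1:2) {
      det_pref <- rbind(det_rows[[d1]], det_rows[[d2]])
      for (st in states) for (i in 1:2) for (j in 1:2) {
        got <- cfadetect:::cpp_decide(i, j, pres_pref, det_pref,
                          st$partner_p, st$partner_d, st$tau_p, st$tau_d)
        want <- oracle_decide(i, j, pres_pref, det_pref, st)
        expect_identical(got$partner_p, want$partner_p)
        expect_identical(got$partner_d, want$partner_d)
        expect_identical(got$tau_p, want$tau_p)
        expect_identical(got$tau_d, want$tau_d)
      }
    }
  }
})

test_that("equal presenter ranks never cause a switch", {
  # presenter 1 paired with detector 1; detector 2 displays the same digit
  pres_pref <- matrix(1L, 2, 2) # both detectors equally preferred
  det_pref <- rbind(c(1L, 2L), c(1L, 2L))
  st <- list(partner_p = c(1L, 0L), partner_d = c(1L, 0L),
             tau_p = c(4L, 0L), tau_d = c(4L, 0L))
  got <- cfadetect:::cpp_decide(1, 2, pres_pref, det_pref,
                    st$partner_p, st$partner_d, st$tau_p, st$tau_d)
  expect_identical(got$partner_p, st$partner_p)
  expect_identical(got$tau_p, st$tau_p)
})

test_that("iterate keeps the matching invariant and ages pairs", {
  fx <- tiny_population(n_features = 10, C = 10, seed = 6)
  set.seed(6)
  x <- as.numeric(as.matrix(fx$split$test_normal[1, 1:10]))
  pop <- iterate(fx$pop, x, n_iter = 1)
  expect_matching_ok(pop)
  # after one iteration from the all-alone state, formed pairs have age 1
  expect_true(all(pop$tau_p[pop$partner_p > 0] == 1))
  pop <- iterate(pop, x, n_iter = 50)
  expect_matching_ok(pop)
  # trajectories are seed-deterministic
  set.seed(11)
  a <- iterate(fx$pop, x, n_iter = 25)
  set.seed(11)
  b <- iterate(fx$pop, x, n_iter = 25)
  expect_identical(a$partner_p, b$partner_p)
  expect_identical(a$tau_d, b$tau_d)
})

test_that("the cyclic-preference toy population never stabilises", {
  toy <- build_toy_population(40, seed = 3)
  set.seed(3)
  out <- iterate(toy, NULL, n_iter = 10000)
  expect_matching_ok(out)
  expect_lt(attr(out, "max_tau"), 1000)
})

test_that("survival counts are nonincreasing and education thins the tail", {
  fx <- tiny_population(n_features = 10, C = 10, seed = 8)
  x <- as.numeric(as.matrix(fx$split$train_normal[1, 1:10]))
  set.seed(8)
  sh_raw <- survival_histogram(fx$pop, x, n_iter = 2000, tau_cap = 100)
  for (ag in unique(sh_raw$agent[sh_raw$type == "detector"])[1:5]) {
    cnt <- sh_raw$count[sh_raw$type == "detector" & sh_raw$agent == ag]
    # the last bin accumulates all ages at or beyond the cap
    expect_true(all(diff(cnt[-length(cnt)]) <= 0))
  }
  tp <- training_params("AIS", W_tau = 1000, T_S = 100, t_max = 300,
                        tau_target = 100, seed = 8)
  tr <- train_population(fx$pop, fx$split$train_normal, tp, label = "class")
  set.seed(8)
  sh_tr <- survival_histogram(tr$population, x, n_iter = 2000, tau_cap = 100)
  tail_mass <- function(sh) sum(sh$count[sh$tau == 100])
  expect_lt(tail_mass(sh_tr), tail_mass(sh_raw))
  # educated survival decays about exponentially over moderate ages
  d <- dplyr::filter(sh_tr, type == "presenter", tau >= 1, tau <= 15)
  d <- dplyr::summarise(dplyr::group_by(d, tau), n = sum(count), .groups = "drop")
  d <- dplyr::filter(d, n > 0)
  expect_lt(cor(log(d$n), d$tau), -0.9)
})
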