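#' Absorbing-chain model of single-list education
#'
#' Education of one interaction list of `N` items (two types, `N/2` each) is
#' modelled as an absorbing Markov chain over waiting states `W_m` (a list
#' with `m` correctly ranked items in the top `n` positions), education
#' states (`E` for the negative-selection strategy, `E_m` for the
#' targeted-swap strategy) and the absorbing state `S` (top `n` fully
#' correct).
#'
#' @param strategy `"IS"` (negative selection: education replaces the whole
#'   list) or `"AIS"` (targeted swap: education corrects at most one item).
#' @param n Number of top positions to educate, `1 <= n <= N/2`.
#' @param N List length (even).
#' @return A `cfa_markov_spec`.
#' @export
markov_spec <- function(strategy = c("IS", "AIS"), n, N) {
  strategy <- match.arg(strategy)
  if (N %% 2 != 0) abort("N must be even (two item types, N/2 each)")
  if (!(n >= 1 && n <= N / 2)) abort("need 1 <= n <= N/2")
  structure(list(strategy = strategy, n = as.integer(n), N = as.integer(N)),
            class = "cfa_markov_spec")
}

#' Transition matrix of the education chain
#'
#' For the negative-selection strategy: from `W_m` the chain enters the
#' education state `E` with probability `(n - m)/N` (an incorrect top item is
#' selected); from `E` it lands on `W_m` with the binomial probability
#' `choose(n, m)/2^n`, reaching the absorbing state with `1/2^n`. For the
#' targeted-swap strategy the chain enters `E_m` with the same `(n - m)/N`
#' and then moves to `W_m` or `W_{m+1}` with probability 1/2 each (the
#' `N >> n` approximation).
#'
#' @param spec A [markov_spec()].
#' @return Row-stochastic matrix with named states; `S` is absorbing.
#' @export
transition_matrix <- function(spec) {
  n <- spec$n
  N <- spec$N
  if (spec$strategy == "IS") {
    states <- c("E", paste0("W", 0:(n - 1)), "S")
    P <- matrix(0, length(states), length(states),
                dimnames = list(states, states))
    P["E", paste0("W", 0:(n - 1))] <- choose(n, 0:(n - 1)) / 2^n
    P["E", "S"] <- 1 / 2^n
    for (m in 0:(n - 1)) {
      w <- paste0("W", m)
      P[w, "E"] <- (n - m) / N
      P[w, w] <- 1 - (n - m) / N
    }
  } else {
    states <- c(rbind(paste0("W", 0:(n - 1)), paste0("E", 0:(n - 1))), "S")
    P <- matrix(0, length(states), length(states),
                dimnames = list(states, states))
    for (m in 0:(n - 1)) {
      w <- paste0("W", m)
      e <- paste0("E", m)
      up <- if (m == n - 1) "S" else paste0("W", m + 1)
      P[w, e] <- (n - m) / N
      P[w, w] <- 1 - (n - m) / N
      P[e, w] <- 0.5
      P[e, up] <- 0.5
    }
  }
  P["S", "S"] <- 1
  P
}

#' Expected absorption times of an absorbing chain
#'
#' Solves `K_i = 1 + sum_j p_ij K_j` over the transient states
#' (fundamental-matrix method) for a chain with exactly one absorbing state
#' reachable from every transient state.
#'
#' @param P Row-stochastic matrix; absorbing states are rows equal to a unit
#'   vector on the diagonal.
#' @return Named vector of expected steps to absorption per transient state.
#' @export
absorption_times_solve <- function(P) {
  if (any(abs(rowSums(P) - 1) > 1e-12)) abort("P must be row-stochastic")
  absorbing <- which(diag(P) == 1)
  if (length(absorbing) == 0L) abort("no absorbing state")
  trans <- setdiff(seq_len(nrow(P)), absorbing)
  Q <- P[trans, trans, drop = FALSE]
  K <- tryCatch(solve(diag(length(trans)) - Q, rep(1, length(trans))),
                error = function(e) abort("absorbing state unreachable from some transient state"))
  setNames(K, rownames(P)[trans])
}

#' Closed-form absorption times, negative-selection strategy
#'
#' `K_E = 2^n + N * sum_{j=0}^{n-1} choose(n, j) / (n - j)` and
#' `K_Wm = K_E + N / (n - m)`. The closed form is stated for `n > 1` but
#' evaluates consistently at `n = 1` (`K_E = 2 + N`), which this
#' implementation allows.
#'
#' @param n Top positions to educate (`>= 1`).
#' @param N List length.
#' @return Expected steps to absorption from the education state.
#' @export
K_E_IS <- function(n, N) {
  stopifnot(n >= 1)
  j <- 0:(n - 1)
  2^n + N * sum(choose(n, j) / (n - j))
}

#' @rdname K_E_IS
#' @param m Correct items in the top `n` at the start, `0 <= m < n`.
#' @return Expected steps to absorption from waiting state `W_m`.
#' @export
K_W_IS <- function(m, n, N) {
  if (any(m < 0 | m >= n)) abort("need 0 <= m < n")
  K_E_IS(n, N) + N / (n - m)
}

#' Closed-form absorption time, targeted-swap strategy
#'
#' `K_Wm = 2 (n - m) + 2 N * sum_{j=m}^{n-1} 1 / (n - j)` under the
#' `N >> n` approximation of the education chain.
#'
#' @inheritParams K_W_IS
#' @return Expected steps to absorption from waiting state `W_m`.
#' @export
K_W_AIS <- function(m, n, N) {
  if (any(m < 0 | m > n - 1)) abort("need 0 <= m <= n - 1")
  vapply(m, function(mm) {
    j <- mm:(n - 1)
    2 * (n - mm) + 2 * N * sum(1 / (n - j))
  }, numeric(1))
}

#' Monte-Carlo simulation of the explicit list-education process
#'
#' Simulates the list process directly: at each step an item position is
#' selected uniformly; an incorrectly ranked item in the top `n` triggers
#' one education step — negative selection (`"IS"`) draws a fresh list with
#' independent equiprobable item types (a new detector from a large
#' receptor pool, realising the chain's binomial education outcome exactly),
#' the targeted swap (`"AIS"`) exchanges the item with a uniform item from
#' the `N - n` positions below (so its finite-`N` correction probability is
#' `(N/2 - m)/(N - n)`, approaching the chain's 1/2 as `N/n` grows). The
#' process starts in `W_0` (top `n` fully incorrect) and stops when the top
#' `n` is fully correct.
#'
#' @inheritParams markov_spec
#' @param reps Number of replicates.
#' @param seed Optional integer seed.
#' @return One-row tibble: `strategy`, `n`, `N`, `reps`, `mean`, `se`.
#' @export
simulate_education <- function(strategy = c("IS", "AIS"), n, N, reps = 1e4,
                               seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(reps >= 1, N %% 2 == 0, n >= 0, n <= N / 2)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) {
    return(tibble::tibble(strategy = strategy, n = n, N = N, reps = reps,
                          mean = 0, se = 0))
  }
  steps <- cpp_simulate_education(if (strategy == "IS") 0L else 1L,
                                  as.integer(n), as.integer(N),
                                  as.integer(reps))
  tibble::tibble(strategy = strategy, n = n, N = N, reps = reps,
                 mean = mean(steps), se = sd(steps) / sqrt(reps))
}

#' Strategy-comparison table for the education theory
#'
#' Tabulates, per strategy and `n`, the closed-form expected absorption time
#' from the fully incorrect state `W_0`, the fundamental-matrix solve on the
#' chain, and (optionally) the explicit-simulation estimate — the data
#' behind the convergence-speed comparison curves.
#'
#' @param n_values Integer vector of `n` values.
#' @param N List length (default 100).
#' @param reps Simulation replicates per cell (0 to skip simulation).
#' @param seed Optional integer seed.
#' @return A `cfa_markov` tibble: `strategy`, `n`, `N`, `K_closed_form`,
#'   `K_solve`, `K_simulated`, `se`.
#' @export
markov_table <- function(n_values, N = 100, reps = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::map_dfr(c("IS", "AIS"), function(strat) {
    purrr::map_dfr(n_values, function(n) {
      spec <- markov_spec(strat, n, N)
      K_closed <- if (strat == "IS") K_W_IS(0, n, N) else K_W_AIS(0, n, N)
      K_solve <- absorption_times_solve(transition_matrix(spec))[["W0"]]
      if (reps > 0) {
        sim <- simulate_education(strat, n, N, reps)
        tibble::tibble(strategy = strat, n = n, N = N,
                       K_closed_form = K_closed, K_solve = K_solve,
                       K_simulated = sim$mean, se = sim$se)
      } else {
        tibble::tibble(strategy = strat, n = n, N = N,
                       K_closed_form = K_closed, K_solve = K_solve,
                       K_simulated = NA_real_, se = NA_real_)
      }
    })
  })
  class(rows) <- c("cfa_markov", class(rows))
  rows
}
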