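#' Training parameters
#'
#' @param strategy `"AIS"` (targeted rank swap) or `"IS"` (negative-selection
#'   full replacement of the IList).
#' @param W_tau Education window length in iterations (default `1e4`).
#' @param T_S Sample-change period in iterations (default 100): every `T_S`
#'   iterations a new uniformly drawn training sample is displayed.
#' @param t_max Maximum number of education windows.
#' @param tau_target Optional early stop: training ends once the adaptive
#'   pairing-duration threshold `tau_n` falls to this value.
#' @param seed Optional integer seed.
#' @return A `cfa_training_params` list.
#' @export
training_params <- function(strategy = c("AIS", "IS"), W_tau = 1e4, T_S = 100,
                            t_max = 100, tau_target = NULL, seed = NULL) {
  strategy <- match.arg(strategy)
  W_tau <- as.integer(W_tau)
  T_S <- as.integer(T_S)
  if (!(W_tau >= T_S && T_S >= 1)) abort("need W_tau >= T_S >= 1")
  stopifnot(t_max >= 1)
  structure(list(strategy = strategy, W_tau = W_tau, T_S = T_S,
                 t_max = as.integer(t_max),
                 tau_target = if (is.null(tau_target)) NULL else as.integer(tau_target),
                 seed = seed),
            class = "cfa_training_params")
}

#' Negative-selection (IS) education of one interaction list
#'
#' Replaces the educable region of the IList — every rank above the frozen
#' bottom block — by a fresh uniform permutation; the frozen tokens stay on
#' the bottom ranks.
#'
#' @param ilist Character (or any) vector of tokens ordered by rank, most
#'   preferred first.
#' @param n_frozen Number of frozen tokens at the tail of the list.
#' @return The educated IList.
#' @export
educate_is <- function(ilist, n_frozen = 0) {
  ne <- length(ilist) - n_frozen
  if (ne > 1) ilist[seq_len(ne)] <- ilist[sample.int(ne)]
  ilist
}

#' Targeted-swap (AIS) education of one interaction list
#'
#' Swaps the token currently sustaining a long-lived pairing with a token at
#' a uniformly drawn strictly lower educable rank, pushing the offending
#' signal down while possibly raising a signal never seen in the current
#' sample. When the token already sits at the last educable rank (or is
#' frozen) the list is unchanged — the detector is still unpaired by the
#' caller, which removes the stable pair.
#'
#' @inheritParams educate_is
#' @param token The token perceived from the long-lived partner.
#' @param p Optional target rank (drawn uniformly from the ranks strictly
#'   below the token's when `NULL`).
#' @return The educated IList.
#' @export
educate_ais <- function(ilist, token, n_frozen = 0, p = NULL) {
  ne <- length(ilist) - n_frozen
  r0 <- match(token, ilist)
  if (is.na(r0)) abort("token not present in the IList")
  if (r0 >= ne) return(ilist) # frozen or last educable rank: nothing to swap
  if (is.null(p)) p <- r0 + sample.int(ne - r0, 1)
  if (p <= r0 || p > ne) abort("p must be an educable rank strictly below the token")
  tmp <- ilist[p]
  ilist[p] <- ilist[r0]
  ilist[r0] <- tmp
  ilist
}

#' Educate one population of detector interaction lists
#'
#' Runs the repertoire-education loop: the frustrated dynamics iterates with
#' a training sample redrawn every `T_S` iterations; any detector paired for
#' `tau_n` or more iterations is educated (per strategy), unpaired and
#' counted. `tau_n` starts at `W_tau` and, at the end of any window of
#' `W_tau` iterations with zero educations, drops to the largest pairing age
#' observed in that window — so the trace of `tau_n` is nonincreasing.
#' Training stops after `t_max` windows or as soon as `tau_n` reaches
#' `tau_target`.
#'
#' @param pop A `cfa_population` (its current ILists are the starting point).
#' @param samples Training samples: tibble/matrix of raw feature rows
#'   (label column dropped via `label`).
#' @param params A [training_params()].
#' @param label Optional label column name in `samples`.
#' @return A `cfa_trained`: list with the educated `population`, a `trace`
#'   tibble (`window`, `iterations`, `tau_n`, `n_subs`), total `iterations`,
#'   and `iterations_to_target` (`Inf` when not reached).
#' @export
train_population <- function(pop, samples, params = training_params(),
                             label = NULL) {
  X <- if (is.matrix(samples)) samples else {
    as.matrix(samples[setdiff(names(samples), label)])
  }
  if (nrow(X) == 0L) abort("no training samples")
  if (!is.null(params$seed)) set.seed(params$seed)
  Fmat <- mapper_cdf(pop$mapper, X)
  res <- cpp_train(pop$conn, pop$ranks, pop$frozen, pop$n_educ,
                   pop$subtype, pop$digit, pop$side, pop$v, Fmat,
                   params$W_tau, params$T_S, params$t_max,
                   if (is.null(params$tau_target)) -1L else params$tau_target,
                   if (params$strategy == "IS") 0L else 1L)
  pop$ranks <- res$ranks
  pop <- reset_pairing(pop)
  trace <- tibble::tibble(
    window = seq_along(res$tau_n),
    iterations = seq_along(res$tau_n) * as.numeric(params$W_tau),
    tau_n = res$tau_n,
    n_subs = res$n_subs
  )
  structure(list(
    population = pop,
    trace = trace,
    iterations = res$total_iterations,
    iterations_to_target = if (is.na(res$iterations_to_target)) Inf else res$iterations_to_target,
    params = params
  ), class = "cfa_trained")
}

#' @export
print.cfa_trained <- function(x, ...) {
  cat(sprintf("<cfa_trained> %s strategy, %d windows, %.3g iterations, final tau_n = %d\n",
              x$params$strategy, nrow(x$trace), x$iterations,
              utils::tail(x$trace$tau_n, 1)))
  invisible(x)
}

#' Iterations needed to reach a pairing-duration threshold
#'
#' First total-iteration count at which the adaptive threshold `tau_n` fell
#' to `tau_target`. The threshold starts at `W_tau`, so a target at or above
#' the starting value costs zero iterations; `Inf` means the trace never
#' crossed.
#'
#' @param trained A `cfa_trained` (or its `trace` tibble).
#' @param tau_target Threshold pairing duration.
#' @return Number of iterations (0, a positive count, or `Inf`).
#' @export
iterations_to_threshold <- function(trained, tau_target) {
  trace <- if (inherits(trained, "cfa_trained")) trained$trace else trained
  if (nrow(trace) == 0L) abort("empty training trace")
  start_tau <- if (inherits(trained, "cfa_trained")) {
    trained$params$W_tau
  } else {
    max(trace$tau_n)
  }
  if (tau_target >= start_tau) return(0)
  hit <- which(trace$tau_n <= tau_target)
  if (length(hit) == 0L) return(Inf)
  trace$iterations[hit[1]]
}

#' Build a repertoire of independently educated populations
#'
#' Re-initialises the detector ILists at random and runs
#' [train_population()] `N_pop` times; every population shares the same
#' connectivity and perception maps, so their IList sets are exchangeable at
#' monitoring time. Pooling independently educated sets raises the chance
#' that some IList ranks a never-displayed rare signal on top, which is what
#' makes single outliers detectable.
#'
#' @inheritParams train_population
#' @param N_pop Number of independently educated IList sets (default 12).
#' @return A `cfa_repertoire`: shared `population` skeleton, `ilists` (list
#'   of rank matrices), per-population `traces`, `params`, `N_pop`.
#' @export
build_repertoire <- function(pop, samples, params = training_params(),
                             N_pop = 12, label = NULL) {
  stopifnot(N_pop >= 1)
  if (!is.null(params$seed)) set.seed(params$seed)
  sub_seeds <- sample.int(.Machine$integer.max, N_pop)
  ilists <- vector("list", N_pop)
  traces <- vector("list", N_pop)
  for (k in seq_len(N_pop)) {
    set.seed(sub_seeds[k])
    pop$ranks <- fresh_ilists(pop)
    pk <- params
    pk$seed <- NULL # already seeded for this population's stream
    tr <- train_population(pop, samples, pk, label = label)
    ilists[[k]] <- tr$population$ranks
    traces[[k]] <- tr$trace
  }
  structure(list(population = pop, ilists = ilists, traces = traces,
                 params = params, N_pop = N_pop),
            class = "cfa_repertoire")
}

#' @export
print.cfa_repertoire <- function(x, ...) {
  cat(sprintf("<cfa_repertoire> %d educated populations (%s), N = %d, C = %d\n",
              x$N_pop, x$params$strategy, x$population$N, x$population$C))
  invisible(x)
}
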