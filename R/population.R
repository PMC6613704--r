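#' Build a cellular frustration agent population
#'
#' Creates `N` presenter agents (one per mapped feature; subtypes I/II
#' alternate so replicas of each feature are balanced across subtypes) and
#' `N` detector agents (display digits 1/2, balanced). Each detector is
#' connected to `C` distinct randomly drawn presenters, receives a one-sided
#' perception map per connection ([draw_perceptions()]), and starts with a
#' random interaction list (IList) over its `2C` frequent/rare tokens. Rare
#' tokens of opposite-subtype presenters are pinned ("frozen") to the bottom
#' ranks so that an absent frequent signal cannot be compensated by its rare
#' twin.
#'
#' A presenter of subtype I prefers detectors displaying 1 (rank 1) over 2,
#' and symmetrically for subtype II; this same-subtype attraction is the
#' stable tendency training must frustrate.
#'
#' @param mapper A fitted [fit_mapper()]; its feature count sets `N` (must be
#'   even).
#' @param C Detector connectivity (default 20); `C <= N`.
#' @param v_max Maximum perception tail probability (default 0.05).
#' @param seed Optional integer seed.
#' @return A `cfa_population`.
#' @export
build_population <- function(mapper, C = 20, v_max = 0.05, seed = NULL) {
  N <- mapper$n_features
  if (N %% 2 != 0) abort("population size (feature count) must be even")
  if (C > N) abort("connectivity C cannot exceed the number of presenters")
  if (!is.null(seed)) set.seed(seed)
  subtype <- rep_len(c(1L, 2L), N)
  digit <- rep_len(c(1L, 2L), N)
  conn <- t(vapply(seq_len(N), function(j) sort(sample.int(N, C)),
                   integer(C)))
  side <- matrix(sample(c(TRUE, FALSE), N * C, replace = TRUE), N, C)
  v <- matrix(runif(N * C, 0, v_max), N, C)
  frozen <- matrix(FALSE, N, 2L * C)
  for (j in seq_len(N)) {
    opp <- subtype[conn[j, ]] != digit[j]
    frozen[j, 2L * seq_len(C)] <- opp # r-tokens of opposite-subtype presenters
  }
  pop <- structure(list(
    N = N, C = C, v_max = v_max,
    subtype = subtype, digit = digit,
    conn = conn, side = side, v = v,
    frozen = frozen, n_educ = as.integer(2L * C - rowSums(frozen)),
    mapper = mapper
  ), class = "cfa_population")
  pop$ranks <- fresh_ilists(pop)
  pop <- reset_pairing(pop)
  pop
}

# internal: random IList ranks with frozen tokens on the bottom ranks
fresh_ilists <- function(pop) {
  twoC <- 2L * pop$C
  ranks <- matrix(0L, pop$N, twoC)
  for (j in seq_len(pop$N)) {
    ne <- pop$n_educ[j]
    educ <- which(!pop$frozen[j, ])
    froz <- which(pop$frozen[j, ])
    ranks[j, educ] <- sample.int(ne)
    if (length(froz)) ranks[j, froz] <- ne + sample.int(length(froz))
  }
  ranks
}

# internal: all agents alone with zero pairing ages
reset_pairing <- function(pop) {
  pop$partner_p <- integer(pop$N)
  pop$partner_d <- integer(pop$N)
  pop$tau_p <- integer(pop$N)
  pop$tau_d <- integer(pop$N)
  pop
}

#' @export
print.cfa_population <- function(x, ...) {
  cat(sprintf("<cfa_population> N = %d presenters/detectors, C = %d, v_max = %g\n",
              x$N, x$C, x$v_max))
  cat(sprintf("  ILists: %d tokens each, %d frozen on average\n",
              2L * x$C, round(mean(2L * x$C - x$n_educ))))
  invisible(x)
}

# internal: empirical CDF values of the displayed sample (0.5 everywhere for
# mapper-less toy populations, where v = 0 makes the value irrelevant)
pop_F <- function(pop, x) {
  if (is.null(x)) return(rep(0.5, pop$N))
  if (is.null(pop$mapper)) return(rep(0.5, pop$N))
  as.numeric(mapper_cdf(pop$mapper, matrix(x, nrow = 1)))
}

# internal: per-connection rare flags under F values
pop_rare <- function(pop, Fv) {
  Fmat <- matrix(Fv[pop$conn], pop$N, pop$C)
  ifelse(pop$side, Fmat < pop$v, Fmat > 1 - pop$v)
}

# internal: preference matrices for the decision rule under a displayed sample
pop_pref <- function(pop, x) {
  Fv <- pop_F(pop, x)
  rare <- pop_rare(pop, Fv)
  pres_pref <- 1L + (outer(pop$subtype, pop$digit, "!=") * 1L)
  det_pref <- matrix(0L, pop$N, pop$N)
  for (j in seq_len(pop$N)) {
    cols <- 2L * seq_len(pop$C) - 1L + rare[j, ]
    det_pref[j, pop$conn[j, ]] <- pop$ranks[j, cols]
  }
  list(pres_pref = pres_pref, det_pref = det_pref, rare = rare)
}

#' Rank of a signal in an agent's interaction list
#'
#' Presenters rank the two detector digits (rank 1 for their own subtype's
#' digit); detectors rank the `2C` frequent/rare tokens of their connected
#' presenters.
#'
#' @param pop A `cfa_population`.
#' @param agent `"presenter"` or `"detector"`.
#' @param index Agent index.
#' @param token For a presenter: a digit (1 or 2). For a detector: a token
#'   string `"f_<i>"` or `"r_<i>"` naming a connected presenter `i`.
#' @return Integer rank (1 = most preferred).
#' @export
rank_of <- function(pop, agent = c("presenter", "detector"), index, token) {
  agent <- match.arg(agent)
  if (agent == "presenter") {
    d <- as.integer(token)
    if (!d %in% c(1L, 2L)) abort("presenters rank only the digits 1 and 2")
    return(if (d == pop$subtype[index]) 1L else 2L)
  }
  m <- regmatches(token, regexec("^([fr])_(\\d+)$", token))[[1]]
  if (length(m) != 3) abort("detector tokens look like 'f_12' or 'r_3'")
  pres <- as.integer(m[3])
  c_idx <- match(pres, pop$conn[index, ])
  if (is.na(c_idx)) {
    abort(sprintf("presenter %d is not in detector %d's connectivity", pres, index))
  }
  col <- 2L * c_idx - 1L + (m[2] == "r")
  pop$ranks[index, col]
}

#' Apply the pairing decision rule to one interaction
#'
#' Puts presenter `i` and detector `j` in interaction under the displayed
#' sample and applies the four-branch rule: two alone agents always pair; a
#' paired agent switches to an alone newcomer only if it strictly prefers
#' it; two paired agents switch only if both strictly prefer each other. All
#' pairing ages touched by a break reset to zero.
#'
#' @param pop A `cfa_population`.
#' @param i Presenter index.
#' @param j Detector index; must have `i` in its connectivity.
#' @param x Displayed sample (raw feature vector), or `NULL` for a toy
#'   population.
#' @return The population with updated pairing state.
#' @export
decide <- function(pop, i, j, x = NULL) {
  pref <- pop_pref(pop, x)
  st <- cpp_decide(i, j, pref$pres_pref, pref$det_pref,
                   pop$partner_p, pop$partner_d, pop$tau_p, pop$tau_d)
  pop$partner_p <- st$partner_p
  pop$partner_d <- st$partner_d
  pop$tau_p <- st$tau_p
  pop$tau_d <- st$tau_d
  pop
}

#' Run global iterations of the frustrated dynamics
#'
#' One iteration visits every agent in a fresh random order; each visited
#' agent draws one uniform-random counterpart from its interaction set (a
#' detector draws one of its `C` presenters, a presenter one of the
#' detectors covering it) and the pairing rule runs. Afterwards every intact
#' pair's age increases by one.
#'
#' @param pop A `cfa_population`.
#' @param x Displayed sample (raw features), or `NULL` for toy populations.
#' @param n_iter Number of global iterations.
#' @return The population with updated pairing state; the maximum pairing
#'   age observed is attached as attribute `max_tau`.
#' @export
iterate <- function(pop, x = NULL, n_iter = 1) {
  stopifnot(n_iter >= 1)
  res <- cpp_run_dynamics(pop$conn, pop$ranks, pop$subtype, pop$digit,
                          pop$side, pop$v, pop_F(pop, x), n_iter,
                          pop$partner_p, pop$partner_d, pop$tau_p, pop$tau_d,
                          1L)
  pop$partner_p <- res$partner_p
  pop$partner_d <- res$partner_d
  pop$tau_p <- res$tau_p
  pop$tau_d <- res$tau_d
  attr(pop, "max_tau") <- res$max_tau
  pop
}

#' Contact survival histogram
#'
#' Runs the dynamics for `n_iter` iterations and counts, per agent, the
#' contacts surviving at least `tau` iterations — the standard diagnostic of
#' frustration: educated populations show a fast, approximately exponential
#' decay, untrained ones a heavy tail of long-lived pairs.
#'
#' @param pop A `cfa_population`.
#' @param x Displayed sample, or `NULL` for toy populations.
#' @param n_iter Iterations to run.
#' @param tau_cap Ages are tallied up to this cap (default 200).
#' @return A `cfa_survival` tibble: `type` (presenter/detector), `agent`,
#'   `tau`, `count` (contacts surviving `>= tau`); `count` is nonincreasing
#'   in `tau` for each agent.
#' @export
survival_histogram <- function(pop, x = NULL, n_iter, tau_cap = 200) {
  stopifnot(n_iter >= 1)
  res <- cpp_run_dynamics(pop$conn, pop$ranks, pop$subtype, pop$digit,
                          pop$side, pop$v, pop_F(pop, x), n_iter,
                          pop$partner_p, pop$partner_d, pop$tau_p, pop$tau_d,
                          as.integer(tau_cap))
  fmt <- function(counts, type) {
    tibble::tibble(
      type = type,
      agent = rep(seq_len(nrow(counts)), ncol(counts)),
      tau = rep(0:(ncol(counts) - 1L), each = nrow(counts)),
      count = as.integer(counts)
    )
  }
  out <- dplyr::bind_rows(fmt(res$counts_p, "presenter"),
                          fmt(res$counts_d, "detector"))
  class(out) <- c("cfa_survival", class(out))
  out
}

#' Two-type toy population with cyclic preferences
#'
#' The minimal frustrated population: two presenter subtypes and two
#' detector digits where every presenter prefers its same-subtype detector
#' while every detector prefers opposite-subtype presenters. Any pairing can
#' be destabilised by an unpaired agent, so no stable matching exists and
#' pairing ages remain bounded no matter how long the dynamics runs.
#'
#' @param n_presenters Population size per side (even, default 40 so the
#'   system is safely above the stable-blocking regime).
#' @param seed Optional integer seed.
#' @return A `cfa_population` with full connectivity and `v_max = 0`; display
#'   samples are irrelevant (`x = NULL` in [iterate()]).
#' @export
build_toy_population <- function(n_presenters = 40, seed = NULL) {
  if (n_presenters %% 2 != 0) abort("n_presenters must be even")
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(n_presenters)
  C <- N
  subtype <- rep_len(c(1L, 2L), N)
  digit <- rep_len(c(1L, 2L), N)
  conn <- matrix(seq_len(N), N, C, byrow = TRUE)
  pop <- structure(list(
    N = N, C = C, v_max = 0,
    subtype = subtype, digit = digit,
    conn = conn,
    side = matrix(TRUE, N, C),
    v = matrix(0, N, C),
    frozen = matrix(FALSE, N, 2L * C),
    n_educ = rep(2L * C, N),
    mapper = NULL
  ), class = "cfa_population")
  # detector j ranks opposite-subtype f-tokens (random order) above
  # same-subtype f-tokens; all r-tokens at the bottom (never displayed)
  ranks <- matrix(0L, N, 2L * C)
  for (j in seq_len(N)) {
    opp <- which(subtype[conn[j, ]] != digit[j])
    same <- which(subtype[conn[j, ]] == digit[j])
    ord <- c(sample(opp), sample(same))
    ranks[j, 2L * ord - 1L] <- seq_len(C)
    ranks[j, 2L * seq_len(C)] <- C + sample.int(C)
  }
  pop$ranks <- ranks
  reset_pairing(pop)
}
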