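# Shared fixtures: everything is generated in code at test time.

# iris with a lowercase label column, as a tibble
iris_tbl <- function() {
  d <- tibble::as_tibble(datasets::iris)
  names(d) <- c("sepal_length", "sepal_width", "petal_length", "petal_width",
                "species")
  d$species <- as.character(d$species)
  d
}

# small labelled gaussian table
tiny_tbl <- function(n = 30, p = 4, seed = 42) {
  set.seed(seed)
  d <- tibble::as_tibble(matrix(rnorm(n * p), n, p,
                                dimnames = list(NULL, paste0("x", seq_len(p)))))
  d$class <- rep_len(c("normal", "anomalous"), n)
  d
}

# a small ready-to-run population on synthetic normal data
tiny_population <- function(n_features = 10, C = 10, v_max = 0.05, seed = 1) {
  cfg <- synthetic_config(n_features = n_features, n_normal = 60,
                          n_anomalous = 20, seed = seed)
  sp <- generate_synthetic(cfg)
  m <- fit_mapper(sp$train_normal, label = "class")
  set.seed(seed)
  list(split = sp, mapper = m,
       pop = build_population(m, C = C, v_max = v_max, seed = seed))
}

# independent R implementation of the four-branch pairing rule, written as a
# literal transcription of the decision table; used as the oracle against
# the engine's decide().
oracle_decide <- function(i, j, pres_pref, det_pref, st) {
  pi <- st$partner_p[i]
  pj <- st$partner_d[j]
  pair_ij <- function(st) {
    st$partner_p[i] <- j; st$partner_d[j] <- i
    st$tau_p[i] <- 0L; st$tau_d[j] <- 0L
    st
  }
  if (pi == j) return(st)
  if (pi == 0 && pj == 0) return(pair_ij(st))
  if (pi != 0 && pj == 0) {
    if (pres_pref[i, j] < pres_pref[i, pi]) {
      st$partner_d[pi] <- 0L; st$tau_d[pi] <- 0L
      st$tau_p[i] <- 0L
      return(pair_ij(st))
    }
    return(st)
  }
  if (pi == 0 && pj != 0) {
    if (det_pref[j, i] < det_pref[j, pj]) {
      st$partner_p[pj] <- 0L; st$tau_p[pj] <- 0L
      st$tau_d[j] <- 0L
      return(pair_ij(st))
    }
    return(st)
  }
  if (pres_pref[i, j] < pres_pref[i, pi] && det_pref[j, i] < det_pref[j, pj]) {
    st$partner_d[pi] <- 0L; st$tau_d[pi] <- 0L
    st$partner_p[pj] <- 0L; st$tau_p[pj] <- 0L
    return(pair_ij(st))
  }
  st
}

# all consistent pairing states for n presenters x n detectors (partial
# matchings), with nonzero ages on intact pairs
enumerate_states <- function(n, age = 3L) {
  states <- list()
  assignments <- expand.grid(rep(list(0:n), n))
  for (r in seq_len(nrow(assignments))) {
    pp <- as.integer(assignments[r, ])
    used <- pp[pp > 0]
    if (anyDuplicated(used)) next
    pd <- integer(n)
    for (i in seq_len(n)) if (pp[i] > 0) pd[pp[i]] <- i
    tau_p <- ifelse(pp > 0, age, 0L)
    tau_d <- ifelse(pd > 0, age, 0L)
    states[[length(states) + 1]] <- list(partner_p = pp, partner_d = pd,
                                         tau_p = as.integer(tau_p),
                                         tau_d = as.integer(tau_d))
  }
  states
}

# checks the pairing-state invariant: symmetric partners, ages agree
expect_matching_ok <- function(pop) {
  for (i in seq_len(pop$N)) {
    j <- pop$partner_p[i]
    if (j > 0) {
      expect_identical(pop$partner_d[j], i)
      expect_identical(pop$tau_p[i], pop$tau_d[j])
    }
  }
  for (j in seq_len(pop$N)) {
    i <- pop$partner_d[j]
    if (i > 0) expect_identical(pop$partner_p[i], j)
  }
  invisible(pop)
}
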