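#' Configuration for the synthetic data generator
#'
#' Normal samples are drawn from configurable per-feature marginals coupled
#' through a Gaussian copula on the declared correlated pairs. Anomalous
#' samples exercise one of the three mechanisms a cellular frustration
#' system can detect:
#'
#' * `"outlier"` — one feature per sample is pushed beyond the normal
#'   training range by `anomaly_magnitude` times that range;
#' * `"excess_absence"` — `n_absent` features are simultaneously shifted
#'   into their low-probability tails (`tail_prob` mass), so more frequent
#'   signals go missing at once than ever happens on normal data;
#' * `"broken_combination"` — the correlated pairs are decoupled by
#'   independently permuting one member across the anomalous set, which
#'   preserves every marginal while destroying the co-occurrence.
#'
#' @param n_features Number of features.
#' @param n_normal Number of normal samples generated (split into train/test).
#' @param n_anomalous Number of anomalous samples.
#' @param n_train Normal samples reserved for training (default half).
#' @param base Marginal family, `"gaussian"` (mean 0, sd 1) or `"uniform"`
#'   (0, 1).
#' @param correlated_pairs Two-column matrix (or list of length-2 vectors) of
#'   feature index pairs; `rho` the shared correlation strength in (-1, 1).
#'   Default: five pairs (1,2), (3,4), ..., (9,10) at `rho = 0.9`, strong
#'   enough that breaking the co-occurrence is a real signal.
#' @param rho Correlation strength for the pairs.
#' @param anomaly_mechanism One of `"outlier"`, `"excess_absence"`,
#'   `"broken_combination"`.
#' @param anomaly_magnitude Outlier displacement in units of the normal
#'   training range.
#' @param n_absent Features shifted under `"excess_absence"`
#'   (default `ceiling(n_features / 4)`).
#' @param tail_prob Tail mass used by `"excess_absence"` (default 0.02).
#' @param seed Integer seed; generation is deterministic given it.
#' @return A `cfa_synthetic_config` list.
#' @export
synthetic_config <- function(n_features = 40, n_normal = 200, n_anomalous = 100,
                             n_train = NULL, base = c("gaussian", "uniform"),
                             correlated_pairs = NULL, rho = 0.9,
                             anomaly_mechanism = c("outlier", "excess_absence",
                                                   "broken_combination"),
                             anomaly_magnitude = 0.5, n_absent = NULL,
                             tail_prob = 0.02, seed = 1L) {
  base <- match.arg(base)
  anomaly_mechanism <- match.arg(anomaly_mechanism)
  stopifnot(n_features >= 1, n_normal >= 2, n_anomalous >= 1,
            abs(rho) < 1, tail_prob > 0, tail_prob < 0.5)
  n_train <- n_train %||% floor(n_normal / 2)
  stopifnot(n_train >= 1, n_train < n_normal)
  if (is.null(correlated_pairs)) {
    np <- min(5L, floor(n_features / 2))
    correlated_pairs <- cbind(seq_len(np) * 2L - 1L, seq_len(np) * 2L)
  }
  if (is.list(correlated_pairs)) {
    correlated_pairs <- do.call(rbind, correlated_pairs)
  }
  if (length(correlated_pairs) && max(correlated_pairs) > n_features) {
    abort("correlated_pairs index exceeds n_features")
  }
  n_absent <- n_absent %||% as.integer(ceiling(n_features / 4))
  structure(list(n_features = n_features, n_normal = n_normal,
                 n_anomalous = n_anomalous, n_train = n_train, base = base,
                 correlated_pairs = correlated_pairs, rho = rho,
                 anomaly_mechanism = anomaly_mechanism,
                 anomaly_magnitude = anomaly_magnitude, n_absent = n_absent,
                 tail_prob = tail_prob, seed = as.integer(seed)),
            class = "cfa_synthetic_config")
}

# quantile function of the configured marginal
synth_quantile <- function(u, base) {
  switch(base, gaussian = qnorm(u), uniform = u)
}

# draw n samples from the coupled normal model; returns n x n_features.
# Correlated pairs share their quantile with probability rho (else draw
# independently): a Frechet-style mixture copula. This preserves every
# marginal exactly while making tail events — the rare signals detectors
# perceive — genuinely co-occur, which is the raw material of the
# broken-co-occurrence anomaly mechanism. (A Gaussian copula at the same
# correlation has vanishing tail dependence: its pairs are correlated in
# the bulk but their rare signals almost never coincide, so there is no
# signal co-occurrence to break.)
synth_draw_normal <- function(cfg, n) {
  u <- matrix(runif(n * cfg$n_features), n, cfg$n_features)
  if (nrow(cfg$correlated_pairs %||% matrix(0, 0, 2)) > 0) {
    for (k in seq_len(nrow(cfg$correlated_pairs))) {
      a <- cfg$correlated_pairs[k, 1]
      b <- cfg$correlated_pairs[k, 2]
      share <- runif(n) < cfg$rho
      u[share, b] <- u[share, a]
    }
  }
  synth_quantile(u, cfg$base)
}

#' Generate a synthetic semi-supervised split
#'
#' Draws normal data from the configured model, splits it into training and
#' test portions, and generates anomalous samples by the configured
#' mechanism (see [synthetic_config()]).
#'
#' @param cfg A [synthetic_config()].
#' @return A `cfa_split` with label column `class`
#'   (`"normal"` / `"anomalous"`) and `normal_labels = "normal"`.
#' @export
generate_synthetic <- function(cfg) {
  stopifnot(inherits(cfg, "cfa_synthetic_config"))
  set.seed(cfg$seed)
  Xn <- synth_draw_normal(cfg, cfg$n_normal)
  train_idx <- sort(sample.int(cfg$n_normal, cfg$n_train))
  Xtr <- Xn[train_idx, , drop = FALSE]
  lo <- apply(Xtr, 2, min)
  hi <- apply(Xtr, 2, max)

  Xa <- synth_draw_normal(cfg, cfg$n_anomalous)
  if (cfg$anomaly_mechanism == "outlier") {
    rng <- hi - lo
    for (s in seq_len(cfg$n_anomalous)) {
      jf <- sample.int(cfg$n_features, 1)
      up <- runif(1) < 0.5
      Xa[s, jf] <- if (up) hi[jf] + cfg$anomaly_magnitude * rng[jf]
                   else lo[jf] - cfg$anomaly_magnitude * rng[jf]
    }
  } else if (cfg$anomaly_mechanism == "excess_absence") {
    for (s in seq_len(cfg$n_anomalous)) {
      jf <- sample.int(cfg$n_features, cfg$n_absent)
      upper <- runif(cfg$n_absent) < 0.5
      u <- runif(cfg$n_absent, 0, cfg$tail_prob)
      u[upper] <- 1 - u[upper]
      Xa[s, jf] <- synth_quantile(u, cfg$base)
    }
  } else { # broken_combination
    for (k in seq_len(nrow(cfg$correlated_pairs))) {
      b <- cfg$correlated_pairs[k, 2]
      Xa[, b] <- Xa[sample.int(cfg$n_anomalous), b]
    }
  }

  nm <- sprintf("f%02d", seq_len(cfg$n_features))
  as_tbl <- function(X) {
    colnames(X) <- nm
    tibble::as_tibble(X)
  }
  add_class <- function(tbl, cls) {
    tbl$class <- cls
    tbl
  }
  structure(list(
    train_normal = add_class(as_tbl(Xtr), "normal"),
    test_normal = add_class(as_tbl(Xn[-train_idx, , drop = FALSE]), "normal"),
    test_anomalous = add_class(as_tbl(Xa), "anomalous"),
    label = "class",
    normal_labels = "normal",
    seed = cfg$seed,
    config = cfg
  ), class = "cfa_split")
}
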