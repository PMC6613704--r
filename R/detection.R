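#' Detection-stage parameters
#'
#' @param W_d Monitoring window per sample, in iterations (default `1e4`).
#' @param tau_A Anergy time: any detector pairing reaching this age is
#'   terminated and the detector replaced from the repertoire. Must be at
#'   least 2 or the kinetic-proofreading effect that converts pairing
#'   lifetimes into signal is lost. Default 5.
#' @param tau_act Pairing duration that counts as activation (defaults to
#'   `tau_A`).
#' @param f Calibration fraction in (0, 1]: activation thresholds are set at
#'   the `ceiling(N_c * f)`-th largest calibration value (default 0.1).
#' @param fpr Operating false-positive rate for [tpr_at_fpr()] (default 0.1).
#' @param seed Optional integer seed.
#' @return A `cfa_detection_params` list.
#' @export
detection_params <- function(W_d = 1e4, tau_A = 5, tau_act = NULL, f = 0.1,
                             fpr = 0.1, seed = NULL) {
  tau_A <- as.integer(tau_A)
  if (tau_A < 2) abort("tau_A must be at least 2")
  if (!(f > 0 && f <= 1)) abort("f must be in (0, 1]")
  if (!(fpr > 0 && fpr < 1)) abort("fpr must be in (0, 1)")
  tau_act <- as.integer(tau_act %||% tau_A)
  if (tau_act > tau_A) abort("tau_act cannot exceed tau_A")
  structure(list(W_d = as.integer(W_d), tau_A = tau_A, tau_act = tau_act,
                 f = f, fpr = fpr, seed = seed),
            class = "cfa_detection_params")
}

#' Monitor one sample with the repertoire
#'
#' Fills every detector slot with a uniformly drawn repertoire member and
#' runs `W_d` iterations of the frustrated dynamics under the displayed
#' sample. Any detector pairing reaching age `tau_A` is terminated (anergy),
#' both members' survival counters are incremented at `tau_A`, and the slot
#' is refilled by a random repertoire member with the same connectivity.
#' Per-iteration survival counters accumulate per agent: `c(tau)` counts
#' contacts surviving at least `tau` iterations, for `tau = 0..tau_A`.
#'
#' @param rep A `cfa_repertoire`.
#' @param x Raw feature vector of the displayed sample.
#' @param params A [detection_params()].
#' @return A `cfa_counts`: list with matrices `c_p` (presenters) and `c_d`
#'   (detectors) of dimension `N x (tau_A + 1)`, plus `tau_A`, `tau_act`.
#' @export
monitor <- function(rep, x, params = detection_params()) {
  pop <- rep$population
  res <- cpp_monitor(pop$conn, rep$ilists, pop$subtype, pop$digit,
                     pop$side, pop$v, pop_F(pop, x),
                     params$W_d, params$tau_A)
  structure(list(c_p = res$c_p, c_d = res$c_d,
                 tau_A = params$tau_A, tau_act = params$tau_act),
            class = "cfa_counts")
}

# internal: normalised long-pairing survival fraction per presenter,
# c~(tau_act) = c(tau_act) / c(0), defined as 0 when c(0) = 0
ctilde <- function(counts) {
  c0 <- counts$c_p[, 1]
  ca <- counts$c_p[, counts$tau_act + 1L]
  ifelse(c0 > 0, ca / c0, 0)
}

#' Calibrate activation thresholds on normal samples
#'
#' Monitors each calibration sample (only normal training samples are used),
#' computes the normalised survival fraction per presenter, and sets the
#' activation threshold of presenter `i` to the `x`-th largest value over
#' samples, `x = ceiling(N_c * f)`. With `f = 1` the threshold is the
#' minimum (most permissive).
#'
#' @param rep A `cfa_repertoire`.
#' @param samples Calibration samples: tibble/matrix of raw feature rows.
#' @param params A [detection_params()].
#' @param label Optional label column name in `samples`.
#' @return A `cfa_thresholds`: `n_tilde` (per-presenter threshold in
#'   `[0, 1]`), the calibration `c_tilde` matrix, `N_c`, `f`.
#' @export
calibrate <- function(rep, samples, params = detection_params(), label = NULL) {
  X <- if (is.matrix(samples)) samples else {
    as.matrix(samples[setdiff(names(samples), label)])
  }
  if (nrow(X) == 0L) abort("empty calibration set")
  if (!is.null(params$seed)) set.seed(params$seed)
  ct <- t(vapply(seq_len(nrow(X)), function(s) {
    ctilde(monitor(rep, X[s, ], params))
  }, numeric(rep$population$N)))
  x_idx <- as.integer(ceiling(nrow(X) * params$f))
  n_tilde <- apply(ct, 2, function(col) sort(col, decreasing = TRUE)[x_idx])
  structure(list(n_tilde = n_tilde, c_tilde = ct,
                 N_c = nrow(X), f = params$f, params = params),
            class = "cfa_thresholds")
}

#' Frustration response of a sample
#'
#' The response sums, over presenters, the positive part of the excess of
#' the sample's normalised long-pairing fraction over the calibrated
#' activation threshold: `R_s = sum_i max(0, c~_i - n~_i)`. Large responses
#' indicate that some presenters sustained unusually many long pairings —
#' the signature of an anomaly.
#'
#' @param counts A `cfa_counts` from [monitor()], or directly a numeric
#'   vector of normalised survival fractions.
#' @param thresholds A `cfa_thresholds` from [calibrate()], or a numeric
#'   vector of thresholds.
#' @return Nonnegative scalar response.
#' @export
response <- function(counts, thresholds) {
  ct <- if (inherits(counts, "cfa_counts")) ctilde(counts) else as.numeric(counts)
  nt <- if (inherits(thresholds, "cfa_thresholds")) thresholds$n_tilde else as.numeric(thresholds)
  if (length(ct) != length(nt)) abort("counts and thresholds cover different presenter sets")
  sum(pmax(0, ct - nt))
}

#' Score a set of samples
#'
#' Runs [monitor()] on each row (a fresh repertoire draw per sample) and
#' computes its [response()].
#'
#' @param rep A `cfa_repertoire`.
#' @param thresholds A `cfa_thresholds`.
#' @param newdata Tibble/matrix of raw feature rows.
#' @param params A [detection_params()].
#' @param label Optional label column name; if present in `newdata` it is
#'   carried into the result.
#' @return Tibble with columns `sample`, `response` (and `label` if given).
#' @export
score_samples <- function(rep, thresholds, newdata, params = detection_params(),
                          label = NULL) {
  lab <- if (!is.null(label) && label %in% names(newdata)) newdata[[label]] else NULL
  X <- if (is.matrix(newdata)) newdata else {
    as.matrix(newdata[setdiff(names(newdata), label)])
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  R <- vapply(seq_len(nrow(X)), function(s) {
    response(monitor(rep, X[s, ], params), thresholds)
  }, numeric(1))
  out <- tibble::tibble(sample = seq_len(nrow(X)), response = R)
  if (!is.null(lab)) out$label <- lab
  out
}

#' True positive rate at a fixed false positive rate
#'
#' The decision threshold is the `x`-th largest normal response with
#' `x = ceiling(N * FPR)`; the TPR is the fraction of anomalous responses
#' strictly above it.
#'
#' @param normal_r Responses of normal test samples.
#' @param anomalous_r Responses of anomalous test samples.
#' @param fpr Operating false positive rate.
#' @return TPR in `[0, 1]`.
#' @export
tpr_at_fpr <- function(normal_r, anomalous_r, fpr = 0.1) {
  if (length(normal_r) == 0L || length(anomalous_r) == 0L) {
    abort("both response vectors must be non-empty")
  }
  x <- as.integer(ceiling(length(normal_r) * fpr))
  r_x <- sort(normal_r, decreasing = TRUE)[x]
  mean(anomalous_r > r_x)
}

#' ROC curve over a grid of false positive rates
#'
#' @inheritParams tpr_at_fpr
#' @param fpr_grid Grid of FPR values.
#' @return A `cfa_roc` tibble (`fpr`, `tpr`), nondecreasing in `fpr`.
#' @export
roc_curve <- function(normal_r, anomalous_r, fpr_grid = seq(0.02, 1, by = 0.02)) {
  out <- tibble::tibble(
    fpr = fpr_grid,
    tpr = vapply(fpr_grid, function(a) tpr_at_fpr(normal_r, anomalous_r, a),
                 numeric(1))
  )
  class(out) <- c("cfa_roc", class(out))
  out
}

# internal: rare-signal counts per sample row for a tail size
rare_signal_counts <- function(mapper, X, tail) {
  X <- if (is.matrix(X)) X else as.matrix(X)
  if (tail == 0) {
    lo <- matrix(mapper$x_min, nrow(X), ncol(X), byrow = TRUE)
    hi <- matrix(mapper$x_max, nrow(X), ncol(X), byrow = TRUE)
    rowSums(X < lo | X > hi)
  } else {
    Fm <- mapper_cdf(mapper, X)
    rowSums(Fm < tail | Fm > 1 - tail)
  }
}

#' Counting-rule baseline: rare signals per sample
#'
#' Counts, per sample, the features falling in a left or right tail of size
#' `tail` of the training distribution (`tail = 0` counts features outside
#' the observed training range) and thresholds the count at the level
#' exceeded by a fraction `fpr` of normal test samples.
#'
#' @param mapper A `cfa_mapper` fitted on the training normals.
#' @param split A `cfa_split` (its test sets are scored).
#' @param tail Tail probability (0 or e.g. 0.05).
#' @param fpr Operating false positive rate (default 0.1).
#' @return List with `tpr`, and the per-sample `normal_counts` /
#'   `anomalous_counts`.
#' @export
baseline_rare_count <- function(mapper, split, tail = 0, fpr = 0.1) {
  feats <- setdiff(names(split$test_normal), split$label)
  cn <- rare_signal_counts(mapper, split$test_normal[feats], tail)
  ca <- rare_signal_counts(mapper, split$test_anomalous[feats], tail)
  list(tpr = tpr_at_fpr(cn, ca, fpr), tail = tail,
       normal_counts = cn, anomalous_counts = ca)
}

#' Counting-rule baseline: rare perceptions in the detectors' ILists
#'
#' Counts, per sample, the number of (detector, presenter) perceptions the
#' repertoire's perception maps classify as rare — each detector applies its
#' own one-sided tail `v` per connected presenter — and thresholds like
#' [baseline_rare_count()].
#'
#' @param rep A `cfa_repertoire` (its shared perception maps define the
#'   tails).
#' @param split A `cfa_split`.
#' @param fpr Operating false positive rate (default 0.1).
#' @return List with `tpr` and the per-sample count vectors.
#' @export
baseline_ilists_rare_count <- function(rep, split, fpr = 0.1) {
  pop <- rep$population
  feats <- setdiff(names(split$test_normal), split$label)
  count_rows <- function(tbl) {
    Fm <- mapper_cdf(pop$mapper, as.matrix(tbl[feats]))
    vapply(seq_len(nrow(Fm)), function(s) {
      sum(pop_rare(pop, Fm[s, ]))
    }, numeric(1))
  }
  cn <- count_rows(split$test_normal)
  ca <- count_rows(split$test_anomalous)
  list(tpr = tpr_at_fpr(cn, ca, fpr), normal_counts = cn, anomalous_counts = ca)
}
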