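#' Fit the presenter signal mapper on training data
#'
#' Presenter `i` displays the signal
#' `s_i = i + (x_i - x_min_i) / (x_max_i - x_min_i + eps)`, so signals of
#' distinct presenters live in disjoint unit intervals `[i, i+1)`. The
#' extremes and the per-feature empirical CDF `F_i` are estimated from the
#' training rows only; `eps` is a small range-scaled guard that keeps
#' `s_i` strictly below `i + 1`.
#'
#' @param train Training data: a tibble/data.frame (label column dropped via
#'   `label`) or a numeric matrix. Must be non-empty.
#' @param label Optional name of a label column to drop.
#' @return A `cfa_mapper`.
#' @export
fit_mapper <- function(train, label = NULL) {
  X <- if (is.matrix(train)) train else {
    as.matrix(train[setdiff(names(train), label)])
  }
  storage.mode(X) <- "double"
  if (nrow(X) == 0L) abort("empty training set")
  if (anyNA(X)) abort("missing values in training data")
  x_min <- apply(X, 2, min)
  x_max <- apply(X, 2, max)
  # small guard keeping s_i strictly below i + 1; floored at range * 2^-32
  # so every in-range signal also stays strictly below the out-of-range
  # clip value i + (1 - 2^-33) used by map_sample()
  eps <- pmax(x_max - x_min, 2^-20) * 2^-32
  m <- structure(list(
    n_features = ncol(X),
    feature_names = colnames(X) %||% sprintf("f%02d", seq_len(ncol(X))),
    x_min = x_min, x_max = x_max, eps = eps,
    n_train = nrow(X),
    sorted_x = lapply(seq_len(ncol(X)), function(j) sort(X[, j]))
  ), class = "cfa_mapper")
  m$sorted_s <- lapply(seq_len(m$n_features), function(j) {
    j + (m$sorted_x[[j]] - x_min[j]) / (x_max[j] - x_min[j] + eps[j])
  })
  m
}

#' @export
print.cfa_mapper <- function(x, ...) {
  cat(sprintf("<cfa_mapper> %d features, fitted on %d training samples\n",
              x$n_features, x$n_train))
  invisible(x)
}

#' Map a feature vector onto presenter signals
#'
#' Applies the disjoint-interval signal transform fitted by [fit_mapper()].
#' Values outside the training range are clipped into `[i, i+1)`; their CDF
#' still evaluates to 0 or 1, so any detector with a positive tail threshold
#' perceives them as rare.
#'
#' @param mapper A `cfa_mapper`.
#' @param x Numeric feature vector of length `n_features`.
#' @return Numeric vector of signals, `s[i]` in `[i, i+1)`.
#' @export
map_sample <- function(mapper, x) {
  if (length(x) != mapper$n_features) {
    abort(sprintf("expected %d features, got %d", mapper$n_features, length(x)))
  }
  i <- seq_len(mapper$n_features)
  frac <- (x - mapper$x_min) / (mapper$x_max - mapper$x_min + mapper$eps)
  # values above the training range clip to i + (1 - 2^-33), strictly above
  # every in-range signal (the eps floor guarantees the gap) and strictly
  # below i + 1 in floating point; values below the range clip to i
  frac <- pmin(pmax(frac, 0), 1 - 2^-33)
  unname(i + frac)
}

#' Map many samples at once
#'
#' @param mapper A `cfa_mapper`.
#' @param X Matrix or data frame of rows to map (label column dropped via
#'   `label`).
#' @param label Optional label column name.
#' @return Matrix of signals, one row per sample.
#' @export
map_samples <- function(mapper, X, label = NULL) {
  X <- if (is.matrix(X)) X else as.matrix(X[setdiff(names(X), label)])
  t(apply(X, 1, function(r) map_sample(mapper, r)))
}

# internal: empirical CDF values per feature for raw feature rows.
# F_i(x) = #{training values <= x} / n_train (right-continuous). Values
# strictly outside the training range carry a sentinel just beyond [0, 1] so
# that the strict tail tests (F < v, F > 1 - v) classify them as rare for
# every tail size including v = 0: a signal never displayed during training
# is an outlier to every detector on the matching side.
mapper_cdf <- function(mapper, X) {
  X <- if (is.matrix(X)) X else as.matrix(X)
  out <- matrix(0, nrow(X), mapper$n_features)
  for (j in seq_len(mapper$n_features)) {
    Fj <- findInterval(X[, j], mapper$sorted_x[[j]]) / mapper$n_train
    Fj[X[, j] > mapper$x_max[j]] <- 1 + 1e-9
    Fj[X[, j] < mapper$x_min[j]] <- -1e-9
    out[, j] <- Fj
  }
  out
}

#' Empirical CDF of a displayed signal
#'
#' Evaluates the training empirical CDF of presenter `i`'s signal; `s` below
#' (above) every training signal yields 0 (1).
#'
#' @param mapper A `cfa_mapper`.
#' @param s A signal value; its presenter is `floor(s)`.
#' @return CDF value in `[0, 1]`.
#' @export
signal_cdf <- function(mapper, s) {
  i <- as.integer(floor(s))
  if (i < 1 || i > mapper$n_features) abort("signal outside any presenter range")
  findInterval(s, mapper$sorted_s[[i]]) / mapper$n_train
}

#' Draw one-sided perception maps for a detector
#'
#' Each detector perceives each connected presenter's signal through a
#' one-sided tail test: a tail side (left/right, equiprobable) and a tail
#' probability `v ~ Uniform(0, v_max)`. Signals whose training CDF falls in
#' the tail are perceived as rare (`r_i`), all others as frequent (`f_i`).
#'
#' @param presenters Integer vector of presenter indices the detector is
#'   connected to.
#' @param v_max Maximum tail probability, in `[0, 1)`.
#' @return Tibble with columns `presenter`, `side` (`"left"`/`"right"`), `v`.
#' @export
draw_perceptions <- function(presenters, v_max) {
  if (v_max < 0 || v_max >= 1) abort("v_max must be in [0, 1)")
  n <- length(presenters)
  tibble::tibble(
    presenter = presenters,
    side = sample(c("left", "right"), n, replace = TRUE),
    v = runif(n, 0, v_max)
  )
}

#' Perceive a signal as frequent or rare
#'
#' A left-sided perception maps `s` to rare when `F(s) < v`; a right-sided
#' one when `F(s) > 1 - v`. With `v = 0` no training signal is ever rare; a
#' signal strictly above every training signal is rare to every right-sided
#' detector, whatever its `v`. (Signals clipped at the lower interval
#' boundary coincide with the training minimum, so left-side out-of-range
#' handling is exact only in the raw-value pipeline, which evaluates the
#' CDF before clipping.)
#'
#' @param mapper A `cfa_mapper`.
#' @param s Signal value (presenter `floor(s)`).
#' @param side `"left"` or `"right"`.
#' @param v Tail probability.
#' @return Token string, `"f_<i>"` or `"r_<i>"`.
#' @export
perceive <- function(mapper, s, side, v) {
  i <- as.integer(floor(s))
  Fs <- signal_cdf(mapper, s)
  if (s > max(mapper$sorted_s[[i]])) Fs <- 1 + 1e-9
  rare <- if (side == "left") Fs < v else Fs > 1 - v
  paste0(if (rare) "r" else "f", "_", i)
}
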