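#' Tidy a training run
#'
#' @param x A `cfa_trained`.
#' @param ... Ignored.
#' @return The per-window trace tibble (`window`, `iterations`, `tau_n`,
#'   `n_subs`).
#' @export
tidy.cfa_trained <- function(x, ...) x$trace

#' @rdname tidy.cfa_trained
#' @return For `glance()`: one row with `strategy`, `windows`, `iterations`,
#'   `final_tau_n`, `reached_target`.
#' @export
glance.cfa_trained <- function(x, ...) {
  tibble::tibble(
    strategy = x$params$strategy,
    windows = nrow(x$trace),
    iterations = x$iterations,
    final_tau_n = utils::tail(x$trace$tau_n, 1),
    reached_target = is.finite(x$iterations_to_target)
  )
}

#' Tidy a repertoire
#'
#' @param x A `cfa_repertoire`.
#' @param ... Ignored.
#' @return Stacked per-population training traces with a `population`
#'   column.
#' @export
tidy.cfa_repertoire <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$traces), function(k) {
    dplyr::mutate(x$traces[[k]], population = k)
  }))
}

#' @rdname tidy.cfa_repertoire
#' @export
glance.cfa_repertoire <- function(x, ...) {
  tibble::tibble(
    strategy = x$params$strategy,
    N_pop = x$N_pop,
    N = x$population$N,
    C = x$population$C,
    v_max = x$population$v_max,
    mean_final_tau_n = mean(vapply(x$traces, function(tr) {
      utils::tail(tr$tau_n, 1)
    }, numeric(1)))
  )
}

#' Tidy an experiment
#'
#' @param x A `cfa_experiment`.
#' @param ... Ignored.
#' @return The per-fold tibble (`fold`, `seed`, `tpr`).
#' @export
tidy.cfa_experiment <- function(x, ...) x$folds

#' @rdname tidy.cfa_experiment
#' @return For `glance()`: one row with `strategy`, `folds`, `mean_tpr`,
#'   `sd_tpr`, `fpr`.
#' @export
glance.cfa_experiment <- function(x, ...) {
  tibble::tibble(
    strategy = x$config$strategy,
    folds = nrow(x$folds),
    mean_tpr = mean(x$folds$tpr),
    sd_tpr = if (nrow(x$folds) > 1) sd(x$folds$tpr) else 0,
    fpr = x$config$fpr
  )
}
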