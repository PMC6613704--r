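#' Experiment configuration
#'
#' Bundles every tunable of an end-to-end run with defaults matching the
#' reference parameterisation: `v_max = 5%`, `N_pop = 12`, `C = 20`,
#' `W_tau = 1e4`, `T_S = 100`, `W_d = 1e4`, `tau_A = 5`, `tau_act = tau_A`,
#' `f = 0.1`, all overridable.
#'
#' @param label Label column name.
#' @param normal_labels Labels of the normal class.
#' @param n_train Normal samples drawn for training per fold.
#' @param folds Monte-Carlo cross-validation folds (default 10).
#' @param strategy Education strategy, `"AIS"` or `"IS"`.
#' @param v_max,C Population parameters, see [build_population()].
#' @param N_pop,W_tau,T_S,t_max,tau_target Training parameters, see
#'   [training_params()] and [build_repertoire()].
#' @param W_d,tau_A,tau_act,f,fpr Detection parameters, see
#'   [detection_params()].
#' @param min_presenters Presenter count that feature replication must
#'   exceed (see [replicate_features()]).
#' @param fpr_grid FPR grid for the ROC.
#' @param csv Optional path of a CSV dataset (see [load_csv()]).
#' @param synthetic Optional [synthetic_config()] (or list of its arguments)
#'   used instead of a CSV; each fold regenerates with a fold-derived seed.
#' @param out_dir Optional directory for response tables, ROC CSV,
#'   repertoire JSONs and a run log.
#' @param seed Master seed; every fold derives its own stream from it.
#' @return A `cfa_run_config` list.
#' @export
run_config <- function(label = "class", normal_labels = "normal",
                       n_train = 100, folds = 10,
                       strategy = c("AIS", "IS"),
                       v_max = 0.05, C = 20, N_pop = 12,
                       W_tau = 1e4, T_S = 100, t_max = 100, tau_target = NULL,
                       W_d = 1e4, tau_A = 5, tau_act = NULL, f = 0.1,
                       fpr = 0.1, min_presenters = 32,
                       fpr_grid = seq(0.05, 1, by = 0.05),
                       csv = NULL, synthetic = NULL, out_dir = NULL,
                       seed = 1L) {
  strategy <- match.arg(strategy)
  cfg <- list(label = label, normal_labels = normal_labels, n_train = n_train,
              folds = as.integer(folds), strategy = strategy, v_max = v_max,
              C = as.integer(C), N_pop = as.integer(N_pop),
              W_tau = as.integer(W_tau), T_S = as.integer(T_S),
              t_max = as.integer(t_max), tau_target = tau_target,
              W_d = as.integer(W_d), tau_A = as.integer(tau_A),
              tau_act = tau_act, f = f, fpr = fpr,
              min_presenters = as.integer(min_presenters),
              fpr_grid = fpr_grid, csv = csv, synthetic = synthetic,
              out_dir = out_dir, seed = as.integer(seed))
  structure(cfg, class = "cfa_run_config")
}

#' Read an experiment configuration from a YAML/JSON file
#'
#' Flat keys named after the algorithm's symbols (`v_max`, `N_pop`, `C`,
#' `W_tau`, `T_S`, `W_d`, `tau_A`, `tau_act`, `f`, `fpr`, ...) override the
#' [run_config()] defaults. A `synthetic` block is passed to
#' [synthetic_config()].
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A `cfa_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$synthetic)) {
    raw$synthetic <- do.call(synthetic_config, raw$synthetic)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, raw)
}

# internal: one fold end-to-end; fold_seed drives every stochastic stage
run_fold <- function(data, cfg, fold_seed) {
  set.seed(fold_seed)
  if (!is.null(cfg$synthetic)) {
    syn <- cfg$synthetic
    syn$seed <- sample.int(.Machine$integer.max, 1)
    split <- generate_synthetic(syn)
  } else {
    split <- make_split(data, cfg$label, cfg$normal_labels, cfg$n_train,
                        seed = sample.int(.Machine$integer.max, 1))
  }
  split$train_normal <- replicate_features(split$train_normal, cfg$label,
                                           cfg$min_presenters)
  split$test_normal <- replicate_features(split$test_normal, cfg$label,
                                          cfg$min_presenters)
  split$test_anomalous <- replicate_features(split$test_anomalous, cfg$label,
                                             cfg$min_presenters)
  mapper <- fit_mapper(split$train_normal, label = cfg$label)
  pop <- build_population(mapper, C = cfg$C, v_max = cfg$v_max)
  tp <- training_params(strategy = cfg$strategy, W_tau = cfg$W_tau,
                        T_S = cfg$T_S, t_max = cfg$t_max,
                        tau_target = cfg$tau_target)
  rep <- build_repertoire(pop, split$train_normal, tp, N_pop = cfg$N_pop,
                          label = cfg$label)
  dp <- detection_params(W_d = cfg$W_d, tau_A = cfg$tau_A,
                         tau_act = cfg$tau_act, f = cfg$f, fpr = cfg$fpr)
  th <- calibrate(rep, split$train_normal, dp, label = cfg$label)
  rn <- score_samples(rep, th, split$test_normal, dp, label = cfg$label)
  ra <- score_samples(rep, th, split$test_anomalous, dp, label = cfg$label)
  list(split = split, repertoire = rep, thresholds = th,
       responses = dplyr::bind_rows(
         dplyr::mutate(rn, truth = "normal"),
         dplyr::mutate(ra, truth = "anomalous")
       ),
       tpr = tpr_at_fpr(rn$response, ra$response, cfg$fpr),
       roc = roc_curve(rn$response, ra$response, cfg$fpr_grid))
}

#' Run an end-to-end cross-validated experiment
#'
#' Executes `folds` independent splits: split (or regenerate synthetic
#' data), replicate features, fit the signal mapper, build and educate a
#' repertoire, calibrate, score both test sets, and evaluate TPR at the
#' operating FPR plus the full ROC. Every fold derives its own seed from the
#' master seed, so two runs with the same configuration are identical.
#'
#' @param config A [run_config()] (or [read_run_config()] result).
#' @param data Optional labelled tibble; otherwise taken from `config$csv`
#'   or generated from `config$synthetic`.
#' @return A `cfa_experiment`: `folds` tibble (`fold`, `seed`, `tpr`), mean
#'   ROC tibble (`fpr`, `mean_tpr`, `sd_tpr`), per-fold `responses`, and the
#'   `config`.
#' @export
run_experiment <- function(config = run_config(), data = NULL) {
  cfg <- config
  if (is.null(data) && !is.null(cfg$csv)) data <- load_csv(cfg$csv, cfg$label)
  if (is.null(data) && is.null(cfg$synthetic)) {
    abort("provide `data`, config$csv or config$synthetic")
  }
  set.seed(cfg$seed)
  fold_seeds <- sample.int(.Machine$integer.max, cfg$folds)
  fold_runs <- lapply(seq_len(cfg$folds), function(k) {
    run_fold(data, cfg, fold_seeds[k])
  })
  folds <- tibble::tibble(
    fold = seq_len(cfg$folds),
    seed = fold_seeds,
    tpr = vapply(fold_runs, `[[`, numeric(1), "tpr")
  )
  roc_all <- dplyr::bind_rows(lapply(seq_len(cfg$folds), function(k) {
    dplyr::mutate(fold_runs[[k]]$roc, fold = k)
  }))
  roc <- dplyr::summarise(dplyr::group_by(roc_all, .data$fpr),
                          mean_tpr = mean(.data$tpr),
                          sd_tpr = if (cfg$folds > 1) sd(.data$tpr) else 0,
                          .groups = "drop")
  class(roc) <- c("cfa_roc", class(roc))
  out <- structure(list(
    folds = folds, roc = roc,
    responses = lapply(fold_runs, `[[`, "responses"),
    config = cfg
  ), class = "cfa_experiment")
  if (!is.null(cfg$out_dir)) write_experiment(out, fold_runs)
  out
}

# internal: side-effect outputs of a run (response tables, ROC, repertoire
# JSONs, run log)
write_experiment <- function(exp, fold_runs) {
  cfg <- exp$config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(fold_runs)) {
    readr::write_csv(fold_runs[[k]]$responses,
                     file.path(cfg$out_dir, sprintf("responses_fold%02d.csv", k)))
    write_repertoire(fold_runs[[k]]$repertoire,
                     file.path(cfg$out_dir, sprintf("repertoire_fold%02d.json", k)),
                     thresholds = fold_runs[[k]]$thresholds)
  }
  readr::write_csv(exp$roc, file.path(cfg$out_dir, "roc.csv"))
  readr::write_csv(exp$folds, file.path(cfg$out_dir, "folds.csv"))
  log <- cfg
  log$synthetic <- if (!is.null(cfg$synthetic)) unclass(cfg$synthetic)
  jsonlite::write_json(list(config = unclass(log), fold_seeds = exp$folds$seed),
                       file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(exp)
}

#' @export
print.cfa_experiment <- function(x, ...) {
  cat(sprintf("<cfa_experiment> %s, %d folds\n", x$config$strategy,
              x$config$folds))
  cat(sprintf("  TPR at %.0f%% FPR: %.3f +/- %.3f\n", 100 * x$config$fpr,
              mean(x$folds$tpr), if (nrow(x$folds) > 1) sd(x$folds$tpr) else 0))
  invisible(x)
}

#' Serialize a repertoire (and optional thresholds) to JSON
#'
#' Documented layout: `mapper` (training extremes, epsilon, sorted training
#' values), `population` (subtypes, digits, connectivity, perception sides
#' and tail probabilities), `ilists` (one rank matrix per educated
#' population, row = detector, column = token; tokens alternate
#' frequent/rare per connection slot), `params`, and optionally the
#' calibrated `thresholds`.
#'
#' @param rep A `cfa_repertoire`.
#' @param path Output path.
#' @param thresholds Optional `cfa_thresholds` to embed.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(rep, path, thresholds = NULL) {
  pop <- rep$population
  obj <- list(
    mapper = list(
      feature_names = pop$mapper$feature_names,
      x_min = pop$mapper$x_min, x_max = pop$mapper$x_max,
      eps = pop$mapper$eps, n_train = pop$mapper$n_train,
      sorted_x = pop$mapper$sorted_x
    ),
    population = list(N = pop$N, C = pop$C, v_max = pop$v_max,
                      subtype = pop$subtype, digit = pop$digit,
                      conn = pop$conn, side = pop$side, v = pop$v),
    params = list(strategy = rep$params$strategy, W_tau = rep$params$W_tau,
                  T_S = rep$params$T_S, t_max = rep$params$t_max,
                  tau_target = rep$params$tau_target),
    N_pop = rep$N_pop,
    ilists = rep$ilists,
    traces = lapply(rep$traces, as.list)
  )
  if (!is.null(thresholds)) {
    obj$thresholds <- list(n_tilde = thresholds$n_tilde, N_c = thresholds$N_c,
                           f = thresholds$f)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a repertoire written by [write_repertoire()]
#'
#' @param path JSON path.
#' @return A `cfa_repertoire` (with `thresholds` attached as an attribute
#'   when present in the file).
#' @export
read_repertoire <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$mapper
  mapper <- structure(list(
    n_features = length(m$feature_names),
    feature_names = m$feature_names,
    x_min = m$x_min, x_max = m$x_max, eps = m$eps, n_train = m$n_train,
    sorted_x = if (is.matrix(m$sorted_x)) {
      lapply(seq_len(nrow(m$sorted_x)), function(i) m$sorted_x[i, ])
    } else as.list(m$sorted_x)
  ), class = "cfa_mapper")
  mapper$sorted_s <- lapply(seq_len(mapper$n_features), function(j) {
    j + (mapper$sorted_x[[j]] - mapper$x_min[j]) /
      (mapper$x_max[j] - mapper$x_min[j] + mapper$eps[j])
  })
  p <- obj$population
  pop <- structure(list(
    N = p$N, C = p$C, v_max = p$v_max,
    subtype = as.integer(p$subtype), digit = as.integer(p$digit),
    conn = matrix(as.integer(p$conn), p$N, p$C),
    side = matrix(as.logical(p$side), p$N, p$C),
    v = matrix(as.numeric(p$v), p$N, p$C),
    mapper = mapper
  ), class = "cfa_population")
  frozen <- matrix(FALSE, pop$N, 2L * pop$C)
  for (j in seq_len(pop$N)) {
    frozen[j, 2L * seq_len(pop$C)] <- pop$subtype[pop$conn[j, ]] != pop$digit[j]
  }
  pop$frozen <- frozen
  pop$n_educ <- as.integer(2L * pop$C - rowSums(frozen))
  ilists <- obj$ilists
  if (is.array(ilists) && length(dim(ilists)) == 3) {
    ilists <- lapply(seq_len(dim(ilists)[1]), function(k) {
      matrix(as.integer(ilists[k, , ]), pop$N, 2L * pop$C)
    })
  } else if (is.list(ilists)) {
    ilists <- lapply(ilists, function(x) matrix(as.integer(as.matrix(x)),
                                                pop$N, 2L * pop$C))
  }
  pop$ranks <- ilists[[1]]
  pop <- reset_pairing(pop)
  params <- training_params(strategy = obj$params$strategy,
                            W_tau = obj$params$W_tau, T_S = obj$params$T_S,
                            t_max = obj$params$t_max,
                            tau_target = obj$params$tau_target)
  tr_raw <- obj$traces
  traces <- if (is.data.frame(tr_raw)) {
    # an array of trace objects simplifies to a list-column data frame
    lapply(seq_len(nrow(tr_raw)), function(k) {
      tibble::as_tibble(lapply(tr_raw, function(col) unlist(col[k])))
    })
  } else {
    lapply(tr_raw, tibble::as_tibble)
  }
  rep <- structure(list(population = pop, ilists = ilists,
                        traces = traces,
                        params = params, N_pop = obj$N_pop),
                   class = "cfa_repertoire")
  if (!is.null(obj$thresholds)) {
    attr(rep, "thresholds") <- obj$thresholds
  }
  rep
}
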