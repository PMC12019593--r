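col_vars <- function(x) {
  n <- nrow(x)
  (colSums(x^2) - colSums(x)^2 / n) / (n - 1)
}

# deterministic sub-seed derivation (kept well below 2^31)
derive_seed <- function(seed, a, b = 0L) {
  (as.integer(seed) %% 10000L) * 100000L + a * 1000L + b
}

#' Enumerate the full experimental design
#'
#' The two independent variables are the ET-to-MC weight distribution
#' (homogeneous at one of 10 gain levels, or heterogeneous uniform, scaled,
#' adaptive) and the MC duplication factor (4, 8, 16, 32), crossed with the
#' two synthetic datasets: 10 x 4 x 2 = 80 homogeneous runs plus 3 x 4 x 2 =
#' 24 heterogeneous runs, 104 in total.
#'
#' @return A tibble with columns `condition`, `duplication`, `gain_index`
#'   (`NA` for heterogeneous conditions) and `dataset`.
#' @export
enumerate_design <- function() {
  hom <- tidyr::expand_grid(condition = "homogeneous",
                            duplication = c(4L, 8L, 16L, 32L),
                            gain_index = 1:10,
                            dataset = c("concentration", "saturation"))
  het <- tidyr::expand_grid(condition = c("uniform", "scaled", "adaptive"),
                            duplication = c(4L, 8L, 16L, 32L),
                            gain_index = NA_integer_,
                            dataset = c("concentration", "saturation"))
  dplyr::bind_rows(hom, het)[, c("condition", "duplication", "gain_index",
                                 "dataset")]
}

#' Build the eight-fold cross-validation plan
#'
#' One initial shuffle of the pool is partitioned into non-overlapping
#' training splits of two samples per class; each fold's test set is the
#' complement (14 per class for the default 128-sample pool).
#'
#' @param labels Integer class labels of the sample pool (must be balanced,
#'   with `2 * n_folds` samples per class).
#' @param n_folds Number of folds (default 8).
#' @param seed Integer seed for the shuffle.
#' @return A tibble of class `hq_folds` with columns `fold`, `train`
#'   (list of index vectors, 2 per class) and `test` (the complements).
#' @export
make_folds <- function(labels, n_folds = 8L, seed = 1L) {
  counts <- table(labels)
  if (length(unique(counts)) != 1) {
    stop("the sample pool must be class-balanced.", call. = FALSE)
  }
  per_class <- counts[[1]]
  if (per_class != 2L * n_folds) {
    stop("need exactly ", 2L * n_folds, " samples per class for ",
         n_folds, "-fold two-shot splits.", call. = FALSE)
  }
  set.seed(seed)
  shuffled <- sample(seq_along(labels))
  fold_of <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- shuffled[labels[shuffled] == cl]  # class members in shuffle order
    fold_of[idx] <- rep(seq_len(n_folds), each = 2L)
  }
  plan <- tibble::tibble(
    fold = seq_len(n_folds),
    train = lapply(seq_len(n_folds), function(f) which(fold_of == f)),
    test = lapply(seq_len(n_folds), function(f) which(fold_of != f))
  )
  class(plan) <- c("hq_folds", class(plan))
  plan
}

#' Spiking-layer utilization and its regularization metric
#'
#' A unit counts as active on a sample iff its logged phase is positive.
#' Utilization is the percentage of active units per test sample; the
#' regularization metric is the sample (n-1) standard deviation of that
#' percentage across test samples — lower means activity is better yoked to
#' the network's operating range.
#'
#' @param phases Integer matrix, rows = test samples, columns = units of one
#'   layer (0 = silent).
#' @return A list with `mean_pct`, `std_pct` and the per-sample `pct` vector.
#' @export
utilization_regularization <- function(phases) {
  stopifnot(is.matrix(phases), ncol(phases) >= 1)
  if (nrow(phases) < 2) {
    stop("need at least 2 responses to measure utilization spread.",
         call. = FALSE)
  }
  pct <- rowMeans(phases > 0) * 100
  list(mean_pct = mean(pct), std_pct = stats::sd(pct), pct = pct)
}

# stratified fold assignment: per class, shuffled round-robin
strat_assign <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- if (length(idx) > 1) sample(idx) else idx
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# mean accuracy of one (cost, gamma) over few-shot stratified folds:
# train on each single fold (the smaller segment), predict the rest
few_shot_cv_accuracy <- function(X, y, fold, cost, gamma) {
  accs <- vapply(sort(unique(fold)), function(f) {
    tr <- fold == f
    fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
    mean(stats::predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  mean(accs)
}

#' Nested-SVM information measure
#'
#' Quantifies the information a layer's response vectors carry about analyte
#' identity via a hyperparameter-optimized RBF support vector machine. The
#' responses are split in half (stratified): grid search over `cost` and
#' `gamma` runs on the first half under stratified four-fold cross-validation
#' with the *smaller* segment (one fold) used for training, consistent with
#' few-shot learning; the selected model is then trained and tested on the
#' second half under the same four-fold scheme, and predictions are
#' aggregated across the four external folds (each sample is predicted three
#' times, giving 21 predictions per class for the default 112-sample,
#' 14-per-class input).
#'
#' @param features Numeric matrix, rows = test samples, columns = response
#'   features of one layer.
#' @param labels Class labels (coerced to factor); every class needs at
#'   least 4 samples.
#' @param seed Integer seed for the stratified splits.
#' @param c_grid,gamma_grid Hyperparameter grids; defaults cover
#'   `10^-7..10^9` and `10^-8..10^10` at one point per two decades. Ties are
#'   broken toward smaller `cost`, then smaller `gamma`.
#' @return A list: `accuracy` (correct/total over aggregated predictions),
#'   `confusion` (true x predicted count matrix), `best_cost`, `best_gamma`,
#'   `n_predictions`.
#' @export
svm_information <- function(features, labels, seed = 1L,
                            c_grid = 10^seq(-7, 9, by = 2),
                            gamma_grid = 10^seq(-8, 10, by = 2)) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  y <- factor(labels)
  if (min(table(y)) < 4) {
    stop("every class needs at least 4 samples.", call. = FALSE)
  }
  # columns constant across all samples add zero to every pairwise squared
  # distance, so dropping them leaves the RBF kernel (and thus the fitted
  # SVM) exactly unchanged while shrinking the problem
  storage.mode(features) <- "double"
  varying <- col_vars(features) > 0
  if (any(varying)) features <- features[, varying, drop = FALSE]
  else features <- features[, 1, drop = FALSE]
  # stratified half split: tuning half / evaluation half
  half <- strat_assign(y, 2L, derive_seed(seed, 1L))
  tune_i <- which(half == 1L)
  eval_i <- which(half == 2L)
  fold_tune <- strat_assign(y[tune_i], 4L, derive_seed(seed, 2L))
  best <- list(acc = -1, cost = NA_real_, gamma = NA_real_)
  for (cost in c_grid) {
    for (gamma in gamma_grid) {
      acc <- few_shot_cv_accuracy(features[tune_i, , drop = FALSE],
                                  y[tune_i], fold_tune, cost, gamma)
      if (acc > best$acc) best <- list(acc = acc, cost = cost, gamma = gamma)
    }
  }
  # external evaluation with the selected hyperparameters
  fold_eval <- strat_assign(y[eval_i], 4L, derive_seed(seed, 3L))
  truth <- factor(levels(y)[0], levels = levels(y))
  pred <- truth
  for (f in sort(unique(fold_eval))) {
    tr <- fold_eval == f
    fit <- e1071::svm(features[eval_i[tr], , drop = FALSE], y[eval_i[tr]],
                      kernel = "radial", cost = best$cost,
                      gamma = best$gamma, scale = FALSE)
    p <- stats::predict(fit, features[eval_i[!tr], , drop = FALSE])
    truth <- c(truth, y[eval_i[!tr]])
    pred <- c(pred, p)
  }
  list(accuracy = mean(truth == pred),
       confusion = table(truth = truth, predicted = pred),
       best_cost = best$cost, best_gamma = best$gamma,
       n_predictions = length(pred))
}

#' Run one cell of the experimental design
#'
#' For each cross-validation fold: build the quantization scheme (calibrating
#' on the fold's 16 training samples for the scaled/adaptive conditions, with
#' learning off), build the network, two-shot train the GC layer, present all
#' test samples with learning off, log the fifth-cycle ET/MC/GC responses,
#' and compute the utilization-regularization and SVM-information metrics per
#' layer. ET features are the normalized analog inputs and serve as the
#' baseline layer.
#'
#' @param data An `hq_samples` tibble (the 128-sample pool).
#' @param folds An [make_folds()] plan.
#' @param condition,duplication,gain_index Cell coordinates (see
#'   [build_scheme()]).
#' @param seed Integer seed governing connectivity and SVM splits.
#' @param layers Which layers to evaluate (subset of `"et"`, `"mc"`, `"gc"`).
#' @param svm Compute the SVM information measure (default `TRUE`; disable
#'   for utilization-only runs).
#' @param n_cycles Cycles per presentation (default 5; the final cycle is
#'   logged).
#' @param c_grid,gamma_grid Passed to [svm_information()].
#' @param drive_constant Optional precomputed [calibrate_drive_constant()].
#' @param engine Simulation engine.
#' @return A tibble with one row per fold x layer: `condition`,
#'   `duplication`, `gain_index`, `dataset`, `fold`, `layer`, `accuracy`,
#'   `util_mean`, `util_std` (both `NA` for the analog ET layer), and a
#'   `confusion` list-column.
#' @export
run_condition <- function(data, folds, condition, duplication,
                          gain_index = NULL, seed = 1L,
                          layers = c("et", "mc", "gc"), svm = TRUE,
                          n_cycles = 5L,
                          c_grid = 10^seq(-7, 9, by = 2),
                          gamma_grid = 10^seq(-8, 10, by = 2),
                          drive_constant = NULL,
                          engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  layers <- match.arg(layers, several.ok = TRUE)
  stopifnot(inherits(folds, "hq_folds"))
  if (is.null(drive_constant)) drive_constant <- calibrate_drive_constant()
  raw <- sample_matrix(data)
  labels <- data$label
  et_all <- t(apply(raw, 1, function(x) normalize_l1(osn_relay(x))))
  dataset <- attr(data, "dataset_tag") %||% "unknown"
  out <- list()
  for (f in folds$fold) {
    tr <- folds$train[[f]]
    te <- folds$test[[f]]
    calib <- NULL
    if (condition %in% c("scaled", "adaptive")) {
      calib <- calibration_set(et_all[tr, , drop = FALSE],
                               n_segments = duplication)
    }
    scheme <- build_scheme(condition, duplication,
                           n_sensors = ncol(raw), gain_index = gain_index,
                           calib = calib, drive_constant = drive_constant)
    net <- epl_network(scheme, seed = derive_seed(seed, f, 1L))
    net <- train_two_shot(net, data[tr, ], n_cycles = n_cycles,
                          engine = engine)
    mc_log <- matrix(0L, length(te), net$n_mc)
    gc_log <- matrix(0L, length(te), net$n_gc)
    for (i in seq_along(te)) {
      res <- present_sample(net, et_all[te[i], ], n_cycles = n_cycles,
                            learning = FALSE, engine = engine)
      mc_log[i, ] <- res$mc_phases[n_cycles, ]
      gc_log[i, ] <- res$gc_phases[n_cycles, ]
    }
    feats <- list(et = et_all[te, , drop = FALSE], mc = mc_log, gc = gc_log)
    utils_ <- list(et = list(mean_pct = NA_real_, std_pct = NA_real_),
                   mc = utilization_regularization(mc_log),
                   gc = utilization_regularization(gc_log))
    for (layer in layers) {
      sv <- if (svm) {
        svm_information(feats[[layer]], labels[te],
                        seed = derive_seed(seed, f, 2L),
                        c_grid = c_grid, gamma_grid = gamma_grid)
      } else {
        list(accuracy = NA_real_, confusion = NULL)
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        condition = condition, duplication = as.integer(duplication),
        gain_index = if (is.null(gain_index)) NA_integer_
                     else as.integer(gain_index),
        dataset = dataset, fold = f, layer = layer,
        accuracy = sv$accuracy,
        util_mean = utils_[[layer]]$mean_pct,
        util_std = utils_[[layer]]$std_pct,
        confusion = list(sv$confusion)
      )
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("hq_runs", class(res))
  res
}

#' Run several design cells on a shared pool and fold plan
#'
#' @param data An `hq_samples` pool.
#' @param folds An [make_folds()] plan.
#' @param design Tibble with columns `condition`, `duplication`,
#'   `gain_index` (as from [enumerate_design()], possibly filtered).
#' @param ... Passed on to [run_condition()].
#' @return Row-bound [run_condition()] results.
#' @export
run_grid <- function(data, folds, design, ...) {
  rows <- purrr::pmap(
    design[, c("condition", "duplication", "gain_index")],
    function(condition, duplication, gain_index) {
      gi <- if (is.na(gain_index)) NULL else gain_index
      run_condition(data, folds, condition, duplication, gain_index = gi, ...)
    })
  res <- dplyr::bind_rows(rows)
  class(res) <- c("hq_runs", class(res))
  res
}

#' Summarize run results across folds
#'
#' Per design cell and layer: mean accuracy with its standard error and a
#' 95% confidence interval over the fold scores (t distribution, n = number
#' of folds), plus mean utilization and the mean regularization metric.
#'
#' @param results An [run_condition()] / [run_grid()] tibble.
#' @return A summary tibble, one row per (condition, duplication, gain_index,
#'   dataset, layer).
#' @export
report_runs <- function(results) {
  out <- results |>
    dplyr::group_by(.data$condition, .data$duplication, .data$gain_index,
                    .data$dataset, .data$layer) |>
    dplyr::summarise(
      n_folds = dplyr::n(),
      accuracy_mean = mean(.data$accuracy),
      accuracy_se = stats::sd(.data$accuracy) / sqrt(dplyr::n()),
      util_mean = mean(.data$util_mean),
      util_std_mean = mean(.data$util_std),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ci_half = stats::qt(0.975, .data$n_folds - 1) * .data$accuracy_se,
      accuracy_lo = .data$accuracy_mean - .data$ci_half,
      accuracy_hi = .data$accuracy_mean + .data$ci_half
    ) |>
    dplyr::select(-"ci_half")
  class(out) <- c("hq_report", class(out))
  out
}
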