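#' Repeated k-fold cross-validated SVM evaluation
#'
#' The evaluation protocol behind all performance tables: per iteration the
#' dataset is split at random into `n_folds` stratified folds (default
#' twofold, i.e. equal-size halves); each fold in turn is held out, feature
#' scaling is refit on the remaining training rows only ([scale_features()])
#' and applied to the held-out rows, an SVM is trained and the held-out rows
#' are scored. For twofold this is exactly train/test, swap, and pool. Each
#' sample is predicted exactly once per iteration; the four metrics are
#' computed once per iteration on the pooled predictions, and their mean and
#' SD over iterations reported. Splits are keyed to stable sample ids, so
#' results are invariant to dataset row order.
#'
#' @param dataset an unscaled [spectra_dataset()]
#' @param config an [svm_config()]
#' @param n_iterations repeated-CV iterations (default 10)
#' @param n_folds folds per iteration (default 2)
#' @param seed integer seed; per-iteration sub-seeds are derived from it
#' @param stratified stratify folds by class (default TRUE); with FALSE a
#'   fold may degenerate to a single class at small n
#' @param scale_within_folds refit scaling per training fold (default TRUE,
#'   leakage-free); FALSE scales once on the full dataset for comparison
#' @return object of class `cv_result`: `iterations` (data frame of
#'   per-iteration sensitivity/specificity/accuracy/AUC), `mean`, `sd`,
#'   `folds` (per-iteration fold assignment by sample id), `seed`, `config`
#' @export
evaluate_cv <- function(dataset, config = svm_config("poly2"),
                        n_iterations = 10, n_folds = 2, seed,
                        stratified = TRUE, scale_within_folds = TRUE) {
  stopifnot(inherits(dataset, "spectra_dataset"), n_folds >= 2)
  if (missing(seed)) stop("a seed is required")
  if (min(table(dataset$y)) < n_folds)
    stop("each class needs at least n_folds members")

  ord <- order(dataset$ids)  # stable ordering: splits independent of row order
  full_scaled <- if (!scale_within_folds) scale_features(dataset) else NULL

  one_iteration <- function(it) {
    fold_of <- integer(nrow(dataset$X))
    .with_seed(derive_seed(seed, paste0("cv_iter", it)), {
      if (stratified) {
        for (cls in c(-1L, 1L)) {
          members <- ord[dataset$y[ord] == cls]
          perm <- sample(members)
          fold_of[perm] <- rep_len(seq_len(n_folds), length(perm))
        }
      } else {
        perm <- sample(ord)
        fold_of[perm] <- rep_len(seq_len(n_folds), length(perm))
      }
    })
    decision <- numeric(nrow(dataset$X))
    predicted <- integer(nrow(dataset$X))
    for (f in seq_len(n_folds)) {
      test_idx <- which(fold_of == f)
      train_idx <- which(fold_of != f)
      if (length(unique(dataset$y[train_idx])) < 2)
        stop("degenerate single-class training fold (use stratified = TRUE)")
      if (scale_within_folds) {
        train_ds <- scale_features(.dataset_rows(dataset, train_idx))
        X_test <- .apply_scaling(dataset$X[test_idx, , drop = FALSE],
                                 train_ds$scaling)
      } else {
        train_ds <- .dataset_rows(full_scaled, train_idx)
        X_test <- full_scaled$X[test_idx, , drop = FALSE]
      }
      model <- train_svm(train_ds, config)
      pr <- predict(model, X_test)
      decision[test_idx] <- pr$decision
      predicted[test_idx] <- pr$label
    }
    list(metrics = compute_metrics(dataset$y, predicted, decision),
         folds = structure(fold_of, names = dataset$ids))
  }

  runs <- lapply(seq_len(n_iterations), one_iteration)
  iter_df <- do.call(rbind, lapply(runs, function(r)
    as.data.frame(r$metrics)))
  iter_df$iteration <- seq_len(n_iterations)
  structure(list(
    iterations = iter_df,
    mean = colMeans(iter_df[c("sensitivity", "specificity", "accuracy", "auc")]),
    sd = vapply(iter_df[c("sensitivity", "specificity", "accuracy", "auc")],
                sd, numeric(1)),
    folds = lapply(runs, `[[`, "folds"),
    seed = seed, config = config),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d iterations (%s kernel): sens %.1f+-%.1f%% | spec %.1f+-%.1f%% | acc %.1f+-%.1f%% | AUC %.3f+-%.3f\n",
    nrow(x$iterations), x$config$kernel,
    x$mean["sensitivity"], x$sd["sensitivity"],
    x$mean["specificity"], x$sd["specificity"],
    x$mean["accuracy"], x$sd["accuracy"], x$mean["auc"], x$sd["auc"]))
  invisible(x)
}

# "93.5 +- 2.4"-style cell for result tables
.pm <- function(m, s, digits = 1) sprintf("%.*f ± %.*f", digits, m, digits, s)

#' Kernel comparison experiment
#'
#' Runs [evaluate_cv()] for each configuration (default: the six standard
#' kernels of [standard_kernels()]) on one dataset, with the same seed so all
#' configurations see identical splits.
#'
#' @param dataset an unscaled [spectra_dataset()]
#' @param configs named list of [svm_config()] objects
#' @param n_iterations,seed passed to [evaluate_cv()]
#' @param ... further arguments to [evaluate_cv()]
#' @return data frame with one row per configuration (columns `kernel`,
#'   `sensitivity`, `specificity`, `accuracy`, `auc` as "mean +- sd" strings
#'   plus numeric `*_mean`/`*_sd` columns); the full `cv_result` objects are
#'   attached as attribute `cv_results`
#' @export
kernel_comparison <- function(dataset, configs = standard_kernels(),
                              n_iterations = 10, seed, ...) {
  if (missing(seed)) stop("a seed is required")
  results <- lapply(configs, function(cfg)
    evaluate_cv(dataset, cfg, n_iterations = n_iterations, seed = seed, ...))
  tab <- .results_table(results, "kernel")
  attr(tab, "cv_results") <- results
  tab
}

.results_table <- function(results, label_col) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    df <- data.frame(
      label = nm,
      sensitivity = .pm(r$mean["sensitivity"], r$sd["sensitivity"]),
      specificity = .pm(r$mean["specificity"], r$sd["specificity"]),
      accuracy = .pm(r$mean["accuracy"], r$sd["accuracy"]),
      auc = .pm(r$mean["auc"], r$sd["auc"], digits = 3),
      stringsAsFactors = FALSE)
    for (m in c("sensitivity", "specificity", "accuracy", "auc")) {
      df[[paste0(m, "_mean")]] <- unname(r$mean[m])
      df[[paste0(m, "_sd")]] <- unname(r$sd[m])
    }
    df
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- label_col
  out
}

#' The twelve standard wavelength-range specifications
#'
#' The wavelength ranges evaluated in the range experiment: broad ranges,
#' literature sub-ranges, discrete band sets, and the full 350-1919 nm range.
#' Each element is a list with `ranges` (closed intervals, nm) and/or
#' `values` (discrete wavelengths, nm).
#'
#' @return named list of 12 range specifications
#' @export
table4_ranges <- function() {
  list(
    "350-760" = list(ranges = list(c(350, 760))),
    "350-800" = list(ranges = list(c(350, 800))),
    "400-440+540-580" = list(ranges = list(c(400, 440), c(540, 580))),
    "400-1000" = list(ranges = list(c(400, 1000))),
    "405-665" = list(ranges = list(c(405, 665))),
    "405-750" = list(ranges = list(c(405, 750))),
    "470-700" = list(ranges = list(c(470, 700))),
    "415-425+495-505+525-545+465+625" = list(
      ranges = list(c(415, 425), c(495, 505), c(525, 545)),
      values = c(465, 625)),
    "11-discrete" = list(values = c(405.235, 406.42, 408.794, 414.736, 422.48,
                                    468.76, 559.489, 577.506, 594.342,
                                    957.948, 1000.31)),
    "900-1300" = list(ranges = list(c(900, 1300))),
    "1000-1919" = list(ranges = list(c(1000, 1919))),
    "350-1919" = list(ranges = list(c(350, 1919))))
}

#' Wavelength-range experiment
#'
#' For each range specification: subset the dataset columns
#' ([subset_wavelengths()]) and evaluate by repeated twofold CV with the
#' given kernel (default quadratic), all with the same seed so every range
#' sees identical splits.
#'
#' @param dataset an unscaled [spectra_dataset()]
#' @param range_specs named list of range specifications as in
#'   [table4_ranges()] (the default)
#' @param config kernel configuration (default quadratic)
#' @param n_iterations,seed passed to [evaluate_cv()]
#' @param ... further arguments to [evaluate_cv()]
#' @return data frame with one row per range (same layout as
#'   [kernel_comparison()], label column `wavelengths`), `cv_result` objects
#'   attached as attribute `cv_results`
#' @export
wavelength_range_experiment <- function(dataset, range_specs = table4_ranges(),
                                        config = svm_config("poly2"),
                                        n_iterations = 10, seed, ...) {
  if (missing(seed)) stop("a seed is required")
  results <- lapply(range_specs, function(spec) {
    sub <- subset_wavelengths(dataset, ranges = spec$ranges,
                              values = spec$values)
    evaluate_cv(sub, config, n_iterations = n_iterations, seed = seed, ...)
  })
  tab <- .results_table(results, "wavelengths")
  attr(tab, "cv_results") <- results
  tab
}
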