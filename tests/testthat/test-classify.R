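test_that("kernel values match their closed forms", {
  cfg2 <- svm_config("poly2", kernel_scale = 1)
  expect_equal(kernel_value(c(1, 1), c(1, 1), cfg2), 9)  # (2 + 1)^2
  cfg3 <- svm_config("poly3", kernel_scale = 2)
  expect_equal(kernel_value(c(2, 0), c(2, 0), cfg3), 8)  # (4/4 + 1)^3
  g <- svm_config("gaussian", gaussian_sigma = 2)
  expect_equal(kernel_value(c(1, 2, 3), c(1, 2, 3), g), 1)
  x1 <- c(2, 2); x2 <- c(0, 0)  # squared distance 8, sigma 2 -> exp(-1)
  expect_equal(kernel_value(x1, x2, g), exp(-1), tolerance = 1e-12)
  expect_error(kernel_value(1:3, 1:2, cfg2), "length")
  expect_error(kernel_value(1, 2, svm_config("linear")), "auto")
})

test_that("auto kernel scale is the median pairwise distance", {
  expect_equal(auto_kernel_scale(matrix(c(0, 4), 2, 1)), 4)
  expect_equal(auto_kernel_scale(matrix(1, 5, 3)), 1)  # degenerate fallback
  set.seed(71)
  X <- matrix(rnorm(300), 100, 3)
  expect_equal(auto_kernel_scale(X), median(dist(X)))  # subsample >= population
  # seeded subsampling is deterministic
  Xl <- matrix(rnorm(3 * 1200), 1200, 3)
  expect_identical(auto_kernel_scale(Xl, seed = 5), auto_kernel_scale(Xl, seed = 5))
})

test_that("training degenerates correctly on forced cases", {
  sep <- spectra_dataset(matrix(c(-10, -11, 10, 11), 4, 1),
                         c(-1, -1, 1, 1), 500)
  fit <- train_svm(sep, svm_config("linear", kernel_scale = 1))
  pr <- predict(fit, sep)
  expect_identical(pr$label, sep$y)

  contra <- spectra_dataset(matrix(c(1, 1, 1, 1), 4, 1), c(-1, 1, -1, 1), 500)
  prc <- predict(train_svm(contra, svm_config("linear", kernel_scale = 1)),
                 contra)
  expect_equal(mean(prc$label == contra$y), 0.5)

  expect_error(train_svm(spectra_dataset(matrix(1:2, 2, 1), c(1, 1), 500)),
               "single class")
})

test_that("SMO decision values match the reference QP oracle", {
  set.seed(81)
  for (trial in 1:20) {
    n <- sample(6:20, 1)
    m <- sample(2:4, 1)
    X <- matrix(rnorm(n * m), n, m)
    y <- c(-1, 1, sample(c(-1, 1), n - 2, replace = TRUE))  # both classes
    cfg <- switch(sample(3, 1),
                  svm_config("linear", kernel_scale = 1),
                  svm_config("poly2", kernel_scale = 1.5),
                  svm_config("gaussian", gaussian_sigma = 2))
    ds <- spectra_dataset(X, y, seq(400, length.out = m), sdd = 630)
    fit <- train_svm(ds, cfg, kkt_tol = 1e-9)
    kp <- drspectra:::.kernel_pars(cfg, cfg$kernel_scale)
    K <- drspectra:::.kernel_matrix_cpp(X, X, kp$type, kp$p, kp$scale, kp$sigma)
    ref <- qp_svm_oracle(K, y, C = 1)
    f_pkg <- predict(fit, X)$decision
    f_ref <- as.numeric(K %*% (ref$alpha * y)) + ref$b
    expect_equal(f_pkg, f_ref, tolerance = 1e-6)
  }
})

test_that("metrics match hand counts and the brute-force AUC oracle", {
  perfect <- compute_metrics(rep(c(1, -1), 50), rep(c(1, -1), 50),
                             rep(c(1, -1), 50))
  expect_equal(perfect[c("sensitivity", "specificity", "accuracy")],
               list(sensitivity = 100, specificity = 100, accuracy = 100))
  expect_equal(perfect$auc, 1)

  # one concordant + one discordant pair -> AUC 0.5
  m <- compute_metrics(c(1, 1, -1), c(1, 1, -1), c(0.9, 0.3, 0.4))
  expect_equal(m$auc, 0.5)

  set.seed(91)
  labels <- sample(c(-1, 1), 200, replace = TRUE)
  labels[1:2] <- c(-1, 1)
  scores <- round(rnorm(200), 1)  # rounding forces ties
  predicted <- ifelse(scores > 0, 1, -1)
  m2 <- compute_metrics(labels, predicted, scores)
  expect_identical(m2$auc, auc_bruteforce(labels, scores))
  expect_equal(m2$sensitivity,
               100 * sum(labels == 1 & predicted == 1) / sum(labels == 1))

  expect_warning(compute_metrics(c(1, 1), c(1, -1), c(1, 0)), "absent")
})

test_that("CV reaches ceiling on separated data and chance on permuted labels", {
  set.seed(101)
  n <- 100
  X <- matrix(rnorm(n * 4), n, 4) + rep(c(-3, 3), each = n / 2)
  y <- rep(c(-1, 1), each = n / 2)
  ds <- spectra_dataset(X, y, seq(400, 430, 10), sdd = 630)
  cv <- evaluate_cv(ds, svm_config("poly2"), n_iterations = 5, seed = 3)
  expect_equal(unname(cv$mean["accuracy"]), 100)
  expect_equal(unname(cv$mean["auc"]), 1)
  expect_equal(unname(cv$sd["accuracy"]), 0)

  set.seed(102)
  n <- 400
  Xp <- matrix(rnorm(n * 5), n, 5)
  yp <- rep(c(-1, 1), each = n / 2)
  dsp <- spectra_dataset(Xp, yp, seq(400, 440, 10), sdd = 630)
  cvp <- evaluate_cv(dsp, svm_config("poly2"), n_iterations = 10, seed = 4)
  expect_gt(unname(cvp$mean["auc"]), 0.45)
  expect_lt(unname(cvp$mean["auc"]), 0.55)
})

test_that("CV orchestration equals a step-by-step scripted run", {
  set.seed(111)
  X <- matrix(rnorm(12 * 3), 12, 3) + rep(c(-1.2, 1.2), each = 6)
  y <- rep(c(-1, 1), each = 6)
  ds <- spectra_dataset(X, y, c(500, 600, 700), sdd = 630)
  cv <- evaluate_cv(ds, svm_config("poly2"), n_iterations = 2, seed = 13)

  for (it in 1:2) {
    folds <- cv$folds[[it]][ds$ids]  # assignment by stable id
    decision <- numeric(12); predicted <- integer(12)
    for (f in 1:2) {
      tr <- which(folds != f); te <- which(folds == f)
      tr_ds <- scale_features(spectra_dataset(X[tr, ], y[tr], ds$wavelengths,
                                              sdd = 630, ids = ds$ids[tr]))
      model <- train_svm(tr_ds, svm_config("poly2"))
      Xte <- drspectra:::.apply_scaling(X[te, , drop = FALSE], tr_ds$scaling)
      pr <- predict(model, Xte)
      decision[te] <- pr$decision; predicted[te] <- pr$label
    }
    manual <- compute_metrics(y, predicted, decision)
    expect_equal(as.numeric(cv$iterations[it, 1:4]),
                 as.numeric(manual[c("sensitivity", "specificity",
                                     "accuracy", "auc")]),
                 tolerance = 1e-10)
  }
})

test_that("CV is label-symmetric and row-order invariant", {
  set.seed(121)
  # well-separated classes plus explicit label noise: errors are confident
  # mislabels, so no decision value sits near zero and the symmetry is exact
  X <- matrix(rnorm(60 * 3), 60, 3) + rep(c(-4, 4), each = 30)
  y <- rep(c(-1, 1), each = 30)
  y[c(1:3, 31:34)] <- -y[c(1:3, 31:34)]
  ids <- sprintf("id%02d", 1:60)
  ds <- spectra_dataset(X, y, c(500, 600, 700), sdd = 630, ids = ids)
  cv <- evaluate_cv(ds, svm_config("linear"), n_iterations = 3, seed = 31)

  # swapped labels swap sensitivity and specificity exactly
  swapped <- spectra_dataset(X, -y, c(500, 600, 700), sdd = 630, ids = ids)
  cvs <- evaluate_cv(swapped, svm_config("linear"), n_iterations = 3, seed = 31)
  expect_equal(cvs$iterations$sensitivity, cv$iterations$specificity)
  expect_equal(cvs$iterations$specificity, cv$iterations$sensitivity)

  # permuted row order: identical metrics (splits keyed to sample ids)
  perm <- sample(60)
  dsp <- spectra_dataset(X[perm, ], y[perm], c(500, 600, 700), sdd = 630,
                         ids = ids[perm])
  cvp <- evaluate_cv(dsp, svm_config("linear"), n_iterations = 3, seed = 31)
  expect_equal(cvp$iterations, cv$iterations, tolerance = 1e-6)
})

test_that("kernel comparison emits six populated reproducible rows", {
  ds <- toy_dataset(n_per_class = 15, m = 4, sep = 2.5, seed = 9)
  tab <- kernel_comparison(ds, n_iterations = 3, seed = 41)
  expect_identical(tab$kernel, names(standard_kernels()))
  expect_true(all(is.finite(tab$auc_mean)))
  tab2 <- kernel_comparison(ds, n_iterations = 3, seed = 41)
  expect_identical(tab, tab2, ignore_attr = TRUE)
  # ceiling property: on strongly separable data the quadratic kernel sits
  # within 0.02 AUC of linear
  sep <- toy_dataset(n_per_class = 20, m = 4, sep = 6, seed = 10)
  t3 <- kernel_comparison(sep, standard_kernels()[c("linear", "quadratic")],
                          n_iterations = 3, seed = 42)
  expect_lt(abs(t3$auc_mean[1] - t3$auc_mean[2]), 0.02)
})

test_that("wavelength range experiment: identity row and null range", {
  specs <- default_class_specs(n_patients = 6, sites_per_patient = 6)
  g <- generate_dataset(specs$normal, specs$tumor, 630, seed = 55)
  sel <- list("350-1919" = list(ranges = list(c(350, 1919))))
  tab <- wavelength_range_experiment(g$dataset, sel, n_iterations = 3,
                                     seed = 77)
  direct <- evaluate_cv(g$dataset, svm_config("poly2"), n_iterations = 3,
                        seed = 77)
  expect_equal(tab$auc_mean, unname(direct$mean["auc"]), tolerance = 1e-12)
  expect_equal(tab$sensitivity_mean, unname(direct$mean["sensitivity"]),
               tolerance = 1e-12)
})
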