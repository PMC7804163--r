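#' Kernel SVM configuration
#'
#' The six classifier configurations used in the kernel comparison are the
#' linear, quadratic and cubic polynomial kernels (automatic kernel scale)
#' and the fine / medium / coarse Gaussian kernels with
#' \eqn{\sigma = 0.5, 2, 8}. Polynomial kernels divide predictors by the
#' kernel scale `s` before the kernel norm:
#' \eqn{K(x_1, x_2) = (\langle x_1/s, x_2/s\rangle + 1)^p}; Gaussian kernels
#' use \eqn{K(x_1, x_2) = \exp(-\|x_1 - x_2\|^2 / (2\sigma^2))} with
#' \eqn{\sigma} applied directly.
#'
#' @param kernel one of `"linear"`, `"poly2"` (quadratic), `"poly3"` (cubic),
#'   `"gaussian"`
#' @param C soft-margin penalty strength (> 0, default 1)
#' @param gaussian_sigma \eqn{\sigma} for the Gaussian kernel
#' @param kernel_scale positive scale dividing predictors (polynomial
#'   kernels), or `"auto"` for the median-pairwise-distance heuristic
#'   ([auto_kernel_scale()])
#' @return object of class `svm_config`
#' @examples
#' svm_config("poly2")
#' svm_config("gaussian", gaussian_sigma = 2)
#' @export
svm_config <- function(kernel = c("linear", "poly2", "poly3", "gaussian"),
                       C = 1, gaussian_sigma = 2, kernel_scale = "auto") {
  kernel <- match.arg(kernel)
  stopifnot(C > 0)
  if (kernel == "gaussian") stopifnot(gaussian_sigma > 0)
  if (is.numeric(kernel_scale)) stopifnot(kernel_scale > 0)
  p <- switch(kernel, linear = 1L, poly2 = 2L, poly3 = 3L, gaussian = NA_integer_)
  structure(list(kernel = kernel, C = C, poly_order = p,
                 gaussian_sigma = gaussian_sigma, kernel_scale = kernel_scale),
            class = "svm_config")
}

#' The six standard kernel configurations
#'
#' @param C penalty strength shared by all six (default 1)
#' @return named list of [svm_config()] objects: linear, quadratic, cubic,
#'   fine_gaussian (sigma 0.5), medium_gaussian (sigma 2),
#'   coarse_gaussian (sigma 8)
#' @export
standard_kernels <- function(C = 1) {
  list(linear = svm_config("linear", C = C),
       quadratic = svm_config("poly2", C = C),
       cubic = svm_config("poly3", C = C),
       fine_gaussian = svm_config("gaussian", C = C, gaussian_sigma = 0.5),
       medium_gaussian = svm_config("gaussian", C = C, gaussian_sigma = 2),
       coarse_gaussian = svm_config("gaussian", C = C, gaussian_sigma = 8))
}

# resolved (type code, p, scale, sigma) for the C++ kernels
.kernel_pars <- function(config, scale) {
  if (config$kernel == "gaussian")
    list(type = 2L, p = 0, scale = 1, sigma = config$gaussian_sigma)
  else
    list(type = 1L, p = as.numeric(config$poly_order), scale = scale, sigma = 0)
}

#' Evaluate the kernel function on two feature vectors
#'
#' @param x1,x2 equal-length numeric vectors
#' @param config an [svm_config()]; a numeric `kernel_scale` must be given
#'   (use [auto_kernel_scale()] to resolve `"auto"`)
#' @return scalar kernel value
#' @examples
#' kernel_value(c(1, 1), c(1, 1), svm_config("poly2", kernel_scale = 1))  # 9
#' @export
kernel_value <- function(x1, x2, config) {
  if (length(x1) != length(x2)) stop("feature vectors differ in length")
  scale <- config$kernel_scale
  if (identical(scale, "auto")) {
    if (config$kernel != "gaussian")  # sigma is used directly for gaussian
      stop("kernel_scale is 'auto'; resolve it with auto_kernel_scale() first")
    scale <- 1
  }
  kp <- .kernel_pars(config, scale)
  .kernel_matrix_cpp(matrix(x1, 1), matrix(x2, 1),
                     kp$type, kp$p, kp$scale, kp$sigma)[1, 1]
}

#' Automatic kernel scale: median pairwise distance on a subsample
#'
#' Substitute for the undocumented MATLAB subsampling heuristic: the median
#' Euclidean distance over all pairs of a seeded subsample of at most
#' `max_rows` rows. Falls back to 1 when all sampled rows coincide.
#'
#' @param X numeric feature matrix (>= 2 rows)
#' @param seed integer seed for the subsample
#' @param max_rows subsample cap (default 1000)
#' @return positive scalar scale
#' @export
auto_kernel_scale <- function(X, seed = 1, max_rows = 1000) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows")
  idx <- if (nrow(X) > max_rows)
    .with_seed(seed, sample.int(nrow(X), max_rows)) else seq_len(nrow(X))
  d <- stats::dist(X[idx, , drop = FALSE])
  s <- stats::median(d)
  if (!is.finite(s) || s <= 0) 1 else s
}

#' Train a soft-margin kernel SVM
#'
#' Solves the standard soft-margin dual by sequential minimal optimization
#' (maximal-violating-pair working-set selection) to the given KKT tolerance.
#' The decision function is
#' \eqn{f(x) = \sum_i y_i \alpha_i K(x, x_i) + w_0}; predicted labels are its
#' sign.
#'
#' @param dataset a scaled [spectra_dataset()] containing both classes, or a
#'   list with elements `X` and `y`
#' @param config an [svm_config()]
#' @param kkt_tol KKT violation tolerance (default 1e-6)
#' @param max_iter SMO iteration cap
#' @return object of class `drs_svm`: support vectors, dual coefficients
#'   `y_i alpha_i`, intercept `b`, resolved kernel scale, and the training
#'   scaling state if present
#' @export
train_svm <- function(dataset, config = svm_config("poly2"), kkt_tol = 1e-6,
                      max_iter = 1e7) {
  X <- as.matrix(dataset$X)
  y <- dataset$y
  if (length(unique(y)) < 2) stop("training data contains a single class")
  stopifnot(all(y %in% c(-1, 1)))
  scale <- config$kernel_scale
  if (identical(scale, "auto")) scale <- auto_kernel_scale(X)
  kp <- .kernel_pars(config, scale)
  K <- .kernel_matrix_cpp(X, X, kp$type, kp$p, kp$scale, kp$sigma)
  fit <- .svm_smo_cpp(K, as.numeric(y), config$C, kkt_tol, max_iter)
  alpha <- fit$alpha
  sv <- alpha > 1e-12
  structure(list(sv_x = X[sv, , drop = FALSE],
                 dual_coef = (alpha * y)[sv],
                 alpha = alpha, b = fit$b,
                 config = config, kernel_scale = scale,
                 iterations = fit$iterations, kkt_gap = fit$kkt_gap,
                 scaling = if (!is.null(dataset$scaling)) dataset$scaling),
            class = "drs_svm")
}

#' Decision values and predicted labels of a trained SVM
#'
#' @param object a `drs_svm` model
#' @param newdata matrix of feature rows on the model's (scaled) feature
#'   space, or a `spectra_dataset`
#' @param ... unused
#' @return list with `decision` (numeric) and `label` (-1/+1; ties on exactly
#'   zero decision values go to +1)
#' @export
predict.drs_svm <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectra_dataset")) newdata$X else as.matrix(newdata)
  kp <- .kernel_pars(object$config, object$kernel_scale)
  K <- .kernel_matrix_cpp(X, object$sv_x, kp$type, kp$p, kp$scale, kp$sigma)
  f <- as.numeric(K %*% object$dual_coef) + object$b
  list(decision = f, label = ifelse(f >= 0, 1L, -1L))
}
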