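# Independent oracles used by the derived-value tests. These deliberately use
# different algorithms from the package code paths they check.

# Reference soft-margin SVM dual solution, independent of the package's SMO
# solver: accelerated projected gradient (FISTA, exact bisection projection
# onto {0 <= a <= C, sum(a*y) = 0}) to identify the active set, then an exact
# KKT linear solve on the free set, verified against the KKT conditions.
qp_svm_oracle <- function(K, y, C = 1, iters = 2000) {
  n <- length(y)
  Q <- (y %o% y) * K
  L <- max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
  if (L <= 0) L <- 1
  project <- function(v) {
    g <- function(lam) sum(pmin(pmax(v + lam * y, 0), C) * y)
    lo <- -max(abs(v)) - C - 1
    hi <- -lo
    for (k in 1:80) {
      midp <- (lo + hi) / 2
      if (g(midp) > 0) hi <- midp else lo <- midp
    }
    pmin(pmax(v + (lo + hi) / 2 * y, 0), C)
  }
  a <- rep(0, n); z <- a; t_k <- 1
  for (k in seq_len(iters)) {
    grad <- Q %*% z - 1
    a_new <- project(as.numeric(z - grad / L))
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- a_new + (t_k - 1) / t_new * (a_new - a)
    a <- a_new; t_k <- t_new
  }
  # polish: exact KKT solve on the identified free set (equality-constrained
  # quadratic system), falling back to the FISTA iterate if it is inconsistent
  tol_a <- 1e-6 * C
  free <- which(a > tol_a & a < C - tol_a)
  if (length(free) > 0) {
    bound_C <- which(a >= C - tol_a)
    rhs <- c(1 - if (length(bound_C))
      rowSums(Q[free, bound_C, drop = FALSE]) * C else 0, # a_B = C
      -sum(y[bound_C]) * C)
    Amat <- rbind(cbind(Q[free, free, drop = FALSE], y[free]),
                  c(y[free], 0))
    sol <- tryCatch(solve(Amat, rhs), error = function(e) NULL)
    if (!is.null(sol)) {
      a_try <- a
      a_try[free] <- sol[seq_along(free)]
      a_try[setdiff(seq_len(n), c(free, bound_C))] <- 0
      a_try[bound_C] <- C
      G_try <- as.numeric(Q %*% a_try) - 1
      b_try <- sol[length(sol)]  # multiplier of the equality constraint = w0
      # KKT: kkt_i = G_i + b*y_i must be >= 0 at a=0, <= 0 at a=C, 0 if free
      kkt <- G_try + b_try * y
      at0 <- a_try < tol_a
      atC <- a_try > C - tol_a
      ok <- all(a_try >= -1e-9) && all(a_try <= C + 1e-9) &&
        abs(sum(a_try * y)) < 1e-8 &&
        all(kkt[at0] >= -1e-7) && all(kkt[atC] <= 1e-7) &&
        all(abs(kkt[!at0 & !atC]) <= 1e-7)
      if (ok) return(list(alpha = pmin(pmax(a_try, 0), C), b = b_try))
    }
  }
  G <- as.numeric(Q %*% a) - 1
  b <- if (length(free)) mean(-y[free] * G[free]) else {
    up <- (y > 0 & a < C) | (y < 0 & a > 0)
    lo <- (y > 0 & a > 0) | (y < 0 & a < C)
    (max(-y[up] * G[up]) + min(-y[lo] * G[lo])) / 2
  }
  list(alpha = a, b = b)
}

# Brute-force O(n^2) pairwise-concordance AUC with ties counted 1/2
auc_bruteforce <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Small two-class dataset with gaussian-blob features (not spectra); handy for
# classifier unit tests
toy_dataset <- function(n_per_class = 10, m = 3, sep = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * m, -sep / 2), ncol = m),
             matrix(rnorm(n_per_class * m, sep / 2), ncol = m))
  wl <- seq(400, 400 + m - 1)
  spectra_dataset(X, rep(c(-1, 1), each = n_per_class), wl, sdd = 630)
}

# Hand-rolled fluence_map object for PHD unit tests
fake_fluence_map <- function(values, dr = 0.05, dz = 0.05) {
  nr <- nrow(values); nz <- ncol(values)
  structure(list(fluence = values, absorbed = values,
                 rd = rep(0, nr),
                 r_centers = (seq_len(nr) - 0.5) * dr,
                 z_centers = (seq_len(nz) - 0.5) * dz,
                 dr = dr, dz = dz, n_photons = 1,
                 bookkeeping = list(), props = NULL, seed = 0),
            class = "fluence_map")
}

# Independent cylindrical->Cartesian lookup used to cross-check compute_phd:
# plain scalar loops, linear interpolation between radial bin centers,
# constant inside the first center, zero beyond the last.
phd_lookup_oracle <- function(values, r_centers, r) {
  nz <- ncol(values)
  out <- numeric(nz)
  if (r > r_centers[length(r_centers)]) return(out)
  if (r <= r_centers[1]) return(values[1, ])
  i <- max(which(r_centers <= r))
  w <- (r - r_centers[i]) / (r_centers[i + 1] - r_centers[i])
  for (z in seq_len(nz)) out[z] <- (1 - w) * values[i, z] + w * values[i + 1, z]
  out
}
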