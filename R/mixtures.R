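#' Gaussian mixture fit on log2-transformed event statistics
#'
#' Home-cage phenotyping derives behavioral thresholds from Gaussian
#' mixtures fitted to log2-transformed event statistics: three components
#' for shelter-visit durations (log2 seconds) and two for movement
#' distances (log2 cm). The fit is maximum likelihood by
#' expectation-maximization on the raw log2 values with several seeded
#' random restarts; the best likelihood is kept and components are
#' reordered by ascending mean, so "first/second/third curve" always means
#' shortest to longest.
#'
#' @param values Positive raw values (seconds or cm); log2 is taken inside.
#' @param k Number of components (2 or 3).
#' @param n_restarts Seeded EM restarts.
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param min_points Minimum sample size; below it a missing-flagged,
#'   non-converged fit is returned rather than an error so downstream
#'   registries can carry the flag.
#' @param min_sd Lower bound on component standard deviations, guarding
#'   against variance collapse onto single points.
#' @param seed Seed for the restarts (required for deterministic output).
#' @param trace_loglik Keep the per-iteration log-likelihood path of the
#'   winning restart (used to verify EM monotonicity).
#' @return A `phenocage_mixfit`: list with `k`, `weights`, `means`, `sds`
#'   (log2 scale, means ascending), `log_likelihood`, `converged`,
#'   `n_points`, `missing`, and optionally `loglik_path`.
#' @examples
#' x <- 2^c(rnorm(200, 4, 0.5), rnorm(200, 8, 0.5))
#' fit_log2_mixture(x, k = 2, seed = 1)
#' @export
fit_log2_mixture <- function(values, k, n_restarts = 10, max_iter = 500,
                             tol = 1e-8, min_points = 30, min_sd = 1e-3,
                             seed = 1, trace_loglik = FALSE) {
  if (!k %in% c(2L, 3L)) stop_input("k must be 2 or 3")
  values <- values[is.finite(values)]
  if (any(values <= 0)) stop_input("mixture input values must be positive")
  n <- length(values)
  empty <- structure(list(k = as.integer(k), weights = rep(NA_real_, k),
                          means = rep(NA_real_, k), sds = rep(NA_real_, k),
                          log_likelihood = NA_real_, converged = FALSE,
                          n_points = n, missing = TRUE),
                     class = "phenocage_mixfit")
  if (n < min_points) return(empty)
  x <- log2(values)
  if (sd(x) < 1e-12) return(empty)  # degenerate: all values identical

  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- with_local_seed(child_seed(seed, r), {
      mu <- sort(quantile(x, probs = runif(k), names = FALSE, type = 8))
      list(w = rep(1 / k, k),
           mu = mu + rnorm(k, 0, sd(x) / 10),
           s = rep(max(sd(x) / k, min_sd), k))
    })
    fit <- em_gmm1d(x, init$w, init$mu, init$s, max_iter, tol, min_sd)
    replaces <- is.null(best) || (fit$ok && !best$ok) ||
      (fit$ok == best$ok && fit$loglik > best$loglik)
    if (replaces) best <- fit
  }
  ord <- order(best$mu)
  out <- structure(list(k = as.integer(k), weights = best$w[ord],
                        means = best$mu[ord], sds = best$s[ord],
                        log_likelihood = best$loglik,
                        converged = best$ok && best$converged,
                        n_points = n, missing = FALSE),
                   class = "phenocage_mixfit")
  if (trace_loglik) out$loglik_path <- best$path
  out
}

# One EM run for a univariate Gaussian mixture. Responsibilities computed in
# log space (log-sum-exp) for numerical safety.
em_gmm1d <- function(x, w, mu, s, max_iter, tol, min_sd) {
  n <- length(x)
  k <- length(w)
  path <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j) {
      log(w[j]) + dnorm(x, mu[j], s[j], log = TRUE)
    }, numeric(n))
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    path <- c(path, ll)
    resp <- exp(logd - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-10)) return(list(w = w, mu = mu, s = s, loglik = ll,
                                     ok = FALSE, converged = FALSE, path = path))
    w <- nk / n
    mu <- colSums(resp * x) / nk
    s <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
    s <- pmax(s, min_sd)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(w = w, mu = mu, s = s, loglik = path[length(path)], ok = TRUE,
       converged = converged, path = path)
}

#' @export
print.phenocage_mixfit <- function(x, ...) {
  cat(sprintf("<phenocage_mixfit> k=%d, n=%d, %s\n", x$k, x$n_points,
              if (x$missing) "missing" else if (x$converged) "converged" else "not converged"))
  if (!x$missing) {
    print(round(rbind(weight = x$weights, mean = x$means, sd = x$sds), 4))
  }
  invisible(x)
}

#' Intersection of two weighted Gaussian components
#'
#' The crossing point of two weighted Gaussian densities between their
#' means, the construction behind the long shelter-visit threshold
#' (intersection of the second and third fitted curves) and the long
#' movement threshold (intersection of the two curves). Solving
#' `w1 N(x; m1, s1) = w2 N(x; m2, s2)` on the log scale gives a quadratic
#' (linear when the sds are equal); the root inside `(m1, m2)` is returned.
#' When no crossing falls in that interval (extreme weight imbalance) the
#' weight-weighted mean of the two component means is returned with
#' `fallback = TRUE`.
#'
#' @param c1,c2 Numeric vectors `c(weight, mean, sd)`; `mean(c1) < mean(c2)`.
#' @return List with `threshold` (log2 scale) and `fallback` flag.
#' @examples
#' gaussian_intersection(c(0.5, 6, 1), c(0.5, 10, 1))$threshold  # 8
#' @export
gaussian_intersection <- function(c1, c2) {
  w1 <- c1[1]; m1 <- c1[2]; s1 <- c1[3]
  w2 <- c2[1]; m2 <- c2[2]; s2 <- c2[3]
  if (s1 <= 0 || s2 <= 0) stop_input("component sds must be positive")
  if (!(m1 < m2)) stop_input("component means must be ascending")
  check_pos(c(w1, w2), "weights")
  # log w1 - log s1 - (x-m1)^2/(2 s1^2) = log w2 - log s2 - (x-m2)^2/(2 s2^2)
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) +
    log(w1) - log(s1) - log(w2) + log(s2)
  roots <- if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0) else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > m1 & roots < m2]
  if (length(inside) == 0) {
    return(list(threshold = (w1 * m1 + w2 * m2) / (w1 + w2), fallback = TRUE))
  }
  list(threshold = inside[1], fallback = FALSE)
}

#' Percentile of a single Gaussian component
#'
#' `mean + z_q * sd` on the log2 scale: the construction behind the short
#' shelter-visit threshold (90th percentile of the first fitted curve).
#'
#' @param component Numeric `c(mean, sd)` or `c(weight, mean, sd)` (weight
#'   ignored).
#' @param q Probability in (0, 1).
#' @return Threshold on the log2 scale.
#' @export
component_percentile <- function(component, q = 0.9) {
  if (length(component) == 3) component <- component[2:3]
  mu <- component[1]; s <- component[2]
  if (s <= 0) stop_input("component sd must be positive")
  if (q <= 0 || q >= 1) stop_input("q must lie in (0, 1)")
  mu + qnorm(q) * s
}

#' Nearest-rank empirical percentile threshold
#'
#' The long arrest threshold is the 90th percentile of raw arrest durations
#' (no log transform). The nearest-rank convention (value at index
#' `ceiling(q * n)` of the sorted sample) is used for determinism and exact
#' scale equivariance.
#'
#' @param durations Durations in seconds.
#' @param q Probability in (0, 1).
#' @param min_n Minimum sample size; below it `NA` is returned (missing
#'   flag).
#' @return Threshold in the input units, or `NA_real_` when undersampled.
#' @export
empirical_percentile_threshold <- function(durations, q = 0.9, min_n = 10) {
  durations <- durations[is.finite(durations)]
  n <- length(durations)
  if (n < min_n) return(NA_real_)
  if (q <= 0 || q >= 1) stop_input("q must lie in (0, 1)")
  sort(durations)[ceiling(q * n)]
}
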