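# Low-abundance threshold from a three-component Gaussian mixture.
#
# Abundance-score distributions from growth selections are trimodal:
# nonsense-like, intermediate, and synonymous-like variants. The cutoff for
# "low abundance" is taken where the weighted densities of the intermediate
# and synonymous-like components intersect, i.e. the point between their
# means where a score becomes more likely under the intermediate component.

#' Fit a three-component Gaussian mixture to scores
#'
#' Expectation-maximization with multiple random restarts; the best
#' log-likelihood fit is kept and components are relabeled in ascending
#' order of their means. Initialization is quantile-based with jitter so
#' restarts explore different responsibilities.
#'
#' @param scores Numeric vector of scores; non-finite values are rejected
#'   with a count in the error message.
#' @param n_starts Number of random restarts (default 20).
#' @param seed Integer seed making the restarts reproducible.
#' @param tol EM stops when the relative log-likelihood improvement drops
#'   below this (default 1e-8).
#' @param max_iter Iteration cap per restart.
#' @param min_scores Minimum number of scores required (default 100).
#' @param var_floor Lower bound on component variances, guarding against
#'   degenerate spikes (default 1e-6).
#' @return An object of class `gaussian_mixture3`: list with `weights`,
#'   `means`, `sds` (sorted by mean), `loglik`, `n_iter`, `n`, `seed`, and
#'   `threshold` (the intersection cutoff, see [threshold_from_mixture()],
#'   `NA` if undefined).
#' @export
fit_mixture <- function(scores, n_starts = 20L, seed = 1L, tol = 1e-8,
                        max_iter = 1000L, min_scores = 100L,
                        var_floor = 1e-6) {
  n_bad <- sum(!is.finite(scores))
  if (n_bad > 0L) {
    stop(n_bad, " non-finite score(s) in input; remove them before fitting")
  }
  x <- as.numeric(scores)
  if (length(x) < min_scores) {
    stop("need at least ", min_scores, " scores to fit the mixture (have ", length(x), ")")
  }
  if (stats::sd(x) == 0) stop("all scores identical; mixture variance is degenerate")

  restore <- .local_seed(seed)
  on.exit(restore(), add = TRUE)

  best <- NULL
  for (start in seq_len(n_starts)) {
    init <- .gmm3_init(x, jitter = start > 1L)
    fit <- .gmm3_em(x, init, tol = tol, max_iter = max_iter, var_floor = var_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  ord <- order(best$means)
  out <- structure(
    list(
      weights = best$weights[ord], means = best$means[ord], sds = best$sds[ord],
      loglik = best$loglik, n_iter = best$n_iter, n = length(x),
      seed = as.integer(seed), threshold = NA_real_
    ),
    class = "gaussian_mixture3"
  )
  out$threshold <- tryCatch(threshold_from_mixture(out), error = function(e) NA_real_)
  out
}

#' Low-score cutoff from the intersection of mixture components
#'
#' Solves `w2 * N(x; mu2, sd2) = w3 * N(x; mu3, sd3)` for the second and
#' third components (after sorting by mean), restricted to the open interval
#' `(mu2, mu3)`. Equating log-densities gives a quadratic in `x`; when both
#' roots fall inside the interval the one closer to the total mixture's
#' density minimum is returned.
#'
#' @param mixture A `gaussian_mixture3` from [fit_mixture()], or any list
#'   with `weights`, `means`, `sds` sorted ascending by mean.
#' @return The cutoff `t*` (numeric scalar).
#' @examples
#' m <- list(weights = c(0.3, 0.35, 0.35), means = c(0, 0.3, 1), sds = c(0.1, 0.1, 0.1))
#' threshold_from_mixture(m) # symmetric case: midpoint 0.65
#' @export
threshold_from_mixture <- function(mixture) {
  w <- mixture$weights
  mu <- mixture$means
  sd <- mixture$sds
  if (mu[2] >= mu[3]) stop("component means must satisfy mu2 < mu3")

  # log(w2) - log(sd2) - (x-mu2)^2/(2 sd2^2) = log(w3) - log(sd3) - (x-mu3)^2/(2 sd3^2)
  a <- 1 / (2 * sd[3]^2) - 1 / (2 * sd[2]^2)
  b <- mu[2] / sd[2]^2 - mu[3] / sd[3]^2
  cc <- mu[3]^2 / (2 * sd[3]^2) - mu[2]^2 / (2 * sd[2]^2) +
    log(w[2] / sd[2]) - log(w[3] / sd[3])

  roots <- if (abs(a) < 1e-14) {
    if (abs(b) < 1e-14) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0) else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > mu[2] & roots < mu[3]]
  if (length(inside) == 0L) {
    stop(
      "no intersection of components 2 and 3 in (", signif(mu[2], 4), ", ",
      signif(mu[3], 4), "); one component dominates everywhere ",
      "(w2=", signif(w[2], 4), ", sd2=", signif(sd[2], 4),
      ", w3=", signif(w[3], 4), ", sd3=", signif(sd[3], 4), ")"
    )
  }
  if (length(inside) == 1L) {
    return(inside)
  }
  # two intersections between the means: keep the one nearest the density
  # minimum of the full mixture
  dens <- function(x) {
    rowSums(vapply(
      1:3,
      function(k) w[k] * stats::dnorm(x, mu[k], sd[k]),
      numeric(length(x))
    ))
  }
  grid <- seq(mu[2], mu[3], length.out = 512L)
  x_min <- grid[which.min(dens(grid))]
  inside[which.min(abs(inside - x_min))]
}

#' Mixture density of a fitted three-component model
#'
#' @param x Numeric vector of evaluation points.
#' @param mixture A `gaussian_mixture3` (or compatible list).
#' @return Density values of the weighted mixture at `x`.
#' @export
dmixture3 <- function(x, mixture) {
  w <- mixture$weights
  mu <- mixture$means
  sd <- mixture$sds
  w[1] * stats::dnorm(x, mu[1], sd[1]) +
    w[2] * stats::dnorm(x, mu[2], sd[2]) +
    w[3] * stats::dnorm(x, mu[3], sd[3])
}

#' @export
print.gaussian_mixture3 <- function(x, ...) {
  cat("Three-component Gaussian mixture (n =", x$n, ")\n")
  tab <- data.frame(
    component = c("low", "intermediate", "high"),
    weight = round(x$weights, 4), mean = round(x$means, 4), sd = round(x$sds, 4)
  )
  print(tab, row.names = FALSE)
  cat(
    "log-likelihood:", format(x$loglik), " iterations:", x$n_iter,
    "\nlow-abundance threshold t* =", format(x$threshold), "\n"
  )
  invisible(x)
}

# ---- internal EM ------------------------------------------------------------

.gmm3_init <- function(x, jitter = TRUE) {
  qs <- stats::quantile(x, c(1, 3, 5) / 6, names = FALSE)
  spread <- stats::sd(x)
  if (jitter) qs <- qs + stats::rnorm(3L, 0, spread / 4)
  list(
    weights = rep(1 / 3, 3L),
    means = sort(qs),
    sds = rep(max(spread / 3, 1e-3), 3L)
  )
}

.gmm3_em <- function(x, init, tol, max_iter, var_floor) {
  n <- length(x)
  w <- init$weights
  mu <- init$means
  v <- init$sds^2
  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E step in log space for stability
    logp <- vapply(
      1:3,
      function(k) log(w[k]) + stats::dnorm(x, mu[k], sqrt(v[k]), log = TRUE),
      numeric(n)
    )
    m <- apply(logp, 1L, max)
    lse <- m + log(rowSums(exp(logp - m)))
    ll <- sum(lse)
    resp <- exp(logp - lse)

    if (is.finite(ll_old) && (ll - ll_old) < tol * abs(ll)) break
    if (iter >= max_iter) break
    ll_old <- ll

    nk <- pmax(colSums(resp), 1e-12)
    w <- nk / n
    mu <- vapply(1:3, function(k) sum(resp[, k] * x) / nk[k], numeric(1))
    v <- pmax(
      vapply(1:3, function(k) sum(resp[, k] * (x - mu[k])^2) / nk[k], numeric(1)),
      var_floor
    )
  }
  list(weights = w, means = mu, sds = sqrt(v), loglik = ll, n_iter = iter)
}
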