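#' Two-component Gaussian mixture positivity cutoff
#'
#' Fits a two-component normal mixture to continuous biomarker levels by EM
#' (components initialized from the lower and upper terciles) and derives the
#' positivity threshold as the point between the component means where the
#' weighted component densities are equal — i.e. where the posterior
#' probability of either component is 0.5.
#'
#' @param values numeric vector of biomarker levels (`n >= 10`, finite).
#' @param max_iter maximum EM iterations; default `500`.
#' @param tol convergence tolerance on the relative log-likelihood change;
#'   default `1e-8`.
#' @param seed optional seed (used only for jittered restarts after
#'   degeneracy).
#' @return object of class `"cutoff_model"`: `pi` (mixing weight of the
#'   lower component), `mu`, `sigma` (length-2, lower component first),
#'   `threshold`, `log_likelihood`, `loglik_trace`, `n_iter`, `converged`.
#' @examples
#' set.seed(1)
#' v <- c(rnorm(300, -2), rnorm(300, 2))
#' fit_mixture_cutoff(v)$threshold   # close to 0
#' @export
fit_mixture_cutoff <- function(values, max_iter = 500, tol = 1e-8,
                               seed = NULL) {
  values <- as.numeric(values)
  if (length(values) < 10) stop("need at least 10 values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (!is.null(seed)) set.seed(seed)

  for (attempt in 1:3) {
    init <- mixture_init(values, jitter = attempt > 1)
    fit <- tryCatch(mixture_em(values, init, max_iter, tol),
                    error = function(e) e)
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error"))
    stop("EM degenerated after 3 restarts: ", conditionMessage(fit))

  # ensure lower component first
  if (fit$mu[1] > fit$mu[2]) {
    fit$mu <- rev(fit$mu); fit$sigma <- rev(fit$sigma); fit$pi <- 1 - fit$pi
  }
  thr <- mixture_threshold(fit$pi, fit$mu, fit$sigma)
  structure(list(
    pi = fit$pi, mu = fit$mu, sigma = fit$sigma, threshold = thr,
    log_likelihood = utils::tail(fit$trace, 1), loglik_trace = fit$trace,
    n_iter = length(fit$trace), converged = fit$converged
  ), class = "cutoff_model")
}

mixture_init <- function(values, jitter = FALSE) {
  q <- stats::quantile(values, c(1 / 3, 2 / 3), names = FALSE)
  lo <- values[values <= q[1]]; hi <- values[values >= q[2]]
  mu <- c(mean(lo), mean(hi))
  if (jitter) mu <- mu + stats::rnorm(2, sd = 0.1 * stats::sd(values))
  sigma <- pmax(c(stats::sd(lo), stats::sd(hi)), 1e-3 * stats::sd(values))
  list(pi = 0.5, mu = mu, sigma = sigma)
}

mixture_em <- function(values, init, max_iter, tol) {
  n <- length(values)
  pi1 <- init$pi; mu <- init$mu; sigma <- init$sigma
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    d1 <- pi1 * stats::dnorm(values, mu[1], sigma[1])
    d2 <- (1 - pi1) * stats::dnorm(values, mu[2], sigma[2])
    tot <- d1 + d2
    if (any(tot <= 0) || any(!is.finite(tot))) stop("vanishing mixture density")
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(prev) && abs(ll - prev) <= tol * max(1, abs(prev))) {
      converged <- TRUE
      break
    }
    prev <- ll
    r1 <- d1 / tot
    n1 <- sum(r1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) stop("component collapsed")
    pi1 <- n1 / n
    mu <- c(sum(r1 * values) / n1, sum((1 - r1) * values) / n2)
    sigma <- sqrt(c(sum(r1 * (values - mu[1])^2) / n1,
                    sum((1 - r1) * (values - mu[2])^2) / n2))
    if (any(sigma < 1e-6 * stats::sd(values))) stop("sigma collapsed")
  }
  list(pi = pi1, mu = mu, sigma = sigma, trace = trace, converged = converged)
}

# Equal weighted-density point between the means: the quadratic root of
# log(pi1 N(t; mu1, s1)) = log(pi2 N(t; mu2, s2)) restricted to [mu1, mu2].
mixture_threshold <- function(pi1, mu, sigma) {
  s1 <- sigma[1]; s2 <- sigma[2]
  k <- 2 * (log(pi1) - log(1 - pi1) + log(s2) - log(s1))
  a <- 1 / s1^2 - 1 / s2^2
  b <- -2 * (mu[1] / s1^2 - mu[2] / s2^2)
  cc <- mu[1]^2 / s1^2 - mu[2]^2 / s2^2 - k
  roots <- if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0) else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots >= mu[1] & roots <= mu[2]]
  if (length(inside) >= 1) return(inside[1])
  # fall back: numerical root of the weighted-density difference
  f <- function(t) log(pi1) + stats::dnorm(t, mu[1], s1, log = TRUE) -
    log(1 - pi1) - stats::dnorm(t, mu[2], s2, log = TRUE)
  if (f(mu[1]) * f(mu[2]) < 0)
    return(stats::uniroot(f, c(mu[1], mu[2]), tol = 1e-10)$root)
  mean(mu)
}

#' @export
print.cutoff_model <- function(x, ...) {
  cat("Two-component Gaussian mixture cutoff\n")
  cat(sprintf("  components: %.2f * N(%.4g, %.4g) + %.2f * N(%.4g, %.4g)\n",
              x$pi, x$mu[1], x$sigma[1], 1 - x$pi, x$mu[2], x$sigma[2]))
  cat(sprintf("  threshold: %.6g  (log-likelihood %.4f, %d EM iterations)\n",
              x$threshold, x$log_likelihood, x$n_iter))
  invisible(x)
}

#' Assign binary positivity labels from a fitted cutoff
#'
#' Samples strictly above the threshold are positive when higher values mean
#' higher risk (GFAP, NfL, pTau and the reciprocal-transformed amyloid
#' ratio); with `higher_is_risk = FALSE` the comparison flips. A value
#' exactly at the threshold is negative.
#'
#' @param values numeric biomarker levels.
#' @param model a `"cutoff_model"`.
#' @param higher_is_risk logical; default `TRUE`.
#' @return integer 0/1 vector.
#' @export
assign_positivity <- function(values, model, higher_is_risk = TRUE) {
  stopifnot(inherits(model, "cutoff_model"))
  if (higher_is_risk) as.integer(values > model$threshold)
  else as.integer(values < model$threshold)
}

#' Reciprocal transform for the amyloid-beta ratio
#'
#' Lower plasma Abeta42/40 signals higher risk; taking the reciprocal
#' (Abeta40/42) keeps "higher = riskier" consistent across biomarkers.
#'
#' @param values strictly positive ratio values.
#' @return `1 / values`.
#' @export
reciprocal_abeta <- function(values) {
  if (any(values <= 0, na.rm = TRUE))
    stop("amyloid ratio must be strictly positive for the reciprocal")
  1 / values
}
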