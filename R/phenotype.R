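## Phenotype-level statistics for selected clones: degranulation readout,
## FACS stimulation index, normality/skewness tests of clone release
## distributions, and a two-component normal mixture fit.

#' Degranulation release percentage
#'
#' `100 * s1 / (s1 + s2)` — the released fraction of the enzyme signal, where
#' `s1` is the supernatant (released) and `s2` the unreleased signal. When a
#' control release is supplied the result is expressed as a percentage of the
#' control (`100 * raw / raw_control`), matching the convention of reporting
#' release relative to a cell line expressing an irrelevant antibody.
#'
#' @param s1,s2 non-negative signals (absorbance units); `s1 + s2` must be
#'   positive. Vectorised.
#' @param control optional raw control release percentage (a single value).
#' @return release percentage(s).
#' @export
release_percent <- function(s1, s2, control = NULL) {
  stopifnot(all(s1 >= 0), all(s2 >= 0), all(s1 + s2 > 0))
  raw <- 100 * s1 / (s1 + s2)
  if (is.null(control)) return(raw)
  stopifnot(length(control) == 1L, control > 0)
  100 * raw / control
}

#' MFI stimulation index
#'
#' Ratio of the geometric-mean fluorescence intensity of stimulated to
#' unstimulated cells. 1.0 means the stimulation response is fully abolished.
#'
#' @param mfi_stimulated,mfi_unstimulated positive MFI values (vectorised).
#' @return the ratio `S / NS`.
#' @export
stimulation_index <- function(mfi_stimulated, mfi_unstimulated) {
  stopifnot(all(mfi_stimulated > 0), all(mfi_unstimulated > 0))
  mfi_stimulated / mfi_unstimulated
}

# moment-based sample skewness and excess kurtosis (biased, as used by the
# Jarque-Bera statistic)
sample_skewness <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^3) / s2^1.5
}
sample_excess_kurtosis <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^4) / s2^2 - 3
}

#' Jarque-Bera normality test with D'Agostino skewness test
#'
#' `JB = n/6 * (S^2 + K^2/4)` with sample skewness `S` and excess kurtosis
#' `K`, referred to a chi-squared distribution with 2 degrees of freedom.
#' Also reports D'Agostino's skewness z-test (two-sided), the standard
#' normalising transformation of the sample skewness.
#'
#' @param x numeric sample, `n >= 8`.
#' @return list of class `normality_result`: `n`, `jb_stat`, `jb_p`,
#'   `skewness`, `skew_z`, `skew_p`.
#' @export
jarque_bera <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L) stop("need at least 8 observations")
  S <- sample_skewness(x)
  K <- sample_excess_kurtosis(x)
  jb <- n / 6 * (S^2 + K^2 / 4)
  jb_p <- pchisq(jb, df = 2, lower.tail = FALSE)

  # D'Agostino (1970) skewness z-transform
  Y <- S * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z <- delta * asinh(Y / alpha)
  skew_p <- 2 * stats::pnorm(-abs(z))

  structure(list(n = n, jb_stat = jb, jb_p = jb_p,
                 skewness = S, skew_z = z, skew_p = skew_p),
            class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("Jarque-Bera: JB = %.3f, p = %.4g (n = %d)\n",
              x$jb_stat, x$jb_p, x$n))
  cat(sprintf("Skewness %.3f; D'Agostino z = %.3f, p = %.4g\n",
              x$skewness, x$skew_z, x$skew_p))
  invisible(x)
}

#' Fit a two-component normal mixture
#'
#' Maximum-likelihood fit by expectation-maximisation on the raw values with
#' k-means initialisation plus random restarts; the best log-likelihood is
#' kept. Components are reported with `mu1 > mu2` (high mode first), `pi` the
#' weight of component 1. A restart whose component standard deviation
#' collapses is discarded; if every restart degenerates the fit is flagged
#' failed. `method = "histogram"` instead least-squares fits the mixture
#' density to a histogram of the data (the curve-to-distribution variant);
#' its parameters are refit by `optim` from the ML solution's start.
#'
#' @param x numeric sample, `n >= 20`.
#' @param n_restarts random restarts beyond the k-means start (default 5).
#' @param tol EM convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter maximum EM iterations per start (default 500).
#' @param seed seed for the restarts.
#' @param method `"ml"` (default) or `"histogram"`.
#' @param breaks histogram breaks for `method = "histogram"`.
#' @return list of class `mixture_fit`: `pi`, `mu` (length 2, decreasing),
#'   `sigma`, `loglik`, `loglik_trace` (per-iteration, non-decreasing),
#'   `converged`, `failed`, `method`.
#' @export
fit_two_normal_mixture <- function(x, n_restarts = 5L, tol = 1e-8,
                                   max_iter = 500L, seed = 1L,
                                   method = c("ml", "histogram"),
                                   breaks = "Sturges") {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 20L) stop("need at least 20 observations")

  best <- NULL
  with_seed(seed, {
    starts <- c(list(kmeans_start(x)),
                replicate(n_restarts, random_start(x), simplify = FALSE))
    for (st in starts) {
      fit <- em_two_normal(x, st, tol = tol, max_iter = max_iter)
      if (is.null(fit)) next  # degenerate
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  if (is.null(best)) {
    return(structure(list(pi = NA_real_, mu = c(NA_real_, NA_real_),
                          sigma = c(NA_real_, NA_real_), loglik = -Inf,
                          loglik_trace = numeric(0), converged = FALSE,
                          failed = TRUE, method = method),
                     class = "mixture_fit"))
  }
  best <- order_components(best)
  best$failed <- FALSE
  best$method <- method
  class(best) <- "mixture_fit"

  if (method == "histogram") {
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    obj <- function(par) {
      p <- stats::plogis(par[1])
      dens <- p * dnorm(h$mids, par[2], exp(par[4])) +
        (1 - p) * dnorm(h$mids, par[3], exp(par[5]))
      sum((dens - h$density)^2)
    }
    par0 <- c(stats::qlogis(best$pi), best$mu, log(best$sigma))
    opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000))
    best$pi <- stats::plogis(opt$par[1])
    best$mu <- opt$par[2:3]
    best$sigma <- exp(opt$par[4:5])
    best$converged <- opt$convergence == 0
    best <- order_components(best)
  }
  best
}

kmeans_start <- function(x) {
  km <- kmeans(x, centers = 2L, nstart = 5L)
  list(pi = mean(km$cluster == 1L), mu = as.vector(km$centers),
       sigma = rep(max(sd(x) / 2, 1e-3), 2L))
}

random_start <- function(x) {
  q <- sort(sample(x, 2L))
  list(pi = runif(1, 0.2, 0.8), mu = q,
       sigma = rep(max(sd(x) / 2, 1e-3), 2L))
}

em_two_normal <- function(x, start, tol, max_iter) {
  n <- length(x)
  p <- start$pi; mu <- start$mu; sg <- start$sigma
  sigma_floor <- 1e-6 * max(sd(x), 1e-12)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- p * dnorm(x, mu[1], sg[1])
    d2 <- (1 - p) * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    g <- d1 / tot
    p <- mean(g)
    if (p < 1e-8 || p > 1 - 1e-8) return(NULL)
    mu[1] <- sum(g * x) / sum(g)
    mu[2] <- sum((1 - g) * x) / sum(1 - g)
    sg[1] <- sqrt(sum(g * (x - mu[1])^2) / sum(g))
    sg[2] <- sqrt(sum((1 - g) * (x - mu[2])^2) / sum(1 - g))
    if (any(sg < sigma_floor)) return(NULL)
  }
  list(pi = p, mu = mu, sigma = sg, loglik = ll, loglik_trace = trace,
       converged = converged)
}

order_components <- function(fit) {
  if (fit$mu[1] < fit$mu[2]) {
    fit$mu <- rev(fit$mu)
    fit$sigma <- rev(fit$sigma)
    fit$pi <- 1 - fit$pi
  }
  fit
}

#' @export
print.mixture_fit <- function(x, ...) {
  if (x$failed) {
    cat("<mixture_fit> failed (all restarts degenerate)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<mixture_fit %s> pi = %.3f, mu = (%.2f, %.2f), sigma = (%.2f, %.2f)\n",
    x$method, x$pi, x$mu[1], x$mu[2], x$sigma[1], x$sigma[2]))
  cat(sprintf("loglik = %.4f, converged = %s\n", x$loglik, x$converged))
  invisible(x)
}
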