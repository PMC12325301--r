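# One-dimensional K-component Gaussian mixture fitted by EM from a fixed
# initialization. No random restarts: the procedure is deterministic given
# (samples, init), which makes whole-pipeline runs reproducible without
# seeds.

#' Default mixture initialization for normalized FLAIR intensities
#'
#' The empirical three-component starting point for region-normalized
#' T2-FLAIR intensities: a dark fluid component, an intermediate
#' partial-volume component, and a bright choroid-plexus component.
#' Means [0.15, 1.5, 4], standard deviations [0.02, 0.1, 1.5], proportions
#' [0.45, 0.5, 0.05]. These are starting values, not constraints; EM adapts
#' them to the data of each hemisphere.
#'
#' @return A `mixture_params` list with `means`, `sds`, `weights`.
#' @export
gmm_init_default <- function() {
  mixture_params(means = c(0.15, 1.5, 4),
                 sds = c(0.02, 0.1, 1.5),
                 weights = c(0.45, 0.5, 0.05))
}

#' Construct mixture parameters
#'
#' @param means,sds,weights Numeric vectors of equal length K; `sds` must be
#'   positive and `weights` non-negative summing to 1.
#' @return A validated `mixture_params` list.
#' @export
mixture_params <- function(means, sds, weights) {
  K <- length(means)
  if (length(sds) != K || length(weights) != K)
    stop("means, sds and weights must have equal length")
  if (any(sds <= 0)) stop("component standard deviations must be positive")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  structure(list(means = as.numeric(means), sds = as.numeric(sds),
                 weights = as.numeric(weights)),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat("<mixture_params> K =", length(x$means), "\n")
  print(data.frame(mean = x$means, sd = x$sds, weight = x$weights,
                   row.names = paste0("comp", seq_along(x$means))))
  invisible(x)
}

# Log density matrix (n x K) under the mixture, with log weights folded in.
.log_weighted_dens <- function(x, params) {
  K <- length(params$means)
  sapply(seq_len(K), function(k) {
    log(params$weights[k]) +
      stats::dnorm(x, params$means[k], params$sds[k], log = TRUE)
  })
}

# Row-wise log-sum-exp of an n x K matrix.
.logsumexp_rows <- function(lw) {
  m <- apply(lw, 1L, max)
  m + log(rowSums(exp(lw - m)))
}

#' Posterior component responsibilities
#'
#' Computes the posterior probability of each component for each sample,
#' P(k | x) = pi_k N(x; mu_k, sd_k) / sum_j pi_j N(x; mu_j, sd_j), in the
#' log domain for numerical stability. Rows sum to 1.
#'
#' @param x Numeric vector of samples (or a `region_samples` object).
#' @param params A `mixture_params` object.
#' @return An n x K matrix of posteriors.
#' @export
responsibilities <- function(x, params) {
  if (inherits(x, "region_samples")) x <- x$values
  K <- length(params$means)
  if (length(x) == 0L) return(matrix(numeric(0), nrow = 0L, ncol = K))
  lw <- matrix(.log_weighted_dens(x, params), ncol = K)
  exp(lw - .logsumexp_rows(lw))
}

#' Fit a 1-D Gaussian mixture by EM
#'
#' Standard expectation-maximization for a K-component univariate Gaussian
#' mixture, started from a fixed initialization (no restarts). Iterates
#' until the relative change in log-likelihood drops below `tol` or
#' `max_iter` is reached. Component standard deviations are clamped at
#' `sd_floor` to prevent collapse onto single points; any clamping is
#' recorded in the result.
#'
#' @param x Numeric sample vector or a `region_samples` object.
#' @param init Starting `mixture_params`; defaults to [gmm_init_default()].
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param sd_floor Lower bound on component standard deviations
#'   (normalized-intensity units).
#' @return An object of class `cp_gmm`: `params` (fitted `mixture_params`),
#'   `loglik_trace`, `n_iter`, `converged`, `sd_clamped`, `n`, and the
#'   input `init`.
#' @export
gmm_fit <- function(x, init = gmm_init_default(), tol = 1e-6,
                    max_iter = 500L, sd_floor = 1e-4) {
  if (inherits(x, "region_samples")) x <- x$values
  stopifnot(is.numeric(x), tol > 0, max_iter >= 1L)
  K <- length(init$means)
  if (length(x) < K)
    stop("need at least K = ", K, " samples to fit the mixture, got ",
         length(x))
  means <- init$means; sds <- init$sds; weights <- init$weights
  n <- length(x)
  trace <- numeric(0)
  converged <- FALSE
  clamped <- FALSE
  ll_prev <- -Inf
  for (iter in seq_len(max_iter)) {
    # E-step in the log domain
    lw <- matrix(.log_weighted_dens(
      x, list(means = means, sds = sds, weights = weights)), ncol = K)
    lse <- .logsumexp_rows(lw)
    ll <- sum(lse)
    trace <- c(trace, ll)
    r <- exp(lw - lse)
    # M-step
    nk <- colSums(r)
    keep <- nk > n * 1e-12
    weights <- nk / n
    means[keep] <- colSums(r * x)[keep] / nk[keep]
    v <- colSums(r * outer(x, means, "-")^2)
    sds[keep] <- sqrt(v[keep] / nk[keep])
    if (any(sds < sd_floor)) {
      sds <- pmax(sds, sd_floor)
      clamped <- TRUE
    }
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  structure(
    list(params = mixture_params(means, sds, weights / sum(weights)),
         loglik_trace = trace, n_iter = length(trace),
         converged = converged, sd_clamped = clamped, n = n, init = init),
    class = "cp_gmm"
  )
}

#' Index of the brightest (choroid-plexus) component
#'
#' The component with the highest fitted mean takes the choroid-plexus
#' role; if two fitted means tie to machine precision, the heavier
#' component wins (deterministic).
#'
#' @param params A `mixture_params` object.
#' @return Integer component index.
#' @export
cp_component <- function(params) {
  mx <- max(params$means)
  cand <- which(params$means >= mx - .Machine$double.eps * abs(mx))
  if (length(cand) > 1L) cand <- cand[which.max(params$weights[cand])]
  cand
}

#' Hard-assign samples to the choroid plexus
#'
#' Hard posterior clustering: a sample is choroid plexus when the brightest
#' component (highest fitted mean) attains its maximum posterior
#' probability. Posterior ties are broken toward the higher-mean component.
#'
#' @param x Numeric samples or `region_samples`.
#' @param params Fitted `mixture_params` (or a `cp_gmm` object).
#' @return Logical vector, `TRUE` for choroid-plexus voxels.
#' @export
assign_cp <- function(x, params) {
  if (inherits(params, "cp_gmm")) params <- params$params
  if (inherits(x, "region_samples")) x <- x$values
  if (length(x) == 0L) return(logical(0))
  post <- responsibilities(x, params)
  ord <- order(params$means, decreasing = TRUE)
  # which.max returns the first maximum, so ordering columns by decreasing
  # mean resolves posterior ties toward the brighter component
  winner <- ord[max.col(post[, ord, drop = FALSE], ties.method = "first")]
  winner == cp_component(params)
}

#' @export
print.cp_gmm <- function(x, ...) {
  cat("One-dimensional Gaussian mixture (EM), K =",
      length(x$params$means), "\n")
  cat("  n =", x$n, " iterations =", x$n_iter,
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  cat("  final log-likelihood:", format(x$loglik_trace[x$n_iter]), "\n")
  if (x$sd_clamped) cat("  note: sd floor engaged during fitting\n")
  print(x$params)
  cat("  brightest component (choroid-plexus role):",
      cp_component(x$params), "\n")
  invisible(x)
}

#' @export
coef.cp_gmm <- function(object, ...) {
  p <- object$params
  matrix(c(p$means, p$sds, p$weights), ncol = 3,
         dimnames = list(paste0("comp", seq_along(p$means)),
                         c("mean", "sd", "weight")))
}

#' @export
logLik.cp_gmm <- function(object, ...) {
  K <- length(object$params$means)
  structure(object$loglik_trace[object$n_iter],
            df = 3 * K - 1, nobs = object$n, class = "logLik")
}

#' @export
predict.cp_gmm <- function(object, newdata,
                           type = c("responsibility", "class", "cp"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "region_samples")) newdata <- newdata$values
  switch(type,
         responsibility = responsibilities(newdata, object$params),
         class = {
           post <- responsibilities(newdata, object$params)
           ord <- order(object$params$means, decreasing = TRUE)
           ord[max.col(post[, ord, drop = FALSE], ties.method = "first")]
         },
         cp = assign_cp(newdata, object$params))
}

#' @export
plot.cp_gmm <- function(x, samples = NULL, breaks = 60, ...) {
  p <- x$params
  if (!is.null(samples)) {
    if (inherits(samples, "region_samples")) samples <- samples$values
    graphics::hist(samples, breaks = breaks, freq = FALSE,
                   main = "Normalized region intensities and fitted mixture",
                   xlab = "normalized intensity", ...)
    xs <- seq(min(samples), max(samples), length.out = 512)
  } else {
    xs <- seq(min(p$means - 4 * p$sds), max(p$means + 4 * p$sds),
              length.out = 512)
    graphics::plot(NULL, xlim = range(xs), ylim = c(0, 1), xlab =
                   "normalized intensity", ylab = "density",
                   main = "Fitted mixture components", ...)
  }
  for (k in seq_along(p$means))
    graphics::lines(xs, p$weights[k] * stats::dnorm(xs, p$means[k], p$sds[k]),
                    col = k + 1, lwd = 2)
  graphics::legend("topright", bty = "n", lwd = 2,
                   col = seq_along(p$means) + 1,
                   legend = sprintf("comp %d (mu=%.3g)",
                                    seq_along(p$means), p$means))
  invisible(x)
}
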