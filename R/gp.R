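#' @include AllClasses.R
NULL

# Matern 5/2 cross-covariance between row sets X1 (n1 x d) and X2 (n2 x d).
.matern52 <- function(X1, X2, lengthscale, signalSd) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  r <- sqrt(pmax(d2, 0)) / lengthscale
  a <- sqrt(5) * r
  signalSd^2 * (1 + a + a^2 / 3) * exp(-a)
}

# Cholesky with escalating jitter; the covariance is already regularized by
# the noise term, so this only catches near-degenerate inputs.
.cholJitter <- function(K) {
  jit <- 0
  for (j in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    Kj <- K + diag(j, nrow(K))
    L <- tryCatch(t(chol(Kj)), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jit <- j
  }
  stop(sprintf(
    "covariance not positive definite after jitter escalation (last jitter %g)",
    jit))
}

# negative log marginal likelihood at logParams = log(ls, signalSd, noiseSd)
.gpNlml <- function(logParams, X, yc) {
  p <- exp(logParams)
  K <- .matern52(X, X, p[1], p[2]) + diag(p[3]^2 + 1e-10, nrow(X))
  L <- tryCatch(t(chol(K)), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(t(L), forwardsolve(L, yc))
  as.numeric(0.5 * sum(yc * alpha) + sum(log(diag(L))) +
               0.5 * length(yc) * log(2 * pi))
}

#' Fit a Matern 5/2 Gaussian-process surrogate
#'
#' Zero-trend GP regression with an isotropic Matern 5/2 kernel. Kernel
#' hyperparameters (length-scale, signal sd, noise sd) maximize the log
#' marginal likelihood from the supplied start via bounded L-BFGS-B on the
#' log scale; the Cholesky factorization of the training covariance is
#' cached for prediction.
#'
#' @param X numeric matrix of inputs (rows are latent vectors).
#' @param y numeric targets (e.g. KAL scores).
#' @param lengthscale,signalSd,noiseSd starting hyperparameters.
#' @param optimize if FALSE, keep the starting hyperparameters.
#' @return a \linkS4class{GpSurrogate}.
#' @export
fitGp <- function(X, y, lengthscale = NULL, signalSd = NULL,
                  noiseSd = 1e-3, optimize = TRUE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2L, all(is.finite(y)), nrow(X) == length(y))
  yMean <- mean(y)
  yc <- y - yMean
  lengthscale <- lengthscale %||% max(stats::median(stats::dist(X)), 1e-3)
  signalSd <- signalSd %||% max(stats::sd(y), 1e-3)
  lp <- log(c(lengthscale, signalSd, noiseSd))
  if (optimize) {
    opt <- stats::optim(lp, .gpNlml, X = X, yc = yc, method = "L-BFGS-B",
                        lower = lp - log(1e3), upper = lp + log(1e3),
                        control = list(maxit = 100))
    lp <- opt$par
  }
  p <- exp(lp)
  K <- .matern52(X, X, p[1], p[2]) + diag(p[3]^2 + 1e-10, nrow(X))
  L <- .cholJitter(K)
  alpha <- backsolve(t(L), forwardsolve(L, yc))
  new("GpSurrogate", X = X, y = as.numeric(y), logParams = lp,
      yMean = yMean, L = L, alpha = as.numeric(alpha))
}

#' GP posterior mean and standard deviation
#'
#' Closed-form posterior of the latent function at new points; at a
#' (near-)noise-free training point the mean reproduces its target, and far
#' from all data the posterior reverts to the prior mean and sd.
#'
#' @param gp a \linkS4class{GpSurrogate}.
#' @param Xnew matrix (or vector) of query points.
#' @return list with numeric \code{mean} and \code{sd}.
#' @export
gpPredict <- function(gp, Xnew) {
  if (is.null(dim(Xnew))) Xnew <- matrix(Xnew, nrow = 1L)
  p <- exp(gp@logParams)
  Ks <- .matern52(gp@X, Xnew, p[1], p[2])
  mean <- gp@yMean + as.numeric(crossprod(Ks, gp@alpha))
  v <- forwardsolve(gp@L, Ks)
  var <- pmax(p[2]^2 - colSums(v^2), 0)
  list(mean = mean, sd = sqrt(var))
}

#' Expected Improvement
#'
#' EI(x) = (mu - best - xi) Phi(u) + sd phi(u) with
#' u = (mu - best - xi) / sd, and max(mu - best - xi, 0) when sd = 0.
#' Balances exploitation of high-mean regions with exploration of
#' high-uncertainty regions.
#'
#' @param mean,sd posterior mean and sd (vectorized).
#' @param best incumbent best objective value.
#' @param xi exploration jitter (default 0).
#' @return non-negative EI values.
#' @export
expectedImprovement <- function(mean, sd, best, xi = 0) {
  stopifnot(all(sd >= 0))
  d <- mean - best - xi
  out <- pmax(d, 0)
  pos <- sd > 0
  if (any(pos)) {
    u <- d[pos] / sd[pos]
    out[pos] <- d[pos] * stats::pnorm(u) + sd[pos] * stats::dnorm(u)
  }
  pmax(out, 0)
}

#' Propose the next evaluation point
#'
#' Maximizes Expected Improvement inside the search box by bounded
#' L-BFGS-B ascent from \code{config@acqRestarts} uniform random starts;
#' the best local maximum is returned. If every restart fails to produce a
#' finite improvement the best random probe is returned with a warning.
#' Random starts consume the ambient RNG stream.
#'
#' @param gp a fitted \linkS4class{GpSurrogate}.
#' @param config a \linkS4class{BoConfig}.
#' @param best incumbent best (defaults to the surrogate's best target).
#' @return numeric latent vector within bounds.
#' @export
proposeNext <- function(gp, config, best = max(gp@y)) {
  d <- length(config@lower)
  negEi <- function(x) {
    pr <- gpPredict(gp, matrix(x, nrow = 1L))
    -expectedImprovement(pr$mean, pr$sd, best, config@eiJitter)
  }
  starts <- matrix(stats::runif(config@acqRestarts * d, config@lower,
                                config@upper),
                   ncol = d, byrow = TRUE)
  bestX <- NULL; bestVal <- Inf
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], negEi, method = "L-BFGS-B",
                   lower = config@lower, upper = config@upper,
                   control = list(maxit = 60)),
      error = function(e) NULL)
    val <- if (!is.null(res) && is.finite(res$value)) res$value else {
      negEi(starts[i, ])
    }
    x <- if (!is.null(res) && is.finite(res$value)) res$par else starts[i, ]
    if (val < bestVal) {
      bestVal <- val; bestX <- x
    }
  }
  if (!is.finite(bestVal) || is.null(bestX)) {
    warning("all acquisition restarts failed; falling back to random probe")
    bestX <- starts[1, ]
  }
  pmin(pmax(bestX, config@lower), config@upper)
}

#' Default latent search box from a reference embedding
#'
#' Per-dimension [min, max] of the embedded reference library expanded by a
#' margin (10\% of the range by default) on each side.
#'
#' @param Z embedded reference matrix.
#' @param margin fractional expansion.
#' @return list with \code{lower} and \code{upper}.
#' @export
latentBox <- function(Z, margin = 0.1) {
  lo <- apply(Z, 2L, min); hi <- apply(Z, 2L, max)
  span <- pmax(hi - lo, 1e-6)
  list(lower = lo - margin * span, upper = hi + margin * span)
}
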