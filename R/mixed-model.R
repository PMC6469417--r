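#' Random-intercept linear model by maximum likelihood
#'
#' Fits \eqn{y = X\beta + u_g + e} with \eqn{u_g \sim N(0, v)} a per-group
#' (cage) random intercept and \eqn{e \sim N(0, r)} residual noise, by full
#' maximum likelihood. The likelihood is profiled over the variance ratio
#' \eqn{\theta = v/r}: for fixed \eqn{\theta} the GLS estimates of
#' \eqn{\beta} and \eqn{r} are closed-form, leaving a one-dimensional
#' optimization. Full ML (not REML) is used throughout so that the
#' log-likelihood is directly comparable with the pooled fixed-effects fit
#' in a likelihood-ratio test.
#'
#' @param y numeric response (here, natural log of haplotype frequency).
#' @param x numeric predictor (here, generation number).
#' @param group grouping factor (cage identifier); coerced to factor.
#' @return an object of class \code{"ri_ml"}: a list with elements
#'   \code{beta} (intercept and slope), \code{se} (their standard errors,
#'   using the ML residual variance), \code{v} (between-group variance),
#'   \code{r} (residual variance), \code{theta} (\code{v/r}),
#'   \code{logLik}, \code{n}, \code{n_groups}, and the model frame pieces
#'   needed to simulate from the fit.
#' @seealso [fit_pooled_ml()] for the no-random-effect counterpart,
#'   [simulate_ri_ml()] to draw parametric-bootstrap responses.
#' @export
fit_random_intercept <- function(y, x, group) {
  stopifnot(is.numeric(y), is.numeric(x), length(y) == length(x),
            length(group) == length(y))
  if (anyNA(y) || anyNA(x)) stop("NA values in response or predictor")
  g <- factor(group)
  if (nlevels(g) < 2L) stop("need at least 2 groups to fit a random intercept")
  d <- .ri_design(x, g)
  fit <- .ri_fit(d, y)
  fit$call_info <- list(x = x, group = g)
  class(fit) <- "ri_ml"
  fit
}

# Precompute the design quantities shared by every refit on the same (x, group):
# used heavily by the parametric bootstrap, where only y changes.
.ri_design <- function(x, g) {
  X <- cbind(`(Intercept)` = 1, x = x)
  gi <- as.integer(g)
  k <- tabulate(gi, nbins = nlevels(g))          # group sizes
  Sx <- rbind(k, rowsum(x, gi)[, 1])             # 2 x G group sums of X columns
  list(X = X, gi = gi, k = as.numeric(k), Sx = Sx,
       XtX = crossprod(X), n = length(x), G = nlevels(g), levels = levels(g))
}

# Profile log-likelihood machinery. For theta = v/r the inverse correlation
# within a group of size k is I - theta/(1 + k*theta) * J, so the GLS
# estimates and the profiled residual variance reduce to group sums of y
# and X: each likelihood evaluation is O(number of groups).
.ri_profile <- function(d, yty, Xty, Sy) {
  function(theta) {
    cg <- theta / (1 + d$k * theta)
    XtWX <- d$XtX - d$Sx %*% (cg * t(d$Sx))
    XtWy <- Xty - d$Sx %*% (cg * Sy)
    beta <- solve(XtWX, XtWy)
    # floor the weighted RSS so exactly collinear data (zero residuals)
    # yield a finite likelihood instead of a degenerate one
    rss <- max((yty - sum(cg * Sy^2)) - sum(beta * XtWy), d$n * 1e-24)
    r <- rss / d$n
    ll <- -0.5 * d$n * (log(2 * pi * r) + 1) - 0.5 * sum(log1p(d$k * theta))
    list(ll = ll, beta = beta, r = r, XtWX = XtWX)
  }
}

.ri_fit <- function(d, y) {
  yty <- sum(y * y)
  Xty <- crossprod(d$X, y)
  Sy <- rowsum(y, d$gi)[, 1]
  prof <- .ri_profile(d, yty, Xty, Sy)
  # optimize over log(theta); compare against the theta = 0 boundary
  opt <- stats::optimize(function(lt) prof(exp(lt))$ll,
                         interval = c(-30, 15), maximum = TRUE, tol = 1e-8)
  at0 <- prof(0)
  if (opt$objective > at0$ll + 1e-12) {
    theta <- exp(opt$maximum)
    best <- prof(theta)
  } else {
    theta <- 0
    best <- at0
  }
  vc <- best$r * solve(best$XtWX)
  list(beta = c(intercept = best$beta[1L], slope = best$beta[2L]),
       se = sqrt(diag(vc)),
       v = theta * best$r, r = best$r, theta = theta,
       logLik = best$ll, n = d$n, n_groups = d$G,
       design = d, y = y)
}

# REML variance components for the same model. The REML criterion profiles
# out beta and the scale, adding the log-determinant of the GLS information:
# with few groups the ML components divide by n and shrink v toward the
# boundary, so parametric-bootstrap draws simulated from them are
# underdispersed; REML components are the standard small-sample correction.
.ri_reml_vc <- function(d, y) {
  yty <- sum(y * y)
  Xty <- crossprod(d$X, y)
  Sy <- rowsum(y, d$gi)[, 1]
  p <- ncol(d$X)
  crit <- function(theta) {
    cg <- theta / (1 + d$k * theta)
    XtWX <- d$XtX - d$Sx %*% (cg * t(d$Sx))
    XtWy <- Xty - d$Sx %*% (cg * Sy)
    beta <- solve(XtWX, XtWy)
    rss <- max((yty - sum(cg * Sy^2)) - sum(beta * XtWy), d$n * 1e-24)
    -0.5 * ((d$n - p) * log(rss) + sum(log1p(d$k * theta)) +
              determinant(XtWX)$modulus[1])
  }
  opt <- stats::optimize(function(lt) crit(exp(lt)),
                         interval = c(-30, 15), maximum = TRUE, tol = 1e-8)
  theta <- if (opt$objective > crit(0) + 1e-12) exp(opt$maximum) else 0
  cg <- theta / (1 + d$k * theta)
  XtWX <- d$XtX - d$Sx %*% (cg * t(d$Sx))
  XtWy <- Xty - d$Sx %*% (cg * Sy)
  beta <- solve(XtWX, XtWy)
  rss <- max((yty - sum(cg * Sy^2)) - sum(beta * XtWy), d$n * 1e-24)
  r <- rss / (d$n - p)
  list(v = theta * r, r = r)
}

#' Pooled fixed-effects linear fit by maximum likelihood
#'
#' Ordinary least squares of \code{y} on \code{x}, with the log-likelihood
#' evaluated at the ML variance estimate (RSS/n) so it nests inside
#' [fit_random_intercept()] for likelihood-ratio testing.
#'
#' @inheritParams fit_random_intercept
#' @return list with \code{beta}, \code{se}, \code{sigma2} (ML residual
#'   variance), \code{logLik}, \code{n}.
#' @export
fit_pooled_ml <- function(y, x) {
  stopifnot(length(y) == length(x))
  fit <- stats::lm(y ~ x)
  n <- length(y)
  rss <- max(sum(stats::residuals(fit)^2), n * 1e-24)
  s2 <- rss / n
  list(beta = c(intercept = unname(stats::coef(fit)[1L]),
                slope = unname(stats::coef(fit)[2L])),
       se = unname(sqrt(diag(.muffle_perfect_fit(stats::vcov(fit))))),
       sigma2 = s2,
       logLik = -0.5 * n * (log(2 * pi * s2) + 1),
       n = n)
}

#' Simulate responses from a fitted random-intercept model
#'
#' Draws a new response vector from the fitted model: fixed part
#' \eqn{X\hat\beta}, fresh group intercepts \eqn{N(0, \hat v)}, fresh
#' residuals \eqn{N(0, \hat r)}. Used by the parametric bootstrap.
#'
#' @param fit an \code{"ri_ml"} object from [fit_random_intercept()].
#' @param nsim number of response vectors to draw.
#' @return a matrix with \code{fit$n} rows and \code{nsim} columns.
#' @export
simulate_ri_ml <- function(fit, nsim = 1) {
  d <- fit$design
  mu <- as.numeric(d$X %*% fit$beta)
  u <- matrix(stats::rnorm(d$G * nsim, 0, sqrt(fit$v)), d$G, nsim)
  e <- matrix(stats::rnorm(d$n * nsim, 0, sqrt(fit$r)), d$n, nsim)
  mu + u[d$gi, , drop = FALSE] + e
}

#' @export
print.ri_ml <- function(x, ...) {
  cat("Random-intercept linear model (ML)\n")
  cat(sprintf("  n = %d observations in %d groups\n", x$n, x$n_groups))
  cat(sprintf("  slope = %.5f (SE %.5f), intercept = %.5f\n",
              x$beta[2L], x$se[2L], x$beta[1L]))
  cat(sprintf("  variance components: v (between-group) = %.6g, r (residual) = %.6g\n",
              x$v, x$r))
  cat(sprintf("  logLik = %.4f\n", x$logLik))
  invisible(x)
}
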