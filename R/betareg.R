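#' Beta regression log-likelihood and analytic score
#'
#' Parameterization: mean `mu_i = plogis(x_i' beta)`, constant precision
#' `phi` (log-link internally), Beta shapes `(mu_i * phi, (1 - mu_i) * phi)`.
#' `theta` stacks `c(beta, log(phi))`. These are exposed so the score can be
#' cross-checked against finite differences of the log-likelihood.
#'
#' @param theta numeric vector `c(beta, log_phi)`.
#' @param y outcomes strictly inside (0, 1).
#' @param X design matrix (n x P).
#' @return `beta_loglik()`: the log-likelihood; `beta_score()`: its gradient
#'   with respect to `theta`.
#' @export
beta_loglik <- function(theta, y, X) {
  P <- ncol(X)
  beta <- theta[seq_len(P)]
  phi <- exp(theta[P + 1L])
  mu <- stats::plogis(drop(X %*% beta))
  a <- mu * phi; b <- (1 - mu) * phi
  sum(lgamma(phi) - lgamma(a) - lgamma(b) + (a - 1) * log(y) +
        (b - 1) * log1p(-y))
}

#' @rdname beta_loglik
#' @export
beta_score <- function(theta, y, X) {
  P <- ncol(X)
  beta <- theta[seq_len(P)]
  phi <- exp(theta[P + 1L])
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  s_beta <- drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
  s_phi <- sum(mu * (ystar - mustar) + log1p(-y) -
                 digamma((1 - mu) * phi) + digamma(phi))
  c(s_beta, s_phi * phi)  # chain rule for the log(phi) coordinate
}

# Expected Fisher information in theta = (beta, log_phi) coordinates.
beta_expected_info <- function(theta, X) {
  P <- ncol(X)
  beta <- theta[seq_len(P)]
  phi <- exp(theta[P + 1L])
  mu <- stats::plogis(drop(X %*% beta))
  t1 <- trigamma(mu * phi)
  t2 <- trigamma((1 - mu) * phi)
  dmu <- mu * (1 - mu)
  w <- phi^2 * (t1 + t2) * dmu^2
  Kbb <- crossprod(X, X * w)
  cvec <- phi * (t1 * mu - t2 * (1 - mu)) * dmu
  Kbp <- drop(crossprod(X, cvec))
  Kpp <- sum(t1 * mu^2 + t2 * (1 - mu)^2 - trigamma(phi))
  info <- rbind(cbind(Kbb, Kbp * phi), c(Kbp * phi, Kpp * phi^2))
  dimnames(info) <- NULL
  info
}

# Analytic Hessian of the log-likelihood in natural (beta, phi) coordinates.
beta_hessian_natural <- function(beta, phi, y, X) {
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  d <- mu * (1 - mu)                       # dmu/deta (logit link)
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  t1 <- trigamma(mu * phi)
  t2 <- trigamma((1 - mu) * phi)
  r <- ystar - mustar
  # d2l/deta2, per observation
  w <- phi * (-phi * (t1 + t2) * d^2 + r * (1 - 2 * mu) * d)
  Hbb <- crossprod(X, X * w)
  q <- t1 * mu - t2 * (1 - mu)             # dmustar/dphi
  cross <- d * (r - phi * q)               # d2l/deta dphi
  Hbp <- drop(crossprod(X, cross))
  Hpp <- sum(-mu * q - (1 - mu) * t2 + trigamma(phi))
  H <- rbind(cbind(Hbb, Hbp), c(Hbp, Hpp))
  dimnames(H) <- NULL
  H
}

# Hessian in theta = (beta, log_phi) coordinates, given the score s_phi.
beta_hessian_theta <- function(theta, y, X) {
  P <- ncol(X)
  beta <- theta[seq_len(P)]
  phi <- exp(theta[P + 1L])
  H <- beta_hessian_natural(beta, phi, y, X)
  s <- beta_score(theta, y, X)
  s_phi <- s[P + 1L] / phi
  m <- P + 1L
  H[m, seq_len(P)] <- H[seq_len(P), m] <- H[seq_len(P), m] * phi
  H[m, m] <- H[m, m] * phi^2 + s_phi * phi
  H
}

# Core MLE on a prepared design matrix: Newton/Fisher scoring with step
# halving. Observed-information Newton steps give quadratic convergence near
# the optimum; expected-information scoring is the fallback when the observed
# information is not positive definite.
beta_mle <- function(y, X, tol = 1e-6, max_iter = 200L) {
  n <- length(y); P <- ncol(X)
  # starting values: linear fit on logit(y), method-of-moments phi
  ylog <- log(y) - log1p(-y)
  lf <- stats::lm.fit(X, ylog)
  beta0 <- lf$coefficients
  mu0 <- stats::plogis(drop(X %*% beta0))
  sig2 <- sum(lf$residuals^2) / max(n - P, 1L)
  phi0 <- mean(mu0 * (1 - mu0) / (sig2 * (mu0 * (1 - mu0))^2)) - 1
  if (!is.finite(phi0) || phi0 <= 0) phi0 <- 1
  theta <- c(beta0, log(phi0))

  ll <- beta_loglik(theta, y, X)
  trace <- ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- beta_score(theta, y, X)
    if (max(abs(s)) < tol) { converged <- TRUE; break }
    oi <- -beta_hessian_theta(theta, y, X)
    step <- tryCatch(backsolve(chol(oi), forwardsolve(t(chol(oi)), s)),
                     error = function(e) NULL)
    if (is.null(step)) {
      info <- beta_expected_info(theta, X)
      step <- tryCatch(solve(info, s), error = function(e) s / max(abs(s)))
    }
    # step halving: accept log-likelihood increases; at likelihood ties
    # (below rounding) require a strict score-norm decrease to avoid cycling
    lam <- 1
    accepted <- FALSE
    while (lam >= 1e-12) {
      cand <- theta + lam * step
      ll_new <- beta_loglik(cand, y, X)
      if (is.finite(ll_new) &&
          (ll_new > ll ||
           (ll_new == ll &&
            max(abs(beta_score(cand, y, X))) < max(abs(s))))) {
        accepted <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!accepted) {
      # The likelihood can no longer resolve the ascent (its evaluation noise
      # is ~1e-11 at these magnitudes) while the score is still ~1e-5. Take
      # one terminal Newton polish if it lands below tolerance and moves the
      # likelihood only within evaluation noise; it is not an ascent "step",
      # so it is not appended to the monotone trace.
      cand <- theta + step
      ll_new <- beta_loglik(cand, y, X)
      if (is.finite(ll_new) && abs(ll_new - ll) < 1e-7 * (1 + abs(ll)) &&
          max(abs(beta_score(cand, y, X))) < tol) {
        theta <- cand; ll <- ll_new
        converged <- TRUE
      }
      break
    }
    stopifnot(ll_new >= ll)  # monotone by construction
    theta <- cand; ll <- ll_new
    trace <- c(trace, ll)
  }
  if (!converged && max(abs(beta_score(theta, y, X))) < tol) converged <- TRUE
  list(theta = theta, loglik = ll, loglik_trace = trace,
       score = beta_score(theta, y, X), converged = converged,
       n_iter = length(trace) - 1L)
}

#' Fit a beta regression for one cell-type proportion
#'
#' Maximum-likelihood beta regression of a single proportion outcome on the
#' shared exposure/covariate design (see [fit_compositional()] for the design
#' conventions). The mean model uses a logit link, so coefficients are on the
#' log-odds scale; precision `phi` is constant with a log link internally.
#' Fitting is Fisher scoring with step halving (the log-likelihood increases
#' monotonically across accepted steps), started from a linear fit on
#' `logit(y)` with a method-of-moments precision; convergence requires the
#' score max-norm below `tol`.
#'
#' @param y proportions strictly inside (0, 1). Boundary values are an error
#'   unless `squeeze = TRUE`, which applies `(y * (n - 1) + 0.5) / n`.
#' @inheritParams fit_compositional
#' @param cell_type optional label stored in the fit.
#' @param squeeze apply the boundary squeeze transform (default FALSE;
#'   deconvolved-then-zero-replaced inputs are interior).
#' @param tol score max-norm convergence tolerance (default 1e-6).
#' @param max_iter maximum scoring iterations.
#' @return object of class `betareg_fit`: `coefficients` (log-odds scale),
#'   `phi`, `covariance` ((P+1) square, from observed information, order
#'   `c(beta, phi)`), `loglik`, `loglik_trace`, `score`, `converged`,
#'   `n_samples`, `design_columns`.
#' @export
fit_beta_regression <- function(y, cohort,
                                exposures = c("pm25_t1", "pm25_t2", "pm25_t3"),
                                covariates = character(),
                                cell_type = NULL,
                                standardize_exposures = TRUE,
                                squeeze = FALSE,
                                tol = 1e-6, max_iter = 200L) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("`y` contains missing values")
  if (any(y <= 0 | y >= 1)) {
    if (squeeze) {
      y <- (y * (n - 1) + 0.5) / n
    } else {
      bad <- which(y <= 0 | y >= 1)
      stop("proportions on the boundary of (0, 1) for sample(s) ",
           paste(utils::head(bad, 5L), collapse = ", "),
           "; use squeeze = TRUE or replace_zeros()")
    }
  }
  if (stats::var(y) == 0) stop("degenerate outcome: `y` is constant")
  d <- build_design(cohort, exposures, covariates, standardize_exposures)
  X <- d$X
  if (n != nrow(X)) stop("length(y) does not match the cohort")
  if (n <= ncol(X) + 1L) stop("too few samples for ", ncol(X), " predictors")

  m <- beta_mle(y, X, tol = tol, max_iter = max_iter)
  P <- ncol(X)
  beta <- m$theta[seq_len(P)]
  phi <- exp(m$theta[P + 1L])
  names(beta) <- colnames(X)
  covariance <- NULL
  if (m$converged) {
    oi <- -beta_hessian_natural(beta, phi, y, X)
    covariance <- tryCatch(solve(oi), error = function(e) NULL)
    if (!is.null(covariance))
      dimnames(covariance) <- list(c(colnames(X), "phi"), c(colnames(X), "phi"))
  }
  structure(list(
    cell_type = cell_type,
    design_columns = colnames(X),
    coefficients = beta,
    phi = phi,
    covariance = covariance,
    loglik = m$loglik,
    loglik_trace = m$loglik_trace,
    score = m$score,
    converged = m$converged && !is.null(covariance),
    n_samples = n,
    n_iter = m$n_iter,
    exposures = exposures,
    X = X, y = y
  ), class = "betareg_fit")
}

#' Wald summary of a beta-regression fit
#'
#' Normal-theory intervals and two-sided p-values for the mean-model
#' coefficients, on the log-odds scale:
#' `estimate +/- z_{1-alpha/2} * SE`, SEs from the observed-information
#' covariance.
#'
#' @param fit a converged [fit_beta_regression()] object.
#' @param ci_level confidence level (default 0.95).
#' @return data.frame with columns `term`, `estimate`, `se`, `ci_lower`,
#'   `ci_upper`, `z`, `p`.
#' @export
wald_summary <- function(fit, ci_level = 0.95) {
  stopifnot(inherits(fit, "betareg_fit"))
  if (!isTRUE(fit$converged))
    stop("beta regression did not converge; no Wald summary available")
  P <- length(fit$coefficients)
  se <- sqrt(diag(fit$covariance)[seq_len(P)])
  z <- fit$coefficients / se
  zc <- stats::qnorm(1 - (1 - ci_level) / 2)
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = unname(se),
             ci_lower = unname(fit$coefficients - zc * se),
             ci_upper = unname(fit$coefficients + zc * se),
             z = unname(z),
             p = unname(2 * stats::pnorm(-abs(z))),
             row.names = NULL)
}

#' Case-resampling bootstrap intervals for beta regression
#'
#' Percentile confidence intervals for the mean-model coefficients obtained
#' by resampling whole records with replacement and refitting, mirroring the
#' compositional bootstrap. Wald intervals ([wald_summary()]) are the fast
#' default elsewhere; this is the bootstrap alternative.
#'
#' @inheritParams fit_beta_regression
#' @param B bootstrap replicates (default 200).
#' @param ci_level confidence level.
#' @param seed RNG seed.
#' @return data.frame with `term`, `estimate`, `ci_lower`, `ci_upper` and the
#'   number of replicates that converged.
#' @export
bootstrap_beta <- function(y, cohort,
                           exposures = c("pm25_t1", "pm25_t2", "pm25_t3"),
                           covariates = character(),
                           standardize_exposures = TRUE,
                           B = 200L, ci_level = 0.95, seed = 1L,
                           squeeze = FALSE) {
  fit <- fit_beta_regression(y, cohort, exposures, covariates,
                             standardize_exposures = standardize_exposures,
                             squeeze = squeeze)
  X <- fit$X; yy <- fit$y
  n <- length(yy); P <- length(fit$coefficients)
  draws <- matrix(NA_real_, B, P)
  set.seed(as.integer(seed))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    m <- tryCatch(beta_mle(yy[idx], X[idx, , drop = FALSE]),
                  error = function(e) NULL)
    if (!is.null(m) && m$converged) draws[b, ] <- m$theta[seq_len(P)]
  }
  ok <- stats::complete.cases(draws)
  alpha <- 1 - ci_level
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             ci_lower = apply(draws[ok, , drop = FALSE], 2L, stats::quantile,
                              probs = alpha / 2),
             ci_upper = apply(draws[ok, , drop = FALSE], 2L, stats::quantile,
                              probs = 1 - alpha / 2),
             n_converged = sum(ok),
             row.names = NULL)
}

#' @export
print.betareg_fit <- function(x, ...) {
  cat("Beta regression fit",
      if (!is.null(x$cell_type)) paste0("for `", x$cell_type, "`"), "\n")
  cat("  n =", x$n_samples, " phi =", signif(x$phi, 5),
      " loglik =", signif(x$loglik, 7),
      " converged:", x$converged, "\n")
  if (isTRUE(x$converged)) print(wald_summary(x))
  invisible(x)
}
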