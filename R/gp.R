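#' Matérn 5/2 covariance
#'
#' The covariance between two points at Euclidean distance `d` (computed on
#' unit-scaled coordinates) under the Matérn kernel with smoothness fixed at
#' 5/2:
#' \deqn{K(d) = s^2 \left(1 + \frac{\sqrt5\,d}{\ell} + \frac{5 d^2}{3 \ell^2}\right)
#'       \exp\!\left(-\frac{\sqrt5\,d}{\ell}\right)}
#' The smoothness is deliberately not configurable: the kernel is specialized
#' to 5/2, the standard choice for physical response surfaces that are twice
#' differentiable but not infinitely smooth.
#'
#' @param d Non-negative distance(s); vectorized.
#' @param length_scale Positive characteristic length-scale \eqn{\ell} on
#'   unit-scaled inputs.
#' @param signal_var Positive signal variance \eqn{s^2} (amplitude).
#' @return Covariance value(s), same shape as `d`.
#' @examples
#' matern52(0, 1, 2)          # == signal_var
#' matern52(1, 1)             # (1 + sqrt(5) + 5/3) * exp(-sqrt(5))
#' @export
matern52 <- function(d, length_scale, signal_var = 1) {
  assert_number(length_scale, "length_scale", lower = .Machine$double.xmin)
  assert_number(signal_var, "signal_var", lower = .Machine$double.xmin)
  if (any(d < 0)) stop_formbo("distances must be non-negative", "formbo_domain_error")
  r <- sqrt(5) * d / length_scale
  signal_var * (1 + r + r^2 / 3) * exp(-r)
}

# Pairwise Euclidean distance matrices.
dist_matrix <- function(X) as.matrix(stats::dist(X))

cross_dist <- function(X, Z) {
  xn <- rowSums(X^2)
  zn <- rowSums(Z^2)
  d2 <- outer(xn, zn, "+") - 2 * X %*% t(Z)
  sqrt(pmax(d2, 0))
}

# Cholesky with an escalating jitter floor: replicated formulations make the
# Gram matrix numerically singular at small noise, so 1e-10..1e-6 is added to
# the diagonal until factorization succeeds.
chol_jitter <- function(A, start = 1e-10, max_jitter = 1e-6) {
  jit <- start
  repeat {
    L <- tryCatch(chol(A + diag(jit, nrow(A))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jit))
    if (jit >= max_jitter) {
      stop_formbo("covariance matrix not positive definite even after jitter escalation",
                  "formbo_numeric_error")
    }
    jit <- jit * 10
  }
}

gp_nll_terms <- function(D, y, log_l, log_s2, log_sn2) {
  n <- length(y)
  K <- matern52(D, exp(log_l), exp(log_s2))
  ch <- chol_jitter(K + diag(exp(log_sn2), n))
  R <- ch$L                               # upper triangular, A = R'R
  alpha <- backsolve(R, forwardsolve(t(R), y))
  lml <- -0.5 * sum(y * alpha) - sum(log(diag(R))) - 0.5 * n * log(2 * pi)
  list(K = K, R = R, alpha = alpha, lml = lml, jitter = ch$jitter)
}

# Gradient of the log marginal likelihood wrt (log l, log s2, log sn2).
# d lml / d theta = 0.5 * tr((alpha alpha' - A^-1) dA/dtheta).
gp_lml_grad <- function(D, y, log_l, log_s2, log_sn2, terms) {
  l <- exp(log_l); s2 <- exp(log_s2); sn2 <- exp(log_sn2)
  Ainv <- chol2inv(terms$R)
  W <- tcrossprod(terms$alpha) - Ainv
  r <- sqrt(5) * D / l
  dK_dlogl <- s2 * r^2 * (1 + r) * exp(-r) / 3
  dK_dlogs2 <- terms$K
  g <- c(
    0.5 * sum(W * dK_dlogl),
    0.5 * sum(W * dK_dlogs2),
    0.5 * sum(diag(W)) * sn2
  )
  g
}

#' Fit a Gaussian-process surrogate
#'
#' Fits the GP regression model used to drive experiment suggestion: a
#' constant mean (the training mean; responses are standardized internally),
#' an isotropic Matérn 5/2 kernel on unit-scaled inputs, and Gaussian
#' observation noise. The kernel hyperparameters \eqn{\ell}, \eqn{s^2} and
#' the noise variance are chosen by multi-start quasi-Newton maximization of
#' the log marginal likelihood, deterministically given `seed`.
#'
#' @param X Numeric matrix of unit-scaled training inputs (rows =
#'   observations). See [scale_to_unit()].
#' @param y Numeric response vector (original units; standardized
#'   internally).
#' @param noise_var Fix the noise variance at this value instead of fitting
#'   it (in standardized response units squared; `0` is allowed and relies
#'   on the jitter floor). `NULL` (default) fits it.
#' @param n_starts Number of optimizer starts (first start is a data-driven
#'   default, the rest are seeded random draws within the bounds).
#' @param seed Integer seed controlling the random starts.
#' @return An object of class `gp_fit` holding the training data, fitted
#'   `length_scale`, `signal_var`, `noise_var`, standardization constants,
#'   and the cached Cholesky factorization.
#' @export
fit_gp <- function(X, y, noise_var = NULL, n_starts = 8, seed = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) < 2L) stop_formbo("need at least 2 training rows", "formbo_config_error")
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y))) {
    stop_formbo("non-finite values in training data", "formbo_config_error")
  }
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd <= 0) y_sd <- 1
  ys <- (y - y_mean) / y_sd

  D <- dist_matrix(X)
  fit_noise <- is.null(noise_var)
  # bounds in log space: l in [1e-2, 10], s2 in [1e-3, 1e3], sn2 in [1e-8, 10]
  lower <- c(log(1e-2), log(1e-3), log(1e-8))
  upper <- c(log(10), log(1e3), log(10))

  med_d <- stats::median(D[upper.tri(D)])
  if (!is.finite(med_d) || med_d <= 0) med_d <- 0.5
  start0 <- c(log(min(max(med_d, 1e-2), 10)), log(1), log(0.05))
  starts <- with_local_seed(derive_seed(seed, 991L), {
    extra <- max(n_starts - 1L, 0L)
    if (extra > 0) {
      t(replicate(extra, stats::runif(3, lower, upper)))
    } else {
      matrix(numeric(0), 0, 3)
    }
  })
  starts <- rbind(start0, starts)

  obj <- function(par) {
    sn2 <- if (fit_noise) par[3] else log(max(noise_var, 1e-12))
    -gp_nll_terms(D, ys, par[1], par[2], sn2)$lml
  }
  grd <- function(par) {
    sn2 <- if (fit_noise) par[3] else log(max(noise_var, 1e-12))
    terms <- gp_nll_terms(D, ys, par[1], par[2], sn2)
    g <- -gp_lml_grad(D, ys, par[1], par[2], sn2, terms)
    if (fit_noise) g else g[1:2]
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- if (fit_noise) starts[i, ] else starts[i, 1:2]
    res <- tryCatch(
      stats::optim(par0, fn = if (fit_noise) obj else function(p) obj(c(p, 0)),
                   gr = if (fit_noise) grd else function(p) grd(c(p, 0)),
                   method = "L-BFGS-B",
                   lower = if (fit_noise) lower else lower[1:2],
                   upper = if (fit_noise) upper else upper[1:2],
                   control = list(maxit = 200)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop_formbo("GP hyperparameter optimization failed", "formbo_numeric_error")

  par <- best$par
  l <- exp(par[1]); s2 <- exp(par[2])
  sn2 <- if (fit_noise) exp(par[3]) else noise_var
  terms <- gp_nll_terms(D, ys, log(l), log(s2), log(max(sn2, 1e-300)))

  structure(
    list(X = X, y = y, y_std = ys, y_mean = y_mean, y_sd = y_sd,
         length_scale = l, signal_var = s2, noise_var = sn2,
         R = terms$R, alpha = terms$alpha, jitter = terms$jitter,
         lml = terms$lml, seed = seed),
    class = "gp_fit"
  )
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf(
    "<gp_fit> n = %d, d = %d | Matern 5/2: length_scale = %.4g, signal_var = %.4g, noise_var = %.4g | lml = %.3f\n",
    nrow(x$X), ncol(x$X), x$length_scale, x$signal_var, x$noise_var, x$lml))
  invisible(x)
}

#' Gaussian-process posterior prediction
#'
#' Posterior predictive mean and variance at new unit-scaled points. The
#' variance is the observation-predictive variance (latent posterior
#' variance plus the fitted noise variance), de-standardized to original
#' response units; tiny negative values from round-off are clipped at zero.
#' Far from all observations the mean reverts to the training mean and the
#' variance to `signal_var + noise_var` (in standardized units) — uncertainty
#' is lower near observations and higher at a distance.
#'
#' @param state A [fit_gp()] result.
#' @param Xnew Matrix (or single row vector) of unit-scaled points.
#' @param include_noise Include the noise variance in the predictive
#'   variance (default `TRUE`).
#' @return List with numeric vectors `mean` and `var` in original response
#'   units.
#' @export
predict_gp <- function(state, Xnew, include_noise = TRUE) {
  stopifnot(inherits(state, "gp_fit"))
  if (is.null(dim(Xnew))) Xnew <- matrix(Xnew, nrow = 1)
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != ncol(state$X)) {
    stop_formbo(sprintf("expected %d input dimensions, got %d", ncol(state$X), ncol(Xnew)),
                "formbo_config_error")
  }
  Ks <- matern52(cross_dist(state$X, Xnew), state$length_scale, state$signal_var)
  mu_std <- drop(crossprod(Ks, state$alpha))
  V <- forwardsolve(t(state$R), Ks)
  var_std <- state$signal_var - colSums(V^2)
  if (include_noise) var_std <- var_std + state$noise_var
  var_std <- pmax(var_std, 0)
  list(mean = mu_std * state$y_sd + state$y_mean,
       var = var_std * state$y_sd^2)
}

#' @export
predict.gp_fit <- function(object, newdata, ...) predict_gp(object, newdata, ...)

#' Log marginal likelihood of a fitted GP
#'
#' \eqn{-\tfrac12 y^\top (K + \sigma_n^2 I)^{-1} y - \tfrac12 \log\det(K +
#' \sigma_n^2 I) - \tfrac{n}{2}\log 2\pi}, evaluated on the standardized
#' responses via the cached Cholesky factorization.
#'
#' @param state A `gp_fit`.
#' @return The log marginal likelihood (a scalar).
#' @export
log_marginal_likelihood <- function(state) {
  stopifnot(inherits(state, "gp_fit"))
  state$lml
}

# Augment a fitted GP with extra (unit-scaled x, original-unit y) rows,
# keeping the hyperparameters fixed: used by the constant-liar batch rule.
gp_augment <- function(state, xnew, ynew) {
  if (is.null(dim(xnew))) xnew <- matrix(xnew, nrow = 1)
  X2 <- rbind(state$X, xnew)
  y2 <- c(state$y, ynew)
  ys2 <- (y2 - state$y_mean) / state$y_sd
  D <- dist_matrix(X2)
  terms <- gp_nll_terms(D, ys2, log(state$length_scale), log(state$signal_var),
                        log(max(state$noise_var, 1e-300)))
  out <- state
  out$X <- X2; out$y <- y2; out$y_std <- ys2
  out$R <- terms$R; out$alpha <- terms$alpha
  out$jitter <- terms$jitter; out$lml <- terms$lml
  out
}

#' Serialize a fitted GP to JSON (and back)
#'
#' @param state A `gp_fit`.
#' @param path File path.
#' @return `read_gp()` returns a `gp_fit` rebuilt from the stored training
#'   data and hyperparameters (the factorization is recomputed).
#' @export
write_gp <- function(state, path) {
  stopifnot(inherits(state, "gp_fit"))
  jsonlite::write_json(
    list(X = state$X, y = state$y,
         length_scale = state$length_scale, signal_var = state$signal_var,
         noise_var = state$noise_var, y_mean = state$y_mean, y_sd = state$y_sd),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_gp
#' @export
read_gp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- as.matrix(obj$X)
  ys <- (obj$y - obj$y_mean) / obj$y_sd
  terms <- gp_nll_terms(dist_matrix(X), ys, log(obj$length_scale),
                        log(obj$signal_var), log(max(obj$noise_var, 1e-300)))
  structure(
    list(X = X, y = obj$y, y_std = ys, y_mean = obj$y_mean, y_sd = obj$y_sd,
         length_scale = obj$length_scale, signal_var = obj$signal_var,
         noise_var = obj$noise_var, R = terms$R, alpha = terms$alpha,
         jitter = terms$jitter, lml = terms$lml, seed = NA_integer_),
    class = "gp_fit"
  )
}
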