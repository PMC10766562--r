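#' Gaussian-process hyperparameters
#'
#' One mixture component is a Gaussian process with a squared-exponential
#' (or, for the linear-kernel benchmark, homogeneous linear) covariance and
#' a negative linear mean function `m(t) = mean_intercept + mean_slope * t`.
#' The non-positive slope encodes the expectation that function declines
#' over the disease course; the kernel contributes smooth, possibly
#' nonlinear departures from that trend.
#'
#' @param signal_variance Kernel signal variance, points^2 (> 0). Controls
#'   the typical amplitude of departures from the mean function.
#' @param length_scale Kernel length-scale, years (> 0). Controls the
#'   smoothness/stability of the trajectory; must respect `length_scale_floor`.
#' @param noise_variance Observation-noise variance, points^2 (> 0).
#' @param mean_slope Mean-function slope, points/year (<= 0).
#' @param mean_intercept Mean-function intercept, points. Fixed at the scale
#'   maximum when trajectories carry the onset anchor.
#' @param length_scale_floor Lower bound below which a length-scale is
#'   rejected (default 0.05 yr).
#' @return Object of class `gp_hyperparams`.
#' @export
gp_hyperparams <- function(signal_variance, length_scale, noise_variance,
                           mean_slope = 0, mean_intercept = 0,
                           length_scale_floor = 0.05) {
  vals <- c(signal_variance, length_scale, noise_variance,
            mean_slope, mean_intercept)
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("hyperparameters must be finite")
  }
  if (signal_variance <= 0 || noise_variance <= 0) {
    stop("variances must be strictly positive")
  }
  if (length_scale < length_scale_floor) {
    stop(sprintf("length_scale below floor (%g yr)", length_scale_floor))
  }
  if (mean_slope > 0) stop("mean_slope must be <= 0 (monotonic decline bias)")
  structure(list(signal_variance = signal_variance,
                 length_scale = length_scale,
                 noise_variance = noise_variance,
                 mean_slope = mean_slope,
                 mean_intercept = mean_intercept),
            class = "gp_hyperparams")
}

#' @export
print.gp_hyperparams <- function(x, ...) {
  cat(sprintf(paste0("<gp_hyperparams> signal_var=%.4g pts^2, length_scale=",
                     "%.4g yr, noise_var=%.4g pts^2, mean = %.4g %+.4g t\n"),
              x$signal_variance, x$length_scale, x$noise_variance,
              x$mean_intercept, x$mean_slope))
  invisible(x)
}

#' Serialize / deserialize hyperparameters as JSON
#'
#' Fields are written with explicit names and units
#' (`signal_variance_points2`, `length_scale_years`,
#' `noise_variance_points2`, `mean_slope_points_per_year`,
#' `mean_intercept_points`).
#'
#' @param h A [gp_hyperparams()] object.
#' @param json A JSON string or parsed named list.
#' @return `hyperparams_to_json`: a JSON string. `hyperparams_from_json`: a
#'   `gp_hyperparams` object.
#' @export
hyperparams_to_json <- function(h) {
  stopifnot(inherits(h, "gp_hyperparams"))
  # assembled by hand so doubles are written with 17 significant digits
  # (enough to round-trip exactly)
  sprintf(paste0('{"signal_variance_points2":%.17g,',
                 '"length_scale_years":%.17g,',
                 '"noise_variance_points2":%.17g,',
                 '"mean_slope_points_per_year":%.17g,',
                 '"mean_intercept_points":%.17g}'),
          h$signal_variance, h$length_scale, h$noise_variance,
          h$mean_slope, h$mean_intercept)
}

#' @rdname hyperparams_to_json
#' @export
hyperparams_from_json <- function(json) {
  x <- if (is.character(json)) jsonlite::fromJSON(json) else json
  gp_hyperparams(signal_variance = x$signal_variance_points2,
                 length_scale = x$length_scale_years,
                 noise_variance = x$noise_variance_points2,
                 mean_slope = x$mean_slope_points_per_year,
                 mean_intercept = x$mean_intercept_points)
}

#' Squared-exponential kernel
#'
#' `K[i, j] = signal_variance * exp(-(t1[i] - t2[j])^2 / (2 * length_scale^2))`.
#'
#' @param t1,t2 Numeric time vectors (years).
#' @param h A [gp_hyperparams()] object.
#' @return `length(t1) x length(t2)` covariance matrix.
#' @export
se_kernel <- function(t1, t2, h) {
  stopifnot(inherits(h, "gp_hyperparams"),
            all(is.finite(t1)), all(is.finite(t2)))
  d <- outer(t1, t2, "-")
  h$signal_variance * exp(-(d * d) / (2 * h$length_scale^2))
}

#' Homogeneous linear kernel
#'
#' `K[i, j] = signal_variance * t1[i] * t2[j]`; passes through the onset
#' origin, consistent with anchoring at `t = 0`. Used by the linear-kernel
#' mixture benchmark.
#'
#' @inheritParams se_kernel
#' @return Covariance matrix.
#' @export
linear_kernel <- function(t1, t2, h) {
  stopifnot(inherits(h, "gp_hyperparams"),
            all(is.finite(t1)), all(is.finite(t2)))
  h$signal_variance * outer(t1, t2)
}

kernel_matrix <- function(t1, t2, h, kernel = c("se", "linear")) {
  kernel <- match.arg(kernel)
  switch(kernel, se = se_kernel(t1, t2, h), linear = linear_kernel(t1, t2, h))
}

#' Negative linear mean function
#'
#' `m(t) = mean_intercept + mean_slope * t`, elementwise; the slope must be
#' non-positive.
#'
#' @param t Numeric time vector (years).
#' @param h A [gp_hyperparams()] object.
#' @return Numeric vector of mean scores.
#' @export
linear_mean <- function(t, h) {
  stopifnot(inherits(h, "gp_hyperparams"))
  if (h$mean_slope > 0) stop("mean_slope must be <= 0")
  h$mean_intercept + h$mean_slope * t
}

# Relative jitter added to the training Gram diagonal; standard numerical
# safeguard, well below score resolution.
.gp_jitter_rel <- 1e-6

# Cholesky of the training covariance K(T,T) + noise I + jitter I.
.gp_train_chol <- function(t_train, h, kernel) {
  n <- length(t_train)
  K <- kernel_matrix(t_train, t_train, h, kernel)
  diag(K) <- diag(K) + h$noise_variance + .gp_jitter_rel * h$signal_variance
  L <- tryCatch(chol(K), error = function(e) {
    stop("singular training covariance after jitter (n = ", n,
         ", length_scale = ", h$length_scale, "): ", conditionMessage(e))
  })
  L
}

#' Gaussian-process posterior
#'
#' Conditions a GP with the given hyperparameters on training pairs
#' `(t_train, y_train)` (which may be empty, yielding the prior) and returns
#' an evaluator object; call [predict_gp()] (or `predict()`) with query
#' times for the posterior mean and pointwise variance. Predictive variance
#' is for the latent function (noise-free); add `noise_variance` for the
#' predictive distribution of a new observation.
#'
#' @param t_train,y_train Numeric vectors of training times and scores
#'   (equal length; possibly length 0).
#' @param h A [gp_hyperparams()] object.
#' @param kernel `"se"` (default) or `"linear"`.
#' @return Object of class `gp_posterior`.
#' @export
gp_posterior <- function(t_train, y_train, h, kernel = c("se", "linear")) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(h, "gp_hyperparams"), length(t_train) == length(y_train))
  obj <- list(t = as.numeric(t_train), y = as.numeric(y_train), h = h,
              kernel = kernel)
  if (length(t_train) > 0L) {
    obj$L <- .gp_train_chol(obj$t, h, kernel)
    resid <- obj$y - linear_mean(obj$t, h)
    obj$alpha <- backsolve(obj$L, backsolve(obj$L, resid, transpose = TRUE))
  }
  structure(obj, class = "gp_posterior")
}

#' Evaluate a GP posterior at query times
#'
#' @param object A [gp_posterior()] object.
#' @param t_query Numeric vector of query times (years).
#' @param full_cov Return the full posterior covariance matrix as well.
#' @param ... Unused.
#' @return List with `mean`, `var` (pointwise, clipped at 0) and, if
#'   requested, `cov`.
#' @export
predict_gp <- function(object, t_query, full_cov = FALSE, ...) {
  stopifnot(inherits(object, "gp_posterior"))
  h <- object$h
  t_query <- as.numeric(t_query)
  m_q <- linear_mean(t_query, h)
  Kqq <- kernel_matrix(t_query, t_query, h, object$kernel)
  if (length(object$t) == 0L) {
    out <- list(mean = m_q, var = pmax(diag(Kqq), 0))
    if (full_cov) out$cov <- Kqq
    return(out)
  }
  Kqt <- kernel_matrix(t_query, object$t, h, object$kernel)
  mean_q <- m_q + as.numeric(Kqt %*% object$alpha)
  V <- backsolve(object$L, t(Kqt), transpose = TRUE)
  cov_q <- Kqq - crossprod(V)
  out <- list(mean = mean_q, var = pmax(diag(cov_q), 0))
  if (full_cov) out$cov <- cov_q
  out
}

#' @export
predict.gp_posterior <- function(object, t_query, full_cov = FALSE, ...) {
  predict_gp(object, t_query, full_cov = full_cov, ...)
}

#' Log marginal likelihood of a GP
#'
#' `log N(y | m(T), K(T,T) + noise_variance * I)` (jitter included on the
#' diagonal, as in [gp_posterior()]).
#'
#' @inheritParams gp_posterior
#' @return Scalar log density.
#' @export
log_marginal_likelihood <- function(t_train, y_train, h,
                                    kernel = c("se", "linear")) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(h, "gp_hyperparams"), length(t_train) == length(y_train))
  n <- length(t_train)
  if (n == 0L) return(0)
  L <- .gp_train_chol(as.numeric(t_train), h, kernel)
  resid <- as.numeric(y_train) - linear_mean(as.numeric(t_train), h)
  v <- backsolve(L, resid, transpose = TRUE)
  -0.5 * sum(v * v) - sum(log(diag(L))) - 0.5 * n * log(2 * pi)
}

# Predictive log density of new observations (t_new, y_new) given training
# data under hyperparameters h: the GP posterior at t_new plus observation
# noise. Equals the difference of joint and training log marginals.
gp_predictive_loglik <- function(t_train, y_train, t_new, y_new, h,
                                 kernel = "se", post = NULL) {
  if (is.null(post)) post <- gp_posterior(t_train, y_train, h, kernel)
  pr <- predict_gp(post, t_new, full_cov = TRUE)
  S <- pr$cov
  diag(S) <- diag(S) + h$noise_variance + .gp_jitter_rel * h$signal_variance
  L <- chol(S)
  resid <- as.numeric(y_new) - pr$mean
  v <- backsolve(L, resid, transpose = TRUE)
  -0.5 * sum(v * v) - sum(log(diag(L))) - 0.5 * length(t_new) * log(2 * pi)
}

#' Log-normal hyperparameter priors
#'
#' Optional weakly informative priors on the length-scale and signal
#' variance, added to the marginal likelihood during hyperparameter
#' optimization. Defaults centre the length-scale on 1 yr and the signal
#' variance on `(y_max / 6)^2` with generous spread; both are implementation
#' choices, documented in the package vignette.
#'
#' @param length_scale_meanlog,length_scale_sdlog Log-normal parameters for
#'   the length-scale prior (years).
#' @param signal_variance_meanlog,signal_variance_sdlog Log-normal
#'   parameters for the signal-variance prior (points^2).
#' @return Object of class `gp_priors`.
#' @export
gp_priors <- function(length_scale_meanlog = log(1), length_scale_sdlog = 1,
                      signal_variance_meanlog = log(64),
                      signal_variance_sdlog = 1.5) {
  structure(list(length_scale_meanlog = length_scale_meanlog,
                 length_scale_sdlog = length_scale_sdlog,
                 signal_variance_meanlog = signal_variance_meanlog,
                 signal_variance_sdlog = signal_variance_sdlog),
            class = "gp_priors")
}

#' Log prior density of hyperparameters
#'
#' @param h A [gp_hyperparams()] object.
#' @param priors A [gp_priors()] object, or `NULL` for a flat prior.
#' @return Scalar log density (0 when `priors` is `NULL`).
#' @export
log_hyperprior <- function(h, priors = NULL) {
  if (is.null(priors)) return(0)
  stopifnot(inherits(priors, "gp_priors"))
  stats::dlnorm(h$length_scale, priors$length_scale_meanlog,
                priors$length_scale_sdlog, log = TRUE) +
    stats::dlnorm(h$signal_variance, priors$signal_variance_meanlog,
                  priors$signal_variance_sdlog, log = TRUE)
}

#' Default box bounds for hyperparameter optimization
#'
#' Length-scale in `[0.05, 20]` yr, variances in `[1e-4, y_max^2]`, mean
#' slope in `[-2 * y_max, 0]` points/yr; chosen to span plausible clinical
#' regimes for bounded functional scores.
#'
#' @param y_max Scale maximum (points).
#' @return Named list of `c(lower, upper)` pairs.
#' @export
default_gp_bounds <- function(y_max = 48) {
  list(signal_variance = c(1e-4, y_max^2),
       length_scale = c(0.05, 20),
       noise_variance = c(1e-4, y_max^2),
       mean_slope = c(-2 * y_max, 0))
}

#' Type-II maximum-likelihood hyperparameter optimization
#'
#' Maximizes the log marginal likelihood (plus optional log prior) over
#' `signal_variance`, `length_scale`, `noise_variance` (on the log scale)
#' and `mean_slope` (linear scale), under box bounds, by L-BFGS-B started at
#' `init`. The mean intercept is held fixed (it is pinned at the scale
#' maximum for anchored cohorts). The returned value is guaranteed to score
#' at least as well as `init`; on optimizer failure `init` is returned with
#' attribute `warning` set.
#'
#' @inheritParams gp_posterior
#' @param init Starting [gp_hyperparams()].
#' @param bounds Named list as from [default_gp_bounds()].
#' @param priors Optional [gp_priors()].
#' @param fix_mean_slope Hold the mean slope at its initial value.
#' @param maxit Maximum L-BFGS-B iterations.
#' @return A `gp_hyperparams` object; attributes `objective` (achieved log
#'   posterior) and possibly `warning`.
#' @export
optimize_hyperparams <- function(t_train, y_train, init,
                                 bounds = default_gp_bounds(),
                                 priors = NULL,
                                 kernel = c("se", "linear"),
                                 fix_mean_slope = FALSE, maxit = 100) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(init, "gp_hyperparams"))
  use_ls <- kernel == "se"

  make_h <- function(par) {
    i <- 0L
    sv <- exp(par[[i <- i + 1L]])
    ls <- if (use_ls) exp(par[[i <- i + 1L]]) else init$length_scale
    nv <- exp(par[[i <- i + 1L]])
    sl <- if (fix_mean_slope) init$mean_slope else par[[i + 1L]]
    gp_hyperparams(sv, ls, nv, mean_slope = sl,
                   mean_intercept = init$mean_intercept,
                   length_scale_floor = 0)
  }
  objective <- function(par) {
    h <- make_h(par)
    ll <- tryCatch(
      log_marginal_likelihood(t_train, y_train, h, kernel) +
        log_hyperprior(h, priors),
      error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  par0 <- c(log(init$signal_variance),
            if (use_ls) log(init$length_scale),
            log(init$noise_variance),
            if (!fix_mean_slope) init$mean_slope)
  lower <- c(log(bounds$signal_variance[1]),
             if (use_ls) log(bounds$length_scale[1]),
             log(bounds$noise_variance[1]),
             if (!fix_mean_slope) bounds$mean_slope[1])
  upper <- c(log(bounds$signal_variance[2]),
             if (use_ls) log(bounds$length_scale[2]),
             log(bounds$noise_variance[2]),
             if (!fix_mean_slope) bounds$mean_slope[2])
  par0 <- pmin(pmax(par0, lower), upper)

  f0 <- -objective(par0)
  fit <- tryCatch(
    stats::optim(par0, objective, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = maxit)),
    error = function(e) NULL)

  if (is.null(fit) || !is.finite(fit$value) || -fit$value < f0) {
    out <- make_h(par0)
    attr(out, "objective") <- f0
    if (is.null(fit)) attr(out, "warning") <- "optimizer failure; init returned"
    return(out)
  }
  out <- make_h(fit$par)
  attr(out, "objective") <- -fit$value
  out
}
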