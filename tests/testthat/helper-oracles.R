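# Independent oracles used across the suite. These deliberately avoid the
# package's linear-algebra paths: kernels are evaluated by explicit loops
# and Gaussian densities/conditionals use solve() on dense matrices.

oracle_se_kernel <- function(t1, t2, sv, ls) {
  K <- matrix(0, length(t1), length(t2))
  for (i in seq_along(t1)) {
    for (j in seq_along(t2)) {
      K[i, j] <- sv * exp(-(t1[i] - t2[j])^2 / (2 * ls^2))
    }
  }
  K
}

oracle_lin_kernel <- function(t1, t2, sv) {
  K <- matrix(0, length(t1), length(t2))
  for (i in seq_along(t1)) {
    for (j in seq_along(t2)) K[i, j] <- sv * t1[i] * t2[j]
  }
  K
}

oracle_kernel <- function(t1, t2, h, kernel = "se") {
  if (kernel == "se") {
    oracle_se_kernel(t1, t2, h$signal_variance, h$length_scale)
  } else {
    oracle_lin_kernel(t1, t2, h$signal_variance)
  }
}

# Jitter convention shared with the package: the training-block diagonal
# carries noise + 1e-6 * signal variance.
oracle_train_cov <- function(t_train, h, kernel = "se") {
  K <- oracle_kernel(t_train, t_train, h, kernel)
  diag(K) <- diag(K) + h$noise_variance + 1e-6 * h$signal_variance
  K
}

# Dense multivariate-normal log density via solve(), no Cholesky.
oracle_dmvnorm_log <- function(y, mu, S) {
  r <- y - mu
  as.numeric(-0.5 * (t(r) %*% solve(S, r)) -
               0.5 * determinant(S, logarithm = TRUE)$modulus -
               0.5 * length(y) * log(2 * pi))
}

# Brute-force GP conditional: build the full joint covariance over
# (train, query) and condition the multivariate normal directly.
oracle_gp_conditional <- function(t_train, y_train, t_query, h,
                                  kernel = "se") {
  m_t <- h$mean_intercept + h$mean_slope * t_train
  m_q <- h$mean_intercept + h$mean_slope * t_query
  S_tt <- oracle_train_cov(t_train, h, kernel)
  S_qt <- oracle_kernel(t_query, t_train, h, kernel)
  S_qq <- oracle_kernel(t_query, t_query, h, kernel)
  A <- S_qt %*% solve(S_tt)
  list(mean = as.numeric(m_q + A %*% (y_train - m_t)),
       cov = S_qq - A %*% t(S_qt))
}

oracle_gp_lml <- function(t_train, y_train, h, kernel = "se") {
  m_t <- h$mean_intercept + h$mean_slope * t_train
  oracle_dmvnorm_log(y_train, m_t, oracle_train_cov(t_train, h, kernel))
}

# Predictive density of new points given cluster data, as a ratio of joint
# to marginal dense Gaussian densities (collapsed-conditional oracle).
oracle_predictive_loglik <- function(t_c, y_c, t_new, y_new, h,
                                     kernel = "se") {
  if (length(t_c) == 0L) {
    return(oracle_gp_lml(t_new, y_new, h, kernel))
  }
  oracle_gp_lml(c(t_c, t_new), c(y_c, y_new), h, kernel) -
    oracle_gp_lml(t_c, y_c, h, kernel)
}

# Product-limit estimator computed as an explicit product over event times.
oracle_km <- function(time, event, at) {
  ev_times <- sort(unique(time[event == 1]))
  vapply(at, function(tt) {
    s <- 1
    for (u in ev_times[ev_times <= tt]) {
      d <- sum(time == u & event == 1)
      n <- sum(time >= u)
      s <- s * (1 - d / n)
    }
    s
  }, numeric(1))
}

# Exact null distribution of the one-sided Wilcoxon signed-rank statistic
# by enumerating all sign patterns (small n only).
oracle_signed_rank_p <- function(d) {
  stopifnot(all(d != 0), length(d) <= 12)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  mean(v_all <= v_obs)  # one-sided: improvement means small positive-rank sum
}

make_traj <- function(id, t, y, scale = score_scale("alsfrsr"), ...) {
  patient_trajectory(id, t, y, scale, ...)
}

# Small well-separated two-group cohort used by several mixture tests.
two_group_cohort <- function(seed = 3, n_per = 25, noise_sd = 1) {
  generate_cohort(cohort_spec(clusters = list(
    list(shape = "linear", params = list(slope = -12), size = n_per),
    list(shape = "linear", params = list(slope = -2), size = n_per)),
    noise_sd = noise_sd), seed = seed)
}
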