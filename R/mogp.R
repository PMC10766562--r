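#' Fit configuration for mixture-of-GP models
#'
#' Collects the tunable settings of [fit_mogp()] and [fit_lkm()].
#'
#' @param alpha Dirichlet-process concentration (> 0). Larger values favour
#'   more clusters; default 1.
#' @param margin Monotonic-admissibility margin in points: a subject can
#'   only join a cluster whose mean function at the subject's first measured
#'   visit is no more than `margin` points below the observed score.
#'   `NULL` (default) scales 5 ALSFRS-R points proportionally to the scale
#'   maximum (`5 * y_max / 48`). `Inf` disables the constraint.
#' @param n_sweeps Maximum number of Gibbs sweeps (default 50).
#' @param early_stop Stop after this many consecutive sweeps with unchanged
#'   assignments (default 5).
#' @param kernel `"se"` for the squared-exponential mixture, `"linear"` for
#'   the linear-kernel benchmark. Kernel choice is the only difference
#'   between the two models.
#' @param init_hyper Optional [gp_hyperparams()] used for new clusters and
#'   as the optimizer start; `NULL` derives scale-aware defaults.
#' @param bounds Optional box bounds as from [default_gp_bounds()].
#' @param priors Optional [gp_priors()] added to the optimization objective.
#' @param alpha_prior Optional `c(shape, rate)` of a Gamma hyperprior on
#'   `alpha`, resampled each sweep by the standard auxiliary-variable
#'   scheme; `NULL` keeps `alpha` fixed.
#' @param optimize_maxit L-BFGS-B iterations per cluster per
#'   hyperparameter-update phase (default 25; updates are warm-started).
#' @param optimize_every Run the hyperparameter phase every this many
#'   sweeps (default 1).
#' @return Object of class `mogp_config`.
#' @export
mogp_config <- function(alpha = 1.0, margin = NULL, n_sweeps = 50,
                        early_stop = 5, kernel = c("se", "linear"),
                        init_hyper = NULL, bounds = NULL, priors = NULL,
                        alpha_prior = NULL, optimize_maxit = 25,
                        optimize_every = 1) {
  kernel <- match.arg(kernel)
  stopifnot(alpha > 0, n_sweeps >= 1, early_stop >= 1,
            optimize_maxit >= 1, optimize_every >= 1)
  if (!is.null(alpha_prior)) {
    stopifnot(length(alpha_prior) == 2L, all(alpha_prior > 0))
  }
  structure(list(alpha = alpha, margin = margin, n_sweeps = n_sweeps,
                 early_stop = early_stop, kernel = kernel,
                 init_hyper = init_hyper, bounds = bounds, priors = priors,
                 alpha_prior = alpha_prior, optimize_maxit = optimize_maxit,
                 optimize_every = optimize_every),
            class = "mogp_config")
}

.default_margin <- function(y_max) 5 * y_max / 48

.default_init_hyper <- function(y_max) {
  gp_hyperparams(signal_variance = (y_max / 6)^2, length_scale = 1,
                 noise_variance = (y_max / 24)^2,
                 mean_slope = -0.15 * y_max, mean_intercept = y_max)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# --- internal fitting state helpers -------------------------------------

.cl_rebuild <- function(members, ts, ys, h, kernel) {
  t <- unlist(ts[members], use.names = FALSE)
  y <- unlist(ys[members], use.names = FALSE)
  list(members = members, t = t, y = y, h = h,
       post = gp_posterior(t, y, h, kernel))
}

.cl_admissible <- function(cl, t1, y1, margin) {
  if (!is.finite(margin)) return(TRUE)
  m <- predict_gp(cl$post, t1)$mean
  y1 <= m + margin
}

# Log CRP + predictive weights for one subject over existing clusters and a
# new cluster; inadmissible clusters get -Inf.
.assignment_logweights <- function(t_i, y_i, t1, y1, clusters, alpha,
                                   margin, prior_post, prior_h, kernel) {
  K <- length(clusters)
  lw <- numeric(K + 1L)
  for (k in seq_len(K)) {
    cl <- clusters[[k]]
    if (!.cl_admissible(cl, t1, y1, margin)) {
      lw[k] <- -Inf
    } else {
      lw[k] <- log(length(cl$members)) +
        gp_predictive_loglik(t_new = t_i, y_new = y_i, h = cl$h,
                             kernel = kernel, post = cl$post)
    }
  }
  lw[K + 1L] <- log(alpha) +
    gp_predictive_loglik(t_new = t_i, y_new = y_i, h = prior_h,
                         kernel = kernel, post = prior_post)
  lw
}

.crp_log_prior <- function(sizes, alpha, n) {
  length(sizes) * log(alpha) + sum(lgamma(sizes)) +
    lgamma(alpha) - lgamma(alpha + n)
}

.state_log_joint <- function(clusters, alpha, n, priors, kernel) {
  lml <- sum(vapply(clusters, function(cl) {
    log_marginal_likelihood(cl$t, cl$y, cl$h, kernel) +
      log_hyperprior(cl$h, priors)
  }, numeric(1)))
  sizes <- vapply(clusters, function(cl) length(cl$members), numeric(1))
  lml + .crp_log_prior(sizes, alpha, n)
}

# Escobar-West auxiliary-variable update of the DP concentration.
.resample_alpha <- function(alpha, K, n, prior) {
  eta <- stats::rbeta(1, alpha + 1, n)
  a <- prior[1]; b <- prior[2]
  odds <- (a + K - 1) / (n * (b - log(eta)))
  shape <- if (stats::runif(1) < odds / (1 + odds)) a + K else a + K - 1
  stats::rgamma(1, shape, rate = b - log(eta))
}

# --- public operations ---------------------------------------------------

#' Monotonic admissibility of a trajectory for a cluster
#'
#' A subject can only be placed in a cluster if their score at their first
#' measured visit is not substantially higher than the cluster's mean
#' function at that time: `y_first <= mean(t_first) + margin`. This is the
#' inductive bias that discourages clusters from absorbing subjects whose
#' observed function exceeds what the cluster's decline pattern allows.
#'
#' @param traj An anchored [patient_trajectory()].
#' @param cluster A fitted `mogp_cluster` (element of `model$clusters`).
#' @param margin Admissibility margin in points; `Inf` disables the check.
#' @return `TRUE` or `FALSE`.
#' @export
monotonic_admissibility <- function(traj, cluster, margin) {
  stopifnot(inherits(traj, "patient_trajectory"),
            inherits(cluster, "mogp_cluster"))
  v <- measured_visits(traj)
  if (nrow(v) == 0L) return(TRUE)
  if (!is.finite(margin)) return(TRUE)
  m <- cluster_mean_function(cluster, v$t[1L])$mean
  v$y[1L] <= m + margin
}

#' Assignment distribution of a held-out trajectory
#'
#' The collapsed Dirichlet-process conditional: the unnormalized weight of
#' an existing cluster is its size times the predictive likelihood of the
#' trajectory under the cluster's posterior; the weight of opening a new
#' cluster is `alpha` times the prior predictive likelihood. Clusters that
#' fail the monotonic admissibility check get weight zero; the new-cluster
#' option is always admissible.
#'
#' @param traj An anchored [patient_trajectory()] not in the model.
#' @param model A fitted [fit_mogp()] model.
#' @param margin Admissibility margin; defaults to the model's.
#' @return Data frame with columns `option` (cluster id or `"new"`),
#'   `n_members`, `log_weight`, `probability` (summing to 1).
#' @export
assignment_distribution <- function(traj, model, margin = NULL) {
  stopifnot(inherits(model, "mogp_model"),
            inherits(traj, "patient_trajectory"), traj$anchored)
  if (is.null(margin)) margin <- model$margin
  kernel <- model$config$kernel
  prior_h <- model$prior_hyper
  prior_post <- gp_posterior(numeric(0), numeric(0), prior_h, kernel)
  t_i <- traj$visits$t; y_i <- traj$visits$y
  v <- measured_visits(traj)
  t1 <- v$t[1L]; y1 <- v$y[1L]
  clusters <- lapply(model$clusters, function(cl) {
    list(members = cl$member_ids, t = cl$t, y = cl$y, h = cl$hyper,
         post = cluster_posterior(cl))
  })
  lw <- .assignment_logweights(t_i, y_i, t1, y1, clusters, model$alpha,
                               margin, prior_post, prior_h, kernel)
  lz <- .logsumexp(lw)
  data.frame(option = c(names(model$clusters), "new"),
             n_members = c(vapply(model$clusters, function(cl)
               length(cl$member_ids), numeric(1)), NA_real_),
             log_weight = lw,
             probability = exp(lw - lz),
             stringsAsFactors = FALSE)
}

#' Fit a mixture of Gaussian processes by Dirichlet-process clustering
#'
#' Clusters anchored trajectories by collapsed Gibbs sampling over cluster
#' assignments (Chinese-restaurant-process conditional with the monotonic
#' admissibility constraint) interleaved with per-cluster type-II
#' maximum-likelihood hyperparameter updates. Empty clusters are removed
#' immediately. The returned model is the maximum-log-joint state visited,
#' followed by a deterministic admissibility-repair pass so that every
#' member satisfies the monotonic constraint against its final cluster.
#'
#' @param trajs Non-empty list of anchored [patient_trajectory()] objects
#'   sharing one scale, with unique subject ids.
#' @param config A [mogp_config()].
#' @param seed Integer seed; fits are deterministic given `(config, seed)`.
#' @return Object of class `mogp_model` with elements `clusters` (named
#'   list of `mogp_cluster`, ordered by size, largest first), `assignments`
#'   (named character vector, subject id to cluster id), `alpha`, `margin`,
#'   `trace` (data frame: sweep, phase, n_clusters, log_joint), `log_joint`,
#'   `seed`, `config`, `scale`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(
#'   clusters = list(
#'     list(shape = "linear", params = list(slope = -12), size = 10),
#'     list(shape = "linear", params = list(slope = -2), size = 10)),
#'   noise_sd = 1), seed = 1)
#' fit <- fit_mogp(anchor_cohort(cohort$trajectories),
#'                 mogp_config(n_sweeps = 15), seed = 1)
#' fit
#' }
#' @export
fit_mogp <- function(trajs, config = mogp_config(), seed = 1L) {
  stopifnot(inherits(config, "mogp_config"))
  if (!is.list(trajs) || length(trajs) == 0L) {
    stop("cohort must be a non-empty list of trajectories")
  }
  if (!all(vapply(trajs, inherits, logical(1), "patient_trajectory"))) {
    stop("all elements must be patient_trajectory objects")
  }
  if (!all(vapply(trajs, function(x) x$anchored, logical(1)))) {
    stop("all trajectories must be anchored (see add_onset_anchor)")
  }
  ymaxes <- vapply(trajs, function(x) x$scale$y_max, numeric(1))
  if (length(unique(ymaxes)) != 1L) stop("all trajectories must share one scale")
  ids <- vapply(trajs, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) stop("subject ids must be unique")

  n <- length(trajs)
  scale <- trajs[[1L]]$scale
  y_max <- scale$y_max
  kernel <- config$kernel
  margin <- if (is.null(config$margin)) .default_margin(y_max) else config$margin
  prior_h <- if (is.null(config$init_hyper)) .default_init_hyper(y_max) else
    config$init_hyper
  bounds <- if (is.null(config$bounds)) default_gp_bounds(y_max) else
    config$bounds
  priors <- config$priors
  alpha <- config$alpha

  if (!is.null(seed)) set.seed(seed)

  ts <- lapply(trajs, function(x) x$visits$t)
  ys <- lapply(trajs, function(x) x$visits$y)
  t1s <- vapply(trajs, function(x) measured_visits(x)$t[1L], numeric(1))
  y1s <- vapply(trajs, function(x) measured_visits(x)$y[1L], numeric(1))
  prior_post <- gp_posterior(numeric(0), numeric(0), prior_h, kernel)

  clusters <- list()
  z <- integer(n)

  draw_assignment <- function(i) {
    lw <- .assignment_logweights(ts[[i]], ys[[i]], t1s[[i]], y1s[[i]],
                                 clusters, alpha, margin, prior_post,
                                 prior_h, kernel)
    p <- exp(lw - .logsumexp(lw))
    sample.int(length(lw), 1L, prob = p)
  }
  place <- function(i, k) {
    if (k > length(clusters)) {
      clusters[[k]] <<- .cl_rebuild(i, ts, ys, prior_h, kernel)
    } else {
      cl <- clusters[[k]]
      clusters[[k]] <<- .cl_rebuild(c(cl$members, i), ts, ys, cl$h, kernel)
    }
    z[i] <<- k
  }
  displace <- function(i) {
    k <- z[i]
    cl <- clusters[[k]]
    mem <- setdiff(cl$members, i)
    if (length(mem) == 0L) {
      clusters[[k]] <<- NULL
      z[z > k] <<- z[z > k] - 1L
    } else {
      clusters[[k]] <<- .cl_rebuild(mem, ts, ys, cl$h, kernel)
    }
    z[i] <<- 0L
  }

  # sequential CRP initialization
  for (i in seq_len(n)) place(i, draw_assignment(i))

  trace <- vector("list", 2L * config$n_sweeps)
  trace_n <- 0L
  push_trace <- function(sweep, phase, lj) {
    trace_n <<- trace_n + 1L
    trace[[trace_n]] <<- data.frame(sweep = sweep, phase = phase,
                                    n_clusters = length(clusters),
                                    log_joint = lj)
  }
  best <- list(lj = -Inf)
  note_best <- function(lj) {
    if (lj > best$lj) {
      best <<- list(lj = lj, z = z,
                    hypers = lapply(clusters, `[[`, "h"), alpha = alpha)
    }
  }

  lj <- .state_log_joint(clusters, alpha, n, priors, kernel)
  note_best(lj)
  stable <- 0L
  for (sweep in seq_len(config$n_sweeps)) {
    if ((sweep - 1L) %% config$optimize_every == 0L) {
      for (k in seq_along(clusters)) {
        cl <- clusters[[k]]
        h_new <- optimize_hyperparams(cl$t, cl$y, init = cl$h,
                                      bounds = bounds, priors = priors,
                                      kernel = kernel,
                                      maxit = config$optimize_maxit)
        attributes(h_new)[c("objective", "warning")] <- NULL
        clusters[[k]] <- .cl_rebuild(cl$members, ts, ys, h_new, kernel)
      }
      lj <- .state_log_joint(clusters, alpha, n, priors, kernel)
      push_trace(sweep, "hyper", lj)
      note_best(lj)
    }

    z_before <- z
    for (i in seq_len(n)) {
      displace(i)
      place(i, draw_assignment(i))
    }
    if (!is.null(config$alpha_prior)) {
      alpha <- .resample_alpha(alpha, length(clusters), n, config$alpha_prior)
    }
    lj <- .state_log_joint(clusters, alpha, n, priors, kernel)
    push_trace(sweep, "assign", lj)
    note_best(lj)

    if (identical(z, z_before)) stable <- stable + 1L else stable <- 0L
    if (stable >= config$early_stop) break
  }

  # restore maximum-log-joint state
  z <- best$z
  alpha <- best$alpha
  clusters <- lapply(seq_along(best$hypers), function(k) {
    .cl_rebuild(which(z == k), ts, ys, best$hypers[[k]], kernel)
  })

  # admissibility-repair pass: deterministically reassign any member that
  # violates the monotonic constraint against its final cluster. First
  # repairs go to the admissible cluster that best explains the subject;
  # a subject that violates again (cluster means move as members move) is
  # parked in the cluster with the largest margin slack at its first
  # visit, which is stable because one member barely shifts a large
  # cluster's mean. With no admissible cluster at all, a fresh singleton
  # is opened (its posterior tracks the subject's own data).
  n_repair <- 0L
  repaired_once <- rep(FALSE, n)
  for (rep_i in 1:20) {
    viol <- which(vapply(seq_len(n), function(i) {
      !.cl_admissible(clusters[[z[i]]], t1s[[i]], y1s[[i]], margin)
    }, logical(1)))
    if (length(viol) == 0L) break
    for (i in viol) {
      displace(i)
      slack <- vapply(clusters, function(cl) {
        predict_gp(cl$post, t1s[[i]])$mean + margin - y1s[[i]]
      }, numeric(1))
      k <- if (!length(slack) || max(slack) < 0) {
        length(clusters) + 1L
      } else if (repaired_once[i]) {
        which.max(slack)
      } else {
        lw <- .assignment_logweights(ts[[i]], ys[[i]], t1s[[i]], y1s[[i]],
                                     clusters, alpha, margin, prior_post,
                                     prior_h, kernel)
        lw_exist <- lw[seq_along(clusters)]
        if (any(is.finite(lw_exist))) which.max(lw_exist) else
          length(clusters) + 1L
      }
      place(i, k)
      repaired_once[i] <- TRUE
      n_repair <- n_repair + 1L
    }
  }
  lj <- .state_log_joint(clusters, alpha, n, priors, kernel)

  # assemble public model: clusters ordered by size (largest first)
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  ord <- order(sizes, decreasing = TRUE)
  cluster_ids <- sprintf("C%d", seq_along(ord))
  pub <- vector("list", length(ord))
  assignments <- character(n)
  for (j in seq_along(ord)) {
    cl <- clusters[[ord[j]]]
    pub[[j]] <- structure(
      list(cluster_id = cluster_ids[j], member_ids = ids[cl$members],
           hyper = cl$h, kernel = kernel, t = cl$t, y = cl$y, scale = scale),
      class = "mogp_cluster")
    assignments[cl$members] <- cluster_ids[j]
  }
  names(pub) <- cluster_ids
  names(assignments) <- ids

  structure(list(clusters = pub, assignments = assignments, alpha = alpha,
                 margin = margin, prior_hyper = prior_h,
                 trace = do.call(rbind, trace[seq_len(trace_n)]),
                 log_joint = lj, n_repair_moves = n_repair, seed = seed,
                 config = config, scale = scale, shuffled = FALSE),
            class = "mogp_model")
}

#' @export
print.mogp_model <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$member_ids), integer(1))
  cat(sprintf(paste0("<mogp_model> %d subject(s) in %d cluster(s) ",
                     "(%s kernel, alpha = %.3g, margin = %.3g)\n"),
              length(x$assignments), length(x$clusters),
              x$config$kernel, x$alpha, x$margin))
  cat("cluster sizes:", paste(sizes, collapse = ", "), "\n")
  cat(sprintf("log joint: %.3f\n", x$log_joint))
  invisible(x)
}

#' @export
print.mogp_cluster <- function(x, ...) {
  cat(sprintf("<mogp_cluster> %s: %d member(s), length_scale %.3g yr, mean slope %.3g pts/yr\n",
              x$cluster_id, length(x$member_ids), x$hyper$length_scale,
              x$hyper$mean_slope))
  invisible(x)
}

#' Posterior predictive process of a cluster
#'
#' @param cluster A `mogp_cluster`.
#' @return A [gp_posterior()] conditioned on the cluster's pooled member
#'   visits.
#' @export
cluster_posterior <- function(cluster) {
  stopifnot(inherits(cluster, "mogp_cluster"))
  gp_posterior(cluster$t, cluster$y, cluster$hyper, cluster$kernel)
}

#' Cluster mean function with pointwise uncertainty
#'
#' @param cluster A `mogp_cluster`.
#' @param times Numeric vector of query times (years from onset).
#' @return Data frame with `t`, `mean`, `var`, and the 0.95 interval
#'   (`lower`, `upper` = mean -/+ 1.96 sd).
#' @export
cluster_mean_function <- function(cluster, times) {
  pr <- predict_gp(cluster_posterior(cluster), times)
  s <- sqrt(pr$var)
  data.frame(t = times, mean = pr$mean, var = pr$var,
             lower = pr$mean - 1.96 * s, upper = pr$mean + 1.96 * s)
}

#' Predict cluster membership of an unseen participant
#'
#' Scores every existing admissible cluster by the predictive
#' log-likelihood of the trajectory under the cluster posterior and returns
#' the argmax with a normalized confidence. No new cluster is ever created
#' at prediction time. If no cluster is admissible, the subject is assigned
#' to the cluster whose mean at the first measured visit is closest to the
#' observed score, flagged low-confidence.
#'
#' @param model A fitted [fit_mogp()] model.
#' @param traj An anchored [patient_trajectory()] on the model's scale.
#' @param margin Admissibility margin; defaults to the model's.
#' @return Object of class `membership_prediction`: `subject_id`,
#'   `cluster_id`, `log_scores` (named, `-Inf` for inadmissible clusters),
#'   `confidence` (posterior probability of the chosen cluster among
#'   admissible ones), `low_confidence` flag.
#' @export
predict_membership <- function(model, traj, margin = NULL) {
  stopifnot(inherits(model, "mogp_model"),
            inherits(traj, "patient_trajectory"), traj$anchored)
  if (abs(traj$scale$y_max - model$scale$y_max) > 1e-9) {
    stop("trajectory scale does not match the model scale")
  }
  if (is.null(margin)) margin <- model$margin
  kernel <- model$config$kernel
  v <- measured_visits(traj)
  t1 <- v$t[1L]; y1 <- v$y[1L]
  ids <- names(model$clusters)
  scores <- numeric(length(ids))
  mean_at_first <- numeric(length(ids))
  admissible <- logical(length(ids))
  for (j in seq_along(ids)) {
    cl <- model$clusters[[j]]
    post <- cluster_posterior(cl)
    mean_at_first[j] <- predict_gp(post, t1)$mean
    admissible[j] <- !is.finite(margin) || y1 <= mean_at_first[j] + margin
    scores[j] <- gp_predictive_loglik(t_new = traj$visits$t,
                                      y_new = traj$visits$y,
                                      h = cl$hyper, kernel = kernel,
                                      post = post)
  }
  log_scores <- ifelse(admissible, scores, -Inf)
  names(log_scores) <- ids
  if (any(admissible)) {
    lz <- .logsumexp(log_scores)
    probs <- exp(log_scores - lz)
    pick <- which.max(log_scores)
    out <- list(subject_id = traj$subject_id, cluster_id = ids[pick],
                log_scores = log_scores, confidence = probs[[pick]],
                low_confidence = FALSE)
  } else {
    pick <- which.min(abs(mean_at_first - y1))
    out <- list(subject_id = traj$subject_id, cluster_id = ids[pick],
                log_scores = log_scores, confidence = NA_real_,
                low_confidence = TRUE)
  }
  structure(out, class = "membership_prediction")
}

#' @export
print.membership_prediction <- function(x, ...) {
  cat(sprintf("<membership_prediction> %s -> %s (confidence %s%s)\n",
              x$subject_id, x$cluster_id,
              ifelse(is.na(x$confidence), "NA",
                     sprintf("%.3f", x$confidence)),
              if (x$low_confidence) ", low-confidence fallback" else ""))
  invisible(x)
}

#' Randomly shuffle cluster labels (negative control)
#'
#' Permutes the subject-to-cluster assignment map uniformly at random while
#' leaving every cluster's posterior (pooled data and hyperparameters)
#' fixed. Used as the "random cluster assignment" control when benchmarking
#' reconstruction error.
#'
#' @param model A fitted [fit_mogp()] model.
#' @param seed Integer seed.
#' @return A `mogp_model` with permuted assignments and `shuffled = TRUE`.
#' @export
shuffle_cluster_labels <- function(model, seed = 1L) {
  stopifnot(inherits(model, "mogp_model"))
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(length(model$assignments))
  new_assign <- unname(model$assignments)[perm]
  names(new_assign) <- names(model$assignments)
  model$assignments <- new_assign
  for (id in names(model$clusters)) {
    model$clusters[[id]]$member_ids <-
      names(new_assign)[new_assign == id]
  }
  model$shuffled <- TRUE
  model
}

#' Audit the monotonic constraint of a fitted model
#'
#' Re-runs the admissibility check for every (member, cluster) pair of the
#' final model. A correctly fitted model has zero violations.
#'
#' @param model A fitted [fit_mogp()] model.
#' @param trajs The cohort the model was fitted on (anchored trajectories).
#' @param margin Margin to audit at; defaults to the model's.
#' @return Data frame of violations (`subject_id`, `cluster_id`, `y_first`,
#'   `cluster_mean`, `margin`); zero rows when the constraint holds.
#' @export
audit_admissibility <- function(model, trajs, margin = NULL) {
  stopifnot(inherits(model, "mogp_model"))
  if (is.null(margin)) margin <- model$margin
  ids <- vapply(trajs, `[[`, character(1), "subject_id")
  rows <- list()
  for (tr in trajs) {
    cid <- model$assignments[[tr$subject_id]]
    cl <- model$clusters[[cid]]
    v <- measured_visits(tr)
    m <- cluster_mean_function(cl, v$t[1L])$mean
    if (is.finite(margin) && v$y[1L] > m + margin) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = tr$subject_id, cluster_id = cid,
        y_first = v$y[1L], cluster_mean = m, margin = margin)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), cluster_id = character(0),
               y_first = numeric(0), cluster_mean = numeric(0),
               margin = numeric(0))
}
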