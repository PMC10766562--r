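# A cluster whose posterior equals its prior mean function: empty pooled
# data, tiny signal variance, mean 48 - 36 t (mean 30 at t = 0.5).
flat_cluster <- function(slope = -36, icpt = 48, id = "C1",
                         members = "m1") {
  structure(list(cluster_id = id, member_ids = members,
                 hyper = gp_hyperparams(1e-3, 1, 1e-3, mean_slope = slope,
                                        mean_intercept = icpt),
                 kernel = "se", t = numeric(0), y = numeric(0),
                 scale = score_scale("alsfrsr")),
            class = "mogp_cluster")
}

test_that("monotonic admissibility compares first visit to cluster mean", {
  cl <- flat_cluster()  # mean at 0.5 is 30
  t47 <- add_onset_anchor(make_traj("a", 0.5, 47))
  t30 <- add_onset_anchor(make_traj("b", 0.5, 30))
  expect_false(monotonic_admissibility(t47, cl, margin = 5))  # 47 > 35
  expect_true(monotonic_admissibility(t30, cl, margin = 5))   # equality passes
  expect_true(monotonic_admissibility(t47, cl, margin = Inf))
})

test_that("assignment distribution follows the CRP size weighting", {
  # two clusters with identical pooled data and hyperparameters: their
  # predictive likelihoods cancel, so the probability ratio is the size ratio
  h <- gp_hyperparams(4, 1, 1, mean_slope = -6, mean_intercept = 48)
  mk <- function(id, members) {
    structure(list(cluster_id = id, member_ids = members, hyper = h,
                   kernel = "se", t = c(0, 1), y = c(48, 42),
                   scale = score_scale("alsfrsr")),
              class = "mogp_cluster")
  }
  model <- structure(list(
    clusters = list(C1 = mk("C1", c("a", "b")), C2 = mk("C2", "c")),
    assignments = c(a = "C1", b = "C1", c = "C2"), alpha = 1, margin = Inf,
    prior_hyper = h, config = mogp_config(), scale = score_scale("alsfrsr"),
    shuffled = FALSE), class = "mogp_model")
  tr <- add_onset_anchor(make_traj("z", c(0.8, 1.6), c(43, 38)))
  d <- assignment_distribution(tr, model)
  expect_equal(sum(d$probability), 1, tolerance = 1e-12)
  expect_equal(d$probability[d$option == "C1"] /
                 d$probability[d$option == "C2"], 2, tolerance = 1e-12)
  # an inadmissible cluster gets probability exactly zero, rest renormalize
  lowcl <- flat_cluster(slope = -40, icpt = 48, id = "C3", members = "d")
  model$clusters$C3 <- lowcl
  model$assignments <- c(model$assignments, d = "C3")
  hi <- add_onset_anchor(make_traj("y", c(1, 2), c(47, 46)))
  d2 <- assignment_distribution(hi, model, margin = 5)
  expect_identical(d2$probability[d2$option == "C3"], 0)
  expect_equal(sum(d2$probability), 1, tolerance = 1e-12)
})

test_that("assignment distribution matches the collapsed-conditional
           enumeration oracle", {
  co <- two_group_cohort(seed = 13, n_per = 6)
  model <- fit_mogp(anchor_cohort(co$trajectories),
                    mogp_config(n_sweeps = 8), seed = 2)
  set.seed(99)
  for (rep in 1:3) {
    tt <- sort(runif(3, 0.3, 2.5))
    tr <- add_onset_anchor(make_traj(
      paste0("new", rep), tt,
      pmin(pmax(48 - 8 * tt + rnorm(3, 0, 2), 0), 48)))
    d <- assignment_distribution(tr, model, margin = Inf)
    lw <- vapply(names(model$clusters), function(cid) {
      cl <- model$clusters[[cid]]
      log(length(cl$member_ids)) +
        oracle_predictive_loglik(cl$t, cl$y, tr$visits$t, tr$visits$y,
                                 cl$hyper)
    }, numeric(1))
    lw <- c(lw, log(model$alpha) +
              oracle_predictive_loglik(numeric(0), numeric(0),
                                       tr$visits$t, tr$visits$y,
                                       model$prior_hyper))
    p_or <- exp(lw - max(lw)); p_or <- p_or / sum(p_or)
    expect_equal(d$probability, unname(p_or), tolerance = 1e-10)
    expect_equal(sum(d$probability), 1, tolerance = 1e-12)
  }
})

test_that("identical noiseless trajectories collapse to one cluster", {
  sc <- score_scale("alsfrsr")
  trajs <- lapply(1:20, function(i) {
    add_onset_anchor(patient_trajectory(paste0("s", i), c(0.5, 1, 1.5, 2),
                                        48 - 6 * c(0.5, 1, 1.5, 2), sc))
  })
  fit <- fit_mogp(trajs, mogp_config(n_sweeps = 10), seed = 4)
  expect_length(fit$clusters, 1)
  expect_equal(length(fit$clusters[[1]]$member_ids), 20)
})

test_that("well-separated groups are recovered exactly and reproducibly", {
  co <- two_group_cohort(seed = 3)
  anch <- anchor_cohort(co$trajectories)
  fit1 <- fit_mogp(anch, mogp_config(n_sweeps = 20), seed = 1)
  expect_length(fit1$clusters, 2)
  expect_equal(mclust::adjustedRandIndex(
    fit1$assignments[co$truth$subject_id], co$truth$cluster), 1.0)
  fit2 <- fit_mogp(anch, mogp_config(n_sweeps = 20), seed = 1)
  expect_identical(fit1$assignments, fit2$assignments)
  expect_identical(fit1$trace, fit2$trace)
  # partition invariant: clusters tile the cohort exactly
  sizes <- vapply(fit1$clusters, function(cl) length(cl$member_ids),
                  integer(1))
  expect_equal(sum(sizes), length(anch))
  expect_true(all(sizes > 0))
  for (cid in names(fit1$clusters)) {
    expect_setequal(fit1$clusters[[cid]]$member_ids,
                    names(fit1$assignments)[fit1$assignments == cid])
  }
  # monotonic constraint holds for every member/cluster pair post hoc
  expect_equal(nrow(audit_admissibility(fit1, anch)), 0)
  # log joint is non-decreasing across each hyperparameter update
  tr <- fit1$trace
  for (s in unique(tr$sweep)[-1]) {
    before <- tr$log_joint[tr$sweep == s - 1 & tr$phase == "assign"]
    after <- tr$log_joint[tr$sweep == s & tr$phase == "hyper"]
    if (length(before) && length(after)) {
      expect_gte(after, before - 1e-6)
    }
  }
})

test_that("membership prediction is self-consistent and confident", {
  co <- two_group_cohort(seed = 8, n_per = 12)
  model <- fit_mogp(anchor_cohort(co$trajectories),
                    mogp_config(n_sweeps = 12), seed = 1)
  expect_length(model$clusters, 2)
  # a trajectory equal to a cluster's own mean function picks that cluster
  for (cid in names(model$clusters)) {
    tt <- c(0.5, 1, 1.5, 2)
    mu <- cluster_mean_function(model$clusters[[cid]], tt)$mean
    tr <- add_onset_anchor(make_traj("mean_traj", tt,
                                     pmin(pmax(mu, 0), 48)))
    pred <- predict_membership(model, tr)
    expect_equal(pred$cluster_id, cid)
    expect_gt(pred$confidence, 0.5)
  }
  # held-out subjects simulated from each group recover their cluster
  hold <- two_group_cohort(seed = 21, n_per = 50)
  anch <- anchor_cohort(hold$trajectories)
  truth_cl <- hold$truth$cluster
  pred_cl <- vapply(anch, function(tr) {
    predict_membership(model, tr)$cluster_id
  }, character(1))
  map <- c(K1 = names(which.max(table(pred_cl[truth_cl == "K1"]))),
           K2 = names(which.max(table(pred_cl[truth_cl == "K2"]))))
  expect_gte(mean(pred_cl == map[truth_cl]), 0.95)
  # degenerate single-cluster model: confidence 1
  one <- fit_mogp(anchor_cohort(two_group_cohort(seed = 5,
                                                 n_per = 5)$trajectories[1:5]),
                  mogp_config(n_sweeps = 6), seed = 1)
  if (length(one$clusters) == 1) {
    pred1 <- predict_membership(one, anch[[1]])
    expect_equal(pred1$confidence, 1.0)
  }
})

test_that("cluster mean functions pin the anchor and revert to the prior
           mean far from data", {
  co <- two_group_cohort(seed = 8, n_per = 12)
  model <- fit_mogp(anchor_cohort(co$trajectories),
                    mogp_config(n_sweeps = 12), seed = 1)
  for (cid in names(model$clusters)) {
    cl <- model$clusters[[cid]]
    expect_equal(cluster_mean_function(cl, 0)$mean, 48, tolerance = 0.5)
    far <- cluster_mean_function(cl, 30)$mean
    expect_equal(far, linear_mean(30, cl$hyper), tolerance = 0.1)
    # identity: cluster mean is the GP posterior on the pooled member data
    grid <- seq(0, 3, by = 0.25)
    direct <- predict_gp(gp_posterior(cl$t, cl$y, cl$hyper, cl$kernel), grid)
    viaclu <- cluster_mean_function(cl, grid)
    expect_equal(viaclu$mean, direct$mean, tolerance = 1e-12)
    expect_equal(viaclu$var, direct$var, tolerance = 1e-12)
    expect_equal(viaclu$upper, direct$mean + 1.96 * sqrt(direct$var))
  }
})

test_that("label shuffling preserves sizes, fixes posteriors, and degrades
           reconstruction error", {
  co <- two_group_cohort(seed = 3)
  anch <- anchor_cohort(co$trajectories)
  model <- fit_mogp(anch, mogp_config(n_sweeps = 15), seed = 1)
  shuf <- shuffle_cluster_labels(model, seed = 7)
  expect_setequal(unname(table(shuf$assignments)),
                  unname(table(model$assignments)))
  expect_identical(shuf$clusters[[1]]$t, model$clusters[[1]]$t)
  rmse_of <- function(m) {
    mean(vapply(anch, function(tr) {
      rmse_to_cluster_mean(m, tr)$rmse
    }, numeric(1)))
  }
  expect_gt(rmse_of(shuf), rmse_of(model))
  # a single-cluster model is unchanged by shuffling
  one_trajs <- anch[model$assignments == "C1"]
  one <- fit_mogp(one_trajs, mogp_config(n_sweeps = 6), seed = 1)
  if (length(one$clusters) == 1) {
    expect_identical(shuffle_cluster_labels(one, 3)$assignments,
                     one$assignments)
  }
})

test_that("models serialize and reload with identical predictions", {
  co <- two_group_cohort(seed = 8, n_per = 10)
  model <- fit_mogp(anchor_cohort(co$trajectories),
                    mogp_config(n_sweeps = 10), seed = 1)
  dir <- withr::local_tempdir()
  write_mogp(model, dir)
  back <- read_mogp(dir)
  expect_identical(back$assignments, model$assignments)
  expect_equal(back$alpha, model$alpha)
  grid <- seq(0, 3, by = 0.1)
  for (cid in names(model$clusters)) {
    expect_identical(cluster_mean_function(back$clusters[[cid]], grid),
                     cluster_mean_function(model$clusters[[cid]], grid))
  }
  tr <- add_onset_anchor(make_traj("q", c(0.5, 1.2), c(44, 40)))
  expect_identical(predict_membership(back, tr)$log_scores,
                   predict_membership(model, tr)$log_scores)
})

test_that("concentration hyperprior resampling stays positive and
           deterministic", {
  co <- two_group_cohort(seed = 3, n_per = 8)
  cfg <- mogp_config(n_sweeps = 8, alpha_prior = c(2, 1))
  f1 <- fit_mogp(anchor_cohort(co$trajectories), cfg, seed = 6)
  f2 <- fit_mogp(anchor_cohort(co$trajectories), cfg, seed = 6)
  expect_gt(f1$alpha, 0)
  expect_identical(f1$assignments, f2$assignments)
  expect_equal(f1$alpha, f2$alpha)
})

test_that("fit rejects invalid cohorts", {
  sc <- score_scale("alsfrsr")
  expect_error(fit_mogp(list()), "non-empty")
  un <- patient_trajectory("a", 1, 40, sc)
  expect_error(fit_mogp(list(un)), "anchored")
  a1 <- add_onset_anchor(patient_trajectory("a", 1, 40, sc))
  a2 <- add_onset_anchor(patient_trajectory("a", 1, 38, sc))
  expect_error(fit_mogp(list(a1, a2)), "unique")
  b <- add_onset_anchor(patient_trajectory("b", 1, 9,
                                           score_scale("subscore")))
  expect_error(fit_mogp(list(a1, b)), "one scale")
})
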