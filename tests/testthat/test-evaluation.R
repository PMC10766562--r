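# Cluster whose posterior equals a known linear mean (empty pooled data,
# negligible signal variance): mean(t) = 48 + slope * t.
linear_cluster <- function(slope, id = "L1", ls = 1) {
  structure(list(cluster_id = id, member_ids = "m",
                 hyper = gp_hyperparams(1e-6, ls, 1e-6, mean_slope = slope,
                                        mean_intercept = 48),
                 kernel = "se", t = numeric(0), y = numeric(0),
                 scale = score_scale("alsfrsr")),
            class = "mogp_cluster")
}

test_that("per-patient RMSE matches its closed form", {
  cl <- linear_cluster(-6)
  tr <- add_onset_anchor(make_traj("a", c(1, 2), c(42, 36)))
  expect_equal(rmse_to_cluster_mean(cl, tr)$rmse, 0, tolerance = 1e-6)
  # constant offset c at every point gives rmse |c|
  tr2 <- add_onset_anchor(make_traj("b", c(1, 2), c(42, 36) - 3))
  expect_equal(rmse_to_cluster_mean(cl, tr2)$rmse, 3, tolerance = 1e-6)
  # random instance against the direct formula
  set.seed(2)
  tt <- sort(runif(5, 0.5, 3)); yy <- runif(5, 10, 48)
  tr3 <- add_onset_anchor(make_traj("c", tt, yy))
  direct <- sqrt(mean((yy - (48 - 6 * tt))^2))
  expect_equal(rmse_to_cluster_mean(cl, tr3)$rmse, direct, tolerance = 1e-4)
  expect_error(rmse_to_cluster_mean(cl, tr3,
                                    eval_visits = data.frame(t = numeric(0),
                                                             y = numeric(0))),
               "empty")
})

test_that("first-year slope is the anchored decline diagnostic", {
  expect_equal(first_year_slope(linear_cluster(0)), 0, tolerance = 1e-6)
  expect_equal(first_year_slope(linear_cluster(-12)), 12, tolerance = 1e-6)
  # for an exactly linear cluster the extrapolation at 3 yr is error-free
  cl <- linear_cluster(-5)
  fy <- first_year_slope(cl)
  expect_equal(48 - fy * 3, cluster_mean_function(cl, 3)$mean,
               tolerance = 1e-5)
})

test_that("interpolation experiment reconstructs withheld visits and is
           reproducible", {
  spec <- cohort_spec(clusters = list(
    list(shape = "linear", params = list(slope = -8), size = 6),
    list(shape = "linear", params = list(slope = -2), size = 6)),
    noise_sd = 0, visit_rate = 8, followup = c(2, 2.5))
  co <- generate_cohort(spec, seed = 4)
  cfg <- mogp_config(n_sweeps = 8)
  tab <- interpolation_experiment(co$trajectories, fractions = 0.5,
                                  models = c("MoGP", "SM"), config = cfg,
                                  seed = 9)
  # noiseless linear cohort: the anchored slope reconstructs exactly
  expect_lt(max(tab$rmse[tab$model == "SM"]), 1e-8)
  expect_true(all(tab$condition == 0.5))
  tab2 <- interpolation_experiment(co$trajectories, fractions = 0.5,
                                   models = c("MoGP", "SM"), config = cfg,
                                   seed = 9)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
})

test_that("interpolation on sigmoid cohorts favours the SE mixture over
           the linear-kernel mixture", {
  spec <- cohort_spec(clusters = list(
    list(shape = "sigmoid", params = list(d50 = 1.5, dx = 0.25),
         size = 14)), visit_rate = 8, followup = c(2, 2.8),
    noise_sd = 1.5)
  co <- generate_cohort(spec, seed = 8)
  tab <- interpolation_experiment(co$trajectories, fractions = 0.5,
                                  models = c("MoGP", "LKM"),
                                  config = mogp_config(n_sweeps = 10),
                                  seed = 3)
  med <- tapply(tab$rmse, tab$model, median)
  expect_lt(med[["MoGP"]], med[["LKM"]])
})

test_that("censoring experiment trains within the horizon and skips
           subjects without later visits", {
  spec <- cohort_spec(clusters = list(
    list(shape = "linear", params = list(slope = -6), size = 8)),
    noise_sd = 0, visit_rate = 5, followup = c(1.8, 2.2))
  co <- generate_cohort(spec, seed = 3)
  tab <- censoring_experiment(co$trajectories, horizons = c(1, 10),
                              models = "SM", config = mogp_config(n_sweeps = 5),
                              seed = 2)
  # noiseless linear data: the slope model extrapolates exactly
  expect_lt(max(tab$rmse), 1e-8)
  # a horizon beyond every follow-up leaves no test visits: all skipped
  skipped <- attr(tab, "skipped")
  expect_true(all(tab$condition == 1))
  expect_equal(sum(skipped$condition == 10), 8)
  expect_true(all(skipped$reason[skipped$condition == 10] ==
                    "no_post_horizon_visits"))
})

test_that("transfer experiment compares reference, study-specific and
           shuffled models", {
  ref <- anchor_cohort(two_group_cohort(seed = 2, n_per = 12)$trajectories)
  tgt <- anchor_cohort(two_group_cohort(seed = 15, n_per = 8)$trajectories)
  res <- transfer_experiment(ref, list(siteA = tgt), n_splits = 3,
                             config = mogp_config(n_sweeps = 8), seed = 5)
  expect_s3_class(res, "transfer_result")
  expect_setequal(unique(res$per_split$model),
                  c("reference", "study_specific", "shuffled"))
  agg <- res$summary
  ref_err <- agg$mean_rmse[agg$dataset == "siteA" & agg$model == "reference"]
  shuf_err <- agg$mean_rmse[agg$dataset == "siteA" & agg$model == "shuffled"]
  expect_lt(ref_err, shuf_err)  # shuffled-label control degrades error
  # a target drawn from the reference distribution scores comparably
  stu_err <- agg$mean_rmse[agg$dataset == "siteA" &
                             agg$model == "study_specific"]
  expect_lt(abs(ref_err - stu_err), 1.5)
  expect_true(all(res$p_values$p_value >= 0 & res$p_values$p_value <= 1))
  res2 <- transfer_experiment(ref, list(siteA = tgt), n_splits = 3,
                              config = mogp_config(n_sweeps = 8), seed = 5)
  expect_identical(res$per_split, res2$per_split)
  expect_error(transfer_experiment(ref, list(tiny = tgt[1:3])), "smaller")
})

test_that("meta-clustering separates archetypes and ignores input order", {
  mk <- function(id, slope, ls) linear_cluster(slope, id = id, ls = ls)
  # four archetypes: fast/short-ls, slow/long-ls, slow/short-ls,
  # medium/short-ls (two nearby members per archetype)
  clusters <- list(
    mk("a1", -20, 0.3), mk("a2", -19, 0.35),
    mk("b1", -2, 6), mk("b2", -2.5, 5),
    mk("c1", -3, 0.4), mk("c2", -3.5, 0.35),
    mk("d1", -10, 0.4), mk("d2", -10.5, 0.45))
  g <- meta_cluster(clusters, k = 4)
  expect_equal(length(unique(g$group)), 4)
  pairs <- list(c("a1", "a2"), c("b1", "b2"), c("c1", "c2"), c("d1", "d2"))
  for (p in pairs) {
    expect_equal(g$group[g$cluster_id == p[1]],
                 g$group[g$cluster_id == p[2]])
  }
  # group 1 is the fastest-declining archetype
  expect_equal(unique(g$group[g$cluster_id %in% c("a1", "a2")]), 1)
  # permutation invariance
  g2 <- meta_cluster(clusters[c(5, 3, 8, 1, 7, 2, 4, 6)], k = 4)
  for (cid in g$cluster_id) {
    expect_equal(g2$group[g2$cluster_id == cid],
                 g$group[g$cluster_id == cid])
  }
  # identical parameters always share a group
  same <- list(mk("x1", -6, 1), mk("x2", -6, 1), mk("y1", -20, 0.2))
  gs <- meta_cluster(same, k = 2)
  expect_equal(gs$group[gs$cluster_id == "x1"],
               gs$group[gs$cluster_id == "x2"])
  expect_error(meta_cluster(same, k = 5), "fewer clusters")
  expect_error(meta_cluster(same[1], k = 1), "at least two")
})

test_that("error-distribution tests behave at their reference points", {
  # identical paired samples: no evidence of improvement
  x <- c(1.2, 3.4, 2.2, 5.1)
  w <- compare_error_distributions(x, x, "wilcoxon_one_sided")
  expect_equal(w$p_value, 1)
  # disjoint supports give the maximal KS statistic
  k <- compare_error_distributions(1:10, 101:110, "ks_two_sided")
  expect_equal(k$statistic, 1.0)
  # exact signed-rank enumeration oracle on a small instance
  set.seed(44)
  for (rep in 1:5) {
    a <- runif(8, 0, 5); b <- a + runif(8, -2, 1)
    d <- a - b
    if (any(d == 0)) next
    w2 <- compare_error_distributions(a, b, "wilcoxon_one_sided")
    expect_equal(w2$p_value, oracle_signed_rank_p(d), tolerance = 1e-12)
  }
  expect_error(compare_error_distributions(1, 1:2), "at least two")
  expect_error(compare_error_distributions(1:3, 1:4, "wilcoxon_one_sided"),
               "equal length")
})

dummy_model <- function(assignments) {
  ids <- sort(unique(assignments))
  clusters <- lapply(ids, function(cid) {
    structure(list(cluster_id = cid,
                   member_ids = names(assignments)[assignments == cid],
                   hyper = gp_hyperparams(1, 1, 1, mean_intercept = 48),
                   kernel = "se", t = numeric(0), y = numeric(0),
                   scale = score_scale("alsfrsr")),
              class = "mogp_cluster")
  })
  names(clusters) <- ids
  structure(list(clusters = clusters, assignments = assignments,
                 alpha = 1, margin = 5,
                 prior_hyper = gp_hyperparams(1, 1, 1, mean_intercept = 48),
                 config = mogp_config(), scale = score_scale("alsfrsr"),
                 shuffled = FALSE), class = "mogp_model")
}

test_that("hypergeometric enrichment matches combinatorial enumeration", {
  assignments <- setNames(c(rep("C1", 3), rep("C2", 7)),
                          paste0("s", 1:10))
  model <- dummy_model(assignments)
  attr_v <- setNames(c(rep(TRUE, 3), rep(TRUE, 2), rep(FALSE, 5)),
                     paste0("s", 1:10))  # 5 positives, all of C1 positive
  tab <- cluster_enrichment(model, attr_v)
  expect_equal(tab$p_value[tab$cluster_id == "C1"],
               choose(5, 3) / choose(10, 3))  # 10/120
  # constant attribute: p = 1 for every cluster
  tab2 <- cluster_enrichment(model, setNames(rep(TRUE, 10),
                                             paste0("s", 1:10)))
  expect_true(all(tab2$p_value == 1))
  # subjects with missing attribute are excluded from the totals
  attr_na <- attr_v
  attr_na["s10"] <- NA
  tab3 <- cluster_enrichment(model, attr_na)
  expect_equal(attr(tab3, "excluded"), "s10")
  expect_equal(tab3$p_value[tab3$cluster_id == "C1"],
               phyper(2, 5, 4, 3, lower.tail = FALSE))
})
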