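#' Predicted trajectory of a fitted object at given times
#'
#' Dispatches on the fit type: for a mixture model the subject's assigned
#' cluster mean is used when the subject was in the training cohort,
#' otherwise membership is predicted first; slope and sigmoid fits evaluate
#' their parametric curves; a bare cluster evaluates its mean function.
#'
#' @param fit A `mogp_model`, `mogp_cluster`, `slope_fit` or `sigmoid_fit`.
#' @param traj The subject's [patient_trajectory()] (used for membership
#'   lookup/prediction; may be `NULL` for parametric fits and clusters).
#' @param t Numeric vector of query times (years).
#' @return Numeric vector of predicted scores.
#' @export
predict_scores <- function(fit, traj, t) {
  if (inherits(fit, "mogp_model")) {
    cid <- if (!is.null(traj) && traj$subject_id %in% names(fit$assignments)) {
      fit$assignments[[traj$subject_id]]
    } else {
      predict_membership(fit, traj)$cluster_id
    }
    cluster_mean_function(fit$clusters[[cid]], t)$mean
  } else if (inherits(fit, "mogp_cluster")) {
    cluster_mean_function(fit, t)$mean
  } else if (inherits(fit, "slope_fit")) {
    fit$y_max + fit$slope * t
  } else if (inherits(fit, "sigmoid_fit")) {
    .sigmoid_curve(t, fit$d50, fit$dx, fit$y_max)
  } else stop("unsupported fit object")
}

#' Per-patient RMSE against a model's predicted trajectory
#'
#' Root mean squared difference between evaluation scores and the model's
#' prediction at the evaluation times. Lower RMSE means better model
#' performance. By default the subject's measured (never anchor) visits are
#' scored; pass `eval_visits` to score held-out or post-horizon visits.
#'
#' @inheritParams predict_scores
#' @param eval_visits Data frame with columns `t`, `y`; defaults to
#'   `measured_visits(traj)`. Must be non-empty.
#' @param model_label Label recorded in the output (e.g. `"MoGP"`).
#' @return One-row data frame (`subject_id`, `model`, `rmse`,
#'   `n_eval_points`).
#' @export
rmse_to_cluster_mean <- function(fit, traj, eval_visits = NULL,
                                 model_label = class(fit)[1]) {
  if (is.null(eval_visits)) eval_visits <- measured_visits(traj)
  if (is.null(eval_visits) || nrow(eval_visits) == 0L) {
    stop("empty evaluation set")
  }
  pred <- predict_scores(fit, traj, eval_visits$t)
  data.frame(subject_id = traj$subject_id, model = model_label,
             rmse = sqrt(mean((eval_visits$y - pred)^2)),
             n_eval_points = nrow(eval_visits), stringsAsFactors = FALSE)
}

#' First-year slope of a cluster mean function
#'
#' The anchored linear extrapolation diagnostic:
#' `(y_max - mean(1 yr)) / 1 yr`, reported as a decline magnitude in
#' points/year (positive = decline). Comparing this extrapolation with the
#' mean function at later times quantifies how nonlinear a cluster's
#' trajectory is.
#'
#' @param cluster A `mogp_cluster`.
#' @return Decline magnitude, points/year.
#' @export
first_year_slope <- function(cluster) {
  stopifnot(inherits(cluster, "mogp_cluster"))
  y_max <- cluster$scale$y_max
  (y_max - cluster_mean_function(cluster, 1)$mean) / 1
}

# Fit the requested models on an anchored training cohort. Mixture models
# are fitted once on the whole cohort; SM/SG are per-patient.
.fit_models_on <- function(train_anch, models, config, seed) {
  fits <- list()
  if ("MoGP" %in% models) {
    fits$MoGP <- fit_mogp(train_anch, config = config, seed = seed)
  }
  if ("LKM" %in% models) {
    fits$LKM <- fit_lkm(train_anch, config = config, seed = seed)
  }
  fits
}

.per_patient_fit <- function(model_name, traj) {
  switch(model_name,
         SM = fit_anchored_slope(traj),
         SG = if (nrow(measured_visits(traj)) >= 3L) fit_sigmoid(traj) else NULL,
         stop("unknown per-patient model ", model_name))
}

.experiment_row <- function(condition, df) cbind(condition = condition, df)

#' Interpolation experiment: reconstruct randomly withheld visits
#'
#' For each fraction, that share of each subject's clinic visits is
#' provided as training data (selections randomly interspersed across
#' visits; the retained count is `round(fraction * n_visits)`), models are
#' fitted on the retained visits, and per-patient RMSE is scored on the
#' withheld visits. Subjects should have ten or more measured visits;
#' subjects whose retained share leaves fewer than two training visits are
#' skipped and logged.
#'
#' @param trajs List of unanchored [patient_trajectory()] objects.
#' @param fractions Training fractions (default `c(0.25, 0.5, 0.75)`).
#' @param models Character subset of `c("MoGP", "LKM", "SM", "SG")`.
#' @param config A [mogp_config()] for the mixture models.
#' @param seed Integer seed; the experiment is exactly reproducible given
#'   `(config, seed)`.
#' @return Tidy data frame (`condition` = fraction, `subject_id`, `model`,
#'   `rmse`, `n_eval_points`) of class `experiment_table`, with attributes
#'   `seed` and `skipped` (data frame of logged skips).
#' @export
interpolation_experiment <- function(trajs, fractions = c(0.25, 0.5, 0.75),
                                     models = c("MoGP", "LKM", "SM"),
                                     config = mogp_config(), seed = 1L) {
  models <- match.arg(models, c("MoGP", "LKM", "SM", "SG"),
                      several.ok = TRUE)
  n_vis <- vapply(trajs, function(x) nrow(measured_visits(x)), integer(1))
  if (any(n_vis < 10L)) {
    warning(sum(n_vis < 10L),
            " subject(s) with fewer than 10 visits dropped")
    trajs <- trajs[n_vis >= 10L]
  }
  out <- list(); skipped <- list()
  for (fi in seq_along(fractions)) {
    frac <- fractions[fi]
    set.seed(seed + fi)
    train <- list(); eval_sets <- list()
    for (tr in trajs) {
      v <- measured_visits(tr)
      n_keep <- round(frac * nrow(v))
      if (n_keep < 2L || n_keep >= nrow(v)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          condition = frac, subject_id = tr$subject_id,
          reason = "too_few_training_visits", stringsAsFactors = FALSE)
        next
      }
      keep <- sort(sample.int(nrow(v), n_keep))
      train[[length(train) + 1L]] <- add_onset_anchor(
        patient_trajectory(tr$subject_id, v$t[keep], v$y[keep], tr$scale,
                           metadata = tr$metadata))
      eval_sets[[tr$subject_id]] <- v[-keep, , drop = FALSE]
    }
    fits <- .fit_models_on(train, models, config, seed + fi)
    for (tr in train) {
      ev <- eval_sets[[tr$subject_id]]
      for (m in intersect(models, c("MoGP", "LKM"))) {
        out[[length(out) + 1L]] <- .experiment_row(
          frac, rmse_to_cluster_mean(fits[[m]], tr, ev, model_label = m))
      }
      for (m in intersect(models, c("SM", "SG"))) {
        pf <- .per_patient_fit(m, tr)
        if (!is.null(pf)) {
          out[[length(out) + 1L]] <- .experiment_row(
            frac, rmse_to_cluster_mean(pf, tr, ev, model_label = m))
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("experiment_table", class(res)), seed = seed,
            skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
}

#' Forecasting experiment on right-censored training data
#'
#' For each horizon (years since each subject's baseline, i.e. first
#' measured visit), models are trained on the visits within the horizon and
#' per-patient RMSE is scored on the visits after it. Subjects with no
#' post-horizon visits are skipped and logged. Subjects should have four or
#' more measured visits.
#'
#' @inheritParams interpolation_experiment
#' @param horizons Training horizons in years since baseline
#'   (default `c(0.25, 0.5, 1, 1.5, 2)`).
#' @return Tidy `experiment_table` (`condition` = horizon).
#' @export
censoring_experiment <- function(trajs, horizons = c(0.25, 0.5, 1, 1.5, 2),
                                 models = c("MoGP", "LKM", "SM"),
                                 config = mogp_config(), seed = 1L) {
  models <- match.arg(models, c("MoGP", "LKM", "SM", "SG"),
                      several.ok = TRUE)
  n_vis <- vapply(trajs, function(x) nrow(measured_visits(x)), integer(1))
  if (any(n_vis < 4L)) {
    warning(sum(n_vis < 4L), " subject(s) with fewer than 4 visits dropped")
    trajs <- trajs[n_vis >= 4L]
  }
  out <- list(); skipped <- list()
  for (hi in seq_along(horizons)) {
    h <- horizons[hi]
    train <- list(); eval_sets <- list()
    for (tr in trajs) {
      v <- measured_visits(tr)
      cutoff <- v$t[1L] + h
      in_h <- v$t <= cutoff
      if (all(in_h)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          condition = h, subject_id = tr$subject_id,
          reason = "no_post_horizon_visits", stringsAsFactors = FALSE)
        next
      }
      train[[length(train) + 1L]] <- add_onset_anchor(
        patient_trajectory(tr$subject_id, v$t[in_h], v$y[in_h], tr$scale,
                           metadata = tr$metadata))
      eval_sets[[tr$subject_id]] <- v[!in_h, , drop = FALSE]
    }
    if (length(train) == 0L) next
    fits <- .fit_models_on(train, models, config, seed + hi)
    for (tr in train) {
      ev <- eval_sets[[tr$subject_id]]
      for (m in intersect(models, c("MoGP", "LKM"))) {
        out[[length(out) + 1L]] <- .experiment_row(
          h, rmse_to_cluster_mean(fits[[m]], tr, ev, model_label = m))
      }
      for (m in intersect(models, c("SM", "SG"))) {
        pf <- .per_patient_fit(m, tr)
        if (!is.null(pf)) {
          out[[length(out) + 1L]] <- .experiment_row(
            h, rmse_to_cluster_mean(pf, tr, ev, model_label = m))
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("experiment_table", class(res)), seed = seed,
            skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
}

#' Transfer experiment: reference versus study-specific models
#'
#' Fits a reference mixture on a 60 percent training split of the reference
#' cohort and a study-specific mixture on each target cohort's own training
#' split; every target's held-out 40 percent is then scored under both, and
#' under the randomly shuffled-label control. Splits are repeated
#' `n_splits` times. The reference cohort's own held-out subjects provide
#' the baseline error. Per-dataset mean errors carry a normal-approximation
#' 0.95 confidence interval across splits, and a paired one-sided Wilcoxon
#' signed-rank test asks whether the reference model improves on the
#' study-specific model.
#'
#' @param reference List of anchored trajectories (the reference cohort).
#' @param targets Named list of anchored target cohorts (each with at least
#'   5 subjects).
#' @param split Training share (default 0.6).
#' @param n_splits Number of random splits (default 5).
#' @param config A [mogp_config()].
#' @param seed Integer seed.
#' @return List of class `transfer_result`: `per_split` (dataset, model,
#'   split, mean_rmse, n), `summary` (dataset, model, mean_rmse, ci_lower,
#'   ci_upper), `p_values` (dataset, p_value: reference < study_specific).
#' @export
transfer_experiment <- function(reference, targets, split = 0.6,
                                n_splits = 5, config = mogp_config(),
                                seed = 1L) {
  stopifnot(is.list(targets), length(names(targets)) == length(targets))
  small <- vapply(targets, length, integer(1)) < 5L
  if (any(small)) {
    stop("target cohort(s) smaller than 5 subjects: ",
         paste(names(targets)[small], collapse = ", "))
  }
  rows <- list()
  for (s in seq_len(n_splits)) {
    set.seed(seed + 1000L * s)
    idx_ref <- sample.int(length(reference), round(split * length(reference)))
    ref_model <- fit_mogp(reference[idx_ref], config = config,
                          seed = seed + 1000L * s)

    # membership is always predicted afresh: test subjects are held out,
    # and subject ids may recur across cohorts
    score_set <- function(model, test, label, dataset) {
      errs <- vapply(test, function(tr) {
        cl <- model$clusters[[predict_membership(model, tr)$cluster_id]]
        v <- measured_visits(tr)
        sqrt(mean((v$y - cluster_mean_function(cl, v$t)$mean)^2))
      }, numeric(1))
      data.frame(dataset = dataset, model = label, split = s,
                 mean_rmse = mean(errs), n = length(errs),
                 stringsAsFactors = FALSE)
    }
    shuffled_score <- function(test, dataset, salt) {
      preds <- vapply(test, function(tr) {
        predict_membership(ref_model, tr)$cluster_id
      }, character(1))
      set.seed(seed + 1000L * s + salt)
      perm <- sample(preds)
      errs <- vapply(seq_along(test), function(j) {
        cl <- ref_model$clusters[[perm[j]]]
        v <- measured_visits(test[[j]])
        sqrt(mean((v$y - cluster_mean_function(cl, v$t)$mean)^2))
      }, numeric(1))
      data.frame(dataset = dataset, model = "shuffled", split = s,
                 mean_rmse = mean(errs), n = length(errs),
                 stringsAsFactors = FALSE)
    }

    ref_test <- reference[-idx_ref]
    rows[[length(rows) + 1L]] <- score_set(ref_model, ref_test,
                                           "reference", "reference")
    for (d in names(targets)) {
      coh <- targets[[d]]
      set.seed(seed + 1000L * s + match(d, names(targets)))
      idx <- sample.int(length(coh), round(split * length(coh)))
      study_model <- fit_mogp(coh[idx], config = config,
                              seed = seed + 1000L * s + match(d, names(targets)))
      test <- coh[-idx]
      rows[[length(rows) + 1L]] <- score_set(ref_model, test, "reference", d)
      rows[[length(rows) + 1L]] <- score_set(study_model, test,
                                             "study_specific", d)
      rows[[length(rows) + 1L]] <- shuffled_score(test, d,
                                                  500L + match(d, names(targets)))
    }
  }
  per_split <- do.call(rbind, rows)
  rownames(per_split) <- NULL

  agg <- do.call(rbind, lapply(split(per_split,
                                     per_split[c("dataset", "model")],
                                     drop = TRUE), function(g) {
    m <- mean(g$mean_rmse)
    se <- stats::sd(g$mean_rmse) / sqrt(nrow(g))
    data.frame(dataset = g$dataset[1], model = g$model[1], mean_rmse = m,
               ci_lower = m - 1.96 * se, ci_upper = m + 1.96 * se,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL

  pv <- do.call(rbind, lapply(names(targets), function(d) {
    ref <- per_split[per_split$dataset == d &
                       per_split$model == "reference", ]
    stu <- per_split[per_split$dataset == d &
                       per_split$model == "study_specific", ]
    a <- ref$mean_rmse[order(ref$split)]
    b <- stu$mean_rmse[order(stu$split)]
    data.frame(dataset = d,
               p_value = compare_error_distributions(
                 a, b, test = "wilcoxon_one_sided")$p_value,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_split = per_split, summary = agg, p_values = pv,
                 seed = seed),
            class = "transfer_result")
}

#' Group clusters by progression rate and stability
#'
#' Meta-clusters the fitted mixture components in the two-dimensional space
#' of (first-year slope of the mean function, log length-scale) — the two
#' learned parameters that characterise how fast and how stably a cluster
#' progresses — using k-means on standardized features. Group labels are
#' ordered by slope magnitude (group 1 = fastest decline). Grouping is
#' deterministic and invariant to cluster input order.
#'
#' @param x A `mogp_model` or list of `mogp_cluster` objects (at least 2).
#' @param k Number of groups (default 4; must not exceed the number of
#'   clusters).
#' @return Data frame (`cluster_id`, `first_year_slope`, `length_scale`,
#'   `group`), with attribute `method`.
#' @export
meta_cluster <- function(x, k = 4) {
  clusters <- if (inherits(x, "mogp_model")) x$clusters else x
  if (length(clusters) < 2L) stop("at least two clusters required")
  if (k > length(clusters)) {
    stop("fewer clusters (", length(clusters), ") than requested groups (",
         k, ")")
  }
  feats <- data.frame(
    cluster_id = vapply(clusters, `[[`, character(1), "cluster_id"),
    first_year_slope = vapply(clusters, first_year_slope, numeric(1)),
    length_scale = vapply(clusters, function(cl) cl$hyper$length_scale,
                          numeric(1)),
    stringsAsFactors = FALSE)
  ord <- order(feats$cluster_id)  # canonical order for determinism
  f <- feats[ord, ]
  X <- scale(cbind(f$first_year_slope, log(f$length_scale)))
  X[is.nan(X)] <- 0  # zero-variance feature
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(20220908L)
  km <- stats::kmeans(X, centers = k, nstart = 25, iter.max = 100)
  grp_slope <- tapply(f$first_year_slope, km$cluster, mean)
  relabel <- match(km$cluster,
                   as.integer(names(sort(grp_slope, decreasing = TRUE))))
  f$group <- relabel
  out <- f[match(feats$cluster_id, f$cluster_id), ]
  rownames(out) <- NULL
  attr(out, "method") <- sprintf(
    "kmeans k=%d on standardized (first-year slope, log length-scale)", k)
  out
}

#' Compare two error distributions
#'
#' `ks_two_sided` runs the two-sample two-sided Kolmogorov-Smirnov test.
#' `wilcoxon_one_sided` runs the paired Wilcoxon signed-rank test of the
#' hypothesis that model A improves on model B (errors_a shifted lower);
#' the samples must be paired and of equal length. Identical paired samples
#' give p = 1 (no evidence of improvement).
#'
#' @param errors_a,errors_b Numeric vectors of per-patient errors.
#' @param test `"ks_two_sided"` or `"wilcoxon_one_sided"`.
#' @return List with `statistic`, `p_value`, `test`.
#' @export
compare_error_distributions <- function(errors_a, errors_b,
                                        test = c("ks_two_sided",
                                                 "wilcoxon_one_sided")) {
  test <- match.arg(test)
  if (length(errors_a) < 2L || length(errors_b) < 2L) {
    stop("at least two observations per sample required")
  }
  if (test == "ks_two_sided") {
    k <- suppressWarnings(stats::ks.test(errors_a, errors_b,
                                         alternative = "two.sided"))
    list(statistic = unname(k$statistic), p_value = k$p.value,
         test = test)
  } else {
    if (length(errors_a) != length(errors_b)) {
      stop("paired test requires samples of equal length")
    }
    d <- errors_a - errors_b
    if (all(d == 0)) {
      return(list(statistic = 0, p_value = 1, test = test))
    }
    w <- suppressWarnings(stats::wilcox.test(errors_a, errors_b,
                                             paired = TRUE,
                                             alternative = "less"))
    list(statistic = unname(w$statistic), p_value = w$p.value, test = test)
  }
}

#' Hypergeometric enrichment of a binary attribute in clusters
#'
#' For each cluster, the upper-tail hypergeometric probability of drawing
#' at least the observed number of attribute-positive members given the
#' cohort totals. Subjects without a defined attribute are excluded from
#' the totals (and logged in the `excluded` attribute).
#'
#' @param model A fitted [fit_mogp()] model.
#' @param attribute Named logical (or 0/1) vector keyed by subject id.
#' @return Data frame (`cluster_id`, `n_members`, `n_positive`, `p_value`),
#'   with attribute `excluded`.
#' @export
cluster_enrichment <- function(model, attribute) {
  stopifnot(inherits(model, "mogp_model"))
  ids <- names(model$assignments)
  attr_v <- attribute[ids]
  names(attr_v) <- ids
  excluded <- ids[is.na(attr_v)]
  ok <- !is.na(attr_v)
  N <- sum(ok)
  K <- sum(as.logical(attr_v[ok]))
  rows <- lapply(model$clusters, function(cl) {
    mem <- intersect(cl$member_ids, ids[ok])
    x <- sum(as.logical(attr_v[mem]))
    n <- length(mem)
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(cluster_id = cl$cluster_id, n_members = n, n_positive = x,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Write an experiment table and its configuration as tidy output
#'
#' @param tab An `experiment_table` (or any data frame).
#' @param path CSV output path; a JSON sidecar `<path>.json` records the
#'   seed and skip log.
#' @return `path`, invisibly.
#' @export
write_experiment_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  meta <- list(seed = attr(tab, "seed"), skipped = attr(tab, "skipped"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
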