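#' Per-subject survival records
#'
#' Builds time-to-event records on the years-from-symptom-onset time axis.
#' When no death is recorded for a subject, the record is censored at the
#' time of the last recorded visit.
#'
#' @param trajs List of [patient_trajectory()] objects; a subject whose
#'   metadata carries a numeric `death_time` (years from onset) is an
#'   observed event, otherwise the subject is censored at the last visit.
#' @return Data frame of class `survival_records` with columns
#'   `subject_id`, `time` (> 0, years), `event` (1 = death observed).
#' @export
derive_survival_records <- function(trajs) {
  rows <- lapply(trajs, function(tr) {
    dt <- tr$metadata$death_time
    if (!is.null(dt) && is.finite(dt)) {
      data.frame(subject_id = tr$subject_id, time = as.numeric(dt),
                 event = 1L, stringsAsFactors = FALSE)
    } else {
      v <- measured_visits(tr)
      data.frame(subject_id = tr$subject_id, time = max(v$t), event = 0L,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  survival_records(out$subject_id, out$time, out$event)
}

#' @rdname derive_survival_records
#' @param subject_id,time,event Vectors defining the records directly.
#' @export
survival_records <- function(subject_id, time, event) {
  stopifnot(length(subject_id) == length(time),
            length(time) == length(event))
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("survival times must be positive and finite")
  }
  structure(data.frame(subject_id = as.character(subject_id),
                       time = as.numeric(time),
                       event = as.integer(as.logical(event)),
                       stringsAsFactors = FALSE),
            class = c("survival_records", "data.frame"))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function, with the number of
#' individuals at risk, censored and with recorded deaths at each event or
#' censoring time. Thin wrapper over [survival::survfit()].
#'
#' @param records A [survival_records()] data frame (non-empty).
#' @return Data frame of class `km_curve` (`time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `lower`, `upper`); the step function is
#'   right-continuous and starts at 1.
#' @export
km_curve <- function(records) {
  stopifnot(inherits(records, "survival_records"), nrow(records) > 0)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(records))
  structure(data.frame(time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, n_censor = sf$n.censor,
                       surv = sf$surv, lower = sf$lower, upper = sf$upper),
            class = c("km_curve", "data.frame"))
}

#' Survival probability at given times
#'
#' Evaluates a [km_curve()] step function (right-continuous, S(0) = 1).
#'
#' @param curve A `km_curve`.
#' @param times Numeric vector.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, times) {
  vapply(times, function(tt) {
    past <- curve$time <= tt
    if (!any(past)) 1 else curve$surv[max(which(past))]
  }, numeric(1))
}

#' Median survival time from a KM curve
#'
#' @param curve A `km_curve`.
#' @return Smallest time at which survival drops to 0.5 or below
#'   (`NA` if never reached).
#' @export
km_median_survival <- function(curve) {
  hit <- which(curve$surv <= 0.5)
  if (length(hit) == 0L) NA_real_ else curve$time[min(hit)]
}

#' Pairwise logrank tests between cluster survival curves
#'
#' Runs the logrank test for every unordered pair of clusters with survival
#' records, adjusts the p-values for multiple testing by Benjamini-Hochberg
#' FDR across all evaluable pairs, and reports the fraction of pairs with
#' differential survival (adjusted p below `alpha_level`). Clusters without
#' records are excluded (logged); pairs with fewer than two events in total
#' are reported as non-evaluable (`NA`) rather than p = 1.
#'
#' @param model A fitted [fit_mogp()] model.
#' @param records A [survival_records()] data frame covering the model's
#'   subjects.
#' @param alpha_level Significance threshold on the adjusted p-values
#'   (default 0.05).
#' @return List of class `pairwise_logrank`: `p_raw` and `p_adjusted`
#'   (symmetric matrices with unit diagonal), `fraction_differential`,
#'   `n_pairs_evaluable`, `excluded_clusters`.
#' @export
pairwise_logrank <- function(model, records, alpha_level = 0.05) {
  stopifnot(inherits(model, "mogp_model"),
            inherits(records, "survival_records"))
  rec <- as.data.frame(records)
  rec$cluster <- model$assignments[rec$subject_id]
  rec <- rec[!is.na(rec$cluster), , drop = FALSE]
  sizes <- table(rec$cluster)
  cl_ids <- names(model$clusters)
  usable <- cl_ids[cl_ids %in% names(sizes)[sizes >= 2]]
  excluded <- setdiff(cl_ids, usable)
  if (length(usable) < 2L) stop("need at least two clusters with >= 2 records")

  K <- length(usable)
  p_raw <- matrix(NA_real_, K, K, dimnames = list(usable, usable))
  diag(p_raw) <- 1
  pairs <- utils::combn(usable, 2)
  raw <- apply(pairs, 2L, function(pr) {
    sub <- rec[rec$cluster %in% pr, , drop = FALSE]
    if (sum(sub$event) < 2L) return(NA_real_)
    sd <- survival::survdiff(survival::Surv(time, event) ~ cluster,
                             data = sub)
    stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  })
  adj <- rep(NA_real_, length(raw))
  ev <- !is.na(raw)
  adj[ev] <- stats::p.adjust(raw[ev], method = "BH")
  p_adj <- p_raw
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    p_raw[a, b] <- p_raw[b, a] <- raw[j]
    p_adj[a, b] <- p_adj[b, a] <- adj[j]
  }
  structure(list(p_raw = p_raw, p_adjusted = p_adj,
                 fraction_differential =
                   if (any(ev)) mean(adj[ev] < alpha_level) else NA_real_,
                 n_pairs_evaluable = sum(ev),
                 excluded_clusters = excluded,
                 alpha_level = alpha_level),
            class = "pairwise_logrank")
}

#' @export
print.pairwise_logrank <- function(x, ...) {
  cat(sprintf(paste0("<pairwise_logrank> %d evaluable pair(s); %.1f%% ",
                     "differential at adjusted p < %g\n"),
              x$n_pairs_evaluable, 100 * x$fraction_differential,
              x$alpha_level))
  invisible(x)
}

#' Kaplan-Meier curves for every cluster of a model
#'
#' @param model A fitted [fit_mogp()] model.
#' @param records A [survival_records()] data frame.
#' @return Named list of [km_curve()] data frames (clusters with no
#'   records omitted).
#' @export
cluster_km_curves <- function(model, records) {
  rec <- as.data.frame(records)
  rec$cluster <- model$assignments[rec$subject_id]
  out <- list()
  for (cid in names(model$clusters)) {
    sub <- rec[!is.na(rec$cluster) & rec$cluster == cid, , drop = FALSE]
    if (nrow(sub) == 0L) next
    out[[cid]] <- km_curve(survival_records(sub$subject_id, sub$time,
                                            sub$event))
  }
  out
}
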