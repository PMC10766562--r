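#' Template progression curves
#'
#' Deterministic monotone non-increasing decline shapes used by the cohort
#' generator, all starting at (or, for the sigmoid, within numerical
#' tolerance of) the scale maximum:
#' \describe{
#'   \item{linear}{`y_max + slope * t`, `slope <= 0`.}
#'   \item{sigmoid}{`y_max / (1 + exp((t - d50) / dx))`; `d50` = years at
#'     half maximum, `dx` = decline-duration parameter.}
#'   \item{convex}{power-law `y_max * (1 - (t / T)^gamma)` with
#'     `gamma > 1`: slow early decline, then accelerating.}
#'   \item{concave}{the same power law with `0 < gamma < 1`: fast early
#'     decline, then flattening.}
#'   \item{stable}{`y_max - delta * t` with a small `delta` (default
#'     0.5 points/yr).}
#' }
#' All values are clipped to the scale bounds.
#'
#' @param shape One of `"linear"`, `"sigmoid"`, `"convex"`, `"concave"`,
#'   `"stable"`.
#' @param params Named list of shape parameters (see above).
#' @param t Numeric vector of times (years).
#' @param scale A [score_scale()].
#' @return Numeric vector of template scores.
#' @export
template_curve <- function(shape, params, t, scale = score_scale("alsfrsr")) {
  y_max <- scale$y_max; y_min <- scale$y_min
  y <- switch(shape,
    linear = {
      if (is.null(params$slope) || params$slope > 0) {
        stop("linear shape requires slope <= 0")
      }
      y_max + params$slope * t
    },
    sigmoid = {
      if (is.null(params$d50) || is.null(params$dx) ||
          params$d50 <= 0 || params$dx <= 0) {
        stop("sigmoid shape requires d50 > 0 and dx > 0")
      }
      y_max / (1 + exp((t - params$d50) / params$dx))
    },
    convex = ,
    concave = {
      if (is.null(params$T) || is.null(params$gamma) ||
          params$T <= 0 || params$gamma <= 0) {
        stop("power-law shape requires T > 0 and gamma > 0")
      }
      if (shape == "convex" && params$gamma <= 1) {
        stop("convex shape requires gamma > 1")
      }
      if (shape == "concave" && params$gamma >= 1) {
        stop("concave shape requires gamma < 1")
      }
      y_max * (1 - (t / params$T)^params$gamma)
    },
    stable = {
      delta <- if (is.null(params$delta)) 0.5 else params$delta
      if (delta < 0) stop("stable shape requires delta >= 0")
      y_max - delta * t
    },
    stop("unknown shape '", shape, "'"))
  pmin(pmax(y, y_min), y_max)
}

#' Specification of a synthetic longitudinal cohort
#'
#' Describes a clustered cohort of sparse, irregularly sampled, monotone
#' declining trajectories with observation noise, attrition and linked
#' survival outcomes. The defaults describe a four-archetype ALSFRS-R
#' cohort (fast linear, slow linear, sigmoidal, concave decline; 30
#' subjects each) observed roughly six times over about two years of
#' follow-up with 1.5-point observation noise — a sparse-clinic regime
#' typical of ALS study populations.
#'
#' @param clusters List of cluster descriptions, each a list with `shape`
#'   (see [template_curve()]), `params`, `size` (>= 1), and optionally
#'   `p_bulbar` (probability of bulbar site of onset recorded in subject
#'   metadata; defaults to 0.30 for clusters declining by 12+ points in the
#'   first year and 0.15 otherwise).
#' @param visit_rate Mean clinic visits per year; inter-visit gaps are
#'   exponential with mean `1 / visit_rate` (irregular schedules).
#' @param followup `c(min, max)` years of follow-up after the first visit,
#'   drawn uniformly per subject (attrition).
#' @param enrollment_delay `c(min, max)` years from symptom onset to the
#'   first visit, drawn uniformly per subject.
#' @param noise_sd Observation-noise standard deviation, points; noise is
#'   added before clipping to the scale bounds.
#' @param scale A [score_scale()].
#' @param min_visits Minimum measured visits per subject (visit schedules
#'   are redrawn until satisfied; default 3).
#' @param survival_link List `a`, `b`, `sd`: log survival time from onset
#'   is `a - b * (first-year decline of the subject's template) + N(0, sd)`,
#'   so faster-declining templates die sooner.
#' @param censor_window Years after a subject's last visit within which a
#'   death is observable; later deaths are censored at the last visit.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(clusters = list(
                          list(shape = "linear", params = list(slope = -10),
                               size = 30),
                          list(shape = "linear", params = list(slope = -3),
                               size = 30),
                          list(shape = "sigmoid",
                               params = list(d50 = 1.5, dx = 0.25),
                               size = 30),
                          list(shape = "concave",
                               params = list(T = 4, gamma = 0.5),
                               size = 30)),
                        visit_rate = 3, followup = c(1.5, 2.5),
                        enrollment_delay = c(0.2, 1), noise_sd = 1.5,
                        scale = score_scale("alsfrsr"), min_visits = 3,
                        survival_link = list(a = log(5), b = 0.07,
                                             sd = 0.35),
                        censor_window = 3) {
  spec <- structure(list(clusters = clusters, visit_rate = visit_rate,
                         followup = followup,
                         enrollment_delay = enrollment_delay,
                         noise_sd = noise_sd, scale = scale,
                         min_visits = min_visits,
                         survival_link = survival_link,
                         censor_window = censor_window),
                    class = "cohort_spec")
  problems <- validate_cohort_spec(spec)
  if (length(problems)) {
    stop("invalid cohort spec:\n  - ", paste(problems, collapse = "\n  - "))
  }
  spec
}

#' Validate a cohort specification
#'
#' @param spec A `cohort_spec` (or plain list with the same fields).
#' @return Character vector of violations (empty when valid).
#' @export
validate_cohort_spec <- function(spec) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (!length(spec$clusters)) add("at least one cluster required")
  for (i in seq_along(spec$clusters)) {
    cl <- spec$clusters[[i]]
    if (is.null(cl$size) || cl$size < 1) {
      add(sprintf("cluster %d: size must be >= 1", i))
    }
    ok <- tryCatch({
      template_curve(cl$shape, cl$params, c(0, 1), spec$scale)
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) add(sprintf("cluster %d: %s", i, ok))
  }
  if (spec$noise_sd < 0) add("noise_sd must be >= 0")
  if (spec$visit_rate <= 0) add("visit_rate must be > 0")
  if (length(spec$followup) != 2L || any(spec$followup <= 0) ||
      diff(spec$followup) < 0) {
    add("followup must be c(min, max) with 0 < min <= max")
  }
  if (length(spec$enrollment_delay) != 2L ||
      any(spec$enrollment_delay < 0) || diff(spec$enrollment_delay) < 0) {
    add("enrollment_delay must be c(min, max) with 0 <= min <= max")
  }
  if (!inherits(spec$scale, "score_scale")) add("scale must be a score_scale")
  problems
}

.first_year_decline <- function(cl, scale) {
  (scale$y_max - template_curve(cl$shape, cl$params, 1, scale)) / 1
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws, per subject: an irregular visit schedule (uniform enrollment
#' delay, exponential inter-visit gaps, uniform follow-up duration), scores
#' from the cluster's template curve plus independent Gaussian noise
#' clipped to the scale bounds, and a survival time linked to the
#' template's first-year decline. Fully deterministic given `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return List with `trajectories` (unanchored [patient_trajectory()]
#'   objects, with `site_of_onset` and — for observed deaths —
#'   `death_time` metadata), `truth` (data frame: `subject_id`, `cluster`,
#'   `shape`, `first_year_decline`, `survival_time`, `event`), and `spec`.
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  problems <- validate_cohort_spec(spec)
  if (length(problems)) {
    stop("invalid cohort spec:\n  - ", paste(problems, collapse = "\n  - "))
  }
  if (!is.null(seed)) set.seed(seed)
  scale <- spec$scale
  trajs <- list(); truth <- list()
  sid <- 0L
  for (ci in seq_along(spec$clusters)) {
    cl <- spec$clusters[[ci]]
    decline1 <- .first_year_decline(cl, scale)
    p_bulbar <- if (!is.null(cl$p_bulbar)) cl$p_bulbar else
      if (decline1 >= 12) 0.30 else 0.15
    for (s in seq_len(cl$size)) {
      sid <- sid + 1L
      id <- sprintf("S%04d", sid)
      delay <- stats::runif(1, spec$enrollment_delay[1],
                            spec$enrollment_delay[2])
      fup <- stats::runif(1, spec$followup[1], spec$followup[2])
      for (attempt in 1:100) {
        gaps <- stats::rexp(ceiling(4 * spec$visit_rate * fup) + 8,
                            rate = spec$visit_rate)
        times <- delay + c(0, cumsum(gaps))
        times <- times[times <= delay + fup]
        if (length(times) >= spec$min_visits) break
      }
      mu <- template_curve(cl$shape, cl$params, times, scale)
      y <- mu + stats::rnorm(length(times), 0, spec$noise_sd)
      y <- pmin(pmax(y, scale$y_min), scale$y_max)

      lk <- spec$survival_link
      surv_t <- exp(lk$a - lk$b * decline1 + stats::rnorm(1, 0, lk$sd))
      last_visit <- max(times)
      surv_t <- max(surv_t, last_visit + 0.05)
      event <- as.integer(surv_t <= last_visit + spec$censor_window)
      site <- if (stats::runif(1) < p_bulbar) "bulbar" else "limb"

      md <- list(site_of_onset = site)
      if (event == 1L) md$death_time <- surv_t
      trajs[[sid]] <- patient_trajectory(id, times, y, scale, metadata = md)
      truth[[sid]] <- data.frame(
        subject_id = id, cluster = sprintf("K%d", ci), shape = cl$shape,
        first_year_decline = decline1, survival_time = surv_t,
        event = event, site_of_onset = site, stringsAsFactors = FALSE)
    }
  }
  list(trajectories = trajs, truth = do.call(rbind, truth), spec = spec)
}
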