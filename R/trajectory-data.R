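#' Score scales for bounded clinical instruments
#'
#' A score scale declares the bounds of the clinical instrument a trajectory
#' is measured on. Scores outside `[y_min, y_max]` are rejected by
#' [patient_trajectory()]. Built-in presets cover the ALSFRS-R total (0-48),
#' ALSFRS-R domain subscores (0-12) and percent-predicted forced vital
#' capacity (0-100).
#'
#' @param name Label for the scale. One of `"alsfrsr"`, `"subscore"`,
#'   `"fvc"`, or any other string for a custom scale (then `y_max` is
#'   required).
#' @param y_max Maximum attainable score; supplies the onset-anchor value.
#' @param y_min Minimum attainable score (default 0).
#' @return An object of class `score_scale` with fields `name`, `y_min`,
#'   `y_max`.
#' @examples
#' score_scale("alsfrsr")
#' score_scale("grip", y_max = 60)
#' @export
score_scale <- function(name, y_max = NULL, y_min = 0) {
  presets <- list(alsfrsr = 48, subscore = 12, fvc = 100)
  if (is.null(y_max)) {
    if (!name %in% names(presets)) {
      stop("unknown scale '", name, "'; supply y_max for a custom scale")
    }
    y_max <- presets[[name]]
  }
  stopifnot(is.numeric(y_max), is.numeric(y_min), length(y_max) == 1L,
            length(y_min) == 1L, is.finite(y_max), is.finite(y_min))
  if (y_max <= y_min) stop("y_max must exceed y_min")
  structure(list(name = name, y_min = y_min, y_max = y_max),
            class = "score_scale")
}

#' @export
print.score_scale <- function(x, ...) {
  cat(sprintf("<score_scale> %s [%g, %g]\n", x$name, x$y_min, x$y_max))
  invisible(x)
}

#' One subject's longitudinal trajectory
#'
#' Bundles a subject's time-ordered visits on a declared bounded scale.
#' Times are in years from symptom onset. Duplicate visit times are averaged
#' with a warning (a symmetric, deterministic policy). Visits are stored
#' strictly increasing in time.
#'
#' @param subject_id Opaque subject identifier (coerced to character).
#' @param t Numeric vector of visit times, in years from symptom onset
#'   (non-negative).
#' @param y Numeric vector of scores, within the scale bounds.
#' @param scale A [score_scale()].
#' @param anchored Logical; `TRUE` only when the first visit is the imputed
#'   onset anchor `(0, y_max)`. Use [add_onset_anchor()] rather than setting
#'   this directly.
#' @param metadata Optional named list of per-subject metadata (site of
#'   onset, survival fields, ...).
#' @return An object of class `patient_trajectory` with fields `subject_id`,
#'   `visits` (data.frame with columns `t`, `y`), `scale`, `anchored`,
#'   `metadata`.
#' @seealso [add_onset_anchor()], [apply_qc_filters()], [read_long_format()]
#' @export
patient_trajectory <- function(subject_id, t, y, scale,
                               anchored = FALSE, metadata = list()) {
  stopifnot(inherits(scale, "score_scale"), length(t) == length(y))
  t <- as.numeric(t)
  y <- as.numeric(y)
  if (length(t) == 0L) stop("trajectory must contain at least one visit")
  if (anyNA(t) || anyNA(y) || any(!is.finite(t)) || any(!is.finite(y))) {
    stop("visit times and scores must be finite and non-missing")
  }
  if (any(t < 0)) stop("visit times must be non-negative (years from onset)")
  if (any(y < scale$y_min | y > scale$y_max)) {
    stop(sprintf("scores outside scale bounds [%g, %g]",
                 scale$y_min, scale$y_max))
  }
  ord <- order(t)
  t <- t[ord]; y <- y[ord]
  if (anyDuplicated(t)) {
    warning(sprintf("subject %s: duplicate visit times averaged",
                    as.character(subject_id)))
    y <- as.numeric(tapply(y, t, mean))
    t <- sort(unique(t))
  }
  structure(list(subject_id = as.character(subject_id),
                 visits = data.frame(t = t, y = y),
                 scale = scale, anchored = isTRUE(anchored),
                 metadata = metadata),
            class = "patient_trajectory")
}

#' @export
print.patient_trajectory <- function(x, ...) {
  cat(sprintf("<patient_trajectory> %s: %d visit(s) over [%.2f, %.2f] yr on %s%s\n",
              x$subject_id, nrow(x$visits), min(x$visits$t), max(x$visits$t),
              x$scale$name, if (x$anchored) " (anchored)" else ""))
  invisible(x)
}

#' Measured (non-anchor) visits of a trajectory
#'
#' @param traj A [patient_trajectory()].
#' @return Data frame of visits excluding the imputed onset anchor, if any.
#' @export
measured_visits <- function(traj) {
  stopifnot(inherits(traj, "patient_trajectory"))
  if (traj$anchored) traj$visits[-1L, , drop = FALSE] else traj$visits
}

#' Impute the onset anchor
#'
#' Prepends the imputed onset-anchor observation `(0, y_max)`: the maximum
#' score of the clinical metric, assigned to the date of symptom onset. The
#' anchor pins every trajectory's start, which both regularises sparse fits
#' and puts all subjects on a common time origin.
#'
#' A trajectory that is already anchored cannot be anchored again, and a
#' measured visit at exactly `t = 0` blocks anchoring (two observations at
#' one timepoint with conflicting values); shift or drop such a visit first.
#'
#' @param traj A [patient_trajectory()].
#' @return The anchored trajectory; original visits are unchanged.
#' @examples
#' sc <- score_scale("alsfrsr")
#' tr <- patient_trajectory("a", t = 1, y = 40, scale = sc)
#' add_onset_anchor(tr)$visits  # (0, 48), (1, 40)
#' @export
add_onset_anchor <- function(traj) {
  stopifnot(inherits(traj, "patient_trajectory"))
  if (traj$anchored) stop("trajectory is already anchored")
  if (any(traj$visits$t == 0)) {
    stop("measured visit at t = 0 blocks anchoring; shift or drop it first")
  }
  traj$visits <- rbind(data.frame(t = 0, y = traj$scale$y_max), traj$visits)
  traj$anchored <- TRUE
  traj
}

#' Anchor every trajectory in a cohort
#'
#' @param trajs List of [patient_trajectory()] objects.
#' @return List of anchored trajectories.
#' @export
anchor_cohort <- function(trajs) lapply(trajs, add_onset_anchor)

#' Quality-control filtering of a cohort
#'
#' Applies the standard inclusion rules for trajectory modelling, in order:
#' a subject is excluded when (1) fewer than `min_visits` complete visits
#' were recorded, (2) the first visit is more than `max_first_visit_yr`
#' years from symptom onset, or (3) an increase of more than `max_jump`
#' points between consecutive visits was recorded (likely data entry error;
#' declines of any size pass). The first rule that fires is the one
#' reported. The defaults are the rules used for ALSFRS-R cohorts.
#'
#' Filters apply to measured visits only, so trajectories must be
#' unanchored.
#'
#' @param trajs List of unanchored [patient_trajectory()] objects.
#' @param min_visits Minimum number of complete visits (default 3).
#' @param max_first_visit_yr Latest admissible first visit, years from onset
#'   (default 7).
#' @param max_jump Largest admissible score increase between consecutive
#'   visits, in points (default 6).
#' @return A list with elements `trajectories` (the retained subset, input
#'   order preserved) and `report`, a `qc_report` with fields `n_input`,
#'   `n_retained` and `exclusions` (data.frame: `subject_id`, `reason`).
#' @export
apply_qc_filters <- function(trajs, min_visits = 3, max_first_visit_yr = 7,
                             max_jump = 6) {
  stopifnot(is.list(trajs))
  if (any(vapply(trajs, function(x) isTRUE(x$anchored), logical(1)))) {
    stop("QC filters apply to measured visits; unanchor trajectories first")
  }
  reasons <- vapply(trajs, function(tr) {
    v <- tr$visits
    if (nrow(v) < min_visits) return("too_few_visits")
    if (v$t[1L] > max_first_visit_yr) return("late_first_visit")
    if (nrow(v) >= 2L && any(diff(v$y) > max_jump)) return("score_jump")
    NA_character_
  }, character(1))
  keep <- is.na(reasons)
  exclusions <- data.frame(
    subject_id = vapply(trajs[!keep], `[[`, character(1), "subject_id"),
    reason = reasons[!keep],
    stringsAsFactors = FALSE)
  report <- structure(list(n_input = length(trajs),
                           n_retained = sum(keep),
                           exclusions = exclusions),
                      class = "qc_report")
  list(trajectories = trajs[keep], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d input, %d retained, %d excluded\n",
              x$n_input, x$n_retained, nrow(x$exclusions)))
  if (nrow(x$exclusions)) print(table(x$exclusions$reason))
  invisible(x)
}

#' Read a long-format visit table
#'
#' Reads a delimited table with one row per visit and builds one
#' [patient_trajectory()] per subject, visits sorted by time. Rows with a
#' missing or unparseable time or score are dropped and counted (available
#' as `attr(result, "n_dropped")`); the read fails only if no row parses.
#'
#' @param path Path to a CSV/TSV file.
#' @param scale A [score_scale()].
#' @param column_map Named character vector mapping the canonical names
#'   `subject_id`, `time_years`, `score` to the file's column names.
#' @param sep Field separator (default `","`).
#' @param metadata Optional data frame (or path to a CSV) keyed by
#'   `subject_id`; matching rows are attached as per-subject metadata.
#' @return List of `patient_trajectory`, with attribute `n_dropped`.
#' @export
read_long_format <- function(path, scale,
                             column_map = c(subject_id = "subject_id",
                                            time_years = "time_years",
                                            score = "score"),
                             sep = ",", metadata = NULL) {
  stopifnot(inherits(scale, "score_scale"))
  need <- c("subject_id", "time_years", "score")
  if (!all(need %in% names(column_map))) {
    stop("column_map must name subject_id, time_years and score")
  }
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
  missing_cols <- setdiff(unname(column_map[need]), names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  sub <- as.character(df[[column_map[["subject_id"]]]])
  tt <- suppressWarnings(as.numeric(df[[column_map[["time_years"]]]]))
  yy <- suppressWarnings(as.numeric(df[[column_map[["score"]]]]))
  ok <- !is.na(tt) & !is.na(yy) & !is.na(sub)
  if (!any(ok)) stop("no parseable rows in ", path)
  n_dropped <- sum(!ok)
  sub <- sub[ok]; tt <- tt[ok]; yy <- yy[ok]

  meta_df <- NULL
  if (!is.null(metadata)) {
    meta_df <- if (is.character(metadata)) {
      utils::read.csv(metadata, stringsAsFactors = FALSE)
    } else as.data.frame(metadata)
    if (!"subject_id" %in% names(meta_df)) {
      stop("metadata must contain a subject_id column")
    }
  }

  ids <- unique(sub)
  trajs <- lapply(ids, function(id) {
    sel <- sub == id
    md <- list()
    if (!is.null(meta_df)) {
      row <- meta_df[match(id, as.character(meta_df$subject_id)), , drop = FALSE]
      if (nrow(row) == 1L && !is.na(row$subject_id)) {
        md <- as.list(row[setdiff(names(row), "subject_id")])
      }
    }
    patient_trajectory(id, tt[sel], yy[sel], scale, metadata = md)
  })
  attr(trajs, "n_dropped") <- n_dropped
  trajs
}

#' Write a cohort in canonical long format
#'
#' @param trajs List of [patient_trajectory()] objects.
#' @param path Output CSV path.
#' @param include_anchor Include imputed anchor rows (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_long_format <- function(trajs, path, include_anchor = FALSE) {
  rows <- lapply(trajs, function(tr) {
    v <- if (include_anchor) tr$visits else measured_visits(tr)
    data.frame(subject_id = tr$subject_id, time_years = v$t, score = v$y,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a QC report
#'
#' @param report A `qc_report` from [apply_qc_filters()].
#' @param path Output path; `.json` extension selects JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(n_input = report$n_input,
                              n_retained = report$n_retained,
                              exclusions = report$exclusions),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(report$exclusions, path, row.names = FALSE)
  }
  invisible(path)
}
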