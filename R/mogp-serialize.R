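#' Serialize a fitted mixture model to disk
#'
#' Writes a directory containing `model.json` (scale, concentration, seed,
#' config snapshot, per-cluster hyperparameters and member ids, the
#' assignment map) and `visits.csv` (the pooled member visits per cluster,
#' printed at full double precision) — together sufficient to reconstruct
#' every cluster posterior exactly. The fit trace is written to `trace.csv`
#' when present.
#'
#' @param model A fitted [fit_mogp()] model.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_mogp()]
#' @export
write_mogp <- function(model, dir) {
  stopifnot(inherits(model, "mogp_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cl_json <- lapply(model$clusters, function(cl) {
    list(cluster_id = cl$cluster_id,
         member_ids = as.list(cl$member_ids),
         hyper = jsonlite::fromJSON(hyperparams_to_json(cl$hyper)))
  })
  cfg <- model$config
  meta <- list(
    package = "mogp",
    scale = list(name = model$scale$name, y_min = model$scale$y_min,
                 y_max = model$scale$y_max),
    alpha = model$alpha, margin = model$margin, seed = model$seed,
    shuffled = model$shuffled, log_joint = model$log_joint,
    prior_hyper = jsonlite::fromJSON(hyperparams_to_json(model$prior_hyper)),
    config = list(alpha = cfg$alpha, margin = cfg$margin,
                  n_sweeps = cfg$n_sweeps, early_stop = cfg$early_stop,
                  kernel = cfg$kernel, optimize_maxit = cfg$optimize_maxit,
                  optimize_every = cfg$optimize_every,
                  alpha_prior = cfg$alpha_prior),
    assignments = as.list(model$assignments),
    clusters = cl_json)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  rows <- do.call(rbind, lapply(model$clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id,
               t = sprintf("%.17g", cl$t),
               y = sprintf("%.17g", cl$y), stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, file.path(dir, "visits.csv"), row.names = FALSE)
  # authoritative full-precision hyperparameters (model.json repeats them
  # at reduced precision for readability)
  hrows <- do.call(rbind, lapply(c(model$clusters,
                                   list(list(cluster_id = ".prior",
                                             hyper = model$prior_hyper))),
                                 function(cl) {
    h <- cl$hyper
    data.frame(cluster_id = cl$cluster_id,
               signal_variance = sprintf("%.17g", h$signal_variance),
               length_scale = sprintf("%.17g", h$length_scale),
               noise_variance = sprintf("%.17g", h$noise_variance),
               mean_slope = sprintf("%.17g", h$mean_slope),
               mean_intercept = sprintf("%.17g", h$mean_intercept),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(hrows, file.path(dir, "hyperparams.csv"),
                   row.names = FALSE)
  if (!is.null(model$trace)) {
    utils::write.csv(model$trace, file.path(dir, "trace.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Load a serialized mixture model
#'
#' @param dir Directory written by [write_mogp()].
#' @return A `mogp_model` whose cluster posteriors reproduce the saved
#'   model's predictions exactly.
#' @export
read_mogp <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "model.json"),
                             simplifyVector = FALSE)
  visits <- utils::read.csv(file.path(dir, "visits.csv"),
                            stringsAsFactors = FALSE)
  hdf <- utils::read.csv(file.path(dir, "hyperparams.csv"),
                         stringsAsFactors = FALSE)
  hyper_of <- function(cid) {
    r <- hdf[hdf$cluster_id == cid, , drop = FALSE]
    gp_hyperparams(as.numeric(r$signal_variance),
                   as.numeric(r$length_scale),
                   as.numeric(r$noise_variance),
                   mean_slope = as.numeric(r$mean_slope),
                   mean_intercept = as.numeric(r$mean_intercept),
                   length_scale_floor = 0)
  }
  scale <- score_scale(meta$scale$name, y_max = meta$scale$y_max,
                       y_min = meta$scale$y_min)
  cfg <- meta$config
  config <- mogp_config(alpha = cfg$alpha,
                        margin = if (is.null(cfg$margin)) NULL else cfg$margin,
                        n_sweeps = cfg$n_sweeps, early_stop = cfg$early_stop,
                        kernel = cfg$kernel,
                        optimize_maxit = cfg$optimize_maxit,
                        optimize_every = cfg$optimize_every,
                        alpha_prior = if (is.null(cfg$alpha_prior)) NULL else
                          unlist(cfg$alpha_prior))
  clusters <- lapply(meta$clusters, function(cj) {
    sel <- visits$cluster_id == cj$cluster_id
    structure(list(cluster_id = cj$cluster_id,
                   member_ids = unlist(cj$member_ids),
                   hyper = hyper_of(cj$cluster_id),
                   kernel = cfg$kernel,
                   t = as.numeric(visits$t[sel]),
                   y = as.numeric(visits$y[sel]),
                   scale = scale),
              class = "mogp_cluster")
  })
  names(clusters) <- vapply(meta$clusters, `[[`, character(1), "cluster_id")
  assignments <- unlist(meta$assignments)
  trace_path <- file.path(dir, "trace.csv")
  trace <- if (file.exists(trace_path)) {
    utils::read.csv(trace_path, stringsAsFactors = FALSE)
  } else NULL
  structure(list(clusters = clusters, assignments = assignments,
                 alpha = meta$alpha, margin = meta$margin,
                 prior_hyper = hyper_of(".prior"),
                 trace = trace, log_joint = meta$log_joint,
                 n_repair_moves = NA_integer_, seed = meta$seed,
                 config = config, scale = scale,
                 shuffled = isTRUE(meta$shuffled)),
            class = "mogp_model")
}

#' Per-cluster summary table
#'
#' One row per cluster, sorted by size (largest first): size, first-year
#' slope of the mean function, length-scale, mean-function slope and signal
#' variance.
#'
#' @param model A fitted [fit_mogp()] model.
#' @return Data frame.
#' @export
cluster_summary <- function(model) {
  stopifnot(inherits(model, "mogp_model"))
  rows <- lapply(model$clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id,
               n_members = length(cl$member_ids),
               first_year_slope = first_year_slope(cl),
               length_scale = cl$hyper$length_scale,
               mean_slope = cl$hyper$mean_slope,
               signal_variance = cl$hyper$signal_variance,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$n_members, decreasing = TRUE), , drop = FALSE]
}
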