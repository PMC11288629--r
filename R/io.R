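#' @title Configuration files, checkpoints and exports
#'
#' @description
#' Effectors and environments can be described in JSON configuration
#' files; trained policies are checkpointed as flat CSV matrices with a
#' JSON manifest; trajectories and curve samples export to CSV. All
#' formats are plain text.
#'
#' @name io
NULL

#' Build an effector from a configuration list or JSON file
#'
#' Recognized fields: `effector` (`"RigidTendonArm26"` or
#' `"ReluPointMass24"`), `geometry`, `skeleton` (named overrides for
#' [two_link_params()] / [point_mass_params()]; angles in degrees are
#' accepted via `q_lower_deg`/`q_upper_deg`), `muscle` (overrides for
#' [muscle_params()]).
#'
#' @param config list or path to a JSON file
#' @return an [effector()]
#' @export
effector_from_config <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  name <- config$effector %||% "RigidTendonArm26"
  sk <- config$skeleton %||% list()
  if (!is.null(sk$q_lower_deg)) { sk$q_lower <- sk$q_lower_deg * pi / 180; sk$q_lower_deg <- NULL }
  if (!is.null(sk$q_upper_deg)) { sk$q_upper <- sk$q_upper_deg * pi / 180; sk$q_upper_deg <- NULL }
  mu <- config$muscle %||% list()
  if (name == "RigidTendonArm26") {
    mc <- do.call(muscle_params, c(list(max_isometric_force = 1), mu))
    RigidTendonArm26(geometry = config$geometry %||% "polynomial",
                     skeleton_params = do.call(two_link_params, sk),
                     muscle_config = mc)
  } else if (name == "ReluPointMass24") {
    do.call(ReluPointMass24, sk[intersect(names(sk), "mass")])
  } else stop("unknown effector: ", name, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a task environment from a configuration list or JSON file
#'
#' Fields: `task`, `horizon`, `curl_b`, `perturb`, `catch_p`,
#' `n_targets`, `go_time`, `random_go`, and a `feedback` block passed to
#' [feedback_config()] (delays in seconds).
#'
#' @param eff [effector()]
#' @param config list or path to a JSON file
#' @return a [task_env()]
#' @export
env_from_config <- function(eff, config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  fb <- do.call(feedback_config, config$feedback %||% list())
  args <- config[setdiff(names(config), c("feedback", "effector",
                                          "skeleton", "muscle"))]
  do.call(task_env, c(list(eff = eff, fb = fb), args))
}

#' Save / load a policy checkpoint (CSV matrices + JSON manifest)
#'
#' @param params policy parameter list
#' @param dir output directory (created if missing)
#' @param meta named list stored in the manifest (seed, batches, ...)
#' @return invisibly, the manifest path
#' @export
save_checkpoint <- function(params, dir, meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in names(params))
    utils::write.csv(params[[k]], file.path(dir, paste0(k, ".csv")),
                     row.names = FALSE)
  manifest <- c(list(parameters = names(params),
                     dims = lapply(params, dim),
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                meta)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint`: the parameter list
#' @export
load_checkpoint <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  params <- lapply(manifest$parameters, function(k)
    as.matrix(utils::read.csv(file.path(dir, paste0(k, ".csv")))))
  params <- lapply(params, function(p) { dimnames(p) <- NULL; p })
  stats::setNames(params, manifest$parameters)
}

#' Export a trajectory array to CSV (long format)
#'
#' @param traj `T x B x 2` array (e.g. from a protocol's `trajectories`)
#' @param path output file
#' @return invisibly, the path
#' @export
write_trajectories_csv <- function(traj, path) {
  Tn <- dim(traj)[1L]; B <- dim(traj)[2L]
  df <- data.frame(step = rep(seq_len(Tn), B),
                   trial = rep(seq_len(B), each = Tn),
                   x = as.vector(traj[, , 1L]),
                   y = as.vector(traj[, , 2L]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Sample the Hill muscle curves to a data.frame
#'
#' @param params [muscle_params()]
#' @param n samples per curve
#' @return data.frame with normalized length/velocity grids and the
#'   force-length (FL), force-velocity (FV) and passive (FP) factors
#' @export
muscle_curve_samples <- function(params, n = 201L) {
  ln <- seq(0.4, 1.8, length.out = n)
  vn <- seq(-1.2, 1.2, length.out = n)
  data.frame(norm_length = ln,
             FL = as.numeric(.fl_curve(matrix(ln, 1L), params$fl_width)),
             FP = as.numeric(.fp_curve(matrix(ln, 1L),
                                       params$normalized_slack_length,
                                       params$pe_shape, params$pe_strain)),
             norm_velocity = vn,
             FV = as.numeric(.fv_curve(matrix(vn, 1L), params$fv_af,
                                       params$fv_flen)))
}
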