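#' Write / read an optimization history as CSV
#'
#' One row per acquisition: parameter columns, one column per objective,
#' trial id and iteration index.
#'
#' @param history Data.frame history (e.g. \code{mo_run$history}) or an
#'   \code{objective_history}.
#' @param path File path.
#' @param trial Trial identifier stored in the \code{trial} column.
#' @param parameter_names Names for the configuration columns when
#'   \code{history} is an \code{objective_history}.
#' @return \code{read_history_csv} returns a data.frame.
#' @export
write_history_csv <- function(history, path, trial = 1L,
                              parameter_names = NULL) {
  if (inherits(history, "objective_history")) {
    cfg <- history$configs
    if (!is.null(parameter_names)) colnames(cfg) <- parameter_names
    history <- data.frame(iteration = seq_len(history$N), cfg,
                          value = history$observations,
                          check.names = FALSE)
  }
  df <- cbind(trial = trial, history)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_history_csv
#' @export
read_history_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Persist a full optimization run record
#'
#' Writes a run directory in the package's standard layout: config.yaml
#' (space, kernel spec, objectives, T, seed), history.csv, per-round
#' option clouds under clouds/ and a JSON summary.
#'
#' @param run An \code{mo_run}.
#' @param dir Output directory (created).
#' @param space A \code{parameter_space}.
#' @param spec A \code{kernel_spec}.
#' @param seed Seed used for the run.
#' @param trial Trial id.
#' @return The directory path, invisibly.
#' @export
write_run_record <- function(run, dir, space, spec, seed = NA, trial = 1L) {
  stopifnot(inherits(run, "mo_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "clouds"), showWarnings = FALSE)
  yaml::write_yaml(list(
    names = space$names,
    values = space$values,
    lambda = spec$lambda,
    theta_norm_bound = spec$theta_norm_bound,
    noise_var_bounds = c(spec$noise_var_lower, spec$noise_var_upper),
    bandwidths = spec$bandwidths,
    T = nrow(run$history), seed = seed),
    file.path(dir, "config.yaml"), precision = 15L)
  write_history_csv(run$history, file.path(dir, "history.csv"),
                    trial = trial)
  for (t in seq_along(run$clouds)) {
    cl <- run$clouds[[t]]
    df <- data.frame(cl$configs, cl$values, check.names = FALSE)
    utils::write.csv(df, file.path(dir, "clouds",
                                   sprintf("round_%03d.csv", t)),
                     row.names = FALSE)
  }
  objs <- setdiff(names(run$history), c("iteration", space$names))
  jsonlite::write_json(
    list(iterations = nrow(run$history),
         failures = sum(run$failed),
         selections = run$selections,
         final_means = as.list(colMeans(
           run$history[objs], na.rm = TRUE))),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
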