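#' Build an option cloud from per-objective posteriors
#'
#' Independently draws one function per objective from its kernel posterior
#' and joins the per-configuration values into multi-objective option
#' vectors — one option per grid configuration.
#'
#' @param posteriors Named list of \code{kernel_posterior}, one per
#'   objective, all sharing the grid.
#' @param senses Character vector ("maximize"/"minimize") per objective;
#'   recycled from "maximize".
#' @return An object of class \code{option_cloud}: \code{configs} (grid
#'   matrix), \code{values} (grid x objectives matrix),
#'   \code{objective_names}, \code{senses}.
#' @export
build_option_cloud <- function(posteriors,
                               senses = rep("maximize", length(posteriors))) {
  if (length(posteriors) == 0) stop("need at least one posterior")
  if (is.null(names(posteriors)))
    names(posteriors) <- paste0("objective", seq_along(posteriors))
  g0 <- posteriors[[1]]$grid
  for (p in posteriors) {
    stopifnot(inherits(p, "kernel_posterior"))
    if (!isTRUE(all.equal(p$grid, g0)))
      stop("posteriors do not share the grid")
  }
  senses <- rep_len(senses, length(posteriors))
  values <- vapply(posteriors, sample_function, numeric(nrow(g0)))
  values <- matrix(values, nrow = nrow(g0),
                   dimnames = list(NULL, names(posteriors)))
  structure(list(configs = g0, values = values,
                 objective_names = names(posteriors), senses = senses),
            class = "option_cloud")
}

#' Pick a configuration from an option cloud
#'
#' @param cloud An \code{option_cloud}.
#' @param pref A preference function: \code{function(cloud)} returning the
#'   index of the chosen option.
#' @return List with \code{index} and \code{config} (numeric vector).
#' @export
choose_option <- function(cloud, pref) {
  stopifnot(inherits(cloud, "option_cloud"))
  if (nrow(cloud$values) == 0) stop("empty option cloud")
  idx <- pref(cloud)
  if (!is.numeric(idx) || length(idx) != 1 || is.na(idx) ||
      idx < 1 || idx > nrow(cloud$values) || idx != round(idx))
    stop("preference returned an out-of-range option index")
  list(index = as.integer(idx), config = cloud$configs[idx, ])
}

#' Preference that maximizes a single objective coordinate
#'
#' The identity preference for single-objective use: picks the option with
#' the largest (or smallest) value of one coordinate, ties broken by the
#' lowest option index.
#'
#' @param objective Coordinate name or index (default 1).
#' @param sense "maximize" or "minimize".
#' @return A preference function.
#' @export
preference_single <- function(objective = 1L,
                              sense = c("maximize", "minimize")) {
  sense <- match.arg(sense)
  function(cloud) {
    v <- cloud$values[, objective]
    select_config(v, sense)
  }
}

#' Scalarizing preference from a utility function over option vectors
#'
#' @param utility Function mapping an options matrix (one option per row)
#'   to a numeric utility per option; the option with the highest utility
#'   is chosen (ties: lowest index).
#' @return A preference function.
#' @export
preference_utility <- function(utility) {
  function(cloud) {
    u <- utility(cloud$values)
    select_config(as.numeric(u), "maximize")
  }
}

#' Multi-objective online optimization with Kernel Thompson sampling
#'
#' Each round maintains one independent kernel regression model per
#' objective (models never share observations across objectives), draws
#' one function per posterior, joins the draws into an option cloud, lets
#' the preference pick an option, acquires an image at the chosen
#' configuration, evaluates all objectives on it and appends them to the
#' per-objective histories. Failed acquisitions are recorded (configuration
#' retained, objectives NA) and excluded from regression.
#'
#' @param acquire Function(config_index, config_row) returning a named list
#'   or vector of objective values (NA/NULL on failure).
#' @param objective_names Character vector of objective names to extract
#'   from the acquisition result.
#' @param space A \code{parameter_space}.
#' @param spec A single \code{kernel_spec} shared by all objectives, or a
#'   named list of specs per objective.
#' @param pref A preference function over option clouds.
#' @param T Iteration budget (>= 1).
#' @param senses Optimization direction per objective.
#' @return List of class \code{mo_run}: \code{selections}, \code{history}
#'   (data.frame: iteration, parameters, objectives), \code{clouds}
#'   (per-round option clouds), \code{choices}, \code{failed}.
#' @export
run_optimization <- function(acquire, objective_names, space, spec, pref, T,
                             senses = rep("maximize",
                                          length(objective_names))) {
  stopifnot(T >= 1, inherits(space, "parameter_space"))
  K <- length(objective_names)
  senses <- rep_len(senses, K)
  specs <- if (inherits(spec, "kernel_spec"))
    stats::setNames(rep(list(spec), K), objective_names)
  else spec[objective_names]
  G <- grid_matrix(space)
  histories <- stats::setNames(lapply(seq_len(K), function(i)
    objective_history(matrix(numeric(0), 0, ncol(G)), numeric(0))),
    objective_names)
  selections <- integer(T)
  failed <- logical(T)
  clouds <- vector("list", T)
  choices <- integer(T)
  obs <- matrix(NA_real_, T, K, dimnames = list(NULL, objective_names))
  for (t in seq_len(T)) {
    posteriors <- stats::setNames(lapply(objective_names, function(nm)
      compute_posterior(histories[[nm]], space, specs[[nm]])),
      objective_names)
    cloud <- build_option_cloud(posteriors, senses)
    clouds[[t]] <- cloud
    ch <- choose_option(cloud, pref)
    selections[t] <- ch$index
    choices[t] <- ch$index
    res <- tryCatch(acquire(ch$index, ch$config), error = function(e) NULL)
    for (k in seq_len(K)) {
      nm <- objective_names[k]
      y <- if (is.null(res)) NA_real_ else
        suppressWarnings(as.numeric(res[[nm]]))
      if (length(y) != 1) y <- NA_real_
      obs[t, k] <- y
      histories[[nm]] <- history_append(histories[[nm]], ch$config, y)
    }
    failed[t] <- is.null(res)
  }
  hist_df <- data.frame(iteration = seq_len(T), G[selections, , drop = FALSE],
                        obs, check.names = FALSE)
  structure(list(selections = selections, history = hist_df,
                 objective_histories = histories, clouds = clouds,
                 choices = choices, failed = failed, space = space),
            class = "mo_run")
}
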