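#' Discretized acquisition-parameter space
#'
#' A parameter space is the Cartesian product of per-dimension ordered value
#' lists, e.g. the 12 evenly spaced laser excitation powers of a replay
#' experiment, or a 3-D grid over dwelltime, excitation and depletion power.
#' The grid is enumerated row-major over the dimensions in declared order
#' (the first dimension varies fastest), which fixes the index every
#' tie-breaking rule in the package refers to.
#'
#' @param values Named list; one strictly increasing numeric vector of
#'   allowed values per parameter. Names become the parameter names.
#' @return An object of class \code{parameter_space} with elements
#'   \code{dims}, \code{names}, \code{values}, \code{ranges} (per-dimension
#'   span, same units as the parameter) and \code{grid} (a data.frame with
#'   one row per configuration).
#' @examples
#' sp <- parameter_space(list(excitation = seq(0.2, 21.1, length.out = 12)))
#' sp$dims
#' nrow(sp$grid)
#' @export
parameter_space <- function(values) {
  if (!is.list(values) || length(values) == 0L)
    stop("'values' must be a non-empty named list of numeric vectors")
  nm <- names(values)
  if (is.null(nm) || any(nm == ""))
    stop("every dimension of a parameter space must be named")
  for (i in seq_along(values)) {
    v <- values[[i]]
    if (!is.numeric(v) || length(v) < 2L)
      stop("dimension '", nm[i], "' needs at least 2 numeric values")
    if (any(diff(v) <= 0))
      stop("values of dimension '", nm[i], "' must be strictly increasing")
  }
  ranges <- vapply(values, function(v) max(v) - min(v), numeric(1))
  grid <- expand.grid(values, KEEP.OUT.ATTRS = FALSE)
  structure(
    list(dims = length(values), names = nm, values = values,
         ranges = unname(ranges), grid = grid),
    class = "parameter_space")
}

#' @export
print.parameter_space <- function(x, ...) {
  cat("Parameter space:", x$dims, "dimension(s),", nrow(x$grid),
      "grid configurations\n")
  for (i in seq_len(x$dims))
    cat(sprintf("  %s: %d values in [%g, %g]\n", x$names[i],
                length(x$values[[i]]), min(x$values[[i]]),
                max(x$values[[i]])))
  invisible(x)
}

#' Grid configurations as a numeric matrix
#'
#' @param space A \code{parameter_space}.
#' @return Numeric matrix, one row per grid configuration, columns in
#'   dimension order.
#' @export
grid_matrix <- function(space) {
  stopifnot(inherits(space, "parameter_space"))
  m <- as.matrix(space$grid)
  dimnames(m) <- list(NULL, space$names)
  m
}

#' Default anisotropic kernel bandwidths
#'
#' The default bandwidth for dimension i is \eqn{\rho_i = \ell_i D / 3},
#' where \eqn{\ell_i} is the span of the values of parameter i and D the
#' number of parameters. See the methods vignette for a discussion of this
#' formula; the variant \eqn{\ell_i / (3 D)} is available through
#' \code{divide_by_dims = TRUE}.
#'
#' @param space A \code{parameter_space}.
#' @param divide_by_dims If \code{TRUE}, use \eqn{\ell_i / (3 D)} instead.
#' @return Numeric vector of per-dimension bandwidths (parameter units).
#' @export
default_bandwidths <- function(space, divide_by_dims = FALSE) {
  stopifnot(inherits(space, "parameter_space"))
  if (isTRUE(divide_by_dims)) space$ranges / (3 * space$dims)
  else space$ranges * space$dims / 3
}

#' Kernel regression specification
#'
#' Bundles the hyperparameters of the kernelized regression model: the
#' per-dimension Gaussian kernel bandwidths, the ridge regularizer
#' \eqn{\lambda}, a bound on the norm of the weight vector in feature space,
#' and lower/upper bounds used by the empirical noise-variance estimate.
#'
#' @param bandwidths Per-dimension bandwidth \eqn{\rho_i > 0} (parameter
#'   units).
#' @param lambda Ridge regularizer \eqn{\lambda > 0} (dimensionless).
#'   Default 1, which makes the prior variance equal to the noise estimate.
#' @param theta_norm_bound Upper bound on the norm of the feature-space
#'   weights; used only to validate the scale of synthetic ground truths.
#' @param noise_var_lower,noise_var_upper Bounds on the observation noise
#'   variance (objective units squared). Defaults 0.001 and 0.3; 3 is
#'   appropriate for intensity-scale objectives such as the uncaging
#'   maximal intensity.
#' @return An object of class \code{kernel_spec}.
#' @export
kernel_spec <- function(bandwidths, lambda = 1, theta_norm_bound = 5,
                        noise_var_lower = 0.001, noise_var_upper = 0.3) {
  bandwidths <- as.numeric(bandwidths)
  if (any(!is.finite(bandwidths)) || any(bandwidths <= 0))
    stop("bandwidths must be positive and finite")
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (!is.finite(theta_norm_bound) || theta_norm_bound <= 0)
    stop("theta_norm_bound must be > 0")
  if (noise_var_lower <= 0 || noise_var_upper < noise_var_lower)
    stop("need 0 < noise_var_lower <= noise_var_upper")
  structure(
    list(bandwidths = bandwidths, lambda = lambda,
         theta_norm_bound = theta_norm_bound,
         noise_var_lower = noise_var_lower,
         noise_var_upper = noise_var_upper),
    class = "kernel_spec")
}

#' Read a parameter space and kernel spec from a config file
#'
#' The config is a YAML (or JSON) block with keys \code{names},
#' \code{values}, and optionally \code{lambda}, \code{theta_norm_bound},
#' \code{noise_var_bounds} and \code{bandwidths}; when \code{bandwidths}
#' is absent the default formula applies.
#'
#' @param path Path to a YAML file.
#' @return List with elements \code{space} and \code{spec}.
#' @export
read_optimization_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$values)) stop("config must contain a 'values' block")
  vals <- lapply(cfg$values, as.numeric)
  if (!is.null(cfg$names)) names(vals) <- cfg$names
  space <- parameter_space(vals)
  bw <- if (is.null(cfg$bandwidths)) default_bandwidths(space)
        else as.numeric(cfg$bandwidths)
  nb <- if (is.null(cfg$noise_var_bounds)) c(0.001, 0.3)
        else as.numeric(cfg$noise_var_bounds)
  spec <- kernel_spec(
    bandwidths = bw,
    lambda = if (is.null(cfg$lambda)) 1 else as.numeric(cfg$lambda),
    theta_norm_bound = if (is.null(cfg$theta_norm_bound)) 5
                       else as.numeric(cfg$theta_norm_bound),
    noise_var_lower = nb[1], noise_var_upper = nb[2])
  list(space = space, spec = spec)
}
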