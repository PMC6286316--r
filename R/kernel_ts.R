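#' Ordered history of selected configurations and observed objective values
#'
#' @param configs Numeric matrix (one row per acquisition, one column per
#'   parameter) or NULL for an empty history.
#' @param observations Numeric vector of observed objective values, same
#'   length as \code{nrow(configs)}. May contain NA for failed acquisitions;
#'   NA rows are kept for the audit trail but excluded from regression.
#' @return An object of class \code{objective_history}.
#' @export
objective_history <- function(configs = NULL, observations = numeric(0)) {
  if (is.null(configs)) configs <- matrix(numeric(0), nrow = 0, ncol = 0)
  if (is.data.frame(configs)) configs <- as.matrix(configs)
  if (!is.matrix(configs)) configs <- matrix(configs, ncol = 1)
  if (nrow(configs) != length(observations))
    stop("configs and observations must have equal length")
  structure(list(configs = configs, observations = as.numeric(observations),
                 N = nrow(configs)),
            class = "objective_history")
}

#' Append one acquisition to a history
#'
#' @param history An \code{objective_history}.
#' @param config Numeric vector, one configuration.
#' @param observation Observed objective value (NA for a failed acquisition).
#' @return The extended history.
#' @export
history_append <- function(history, config, observation) {
  stopifnot(inherits(history, "objective_history"))
  config <- matrix(as.numeric(config), nrow = 1)
  cfg <- if (history$N == 0L) config else rbind(history$configs, config)
  objective_history(cfg, c(history$observations, observation))
}

## rows of the history carrying a numeric observation
.history_valid <- function(history) {
  ok <- is.finite(history$observations)
  objective_history(history$configs[ok, , drop = FALSE],
                    history$observations[ok])
}

#' Anisotropic Gaussian kernel between two configurations
#'
#' \eqn{k(x, x') = \exp(-\sum_i (x_i - x'_i)^2 / (2 \rho_i^2))}, the product
#' of independent one-dimensional Gaussian kernels with per-parameter
#' bandwidths \eqn{\rho_i}.
#'
#' @param x,x2 Numeric vectors of equal length D.
#' @param spec A \code{kernel_spec} whose bandwidth vector has length D.
#' @return Similarity in (0, 1].
#' @export
kernel_value <- function(x, x2, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  x <- as.numeric(x); x2 <- as.numeric(x2)
  if (length(x) != length(x2) || length(x) != length(spec$bandwidths))
    stop("configuration dimensions do not match the kernel bandwidths")
  exp(-sum((x - x2)^2 / (2 * spec$bandwidths^2)))
}

#' Kernel matrix between two sets of configurations
#'
#' @param A,B Numeric matrices with one configuration per row and D columns.
#' @param spec A \code{kernel_spec}.
#' @return \code{nrow(A)} by \code{nrow(B)} matrix of kernel values.
#' @export
kernel_matrix <- function(A, B, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != length(spec$bandwidths) ||
      ncol(B) != length(spec$bandwidths))
    stop("configuration dimensions do not match the kernel bandwidths")
  As <- sweep(A, 2, spec$bandwidths, "/")
  Bs <- sweep(B, 2, spec$bandwidths, "/")
  d2 <- outer(rowSums(As^2), rowSums(Bs^2), "+") - 2 * tcrossprod(As, Bs)
  d2[d2 < 0] <- 0
  exp(-d2 / 2)
}

#' Empirical observation-noise variance, clipped to declared bounds
#'
#' The estimate is the mean squared residual between the observations and
#' the current predictive mean at the observed configurations, clipped into
#' \code{[noise_var_lower, noise_var_upper]}. With no observations the
#' upper bound is returned (maximal caution).
#'
#' @param history An \code{objective_history} (NA observations ignored).
#' @param posterior_mean_at_configs Predictive mean at the valid history
#'   configurations, in history order.
#' @param spec A \code{kernel_spec} carrying the bounds.
#' @return Scalar noise-variance estimate (objective units squared).
#' @export
estimate_noise_var <- function(history, posterior_mean_at_configs, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  h <- .history_valid(history)
  if (h$N == 0L) return(spec$noise_var_upper)
  if (length(posterior_mean_at_configs) != h$N)
    stop("predictive mean length does not match the history")
  msr <- mean((h$observations - posterior_mean_at_configs)^2)
  min(max(msr, spec$noise_var_lower), spec$noise_var_upper)
}

#' Kernel regression posterior over the parameter grid
#'
#' Computes the predictive mean
#' \eqn{f_{\lambda,N}(x) = k_N(x)^T (K_N + \lambda I)^{-1} y_N}
#' and covariance
#' \eqn{(\sigma^2/\lambda)[k(x,x') - k_N(x)^T (K_N + \lambda I)^{-1} k_N(x')]}
#' at every grid configuration, where \eqn{K_N} is the kernel matrix of the
#' N observed configurations and \eqn{k_N(x)} the vector of kernel values
#' between the history and x. The noise variance \eqn{\sigma^2} is the
#' clipped empirical estimate of \code{\link{estimate_noise_var}}. With an
#' empty history this reduces to the zero-mean prior with covariance
#' \eqn{(\sigma^2/\lambda) k(x, x')}.
#'
#' @param history An \code{objective_history}; NA observations are skipped.
#' @param space A \code{parameter_space}.
#' @param spec A \code{kernel_spec}.
#' @return An object of class \code{kernel_posterior} with elements
#'   \code{mean} (length = grid size), \code{covariance} (grid x grid),
#'   \code{grid} (the grid matrix) and \code{noise_var_used}.
#' @export
compute_posterior <- function(history, space, spec) {
  stopifnot(inherits(space, "parameter_space"), inherits(spec, "kernel_spec"))
  G <- grid_matrix(space)
  Kgg <- kernel_matrix(G, G, spec)
  h <- .history_valid(history)
  if (h$N == 0L) {
    s2 <- spec$noise_var_upper
    post <- list(mean = rep(0, nrow(G)),
                 covariance = (s2 / spec$lambda) * Kgg,
                 grid = G, noise_var_used = s2)
    class(post) <- "kernel_posterior"
    return(post)
  }
  X <- h$configs
  Knn <- kernel_matrix(X, X, spec)
  Kgn <- kernel_matrix(G, X, spec)          # grid x N
  A <- Knn + spec$lambda * diag(h$N)
  ch <- tryCatch(chol(A), error = function(e)
    stop("numerical failure factorizing (K_N + lambda I): ",
         conditionMessage(e)))
  alpha <- backsolve(ch, forwardsolve(t(ch), h$observations))
  mean_grid <- drop(Kgn %*% alpha)
  ## mean at the observed configs, for the residual-based noise estimate
  mean_at_obs <- drop(Knn %*% alpha)
  s2 <- estimate_noise_var(h, mean_at_obs, spec)
  W <- backsolve(ch, forwardsolve(t(ch), t(Kgn)))  # N x grid
  cov_grid <- (s2 / spec$lambda) * (Kgg - Kgn %*% W)
  cov_grid <- (cov_grid + t(cov_grid)) / 2
  post <- list(mean = mean_grid, covariance = cov_grid, grid = G,
               noise_var_used = s2)
  class(post) <- "kernel_posterior"
  post
}

#' Draw one function from a kernel posterior
#'
#' Samples a multivariate normal with the posterior mean and covariance
#' using a symmetric (Cholesky) factorization. If the factorization fails,
#' diagonal jitter of \code{1e-8 * trace / size} is added and escalated by
#' a factor of 10, at most 3 times, before signalling a numerical error.
#'
#' @param posterior A \code{kernel_posterior}.
#' @return Numeric vector: one sampled value per grid configuration. Uses
#'   the current R random-number state; seed with \code{set.seed} for
#'   reproducibility.
#' @export
sample_function <- function(posterior) {
  stopifnot(inherits(posterior, "kernel_posterior"))
  S <- posterior$covariance
  n <- nrow(S)
  tr <- sum(diag(S))
  if (tr <= 0) return(posterior$mean)   # degenerate: zero covariance
  z <- stats::rnorm(n)
  jit <- 1e-8 * tr / n
  for (try in 0:3) {
    Sj <- if (try == 0) S else S + diag(jit, n)
    ch <- tryCatch(chol(Sj), error = function(e) NULL)
    if (!is.null(ch)) return(posterior$mean + drop(t(ch) %*% z))
    if (try > 0) jit <- jit * 10
  }
  stop("covariance factorization failed after jitter escalation")
}

#' Select the configuration optimizing a sampled function
#'
#' @param sampled Numeric vector, one value per grid configuration.
#' @param sense "maximize" or "minimize".
#' @return Index of the selected grid configuration; ties are broken by the
#'   lowest grid index.
#' @export
select_config <- function(sampled, sense = c("maximize", "minimize")) {
  sense <- match.arg(sense)
  if (length(sampled) == 0L) stop("empty sampled vector")
  if (any(!is.finite(sampled))) stop("non-finite sampled values")
  if (sense == "maximize") which.max(sampled) else which.min(sampled)
}

#' Single-objective Kernel Thompson sampling loop
#'
#' Each round recomputes the posterior from the history, draws one function
#' from it, selects the grid configuration optimizing the draw, acquires an
#' observation there and appends it to the history.
#'
#' @param acquire Function(config_index, config_row) returning a scalar
#'   observation of the objective (NA on acquisition failure).
#' @param space A \code{parameter_space}.
#' @param spec A \code{kernel_spec}.
#' @param T Number of rounds.
#' @param sense Optimization direction for the objective.
#' @return List with \code{history} (an \code{objective_history}) and
#'   \code{selections} (integer vector of selected grid indices).
#' @export
kernel_ts_run <- function(acquire, space, spec, T,
                          sense = c("maximize", "minimize")) {
  sense <- match.arg(sense)
  stopifnot(T >= 1)
  G <- grid_matrix(space)
  history <- objective_history(matrix(numeric(0), 0, ncol(G)), numeric(0))
  selections <- integer(T)
  for (t in seq_len(T)) {
    post <- compute_posterior(history, space, spec)
    draw <- sample_function(post)
    idx <- select_config(draw, sense)
    selections[t] <- idx
    y <- acquire(idx, G[idx, ])
    history <- history_append(history, G[idx, ], y)
  }
  list(history = history, selections = selections)
}
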