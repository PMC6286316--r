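#' Ground truth for the synthetic microscope
#'
#' Declares the expected, noise-free responses of the simulated instrument
#' over the parameter grid: a smooth unimodal quality surface in [0, 1]
#' (a Gaussian bump over the normalized parameter coordinates), a
#' photobleaching surface that saturates exponentially with the product of
#' the normalized parameters, and the rendered structure — a periodic
#' ridge lattice emulating the ~180 nm axonal actin rings at 20 nm pixels.
#'
#' @param space A \code{parameter_space}.
#' @param peak Per-dimension location of the quality peak in normalized
#'   [0, 1] coordinates (default: grid center, 0.5 per dimension).
#' @param width Per-dimension width (sd) of the quality bump in normalized
#'   coordinates (default 0.22, placing roughly a third of a 1-D grid in
#'   the high-quality region).
#' @param quality_max Peak expected quality (default 0.9).
#' @param bleach_scale Saturation rate of the bleaching response
#'   (default 1.2; expected bleaching = bleach_max * (1 - exp(-rate * u))
#'   with u the mean normalized parameter value).
#' @param bleach_max Asymptotic bleaching fraction (default 0.6).
#' @param noise_sd Observation noise scale; 0 disables shot noise and
#'   bleaching jitter entirely (deterministic images).
#' @param period_nm Lattice period in nm (default 180).
#' @param pixel_size_nm Pixel size in nm (default 20).
#' @param image_size Image edge in pixels (default 64).
#' @param amplitude Peak STED lattice amplitude in photons (default 20).
#' @param background Background level in photons (default 2).
#' @param detect_min Autocorrelation amplitude below which the lattice is
#'   declared undetected — the simulator's failure rule (default 1.0, half
#'   the ideal amplitude of a noise-free lattice).
#' @param relevant_region Optional logical vector over the grid flagging
#'   the configurations counted as "relevant" for failure accounting
#'   (default: expected quality >= 0.6).
#' @return An object of class \code{ground_truth} with vectorized
#'   \code{quality_fn(configs)} and \code{bleach_fn(configs)} over
#'   normalized grid rows.
#' @export
ground_truth <- function(space, peak = NULL, width = 0.22,
                         quality_max = 0.9, bleach_scale = 1.2,
                         bleach_max = 0.6, noise_sd = 1,
                         period_nm = 180, pixel_size_nm = 20,
                         image_size = 64L, amplitude = 20, background = 2,
                         detect_min = 1.0, relevant_region = NULL) {
  stopifnot(inherits(space, "parameter_space"))
  D <- space$dims
  if (is.null(peak)) peak <- rep(0.5, D)
  if (length(peak) != D) stop("peak must have one coordinate per dimension")
  width <- rep_len(width, D)
  lo <- vapply(space$values, min, numeric(1))
  normalize <- function(configs) {
    configs <- if (is.matrix(configs)) configs else matrix(configs, ncol = D)
    sweep(sweep(configs, 2, lo, "-"), 2, space$ranges, "/")
  }
  quality_fn <- function(configs) {
    u <- normalize(configs)
    d2 <- sweep(u, 2, peak, "-")
    d2 <- sweep(d2^2, 2, 2 * width^2, "/")
    quality_max * exp(-rowSums(d2))
  }
  bleach_fn <- function(configs) {
    u <- rowMeans(normalize(configs))
    bleach_max * (1 - exp(-bleach_scale * u))
  }
  gt <- list(space = space, quality_fn = quality_fn, bleach_fn = bleach_fn,
             noise_sd = noise_sd, period_nm = period_nm,
             pixel_size_nm = pixel_size_nm, image_size = as.integer(image_size),
             amplitude = amplitude, background = background,
             detect_min = detect_min,
             quality_max = quality_max, bleach_max = bleach_max)
  if (is.null(relevant_region))
    relevant_region <- quality_fn(grid_matrix(space)) >= 0.6
  gt$relevant_region <- relevant_region
  class(gt) <- "ground_truth"
  gt
}

#' Render one synthetic acquisition triplet
#'
#' The structure is a horizontal band (the "dendrite", central half of the
#' rows) carrying a vertical periodic ridge lattice whose amplitude scales
#' with the expected quality at the configuration; outside the band only
#' background counts remain. The confocal images are diffraction-limited:
#' inside the band they carry the same mean signal but the lattice
#' contrast is washed out. Shot noise is Poisson on the expected counts
#' when \code{noise_sd > 0}; with \code{noise_sd = 0} the expected counts
#' are returned exactly. The after confocal equals the before confocal
#' with its foreground (band) pixels attenuated by the bleaching fraction
#' of the configuration (jittered when noisy).
#'
#' @param config Numeric vector, one grid configuration.
#' @param truth A \code{ground_truth}.
#' @return An \code{acquisition_triplet}. Uses the current R random state.
#' @export
generate_image <- function(config, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  n <- truth$image_size
  q <- as.numeric(truth$quality_fn(matrix(config, nrow = 1)))
  b <- as.numeric(truth$bleach_fn(matrix(config, nrow = 1)))
  period_px <- truth$period_nm / truth$pixel_size_nm
  xs <- seq_len(n)
  ## raised-cosine ridges along columns; identical in every band row
  ridge <- (1 + cos(2 * pi * xs / period_px)) / 2
  A <- truth$amplitude * q
  band <- seq.int(n %/% 4 + 1L, 3L * (n %/% 4))
  in_band <- matrix(FALSE, n, n)
  in_band[band, ] <- TRUE
  sted_expect <- matrix(truth$background, n, n)
  sted_expect[band, ] <- rep(truth$background + A * ridge, each = length(band))
  ## confocal: same band-mean signal but lattice contrast removed
  conf_expect <- matrix(truth$background, n, n)
  conf_expect[band, ] <- truth$background + A * mean(ridge)
  conf2_expect <- conf_expect
  if (truth$noise_sd > 0) {
    b_eff <- min(max(stats::rnorm(1, b, 0.02 * truth$noise_sd), 0), 1)
    conf2_expect[in_band] <- conf_expect[in_band] * (1 - b_eff)
    sted <- matrix(stats::rpois(n * n, sted_expect), n, n)
    conf1 <- matrix(stats::rpois(n * n, conf_expect), n, n)
    conf2 <- matrix(stats::rpois(n * n, conf2_expect), n, n)
  } else {
    conf2_expect[in_band] <- conf_expect[in_band] * (1 - b)
    sted <- sted_expect
    conf1 <- conf_expect
    conf2 <- conf2_expect
  }
  acquisition_triplet(conf1, sted, conf2, truth$pixel_size_nm)
}

#' Build a replay dataset
#'
#' Pre-generates \code{images_per_config} acquisition triplets per grid
#' configuration, with their objective values computed once, mirroring a
#' replay experiment built from previously acquired images (e.g. 12 laser
#' powers x 39 images = 468 images).
#'
#' @param space A \code{parameter_space}.
#' @param images_per_config Queue length per configuration (>= 1).
#' @param truth A \code{ground_truth}.
#' @param seed Integer seed; the dataset is fully determined by it.
#' @param keep_images Keep pixel data in memory (default FALSE: only the
#'   pre-computed objective values are stored, which replay needs).
#' @return An object of class \code{replay_dataset}: per-config queues of
#'   objective records, \code{n_images} total.
#' @export
build_replay_dataset <- function(space, images_per_config, truth, seed,
                                 keep_images = FALSE) {
  stopifnot(inherits(space, "parameter_space"), images_per_config >= 1)
  G <- grid_matrix(space)
  set.seed(as.integer(seed))
  queues <- vector("list", nrow(G))
  for (i in seq_len(nrow(G))) {
    q <- vector("list", images_per_config)
    for (j in seq_len(images_per_config)) {
      tr <- generate_image(G[i, ], truth)
      obj <- compute_objectives(tr)
      rec <- list(objectives = obj)
      if (keep_images) rec$triplet <- tr
      q[[j]] <- rec
    }
    queues[[i]] <- q
  }
  structure(list(space = space, queues = queues,
                 images_per_config = as.integer(images_per_config),
                 n_images = nrow(G) * as.integer(images_per_config),
                 truth = truth, seed = as.integer(seed)),
            class = "replay_dataset")
}

#' @export
print.replay_dataset <- function(x, ...) {
  cat("Replay dataset:", length(x$queues), "configurations x",
      x$images_per_config, "images =", x$n_images, "images\n")
  invisible(x)
}

#' Run one replay trial
#'
#' Shuffles every queue with the trial seed, then hands the optimizer an
#' acquisition function that pops the head of the selected configuration's
#' queue and returns its pre-computed objective value. Two algorithms
#' issuing identical selection sequences therefore observe identical
#' images. An exhausted queue recycles from its start and the event is
#' flagged.
#'
#' @param dataset A \code{replay_dataset}.
#' @param optimizer Function(acquire, space) running the algorithm;
#'   \code{acquire(config_index, config_row)} returns the objective value.
#' @param objective Name of the objective replayed to the optimizer
#'   (default "autocorrelation").
#' @param trial_seed Integer seed for the queue shuffles (and for the
#'   optimizer's own randomness, seeded just before it runs).
#' @return List with the optimizer's return value (\code{result}), the
#'   \code{selections} actually acquired, per-selection \code{values}, and
#'   \code{recycled} (TRUE if any queue wrapped around).
#' @export
replay_run <- function(dataset, optimizer, objective = "autocorrelation",
                       trial_seed = 1L) {
  stopifnot(inherits(dataset, "replay_dataset"))
  set.seed(as.integer(trial_seed))
  order_in_queue <- lapply(dataset$queues, function(q) sample(length(q)))
  pos <- integer(length(dataset$queues))
  selections <- integer(0)
  values <- numeric(0)
  recycled <- FALSE
  acquire <- function(idx, config_row) {
    pos[idx] <<- pos[idx] + 1L
    qlen <- length(dataset$queues[[idx]])
    if (pos[idx] > qlen) {
      recycled <<- TRUE
      pos[idx] <<- 1L
    }
    rec <- dataset$queues[[idx]][[order_in_queue[[idx]][pos[idx]]]]
    y <- rec$objectives[[objective]]
    selections <<- c(selections, idx)
    values <<- c(values, y)
    y
  }
  result <- optimizer(acquire, dataset$space)
  list(result = result, selections = selections, values = values,
       recycled = recycled)
}
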