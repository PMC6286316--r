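#' Grid-search acquisition plan
#'
#' @param space A \code{parameter_space}.
#' @param images_per_config Repeats per configuration (>= 1).
#' @return An object of class \code{grid_search_plan} with the full grid
#'   enumeration and \code{budget = n_configs * images_per_config}.
#' @export
grid_search_plan <- function(space, images_per_config) {
  stopifnot(inherits(space, "parameter_space"), images_per_config >= 1)
  configs <- grid_matrix(space)
  structure(list(space = space, configs = configs,
                 images_per_config = as.integer(images_per_config),
                 budget = nrow(configs) * as.integer(images_per_config)),
            class = "grid_search_plan")
}

#' Offline grid search
#'
#' Acquires \code{images_per_config} observations at every grid
#' configuration in grid order and estimates the objective at each
#' configuration by the sample mean. The best configuration is the argmax
#' of the estimates (ties: lowest grid index).
#'
#' @param plan A \code{grid_search_plan}.
#' @param acquire Function(config_index, config_row) returning a scalar
#'   observation (NA on failure; failures are excluded from the mean).
#' @param sense Optimization direction.
#' @return List: \code{history} (an \code{objective_history}),
#'   \code{selections}, \code{estimates} (per-config means),
#'   \code{best_index}.
#' @export
grid_search <- function(plan, acquire, sense = c("maximize", "minimize")) {
  sense <- match.arg(sense)
  stopifnot(inherits(plan, "grid_search_plan"))
  G <- plan$configs
  selections <- rep(seq_len(nrow(G)), each = plan$images_per_config)
  ys <- numeric(length(selections))
  for (i in seq_along(selections)) {
    idx <- selections[i]
    ys[i] <- acquire(idx, G[idx, ])
  }
  estimates <- vapply(seq_len(nrow(G)), function(i) {
    v <- ys[selections == i]
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  cmp <- if (sense == "maximize") estimates else -estimates
  best <- which.max(ifelse(is.na(cmp), -Inf, cmp))
  list(history = objective_history(G[selections, , drop = FALSE], ys),
       selections = selections, estimates = estimates, best_index = best)
}

#' Random sampling baseline
#'
#' Draws T configurations uniformly with replacement from the grid and
#' acquires one observation at each.
#'
#' @param space A \code{parameter_space}.
#' @param acquire As in \code{\link{grid_search}}.
#' @param T Number of acquisitions (>= 1).
#' @return List: \code{history}, \code{selections}.
#' @export
random_sampling <- function(space, acquire, T) {
  stopifnot(inherits(space, "parameter_space"), T >= 1)
  G <- grid_matrix(space)
  selections <- sample.int(nrow(G), T, replace = TRUE)
  ys <- vapply(selections, function(idx) acquire(idx, G[idx, ]), numeric(1))
  list(history = objective_history(G[selections, , drop = FALSE], ys),
       selections = selections)
}

## TRUE if point a dominates point b (all senses converted to maximize)
.dominates <- function(a, b) {
  all(a >= b) && any(a > b)
}

#' Non-dominated sorting of a multi-objective value set
#'
#' Front 0 is the non-dominated set; front k is the non-dominated set
#' after removing fronts < k. A point dominates another when it is no
#' worse in all objectives and strictly better in at least one.
#'
#' @param points Numeric matrix, one point per row, one objective per
#'   column.
#' @param senses "maximize"/"minimize" per objective (recycled).
#' @return List of integer index vectors, one per front.
#' @export
nondominated_sort <- function(points, senses = "maximize") {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0) return(list())
  senses <- rep_len(senses, ncol(points))
  P <- sweep(points, 2, ifelse(senses == "minimize", -1, 1), "*")
  remaining <- seq_len(n)
  fronts <- list()
  while (length(remaining) > 0) {
    nd <- vapply(remaining, function(i) {
      !any(vapply(remaining, function(j)
        j != i && .dominates(P[j, ], P[i, ]), logical(1)))
    }, logical(1))
    fronts[[length(fronts) + 1L]] <- remaining[nd]
    remaining <- remaining[!nd]
  }
  fronts
}

#' Crowding distance within one front
#'
#' Per objective, points are sorted and each interior point accumulates
#' the normalized span of its neighbours; boundary points get infinite
#' distance. Permutation-invariant and non-negative.
#'
#' @param points Numeric matrix of the front's objective values.
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0) return(numeric(0))
  d <- numeric(n)
  for (m in seq_len(ncol(points))) {
    o <- order(points[, m])
    rng <- points[o[n], m] - points[o[1], m]
    d[o[1]] <- Inf
    d[o[n]] <- Inf
    if (n > 2 && rng > 0) {
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (points[o[3:n], m] - points[o[1:(n - 2)], m]) / rng
    }
  }
  d
}

#' Bounded simulated binary crossover (SBX)
#'
#' Canonical SBX with crowding degree eta; each gene recombines with
#' probability 0.5, offspring are clipped to the box bounds.
#'
#' @param p1,p2 Parent genomes (numeric vectors).
#' @param lower,upper Box bounds per gene.
#' @param eta Crowding degree (default 20).
#' @return List of two offspring genomes.
#' @export
sbx_crossover <- function(p1, p2, lower, upper, eta = 20) {
  D <- length(p1)
  c1 <- p1; c2 <- p2
  for (i in seq_len(D)) {
    if (stats::runif(1) <= 0.5 && abs(p1[i] - p2[i]) > 1e-14) {
      x1 <- min(p1[i], p2[i]); x2 <- max(p1[i], p2[i])
      xl <- lower[i]; xu <- upper[i]
      u <- stats::runif(1)
      beta <- 1 + 2 * (x1 - xl) / (x2 - x1)
      alpha <- 2 - beta^(-(eta + 1))
      betaq <- if (u <= 1 / alpha) (u * alpha)^(1 / (eta + 1))
               else (1 / (2 - u * alpha))^(1 / (eta + 1))
      y1 <- 0.5 * ((x1 + x2) - betaq * (x2 - x1))
      beta <- 1 + 2 * (xu - x2) / (x2 - x1)
      alpha <- 2 - beta^(-(eta + 1))
      betaq <- if (u <= 1 / alpha) (u * alpha)^(1 / (eta + 1))
               else (1 / (2 - u * alpha))^(1 / (eta + 1))
      y2 <- 0.5 * ((x1 + x2) + betaq * (x2 - x1))
      y1 <- min(max(y1, xl), xu); y2 <- min(max(y2, xl), xu)
      if (stats::runif(1) <= 0.5) { c1[i] <- y2; c2[i] <- y1 }
      else { c1[i] <- y1; c2[i] <- y2 }
    }
  }
  list(c1, c2)
}

#' Bounded polynomial mutation
#'
#' Canonical polynomial mutation with crowding degree eta and independent
#' per-gene mutation probability (default 1/D).
#'
#' @param p Genome (numeric vector).
#' @param lower,upper Box bounds per gene.
#' @param eta Crowding degree (default 20).
#' @param indpb Per-gene mutation probability (default \code{1/length(p)}).
#' @return Mutated genome.
#' @export
polynomial_mutation <- function(p, lower, upper, eta = 20,
                                indpb = 1 / length(p)) {
  D <- length(p)
  for (i in seq_len(D)) {
    if (stats::runif(1) <= indpb) {
      x <- p[i]; xl <- lower[i]; xu <- upper[i]
      if (xu <= xl) next
      d1 <- (x - xl) / (xu - xl); d2 <- (xu - x) / (xu - xl)
      u <- stats::runif(1)
      mp <- 1 / (eta + 1)
      if (u < 0.5) {
        val <- 2 * u + (1 - 2 * u) * (1 - d1)^(eta + 1)
        dq <- val^mp - 1
      } else {
        val <- 2 * (1 - u) + 2 * (u - 0.5) * (1 - d2)^(eta + 1)
        dq <- 1 - val^mp
      }
      p[i] <- min(max(x + dq * (xu - xl), xl), xu)
    }
  }
  p
}

#' NSGA-II settings
#'
#' @param generations,population,images_per_evaluation Counts (defaults
#'   10, 10, 3).
#' @param eta_crossover,eta_mutation Crowding degrees (default 20).
#' @param p_mate Mating probability (default 0.9).
#' @return An object of class \code{nsga2_settings}; \code{budget} is
#'   \code{generations * population * images_per_evaluation}.
#' @export
nsga2_settings <- function(generations = 10, population = 10,
                           images_per_evaluation = 3, eta_crossover = 20,
                           eta_mutation = 20, p_mate = 0.9) {
  stopifnot(generations >= 1, population >= 1, images_per_evaluation >= 1,
            p_mate >= 0, p_mate <= 1)
  structure(list(generations = as.integer(generations),
                 population = as.integer(population),
                 images_per_evaluation = as.integer(images_per_evaluation),
                 eta_crossover = eta_crossover, eta_mutation = eta_mutation,
                 p_mate = p_mate,
                 budget = as.integer(generations) * as.integer(population) *
                   as.integer(images_per_evaluation)),
            class = "nsga2_settings")
}

## rank (front number, 0-based) per individual
.nsga2_ranks <- function(values, senses) {
  fronts <- nondominated_sort(values, senses)
  r <- integer(nrow(values))
  for (f in seq_along(fronts)) r[fronts[[f]]] <- f - 1L
  r
}

## environmental selection: best `k` individuals by (rank, crowding)
.nsga2_select <- function(values, senses, k) {
  fronts <- nondominated_sort(values, senses)
  chosen <- integer(0)
  for (f in fronts) {
    if (length(chosen) + length(f) <= k) {
      chosen <- c(chosen, f)
    } else {
      cd <- crowding_distance(values[f, , drop = FALSE])
      chosen <- c(chosen, f[order(-cd)][seq_len(k - length(chosen))])
      break
    }
  }
  chosen
}

#' NSGA-II offline multi-objective optimization
#'
#' Operates on continuous genomes within the parameter box bounds.
#' Evaluation of an individual is the mean objective vector over
#' \code{images_per_evaluation} acquisitions; every evaluation re-acquires
#' (total acquisitions = generations x population x images per
#' evaluation). Selection is by non-dominated rank then crowding distance;
#' offspring come from binary tournaments followed by bounded SBX and
#' bounded polynomial mutation.
#'
#' @param lower,upper Box bounds per parameter.
#' @param settings An \code{nsga2_settings}.
#' @param acquire Function(config_row) returning a named numeric vector of
#'   objective values for one acquisition (NA entries allowed; an
#'   individual with zero valid images gets the worst rank via -Inf/Inf).
#' @param objective_names Names of the objectives to extract.
#' @param senses "maximize"/"minimize" per objective.
#' @return List: \code{population} (genomes matrix), \code{values} (mean
#'   objective vectors), \code{n_acquisitions}, \code{history} (all
#'   evaluated genomes and values).
#' @export
nsga2_optimize <- function(lower, upper, settings, acquire, objective_names,
                           senses = rep("maximize", length(objective_names))) {
  stopifnot(inherits(settings, "nsga2_settings"))
  D <- length(lower)
  K <- length(objective_names)
  senses <- rep_len(senses, K)
  n_acq <- 0L
  worst <- ifelse(senses == "minimize", Inf, -Inf)
  evaluate <- function(genome) {
    vals <- matrix(NA_real_, settings$images_per_evaluation, K)
    for (r in seq_len(settings$images_per_evaluation)) {
      res <- tryCatch(acquire(genome), error = function(e) NULL)
      n_acq <<- n_acq + 1L
      if (!is.null(res)) vals[r, ] <- as.numeric(res[objective_names])
    }
    m <- colMeans(vals, na.rm = TRUE)
    m[!is.finite(m)] <- worst[!is.finite(m)]
    m
  }
  tournament <- function(ranks, cd) {
    pick <- function() {
      a <- sample.int(length(ranks), 1); b <- sample.int(length(ranks), 1)
      if (ranks[a] < ranks[b]) a
      else if (ranks[b] < ranks[a]) b
      else if (cd[a] >= cd[b]) a else b
    }
    pick()
  }
  P <- settings$population
  pop <- matrix(stats::runif(P * D, rep(lower, each = P),
                             rep(upper, each = P)), P, D)
  vals <- t(apply(pop, 1, evaluate))
  if (K == 1) vals <- matrix(vals, ncol = 1)
  hist_genomes <- pop
  hist_values <- vals
  for (g in seq_len(settings$generations - 1L)) {
    ranks <- .nsga2_ranks(vals, senses)
    cd <- numeric(P)
    for (f in unique(ranks)) {
      idx <- which(ranks == f)
      cd[idx] <- crowding_distance(vals[idx, , drop = FALSE])
    }
    off <- matrix(NA_real_, P, D)
    i <- 1L
    while (i <= P) {
      a <- tournament(ranks, cd); b <- tournament(ranks, cd)
      pa <- pop[a, ]; pb <- pop[b, ]
      if (stats::runif(1) <= settings$p_mate) {
        ch <- sbx_crossover(pa, pb, lower, upper, settings$eta_crossover)
      } else ch <- list(pa, pb)
      ch[[1]] <- polynomial_mutation(ch[[1]], lower, upper,
                                     settings$eta_mutation, 1 / D)
      ch[[2]] <- polynomial_mutation(ch[[2]], lower, upper,
                                     settings$eta_mutation, 1 / D)
      off[i, ] <- ch[[1]]
      if (i + 1L <= P) off[i + 1L, ] <- ch[[2]]
      i <- i + 2L
    }
    off_vals <- t(apply(off, 1, evaluate))
    if (K == 1) off_vals <- matrix(off_vals, ncol = 1)
    hist_genomes <- rbind(hist_genomes, off)
    hist_values <- rbind(hist_values, off_vals)
    comb <- rbind(pop, off)
    comb_vals <- rbind(vals, off_vals)
    keep <- .nsga2_select(comb_vals, senses, P)
    pop <- comb[keep, , drop = FALSE]
    vals <- comb_vals[keep, , drop = FALSE]
  }
  colnames(vals) <- objective_names
  list(population = pop, values = vals, n_acquisitions = n_acq,
       history = list(genomes = hist_genomes, values = hist_values))
}

#' Snap continuous genomes to the nearest grid configuration
#'
#' @param genomes Numeric matrix of genomes (one per row).
#' @param space A \code{parameter_space}.
#' @return Integer vector of nearest grid indices (per-dimension nearest
#'   value, then the row-major grid index).
#' @export
snap_to_grid <- function(genomes, space) {
  stopifnot(inherits(space, "parameter_space"))
  genomes <- as.matrix(genomes)
  sizes <- vapply(space$values, length, integer(1))
  idx_per_dim <- vapply(seq_len(space$dims), function(d)
    vapply(genomes[, d], function(x)
      which.min(abs(space$values[[d]] - x)), integer(1)),
    integer(nrow(genomes)))
  idx_per_dim <- matrix(idx_per_dim, nrow = nrow(genomes))
  mult <- cumprod(c(1L, sizes[-length(sizes)]))
  as.integer(1L + (idx_per_dim - 1L) %*% mult)
}
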