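#' One recorded preference choice
#'
#' @param cloud Numeric matrix of option vectors (one option per row, one
#'   objective per column), at least 2 options.
#' @param chosen_index Index of the option the expert chose.
#' @return An object of class \code{choice_record}.
#' @export
choice_record <- function(cloud, chosen_index) {
  cloud <- as.matrix(cloud)
  if (nrow(cloud) < 2) stop("a choice record needs at least 2 options")
  if (chosen_index < 1 || chosen_index > nrow(cloud))
    stop("chosen_index out of range")
  structure(list(cloud = cloud, chosen_index = as.integer(chosen_index)),
            class = "choice_record")
}

#' Margin ranking loss
#'
#' \eqn{l_i = \max(s_i - s_\star - m, 0)}: the network is penalized when a
#' rejected option's score exceeds the chosen option's score by more than
#' the margin. \code{variant = "hinge"} gives the conventional
#' \eqn{\max(s_i - s_\star + m, 0)}, which also penalizes score ties.
#'
#' @param s_star Score of the chosen option.
#' @param s_i Score of a rejected option.
#' @param m Margin (>= 0, default 0.1).
#' @param variant "printed" (default) or "hinge".
#' @return Non-negative loss (vectorized over \code{s_i}).
#' @export
margin_ranking_loss <- function(s_star, s_i, m = 0.1,
                                variant = c("printed", "hinge")) {
  variant <- match.arg(variant)
  stopifnot(m >= 0)
  if (variant == "printed") pmax(s_i - s_star - m, 0)
  else pmax(s_i - s_star + m, 0)
}

#' Build (chosen, rejected) training pairs from a choice record
#'
#' One pair per non-chosen option, in cloud order: a cloud of N options
#' yields N - 1 pairs.
#'
#' @param record A \code{choice_record}.
#' @return List with matrices \code{chosen} and \code{rejected} (one pair
#'   per row).
#' @export
make_pairs <- function(record) {
  stopifnot(inherits(record, "choice_record"))
  rej <- setdiff(seq_len(nrow(record$cloud)), record$chosen_index)
  list(chosen = record$cloud[rep(record$chosen_index, length(rej)), ,
                             drop = FALSE],
       rejected = record$cloud[rej, , drop = FALSE])
}

## He-style seeded initialization of the 2x10 ReLU scorer
.snn_init <- function(n_obj) {
  W1 <- matrix(stats::rnorm(n_obj * 10, 0, sqrt(2 / n_obj)), n_obj, 10)
  W2 <- matrix(stats::rnorm(100, 0, sqrt(2 / 10)), 10, 10)
  w3 <- matrix(stats::rnorm(10, 0, sqrt(2 / 10)), 10, 1)
  list(W1 = W1, b1 = rep(0.01, 10), W2 = W2, b2 = rep(0.01, 10),
       w3 = w3, b3 = 0)
}

## forward pass; returns scores and (optionally) the activations needed
## for backpropagation
.snn_forward <- function(par, X, keep = FALSE) {
  Z1 <- sweep(X %*% par$W1, 2, par$b1, "+")
  H1 <- pmax(Z1, 0)
  Z2 <- sweep(H1 %*% par$W2, 2, par$b2, "+")
  H2 <- pmax(Z2, 0)
  s <- drop(H2 %*% par$w3) + par$b3
  if (!keep) return(s)
  list(s = s, X = X, Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2)
}

## gradient of sum(g * s) w.r.t. parameters for one forward pass
.snn_backward <- function(par, fwd, g) {
  dH2 <- tcrossprod(g, drop(par$w3))          # n x 10
  dZ2 <- dH2 * (fwd$Z2 > 0)
  dH1 <- dZ2 %*% t(par$W2)
  dZ1 <- dH1 * (fwd$Z1 > 0)
  list(W1 = crossprod(fwd$X, dZ1), b1 = colSums(dZ1),
       W2 = crossprod(fwd$H1, dZ2), b2 = colSums(dZ2),
       w3 = crossprod(fwd$H2, g), b3 = sum(g))
}

.adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(par, grad, state, lr = 0.001, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(par)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grad[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

## normalize options to [0,1] per objective by the declared ranges
.normalize_options <- function(X, ranges) {
  if (is.null(ranges)) return(X)
  lo <- ranges[1, ]; hi <- ranges[2, ]
  sweep(sweep(X, 2, lo, "-"), 2, pmax(hi - lo, .Machine$double.eps), "/")
}

## mean margin ranking loss of a scorer over stacked pair matrices
.pair_loss <- function(par, chosen, rejected, m, variant) {
  sc <- .snn_forward(par, chosen)
  sr <- .snn_forward(par, rejected)
  mean(margin_ranking_loss(sc, sr, m, variant))
}

#' Train the preference-articulation scorer
#'
#' A shallow fully connected network (two hidden layers of ten rectifier
#' units, scalar output) is trained in a ranking fashion: each choice
#' record contributes one (chosen, rejected) pair per non-chosen option,
#' the loss is the mean margin ranking loss over batches of 128 pairs, and
#' the adaptive-moment optimizer (learning rate 0.001, moment decays
#' 0.9/0.999) updates the weights. Training stops when the validation loss
#' has not improved for 10 consecutive epochs; the weights with the best
#' validation loss are returned. Option vectors are normalized to [0, 1]
#' per objective by the declared ranges before scoring.
#'
#' Training defaults to the conventional hinge variant
#' \eqn{\max(s_i - s_\star + m, 0)}: under the "printed" variant a scorer
#' that gives every option the same score attains zero loss, so gradient
#' training can stall at a constant function before any ranking is
#' learned (see the methods vignette).
#'
#' @param records List of \code{choice_record}s (training).
#' @param validation List of \code{choice_record}s (validation).
#' @param obj_ranges 2 x K matrix (rows: lower, upper) of declared
#'   objective ranges, or NULL for no normalization.
#' @param margin Margin m (default 0.1).
#' @param variant Loss variant (see \code{\link{margin_ranking_loss}}).
#' @param lr Learning rate (default 0.001).
#' @param batch_size Pairs per batch (default 128).
#' @param max_epochs Epoch cap (default 200).
#' @param patience Early-stopping patience in epochs (default 10).
#' @return An object of class \code{preference_scorer}. Uses the current R
#'   random state for initialization and shuffling; seed for
#'   reproducibility.
#' @export
train_preference <- function(records, validation, obj_ranges = NULL,
                             margin = 0.1,
                             variant = c("hinge", "printed"), lr = 0.001,
                             batch_size = 128L, max_epochs = 200L,
                             patience = 10L) {
  variant <- match.arg(variant)
  if (length(records) == 0 || length(validation) == 0)
    stop("need non-empty training and validation sets")
  stack <- function(recs) {
    ps <- lapply(recs, make_pairs)
    list(chosen = do.call(rbind, lapply(ps, `[[`, "chosen")),
         rejected = do.call(rbind, lapply(ps, `[[`, "rejected")))
  }
  tr <- stack(records)
  va <- stack(validation)
  K <- ncol(tr$chosen)
  tr$chosen <- .normalize_options(tr$chosen, obj_ranges)
  tr$rejected <- .normalize_options(tr$rejected, obj_ranges)
  va$chosen <- .normalize_options(va$chosen, obj_ranges)
  va$rejected <- .normalize_options(va$rejected, obj_ranges)
  par <- .snn_init(K)
  state <- .adam_init(par)
  n_pairs <- nrow(tr$chosen)
  best <- list(par = par,
               loss = .pair_loss(par, va$chosen, va$rejected, margin,
                                 variant))
  stall <- 0L
  epochs_run <- 0L
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n_pairs)
    for (start in seq(1L, n_pairs, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n_pairs)]
      Xc <- tr$chosen[idx, , drop = FALSE]
      Xr <- tr$rejected[idx, , drop = FALSE]
      fc <- .snn_forward(par, Xc, keep = TRUE)
      fr <- .snn_forward(par, Xr, keep = TRUE)
      l <- margin_ranking_loss(fc$s, fr$s, margin, variant)
      if (any(!is.finite(l))) stop("training loss diverged (non-finite)")
      active <- as.numeric(l > 0) / length(idx)
      gr <- .snn_backward(par, fr, active)
      gc_ <- .snn_backward(par, fc, -active)
      grad <- Map(`+`, gr, gc_)
      upd <- .adam_step(par, grad, state, lr)
      par <- upd$par; state <- upd$state
    }
    epochs_run <- epoch
    vloss <- .pair_loss(par, va$chosen, va$rejected, margin, variant)
    if (vloss < best$loss - 1e-12) {
      best <- list(par = par, loss = vloss)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  structure(list(par = best$par, n_obj = K, margin = margin,
                 variant = variant, obj_ranges = obj_ranges,
                 validation_loss = best$loss, epochs = epochs_run),
            class = "preference_scorer")
}

#' Score options with a trained preference scorer
#'
#' @param scorer A \code{preference_scorer}.
#' @param cloud Numeric matrix of option vectors (one per row).
#' @return Numeric vector of scores.
#' @export
score_options <- function(scorer, cloud) {
  stopifnot(inherits(scorer, "preference_scorer"))
  X <- .normalize_options(as.matrix(cloud), scorer$obj_ranges)
  .snn_forward(scorer$par, X)
}

#' Predict the expert's choice on an option cloud
#'
#' The predicted choice is the option with the highest score; ties are
#' broken by the lowest index.
#'
#' @param scorer A \code{preference_scorer}.
#' @param cloud Option matrix or an \code{option_cloud}.
#' @return Index of the predicted option.
#' @export
predict_choice <- function(scorer, cloud) {
  X <- if (inherits(cloud, "option_cloud")) cloud$values else as.matrix(cloud)
  if (nrow(X) == 0) stop("empty cloud")
  if (any(!is.finite(X))) stop("non-finite option values")
  which.max(score_options(scorer, X))
}

#' Use a trained scorer as a preference function
#'
#' Wraps \code{\link{predict_choice}} into the preference-function
#' contract of \code{\link{choose_option}}.
#'
#' @param scorer A \code{preference_scorer}.
#' @return A preference function over option clouds.
#' @export
preference_from_scorer <- function(scorer) {
  function(cloud) predict_choice(scorer, cloud)
}

#' Save / load a preference scorer as JSON
#'
#' @param scorer A \code{preference_scorer}.
#' @param path File path.
#' @return \code{load_preference_scorer} returns the scorer.
#' @export
save_preference_scorer <- function(scorer, path) {
  stopifnot(inherits(scorer, "preference_scorer"))
  obj <- list(architecture = list(hidden = c(10L, 10L),
                                  activation = "relu",
                                  n_obj = scorer$n_obj),
              margin = scorer$margin, variant = scorer$variant,
              obj_ranges = scorer$obj_ranges,
              par = lapply(scorer$par, function(p) {
                if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
                else list(dim = NULL, data = as.numeric(p))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_preference_scorer
#' @export
load_preference_scorer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- lapply(obj$par, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2)
      matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  rng <- obj$obj_ranges
  if (length(rng) == 0) rng <- NULL
  else rng <- matrix(as.numeric(unlist(rng)), nrow = 2)
  structure(list(par = par, n_obj = obj$architecture$n_obj,
                 margin = obj$margin, variant = obj$variant,
                 obj_ranges = rng, validation_loss = NA_real_,
                 epochs = NA_integer_),
            class = "preference_scorer")
}

#' Read / write choice records as JSON lines
#'
#' One JSON object per line with fields \code{cloud} (matrix) and
#' \code{chosen_index}.
#'
#' @param records List of \code{choice_record}s.
#' @param path File path.
#' @return \code{read_choice_records} returns a list of records.
#' @export
write_choice_records <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    stopifnot(inherits(r, "choice_record"))
    writeLines(jsonlite::toJSON(list(cloud = r$cloud,
                                     chosen_index = r$chosen_index),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_choice_records
#' @export
read_choice_records <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l)
    choice_record(o$cloud, o$chosen_index)
  })
}
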