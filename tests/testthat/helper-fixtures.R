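# Shared fixture builders; everything is generated in code at test time.

# the replay-experiment excitation-power grid: 12 evenly spaced values
replay_space <- function() {
  parameter_space(list(excitation = seq(0.2, 21.1, length.out = 12)))
}

small_space <- function(n = 10, d = 1) {
  vals <- lapply(seq_len(d), function(i) seq(0, 1, length.out = n))
  names(vals) <- paste0("p", seq_len(d))
  parameter_space(vals)
}

# literal dense transcription of the posterior equations, kept independent
# of compute_posterior: elementwise kernel, explicit solve()
oracle_posterior <- function(history, space, spec) {
  G <- grid_matrix(space)
  kv <- function(a, b) kernel_value(a, b, spec)
  Kgg <- outer(seq_len(nrow(G)), seq_len(nrow(G)),
               Vectorize(function(i, j) kv(G[i, ], G[j, ])))
  ok <- is.finite(history$observations)
  X <- history$configs[ok, , drop = FALSE]
  y <- history$observations[ok]
  N <- nrow(X)
  if (N == 0)
    return(list(mean = rep(0, nrow(G)),
                covariance = (spec$noise_var_upper / spec$lambda) * Kgg))
  Kn <- outer(seq_len(N), seq_len(N),
              Vectorize(function(i, j) kv(X[i, ], X[j, ])))
  kgn <- outer(seq_len(nrow(G)), seq_len(N),
               Vectorize(function(i, j) kv(G[i, ], X[j, ])))
  inv <- solve(Kn + spec$lambda * diag(N))
  mean_grid <- drop(kgn %*% inv %*% y)
  resid <- y - drop(Kn %*% inv %*% y)
  s2 <- min(max(mean(resid^2), spec$noise_var_lower), spec$noise_var_upper)
  cov_grid <- (s2 / spec$lambda) * (Kgg - kgn %*% inv %*% t(kgn))
  list(mean = mean_grid, covariance = cov_grid, noise_var = s2)
}

# choice records from a linear teacher utility over uniform option clouds
teacher_records <- function(n_records, w, n_options = 50) {
  lapply(seq_len(n_records), function(i) {
    cloud <- matrix(stats::runif(n_options * length(w)), n_options)
    choice_record(cloud, which.max(cloud %*% w))
  })
}

# calcium stacks where `n_responding` of the four 8x8 foreground tiles
# multiply their intensity by `factor` after the pulse
uncaging_stacks <- function(n_responding, factor = 2, base_level = 10,
                            n_base = 25L, n_resp = 75L) {
  base <- array(base_level, c(16, 16, n_base))
  resp <- array(base_level, c(16, 16, n_resp))
  tiles <- list(1:8, 9:16)
  k <- 0
  for (tr in 1:2) for (tc in 1:2) {
    k <- k + 1
    if (k <= n_responding)
      resp[tiles[[tr]], tiles[[tc]], ] <- base_level * factor
  }
  calcium_recording(base, resp)
}

# a quality net whose 3x3 kernels are 4-fold rotation symmetric, for
# testing the rotational alignment of padding/pooling/upsampling
symmetric_quality_net <- function(seed = 1) {
  net <- quality_net(seed = seed)
  for (l in seq_along(net$layers)) {
    W <- net$layers[[l]]$W
    cin <- nrow(W) / 9L
    for (co in seq_len(ncol(W))) {
      k <- array(W[, co], c(cin, 3, 3))  # (channel, dy, dx) blocks
      krot <- k
      for (ci in seq_len(cin)) {
        m <- k[ci, , ]
        sym <- (m + t(m[3:1, ]) + m[3:1, 3:1] + t(m)[3:1, ]) / 4
        krot[ci, , ] <- sym
      }
      W[, co] <- as.numeric(krot)
    }
    net$layers[[l]]$W <- W
  }
  net
}
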