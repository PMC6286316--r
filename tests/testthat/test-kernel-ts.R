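test_that("anisotropic Gaussian kernel matches hand evaluations", {
  ks1 <- kernel_spec(1 / 3)
  expect_equal(kernel_value(0.4, 0.4, ks1), 1.0)
  expect_equal(kernel_value(0, 1 / 3, ks1), exp(-0.5))
  ks2 <- kernel_spec(c(1, 2))
  expect_equal(kernel_value(c(0, 0), c(1, 2), ks2), exp(-1))
  # symmetry and bound
  expect_equal(kernel_value(c(0, 1), c(2, 3), ks2),
               kernel_value(c(2, 3), c(0, 1), ks2))
  expect_lte(kernel_value(c(0, 1), c(2, 3), ks2), 1)
  expect_error(kernel_value(1, c(1, 2), ks1), "dimension")
})

test_that("kernel_matrix agrees with elementwise kernel_value", {
  set.seed(4)
  ks <- kernel_spec(c(0.5, 3))
  A <- matrix(rnorm(10), 5, 2)
  B <- matrix(rnorm(6), 3, 2)
  M <- kernel_matrix(A, B, ks)
  for (i in 1:5) for (j in 1:3)
    expect_equal(M[i, j], kernel_value(A[i, ], B[j, ], ks))
})

test_that("noise variance estimate is the clipped mean squared residual", {
  ks <- kernel_spec(1)
  h <- objective_history(matrix(c(0.1, 0.5), ncol = 1), c(1, 2))
  # all-zero residuals clip to the lower bound 0.001
  expect_equal(estimate_noise_var(h, c(1, 2), ks), 0.001)
  # large residuals clip to the upper bound
  expect_equal(estimate_noise_var(h, c(1 + 2, 2 - 2.4), ks), 0.3)
  # residuals (0.1, -0.1) give 0.01
  expect_equal(estimate_noise_var(h, c(0.9, 2.1), ks), 0.01)
  # empty history: maximal caution
  expect_equal(estimate_noise_var(objective_history(), numeric(0), ks), 0.3)
})

test_that("empty-history posterior is the scaled prior", {
  sp <- small_space(6)
  ks <- kernel_spec(default_bandwidths(sp), lambda = 2)
  post <- compute_posterior(objective_history(), sp, ks)
  expect_equal(post$mean, rep(0, 6))
  G <- grid_matrix(sp)
  expect_equal(post$covariance,
               (ks$noise_var_upper / ks$lambda) * kernel_matrix(G, G, ks))
})

test_that("single-observation posterior mean shrinks by 1/(1+lambda)", {
  sp <- small_space(5)
  ks <- kernel_spec(default_bandwidths(sp), lambda = 0.7)
  G <- grid_matrix(sp)
  h <- objective_history(G[3, , drop = FALSE], 2.0)
  post <- compute_posterior(h, sp, ks)
  expect_equal(post$mean[3], 2.0 / (1 + 0.7), tolerance = 1e-12)
})

test_that("posterior matches the literal dense oracle on random instances", {
  set.seed(101)
  for (rep in 1:12) {
    d <- sample(1:2, 1)
    n_per <- sample(4:7, 1)
    sp <- small_space(n_per, d)
    ks <- kernel_spec(default_bandwidths(sp),
                      lambda = runif(1, 0.3, 2))
    G <- grid_matrix(sp)
    N <- sample(0:20, 1)
    h <- objective_history(G[sample(nrow(G), N, replace = TRUE), ,
                             drop = FALSE], rnorm(N))
    post <- compute_posterior(h, sp, ks)
    orc <- oracle_posterior(h, sp, ks)
    expect_lt(max(abs(post$mean - orc$mean)), 1e-10)
    expect_lt(max(abs(post$covariance - orc$covariance)), 1e-10)
  }
})

test_that("NA observations are excluded from the regression", {
  sp <- small_space(5)
  ks <- kernel_spec(default_bandwidths(sp))
  G <- grid_matrix(sp)
  h_clean <- objective_history(G[c(1, 4), , drop = FALSE], c(1, -1))
  h_na <- objective_history(G[c(1, 3, 4), , drop = FALSE], c(1, NA, -1))
  expect_equal(compute_posterior(h_na, sp, ks)$mean,
               compute_posterior(h_clean, sp, ks)$mean)
})

test_that("posterior variance never exceeds the prior and shrinks with
           repeated observations", {
  sp <- small_space(8)
  ks <- kernel_spec(default_bandwidths(sp))
  G <- grid_matrix(sp)
  prior_var <- ks$noise_var_upper / ks$lambda
  h <- objective_history()
  prev_var <- Inf
  set.seed(5)
  for (k in 1:6) {
    h <- history_append(h, G[4, ], rnorm(1, 1, 0.05))
    post <- compute_posterior(h, sp, ks)
    expect_true(all(diag(post$covariance) <=
                      prior_var * diag(kernel_matrix(G, G, ks)) + 1e-8))
    v <- diag(post$covariance)[4]
    expect_lte(v, prev_var + 1e-12)
    prev_var <- v
  }
})

test_that("with tiny lambda a single observation is interpolated", {
  sp <- small_space(5)
  ks <- kernel_spec(default_bandwidths(sp), lambda = 1e-6)
  G <- grid_matrix(sp)
  h <- objective_history(G[2, , drop = FALSE], 1.7)
  post <- compute_posterior(h, sp, ks)
  expect_equal(post$mean[2], 1.7, tolerance = 1e-4)
})

test_that("posterior sampling is seeded, degenerate-safe and unbiased", {
  sp <- small_space(4)
  ks <- kernel_spec(default_bandwidths(sp))
  set.seed(9)
  h <- objective_history(grid_matrix(sp)[c(1, 3), , drop = FALSE],
                         c(0.5, 1.5))
  post <- compute_posterior(h, sp, ks)
  set.seed(42); s1 <- sample_function(post)
  set.seed(42); s2 <- sample_function(post)
  expect_identical(s1, s2)
  # zero covariance: the sample is the mean exactly
  post0 <- post
  post0$covariance <- matrix(0, 4, 4)
  expect_equal(sample_function(post0), post$mean)
  # moments over many draws match the posterior within 3 Monte-Carlo SEs
  set.seed(7)
  n_draw <- 20000
  draws <- t(replicate(n_draw, sample_function(post)))
  sdv <- sqrt(diag(post$covariance))
  se_mean <- sdv / sqrt(n_draw)
  expect_true(all(abs(colMeans(draws) - post$mean) <= 3 * se_mean))
  emp_cov <- stats::cov(draws)
  se_var <- sqrt(2 / (n_draw - 1)) * diag(post$covariance)
  expect_true(all(abs(diag(emp_cov) - diag(post$covariance)) <=
                    3 * se_var + 1e-12))
})

test_that("argmax/argmin selection breaks ties at the lowest index", {
  expect_equal(select_config(c(0.1, 0.9, 0.3), "maximize"), 2)
  expect_equal(select_config(c(0.5, 0.5), "maximize"), 1)
  expect_equal(select_config(c(0.4, 0.2, 0.6), "minimize"), 2)
  expect_error(select_config(c(1, NA), "maximize"), "non-finite")
  expect_error(select_config(numeric(0)), "empty")
})

test_that("the Thompson sampling loop is seeded and concentrates", {
  sp <- small_space(8)
  ks <- kernel_spec(default_bandwidths(sp))
  f <- function(idx, cfg) exp(-((cfg - 0.6)^2) / 0.02)
  acq <- function(idx, cfg) f(idx, cfg) + rnorm(1, 0, 0.05)
  set.seed(31); r1 <- kernel_ts_run(acq, sp, ks, 25)
  set.seed(31); r2 <- kernel_ts_run(acq, sp, ks, 25)
  expect_identical(r1$selections, r2$selections)
  expect_equal(r1$history$N, 25)
  # late selections cluster near the optimum (grid value 0.571 or 0.714)
  late <- r1$selections[16:25]
  best <- which.max(f(NULL, grid_matrix(sp)[, 1]))
  expect_gte(mean(abs(late - best) <= 1), 0.7)
})
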