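test_that("grid-search estimates are per-config means with lowest-index
           tie-break", {
  sp <- small_space(5)
  plan <- grid_search_plan(sp, 4)
  f <- c(0.2, 0.8, 0.8, 0.5, 0.1)
  acq <- function(idx, cfg) f[idx]
  out <- grid_search(plan, acq)
  expect_equal(out$estimates, f)
  expect_equal(out$best_index, 2)  # tie between 2 and 3 -> lowest index
  expect_equal(out$history$N, 20)
  expect_equal(out$selections, rep(1:5, each = 4))
  # failed acquisitions are excluded from the mean
  acq_na <- function(idx, cfg) if (idx == 1) NA else f[idx]
  expect_true(is.na(grid_search(plan, acq_na)$estimates[1]))
})

test_that("random sampling is seeded and near-uniform", {
  sp <- small_space(4)
  acq <- function(idx, cfg) 0
  set.seed(10); r1 <- random_sampling(sp, acq, 50)
  set.seed(10); r2 <- random_sampling(sp, acq, 50)
  expect_identical(r1$selections, r2$selections)
  expect_equal(length(random_sampling(sp, acq, 1)$selections), 1)
  set.seed(11)
  big <- random_sampling(sp, acq, 20000)
  counts <- tabulate(big$selections, 4)
  expected <- 20000 / 4
  sd_mult <- sqrt(20000 * 0.25 * 0.75)
  expect_true(all(abs(counts - expected) <= 3 * sd_mult))
})

test_that("non-dominated sorting matches hand cases and a brute-force
           oracle", {
  pts <- rbind(c(1, 1), c(0, 0), c(1, 0))
  fr <- nondominated_sort(pts, "maximize")
  expect_equal(fr, list(1L, 3L, 2L))
  same <- matrix(1, 5, 2)
  expect_equal(nondominated_sort(same), list(1:5))
  # oracle: a point's front is the longest domination chain above it
  oracle_fronts <- function(P) {
    n <- nrow(P)
    dom <- matrix(FALSE, n, n)
    for (i in 1:n) for (j in 1:n)
      dom[i, j] <- all(P[i, ] >= P[j, ]) && any(P[i, ] > P[j, ])
    level <- integer(n)
    left <- 1:n
    k <- 0
    while (length(left)) {
      nd <- left[vapply(left, function(j) !any(dom[left, j]), logical(1))]
      level[nd] <- k
      left <- setdiff(left, nd)
      k <- k + 1
    }
    level
  }
  set.seed(17)
  for (rep in 1:5) {
    P <- matrix(runif(20 * 3), 20, 3)
    fr <- nondominated_sort(P, "maximize")
    lev <- integer(20)
    for (f in seq_along(fr)) lev[fr[[f]]] <- f - 1L
    expect_equal(lev, oracle_fronts(P))
  }
  # minimize sense flips domination
  fr_min <- nondominated_sort(pts, "minimize")
  expect_equal(fr_min[[1]], 2L)
})

test_that("crowding distance is non-negative, permutation-invariant, and
           infinite on the boundary", {
  set.seed(19)
  P <- matrix(runif(16), 8, 2)
  d <- crowding_distance(P)
  expect_true(all(d >= 0))
  perm <- sample(8)
  expect_equal(crowding_distance(P[perm, ])[order(perm)][order(1:8)],
               d[1:8])
  for (m in 1:2) {
    expect_true(is.infinite(d[which.min(P[, m])]))
    expect_true(is.infinite(d[which.max(P[, m])]))
  }
})

test_that("SBX and polynomial mutation respect bounds and leave genes
           unchanged at probability extremes", {
  set.seed(23)
  lo <- c(0, -1); hi <- c(1, 2)
  for (i in 1:50) {
    p1 <- runif(2, lo, hi); p2 <- runif(2, lo, hi)
    ch <- sbx_crossover(p1, p2, lo, hi)
    for (c in ch) expect_true(all(c >= lo - 1e-12 & c <= hi + 1e-12))
    mu <- polynomial_mutation(p1, lo, hi, indpb = 1)
    expect_true(all(mu >= lo - 1e-12 & mu <= hi + 1e-12))
    expect_identical(polynomial_mutation(p1, lo, hi, indpb = 0), p1)
  }
})

test_that("NSGA-II consumes exactly its declared acquisition budget", {
  st <- nsga2_settings()
  expect_equal(st$budget, 300)
  expect_equal(nsga2_settings(5, 4, 2)$budget, 40)
  set.seed(29)
  st_small <- nsga2_settings(generations = 4, population = 6,
                             images_per_evaluation = 2)
  out <- nsga2_optimize(0, 1, st_small,
                        function(g) c(f1 = g[1], f2 = 1 - g[1]),
                        c("f1", "f2"))
  expect_equal(out$n_acquisitions, st_small$budget)
  expect_equal(nrow(out$population), 6)
})

test_that("NSGA-II covers the linear Pareto front of the toy problem", {
  # maximize f1 = x and f2 = 1 - x on [0,1]: every x is Pareto-optimal.
  # The best hypervolume a P-point population can reach w.r.t. (0,0) is
  # attained by evenly spaced points x = i/(P+1), giving
  # sum_i (i/(P+1)) * (1/(P+1)) = P / (2(P+1)) ... = 5/11 for P = 10
  hypervolume2 <- function(P) {
    P <- P[order(P[, 1], decreasing = TRUE), , drop = FALSE]
    hv <- 0; y_prev <- 0
    for (i in seq_len(nrow(P))) {
      if (P[i, 2] > y_prev) {
        hv <- hv + P[i, 1] * (P[i, 2] - y_prev)
        y_prev <- P[i, 2]
      }
    }
    hv
  }
  st <- nsga2_settings()  # 10 x 10 x 3 = 300 acquisitions
  ok <- 0
  set.seed(31)
  n_runs <- 50
  for (r in seq_len(n_runs)) {
    out <- nsga2_optimize(0, 1, st,
                          function(g) c(f1 = g[1], f2 = 1 - g[1]),
                          c("f1", "f2"))
    if (hypervolume2(out$values) >= 0.9 * (5 / 11)) ok <- ok + 1
  }
  expect_gte(ok, 45)
})

test_that("continuous genomes snap to the nearest grid configuration", {
  sp <- parameter_space(list(a = c(0, 1, 2), b = c(10, 20)))
  idx <- snap_to_grid(rbind(c(0.9, 11), c(2.2, 19)), sp)
  G <- grid_matrix(sp)
  expect_equal(G[idx[1], ], c(a = 1, b = 10))
  expect_equal(G[idx[2], ], c(a = 2, b = 20))
})
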