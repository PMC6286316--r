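test_that("margin ranking loss matches the printed formula and the hinge
           variant", {
  expect_equal(margin_ranking_loss(0.9, 0.5, 0.1), 0)
  expect_equal(margin_ranking_loss(0.5, 0.7, 0.1), 0.1)
  # score equality: zero under the printed form for any margin
  expect_equal(margin_ranking_loss(0.3, 0.3, 0.25), 0)
  # hinge penalizes ties by the margin
  expect_equal(margin_ranking_loss(0.3, 0.3, 0.25, variant = "hinge"), 0.25)
  expect_equal(margin_ranking_loss(0.5, 0.7, 0.1, variant = "hinge"), 0.3)
  expect_true(all(margin_ranking_loss(rnorm(10), rnorm(10), 0.1) >= 0))
})

test_that("pair construction yields one pair per non-chosen option in
           cloud order", {
  cl <- matrix(1:10, 5, 2)
  rec <- choice_record(cl, 3)
  prs <- make_pairs(rec)
  expect_equal(nrow(prs$chosen), 4)
  expect_true(all(prs$chosen[, 1] == cl[3, 1]))
  expect_equal(prs$rejected, cl[c(1, 2, 4, 5), ])
  two <- make_pairs(choice_record(matrix(1:4, 2, 2), 1))
  expect_equal(nrow(two$chosen), 1)
  expect_error(choice_record(matrix(1:2, 1, 2), 1), "at least 2")
})

test_that("prediction is the argmax score with lowest-index ties and
           permutation consistency", {
  # fixed scorer realizing s = o1 - o2 on non-negative inputs: pass the
  # two coordinates through the hidden layers untouched, weight them 1/-1
  W2 <- matrix(0, 10, 10); W2[1, 1] <- 1; W2[2, 2] <- 1
  w3 <- matrix(0, 10, 1); w3[1] <- 1; w3[2] <- -1
  lin <- structure(list(
    par = list(W1 = cbind(diag(2), matrix(0, 2, 8)), b1 = rep(0, 10),
               W2 = W2, b2 = rep(0, 10), w3 = w3, b3 = 0),
    n_obj = 2, margin = 0.1, variant = "printed", obj_ranges = NULL),
    class = "preference_scorer")
  cloud <- rbind(c(0.9, 0.5), c(0.7, 0.1))
  s <- score_options(lin, cloud)
  expect_equal(s, c(0.4, 0.6))
  expect_equal(predict_choice(lin, cloud), 2)
  expect_equal(predict_choice(lin, cloud[1, , drop = FALSE]), 1)
  expect_equal(predict_choice(lin, cloud[2:1, ]), 1)
  expect_error(predict_choice(lin, rbind(c(NA, 1))), "non-finite")
})

test_that("training memorizes a single repeated record and batches are
           sized by ceiling(pairs/128)", {
  set.seed(55)
  cloud <- matrix(runif(20), 10, 2)
  rec <- choice_record(cloud, 4)
  sc <- train_preference(rep(list(rec), 30), list(rec),
                         obj_ranges = rbind(c(0, 0), c(1, 1)),
                         max_epochs = 150)
  prs <- make_pairs(rec)
  final_loss <- mean(margin_ranking_loss(
    score_options(sc, prs$chosen), score_options(sc, prs$rejected),
    sc$margin, sc$variant))
  expect_lt(final_loss, 0.01)
  expect_equal(predict_choice(sc, cloud), 4)
})

test_that("a trained scorer recovers a linear teacher and plugs into the
           MO loop", {
  set.seed(71)
  w <- c(1, -1)
  train <- teacher_records(120, w, n_options = 30)
  val <- teacher_records(30, w, n_options = 30)
  sc <- train_preference(train, val, obj_ranges = rbind(c(0, 0), c(1, 1)))
  held <- teacher_records(50, w, n_options = 30)
  agree <- mean(vapply(held, function(r)
    predict_choice(sc, r$cloud) == r$chosen_index, logical(1)))
  expect_gte(agree, 0.8)

  # the scorer satisfies the preference-function contract end to end
  sp <- small_space(5)
  ks <- kernel_spec(default_bandwidths(sp))
  pref <- preference_from_scorer(sc)
  run <- run_optimization(
    function(idx, cfg) list(q = as.numeric(cfg), b = 1 - as.numeric(cfg)),
    c("q", "b"), sp, ks, pref, T = 4, senses = c("maximize", "minimize"))
  expect_equal(nrow(run$history), 4)
})

test_that("scorers and choice records persist losslessly", {
  set.seed(81)
  sc <- train_preference(teacher_records(5, c(1, 1), 10),
                         teacher_records(2, c(1, 1), 10), max_epochs = 3)
  p <- tempfile(fileext = ".json")
  save_preference_scorer(sc, p)
  sc2 <- load_preference_scorer(p)
  cloud <- matrix(runif(12), 6, 2)
  expect_equal(score_options(sc2, cloud), score_options(sc, cloud),
               tolerance = 1e-12)
  rp <- tempfile(fileext = ".jsonl")
  recs <- teacher_records(3, c(1, -2), 7)
  write_choice_records(recs, rp)
  recs2 <- read_choice_records(rp)
  expect_equal(recs2[[2]]$cloud, recs[[2]]$cloud)
  expect_equal(recs2[[3]]$chosen_index, recs[[3]]$chosen_index)
})

test_that("SNN backpropagation matches finite differences", {
  set.seed(91)
  par <- stedopt:::.snn_init(2)
  Xc <- matrix(runif(6), 3, 2); Xr <- matrix(runif(6), 3, 2)
  m <- 0.1
  loss_fn <- function(par) {
    sc <- stedopt:::.snn_forward(par, Xc)
    sr <- stedopt:::.snn_forward(par, Xr)
    mean(pmax(sr - sc + m, 0))
  }
  fc <- stedopt:::.snn_forward(par, Xc, keep = TRUE)
  fr <- stedopt:::.snn_forward(par, Xr, keep = TRUE)
  act <- as.numeric(fr$s - fc$s + m > 0) / 3
  grad <- Map(`+`, stedopt:::.snn_backward(par, fr, act),
              stedopt:::.snn_backward(par, fc, -act))
  eps <- 1e-6
  for (nm in c("W1", "W2", "w3", "b3")) {
    p <- par
    target <- if (is.matrix(p[[nm]])) c(1, 1) else 1
    pp <- p; pm <- p
    if (is.matrix(p[[nm]])) {
      pp[[nm]][1, 1] <- pp[[nm]][1, 1] + eps
      pm[[nm]][1, 1] <- pm[[nm]][1, 1] - eps
      g_num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(as.numeric(grad[[nm]][1, 1]), g_num, tolerance = 1e-4)
    } else {
      pp[[nm]][1] <- pp[[nm]][1] + eps
      pm[[nm]][1] <- pm[[nm]][1] - eps
      g_num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(as.numeric(grad[[nm]])[1], g_num, tolerance = 1e-4)
    }
  }
})
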