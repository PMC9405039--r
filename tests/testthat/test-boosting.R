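test_that("round weight follows the log-odds closed form", {
  # alpha(eps) = 0.5 ln((1-eps)/eps): spot values and behavior near 0.5
  alpha <- function(eps) {
    e <- ckdboost:::clamp_eps(eps)
    0.5 * log((1 - e) / e)
  }
  expect_equal(alpha(0.25), 0.5 * log(3), tolerance = 1e-12)
  expect_lt(alpha(0.5 - 1e-8), 1e-7)   # vanishes as eps -> 0.5
  expect_gt(alpha(1e-12), 10)          # clamped, large but finite at eps = 0
  # strictly decreasing in eps on (0, 0.5)
  grid <- seq(0.01, 0.49, by = 0.01)
  expect_true(all(diff(vapply(grid, alpha, numeric(1))) < 0))
})

test_that("boosting drives training error to zero on separable data", {
  dm <- make_separable_dm(n = 40, seed = 2)
  ens <- fit_adaboost(dm, weak_learner(max_depth = 1), T = 20, seed = 7)
  expect_equal(predict(ens, dm), dm$y)
  expect_true(all(ens$alphas > 0))
  expect_lte(ens$T_effective, ens$T_requested)
})

test_that("conventional AdaBoost matches its line-by-line transcription", {
  for (case in list(list(n_pos = 30, n_neg = 20, seed = 11),
                    list(n_pos = 120, n_neg = 80, seed = 23))) {
    dm <- make_dm(case$n_pos, case$n_neg, shift = 1.2, seed = case$seed)
    T <- 10
    ens <- fit_adaboost(dm, weak_learner(max_depth = 2), T = T,
                        seed = case$seed, trace = TRUE)
    orc <- oracle_adaboost(dm$X, dm$y, max_depth = 2, T = T,
                           seed = case$seed)
    expect_equal(length(orc), ens$T_effective)
    for (t in seq_along(orc)) {
      expect_equal(ens$log$eps[t], orc[[t]]$eps, tolerance = 1e-9)
      expect_equal(ens$log$alpha[t], orc[[t]]$alpha, tolerance = 1e-9)
      expect_equal(ens$trace[[t]]$D, orc[[t]]$D, tolerance = 1e-9)
    }
  }
})

test_that("cost-sensitive AdaBoost matches its line-by-line transcription", {
  for (case in list(list(n_pos = 15, n_neg = 35, seed = 5),
                    list(n_pos = 60, n_neg = 140, seed = 17))) {
    dm <- make_dm(case$n_pos, case$n_neg, shift = 1.2, seed = case$seed)
    T <- 10
    ens <- fit_cs_adaboost(dm, weak_learner(max_depth = 2), T = T,
                           costs = cost_matrix(2, 2, 1, 1),
                           seed = case$seed, trace = TRUE)
    orc <- oracle_cs_adaboost(dm$X, dm$y, max_depth = 2, T = T,
                              seed = case$seed)
    expect_equal(length(orc), ens$T_effective)
    for (t in seq_along(orc)) {
      expect_equal(ens$log$eps[t], orc[[t]]$eps, tolerance = 1e-9)
      expect_equal(ens$log$eps_p[t], orc[[t]]$eps_p, tolerance = 1e-9)
      expect_equal(ens$log$eps_n[t], orc[[t]]$eps_n, tolerance = 1e-9)
      expect_equal(ens$log$alpha[t], orc[[t]]$alpha, tolerance = 1e-9)
      expect_equal(ens$trace[[t]]$beta, orc[[t]]$beta, tolerance = 1e-9)
      expect_equal(ens$trace[[t]]$D, orc[[t]]$D, tolerance = 1e-9)
    }
  }
})

test_that("class-wise error identity eps = (eps_p + eps_n)/2 holds per round", {
  dm <- make_dm(40, 80, shift = 1, seed = 31)
  ens <- fit_cs_adaboost(dm, weak_learner(max_depth = 2), T = 8, seed = 3)
  expect_equal(ens$log$eps, (ens$log$eps_p + ens$log$eps_n) / 2,
               tolerance = 1e-12)
  # confusion counts per round partition each class
  expect_true(all(ens$log$tp + ens$log$fn == sum(dm$y == 1)))
  expect_true(all(ens$log$tn + ens$log$fp == sum(dm$y == -1)))
})

test_that("cost items follow the four-case precision rule", {
  costs <- cost_matrix(c10 = 2, c01 = 3, c11 = 1.2, c00 = 1.1)
  # TP=3, FP=1, one misclassified positive (FN=1), TN=2
  y    <- c(1, 1, 1, 1, -1, -1, -1)
  pred <- c(1, 1, 1, -1, 1, -1, -1)
  beta <- ckdboost:::beta_items(y, pred, costs)
  expect_equal(beta[4], 0.75 * 2)          # (TP/(FP+TP)) c10 = 3/4 * 2
  expect_equal(beta[5], (2 / 3) * 3)       # (TN/(FN+TN)) c01 = 2/3 * 3
  expect_equal(beta[1:3], rep(0.75 * 1.2, 3))
  expect_equal(beta[6:7], rep((2 / 3) * 1.1, 2))
  expect_true(all(beta > 0))
  # FN = FP = 0: precision factors are 1, betas reduce to the raw costs
  beta0 <- ckdboost:::beta_items(c(1, 1, -1), c(1, 1, -1), costs)
  expect_equal(beta0, c(1.2, 1.2, 1.1))
  # degenerate round predicting a single class: neutral factor 1
  beta1 <- ckdboost:::beta_items(c(1, -1), c(-1, -1), costs)
  expect_equal(beta1[1], 1 * 2)            # no predicted positives
})

test_that("weights stay normalized and move in the right direction", {
  dm <- make_dm(25, 55, shift = 1, seed = 13)
  n <- length(dm$y)
  ens <- fit_adaboost(dm, weak_learner(max_depth = 1), T = 12, seed = 19,
                      trace = TRUE)
  D_prev <- rep(1 / n, n)
  for (t in seq_len(ens$T_effective)) {
    D <- ens$trace[[t]]$D
    expect_true(all(D >= 0))
    expect_equal(sum(D), 1, tolerance = 1e-9)
    eps <- ens$log$eps[t]
    if (eps > 0 && eps < 0.5) {
      pred <- ckdboost:::predict_weak(ens$rounds[[t]]$h, dm$X)
      mis <- pred != dm$y
      expect_true(all(D[mis] > D_prev[mis]))
      expect_true(all(D[!mis] < D_prev[!mis]))
    }
    D_prev <- D
  }
  # cost-sensitive update conserves weight mass too
  cs <- fit_cs_adaboost(dm, weak_learner(max_depth = 1), T = 12, seed = 19,
                        trace = TRUE)
  for (t in seq_len(cs$T_effective)) {
    expect_true(all(cs$trace[[t]]$D >= 0))
    expect_equal(sum(cs$trace[[t]]$D), 1, tolerance = 1e-9)
  }
})

test_that("prediction is the sign of the weighted vote, ties to +1", {
  dm <- make_separable_dm(n = 30, seed = 6)
  ens1 <- fit_adaboost(dm, weak_learner(max_depth = 1), T = 1, seed = 2)
  h_pred <- ckdboost:::predict_weak(ens1$rounds[[1]]$h, dm$X)
  expect_equal(predict(ens1, dm), h_pred)  # one round: the weak hypothesis
  # two identical hypotheses with equal alpha: same predictions as one
  ens2 <- ens1
  ens2$rounds <- c(ens1$rounds, ens1$rounds)
  ens2$alphas <- rep(ens1$alphas, 2)
  expect_equal(predict(ens2, dm), predict(ens1, dm))
  # opposite hypotheses with equal alpha: score 0 everywhere -> +1
  flip <- ckdboost:::fit_weak(weak_learner(max_depth = 1), dm$X, -dm$y)
  tie <- ens1
  tie$rounds <- list(list(h = ens1$rounds[[1]]$h, alpha = 1),
                     list(h = flip, alpha = 1))
  tie$alphas <- c(1, 1)
  expect_equal(decision_score(tie, dm$X), rep(0, nrow(dm$X)))
  expect_equal(predict(tie, dm), rep(1, nrow(dm$X)))
})

test_that("decision scores are bounded, consistent with predictions", {
  dm <- make_dm(40, 40, shift = 1.5, seed = 9)
  ens <- fit_cs_adaboost(dm, weak_learner(max_depth = 2), T = 10, seed = 4)
  s <- decision_score(ens, dm$X)
  expect_true(all(s >= -1 & s <= 1))
  expect_equal(ifelse(s >= 0, 1, -1), predict(ens, dm))
  expect_equal(predict(ens, dm, type = "score"), s)
  # unanimous vote reaches the bound
  sep <- make_separable_dm(40, seed = 3)
  ens_sep <- fit_adaboost(sep, weak_learner(max_depth = 1), T = 5, seed = 5)
  expect_equal(abs(decision_score(ens_sep, sep$X)), rep(1, 40))
})

test_that("identical seeds give identical ensembles; inputs are validated", {
  dm <- make_dm(30, 30, seed = 1)
  a <- fit_adaboost(dm, weak_learner(max_depth = 2), T = 6, seed = 42)
  b <- fit_adaboost(dm, weak_learner(max_depth = 2), T = 6, seed = 42)
  expect_identical(a$alphas, b$alphas)
  expect_identical(predict(a, dm), predict(b, dm))
  one_class <- design_matrix(matrix(rnorm(20), 10), rep(1, 10))
  expect_error(fit_adaboost(one_class, T = 3), "both classes")
  expect_error(fit_cs_adaboost(dm, costs = list(c10 = 2)), "cost_matrix")
  expect_error(cost_matrix(c10 = 1, c00 = 2), "c10 > c00")
  expect_error(cost_matrix(c01 = 1, c11 = 2), "c01 > c11")
  expect_error(cost_matrix(c10 = -1), "positive")
  expect_error(decision_score(a, dm$X[, 1:2]), "arity")
})

test_that("ensembles round-trip through disk with bit-identical predictions", {
  dm <- make_dm(30, 50, seed = 14)
  ens <- fit_cs_adaboost(dm, weak_learner(max_depth = 2), T = 5, seed = 8)
  path <- tempfile(fileext = ".rds")
  save_ensemble(ens, path)
  back <- load_ensemble(path)
  expect_identical(predict(back, dm, type = "score"),
                   predict(ens, dm, type = "score"))
  expect_identical(back$alphas, ens$alphas)
  unlink(path)
})
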