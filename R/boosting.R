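#' Weak-learner specification
#'
#' Boosting needs a base learner only slightly better than chance; the
#' canonical choice is the decision stump (a depth-1 tree), fitted here
#' with \pkg{rpart}. Deeper trees are available but erode the benefit of
#' the cost-sensitive weight update: the class-balanced round error can
#' never reject a hypothesis that sacrifices one class, so base learners
#' strong enough to dominate single rounds drive the ensemble into a
#' majority-vs-minority tug of war (see the methods vignette).
#'
#' @param kind Weak-learner family; only `"tree"` is provided.
#' @param max_depth Maximum tree depth (default 1, a stump).
#' @return An object of class `weak_learner`.
#' @export
weak_learner <- function(kind = "tree", max_depth = 1) {
  kind <- match.arg(kind, "tree")
  stopifnot(max_depth >= 1)
  structure(list(kind = kind, max_depth = max_depth), class = "weak_learner")
}

# Fit one weak hypothesis h: X -> {+1,-1}. rpart is deterministic given the
# sample, so ensemble reproducibility rests solely on the bootstrap RNG.
fit_weak <- function(weak, X, y, w = NULL) {
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(X)))
  df$.y <- factor(y, levels = c(-1, 1))
  ctrl <- rpart::rpart.control(maxdepth = weak$max_depth, cp = 0,
                               minsplit = 2, minbucket = 1, xval = 0,
                               maxsurrogate = 0, maxcompete = 0)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class", weights = w,
                      control = ctrl)
  structure(list(fit = fit, d = ncol(X)), class = "weak_hypothesis")
}

predict_weak <- function(h, X) {
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(X)))
  as.numeric(as.character(predict(h$fit, df, type = "class")))
}

#' Cost matrix for cost-sensitive boosting
#'
#' The four cost factors entering the cost-sensitive weight update. Each is
#' defined by the algorithmic case it multiplies, with positive = +1 the
#' disease class:
#' \describe{
#'   \item{c10}{cost applied when a positive instance is predicted negative
#'     (a missed case; the expensive error under imbalance).}
#'   \item{c01}{cost applied when a negative instance is predicted positive
#'     (a false alarm).}
#'   \item{c11, c00}{costs applied to correctly classified positives and
#'     negatives.}
#' }
#' Construction enforces `c10 > c00` and `c01 > c11`, so errors always cost
#' more than the matching correct decision. The defaults (2, 2, 1, 1) are
#' the minimal asymmetric choice consistent with those constraints.
#'
#' @param c10,c01,c11,c00 Positive reals.
#' @return An object of class `cost_matrix`.
#' @export
cost_matrix <- function(c10 = 2, c01 = 2, c11 = 1, c00 = 1) {
  vals <- c(c10 = c10, c01 = c01, c11 = c11, c00 = c00)
  if (any(vals <= 0)) stop("all cost factors must be positive")
  if (!(c10 > c00)) stop("cost matrix requires c10 > c00")
  if (!(c01 > c11)) stop("cost matrix requires c01 > c11")
  structure(as.list(vals), class = "cost_matrix")
}

EPS_CLAMP <- 1e-10
MAX_RETRIES <- 10L

# Per-instance cost items for the cost-sensitive weight update: the round's
# class-wise precision times the cost factor of the instance's case. A zero
# precision denominator (no predicted positives / negatives) gives a neutral
# factor of 1 so a degenerate round cannot annihilate weights.
beta_items <- function(y, pred, costs) {
  tp <- sum(y == 1 & pred == 1);  fn <- sum(y == 1 & pred == -1)
  tn <- sum(y == -1 & pred == -1); fp <- sum(y == -1 & pred == 1)
  prec_p <- if (tp + fp > 0) tp / (tp + fp) else 1
  prec_n <- if (tn + fn > 0) tn / (tn + fn) else 1
  beta <- numeric(length(y))
  beta[y == 1 & pred == -1]  <- prec_p * costs$c10
  beta[y == -1 & pred == 1]  <- prec_n * costs$c01
  beta[y == 1 & pred == 1]   <- prec_p * costs$c11
  beta[y == -1 & pred == -1] <- prec_n * costs$c00
  beta
}

clamp_eps <- function(eps) min(max(eps, EPS_CLAMP), 0.5 - EPS_CLAMP)

check_boost_input <- function(dm, T) {
  stopifnot(inherits(dm, "design_matrix"), T >= 1)
  if (nrow(dm$X) < 2) stop("boosting needs at least two instances")
  if (length(unique(dm$y)) < 2) stop("boosting needs both classes present")
}

# Draw the round-t training subset: weighted bootstrap of size n with
# replacement, probabilities D (resampling AdaBoost). Guarantees both
# classes in the subset by redrawing (rpart needs two classes).
draw_subset <- function(n, D, y) {
  for (k in 1:20) {
    idx <- sample.int(n, n, replace = TRUE, prob = D)
    if (length(unique(y[idx])) == 2) return(idx)
  }
  idx
}

#' Fit a conventional AdaBoost ensemble
#'
#' The classical binary AdaBoost procedure: starting from uniform instance
#' weights \eqn{D_1(i) = 1/n}, each round draws a weighted bootstrap sample,
#' fits a weak hypothesis \eqn{h_t}, measures its weighted error
#' \eqn{\varepsilon_t = \sum_i D_t(i)\,I[h_t(x_i) \ne y_i]} on the full
#' training set, sets \eqn{\alpha_t = \frac12 \ln\frac{1-\varepsilon_t}
#' {\varepsilon_t}}, and reweights
#' \eqn{D_{t+1}(i) = D_t(i) \exp(-\alpha_t y_i h_t(x_i)) / Z_t} so that
#' misclassified instances gain weight. The final classifier is
#' \eqn{H(x) = \mathrm{sign}\sum_t \alpha_t h_t(x)}.
#'
#' A round whose raw error reaches 0.5 is discarded and redrawn (up to 10
#' retries, then training stops early with a warning); the error is clamped
#' away from 0 and 0.5 before the log-odds formula so \eqn{\alpha_t} stays
#' finite and positive.
#'
#' @param dm A [design_matrix()].
#' @param weak A [weak_learner()].
#' @param T Number of boosting rounds requested (default 50).
#' @param seed Optional integer seed; fixes the bootstrap draws, hence the
#'   whole ensemble.
#' @param sampling `"resample"` (weighted bootstrap, default) or
#'   `"reweight"` (fit on the full set with instance weights).
#' @param trace Keep the per-round instance-weight vectors in the ensemble
#'   (`$trace`)? O(nT) memory; off by default.
#' @return A `boost_ensemble`: rounds (weak hypotheses + alphas), a
#'   per-round training log, and the fitting configuration.
#' @export
fit_adaboost <- function(dm, weak = weak_learner(), T = 50, seed = NULL,
                         sampling = c("resample", "reweight"),
                         trace = FALSE) {
  sampling <- match.arg(sampling)
  check_boost_input(dm, T)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dm$X)
  D <- rep(1 / n, n)
  rounds <- list()
  log <- vector("list", T)
  tr <- if (trace) vector("list", T) else NULL
  for (t in seq_len(T)) {
    res <- NULL
    for (try in seq_len(MAX_RETRIES)) {
      if (sampling == "resample") {
        idx <- draw_subset(n, D, dm$y)
        h <- fit_weak(weak, dm$X[idx, , drop = FALSE], dm$y[idx])
      } else {
        h <- fit_weak(weak, dm$X, dm$y, w = D * n)
      }
      pred <- predict_weak(h, dm$X)
      eps <- sum(D[pred != dm$y])
      if (eps < 0.5) { res <- list(h = h, pred = pred, eps = eps); break }
      if (sampling == "reweight") break  # deterministic; retrying is futile
    }
    if (is.null(res)) {
      warning("round ", t, ": weak learner no better than chance after ",
              MAX_RETRIES, " retries; stopping early")
      break
    }
    eps_c <- clamp_eps(res$eps)
    alpha <- 0.5 * log((1 - eps_c) / eps_c)
    upd <- D * exp(-alpha * dm$y * res$pred)
    Z <- sum(upd)
    D <- upd / Z
    rounds[[t]] <- list(h = res$h, alpha = alpha)
    log[[t]] <- data.frame(t = t, eps = res$eps, alpha = alpha)
    if (trace) tr[[t]] <- list(D = D)
  }
  new_boost_ensemble(rounds, log, T, dm, weak,
                     method = "adaboost", sampling = sampling, seed = seed,
                     trace = tr)
}

#' Fit a cost-sensitive AdaBoost ensemble
#'
#' A variant of AdaBoost built for imbalanced data. Two changes relative to
#' [fit_adaboost()]:
#'
#' \enumerate{
#'   \item The round error averages class-wise error rates instead of
#'     pooling: \eqn{\varepsilon_t = (\varepsilon_t^p + \varepsilon_t^n)/2},
#'     where \eqn{\varepsilon_t^p} sums the weights of misclassified
#'     positives and \eqn{\varepsilon_t^n} those of misclassified negatives.
#'     A weak hypothesis that sacrifices the minority class no longer looks
#'     accurate.
#'   \item Per-instance cost items \eqn{\beta_i} enter the weight update
#'     \eqn{D_{t+1}(i) = D_t(i) \exp(-\alpha_t \beta_i y_i h_t(x_i)) / Z_t},
#'     combining the round's class-wise precision with the cost factors by a
#'     four-case rule on the counts \eqn{TP_t, FP_t, TN_t, FN_t} of
#'     \eqn{h_t} on the full training set:
#'     \deqn{\beta_i = \frac{TP_t}{FP_t+TP_t} c_{10} \; (y_i=1, h_t=-1);\quad
#'           \frac{TN_t}{FN_t+TN_t} c_{01} \; (y_i=-1, h_t=1);}
#'     \deqn{\frac{TP_t}{FP_t+TP_t} c_{11} \; (y_i=1, h_t=1);\quad
#'           \frac{TN_t}{FN_t+TN_t} c_{00} \; (y_i=-1, h_t=-1).}
#'     Because errors cost more than correct decisions (`c10 > c00`,
#'     `c01 > c11`), expensive mistakes — above all missed positives —
#'     accumulate weight faster than under the conventional update.
#' }
#'
#' If a precision denominator is zero (no predicted positives, or no
#' predicted negatives), the corresponding factor is set to 1 so a
#' degenerate round does not annihilate weights. The cost items affect
#' training only; the final classifier is still
#' \eqn{\mathrm{sign}\sum_t \alpha_t h_t(x)}.
#'
#' @inheritParams fit_adaboost
#' @param costs A [cost_matrix()].
#' @return A `boost_ensemble` whose training log additionally records
#'   per-round `eps_p`, `eps_n` and the confusion counts of each weak
#'   hypothesis.
#' @export
fit_cs_adaboost <- function(dm, weak = weak_learner(), T = 50,
                            costs = cost_matrix(), seed = NULL,
                            sampling = c("resample", "reweight"),
                            trace = FALSE) {
  sampling <- match.arg(sampling)
  check_boost_input(dm, T)
  if (!inherits(costs, "cost_matrix")) stop("costs must be a cost_matrix()")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dm$X)
  y <- dm$y
  D <- rep(1 / n, n)
  rounds <- list()
  log <- vector("list", T)
  tr <- if (trace) vector("list", T) else NULL
  for (t in seq_len(T)) {
    res <- NULL
    for (try in seq_len(MAX_RETRIES)) {
      if (sampling == "resample") {
        idx <- draw_subset(n, D, y)
        h <- fit_weak(weak, dm$X[idx, , drop = FALSE], y[idx])
      } else {
        h <- fit_weak(weak, dm$X, y, w = D * n)
      }
      pred <- predict_weak(h, dm$X)
      eps_p <- sum(D[y == 1 & pred != y])
      eps_n <- sum(D[y == -1 & pred != y])
      eps <- (eps_p + eps_n) / 2
      if (eps < 0.5) {
        res <- list(h = h, pred = pred, eps = eps, eps_p = eps_p, eps_n = eps_n)
        break
      }
      if (sampling == "reweight") break
    }
    if (is.null(res)) {
      warning("round ", t, ": weak learner no better than chance after ",
              MAX_RETRIES, " retries; stopping early")
      break
    }
    pred <- res$pred
    eps_c <- clamp_eps(res$eps)
    alpha <- 0.5 * log((1 - eps_c) / eps_c)
    tp <- sum(y == 1 & pred == 1);  fn <- sum(y == 1 & pred == -1)
    tn <- sum(y == -1 & pred == -1); fp <- sum(y == -1 & pred == 1)
    beta <- beta_items(y, pred, costs)
    upd <- D * exp(-alpha * beta * y * pred)
    Z <- sum(upd)
    D <- upd / Z
    rounds[[t]] <- list(h = res$h, alpha = alpha)
    log[[t]] <- data.frame(t = t, eps = res$eps, eps_p = res$eps_p,
                           eps_n = res$eps_n, alpha = alpha,
                           tp = tp, fp = fp, tn = tn, fn = fn)
    if (trace) tr[[t]] <- list(D = D, beta = beta)
  }
  new_boost_ensemble(rounds, log, T, dm, weak, method = "cs_adaboost",
                     sampling = sampling, seed = seed, costs = costs,
                     trace = tr)
}

new_boost_ensemble <- function(rounds, log, T_requested, dm, weak, method,
                               sampling, seed, costs = NULL, trace = NULL) {
  rounds <- rounds[!vapply(rounds, is.null, logical(1))]
  if (length(rounds) == 0) stop("no usable boosting round was produced")
  log <- do.call(rbind, log[!vapply(log, is.null, logical(1))])
  structure(list(
    rounds = rounds,
    alphas = vapply(rounds, function(r) r$alpha, numeric(1)),
    T_requested = T_requested,
    T_effective = length(rounds),
    log = log,
    weak = weak,
    method = method,
    sampling = sampling,
    seed = seed,
    costs = costs,
    trace = if (is.null(trace)) NULL else
      trace[!vapply(trace, is.null, logical(1))],
    d = ncol(dm$X),
    feature_names = dm$feature_names
  ), class = "boost_ensemble")
}

#' @export
print.boost_ensemble <- function(x, ...) {
  lab <- if (x$method == "cs_adaboost") "cost-sensitive AdaBoost" else "AdaBoost"
  cat(lab, "ensemble:", x$T_effective, "rounds (requested",
      paste0(x$T_requested, ");"), x$d, "features; weak learner:",
      x$weak$kind, "depth", x$weak$max_depth, "\n")
  invisible(x)
}

#' Continuous ensemble score
#'
#' \eqn{\sum_t \alpha_t h_t(x) / \sum_t \alpha_t}: the normalized weighted
#' vote, in \[-1, 1\]. Thresholding at 0 reproduces [predict.boost_ensemble()]
#' up to the tie policy.
#'
#' @param ensemble A fitted `boost_ensemble`.
#' @param X Feature matrix with the training arity.
#' @return Numeric score vector.
#' @export
decision_score <- function(ensemble, X) {
  X <- as.matrix(X)
  if (ncol(X) != ensemble$d) {
    stop("feature arity mismatch: ensemble expects ", ensemble$d,
         " features, got ", ncol(X))
  }
  votes <- vapply(ensemble$rounds,
                  function(r) r$alpha * predict_weak(r$h, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1) votes <- matrix(votes, nrow = 1)
  rowSums(votes) / sum(ensemble$alphas)
}

#' Predict class labels from a boosted ensemble
#'
#' The sign of the weighted vote \eqn{\sum_t \alpha_t h_t(x)}; a score of
#' exactly 0 predicts +1 (disease), the conservative tie policy for a
#' screening tool.
#'
#' @param object A fitted `boost_ensemble`.
#' @param newdata Feature matrix (or [design_matrix()]).
#' @param type `"class"` for +/-1 labels, `"score"` for the normalized vote.
#' @param ... Unused.
#' @return Numeric vector of labels or scores.
#' @export
predict.boost_ensemble <- function(object, newdata, type = c("class", "score"),
                                   ...) {
  type <- match.arg(type)
  if (inherits(newdata, "design_matrix")) newdata <- newdata$X
  s <- decision_score(object, newdata)
  if (type == "score") return(s)
  ifelse(s >= 0, 1, -1)
}

#' Export a boosting training log as TSV
#'
#' @param ensemble A fitted `boost_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(ensemble, path) {
  utils::write.table(ensemble$log, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
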