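# Independent oracles: plain, loop-level transcriptions of the boosting
# procedures and brute-force reference computations. Kept deliberately
# naive and separate from the package internals they check.

# -- weak learner transcription (same contract the package documents:
#    rpart, method class, cp 0, minsplit 2, minbucket 1, no surrogates) --
oracle_fit_tree <- function(X, y, max_depth) {
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(X)))
  df$.y <- factor(y, levels = c(-1, 1))
  rpart::rpart(.y ~ ., data = df, method = "class",
               control = rpart::rpart.control(maxdepth = max_depth, cp = 0,
                                              minsplit = 2, minbucket = 1,
                                              xval = 0, maxsurrogate = 0,
                                              maxcompete = 0))
}

oracle_predict_tree <- function(fit, X) {
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(X)))
  as.numeric(as.character(predict(fit, df, type = "class")))
}

# same weighted-bootstrap policy the package documents: size-n draw with
# replacement, probabilities D, redrawn (<= 20 times) if single-class
oracle_draw <- function(n, D, y) {
  for (k in 1:20) {
    idx <- sample.int(n, n, replace = TRUE, prob = D)
    if (length(unique(y[idx])) == 2) return(idx)
  }
  idx
}

# Line-by-line conventional AdaBoost: returns per-round eps, alpha and the
# post-update weight vector.
oracle_adaboost <- function(X, y, max_depth, T, seed) {
  set.seed(seed)
  n <- nrow(X)
  D <- rep(1 / n, n)
  out <- list()
  for (t in seq_len(T)) {
    eps <- NA
    for (try in 1:10) {
      idx <- oracle_draw(n, D, y)
      fit <- oracle_fit_tree(X[idx, , drop = FALSE], y[idx], max_depth)
      pred <- oracle_predict_tree(fit, X)
      eps <- 0
      for (i in seq_len(n)) if (pred[i] != y[i]) eps <- eps + D[i]
      if (eps < 0.5) break
    }
    if (eps >= 0.5) break
    eps_c <- min(max(eps, 1e-10), 0.5 - 1e-10)
    alpha <- 0.5 * log((1 - eps_c) / eps_c)
    newD <- numeric(n)
    for (i in seq_len(n)) newD[i] <- D[i] * exp(-alpha * y[i] * pred[i])
    Z <- sum(newD)
    D <- newD / Z
    out[[t]] <- list(eps = eps, alpha = alpha, D = D)
  }
  out
}

# Line-by-line cost-sensitive AdaBoost: class-wise error rates, four-case
# cost items, biased weight update.
oracle_cs_adaboost <- function(X, y, max_depth, T, seed,
                               c10 = 2, c01 = 2, c11 = 1, c00 = 1) {
  set.seed(seed)
  n <- nrow(X)
  D <- rep(1 / n, n)
  out <- list()
  for (t in seq_len(T)) {
    eps <- NA
    for (try in 1:10) {
      idx <- oracle_draw(n, D, y)
      fit <- oracle_fit_tree(X[idx, , drop = FALSE], y[idx], max_depth)
      pred <- oracle_predict_tree(fit, X)
      eps_p <- 0; eps_n <- 0
      for (i in seq_len(n)) {
        if (pred[i] != y[i]) {
          if (y[i] == 1) eps_p <- eps_p + D[i] else eps_n <- eps_n + D[i]
        }
      }
      eps <- (eps_p + eps_n) / 2
      if (eps < 0.5) break
    }
    if (eps >= 0.5) break
    eps_c <- min(max(eps, 1e-10), 0.5 - 1e-10)
    alpha <- 0.5 * log((1 - eps_c) / eps_c)
    tp <- sum(y == 1 & pred == 1);  fn <- sum(y == 1 & pred == -1)
    tn <- sum(y == -1 & pred == -1); fp <- sum(y == -1 & pred == 1)
    beta <- numeric(n)
    for (i in seq_len(n)) {
      if (y[i] == 1 && pred[i] == -1) {
        beta[i] <- (if (fp + tp > 0) tp / (fp + tp) else 1) * c10
      } else if (y[i] == -1 && pred[i] == 1) {
        beta[i] <- (if (fn + tn > 0) tn / (fn + tn) else 1) * c01
      } else if (y[i] == 1 && pred[i] == 1) {
        beta[i] <- (if (fp + tp > 0) tp / (fp + tp) else 1) * c11
      } else {
        beta[i] <- (if (fn + tn > 0) tn / (fn + tn) else 1) * c00
      }
    }
    newD <- numeric(n)
    for (i in seq_len(n)) {
      newD[i] <- D[i] * exp(-alpha * beta[i] * y[i] * pred[i])
    }
    Z <- sum(newD)
    D <- newD / Z
    out[[t]] <- list(eps = eps, eps_p = eps_p, eps_n = eps_n,
                     alpha = alpha, beta = beta, D = D)
  }
  out
}

# Brute-force AUC: fraction of positive-negative pairs ranked correctly,
# ties counted one half.
oracle_auc_pairs <- function(y, scores) {
  sp <- scores[y == 1]; sn <- scores[y == -1]
  total <- 0
  for (a in sp) for (b in sn) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(sp) * length(sn))
}

# Brute-force conditional entropy by enumerating the joint distribution.
oracle_cond_entropy <- function(feature, labels) {
  n <- length(feature)
  total <- 0
  for (v in unique(feature)) {
    pv <- sum(feature == v) / n
    sub <- labels[feature == v]
    h <- 0
    for (l in unique(sub)) {
      p <- sum(sub == l) / length(sub)
      if (p > 0) h <- h - p * log2(p)
    }
    total <- total + pv * h
  }
  total
}

# -- shared fixtures --

# small numeric two-class design matrix with separation `shift`
make_dm <- function(n_pos, n_neg, d = 4, shift = 1.5, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  y <- c(rep(1, n_pos), rep(-1, n_neg))
  X <- matrix(rnorm(n * d), n, d)
  X[y == 1, 1] <- X[y == 1, 1] + shift
  X[y == 1, 2] <- X[y == 1, 2] + shift / 2
  colnames(X) <- paste0("f", seq_len(d))
  design_matrix(X, y)
}

# linearly separable toy set
make_separable_dm <- function(n = 40, seed = 1) {
  set.seed(seed)
  y <- rep(c(1, -1), each = n / 2)
  x1 <- ifelse(y == 1, runif(n, 1, 2), runif(n, -2, -1))
  x2 <- rnorm(n)
  design_matrix(cbind(a = x1, b = x2), y)
}
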