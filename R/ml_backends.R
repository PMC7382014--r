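# Classifier backbone: grouped cross-validation, binary metrics, and
# self-contained implementations of an RBF-kernel soft-margin SVM (SMO),
# a CART decision tree (Gini) and a bagged random forest with impurity
# importances.  These are implemented here because the target environment
# ships no SVM/tree/forest package; hyperparameters follow the common
# library defaults (C = 1 RBF SVM with "scale" gamma, unlimited-depth CART,
# 100-tree forest with sqrt(p) features per split).

# ---- folds & metrics -------------------------------------------------------

#' Subject-grouped stratified fold assignment
#'
#' All records of one subject share a fold (no identity leakage across
#' folds); subjects are stratified by class label before being dealt
#' round-robin into folds.
#'
#' @param groups Subject id per record.
#' @param labels Class label per record (constant within subject).
#' @param k Number of folds.
#' @param seed Integer seed for the subject shuffle.
#' @return Integer fold id (1..k) per record.
#' @export
grouped_folds <- function(groups, labels, k = 5, seed = 1L) {
  subj <- unique(groups)
  slab <- vapply(subj, function(s) as.character(labels[groups == s][1]), "")
  if (any(vapply(subj, function(s) length(unique(labels[groups == s])), 1L)
          > 1L)) {
    stop("labels must be constant within subject")
  }
  rng <- local({ set.seed(seed); sample.int(1e9, 1) })
  set.seed(rng)
  fold_of <- integer(length(subj)); names(fold_of) <- subj
  for (cl in unique(slab)) {
    s_cl <- sample(subj[slab == cl])
    fold_of[s_cl] <- rep_len(seq_len(k), length(s_cl))
  }
  unname(fold_of[groups])
}

#' Binary classification metrics
#'
#' Precision, recall and F1 with PD as the positive class (the clinically
#' meaningful convention), computed from pooled confusion counts.
#'
#' @param truth,pred Factors/characters with levels PD/control.
#' @param average `"binary"` (PD-positive; default) or `"weighted"`
#'   (per-class metrics weighted by class prevalence).
#' @return List: `precision`, `recall`, `f1`, `accuracy`, `confusion`
#'   (named counts tp/fp/fn/tn).
#' @export
classification_metrics <- function(truth, pred, average = c("binary",
                                                            "weighted")) {
  average <- match.arg(average)
  truth <- as.character(truth); pred <- as.character(pred)
  cf <- c(tp = sum(pred == "PD" & truth == "PD"),
          fp = sum(pred == "PD" & truth == "control"),
          fn = sum(pred == "control" & truth == "PD"),
          tn = sum(pred == "control" & truth == "control"))
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p, r, f)
  }
  if (average == "binary") {
    m <- prf(cf["tp"], cf["fp"], cf["fn"])
  } else {
    m_pd <- prf(cf["tp"], cf["fp"], cf["fn"])
    m_ct <- prf(cf["tn"], cf["fn"], cf["fp"])
    w <- c(sum(truth == "PD"), sum(truth == "control")) / length(truth)
    m <- w[1] * m_pd + w[2] * m_ct
  }
  list(precision = unname(m[1]), recall = unname(m[2]), f1 = unname(m[3]),
       accuracy = mean(pred == truth), confusion = cf)
}

# ---- feature standardization ----------------------------------------------

standardizer <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

apply_standardizer <- function(std, x) {
  sweep(sweep(x, 2, std$mu), 2, std$sd, "/")
}

# ---- logistic regression (weak ridge via glmnet) --------------------------

fit_lr <- function(x, y01, lambda = NULL) {
  if (is.null(lambda)) lambda <- 1 / nrow(x)
  # suppress glmnet's small-class advisory: tiny folds are intentional here
  fit <- suppressWarnings(
    glmnet::glmnet(x, y01, family = "binomial", alpha = 0,
                   lambda = lambda * c(100, 10, 1),
                   standardize = FALSE, thresh = 1e-10))
  list(kind = "lr", fit = fit, s = lambda)
}

predict_lr <- function(model, x) {
  p <- stats::predict(model$fit, x, s = model$s, type = "response")
  as.numeric(p > 0.5)
}

# ---- RBF-kernel SVM via simplified SMO ------------------------------------

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

#' Fit a soft-margin RBF-kernel SVM (sequential minimal optimization)
#'
#' @param x Numeric matrix (standardized).
#' @param y01 0/1 labels (1 = positive class).
#' @param C Box constraint (default 1).
#' @param gamma RBF width; default `1 / (ncol(x) * var(x))` ("scale").
#' @param tol KKT violation tolerance.
#' @param max_passes Full passes without any update before stopping.
#' @return Model list usable with [predict_svm()].
#' @keywords internal
fit_svm <- function(x, y01, C = 1, gamma = NULL, tol = 1e-3,
                    max_passes = 10, max_iter = 5000) {
  y <- ifelse(y01 > 0, 1, -1)
  n <- nrow(x)
  if (is.null(gamma)) {
    v <- stats::var(as.vector(x))
    gamma <- 1 / (ncol(x) * if (v > 0) v else 1)
  }
  K <- rbf_kernel(x, x, gamma)
  alpha <- numeric(n); b <- 0
  passes <- 0; iter <- 0
  fcache <- function(i) sum(alpha * y * K[, i]) + b
  while (passes < max_passes && iter < max_iter) {
    changed <- 0
    for (i in seq_len(n)) {
      Ei <- fcache(i) - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        E_all <- as.vector(K %*% (alpha * y)) + b - y
        j <- which.max(abs(E_all - Ei)); if (j == i) next
        Ej <- E_all[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (Ei - Ej) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-7) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else
          (b1 + b2) / 2
        changed <- changed + 1
      }
      iter <- iter + 1
    }
    passes <- if (changed == 0) passes + 1 else 0
  }
  sv <- alpha > 1e-8
  list(kind = "svm", x = x[sv, , drop = FALSE], ay = (alpha * y)[sv], b = b,
       gamma = gamma)
}

predict_svm <- function(model, x) {
  f <- rbf_kernel(x, model$x, model$gamma) %*% model$ay + model$b
  as.numeric(f > 0)
}

# ---- CART decision tree ----------------------------------------------------

gini <- function(n1, n0) {
  n <- n1 + n0
  ifelse(n == 0, 0, 1 - (n1 / n)^2 - (n0 / n)^2)
}

# best split of one feature; returns c(score, threshold) or NULL
.best_split_feature <- function(v, y01) {
  o <- order(v)
  vs <- v[o]; ys <- y01[o]
  n <- length(v)
  cut_ok <- which(diff(vs) > 0)      # split between distinct values
  if (!length(cut_ok)) return(NULL)
  c1 <- cumsum(ys); c0 <- seq_len(n) - c1
  tot1 <- c1[n]; tot0 <- c0[n]
  nl <- cut_ok
  gl <- gini(c1[cut_ok], c0[cut_ok])
  gr <- gini(tot1 - c1[cut_ok], tot0 - c0[cut_ok])
  score <- (nl * gl + (n - nl) * gr) / n    # weighted child impurity
  k <- which.min(score)
  c(score[k], (vs[cut_ok[k]] + vs[cut_ok[k] + 1]) / 2)
}

#' Fit a CART classification tree (Gini impurity)
#'
#' @param x Numeric matrix, `y01` 0/1 labels.
#' @param max_depth Maximum depth (default unlimited, like common library
#'   defaults).
#' @param min_split Minimum node size to attempt a split.
#' @param mtry Number of features sampled per node (default all; `sqrt(p)`
#'   inside the random forest).
#' @return Model list usable with [predict_tree()]; `$importance` holds
#'   per-feature total impurity decrease.
#' @keywords internal
fit_tree <- function(x, y01, max_depth = Inf, min_split = 2, mtry = ncol(x)) {
  p <- ncol(x)
  importance <- numeric(p)
  n_total <- nrow(x)
  nodes <- list()
  new_node <- function(node) { nodes[[length(nodes) + 1L]] <<- node
    length(nodes) }
  build <- function(idx, depth) {
    y <- y01[idx]; n <- length(idx)
    prob1 <- mean(y)
    g <- gini(sum(y), n - sum(y))
    if (depth >= max_depth || n < min_split || g == 0) {
      return(new_node(list(leaf = TRUE, prob1 = prob1)))
    }
    feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
    best <- NULL
    for (f in feats) {
      sp <- .best_split_feature(x[idx, f], y)
      if (!is.null(sp) && (is.null(best) || sp[1] < best$score - 1e-12)) {
        best <- list(score = sp[1], feature = f, threshold = sp[2])
      }
    }
    if (is.null(best) || best$score >= g - 1e-12) {
      return(new_node(list(leaf = TRUE, prob1 = prob1)))
    }
    importance[best$feature] <<- importance[best$feature] +
      (n / n_total) * (g - best$score)
    left <- idx[x[idx, best$feature] <= best$threshold]
    right <- setdiff(idx, left)
    li <- build(left, depth + 1)
    ri <- build(right, depth + 1)
    new_node(list(leaf = FALSE, feature = best$feature,
                  threshold = best$threshold, left = li, right = ri))
  }
  root <- build(seq_len(n_total), 0)
  list(kind = "tree", nodes = nodes, root = root, importance = importance)
}

predict_tree_prob <- function(model, x) {
  apply(x, 1, function(row) {
    i <- model$root
    repeat {
      nd <- model$nodes[[i]]
      if (nd$leaf) return(nd$prob1)
      i <- if (row[nd$feature] <= nd$threshold) nd$left else nd$right
    }
  })
}

predict_tree <- function(model, x) as.numeric(predict_tree_prob(model, x) > 0.5)

# ---- random forest ---------------------------------------------------------

#' Fit a bagged random forest of CART trees
#'
#' Bootstrap resampling per tree, `sqrt(p)` features per split, majority
#' vote; per-feature impurity importances averaged over trees.
#'
#' @param x Numeric matrix, `y01` 0/1 labels.
#' @param num_trees Number of trees (default 100).
#' @param mtry Features per split (default `floor(sqrt(p))`).
#' @return Model list usable with [predict_forest()].
#' @keywords internal
fit_forest <- function(x, y01, num_trees = 100, mtry = NULL) {
  n <- nrow(x); p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  trees <- vector("list", num_trees)
  importance <- numeric(p)
  for (t in seq_len(num_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    tr <- fit_tree(x[idx, , drop = FALSE], y01[idx], mtry = mtry)
    importance <- importance + tr$importance
    tr$importance <- NULL
    trees[[t]] <- tr
  }
  list(kind = "forest", trees = trees, importance = importance / num_trees,
       feature_names = colnames(x))
}

predict_forest <- function(model, x) {
  votes <- rowMeans(vapply(model$trees, function(tr) predict_tree_prob(tr, x),
                           numeric(nrow(x))))
  as.numeric(votes > 0.5)
}
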