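# Sequence classification of key-point trajectories.
#
# Each record's relative-coordinate track is first-order differenced,
# Delta_x_i = x_{i-1} - x_i (note the sign convention: previous minus
# current), giving an (N-1) x 212 multichannel series (dx, dy per key
# point).  A single-layer LSTM (or simple tanh RNN) reads the series and a
# linear softmax head on the final hidden state classifies PD vs control.
# The nets are implemented here in base R (batched matrix ops + BPTT +
# Adam): the target environment has no deep-learning package, and at this
# scale (hundreds of records, ~50 steps) full-batch training is seconds of
# CPU.  The output layer is zero-initialized, so an untrained model predicts
# the training majority class (ties break toward it).

#' First-order difference of a relative sequence
#'
#' @param rel A `relative_sequence` (or `landmark_sequence` when modelling
#'   absolute coordinates) with N >= 2 frames.
#' @return Object of class `diff_series`: list with `series` (matrix
#'   `(N-1) x 212`, channels `"{point}__dx"`, `"{point}__dy"` point-major),
#'   `label`, `subject_id`, `record_id`.
#' @export
difference <- function(rel) {
  stopifnot(inherits(rel, c("relative_sequence", "landmark_sequence")))
  N <- n_frames(rel)
  if (N < 2) stop("differencing needs at least 2 frames")
  pn <- dimnames(rel$coords)[[2]]
  dx <- -apply(rel$coords[, , 1, drop = FALSE], 2, diff)  # x_{i-1} - x_i
  dy <- -apply(rel$coords[, , 2, drop = FALSE], 2, diff)
  series <- matrix(NA_real_, N - 1, 2 * length(pn))
  series[, seq(1, ncol(series), by = 2)] <- dx
  series[, seq(2, ncol(series), by = 2)] <- dy
  colnames(series) <- as.vector(rbind(paste0(pn, "__dx"), paste0(pn, "__dy")))
  structure(list(series = series, label = rel$label,
                 subject_id = rel$subject_id, record_id = rel$record_id),
            class = "diff_series")
}

#' Invert a first-order difference
#'
#' Reconstructs the coordinate track from a `diff_series` and the first
#' frame: cumulative subtraction inverts `Delta_x_i = x_{i-1} - x_i`.
#'
#' @param d A [difference()] result.
#' @param first_frame `P x 2` matrix of frame-0 coordinates.
#' @return Array `N x P x 2` of reconstructed coordinates.
#' @export
undifference <- function(d, first_frame) {
  ser <- d$series
  P <- ncol(ser) / 2
  N <- nrow(ser) + 1
  out <- array(NA_real_, c(N, P, 2))
  dx <- ser[, seq(1, ncol(ser), by = 2), drop = FALSE]
  dy <- ser[, seq(2, ncol(ser), by = 2), drop = FALSE]
  out[, , 1] <- rbind(first_frame[, 1],
                      matrix(first_frame[, 1], nrow(ser), P, byrow = TRUE) -
                        apply(dx, 2, cumsum))
  out[, , 2] <- rbind(first_frame[, 2],
                      matrix(first_frame[, 2], nrow(ser), P, byrow = TRUE) -
                        apply(dy, 2, cumsum))
  out
}

# ---- padding & standardization --------------------------------------------

.pack_series <- function(diffs) {
  Ts <- vapply(diffs, function(d) nrow(d$series), 1L)
  C <- ncol(diffs[[1]]$series)
  B <- length(diffs)
  Tmax <- max(Ts)
  X <- array(0, c(B, Tmax, C))
  mask <- matrix(0, B, Tmax)
  for (r in seq_len(B)) {
    X[r, seq_len(Ts[r]), ] <- diffs[[r]]$series
    mask[r, seq_len(Ts[r])] <- 1
  }
  list(X = X, mask = mask,
       y01 = as.numeric(vapply(diffs, `[[`, "", "label") == "PD"),
       groups = vapply(diffs, `[[`, "", "subject_id"),
       labels = vapply(diffs, `[[`, "", "label"))
}

.series_std <- function(X, mask, idx) {
  v <- lapply(seq_len(dim(X)[3]), function(c) {
    vals <- X[idx, , c][mask[idx, ] > 0]
    c(mean(vals), stats::sd(vals))
  })
  mu <- vapply(v, `[`, 0, 1)
  sd <- vapply(v, `[`, 0, 2)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

.apply_series_std <- function(X, std) {
  for (c in seq_len(dim(X)[3])) X[, , c] <- (X[, , c] - std$mu[c]) / std$sd[c]
  X
}

# ---- network core ----------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

.init_params <- function(arch, C, H) {
  gl <- function(fan_in, fan_out) {
    matrix(stats::runif(fan_in * fan_out, -1, 1) * sqrt(6 / (fan_in + fan_out)),
           fan_in, fan_out)
  }
  if (arch == "lstm") {
    b <- numeric(4 * H)
    b[(H + 1):(2 * H)] <- 1          # forget-gate bias
    list(Wx = gl(C, 4 * H), Wh = gl(H, 4 * H), b = b,
         Wy = matrix(0, H, 2), by = numeric(2))
  } else {
    list(Wx = gl(C, H), Wh = gl(H, H), b = numeric(H),
         Wy = matrix(0, H, 2), by = numeric(2))
  }
}

.seq_forward <- function(params, X, mask, arch, keep_cache = FALSE) {
  B <- dim(X)[1]; Tn <- dim(X)[2]
  H <- nrow(params$Wh)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    Xt <- matrix(X[, t, ], B)
    m <- mask[, t]
    if (arch == "lstm") {
      Z <- Xt %*% params$Wx + h %*% params$Wh +
        matrix(params$b, B, 4 * H, byrow = TRUE)
      i <- sigmoid(Z[, 1:H, drop = FALSE])
      f <- sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
      g <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
      o <- sigmoid(Z[, (3 * H + 1):(4 * H), drop = FALSE])
      c_new <- f * cc + i * g
      tc <- tanh(c_new)
      h_new <- o * tc
      if (keep_cache) {
        cache[[t]] <- list(Xt = Xt, h_prev = h, c_prev = cc, i = i, f = f,
                           g = g, o = o, tc = tc, m = m)
      }
      h <- m * h_new + (1 - m) * h
      cc <- m * c_new + (1 - m) * cc
    } else {
      Z <- Xt %*% params$Wx + h %*% params$Wh +
        matrix(params$b, B, H, byrow = TRUE)
      h_new <- tanh(Z)
      if (keep_cache) {
        cache[[t]] <- list(Xt = Xt, h_prev = h, h_new = h_new, m = m)
      }
      h <- m * h_new + (1 - m) * h
    }
  }
  logits <- h %*% params$Wy + matrix(params$by, B, 2, byrow = TRUE)
  list(logits = logits, h_final = h, cache = cache)
}

.softmax <- function(logits) {
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

.seq_loss_grad <- function(params, X, mask, y01, arch) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; H <- nrow(params$Wh)
  fw <- .seq_forward(params, X, mask, arch, keep_cache = TRUE)
  probs <- .softmax(fw$logits)
  onehot <- cbind(1 - y01, y01)   # column 1 = control, 2 = PD
  loss <- -mean(log(pmax(rowSums(probs * onehot), 1e-12)))
  dlogits <- (probs - onehot) / B
  grads <- list(Wx = params$Wx * 0, Wh = params$Wh * 0, b = params$b * 0,
                Wy = t(fw$h_final) %*% dlogits, by = colSums(dlogits))
  dh <- dlogits %*% t(params$Wy)
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    ch <- fw$cache[[t]]
    m <- ch$m
    if (arch == "lstm") {
      dh_new <- m * dh; dh_pass <- (1 - m) * dh
      dc_new <- m * dc; dc_pass <- (1 - m) * dc
      do <- dh_new * ch$tc
      dc_new <- dc_new + dh_new * ch$o * (1 - ch$tc^2)
      di <- dc_new * ch$g
      dg <- dc_new * ch$i
      df <- dc_new * ch$c_prev
      dc_prev <- dc_new * ch$f + dc_pass
      dZ <- cbind(di * ch$i * (1 - ch$i), df * ch$f * (1 - ch$f),
                  dg * (1 - ch$g^2), do * ch$o * (1 - ch$o))
      grads$Wx <- grads$Wx + t(ch$Xt) %*% dZ
      grads$Wh <- grads$Wh + t(ch$h_prev) %*% dZ
      grads$b <- grads$b + colSums(dZ)
      dh <- dZ %*% t(params$Wh) + dh_pass
      dc <- dc_prev
    } else {
      dh_new <- m * dh; dh_pass <- (1 - m) * dh
      dZ <- dh_new * (1 - ch$h_new^2)
      grads$Wx <- grads$Wx + t(ch$Xt) %*% dZ
      grads$Wh <- grads$Wh + t(ch$h_prev) %*% dZ
      grads$b <- grads$b + colSums(dZ)
      dh <- dZ %*% t(params$Wh) + dh_pass
    }
  }
  list(loss = loss, grads = grads)
}

.adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.seq_eval_loss <- function(params, X, mask, y01, arch) {
  probs <- .softmax(.seq_forward(params, X, mask, arch)$logits)
  onehot <- cbind(1 - y01, y01)
  -mean(log(pmax(rowSums(probs * onehot), 1e-12)))
}

# ---- public training API ---------------------------------------------------

#' Fit an LSTM / RNN sequence classifier
#'
#' Single recurrent layer (hidden size `hidden`), final hidden state into a
#' linear softmax head; full-batch Adam with early stopping on a
#' subject-grouped validation split.  Deterministic given `seed` (and a
#' fixed BLAS).
#'
#' @param diffs List of [difference()] objects (training records).
#' @param arch `"lstm"` or `"rnn"`.
#' @param hidden Hidden units (default 64).
#' @param epochs Maximum epochs (default 60; 0 gives the untrained
#'   majority-class model).
#' @param lr Adam learning rate (default 2e-3, sized for full-batch updates
#'   on cohorts of a few hundred records).
#' @param val_fraction Fraction of subjects held out for early stopping.
#' @param patience Epochs without validation improvement before stopping.
#' @param seed Integer seed.
#' @return Object of class `sequence_model`.
#' @export
fit_sequence_classifier <- function(diffs, arch = c("lstm", "rnn"),
                                    hidden = 64, epochs = 60, lr = 2e-3,
                                    val_fraction = 0.2, patience = 10,
                                    seed = 1L) {
  arch <- match.arg(arch)
  pk <- .pack_series(diffs)
  B <- dim(pk$X)[1]; C <- dim(pk$X)[3]
  set.seed(seed)
  # grouped validation split for early stopping
  subj <- unique(pk$groups)
  n_val <- max(1L, round(val_fraction * length(subj)))
  val_subj <- sample(subj, n_val)
  val <- pk$groups %in% val_subj
  if (length(unique(pk$y01[!val])) < 2) val[] <- FALSE  # tiny-data fallback
  std <- .series_std(pk$X, pk$mask, which(!val))
  X <- .apply_series_std(pk$X, std)
  params <- .init_params(arch, C, hidden)
  majority <- if (mean(pk$y01[!val]) > 0.5) "PD" else "control"
  best <- params; best_loss <- Inf; bad <- 0
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  hist <- numeric(0)
  if (epochs > 0) {
    Xtr <- X[!val, , , drop = FALSE]; mtr <- pk$mask[!val, , drop = FALSE]
    ytr <- pk$y01[!val]
    Xv <- X[val, , , drop = FALSE]; mv <- pk$mask[val, , drop = FALSE]
    yv <- pk$y01[val]
    for (ep in seq_len(epochs)) {
      lg <- .seq_loss_grad(params, Xtr, mtr, ytr, arch)
      up <- .adam_step(params, lg$grads, state, lr, ep)
      params <- up$params; state <- up$state
      mon <- if (any(val)) .seq_eval_loss(params, Xv, mv, yv, arch) else
        lg$loss
      hist <- c(hist, mon)
      if (mon < best_loss - 1e-5) {
        best_loss <- mon; best <- params; bad <- 0
      } else {
        bad <- bad + 1
        if (bad >= patience) break
      }
    }
    params <- best
  }
  structure(list(arch = arch, params = params, std = std, hidden = hidden,
                 majority = majority, seed = seed, loss_history = hist,
                 channels = colnames(diffs[[1]]$series)),
            class = "sequence_model")
}

#' Predict labels with a sequence model
#' @param object A [fit_sequence_classifier()] model.
#' @param diffs List of `diff_series`.
#' @param ... Unused.
#' @return Character vector of PD/control predictions.
#' @export
predict.sequence_model <- function(object, diffs, ...) {
  pk <- .pack_series(diffs)
  X <- .apply_series_std(pk$X, object$std)
  logits <- .seq_forward(object$params, X, pk$mask, object$arch)$logits
  out <- ifelse(logits[, 2] > logits[, 1], "PD",
                ifelse(logits[, 2] < logits[, 1], "control",
                       object$majority))
  unname(out)
}

#' Cross-validated training of a sequence classifier
#'
#' Subject-grouped stratified k-fold evaluation plus a final model trained
#' on all records.
#'
#' @inheritParams fit_sequence_classifier
#' @param folds CV folds (default 3 -- sequence training dominates runtime).
#' @param average Metric averaging, see [classification_metrics()].
#' @return List with `model` (final `sequence_model`) and `report`
#'   (`classification_report`-style list with pooled metrics).
#' @export
train_sequence_classifier <- function(diffs, arch = c("lstm", "rnn"),
                                      folds = 3, hidden = 64, epochs = 60,
                                      lr = 2e-3, seed = 1L,
                                      average = "binary") {
  arch <- match.arg(arch)
  pk <- .pack_series(diffs)
  fold_id <- grouped_folds(pk$groups, pk$labels, k = folds, seed = seed)
  pred <- rep(NA_character_, length(diffs))
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    if (!length(te)) next
    m <- fit_sequence_classifier(diffs[tr], arch, hidden, epochs, lr,
                                 seed = seed * 100L + f)
    pred[te] <- predict(m, diffs[te])
  }
  mm <- classification_metrics(pk$labels, pred, average)
  metrics <- data.frame(algorithm = arch, precision = mm$precision,
                        recall = mm$recall, f1 = mm$f1,
                        accuracy = mm$accuracy, stringsAsFactors = FALSE)
  final <- fit_sequence_classifier(diffs, arch, hidden, epochs, lr,
                                   seed = seed)
  list(model = final,
       report = structure(list(metrics = metrics,
                               confusion = stats::setNames(
                                 list(mm$confusion), arch),
                               fold_id = fold_id, folds = folds, seed = seed,
                               average = average, predictions = pred),
                          class = "classification_report"))
}
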