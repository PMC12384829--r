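#' Focal loss configuration
#'
#' Focal cross-entropy `-alpha_t * (1 - p_t)^gamma * log(p_t)` down-weights
#' easy examples and re-weights classes. `alpha` is ordered as
#' `(Intact, Impaired)`; the default `(0.5, 2)` upweights the minority
#' Impaired class, and `gamma = 1.5` amplifies the penalty on
#' hard-to-classify cases.
#'
#' @param alpha per-class weights, ordered (Intact, Impaired).
#' @param gamma focusing exponent, `>= 0`.
#' @return list of class `focal_loss_config`.
#' @export
focal_loss_config <- function(alpha = c(0.5, 2.0), gamma = 1.5) {
  stopifnot(length(alpha) == 2, all(alpha > 0), gamma >= 0)
  structure(list(alpha = alpha, gamma = gamma),
            class = "focal_loss_config")
}

#' Training configuration
#'
#' @param batch_size mini-batch size (default 8).
#' @param max_epochs maximum training epochs (default 50).
#' @param early_stopping_patience epochs without validation-loss
#'   improvement before stopping (default 5).
#' @param validation_fraction stratified fraction of the training data held
#'   out internally to drive early stopping (default 0.1).
#' @param step_size Adam learning rate.
#' @param moment_decays Adam first/second moment decay pair.
#' @param epsilon Adam denominator stabilizer.
#' @param threshold decision threshold on P(Impaired); ties go to Impaired.
#' @param seed integer seed for the validation split, initialization and
#'   per-epoch shuffling.
#' @return list of class `train_config`.
#' @export
train_config <- function(batch_size = 8L, max_epochs = 50L,
                         early_stopping_patience = 5L,
                         validation_fraction = 0.1,
                         step_size = 1e-3,
                         moment_decays = c(0.9, 0.999),
                         epsilon = 1e-8,
                         threshold = 0.5,
                         seed = 1L) {
  stopifnot(batch_size >= 1, max_epochs >= 1,
            threshold > 0, threshold < 1,
            validation_fraction >= 0, validation_fraction < 0.5)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 validation_fraction = validation_fraction,
                 step_size = step_size,
                 moment_decays = moment_decays,
                 epsilon = epsilon,
                 threshold = threshold,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize network parameters
#'
#' Builds the weight/bias stack for a feed-forward classifier with leaky
#' ReLU hidden layers and a 2-unit softmax output. Weights are drawn from
#' a symmetric uniform distribution scaled by fan-in and fan-out
#' (Glorot-style); biases start at zero.
#'
#' @param n_inputs number of input features.
#' @param hidden_sizes integer vector of hidden-layer widths (default 7).
#' @param seed integer seed.
#' @param leaky_slope negative-side slope of the hidden activation.
#' @return object of class `network_params` with `weights` (list of
#'   out-by-in matrices), `biases`, `hidden_sizes`, `leaky_slope`.
#' @export
init_network <- function(n_inputs, hidden_sizes = 7L, seed = 1L,
                         leaky_slope = 0.01) {
  stopifnot(n_inputs >= 1)
  if (length(hidden_sizes) == 0) stop("hidden_sizes must be non-empty")
  stopifnot(all(hidden_sizes >= 1))
  sizes <- c(n_inputs, as.integer(hidden_sizes), 2L)
  set.seed(as.integer(seed))
  weights <- vector("list", length(sizes) - 1)
  biases <- vector("list", length(sizes) - 1)
  for (l in seq_along(weights)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1]
    lim <- sqrt(6 / (fan_in + fan_out))
    weights[[l]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim),
                           nrow = fan_out, ncol = fan_in)
    biases[[l]] <- rep(0, fan_out)
  }
  structure(list(weights = weights, biases = biases,
                 hidden_sizes = as.integer(hidden_sizes),
                 leaky_slope = leaky_slope),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  dims <- c(ncol(x$weights[[1]]), x$hidden_sizes, 2L)
  cat("Feed-forward classifier:", paste(dims, collapse = " -> "),
      sprintf("(leaky ReLU slope %g, softmax output)\n", x$leaky_slope))
  invisible(x)
}

# Forward pass keeping every layer's pre-activation and activation, for
# backpropagation.
forward_full <- function(params, X) {
  stopifnot(is.matrix(X))
  if (ncol(X) != ncol(params$weights[[1]])) {
    stop("input has ", ncol(X), " columns but the network expects ",
         ncol(params$weights[[1]]))
  }
  L <- length(params$weights)
  pre <- vector("list", L)
  act <- vector("list", L + 1)
  act[[1]] <- X
  for (l in seq_len(L)) {
    z <- act[[l]] %*% t(params$weights[[l]])
    z <- sweep(z, 2, params$biases[[l]], "+")
    pre[[l]] <- z
    act[[l + 1]] <- if (l < L) leaky_relu(z, params$leaky_slope) else
      softmax_rows(z)
  }
  list(pre = pre, act = act, probs = act[[L + 1]])
}

#' Forward pass: class probabilities
#'
#' @param params a `network_params`.
#' @param X numeric matrix `[n x n_inputs]`.
#' @return matrix `[n x 2]` of class probabilities, columns
#'   `(Intact, Impaired)`; rows sum to 1.
#' @export
forward <- function(params, X) {
  p <- forward_full(params, X)$probs
  colnames(p) <- COG_LEVELS
  p
}

#' Focal cross-entropy loss
#'
#' Mean over samples of `-alpha_t * (1 - p_t)^gamma * log(p_t)`, where
#' `p_t` is the predicted probability of the true class (clipped to
#' `[1e-7, 1 - 1e-7]`) and `alpha_t` the true class's weight. With
#' `gamma = 0` and `alpha = (1, 1)` this is ordinary cross-entropy.
#'
#' @param probs matrix `[n x 2]` of class probabilities.
#' @param labels one-hot matrix `[n x 2]`, column order (Intact, Impaired).
#' @param config a [focal_loss_config()].
#' @return scalar loss.
#' @export
focal_loss <- function(probs, labels, config = focal_loss_config()) {
  stopifnot(is.matrix(probs), is.matrix(labels),
            all(dim(probs) == dim(labels)), ncol(probs) == 2)
  if (!all(labels %in% c(0, 1)) || any(rowSums(labels) != 1)) {
    stop("labels must be one-hot rows")
  }
  eps <- 1e-7
  p_t <- pmin(pmax(rowSums(probs * labels), eps), 1 - eps)
  a_t <- drop(labels %*% config$alpha)
  mean(-a_t * (1 - p_t)^config$gamma * log(p_t))
}

# d(mean focal loss)/d(p_t) per sample, on clipped p_t. Inside the clip
# band the derivative is zero (the loss is locally constant in p_t there).
focal_loss_dp <- function(p_t_raw, a_t, gamma) {
  eps <- 1e-7
  inside <- p_t_raw > eps & p_t_raw < 1 - eps
  p_t <- pmin(pmax(p_t_raw, eps), 1 - eps)
  d <- -a_t * (-gamma * (1 - p_t)^(gamma - 1) * log(p_t) +
                 (1 - p_t)^gamma / p_t)
  d[!inside] <- 0
  d
}

#' Analytic gradient of the focal loss
#'
#' Exact gradient of the mean focal loss with respect to every weight and
#' bias, by backpropagation through the softmax output and leaky ReLU
#' hidden layers.
#'
#' @param params a `network_params`.
#' @param X batch feature matrix.
#' @param y one-hot label matrix.
#' @param config a [focal_loss_config()].
#' @return list with `weights` and `biases` gradients, shaped like
#'   `params`.
#' @export
focal_loss_gradient <- function(params, X, y,
                                config = focal_loss_config()) {
  fw <- forward_full(params, X)
  n <- nrow(X)
  L <- length(params$weights)
  p <- fw$probs
  p_t_raw <- rowSums(p * y)
  a_t <- drop(y %*% config$alpha)
  dL_dpt <- focal_loss_dp(p_t_raw, a_t, config$gamma) / n

  # Loss depends on the output logits only through p_t = p_c (true class c):
  # dp_c/dz_j = p_c (1[c=j] - p_j), so dL/dz_j = dL_dpt * p_c * (y_j - p_j).
  delta <- dL_dpt * p_t_raw * (y - p)

  gw <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gw[[l]] <- t(delta) %*% fw$act[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% params$weights[[l]]) *
        leaky_relu_grad(fw$pre[[l - 1]], params$leaky_slope)
    }
  }
  list(weights = gw, biases = gb)
}

# Stratified holdout indices for the internal validation split.
stratified_holdout <- function(labels, fraction, seed) {
  set.seed(seed)
  idx <- unlist(lapply(levels(labels), function(lv) {
    members <- which(labels == lv)
    n_take <- max(1L, round(length(members) * fraction))
    sample(members, n_take)
  }))
  sort(idx)
}

#' Train the classifier with focal loss and Adam
#'
#' Mini-batch training with per-epoch seeded shuffling, an internal
#' stratified validation split, early stopping on validation loss with
#' best-weight restoration, and adaptive-moment (Adam) updates. Fully
#' deterministic given the seeds in `tc`.
#'
#' @param X feature matrix `[n x p]`.
#' @param y one-hot label matrix `[n x 2]` or a label vector coercible via
#'   [cog_factor()].
#' @param hidden_sizes hidden-layer widths.
#' @param tc a [train_config()].
#' @param lc a [focal_loss_config()].
#' @param init_seed seed for weight initialization (defaults to
#'   `tc$seed + 1`).
#' @return list with `params` (trained `network_params`) and `history`
#'   (class `train_history`: per-epoch train/validation loss and accuracy,
#'   `stopped_epoch`, `best_epoch`).
#' @export
train_network <- function(X, y, hidden_sizes = 7L,
                          tc = train_config(), lc = focal_loss_config(),
                          init_seed = NULL) {
  if (!is.matrix(y)) y <- one_hot(y)
  stopifnot(nrow(X) == nrow(y))
  lab <- cog_factor(COG_LEVELS[max.col(y)])
  if (any(table(lab) == 0)) {
    stop("both classes must be present in the training data")
  }
  init_seed <- init_seed %||% (tc$seed + 1L)

  if (tc$validation_fraction > 0) {
    val_idx <- stratified_holdout(lab, tc$validation_fraction,
                                  derive_seed(tc$seed, "val-split"))
  } else {
    val_idx <- integer(0)
  }
  tr_idx <- setdiff(seq_len(nrow(X)), val_idx)
  Xt <- X[tr_idx, , drop = FALSE]; yt <- y[tr_idx, , drop = FALSE]
  Xv <- X[val_idx, , drop = FALSE]; yv <- y[val_idx, , drop = FALSE]
  monitor_val <- length(val_idx) > 0

  params <- init_network(ncol(X), hidden_sizes, seed = init_seed)
  L <- length(params$weights)
  m_w <- lapply(params$weights, function(w) w * 0)
  v_w <- m_w
  m_b <- lapply(params$biases, function(b) b * 0)
  v_b <- m_b
  b1 <- tc$moment_decays[1]; b2 <- tc$moment_decays[2]
  t_step <- 0

  acc_of <- function(p, yy) mean(max.col(p) == max.col(yy))
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), train_acc = numeric(0),
                     val_acc = numeric(0))
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  wait <- 0L; stopped_epoch <- tc$max_epochs

  for (epoch in seq_len(tc$max_epochs)) {
    set.seed(derive_seed(tc$seed, paste0("epoch-", epoch)))
    ord <- sample(nrow(Xt))
    starts <- seq(1, length(ord), by = tc$batch_size)
    for (s in starts) {
      bi <- ord[s:min(s + tc$batch_size - 1, length(ord))]
      g <- focal_loss_gradient(params, Xt[bi, , drop = FALSE],
                               yt[bi, , drop = FALSE], lc)
      t_step <- t_step + 1
      corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
      for (l in seq_len(L)) {
        m_w[[l]] <- b1 * m_w[[l]] + (1 - b1) * g$weights[[l]]
        v_w[[l]] <- b2 * v_w[[l]] + (1 - b2) * g$weights[[l]]^2
        params$weights[[l]] <- params$weights[[l]] - tc$step_size *
          (m_w[[l]] / corr1) / (sqrt(v_w[[l]] / corr2) + tc$epsilon)
        m_b[[l]] <- b1 * m_b[[l]] + (1 - b1) * g$biases[[l]]
        v_b[[l]] <- b2 * v_b[[l]] + (1 - b2) * g$biases[[l]]^2
        params$biases[[l]] <- params$biases[[l]] - tc$step_size *
          (m_b[[l]] / corr1) / (sqrt(v_b[[l]] / corr2) + tc$epsilon)
      }
    }
    pt <- forward(params, Xt)
    train_loss <- focal_loss(pt, yt, lc)
    train_acc <- acc_of(pt, yt)
    if (monitor_val) {
      pv <- forward(params, Xv)
      val_loss <- focal_loss(pv, yv, lc)
      val_acc <- acc_of(pv, yv)
    } else {
      val_loss <- train_loss; val_acc <- train_acc
    }
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss,
                                   train_acc = train_acc,
                                   val_acc = val_acc))
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss; best_params <- params
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tc$early_stopping_patience) {
        stopped_epoch <- epoch
        break
      }
    }
    stopped_epoch <- epoch
  }
  history <- structure(list(epochs = hist, stopped_epoch = stopped_epoch,
                            best_epoch = best_epoch), class = "train_history")
  list(params = best_params, history = history)
}

#' @export
print.train_history <- function(x, ...) {
  cat("Training history:", nrow(x$epochs), "epochs run, best epoch",
      x$best_epoch, sprintf("(val loss %.4f)\n",
                            x$epochs$val_loss[x$best_epoch]))
  invisible(x)
}

#' Predict class labels
#'
#' Assigns `Impaired` when the predicted probability of the Impaired class
#' is greater than or equal to the threshold (ties at the threshold go to
#' Impaired).
#'
#' @param params a `network_params`.
#' @param X feature matrix.
#' @param threshold decision threshold in `(0, 1)`, default 0.5.
#' @return factor of predicted labels.
#' @export
predict_labels <- function(params, X, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  p <- forward(params, X)
  cog_factor(ifelse(p[, "Impaired"] >= threshold, "Impaired", "Intact"))
}

n_parameters <- function(params) {
  sum(vapply(params$weights, length, 1L)) +
    sum(vapply(params$biases, length, 1L))
}

#' Architecture grid search
#'
#' Cross-validates every combination of hidden-layer depth and layer width,
#' scoring each architecture by held-out Impaired recall. The report is
#' sorted by recall (descending), then by fewest Intact-class errors
#' (false positives), then by fewest parameters, mirroring a selection
#' rule that prefers the most parsimonious network among those with top
#' sensitivity.
#'
#' @param X,y features and labels (one-hot or labels).
#' @param depths hidden-layer counts to try (default `1:3`).
#' @param widths per-layer widths to try (default `c(7, 9, 14)`).
#' @param k folds for the stratified cross-validation.
#' @param tc,lc training and loss configs.
#' @return data.frame, one row per architecture: `depth`, `width`,
#'   `recall_impaired`, `intact_errors`, `n_params`.
#' @export
grid_search <- function(X, y, depths = 1:3, widths = c(7L, 9L, 14L),
                        k = 5L, tc = train_config(),
                        lc = focal_loss_config()) {
  if (!is.matrix(y)) y <- one_hot(y)
  lab <- cog_factor(COG_LEVELS[max.col(y)])
  plan <- make_stratified_folds(lab, k = k, seed = derive_seed(tc$seed, "grid"))
  grid <- expand.grid(depth = depths, width = widths)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    hs <- rep(grid$width[i], grid$depth[i])
    cvr <- cross_validate(X, lab, plan, hidden_sizes = hs, tc = tc, lc = lc)
    agg <- Reduce(`+`, lapply(cvr$folds, function(f) {
      c(TP = f$confusion$TP, FP = f$confusion$FP,
        TN = f$confusion$TN, FN = f$confusion$FN)
    }))
    data.frame(depth = grid$depth[i], width = grid$width[i],
               recall_impaired = unname(agg["TP"] /
                                          (agg["TP"] + agg["FN"])),
               intact_errors = unname(agg["FP"]),
               n_params = n_parameters(init_network(ncol(X), hs, seed = 1L)))
  })
  report <- do.call(rbind, rows)
  report[order(-report$recall_impaired, report$intact_errors,
               report$n_params), , drop = FALSE]
}
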