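# All three attribution methods share one value function: the model's
# predicted probability of the Impaired class, with "absent" features
# replaced by a fixed background (zeros by default, i.e. the feature means
# after standardization). This makes Shapley attributions and the two
# masking procedures directly commensurable.

#' Exact Shapley values by subset enumeration
#'
#' Computes exact Shapley values for one subject of the coalition game
#' `v(S) = P(Impaired | features outside S set to the background)`. The
#' attribution satisfies the efficiency identity
#' `sum(phi) = v(full) - v(empty)` and the symmetry and dummy axioms.
#' Enumeration is exponential in the feature count and guarded at 15
#' features; use [shapley_sampling()] beyond that.
#'
#' @param params a `network_params`.
#' @param x numeric feature vector for one subject.
#' @param background per-feature replacement values (default all zeros).
#' @param value_fn optional replacement value function taking a matrix of
#'   masked inputs and returning one value per row; defaults to the
#'   model's predicted Impaired probability.
#' @return named numeric vector of per-feature Shapley values.
#' @export
shapley_exact <- function(params, x, background = NULL, value_fn = NULL) {
  d <- length(x)
  if (d > 15) {
    stop("exact enumeration is limited to 15 features; ",
         "use shapley_sampling() for larger models")
  }
  background <- background %||% rep(0, d)
  stopifnot(length(background) == d)
  value_fn <- value_fn %||% function(Xs) forward(params, Xs)[, "Impaired"]

  # All 2^d coalitions as a logical matrix; one batched value evaluation.
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d)))
  Xs <- matrix(background, nrow = nrow(subsets), ncol = d, byrow = TRUE)
  Xs[subsets] <- matrix(x, nrow = nrow(subsets), ncol = d,
                        byrow = TRUE)[subsets]
  v <- value_fn(Xs)

  sizes <- rowSums(subsets)
  # Weight for adding feature i to coalition S: |S|! (d-|S|-1)! / d!
  w <- exp(lgamma(sizes + 1) + lgamma(d - sizes) - lgamma(d + 1))
  key <- subsets %*% (2^(seq_len(d) - 1))
  v_by_key <- numeric(2^d)
  v_by_key[key + 1] <- v

  phi <- numeric(d)
  for (i in seq_len(d)) {
    without_i <- !subsets[, i]
    S <- which(without_i)
    key_S <- key[S]
    key_Si <- key_S + 2^(i - 1)
    phi[i] <- sum(w[S] * (v_by_key[key_Si + 1] - v_by_key[key_S + 1]))
  }
  names(phi) <- names(x) %||% colnames(params$weights[[1]])
  phi
}

#' Sampled Shapley attributions for a cohort
#'
#' Monte-Carlo Shapley estimation over random feature orderings: for each
#' permutation, features are revealed one at a time from the background
#' toward the subject's actual values, and each feature is credited with
#' the change in predicted Impaired probability when it is revealed. The
#' estimator is unbiased for the exact enumeration values and deterministic
#' given the seed. Permutations are shared across subjects, with all
#' subjects evaluated in one batched forward pass per revelation step.
#'
#' @param params a `network_params`.
#' @param X feature matrix `[n x d]`.
#' @param n_permutations Monte-Carlo sample size (default 200).
#' @param background per-feature replacement values (default zeros).
#' @param seed integer seed.
#' @return object of class `attribution_result`: `phi` (`[n x d]` matrix of
#'   per-subject attributions), `mean_abs` (per-feature mean absolute
#'   value), `ranking` (feature names by decreasing `mean_abs`).
#' @export
shapley_sampling <- function(params, X, n_permutations = 200L,
                             background = NULL, seed = 1L) {
  stopifnot(is.matrix(X), n_permutations >= 1)
  n <- nrow(X); d <- ncol(X)
  background <- background %||% rep(0, d)
  stopifnot(length(background) == d)
  Xbg <- matrix(background, nrow = n, ncol = d, byrow = TRUE)

  set.seed(as.integer(seed))
  phi <- matrix(0, n, d, dimnames = list(NULL, colnames(X)))
  for (p in seq_len(n_permutations)) {
    ord <- sample(d)
    Xc <- Xbg
    v_prev <- forward(params, Xc)[, "Impaired"]
    for (j in ord) {
      Xc[, j] <- X[, j]
      v_new <- forward(params, Xc)[, "Impaired"]
      phi[, j] <- phi[, j] + (v_new - v_prev)
      v_prev <- v_new
    }
  }
  phi <- phi / n_permutations
  mean_abs <- colMeans(abs(phi))
  structure(list(
    phi = phi,
    mean_abs = mean_abs,
    ranking = names(sort(mean_abs, decreasing = TRUE))
  ), class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, n = 10, ...) {
  cat("Shapley attributions for", nrow(x$phi), "subjects x",
      ncol(x$phi), "features; top features by mean |phi|:\n")
  top <- utils::head(sort(x$mean_abs, decreasing = TRUE), n)
  print(round(top, 4))
  invisible(x)
}

# Per-group first-layer contribution cache. The hidden pre-activation is
# b1 + sum_g X[, g] %*% t(W1[, g]), so masking a set of groups just
# subtracts their cached contributions -- no per-subset matrix rebuild.
group_contribution_cache <- function(params, X, groups_reduced) {
  assert_partition(groups_reduced, colnames(X))
  W1 <- params$weights[[1]]
  z_full <- X %*% t(W1)
  z_full <- sweep(z_full, 2, params$biases[[1]], "+")
  contrib <- lapply(groups_reduced, function(cols) {
    idx <- match(cols, colnames(X))
    X[, idx, drop = FALSE] %*% t(W1[, idx, drop = FALSE])
  })
  list(z_full = z_full, contrib = contrib)
}

# Predicted Impaired probability with a set of groups masked to the
# background (zeros), via the contribution cache.
masked_p_impaired <- function(params, cache, mask_groups) {
  z <- cache$z_full
  for (g in mask_groups) z <- z - cache$contrib[[g]]
  h <- leaky_relu(z, params$leaky_slope)
  L <- length(params$weights)
  for (l in seq(2, L)) {
    z <- h %*% t(params$weights[[l]])
    z <- sweep(z, 2, params$biases[[l]], "+")
    if (l < L) h <- leaky_relu(z, params$leaky_slope)
  }
  softmax_rows(z)[, 2]
}

masked_recall <- function(params, cache, mask_groups, y_true, threshold) {
  p <- masked_p_impaired(params, cache, mask_groups)
  pred <- ifelse(p >= threshold, "Impaired", "Intact")
  pos <- y_true == "Impaired"
  sum(pred == "Impaired" & pos) / sum(pos)
}

#' Group-wise masking importance
#'
#' Iteratively zeroes each variable group's columns (equivalent to
#' replacing standardized features by their means), re-runs the trained
#' network without retraining, and records the change in Impaired-class
#' recall. More negative `delta_recall` means the group is more critical
#' to the model's sensitivity.
#'
#' @param params a `network_params`.
#' @param X (reduced) feature matrix the model was trained on.
#' @param y_true follow-up labels.
#' @param groups a `group_map` whose `reduced_entries` partition the
#'   columns of `X` (falls back to `entries` when no reduction happened).
#' @param threshold decision threshold (default 0.5).
#' @return data.frame of class `group_masking_result`: `group`,
#'   `baseline_recall`, `masked_recall`, `delta_recall`, sorted ascending
#'   by `delta_recall`.
#' @export
group_mask_delta_recall <- function(params, X, y_true, groups,
                                    threshold = 0.5) {
  ge <- groups$reduced_entries %||% groups$entries
  lab <- cog_factor(y_true)
  cache <- group_contribution_cache(params, X, ge)
  base <- masked_recall(params, cache, character(0), lab, threshold)
  rows <- lapply(names(ge), function(g) {
    mr <- masked_recall(params, cache, g, lab, threshold)
    data.frame(group = g, baseline_recall = base, masked_recall = mr,
               delta_recall = mr - base, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$delta_recall, out$group), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("group_masking_result", "data.frame")
  out
}

#' Brute-force combinatorial masking
#'
#' Exhaustively enumerates every subset of variable groups of size 1 to
#' `max_size` (in deterministic lexicographic order), recomputes the
#' Impaired-class recall with all member groups zeroed, and returns the
#' subsets sorted by ascending recall (ties broken lexicographically).
#' With 20 groups and `max_size = 5` this evaluates 21,699 subsets.
#'
#' @inheritParams group_mask_delta_recall
#' @param max_size largest subset cardinality (default 5).
#' @return data.frame of class `combo_masking_result`: `subset`
#'   (`+`-joined group names), `size`, `recall`.
#' @export
combo_mask_recall <- function(params, X, y_true, groups, max_size = 5L,
                              threshold = 0.5) {
  ge <- groups$reduced_entries %||% groups$entries
  gnames <- names(ge)
  if (max_size < 1) stop("max_size must be at least 1")
  if (max_size > length(gnames)) stop("max_size exceeds the group count")
  lab <- cog_factor(y_true)
  cache <- group_contribution_cache(params, X, ge)

  n_total <- sum(choose(length(gnames), seq_len(max_size)))
  subset_str <- character(n_total)
  sizes <- integer(n_total)
  recalls <- numeric(n_total)
  pos <- 0L
  for (k in seq_len(max_size)) {
    combos <- utils::combn(gnames, k, simplify = FALSE)
    for (s in combos) {
      pos <- pos + 1L
      subset_str[pos] <- paste(s, collapse = "+")
      sizes[pos] <- k
      recalls[pos] <- masked_recall(params, cache, s, lab, threshold)
    }
  }
  out <- data.frame(subset = subset_str, size = sizes, recall = recalls,
                    stringsAsFactors = FALSE)
  out <- out[order(out$recall, out$subset), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("combo_masking_result", "data.frame")
  out
}

#' Aggregate per-feature attributions to variable groups
#'
#' Sums the mean absolute Shapley value over each group's columns, giving
#' a group-level importance comparable with the masking methods.
#'
#' @param attribution an `attribution_result`.
#' @param groups a `group_map` (reduced entries preferred).
#' @return named numeric vector, sorted decreasing.
#' @export
aggregate_attribution_by_group <- function(attribution, groups) {
  ge <- groups$reduced_entries %||% groups$entries
  v <- vapply(ge, function(cols) {
    sum(attribution$mean_abs[cols])
  }, 1.0)
  sort(v, decreasing = TRUE)
}
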