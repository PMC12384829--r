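#' Variable group map
#'
#' A named, ordered partition of feature-matrix columns into variable
#' groups. `reduced_entries` carries the same partition after group-wise
#' PCA has replaced eligible groups' columns by component scores.
#'
#' @param entries named list: group name -> character vector of column
#'   names.
#' @param reduced_entries optional post-PCA partition, same group order.
#' @return object of class `group_map`.
#' @export
new_group_map <- function(entries, reduced_entries = NULL) {
  stopifnot(is.list(entries), !is.null(names(entries)),
            !anyDuplicated(names(entries)))
  cols <- unlist(entries, use.names = FALSE)
  if (anyDuplicated(cols)) {
    stop("group map is not a partition: column(s) in more than one group: ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  }
  if (!is.null(reduced_entries)) {
    stopifnot(identical(names(reduced_entries), names(entries)))
  }
  structure(list(entries = entries, reduced_entries = reduced_entries),
            class = "group_map")
}

#' @export
print.group_map <- function(x, ...) {
  n <- vapply(x$entries, length, 1L)
  cat("Group map:", length(n), "groups,", sum(n), "columns\n")
  if (!is.null(x$reduced_entries)) {
    nr <- vapply(x$reduced_entries, length, 1L)
    cat("  reduced to", sum(nr), "columns\n")
  }
  invisible(x)
}

assert_partition <- function(group_entries, column_names) {
  cols <- unlist(group_entries, use.names = FALSE)
  if (!setequal(cols, column_names) || length(cols) != length(column_names)) {
    stop("group map does not partition the matrix columns")
  }
  invisible(TRUE)
}

#' Impute missing values
#'
#' Fills missing cells either by a seeded iterative random-forest scheme
#' (default) or by column means. The iterative mode initializes every
#' missing cell at its column mean, then cycles over columns in decreasing
#' order of missingness, refitting a regression forest of each incomplete
#' column on all others and re-predicting its missing cells, until the
#' relative change over imputed cells drops below `tol` or `max_iter`
#' rounds have run. Observed cells are never altered.
#'
#' @param X numeric matrix with `NA`s; every column must have < 20%
#'   missing and at least one observed value.
#' @param method `"forest"` (iterative regression-forest) or `"mean"`.
#' @param seed integer seed controlling the forest fits.
#' @param num_trees trees per forest fit.
#' @param mtry candidate predictors per split; defaults to the square root
#'   of the predictor count, the usual random-forest-imputation setting.
#' @param max_iter maximum round-robin sweeps.
#' @param tol relative-change convergence threshold.
#' @return numeric matrix with no missing entries.
#' @export
impute_missing <- function(X, method = c("forest", "mean"), seed = 1L,
                           num_trees = 50L, mtry = NULL,
                           max_iter = 10L, tol = 1e-3) {
  method <- match.arg(method)
  stopifnot(is.matrix(X), is.numeric(X))
  miss_frac <- colMeans(is.na(X))
  if (any(miss_frac >= 1)) {
    stop("column(s) entirely missing: ",
         paste(colnames(X)[miss_frac >= 1], collapse = ", "))
  }
  if (any(miss_frac >= 0.2)) {
    stop("column(s) with >= 20% missing values: ",
         paste(colnames(X)[miss_frac >= 0.2], collapse = ", "))
  }
  if (!anyNA(X)) return(X)

  mask <- is.na(X)
  mu <- colMeans(X, na.rm = TRUE)
  Xf <- X
  for (j in seq_len(ncol(X))) Xf[mask[, j], j] <- mu[j]
  if (method == "mean") return(Xf)

  order_cols <- order(miss_frac, decreasing = TRUE)
  order_cols <- order_cols[miss_frac[order_cols] > 0]
  # Forests are re-seeded per column but not per sweep, so successive
  # sweeps differ only through the updated imputations and the change
  # statistic measures genuine convergence. Sweeps stop when the relative
  # change falls below tol or first increases (the usual random-forest
  # imputation stopping rule); on an increase the previous sweep's result
  # is returned.
  delta_prev <- Inf
  for (iter in seq_len(max_iter)) {
    X_prev <- Xf
    for (j in order_cols) {
      obs <- !mask[, j]
      preds <- as.data.frame(Xf[, -j, drop = FALSE])
      names(preds) <- paste0("p", seq_len(ncol(preds)))
      fit <- ranger::ranger(
        y = Xf[obs, j], x = preds[obs, , drop = FALSE],
        num.trees = num_trees,
        mtry = mtry %||% max(1L, floor(sqrt(ncol(preds)))),
        seed = derive_seed(seed, paste0("impute-", j)),
        num.threads = 1
      )
      Xf[mask[, j], j] <-
        stats::predict(fit, preds[mask[, j], , drop = FALSE],
                       num.threads = 1)$predictions
    }
    delta <- sum((Xf[mask] - X_prev[mask])^2) / max(sum(Xf[mask]^2), 1e-12)
    if (delta < tol) break
    if (delta >= delta_prev) {
      Xf <- X_prev
      break
    }
    delta_prev <- delta
  }
  stopifnot(!anyNA(Xf), all(Xf[!mask] == X[!mask]))
  Xf
}

#' Standardize features column-wise
#'
#' Z-scores each column (subtract mean, divide by standard deviation) and
#' stores the scaling parameters so the same transform can be replayed on
#' new data. Constant columns are mapped to all zeros and flagged.
#'
#' @param X numeric matrix without missing entries.
#' @return object of class `feature_matrix`: `values`, `column_names`,
#'   `center`, `scale`, `constant_columns`.
#' @export
standardize <- function(X) {
  stopifnot(is.matrix(X), !anyNA(X))
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  constant <- scale_ < 1e-12
  scale_safe <- ifelse(constant, 1, scale_)
  Z <- sweep(sweep(X, 2, center, "-"), 2, scale_safe, "/")
  Z[, constant] <- 0
  if (any(constant)) {
    message("constant column(s) standardized to zero: ",
            paste(colnames(X)[constant], collapse = ", "))
  }
  structure(list(
    values = Z,
    column_names = colnames(X),
    center = center,
    scale = scale_,
    constant_columns = colnames(X)[constant]
  ), class = "feature_matrix")
}

#' Apply stored scaling parameters to new data
#'
#' @param fm a `feature_matrix` produced by [standardize()].
#' @param X new numeric matrix with the same columns.
#' @return z-scored numeric matrix.
#' @export
apply_standardize <- function(fm, X) {
  stopifnot(inherits(fm, "feature_matrix"),
            identical(colnames(X), fm$column_names))
  constant <- fm$scale < 1e-12
  scale_safe <- ifelse(constant, 1, fm$scale)
  Z <- sweep(sweep(X, 2, fm$center, "-"), 2, scale_safe, "/")
  Z[, constant] <- 0
  Z
}

#' Group-wise principal component reduction
#'
#' For every variable group with at least `min_group_size_for_pca` columns,
#' replaces the group's (standardized) columns by the scores of the
#' principal components of its correlation matrix whose eigenvalues reach
#' `eigenvalue_min`. Smaller groups pass through unchanged. If no
#' eigenvalue in an eligible group reaches the threshold, the first
#' component is retained anyway so that no group silently vanishes from
#' the feature space. Component columns are named `<GROUP>_PC<k>`, and each
#' component's sign is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param Z a `feature_matrix` from [standardize()] (or a plain z-scored
#'   matrix).
#' @param groups a `group_map` partitioning the columns of `Z`.
#' @param eigenvalue_min eigenvalue retention threshold (default 1.5; the
#'   retention rule is `>=`).
#' @param min_group_size_for_pca smallest group size eligible for PCA
#'   (default 6, i.e. groups with more than 5 variables).
#' @return list with `features` (a `feature_matrix` carrying the reduced
#'   matrix), `groups` (the map with `reduced_entries` filled), and
#'   `loadings` (per reduced group, the retained eigenvector matrix).
#' @export
groupwise_pca <- function(Z, groups, eigenvalue_min = 1.5,
                          min_group_size_for_pca = 6L) {
  stopifnot(eigenvalue_min > 0, inherits(groups, "group_map"))
  Zm <- if (inherits(Z, "feature_matrix")) Z$values else Z
  if (!all(is.finite(Zm))) stop("non-finite values in standardized matrix")
  assert_partition(groups$entries, colnames(Zm))

  out_cols <- list()
  reduced_entries <- list()
  loadings <- list()
  n <- nrow(Zm)
  for (gname in names(groups$entries)) {
    gcols <- groups$entries[[gname]]
    block <- Zm[, gcols, drop = FALSE]
    if (length(gcols) < min_group_size_for_pca) {
      out_cols[[gname]] <- block
      reduced_entries[[gname]] <- gcols
      next
    }
    R <- stats::cor(block)
    # Guard: constant columns inside a block yield NA correlations; treat
    # them as zero association.
    R[is.na(R)] <- 0
    diag(R) <- 1
    eig <- eigen(R, symmetric = TRUE)
    keep <- which(eig$values >= eigenvalue_min)
    if (length(keep) == 0) keep <- 1L
    V <- eig$vectors[, keep, drop = FALSE]
    # Sign convention: largest-|loading| entry positive.
    for (k in seq_len(ncol(V))) {
      i_max <- which.max(abs(V[, k]))
      if (V[i_max, k] < 0) V[, k] <- -V[, k]
    }
    scores <- block %*% V
    colnames(scores) <- sprintf("%s_PC%d", gname, seq_len(ncol(scores)))
    out_cols[[gname]] <- scores
    reduced_entries[[gname]] <- colnames(scores)
    rownames(V) <- gcols
    colnames(V) <- colnames(scores)
    loadings[[gname]] <- V
  }
  reduced <- do.call(cbind, out_cols)
  fm <- structure(list(
    values = reduced,
    column_names = colnames(reduced),
    center = rep(0, ncol(reduced)),
    scale = rep(1, ncol(reduced)),
    constant_columns = character(0)
  ), class = "feature_matrix")
  list(
    features = fm,
    groups = new_group_map(groups$entries, reduced_entries),
    loadings = loadings
  )
}

#' Binarize a MoCA total score
#'
#' Scores of 26 or above indicate preserved cognition (`Intact`); scores
#' below 26 indicate possible impairment (`Impaired`).
#'
#' @param score integer vector in `[0, 30]`.
#' @param cutoff intact threshold (default 26).
#' @return factor with levels `Intact`, `Impaired`.
#' @export
binarize_moca <- function(score, cutoff = 26L) {
  if (any(score < 0 | score > 30)) {
    stop("MoCA scores must lie in [0, 30]")
  }
  cog_factor(ifelse(score >= cutoff, "Intact", "Impaired"))
}

TRANSITION_LEVELS <- c("Cognitively Intact", "Stable Impaired",
                       "Conversion to Impaired",
                       "Reversion to Cognitively Intact")

#' Assign longitudinal transition classes
#'
#' Maps (baseline, follow-up) label pairs to the four trajectory classes:
#' stable intact, stable impaired, conversion to impaired, and reversion
#' to cognitively intact.
#'
#' @param baseline,followup factors from [binarize_moca()] (or coercible).
#' @return factor over the four transition classes.
#' @export
assign_transition_class <- function(baseline, followup) {
  b <- cog_factor(baseline)
  f <- cog_factor(followup)
  stopifnot(length(b) == length(f))
  out <- ifelse(b == "Intact" & f == "Intact", TRANSITION_LEVELS[1],
         ifelse(b == "Impaired" & f == "Impaired", TRANSITION_LEVELS[2],
         ifelse(b == "Intact" & f == "Impaired", TRANSITION_LEVELS[3],
                TRANSITION_LEVELS[4])))
  factor(out, levels = TRANSITION_LEVELS)
}
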