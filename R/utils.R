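#' @keywords internal
"_PACKAGE"

# Canonical label order used everywhere: one-hot column 1 = Intact,
# column 2 = Impaired. The Impaired class is the positive class.
COG_LEVELS <- c("Intact", "Impaired")

#' Cognitive status factor
#'
#' Coerces a character/factor vector to the package's canonical two-level
#' factor `c("Intact", "Impaired")`.
#'
#' @param x character or factor vector of labels.
#' @return factor with levels `Intact`, `Impaired`.
#' @export
cog_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), COG_LEVELS)
  if (length(bad) > 0) {
    stop("unknown cognitive label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = COG_LEVELS)
}

#' One-hot encode cognitive labels
#'
#' @param labels vector coercible via [cog_factor()].
#' @return numeric matrix `[n x 2]`, columns `Intact`, `Impaired`.
#' @export
one_hot <- function(labels) {
  f <- cog_factor(labels)
  y <- matrix(0, nrow = length(f), ncol = 2,
              dimnames = list(NULL, COG_LEVELS))
  y[cbind(seq_along(f), as.integer(f))] <- 1
  y
}

# Derive a reproducible per-stage child seed from a master seed, keeping the
# result inside the 32-bit integer range R requires of set.seed().
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 48271 + h * 7919) %% 2147483629 + 1)
}

leaky_relu <- function(z, slope = 0.01) {
  ifelse(z >= 0, z, slope * z)
}

leaky_relu_grad <- function(z, slope = 0.01) {
  ifelse(z >= 0, 1, slope)
}

# Row-wise softmax with the usual max-shift for numerical stability.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
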