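test_that("initialization produces chained shapes, deterministically", {
  p <- init_network(28, hidden_sizes = 7L, seed = 1L)
  expect_equal(dim(p$weights[[1]]), c(7L, 28L))
  expect_equal(dim(p$weights[[2]]), c(2L, 7L))
  expect_identical(init_network(28, 7L, seed = 1L), p)
  p2 <- init_network(28, c(9L, 9L), seed = 2L)
  expect_equal(lapply(p2$weights, dim),
               list(c(9L, 28L), c(9L, 9L), c(2L, 9L)))
  expect_error(init_network(28, integer(0)), "non-empty")
})

test_that("forward produces softmax probabilities", {
  p <- init_network(4, 3L, seed = 5L)
  # zero weights and biases: equal logits -> (0.5, 0.5)
  p0 <- p
  p0$weights <- lapply(p0$weights, function(w) w * 0)
  probs0 <- forward(p0, matrix(rnorm(20), 5, 4))
  expect_equal(unname(probs0), matrix(0.5, 5, 2), tolerance = 1e-12)
  # rows always sum to one
  X <- matrix(rnorm(40), 10, 4)
  expect_lt(max(abs(rowSums(forward(p, X)) - 1)), 1e-9)
  # shift invariance: adding a constant to both output logits via the
  # output biases leaves the probabilities unchanged
  p_shift <- p
  p_shift$biases[[2]] <- p_shift$biases[[2]] + 3.7
  expect_equal(forward(p_shift, X), forward(p, X), tolerance = 1e-9)
  expect_error(forward(p, matrix(0, 2, 5)), "expects")
})

test_that("forward matches hand arithmetic on a one-hidden-unit network", {
  # x = (0.5, -2); hidden: w = (2, 1), b = 0.25
  #   z = 2*0.5 + 1*(-2) + 0.25 = -0.75, leaky relu -> h = -0.0075
  # output weights (1, -1), biases (0.1, -0.2):
  #   logits = (0.1 - 0.0075, -0.2 + 0.0075)
  p <- structure(list(
    weights = list(matrix(c(2, 1), 1, 2), matrix(c(1, -1), 2, 1)),
    biases = list(0.25, c(0.1, -0.2)),
    hidden_sizes = 1L, leaky_slope = 0.01), class = "network_params")
  h <- -0.75 * 0.01
  logits <- c(0.1 + h, -0.2 - h)
  expected <- exp(logits) / sum(exp(logits))
  got <- forward(p, matrix(c(0.5, -2), 1, 2))
  expect_equal(unname(drop(got)), expected, tolerance = 1e-12)
  # positive regime passes the pre-activation through unscaled
  got_pos <- forward(p, matrix(c(1, 0), 1, 2))  # z = 2.25, h = 2.25
  logits_pos <- c(0.1 + 2.25, -0.2 - 2.25)
  expect_equal(unname(drop(got_pos)),
               exp(logits_pos) / sum(exp(logits_pos)), tolerance = 1e-12)
})

test_that("focal loss evaluates its closed forms", {
  lc11 <- focal_loss_config(alpha = c(1, 1), gamma = 0)
  # perfect prediction
  probs <- cbind(Intact = c(1, 0), Impaired = c(0, 1))
  y <- cbind(c(1, 0), c(0, 1))
  expect_lt(focal_loss(probs, y, focal_loss_config()), 1e-6)
  # gamma = 0, alpha = (1,1): plain cross-entropy; p_t = 0.5 -> ln 2
  expect_equal(focal_loss(cbind(0.5, 0.5), cbind(1, 0), lc11), log(2),
               tolerance = 1e-12)
  # single Impaired sample at p_t = 0.9 with the study weights:
  # 2 * 0.1^1.5 * (-ln 0.9)
  expect_equal(focal_loss(cbind(0.1, 0.9), cbind(0, 1),
                          focal_loss_config(alpha = c(0.5, 2), gamma = 1.5)),
               2 * 0.1^1.5 * (-log(0.9)), tolerance = 1e-12)
  expect_error(focal_loss(cbind(0.5, 0.5), cbind(1, 1), lc11), "one-hot")
})

test_that("focal loss is non-negative and decreasing in p_t", {
  lc <- focal_loss_config()
  pt <- seq(0.05, 0.95, by = 0.05)
  losses <- vapply(pt, function(p) {
    focal_loss(cbind(1 - p, p), cbind(0, 1), lc)
  }, 1.0)
  expect_true(all(losses >= 0))
  expect_true(all(diff(losses) < 0))
})

test_that("analytic gradients match central finite differences", {
  set.seed(21)
  p <- init_network(4, 3L, seed = 8L)
  X <- matrix(rnorm(32), 8, 4)
  y <- one_hot(sample(c("Intact", "Impaired"), 8, replace = TRUE,
                      prob = c(0.6, 0.4)))
  for (lc in list(focal_loss_config(),
                  focal_loss_config(alpha = c(1, 1), gamma = 0),
                  focal_loss_config(alpha = c(0.25, 4), gamma = 2))) {
    g <- focal_loss_gradient(p, X, y, lc)
    num <- numeric_gradient(p, X, y, lc)
    for (l in 1:2) {
      denom <- pmax(abs(num$weights[[l]]), 1e-3)
      expect_lt(max(abs(g$weights[[l]] - num$weights[[l]]) / denom), 1e-5)
      denomb <- pmax(abs(num$biases[[l]]), 1e-3)
      expect_lt(max(abs(g$biases[[l]] - num$biases[[l]]) / denomb), 1e-5)
    }
  }
})

test_that("gamma = 0, alpha = (1,1) reduces to the softmax cross-entropy
          gradient", {
  set.seed(22)
  p <- init_network(3, 2L, seed = 9L)
  X <- matrix(rnorm(18), 6, 3)
  y <- one_hot(rep(c("Intact", "Impaired"), 3))
  g <- focal_loss_gradient(p, X, y,
                           focal_loss_config(alpha = c(1, 1), gamma = 0))
  # independent reference: standard CE backprop, delta_out = (p - y)/n
  fw_act_h <- leaky_relu(sweep(X %*% t(p$weights[[1]]), 2,
                               p$biases[[1]], "+"), p$leaky_slope)
  z_out <- sweep(fw_act_h %*% t(p$weights[[2]]), 2, p$biases[[2]], "+")
  probs <- exp(z_out - apply(z_out, 1, max))
  probs <- probs / rowSums(probs)
  delta <- (probs - y) / nrow(X)
  gw2 <- t(delta) %*% fw_act_h
  expect_lt(max(abs(g$weights[[2]] - gw2)), 1e-9)
  expect_lt(max(abs(g$biases[[2]] - colSums(delta))), 1e-9)
})

test_that("gradient vanishes at a symmetric stationary point", {
  # all-zero parameters give equal logits; with a class-balanced batch,
  # alpha = (1,1) and any gamma the output-layer gradient cancels
  p <- init_network(2, 2L, seed = 1L)
  p$weights <- lapply(p$weights, function(w) w * 0)
  X <- matrix(c(1, -1, 2, -2), 2, 2)
  X <- rbind(X, X)
  y <- one_hot(c("Intact", "Intact", "Impaired", "Impaired"))
  X <- X[c(1, 3, 2, 4), ]; y <- y[c(1, 3, 2, 4), ]
  g <- focal_loss_gradient(p, X, y, focal_loss_config(alpha = c(1, 1),
                                                      gamma = 1.5))
  expect_lt(max(abs(g$weights[[2]])), 1e-12)
  expect_lt(max(abs(g$biases[[2]])), 1e-12)
})

test_that("training separates two Gaussian blobs", {
  set.seed(30)
  n <- 100
  X <- rbind(matrix(rnorm(2 * n, mean = -1.5), n, 2),
             matrix(rnorm(2 * n, mean = 1.5), n, 2))
  lab <- rep(c("Intact", "Impaired"), each = n)
  fit <- train_network(X, one_hot(lab), hidden_sizes = 7L,
                       tc = train_config(seed = 3L))
  acc <- mean(predict_labels(fit$params, X) == cog_factor(lab))
  expect_gte(acc, 0.95)
  expect_lte(fit$history$stopped_epoch, 50L)
})

test_that("training is deterministic and early stopping improves on epoch 1", {
  co <- small_cohort(seed = 8L, n = 200L, missing_rate = 0)
  fm <- standardize(co$X_raw)
  y <- binarize_moca(co$moca_followup)
  tc <- train_config(seed = 17L)
  f1 <- train_network(fm$values, y, tc = tc)
  f2 <- train_network(fm$values, y, tc = tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  h <- f1$history$epochs
  expect_lte(h$val_loss[f1$history$best_epoch], h$val_loss[1])
  # training loss decreases over most epoch transitions
  expect_gte(mean(diff(h$train_loss) <= 0), 0.8)
  expect_error(train_network(fm$values, one_hot(rep("Intact", nrow(fm$values)))),
               "both classes")
})

test_that("prediction thresholds: ties go to Impaired", {
  p <- init_network(3, 2L, seed = 4L)
  p$weights <- lapply(p$weights, function(w) w * 0)  # P(Impaired) = 0.5
  X <- matrix(rnorm(9), 3, 3)
  expect_true(all(predict_labels(p, X, threshold = 0.5) == "Impaired"))
  # just below the threshold -> Intact: tilt the output bias
  p$biases[[2]] <- c(1e-3, 0)  # P(Impaired) just under 0.5
  expect_true(all(predict_labels(p, X, threshold = 0.5) == "Intact"))
  # high threshold
  p$biases[[2]] <- c(0, 1)     # P(Impaired) ~ 0.73
  expect_true(all(predict_labels(p, X, threshold = 0.9) == "Intact"))
  expect_error(predict_labels(p, X, threshold = 0), "threshold")
})

test_that("the architecture grid search ranks nine candidates", {
  set.seed(31)
  n <- 200
  x1 <- rnorm(2 * n); x2 <- rnorm(2 * n)
  p_imp <- plogis(2.5 * x1 - 2 * x2)
  lab <- ifelse(runif(2 * n) < p_imp, "Impaired", "Intact")
  X <- cbind(x1, x2, matrix(rnorm(2 * n * 3), ncol = 3))
  report <- grid_search(X, lab, k = 3L,
                        tc = train_config(max_epochs = 40L, seed = 7L))
  expect_equal(nrow(report), 9L)
  expect_setequal(paste(report$depth, report$width),
                  paste(rep(1:3, 3), rep(c(7, 9, 14), each = 3)))
  expect_true(all(report$recall_impaired >= 0 & report$recall_impaired <= 1))
  # on a linear signal the single-layer 7-unit model is competitive
  top <- report$recall_impaired[1]
  r17 <- report$recall_impaired[report$depth == 1 & report$width == 7]
  expect_gte(r17, top - 0.03)
  # sorted by recall, then fewest Intact errors, then fewest parameters
  expect_true(all(diff(report$recall_impaired) <= 0))
})
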