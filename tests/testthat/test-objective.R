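test_that("the prediction head is a plain linear map", {
  H <- rbind(c(1, 2), c(3, 4), c(5, 6))
  W <- rbind(c(0.5, -1), c(1, 0.25))
  b <- c(0.1, -0.1)
  expect_equal(predict_head(H, W, b),
               sweep(H %*% W, 2, b, `+`))
  ## zero weights -> zero logits -> probability one half
  z <- predict_head(H, matrix(0, 2, 1))
  expect_equal(stats::plogis(z), matrix(0.5, 3, 1))
  ## identity-like head on 1-dim embeddings
  expect_equal(predict_head(matrix(c(1, -2)), matrix(1), 0),
               matrix(c(1, -2)))
})

test_that("prediction loss is the masked mean and matches hand values", {
  y <- matrix(c(0, 1), 2, 1)
  expect_equal(prediction_loss(y, y, matrix(TRUE, 2, 1), "regression"), 0)
  ## single observed pair (2 vs 0) -> squared error 4
  yh <- matrix(c(2, 99), 2, 1)
  mk <- matrix(c(TRUE, FALSE), 2, 1)
  expect_equal(prediction_loss(yh, matrix(0, 2, 1), mk, "regression"), 4)
  expect_error(prediction_loss(yh, y, matrix(FALSE, 2, 1), "regression"),
               "no observed")
})

test_that("masked positions never influence the loss", {
  set.seed(51)
  yh <- matrix(rnorm(8), 4, 2)
  y <- matrix(rbinom(8, 1, 0.5), 4, 2)
  mask <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                 4, 2)
  base <- prediction_loss(yh, y, mask, "classification")
  y2 <- y; y2[!mask] <- 999
  yh2 <- yh; yh2[, 2] <- -50  # fully masked second task
  expect_equal(prediction_loss(yh2, y2, mask, "classification"), base)
  ## equals the single-task loss on the observed task
  expect_equal(base, prediction_loss(yh[, 1, drop = FALSE],
                                     y[, 1, drop = FALSE],
                                     mask[, 1, drop = FALSE],
                                     "classification"))
})

test_that("classification graph loss matches its hand evaluation", {
  labels <- matrix(c(1, 1, 0), ncol = 1)
  ## fused weights exactly match A*: zero loss
  A_perfect <- rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0))
  expect_equal(gsl_loss_classification(A_perfect, labels, 1:3), 0)
  ## same-label pair with zero weight contributes (0 - 1)^2 = 1
  A_zero <- matrix(0, 3, 3)
  expect_equal(gsl_loss_classification(A_zero, labels[1:2, , drop = FALSE],
                                       1:2), 1)
  ## different-label pair with zero weight contributes nothing
  expect_equal(gsl_loss_classification(A_zero, matrix(c(1, 0), ncol = 1),
                                       1:2), 0)
  expect_warning(v <- gsl_loss_classification(A_zero, labels, 1),
                 "fewer than 2")
  expect_equal(v, 0)
})

test_that("classification graph loss decreases as a same-label edge approaches 1", {
  labels <- matrix(c(1, 1, 0), ncol = 1)
  losses <- vapply(c(0, 0.4, 0.8, 1), function(w) {
    A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- w
    gsl_loss_classification(A, labels, 1:3)
  }, 0)
  expect_true(all(diff(losses) < 0))
})

test_that("multi-task agreement requires every co-observed task to match", {
  labels <- rbind(c(1, 0), c(1, 1), c(1, NA))
  mask <- rbind(c(TRUE, TRUE), c(TRUE, TRUE), c(TRUE, FALSE))
  A <- matrix(0, 3, 3)
  ## pair (1,2): disagree on task 2 -> A* = 0; pair (1,3) and (2,3):
  ## co-observed task 1 agrees -> A* = 1 each
  expect_equal(gsl_loss_classification(A, labels, 1:3, mask), 2)
})

test_that("regression graph loss penalizes only discordant pairs", {
  y <- c(0, 0.2, 2)
  A <- matrix(0, 3, 3)
  A[1, 3] <- A[3, 1] <- 0.4
  ## only |y1 - y3| and |y2 - y3| exceed 0.5; weights 0.4 and 0
  expect_equal(gsl_loss_regression(A, y, 1:3, epsilon_y = 0.5), 0.16)
  ## no qualifying pair
  expect_equal(gsl_loss_regression(A, c(0, 0.1, 0.2), 1:3, 0.5), 0)
  expect_error(gsl_loss_regression(A, y, 1:3, epsilon_y = 0), "> 0")
})

test_that("total loss combines components with the configured weight", {
  expect_equal(total_loss(0.5, 0.25), 0.75)
  expect_equal(total_loss(0.5, 0.25, gsl_weight = 0), 0.5)
  expect_equal(total_loss(1, 0), 1)
  expect_error(total_loss(Inf, 0), "non-finite")
  expect_error(total_loss(1, 1, gsl_weight = -1), ">= 0")
})
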