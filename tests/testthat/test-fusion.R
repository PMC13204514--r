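# Dice index, zero-clipping, logistic probability and grid-search fitting.

test_that("Dice index covers the defining cases", {
  a <- array(c(1, 1, 0, 0), c(2, 2, 1))
  expect_equal(dice_index(a, a)$dice, 1)
  b <- array(c(0, 0, 1, 1), c(2, 2, 1))
  expect_equal(dice_index(a, b)$dice, 0)
  # TP = 2, FP = 1, FN = 1 -> 2*2/(2*2+1+1)
  pred <- c(1, 1, 1, 0, 0)
  truth <- c(1, 1, 0, 1, 0)
  r <- dice_index(pred, truth)
  expect_equal(r$tp, 2); expect_equal(r$fp, 1); expect_equal(r$fn, 1)
  expect_equal(r$dice, 2 * 2 / (2 * 2 + 1 + 1))
  # conventions: empty vs empty = 1 (flagged); empty vs non-empty = 0
  e <- dice_index(numeric(4), numeric(4))
  expect_equal(e$dice, 1); expect_true(e$both_empty)
  expect_equal(dice_index(numeric(4), c(1, 0, 0, 0))$dice, 0)
  expect_error(dice_index(matrix(0, 2, 2), matrix(0, 3, 3)), "grid")
})

test_that("zero-clipping is directional and matches element-wise thresholding", {
  expect_true(all(zero_clip(rep(0.05, 5), +1) == 0))
  expect_equal(zero_clip(0.5, +1), 0.5)
  expect_equal(zero_clip(-0.5, -1), -0.5)
  expect_equal(zero_clip(-0.5, +1), 0)
  expect_equal(zero_clip(0.5, -1), 0)
  set.seed(1)
  z <- rnorm(200)
  zp <- zero_clip(z, "+")
  expect_equal(sum(zp != 0), sum(z >= 0.1))
  zn <- zero_clip(z, "-")
  expect_equal(sum(zn != 0), sum(z <= -0.1))
})

test_that("logistic probability follows the closed form", {
  p0 <- list(beta0 = 0, beta1 = 0, beta_features = c(0, 0))
  roi <- array(1L, c(2, 2, 2))
  pm <- array(rnorm(8), c(2, 2, 2))
  f <- list(array(rnorm(8), c(2, 2, 2)), array(rnorm(8), c(2, 2, 2)))
  expect_true(all(logistic_probability(p0, pm, f, roi) == 0.5))
  p1 <- list(beta0 = log(3), beta1 = 0, beta_features = numeric(0))
  expect_equal(unique(as.numeric(logistic_probability(p1, pm))), 0.75,
               tolerance = 1e-12)
  # oracle: independent sigmoid evaluation
  pb <- list(beta0 = 0.3, beta1 = -1.2, beta_features = c(0.7, 2))
  got <- logistic_probability(pb, pm, f)
  want <- 1 / (1 + exp(-(0.3 - 1.2 * pm + 0.7 * f[[1]] + 2 * f[[2]])))
  expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
  # outside-ROI voxels get probability 0
  roi2 <- roi; roi2[1, 1, 1] <- 0L
  expect_equal(logistic_probability(pb, pm, f, roi2)[1, 1, 1], 0)
  # monotonicity: raising a feature value never lowers the probability
  f2 <- f; f2[[1]] <- f[[1]] + 1
  expect_true(all(logistic_probability(pb, pm, f2) >=
                    logistic_probability(pb, pm, f)))
})

test_that("the default grid enumerates 432 combinations", {
  g <- fusion_grid(2)
  expect_equal(vapply(g, length, integer(1)),
               c(beta0 = 3L, beta1 = 4L, beta2 = 6L, beta3 = 6L))
  expect_equal(grid_size(g), 432)
  expect_equal(grid_size(fusion_grid(0)), 12)
})

make_designs <- function(n = 4, nvox = 60, nf = 2, seed = 1, signal = TRUE) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    truth <- rbinom(nvox, 1, 0.2) == 1
    prob_z <- rnorm(nvox) + ifelse(truth, runif(1, 0, 2), 0)
    feats <- matrix(rnorm(nvox * nf), nvox, nf)
    if (signal && nf > 0)
      feats[truth, 1] <- feats[truth, 1] + 3
    list(prob_z = prob_z, feats = zero_clip(feats, 1), truth = truth)
  })
}

test_that("grid search returns the exhaustive optimum", {
  designs <- make_designs()
  g <- fusion_grid(2, beta0 = c(-1, 0), beta1 = c(0.5, 1),
                   betaf = c(0, 1, 2))
  fit <- grid_search_fit(designs, g, n_features = 2)
  # brute force over every combination, recomputing Dice independently
  combos <- expand.grid(g)
  dice_of <- function(beta) {
    mean(vapply(designs, function(d) {
      eta <- beta[1] + beta[2] * d$prob_z +
        beta[3] * d$feats[, 1] + beta[4] * d$feats[, 2]
      p <- 1 / (1 + exp(-eta))
      dice_index(p > 0.5, d$truth)$dice
    }, numeric(1)))
  }
  all_dice <- apply(as.matrix(combos), 1, dice_of)
  expect_equal(fit$train_mean_dice, max(all_dice), tolerance = 1e-12)
  expect_true(all(c(fit$beta0, fit$beta1, fit$beta_features) %in%
                    unlist(g)))
  # chosen params are a member of the grid
  expect_true(fit$beta0 %in% g$beta0 && fit$beta1 %in% g$beta1)
  expect_error(grid_search_fit(designs, fusion_grid(0), n_features = 2),
               "parameters")
})

test_that("re-optimised fit dominates any fixed grid member; informative features get weight", {
  designs <- make_designs(n = 6, seed = 3)
  fit0 <- grid_search_fit(designs, fusion_grid(0), n_features = 0)
  # argmax dominates every enumerated alternative
  expect_equal(fit0$train_mean_dice, max(fit0$train_report$mean_dice))
  # a planted informative biomarker receives a nonzero coefficient
  fit2 <- grid_search_fit(designs, fusion_grid(2), n_features = 2)
  expect_gt(fit2$beta_features[1], 0)
  expect_gte(fit2$train_mean_dice, fit0$train_mean_dice)
})

test_that("apply_model reproduces its contract", {
  # params reproducing the identity on a perfect probability map -> Dice 1
  truth <- c(rep(TRUE, 5), rep(FALSE, 15))
  d <- list(prob_z = ifelse(truth, 5, -5), feats = NULL, truth = truth)
  p <- structure(list(beta0 = 0, beta1 = 4, beta_features = numeric(0),
                      n_features = 0), class = "fusion_params")
  expect_equal(apply_model(p, d)$dice$dice, 1)
  # beta1 large, features zeroed: prediction equals the thresholded map
  d2 <- list(prob_z = rnorm(50), feats = matrix(rnorm(100), 50, 2),
             truth = rbinom(50, 1, 0.3) == 1)
  p2 <- structure(list(beta0 = 0, beta1 = 100, beta_features = c(0, 0),
                       n_features = 2), class = "fusion_params")
  expect_equal(apply_model(p2, d2)$prediction, d2$prob_z > 0)
  # pathological all-zero maps: empty prediction, Dice 0 against truth
  d3 <- list(prob_z = rep(0, 20), feats = NULL,
             truth = c(rep(TRUE, 3), rep(FALSE, 17)))
  p3 <- structure(list(beta0 = -1, beta1 = 2, beta_features = numeric(0),
                       n_features = 0), class = "fusion_params")
  r3 <- apply_model(p3, d3)
  expect_false(any(r3$prediction))
  expect_equal(r3$dice$dice, 0)
})
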