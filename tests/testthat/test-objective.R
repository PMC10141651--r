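# Losses and metrics: closed forms, region composition, and the
# 95th-percentile boundary Hausdorff distance.

test_that("cross entropy: uniform logits give log(nClasses), shift invariance, near-zero at confidence", {
  lg <- array(0, c(4, 4, 4, 2))
  lab <- array(sample(0:3, 32, TRUE), c(4, 4, 2))
  expect_equal(crossEntropyLoss(lg, lab), log(4), tolerance = 1e-9)
  expect_equal(crossEntropyLoss(lg + 3.7, lab), log(4), tolerance = 1e-9)
  conf <- array(0, c(4, 4, 4, 2))
  for (n in 1:2) for (i in 1:4) for (j in 1:4)
    conf[i, j, lab[i, j, n] + 1, n] <- 50
  expect_lt(crossEntropyLoss(conf, lab), 1e-8)
})

test_that("Dice loss: perfect one-hot ~ 0, disjoint ~ 1, closed form at one pixel", {
  lab <- array(sample(0:3, 64, TRUE), c(8, 8, 1))
  onehot <- array(0, c(8, 8, 4, 1))
  for (i in 1:8) for (j in 1:8) onehot[i, j, lab[i, j, 1] + 1, 1] <- 1
  expect_lt(diceLoss(onehot, lab), 1e-4)
  # fully disjoint prediction: every pixel assigned a wrong class
  wrong <- array(0, c(8, 8, 4, 1))
  for (i in 1:8) for (j in 1:8)
    wrong[i, j, ((lab[i, j, 1] + 1) %% 4) + 1, 1] <- 1
  expect_gt(diceLoss(wrong, lab), 1 - 1e-3)
  # one-pixel closed form: uniform probabilities, true class 0
  s <- 1e-5
  p1 <- array(0.25, c(1, 1, 4, 1))
  l1 <- array(0L, c(1, 1, 1))
  d0 <- (2 * 0.25 + s) / (0.25 + 1 + s)      # true class
  dx <- s / (0.25 + 0 + s)                   # the three absent classes
  expect_equal(diceLoss(p1, l1), 1 - (d0 + 3 * dx) / 4, tolerance = 1e-12)
})

test_that("segmentation loss combines Dice and CE with alpha/beta and batch-mean normalisation", {
  lab <- array(sample(0:3, 32, TRUE), c(4, 4, 2))
  lg <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  probs <- asNamespace("hafnet")$softmax4(lg)
  oracle <- 1 * diceLoss(probs, lab) + 0.5 * crossEntropyLoss(lg, lab)
  expect_equal(segLoss(lg, lab), oracle, tolerance = 1e-9)
  # batch of two identical samples scores the same as one
  lg2 <- array(c(lg[, , , 1], lg[, , , 1]), c(4, 4, 4, 2))
  lab2 <- array(c(lab[, , 1], lab[, , 1]), c(4, 4, 2))
  expect_equal(segLoss(lg2, lab2),
               segLoss(array(lg[, , , 1], c(4, 4, 4, 1)),
                       array(lab[, , 1], c(4, 4, 1))),
               tolerance = 1e-6)
  # perfect prediction
  conf <- array(-20, c(4, 4, 4, 2))
  for (n in 1:2) for (i in 1:4) for (j in 1:4)
    conf[i, j, lab[i, j, n] + 1, n] <- 20
  expect_lt(segLoss(conf, lab), 1e-3)
  expect_equal(totalLoss(0.3, 0.2), 0.5)
  expect_equal(totalLoss(0.3, 0.2, lambdaSim = 0), 0.3)
})

test_that("region composition: WT = {1,2,3}, TC = {1,3}, ET = {3}, always nested", {
  lab <- matrix(0L, 4, 4)
  lab[1, 1] <- 1L; lab[2, 2] <- 2L; lab[3, 3] <- 3L
  rm_ <- regionMasks(lab)
  expect_equal(sum(rm_$WT), 3)
  expect_equal(sum(rm_$TC), 2)
  expect_equal(sum(rm_$ET), 1)
  empty <- regionMasks(matrix(0L, 3, 3))
  expect_true(!any(empty$WT) && !any(empty$TC) && !any(empty$ET))
  for (seed in 1:5) {
    lab2 <- matrix(sample(0:3, 64, TRUE), 8, 8)
    r <- regionMasks(lab2)
    expect_true(all(r$ET <= r$TC) && all(r$TC <= r$WT))
  }
  expect_error(regionMasks(matrix(4L, 2, 2)), "invalid label")
})

test_that("self-evaluation is perfect and disjoint regions score zero Dice", {
  lab <- labelMap(generateCase(phantomSpec(imageSide = 64, seed = 31)))
  sc <- evaluateSegmentation(lab, lab)
  expect_equal(sc$dice, rep(1, 3))
  expect_equal(sc$sensitivity, rep(1, 3))
  expect_equal(sc$specificity, rep(1, 3))
  expect_equal(sc$hd95, rep(0, 3))
  # shifted prediction far from truth: ET disjoint -> dice 0
  p <- matrix(0L, 16, 16); p[1:2, 1:2] <- 3L
  t_ <- matrix(0L, 16, 16); t_[10:11, 10:11] <- 3L
  sc2 <- evaluateSegmentation(p, t_)
  expect_equal(sc2$dice[sc2$region == "ET"], 0)
  expect_error(evaluateSegmentation(matrix(0L, 2, 2), matrix(0L, 3, 3)),
               "shape")
})

test_that("HD95 matches the exhaustive toy oracle and is symmetric", {
  # 2x2 grid: truth at (1,1), prediction at (1,2): all distances are 1
  p <- matrix(FALSE, 2, 2); p[1, 2] <- TRUE
  t_ <- matrix(FALSE, 2, 2); t_[1, 1] <- TRUE
  expect_equal(hd95(p, t_), 1.0)
  expect_equal(hd95(t_, p), hd95(p, t_))
  expect_equal(hd95(p, p), 0)
  # empty handling
  e <- matrix(FALSE, 2, 2)
  expect_equal(hd95(e, e), 0)
  expect_equal(hd95(e, p), sqrt(8))              # default penalty: diagonal
  expect_equal(hd95(e, p, penalty = 99), 99)
  # exhaustive oracle on a random pair of blobs
  set.seed(5)
  A <- matrix(runif(144) < 0.2, 12, 12)
  B <- matrix(runif(144) < 0.2, 12, 12)
  bnd <- function(m) which(m & !(m &
    rbind(FALSE, m[-12, ]) & rbind(m[-1, ], FALSE) &
    cbind(FALSE, m[, -12]) & cbind(m[, -1], FALSE)), arr.ind = TRUE)
  ba <- bnd(A); bb <- bnd(B)
  dmat <- sqrt(outer(ba[, 1], bb[, 1], "-")^2 + outer(ba[, 2], bb[, 2], "-")^2)
  pooled <- c(apply(dmat, 1, min), apply(dmat, 2, min))
  expect_equal(hd95(A, B), unname(quantile(pooled, 0.95)))
})

test_that("mean region scores average across cases", {
  s1 <- data.frame(region = c("WT", "TC", "ET"), dice = c(1, 1, 1),
                   sensitivity = 1, specificity = 1, hd95 = 0)
  s2 <- data.frame(region = c("WT", "TC", "ET"), dice = c(0, 0.5, 1),
                   sensitivity = 0, specificity = 1, hd95 = 2)
  m <- meanRegionScores(list(s1, s2))
  expect_equal(m$dice, c(0.5, 0.75, 1))
  expect_equal(m$hd95, rep(1, 3))
})
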