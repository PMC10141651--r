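# Masked self-supervision: mask geometry, per-modality distinct placement,
# the feature-similarity loss, and the shared-encoder dual branch.

ns <- asNamespace("hafnet")

test_that("mask strategies cover the documented pixel budgets", {
  for (s in c(1, 2, 3)) {
    b20 <- makeMask("block20", 224, seed = s)
    expect_equal(sum(b20$mask), 400)
    b50 <- makeMask("block50", 224, seed = s)
    expect_equal(sum(b50$mask), 2500)
    gr <- makeMask("grid", 224, seed = s)
    expect_equal(sum(gr$mask), 400)
    rnd <- makeMask("random", 224, seed = s)
    expect_equal(sum(rnd$mask), 400)
    # random: all masked pixels inside one 35x35 window
    o <- rnd$spec@windowOrigin
    idx <- which(rnd$mask, arr.ind = TRUE)
    expect_true(all(idx[, 1] > o[1] & idx[, 1] <= o[1] + 35))
    expect_true(all(idx[, 2] > o[2] & idx[, 2] <= o[2] + 35))
  }
})

test_that("the grid mask is 16 disjoint 5x5 blocks on a 10-pixel period in a 35x35 window", {
  gr <- makeMask("grid", 128, seed = 7)
  o <- gr$spec@windowOrigin
  idx <- which(gr$mask, arr.ind = TRUE)
  expect_true(all(idx[, 1] > o[1] & idx[, 1] <= o[1] + 35))
  rel_r <- (idx[, 1] - o[1] - 1) %% 10
  rel_c <- (idx[, 2] - o[2] - 1) %% 10
  expect_true(all(rel_r < 5 & rel_c < 5))     # 5-on / 5-off periodic layout
  # connected components: 16 blocks of exactly 25 pixels
  if (requireNamespace("EBImage", quietly = TRUE)) {
    labs <- EBImage::bwlabel(gr$mask)
    expect_equal(max(labs), 16)
    expect_true(all(table(labs[labs > 0]) == 25))
  }
})

test_that("mask placement is seeded, in-bounds and errors on tiny images", {
  a <- makeMask("block20", 64, seed = 5)
  b <- makeMask("block20", 64, seed = 5)
  expect_identical(a$mask, b$mask)
  expect_identical(a$spec@windowOrigin, b$spec@windowOrigin)
  expect_error(makeMask("block50", 40, seed = 1), "too small")
  expect_error(makeMask("nope", 64), "strategy")
})

test_that("per-modality occlusion uses pairwise-distinct origins and leaves the rest untouched", {
  st <- generateCase(phantomSpec(imageSide = 64, seed = 20))
  r <- applyMasks(st, "block20", seed = 3)
  origins <- lapply(r$specs, function(s) s@windowOrigin)
  expect_equal(length(unique(origins)), 4)
  for (m in 1:4) {
    clean <- modalityImages(st)[[m]]
    masked <- modalityImages(r$stack)[[m]]
    expect_true(all(masked[r$masks[[m]]] == 0))
    expect_identical(masked[!r$masks[[m]]], clean[!r$masks[[m]]])
  }
  expect_identical(labelMap(r$stack), labelMap(st))
  r2 <- applyMasks(st, "block20", seed = 3)
  expect_identical(modalityImages(r2$stack), modalityImages(r$stack))
  # custom fill value
  r3 <- applyMasks(st, "block20", seed = 3, fillValue = -1)
  expect_true(all(modalityImages(r3$stack)[[1]][r3$masks[[1]]] == -1))
})

test_that("similarity loss is a cosine dissimilarity with the documented limits", {
  x <- array(runif(48) + 0.5, c(4, 4, 3, 1))
  expect_equal(similarityLoss(x, x), 0, tolerance = 1e-5)
  # disjoint supports -> orthogonal features -> loss ~ 1
  a <- array(0, c(2, 2, 2, 1)); a[1, 1, 1, 1] <- 1
  b <- array(0, c(2, 2, 2, 1)); b[2, 2, 2, 1] <- 1
  oracle <- 1 - (0 + 1e-5) / (1 * 1 + 1e-5)    # direct evaluation
  expect_equal(similarityLoss(a, b), oracle, tolerance = 1e-9)
  # symmetry
  expect_equal(similarityLoss(a, b), similarityLoss(b, a))
  # monotone in alignment: rotating b toward a decreases the loss
  losses <- sapply(c(0, 0.25, 0.5, 1), function(t)
    similarityLoss(a, (1 - t) * b + t * a))
  expect_true(all(diff(losses) < 0))
  # printed form does not vanish for identical unit-norm-free inputs
  y <- array(2, c(2, 2, 1, 1))
  expect_gt(similarityLoss(y, y, form = "printed"), 0.5)
  expect_error(similarityLoss(a, array(0, c(2, 2, 1, 1))), "shape")
})

test_that("dual branch shares encoder parameters and decodes the clean branch", {
  cfg <- networkConfig(baseFilters = 4, nModalities = 2, dropoutRate = 0)
  net <- buildNetwork(cfg, seed = 11)
  st <- small_stack(21)
  r <- dualBranchForward(net, list(st), strategy = "block20", seed = 2)
  expect_equal(dim(r$cleanFeatures), dim(r$maskedFeatures))
  expect_gt(similarityLoss(r$cleanFeatures, r$maskedFeatures), 0)
  # segmentation output is decoded from the clean branch: identical to a
  # plain forward pass without any masking
  fw <- networkForward(net, list(st))
  expect_equal(r$logits, fw$logits, tolerance = 1e-10)
  expect_equal(r$cleanFeatures, fw$bottleneck, tolerance = 1e-10)
})

test_that("the similarity loss back-propagates into shared encoder weights from both branches", {
  cfg <- networkConfig(baseFilters = 2, nModalities = 2, dropoutRate = 0)
  net <- buildNetwork(cfg, seed = 12)
  st <- small_stack(22)
  masked <- applyMasks(st, "block20", seed = 5)$stack
  tp <- ns$new_tape(TRUE)
  enc_c <- ns$network_encode(net, tp, ns$stack_inputs(net, tp, list(st)))
  enc_m <- ns$network_encode(net, tp, ns$stack_inputs(net, tp, list(masked)))
  sim <- ns$op_similarity(tp, ns$op_concat_c(tp, enc_c$bottleneck),
                          ns$op_concat_c(tp, enc_m$bottleneck))
  ns$tape_backward(tp, sim)
  enc_params <- ns$collect_params(
    lapply(net@env$encoders, function(e) lapply(e, `[[`, "params")))
  gnorm <- vapply(enc_params, function(p)
    if (is.null(p$grad)) 0 else max(abs(p$grad)), numeric(1))
  expect_true(all(gnorm[grepl("conv", vapply(enc_params, `[[`, "", "name"))] > 0))
  # shared, not copied: both branches map onto ONE leaf per parameter, so
  # the leaf count equals the number of encoder + pyramid parameters
  aspp_params <- ns$collect_params(lapply(net@env$aspp, `[[`, "params"))
  expect_equal(length(ls(tp$leaves)),
               length(enc_params) + length(aspp_params))
})

test_that("degenerate masking (masked input equals clean) gives zero similarity loss", {
  cfg <- networkConfig(baseFilters = 2, nModalities = 2, dropoutRate = 0)
  net <- buildNetwork(cfg, seed = 13)
  st <- small_stack(23)
  fw <- networkForward(net, list(st))
  expect_equal(similarityLoss(fw$bottleneck, fw$bottleneck), 0,
               tolerance = 1e-5)
})
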