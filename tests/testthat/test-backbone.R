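# Backbone architecture: block contracts, shape laws, channel plan and
# parameter accounting.

ns <- asNamespace("hafnet")

fwd1 <- function(mod, x, train = FALSE) {
  tp <- ns$new_tape(train)
  mod$forward(tp, ns$op_input(tp, x))$value
}

test_that("conv block: size preservation, zero trace and 352 learnables for 1 -> 32", {
  set.seed(1)
  cb <- ns$sg_conv_block(1L, 32L)
  out <- fwd1(cb, array(0, c(16, 16, 1, 1)))
  expect_equal(dim(out), c(16, 16, 32, 1))
  # zero input, fresh running statistics, inference mode -> zero output
  expect_true(all(out == 0))
  n <- sum(vapply(ns$collect_params(cb$params), function(p) length(p$value),
                  numeric(1)))
  expect_equal(n, 3 * 3 * 1 * 32 + 2 * 32)   # weights + BN gamma/beta
  expect_equal(ns$pc_conv_block(1, 32), 352)
})

test_that("residual conv: channel doubling, zero trace, and residual path isolation", {
  set.seed(2)
  rc <- ns$sg_res_conv(4L, 8L, dropout_rate = 0)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  out <- fwd1(rc, x)
  expect_equal(dim(out), c(8, 8, 8, 1))
  expect_true(all(fwd1(rc, array(0, c(8, 8, 4, 1))) == 0))
  # zero the residual-branch weights; keep an identity-like projection:
  # output must equal the projected input alone
  rc$params$cb1$W$value[] <- 0
  rc$params$cb2$W$value[] <- 0
  rc$params$proj$W$value[] <- 0
  rc$params$proj$W$value[1, 1] <- 1      # out channel 1 <- in channel 1
  rc$params$proj$b$value[] <- 0
  out2 <- fwd1(rc, x)
  expect_equal(out2[, , 1, 1], x[, , 1, 1], tolerance = 1e-6)
  expect_true(all(out2[, , 2:8, ] == 0))
})

test_that("encoder: 224 input with 4 layers gives skips 224/112/56/28 and bottleneck side 14", {
  cfg <- networkConfig(baseFilters = 2, nModalities = 1)
  net <- buildNetwork(cfg, seed = 1)
  tp <- ns$new_tape(FALSE)
  x <- ns$op_input(tp, array(rnorm(224 * 224), c(224, 224, 1, 1)))
  enc <- ns$network_encode(net, tp, list(x))
  sides <- vapply(enc$skips[[1]], function(s) dim(s$value)[1], numeric(1))
  expect_equal(sides, c(224, 112, 56, 28))
  expect_equal(dim(enc$bottleneck[[1]]$value)[1], 14)       # 224 / 2^4
  # indivisible spatial size errors out at pooling
  tp2 <- ns$new_tape(FALSE)
  x2 <- ns$op_input(tp2, array(rnorm(50 * 50), c(50, 50, 1, 1)))
  expect_error(ns$network_encode(net, tp2, list(x2)), "even")
})

test_that("encoder forward is deterministic in inference mode", {
  net <- buildNetwork(networkConfig(baseFilters = 4, nModalities = 2), seed = 3)
  st <- small_stack(5)
  a <- networkForward(net, st)
  b <- networkForward(net, st)
  expect_identical(a$logits, b$logits)
})

test_that("atrous pyramid preserves spatial size and projects to the input width", {
  set.seed(4)
  for (dil in list(c(1L, 6L, 12L, 18L), 1L)) {
    as_ <- ns$sg_aspp(6L, dil)
    out <- fwd1(as_, array(rnorm(12 * 12 * 6 * 2), c(12, 12, 6, 2)))
    expect_equal(dim(out), c(12, 12, 6, 2))   # width independent of branches
  }
})

test_that("bottleneck merge concatenates then reduces, and is order sensitive", {
  net <- buildNetwork(networkConfig(baseFilters = 4, nModalities = 2), seed = 5)
  st <- small_stack(6)
  imgs <- modalityImages(st)
  swapped <- modalityStack(imgs[c(2, 1)], labelMap(st), st@modalities[c(2, 1)])
  a <- networkForward(net, st)
  b <- networkForward(net, swapped)
  # concatenation is ordered: modality order changes the result
  expect_gt(max(abs(a$logits - b$logits)), 1e-8)
})

test_that("decoder returns class scores at input resolution", {
  cfg <- networkConfig(baseFilters = 4, nModalities = 2)
  net <- buildNetwork(cfg, seed = 7)
  st <- small_stack(8)
  fw <- networkForward(net, st)
  expect_equal(dim(fw$logits), c(64, 64, 4, 1))    # n_classes channels
  # bottleneck at 1/16 side, concatenated across modalities
  expect_equal(dim(fw$bottleneck), c(4, 4, 2 * 32, 1))
})

test_that("analytic parameter counts match the assembled networks exactly", {
  cfgs <- list(networkConfig(baseFilters = 4),
               networkConfig(baseFilters = 4, useHAFB = FALSE, nModalities = 3),
               networkConfig(baseFilters = 8, multiModal = FALSE,
                             nModalities = 2),
               networkConfig(baseFilters = 4, nLayers = 3, useHAFB = FALSE,
                             multiModal = FALSE))
  for (cfg in cfgs)
    expect_equal(nParams(buildNetwork(cfg, seed = 1)), countParameters(cfg))
})

test_that("parameter scaling: affine with fusion, quadratic without, crossover at 4 modalities", {
  cnt <- function(n, hafb, multi = TRUE)
    countParameters(networkConfig(nModalities = n, useHAFB = hafb,
                                  multiModal = multi))
  hafb <- sapply(1:6, cnt, hafb = TRUE)
  plain <- sapply(1:6, cnt, hafb = FALSE)
  # exactly constant first differences (affine in modality count)
  expect_equal(length(unique(diff(hafb))), 1L)
  # exactly constant second differences (quadratic in modality count)
  expect_equal(length(unique(diff(diff(plain)))), 1L)
  expect_gt(diff(diff(plain))[1], 0)
  # the fusion block pays off from 4 modalities onward, costs below 3
  expect_true(all(hafb[4:6] < plain[4:6]))
  expect_true(all(hafb[1:2] > plain[1:2]))
  # single-encoder mode: count nearly independent of modality count
  single <- sapply(1:6, cnt, hafb = FALSE, multi = FALSE)
  expect_lt(max(single) / min(single), 1.001)
  expect_equal(length(unique(diff(single))), 1L)  # only the first conv grows
})

test_that("channel plan mirrors the bundle multiplier", {
  p1 <- layerChannelPlan(networkConfig())                     # HAFB: k = 3
  expect_equal(p1$encoder_out, c(32, 64, 128, 256))
  expect_equal(p1$decoder_out, 3 * c(32, 64, 128, 256))
  expect_equal(p1$bottleneck, 3 * 256)
  p2 <- layerChannelPlan(networkConfig(useHAFB = FALSE, nModalities = 5))
  expect_equal(p2$decoder_out, 5 * c(32, 64, 128, 256))
  p3 <- layerChannelPlan(networkConfig(useHAFB = FALSE, multiModal = FALSE))
  expect_equal(p3$decoder_out, c(32, 64, 128, 256))
})

test_that("configuration validity is enforced", {
  expect_error(networkConfig(nLayers = 0), "nLayers")
  expect_error(networkConfig(asppDilations = c(1, 1)), "distinct")
  expect_error(networkConfig(dropoutRate = 1.2), "dropoutRate")
})
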