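# genome-to-network compiler: shapes, strides, parameter accounting

# brute-force inventory oracle: walk the actual parameter arrays
bruteForceParamCount <- function(net) {
  total <- 0L
  for (p in net@params) total <- total + length(p)
  total
}

test_that("single operations have the hand-counted parameter shapes", {
  env <- evonas:::.newBuilder()
  inBuf <- evonas:::.addBuffer(env, c(1L, 10L, 10L))
  set.seed(1)
  # CONV_3x3, 1 -> 4 channels: bias-free conv (1*4*9) + BN gamma/beta (2*4)
  evonas:::.buildOperation(env, inBuf, "CONV_3x3", 4L, 1L, "t")
  expect_equal(sum(vapply(env$params, length, integer(1))), 44)

  # IDENTITY at stride 1 with equal channels adds nothing
  env2 <- evonas:::.newBuilder()
  b <- evonas:::.addBuffer(env2, c(4L, 10L, 10L))
  evonas:::.buildOperation(env2, b, "IDENTITY", 4L, 1L, "t")
  expect_length(env2$params, 0)

  # pooling preserves channels with no parameters when in == out
  env3 <- evonas:::.newBuilder()
  b3 <- evonas:::.addBuffer(env3, c(4L, 10L, 10L))
  evonas:::.buildOperation(env3, b3, "MAX_POOL_3x3", 4L, 1L, "t")
  expect_length(env3$params, 0)

  # separable conv 4 -> 4: 2 x (dw 4*9 + pw 4*4 + bn 8) = 120
  env4 <- evonas:::.newBuilder()
  b4 <- evonas:::.addBuffer(env4, c(4L, 10L, 10L))
  evonas:::.buildOperation(env4, b4, "SEP_CONV_3x3", 4L, 1L, "t")
  expect_equal(sum(vapply(env4$params, length, integer(1))), 120)

  expect_error(evonas:::.buildOperation(env4, b4, "CONV_9x9", 4L, 1L, "t"),
               "unknown op")
})

test_that("same-padding stride-2 halves 77 x 104 to 39 x 52", {
  x <- array(rnorm(77 * 104), c(77, 104, 1, 1))
  w <- array(rnorm(9), c(3, 3, 1, 1))
  y <- evonas:::.conv2d_fwd(x, w, 2L, 1L, 1L)
  expect_identical(dim(y)[1:2], c(39L, 52L))
  # and stride 1 with dilation 2 preserves the frame
  y2 <- evonas:::.conv2d_fwd(x, w, 1L, 2L, 1L)
  expect_identical(dim(y2)[1:2], c(77L, 104L))
})

test_that("macro plan doubles filters at each reduction stage", {
  expect_identical(macroPlan(searchConfig())$filters, c(4L, 8L, 8L, 16L))
  expect_identical(macroPlan(searchConfig())$kind,
                   c("normal", "reduction", "normal", "reduction"))
  expect_identical(macroPlan(searchConfig(filters = 8, nLayers = 6))$filters,
                   c(8L, 16L, 16L, 32L, 32L, 64L))
})

test_that("default network maps a 77 x 104 slice to 3 class scores", {
  set.seed(21)
  g <- randomArchitectureGenome()
  net <- buildNetwork(g, searchConfig(), inputSize = c(77, 104))
  x <- array(abs(rnorm(77 * 104)), c(77, 104, 1, 1))
  sc <- predictNetwork(net, x)
  expect_identical(dim(sc), c(1L, 3L))
  # spatial trace through the two reduction stages: 77x104 -> 39x52 -> 20x26
  shapes <- net@shapes
  hw <- t(vapply(shapes, function(s) s[2:3], integer(2)))
  expect_true(any(hw[, 1] == 39 & hw[, 2] == 52))
  expect_true(any(hw[, 1] == 20 & hw[, 2] == 26))
  expect_false(any(hw[, 1] < 20 & hw[, 1] > 1))
  # head: affine map from 16 pooled channels = 16*3 + 3 = 51 parameters
  expect_equal(length(net@params[["head.w"]]) + length(net@params[["head.b"]]),
               51)
})

test_that("all-identity cells add no parameters beyond stem/projections/head", {
  set.seed(22)
  g <- allIdentityGenome(6)
  cfg <- searchConfig(filters = 4, nLayers = 1)   # single normal cell
  net <- buildNetwork(g, cfg, inputSize = c(16, 16))
  expected <- c("stem.w",
                "cell1.pre2.w", "cell1.pre2.bn.gamma", "cell1.pre2.bn.beta",
                "cell1.pre1.w", "cell1.pre1.bn.gamma", "cell1.pre1.bn.beta",
                "head.w", "head.b")
  expect_setequal(names(net@params), expected)
})

test_that("an all-identity normal cell is a fixed point of its projections", {
  set.seed(23)
  g <- allIdentityGenome(4)
  cfg <- searchConfig(filters = 3, nOps = 4, nLayers = 1)
  net <- buildNetwork(g, cfg, inputSize = c(8, 8))
  x <- array(abs(rnorm(8 * 8 * 2)), c(8, 8, 1, 2))
  fw <- evonas:::.forwardTape(net, x, training = FALSE)
  # cell output = node1 + node2 sums of the two projected inputs; with both
  # projections of the same stem, every node output is pre2 + pre1
  tape <- net@tape
  addOuts <- vapply(Filter(function(e) e$type == "add", tape),
                    function(e) e$out, integer(1))
  first <- fw$bufs[[addOuts[1]]]
  for (o in addOuts[-1]) expect_equal(fw$bufs[[o]], first)
})

test_that("networks reject rasters that reduce below 4 x 4", {
  set.seed(24)
  g <- randomArchitectureGenome()
  expect_error(buildNetwork(g, searchConfig(), inputSize = c(8, 8)),
               "stage .* smaller than 4x4")
})

test_that("invalid genomes are refused before graph construction", {
  set.seed(25)
  g <- randomArchitectureGenome()
  g@normal@nodes[[1]][[1]]$src <- 9L
  expect_error(buildNetwork(g, searchConfig()), "invalid genome")
})

test_that("random-genome sweep: shape contract and parameter-count oracle", {
  cfg <- searchConfig()
  set.seed(26)
  for (i in 1:40) {
    g <- randomArchitectureGenome()
    net <- buildNetwork(g, cfg, inputSize = c(17, 19))
    x <- array(abs(rnorm(17 * 19)), c(17, 19, 1, 1))
    fw <- evonas:::.forwardTape(net, x, training = FALSE)
    sc <- fw$bufs[[net@outBuffer]]
    expect_identical(dim(sc), c(1L, 3L))
    expect_true(all(is.finite(sc)))
    # inventory-declared count equals the brute-force array walk
    expect_equal(countParameters(net), bruteForceParamCount(net))
    # recorded buffer shapes match the realized activations
    for (k in seq_along(net@tape)) {
      e <- net@tape[[k]]
      if (e$type %in% c("gap", "linear")) next
      b <- fw$bufs[[e$out]]
      s <- net@shapes[[e$out]]
      expect_identical(dim(b), c(s[2], s[3], s[1], 1L))
    }
  }
})

test_that("normal cells preserve and reduction cells ceil-halve the frame", {
  set.seed(27)
  cfg <- searchConfig(filters = 2, nOps = 6, nLayers = 2)
  for (i in 1:10) {
    g <- randomArchitectureGenome()
    net <- buildNetwork(g, cfg, inputSize = c(15, 21))
    hw <- t(vapply(net@shapes, function(s) s[2:3], integer(2)))
    # stage 1 (normal) keeps 15x21 everywhere; stage 2 (reduction) ends 8x11
    expect_true(any(hw[, 1] == 8 & hw[, 2] == 11))
    expect_false(any(!(hw[, 1] %in% c(15, 8, 1)) | !(hw[, 2] %in% c(21, 11, 1))))
  }
})

test_that("parameter counts sit in the small-network regime", {
  set.seed(28)
  counts <- replicate(20, countParameters(
    buildNetwork(randomArchitectureGenome(), searchConfig(),
                 inputSize = c(77, 104))))
  expect_true(all(counts >= 1e3 & counts <= 1e5))
})
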