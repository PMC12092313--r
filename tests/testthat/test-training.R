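# training engine: schedules, resume semantics, fitness determinism,
# k-fold summaries

makeTinyTensors <- function(seed = 81, nPer = 2, slices = 8) {
  ds <- tinyDataset(seed = seed, nPer = nPer, slices = slices)
  ds <- evonas:::.withSeed(seed, function()
    splitByPatient(ds, valCounts = c(AL = 1, ATTR = 1, CTRL = 1)))
  list(train = partitionTensors(ds, "train"),
       val = partitionTensors(ds, "val"),
       dataset = ds)
}

test_that("zero epochs leave parameters untouched and curves empty", {
  d <- makeTinyTensors()
  cfg <- tinyConfig()
  set.seed(82)
  net <- buildNetwork(randomArchitectureGenome(4), cfg, inputSize = c(12, 12))
  out <- trainModel(net, d$train, d$val, trainingSchedule(epochs = 0))
  expect_identical(out$net@params, net@params)
  expect_equal(nrow(out$curves), 0)
})

test_that("resumed training continues the epoch count and the curves", {
  d <- makeTinyTensors()
  cfg <- tinyConfig()
  set.seed(83)
  net <- buildNetwork(randomArchitectureGenome(4), cfg, inputSize = c(12, 12))
  s1 <- trainingSchedule(epochs = 2, batchSize = 16, seed = 9)
  ph1 <- trainModel(net, d$train, d$val, s1)
  expect_equal(ph1$curves$epoch, 1:2)
  s2 <- trainingSchedule(epochs = 3, batchSize = 16, seed = 9)
  ph2 <- trainModel(ph1$net, d$train, d$val, s2, opt = ph1$opt)
  # the two-phase protocol: 2 + 3 epochs give one contiguous 5-epoch record
  expect_equal(ph2$curves$epoch, 1:5)
  expect_equal(ph2$opt$epoch, 5L)
  # resumed weights moved on from phase 1
  expect_false(identical(ph1$net@params, ph2$net@params))
})

test_that("training a small net on separable phantoms improves accuracy", {
  d <- makeTinyTensors(seed = 84, nPer = 3, slices = 8)
  cfg <- tinyConfig()
  set.seed(85)
  net <- buildNetwork(randomArchitectureGenome(4), cfg, inputSize = c(12, 12))
  out <- trainModel(net, d$train, d$val,
                    trainingSchedule(epochs = 25, learningRate = 3e-3,
                                     batchSize = 16, seed = 3))
  last <- nrow(out$curves)
  expect_lt(out$curves$train_loss[last], out$curves$train_loss[1])
  expect_gt(out$curves$train_acc[last], out$curves$train_acc[1])
  expect_gt(out$curves$train_acc[last], 1 / 3)
  expect_true(all(is.finite(out$curves$val_loss)))
})

test_that("a class missing from the training partition is a data error", {
  d <- makeTinyTensors()
  bad <- d$train
  keep <- bad$y != 3L
  bad$x <- bad$x[, , , keep, drop = FALSE]
  bad$y <- bad$y[keep]
  cfg <- tinyConfig()
  set.seed(86)
  net <- buildNetwork(randomArchitectureGenome(4), cfg, inputSize = c(12, 12))
  expect_error(trainModel(net, bad, d$val), "class is absent")
})

test_that("a degenerate constant-score network scores the majority floor", {
  d <- makeTinyTensors(seed = 87, nPer = 3)
  cfg <- tinyConfig()
  set.seed(88)
  net <- buildNetwork(randomArchitectureGenome(4), cfg, inputSize = c(12, 12))
  net@params[["head.w"]][] <- 0
  net@params[["head.b"]][] <- 0
  # balanced validation set (1 subject x 8 slices per class)
  acc <- evonas:::.evalOn(net, d$val$x, d$val$y)$acc
  expect_equal(acc, 1 / 3, tolerance = 1e-12)
})

test_that("the fitness evaluator is deterministic per genome and seed", {
  d <- makeTinyTensors(seed = 89)
  cfg <- tinyConfig()
  ev <- fitnessEvaluator(d$train, d$val, cfg, inputSize = c(12, 12), seed = 4,
                         epochs = 1)
  set.seed(90)
  g <- randomArchitectureGenome(4)
  f1 <- ev(g)
  f2 <- ev(g)
  expect_identical(f1, f2)
  expect_true(f1 >= 0 && f1 <= 1)
  # a fresh evaluator with the same seed reproduces the value
  ev2 <- fitnessEvaluator(d$train, d$val, cfg, inputSize = c(12, 12), seed = 4,
                          epochs = 1)
  expect_identical(ev2(g), f1)
})

test_that("k-fold validation reports per-fold matrices and fold statistics", {
  ds <- tinyDataset(seed = 91, nPer = 3, slices = 6)
  ds <- evonas:::.withSeed(91, function()
    splitByPatient(ds, testCounts = c(AL = 1, ATTR = 1, CTRL = 1)))
  cfg <- tinyConfig()
  set.seed(92)
  g <- randomArchitectureGenome(4)
  kv <- kfoldValidate(g, ds, k = 2, cfg = cfg,
                      valCounts = c(AL = 1, ATTR = 1, CTRL = 1),
                      epochs = 1, inputSize = c(12, 12), seed = 93)
  expect_length(kv$folds, 2)
  # each fold's confusion matrix conserves the fixed test-set size
  for (cm in kv$folds) expect_equal(sum(cm), 18)
  # mean/SD equal the hand computation from the per-fold metrics
  perFold <- lapply(kv$folds, function(cm)
    suppressWarnings(confusionMetrics(cm)))
  alSens <- vapply(perFold, function(m)
    m$perClass$sensitivity[m$perClass$class == "AL"], numeric(1))
  expect_equal(kv$metrics$sensitivity_mean[kv$metrics$class == "AL"],
               mean(alSens))
  expect_equal(kv$metrics$sensitivity_sd[kv$metrics$class == "AL"],
               sd(alSens))
  ov <- vapply(perFold, function(m) m$overall, numeric(1))
  expect_equal(unname(kv$overall["mean"]), mean(ov))
  expect_equal(unname(kv$overall["sd"]), sd(ov))
})

test_that("k = 1 fold reports zero SD by convention", {
  ds <- tinyDataset(seed = 94, nPer = 3, slices = 4)
  ds <- evonas:::.withSeed(94, function()
    splitByPatient(ds, testCounts = c(AL = 1, ATTR = 1, CTRL = 1)))
  cfg <- tinyConfig()
  set.seed(95)
  g <- randomArchitectureGenome(4)
  kv <- kfoldValidate(g, ds, k = 1, cfg = cfg,
                      valCounts = c(AL = 0, ATTR = 0, CTRL = 1),
                      epochs = 1, inputSize = c(12, 12), seed = 96)
  expect_length(kv$folds, 1)
  expect_true(all(kv$metrics$sensitivity_sd == 0))
  expect_equal(unname(kv$overall["sd"]), 0)
})
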