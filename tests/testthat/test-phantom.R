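# synthetic phantom generator: determinism, class effect, cohort preset

test_that("phantom slices are deterministic given the RNG state", {
  cfg <- phantomConfig(imageSize = c(24, 30))
  set.seed(71)
  a <- phantomSlice("ATTR", cfg)
  set.seed(71)
  b <- phantomSlice("ATTR", cfg)
  expect_identical(a, b)
  expect_true(all(a >= 0))
  expect_identical(dim(a), c(24L, 30L))
  expect_error(phantomSlice("HCM", cfg), "unknown label")
  expect_error(phantomConfig(noise = 0), "noise scale")
})

test_that("mean ring intensity follows the configured class ordering", {
  cfg <- phantomConfig(imageSize = c(32, 36))
  set.seed(72)
  ringMean <- function(label, n = 200) {
    mean(vapply(seq_len(n), function(i) {
      sl <- phantomSlice(label, cfg, uptakeFactor = 1)
      # top decile of pixel intensities tracks the ring region
      mean(sort(sl, decreasing = TRUE)[1:80])
    }, numeric(1)))
  }
  mAL <- ringMean("AL"); mATTR <- ringMean("ATTR"); mCTRL <- ringMean("CTRL")
  expect_gt(mAL, mATTR + 1)
  expect_gt(mATTR, mCTRL + 0.3)
})

test_that("null class effect makes the class distributions identical", {
  cfg <- phantomConfig(ringMean = c(AL = 2, ATTR = 2, CTRL = 2),
                       imageSize = c(20, 20))
  set.seed(73)
  a <- phantomSlice("AL", cfg, uptakeFactor = 1)
  set.seed(73)
  b <- phantomSlice("CTRL", cfg, uptakeFactor = 1)
  expect_identical(a, b)
})

test_that("dataset generation is reproducible and respects slice bounds", {
  cfg <- phantomConfig(nSubjects = c(AL = 2, ATTR = 2, CTRL = 2),
                       sliceRange = c(8, 19), imageSize = c(16, 16))
  d1 <- generatePhantomDataset(cfg, seed = 74)
  d2 <- generatePhantomDataset(cfg, seed = 74)
  expect_equal(d1@subjects, d2@subjects)
  expect_true(all(sliceCounts(d1) >= 8 & sliceCounts(d1) <= 19))
  # generated datasets pass dataset validation
  expect_true(validObject(d1))
})

test_that("a one-subject-per-class smoke dataset has the requested size", {
  cfg <- phantomConfig(nSubjects = c(AL = 1, ATTR = 1, CTRL = 1),
                       sliceRange = c(8, 8), imageSize = c(16, 16))
  ds <- generatePhantomDataset(cfg, seed = 75)
  expect_equal(length(ds), 3)
  expect_equal(sum(sliceCounts(ds)), 24)
})

test_that("the cohort preset reproduces the printed composition exactly", {
  preset <- caPhantomPreset(imageSize = c(16, 16))
  ds <- generatePhantomDataset(preset, seed = 76)
  labels <- subjectLabels(ds)
  counts <- sliceCounts(ds)
  parts <- subjectPartitions(ds)
  expect_equal(length(ds), 47)
  expect_equal(unname(table(labels)[classLabels()]), c(13L, 15L, 19L),
               ignore_attr = TRUE)
  expect_equal(sum(counts), 592)
  for (want in list(c("AL", 240), c("ATTR", 159), c("CTRL", 193)))
    expect_equal(sum(counts[labels == want[1]]), as.integer(want[2]))
  # partitions: train 384, val 96, test 112; test subjects 3/3/5
  expect_equal(sum(counts[parts == "train"]), 384)
  expect_equal(sum(counts[parts == "val"]), 96)
  expect_equal(sum(counts[parts == "test"]), 112)
  expect_equal(unname(table(labels[parts == "test"])[classLabels()]),
               c(3L, 3L, 5L), ignore_attr = TRUE)
  # per-class test slice counts 45 / 33 / 34
  for (want in list(c("AL", 45), c("ATTR", 33), c("CTRL", 34)))
    expect_equal(sum(counts[parts == "test" & labels == want[1]]),
                 as.integer(want[2]))
  # per-class training slice counts match the augmented /10 breakdown
  for (want in list(c("AL", 155), c("ATTR", 101), c("CTRL", 128)))
    expect_equal(sum(counts[parts == "train" & labels == want[1]]),
                 as.integer(want[2]))
})

test_that("separability rises with the configured effect size", {
  # a fixed simple classifier: threshold on mean intensity of the top decile
  sliceScore <- function(sl) mean(sort(sl, decreasing = TRUE)[1:26])
  accAtEffect <- function(gap, seed) {
    cfg <- phantomConfig(nSubjects = c(AL = 4, ATTR = 4, CTRL = 4),
                         sliceRange = c(6, 6), imageSize = c(16, 16),
                         ringMean = c(AL = 1 + 2 * gap, ATTR = 1 + gap,
                                      CTRL = 1),
                         subjectJitter = 0.05, seed = seed)
    ds <- generatePhantomDataset(cfg, seed = seed)
    fl <- datasetSlices(ds)
    sc <- vapply(fl$slices, sliceScore, numeric(1))
    # 1-NN on the class-mean score, a fixed weak classifier
    mu <- vapply(classLabels(), function(l) mean(sc[fl$labels == l]),
                 numeric(1))
    pred <- classLabels()[apply(abs(outer(sc, mu, "-")), 1, which.min)]
    mean(pred == fl$labels)
  }
  set.seed(77)
  accs <- vapply(c(0, 1.5, 6), function(g)
    mean(vapply(1:3, function(s) accAtEffect(g, 100 + s), numeric(1))),
    numeric(1))
  expect_true(all(diff(accs) >= -0.02))   # non-decreasing up to MC noise
  expect_gt(accs[3], accs[1] + 0.2)
})
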