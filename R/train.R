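# training_eval module: schedules, mini-batch training, the two-phase
# lower-fidelity fitness, and the full search protocol.

#' Construct a training schedule
#'
#' Defaults follow the study protocol: Adam with default moment parameters,
#' learning rate 1e-3, cross-entropy loss over the three classes, batch
#' size 32.
#'
#' @param epochs Number of epochs.
#' @param learningRate Adam learning rate.
#' @param batchSize Mini-batch size.
#' @param seed Seed for batch shuffling (and nothing else).
#' @return List of class "evonas_schedule".
#' @export
trainingSchedule <- function(epochs = 25, learningRate = 1e-3,
                             batchSize = 32, seed = 1) {
  structure(list(epochs = as.integer(epochs), learningRate = learningRate,
                 batchSize = as.integer(batchSize), seed = as.integer(seed)),
            class = "evonas_schedule")
}

# stack a list of (H x W) matrices into an (H, W, 1, N) tensor
.stackSlices <- function(slices) {
  d <- dim(slices[[1]])
  x <- array(0, c(d[1], d[2], 1L, length(slices)))
  for (i in seq_along(slices)) x[, , 1L, i] <- slices[[i]]
  x
}

#' Convert a dataset partition to training tensors
#'
#' @param dataset A \linkS4class{SubjectDataset}.
#' @param partition Partition name(s) to extract.
#' @return List with `x` (H, W, 1, N array), `y` (integer labels, 1 = AL,
#'   2 = ATTR, 3 = CTRL) and `subject_id`.
#' @export
partitionTensors <- function(dataset, partition) {
  fl <- datasetSlices(dataset, partition)
  if (!length(fl$slices))
    stop("partitionTensors: partition '", paste(partition, collapse = ","),
         "' is empty")
  list(x = .stackSlices(fl$slices),
       y = match(fl$labels, classLabels()),
       subject_id = fl$subject_id)
}

.evalOn <- function(net, x, y, batchSize = 64L) {
  n <- dim(x)[4]
  loss <- 0; correct <- 0
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    xb <- x[, , , idx, drop = FALSE]
    fw <- .forwardTape(net, xb, training = FALSE)
    sc <- fw$bufs[[net@outBuffer]]
    ce <- .softmaxCE(sc, y[idx])
    loss <- loss + ce$loss * length(idx)
    correct <- correct + sum(max.col(sc, ties.method = "first") == y[idx])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Train a compiled network by mini-batch Adam
#'
#' Runs `sched$epochs` epochs of shuffled mini-batch optimization of the
#' cross-entropy loss, recording per-epoch training loss/accuracy (running
#' averages over batches, train mode) and validation loss/accuracy (full
#' validation set, eval mode). Passing the returned `opt` state back in
#' resumes training where it stopped (the phase-2 extension of the
#' two-phase protocol).
#'
#' @param net A \linkS4class{CompiledNetwork}.
#' @param train,val Lists with `x` (H, W, 1, N array) and `y` (integer
#'   labels in 1..3), e.g. from \code{\link{partitionTensors}}.
#' @param sched A schedule from \code{\link{trainingSchedule}}.
#' @param opt Optional optimizer/resume state from a previous call.
#' @return List with `net` (trained network), `curves` (per-epoch
#'   data.frame), `opt` (resume state).
#' @export
trainModel <- function(net, train, val, sched = trainingSchedule(),
                       opt = NULL) {
  if (!length(train$y)) stop("trainModel: empty training partition")
  if (length(unique(train$y)) < net@nClasses)
    stop("trainModel: a class is absent from the training partition")
  params <- net@params
  if (is.null(opt))
    opt <- list(adam = .adamInit(params), epoch = 0L,
                rngSeed = sched$seed, curves = NULL)
  # private RNG stream for batch shuffling so training does not disturb
  # (and is not disturbed by) the caller's RNG
  rng <- .withSeed(opt$rngSeed + opt$epoch, function() .Random.seed)
  n <- dim(train$x)[4]
  curves <- list()
  if (sched$epochs > 0) for (ep in seq_len(sched$epochs)) {
    ord <- .withRNG(rng, function() sample.int(n))
    rng <- attr(ord, "rng"); ord <- c(ord)
    epLoss <- 0; epCorrect <- 0
    for (start in seq(1L, n, by = sched$batchSize)) {
      idx <- ord[start:min(start + sched$batchSize - 1L, n)]
      xb <- train$x[, , , idx, drop = FALSE]
      yb <- train$y[idx]
      netTmp <- net; netTmp@params <- params
      fw <- .forwardTape(netTmp, xb, training = TRUE)
      net@state <- fw$state
      ce <- .softmaxCE(fw$bufs[[net@outBuffer]], yb)
      if (!is.finite(ce$loss))
        stop("trainModel: non-finite loss at epoch ", opt$epoch + ep)
      epLoss <- epLoss + ce$loss * length(idx)
      epCorrect <- epCorrect +
        sum(max.col(ce$probs, ties.method = "first") == yb)
      grads <- .backwardTape(netTmp, fw$bufs, fw$caches, ce$glogits)
      st <- .adamStep(params, grads, opt$adam, sched$learningRate)
      params <- st$params; opt$adam <- st$opt
    }
    net@params <- params
    vl <- if (!is.null(val) && length(val$y))
      .evalOn(net, val$x, val$y) else list(loss = NA_real_, acc = NA_real_)
    curves[[ep]] <- data.frame(epoch = opt$epoch + ep,
                               train_loss = epLoss / n,
                               train_acc = epCorrect / n,
                               val_loss = vl$loss, val_acc = vl$acc)
  }
  net@params <- params
  opt$epoch <- opt$epoch + sched$epochs
  curves <- if (length(curves)) do.call(rbind, curves) else
    data.frame(epoch = integer(), train_loss = numeric(),
               train_acc = numeric(), val_loss = numeric(),
               val_acc = numeric())
  opt$curves <- rbind(opt$curves, curves)
  list(net = net, curves = opt$curves, opt = opt)
}

# run f() under a temporary RNG seed / stored RNG state, restoring the
# caller's stream afterwards
.withSeed <- function(seed, f) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  f()
}

.withRNG <- function(state, f) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  assign(".Random.seed", state, globalenv())
  out <- f()
  attr(out, "rng") <- get(".Random.seed", globalenv())
  out
}

#' Lower-fidelity fitness evaluator (phase 1)
#'
#' Returns the evaluator the evolutionary loop consumes: build the network
#' for a genome, train it for `cfg@epochsPhase1` epochs, and return the
#' validation accuracy in [0, 1]. Weight initialization and batch shuffling
#' are seeded deterministically from the base seed and a structural hash of
#' the genome, so the same genome always receives the same fitness. A
#' training failure (e.g. non-finite loss) scores 0 with a warning.
#'
#' @param train,val Tensor lists (see \code{\link{partitionTensors}}).
#' @param cfg A \linkS4class{SearchConfig}.
#' @param inputSize Raster size (rows, cols).
#' @param seed Base seed.
#' @param epochs Training epochs; defaults to `cfg@epochsPhase1`.
#' @return Function(genome) -> accuracy in [0, 1].
#' @export
fitnessEvaluator <- function(train, val, cfg, inputSize = c(77, 104),
                             seed = cfg@seed, epochs = cfg@epochsPhase1) {
  force(train); force(val); force(cfg); force(inputSize); force(seed)
  force(epochs)
  function(genome) {
    gSeed <- (seed + round(genomeHash(genome) * 1e6)) %% 2147483647L
    tryCatch({
      net <- .withSeed(gSeed, function() buildNetwork(genome, cfg, inputSize))
      sched <- trainingSchedule(epochs = epochs,
                                learningRate = cfg@learningRate,
                                batchSize = cfg@batchSize, seed = gSeed)
      fit <- trainModel(net, train, val, sched)
      .evalOn(fit$net, val$x, val$y)$acc
    }, error = function(e) {
      warning("fitnessEvaluator: scoring 0 (", conditionMessage(e), ")",
              call. = FALSE)
      0
    })
  }
}

#' Run the full two-phase search protocol
#'
#' For each of `cfg@nRuns` independent runs (seeded base seed + run index):
#' evolve a population with the phase-1 lower-fidelity fitness
#' (`epochsPhase1` epochs per candidate), take the `topK` individuals by
#' phase-1 fitness, and extend each by `epochsPhase2` further epochs
#' (resuming from the phase-1 weights). The global best individual is the
#' one with the highest final validation accuracy across runs.
#'
#' @param cfg A \linkS4class{SearchConfig}.
#' @param dataset A partitioned \linkS4class{SubjectDataset} with train and
#'   val assigned.
#' @param inputSize Raster size (rows, cols).
#' @param evaluatorFactory Optional function(train, val, cfg, seed) -> fitness
#'   function, replacing the training-based phase-1 evaluator (for
#'   structural testing with a stub); when supplied, phase 2 re-uses the
#'   stub fitness as the final accuracy.
#' @return List with `best` (list: genome, run, birthIndex, phase1, final),
#'   `report` (data.frame with one row per promoted individual: run,
#'   birth_index, phase1_accuracy, final_accuracy), `histories` (list of
#'   \linkS4class{SearchHistory}).
#' @export
runSearchProtocol <- function(cfg, dataset, inputSize = c(77, 104),
                              evaluatorFactory = NULL) {
  stub <- !is.null(evaluatorFactory)
  if (!stub) {
    train <- partitionTensors(dataset, "train")
    val <- partitionTensors(dataset, "val")
  }
  reports <- list(); histories <- list()
  for (r in seq_len(cfg@nRuns)) {
    runSeed <- cfg@seed + r
    evaluator <- if (stub) evaluatorFactory(NULL, NULL, cfg, runSeed)
      else fitnessEvaluator(train, val, cfg, inputSize, seed = runSeed)
    hist <- .withSeed(runSeed,
                      function() evolve(cfg, evaluator,
                                        runId = sprintf("run%d", r)))
    histories[[r]] <- hist
    promoted <- topK(hist, cfg@topK)
    rows <- list()
    for (i in seq_along(promoted)) {
      ind <- promoted[[i]]
      final <- if (stub) ind@fitness else {
        gSeed <- (runSeed + round(genomeHash(ind@genome) * 1e6)) %% 2147483647L
        net <- .withSeed(gSeed,
                         function() buildNetwork(ind@genome, cfg, inputSize))
        sched1 <- trainingSchedule(cfg@epochsPhase1, cfg@learningRate,
                                   cfg@batchSize, seed = gSeed)
        ph1 <- trainModel(net, train, val, sched1)
        sched2 <- trainingSchedule(cfg@epochsPhase2, cfg@learningRate,
                                   cfg@batchSize, seed = gSeed)
        ph2 <- trainModel(ph1$net, train, val, sched2, opt = ph1$opt)
        .evalOn(ph2$net, val$x, val$y)$acc
      }
      rows[[i]] <- data.frame(run = r, birth_index = ind@birthIndex,
                              phase1_accuracy = ind@fitness,
                              final_accuracy = final)
    }
    reports[[r]] <- do.call(rbind, rows)
  }
  report <- do.call(rbind, reports)
  bi <- order(-report$final_accuracy, -report$birth_index)[1]
  bestHist <- histories[[report$run[bi]]]
  bestInd <- Filter(function(x) x@birthIndex == report$birth_index[bi],
                    bestHist@individuals)[[1]]
  list(best = list(genome = bestInd@genome, run = report$run[bi],
                   birthIndex = report$birth_index[bi],
                   phase1 = report$phase1_accuracy[bi],
                   final = report$final_accuracy[bi]),
       report = report, histories = histories)
}

#' Stochastic k-fold validation of one architecture
#'
#' Keeps the test partition fixed, and for each of k folds: re-splits the
#' non-test subjects into train/validation at the patient level, re-
#' initializes all weights, trains the full schedule, and evaluates on the
#' fixed test set. Reports the per-fold confusion matrices and per-class
#' metric means and SDs (sample SD, n - 1 denominator).
#'
#' @param genome An \linkS4class{ArchitectureGenome}.
#' @param dataset A \linkS4class{SubjectDataset} whose test partition is
#'   already assigned; non-test subjects are re-split each fold.
#' @param k Number of folds (>= 1).
#' @param cfg A \linkS4class{SearchConfig}.
#' @param valCounts Named per-class subject counts for the validation side
#'   of each re-split.
#' @param epochs Training epochs per fold (default phase1 + phase2).
#' @param inputSize Raster size.
#' @param seed Base seed; fold i uses seed + i.
#' @return List with `folds` (list of per-fold confusion matrices),
#'   `metrics` (data.frame of per-class mean/SD sensitivity, specificity,
#'   accuracy in percent) and `overall` (mean/SD overall accuracy, percent).
#' @export
kfoldValidate <- function(genome, dataset, k = 5, cfg = searchConfig(),
                          valCounts = c(AL = 2, ATTR = 2, CTRL = 3),
                          epochs = cfg@epochsPhase1 + cfg@epochsPhase2,
                          inputSize = c(77, 104), seed = cfg@seed) {
  if (k < 1) stop("kfoldValidate: k must be >= 1")
  test <- partitionTensors(dataset, "test")
  folds <- list(); perFold <- list(); overall <- numeric(k)
  for (i in seq_len(k)) {
    foldSeed <- seed + i
    ds <- .withSeed(foldSeed, function()
      resplitTrainVal(dataset, valCounts = valCounts))
    train <- partitionTensors(ds, "train")
    val <- partitionTensors(ds, "val")
    net <- .withSeed(foldSeed, function() buildNetwork(genome, cfg, inputSize))
    sched <- trainingSchedule(epochs, cfg@learningRate, cfg@batchSize,
                              seed = foldSeed)
    fit <- trainModel(net, train, val, sched)
    pred <- predictNetwork(fit$net, test$x, type = "class")
    cm <- confusionMatrix3(classLabels()[test$y], classLabels()[pred])
    folds[[i]] <- cm
    m <- confusionMetrics(cm)
    perFold[[i]] <- m$perClass
    overall[i] <- m$overall
  }
  agg <- do.call(rbind, perFold)
  metrics <- do.call(rbind, lapply(classLabels(), function(cl) {
    sub <- agg[agg$class == cl, ]
    data.frame(class = cl,
               sensitivity_mean = mean(sub$sensitivity),
               sensitivity_sd = if (k > 1) sd(sub$sensitivity) else 0,
               specificity_mean = mean(sub$specificity),
               specificity_sd = if (k > 1) sd(sub$specificity) else 0,
               accuracy_mean = mean(sub$accuracy),
               accuracy_sd = if (k > 1) sd(sub$accuracy) else 0)
  }))
  list(folds = folds, metrics = metrics,
       overall = c(mean = mean(overall),
                   sd = if (k > 1) sd(overall) else 0))
}

#' Scaled-down end-to-end search benchmark
#'
#' A complete miniature run of the whole pipeline: generate a
#' high-separability phantom cohort (6 subjects per class, 10 slices each,
#' 16 x 16 rasters), split 4 train / 2 validation subjects per class at the
#' patient level, augment the training slices x5 (translations scaled to
#' the small raster), then search with P = 8 founders, C = 16 steps and a
#' 2-epoch lower-fidelity fitness. Returns the best individual's
#' validation accuracy. One call takes a few minutes on one CPU.
#'
#' @param seed Base seed driving phantoms, split, augmentation and search.
#' @param popSize,steps,epochs Search scale.
#' @param copies Augmentation factor for the mini protocol.
#' @return List with `bestFitness`, `best` (the \linkS4class{Individual})
#'   and `history` (the \linkS4class{SearchHistory}).
#' @export
miniSearchRun <- function(seed = 1, popSize = 8, steps = 16, epochs = 2,
                          copies = 5) {
  cfg <- miniPhantomConfig(seed = seed)
  ds <- generatePhantomDataset(cfg, seed = seed)
  ds <- .withSeed(seed, function()
    splitByPatient(ds, valCounts = c(AL = 2, ATTR = 2, CTRL = 2)))
  ds <- .withSeed(seed + 1, function()
    augmentTrainingSet(ds, augmentationPolicy(copiesPerImage = copies,
                                              maxTranslation = 2,
                                              maxRotation = 10)))
  train <- partitionTensors(ds, "train")
  val <- partitionTensors(ds, "val")
  scfg <- searchConfig(popSize = popSize, steps = steps,
                       epochsPhase1 = epochs, sampleSize = 1)
  ev <- fitnessEvaluator(train, val, scfg, inputSize = cfg@imageSize,
                         seed = seed)
  hist <- .withSeed(seed, function() evolve(scfg, ev))
  best <- topK(hist, 1)[[1]]
  list(bestFitness = best@fitness, best = best, history = hist)
}
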