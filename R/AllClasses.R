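#' @import methods
#' @importFrom stats rnorm runif sd
#' @importFrom utils read.csv write.csv head
NULL

#' Primitive operation vocabulary
#'
#' The closed set of cell operations: identity, 3x3 max/average pooling and
#' plain / dilated / depthwise-separable 3x3 convolutions. All kernel-bearing
#' operations use 3x3 kernels only; larger kernels are excluded from the
#' search space by design.
#'
#' @return Character vector of the six operation codes.
#' @export
#' @examples
#' opVocabulary()
opVocabulary <- function() {
  c("IDENTITY", "MAX_POOL_3x3", "AVG_POOL_3x3",
    "CONV_3x3", "DIL_CONV_3x3", "SEP_CONV_3x3")
}

#' Mutation kinds and their default categorical distribution
#'
#' Operation and hidden-state mutations each occur with probability 0.475;
#' the identity (no-op) mutation with probability 0.05.
#'
#' @return Named numeric vector of mutation probabilities summing to one.
#' @export
defaultMutationProbs <- function() {
  c(OPERATION = 0.475, HIDDEN_STATE = 0.475, IDENTITY = 0.05)
}

# ---- CellGenome -------------------------------------------------------------

#' CellGenome: DAG description of one cell
#'
#' A cell is a small DAG over hidden states. States 0 and 1 are the two cell
#' inputs (the outputs of the two previous cells, c_{k-2} and c_{k-1});
#' combine node j (0-based) creates state j+2 by applying one operation to
#' each of two earlier states and summing the results. A cell with n
#' operation slots has n/2 combine nodes and n-1 hidden states in total; the
#' last node's output is the cell output c_k.
#'
#' @slot kind "normal" (spatial-size preserving) or "reduction" (halving).
#' @slot nodes List of combine nodes; each node is a list of two branches,
#'   each branch a list with `src` (0-based source state) and `op` (an
#'   \code{\link{opVocabulary}} code).
#' @export
setClass("CellGenome",
  representation(kind = "character", nodes = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("normal", "reduction"))
      msg <- c(msg, "kind must be 'normal' or 'reduction'")
    for (j in seq_along(object@nodes)) {
      node <- object@nodes[[j]]
      if (length(node) != 2L) {
        msg <- c(msg, sprintf("node %d must have exactly two branches", j - 1L))
        next
      }
      for (b in 1:2) {
        br <- node[[b]]
        if (!is.list(br) || is.null(br$src) || is.null(br$op)) {
          msg <- c(msg, sprintf("node %d branch %d malformed", j - 1L, b))
          next
        }
        if (!br$op %in% opVocabulary())
          msg <- c(msg, sprintf("node %d branch %d: unknown op '%s'",
                                j - 1L, b, br$op))
        if (br$src < 0L || br$src > j)  # 0-based node j-1 sees states 0..j
          msg <- c(msg, sprintf("node %d branch %d: source %d outside {0..%d}",
                                j - 1L, b, br$src, j))
      }
    }
    if (length(msg)) msg else TRUE
  }
)

# ---- ArchitectureGenome -----------------------------------------------------

#' ArchitectureGenome: the unit of evolution
#'
#' A pair of cell genomes (normal + reduction) sharing the same number of
#' operation slots, plus a schema version for serialization.
#'
#' @slot normal,reduction \linkS4class{CellGenome} objects.
#' @slot nOps Integer; operation slots per cell (even, >= 4).
#' @slot schemaVersion Serialization schema identifier.
#' @export
setClass("ArchitectureGenome",
  representation(normal = "CellGenome", reduction = "CellGenome",
                 nOps = "integer", schemaVersion = "character"),
  prototype(schemaVersion = "evonas-genome/1"),
  validity = function(object) {
    msg <- character()
    if (object@nOps < 4L || object@nOps %% 2L != 0L)
      msg <- c(msg, "nOps must be even and >= 4")
    if (object@normal@kind != "normal") msg <- c(msg, "normal cell has wrong kind")
    if (object@reduction@kind != "reduction") msg <- c(msg, "reduction cell has wrong kind")
    for (cell in c("normal", "reduction"))
      if (length(slot(object, cell)@nodes) != object@nOps %/% 2L)
        msg <- c(msg, sprintf("%s cell must have nOps/2 = %d nodes",
                              cell, object@nOps %/% 2L))
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "ArchitectureGenome", function(object) {
  cat(sprintf("ArchitectureGenome (%d ops/cell, schema %s)\n",
              object@nOps, object@schemaVersion))
  for (kind in c("normal", "reduction")) {
    cell <- slot(object, kind)
    cat(sprintf("  %s cell:\n", kind))
    for (j in seq_along(cell@nodes)) {
      n <- cell@nodes[[j]]
      cat(sprintf("    state %d = %s(s%d) + %s(s%d)\n", j + 1L,
                  n[[1]]$op, n[[1]]$src, n[[2]]$op, n[[2]]$src))
    }
  }
})

# ---- SearchConfig -----------------------------------------------------------

#' SearchConfig: hyperparameters of the architecture search
#'
#' Defaults follow the study protocol: F = 4 starting filters, 6 operations
#' per cell, 3 classes, 1 input channel, 4 layers, population P = 100,
#' C = 900 evolutionary steps, tournament size S = 1, 25 + 175 training
#' epochs, batch size 32, Adam with learning rate 1e-3, top-5 selection and
#' 5 independent runs.
#'
#' @slot filters Starting filter count F of the first normal stage.
#' @slot nOps Operations per cell.
#' @slot nClasses,nChannels,nLayers Network macro parameters.
#' @slot popSize Population size P.
#' @slot steps Evolutionary steps C.
#' @slot sampleSize Tournament sample size S.
#' @slot epochsPhase1,epochsPhase2 Lower-fidelity and extension epochs.
#' @slot batchSize,learningRate Optimization settings.
#' @slot topK Architectures per run promoted to phase 2.
#' @slot nRuns Independent search repetitions.
#' @slot seed Base random seed.
#' @export
setClass("SearchConfig",
  representation(filters = "integer", nOps = "integer", nClasses = "integer",
                 nChannels = "integer", nLayers = "integer", popSize = "integer",
                 steps = "integer", sampleSize = "integer",
                 epochsPhase1 = "integer", epochsPhase2 = "integer",
                 batchSize = "integer", learningRate = "numeric",
                 topK = "integer", nRuns = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nOps < 4L || object@nOps %% 2L != 0L)
      msg <- c(msg, "nOps must be even and >= 4")
    if (object@popSize < 1L) msg <- c(msg, "popSize must be >= 1")
    if (object@steps < 0L) msg <- c(msg, "steps must be >= 0")
    if (object@sampleSize < 1L) msg <- c(msg, "sampleSize must be >= 1")
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a search configuration
#'
#' @param filters,nOps,nClasses,nChannels,nLayers,popSize,steps,sampleSize
#'   Macro and evolutionary parameters; see \linkS4class{SearchConfig}.
#' @param epochsPhase1,epochsPhase2,batchSize,learningRate Training settings.
#' @param topK,nRuns,seed Protocol settings.
#' @return A \linkS4class{SearchConfig}.
#' @export
#' @examples
#' cfg <- searchConfig(popSize = 10, steps = 20)
searchConfig <- function(filters = 4, nOps = 6, nClasses = 3, nChannels = 1,
                         nLayers = 4, popSize = 100, steps = 900,
                         sampleSize = 1, epochsPhase1 = 25, epochsPhase2 = 175,
                         batchSize = 32, learningRate = 1e-3, topK = 5,
                         nRuns = 5, seed = 1) {
  new("SearchConfig",
      filters = as.integer(filters), nOps = as.integer(nOps),
      nClasses = as.integer(nClasses), nChannels = as.integer(nChannels),
      nLayers = as.integer(nLayers), popSize = as.integer(popSize),
      steps = as.integer(steps), sampleSize = as.integer(sampleSize),
      epochsPhase1 = as.integer(epochsPhase1),
      epochsPhase2 = as.integer(epochsPhase2),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      topK = as.integer(topK), nRuns = as.integer(nRuns),
      seed = as.integer(seed))
}

setMethod("show", "SearchConfig", function(object) {
  cat("SearchConfig:\n")
  cat(sprintf("  F=%d, nOps=%d, classes=%d, channels=%d, layers=%d\n",
              object@filters, object@nOps, object@nClasses, object@nChannels,
              object@nLayers))
  cat(sprintf("  P=%d, C=%d, S=%d; epochs %d + %d; batch %d; lr %g\n",
              object@popSize, object@steps, object@sampleSize,
              object@epochsPhase1, object@epochsPhase2, object@batchSize,
              object@learningRate))
  cat(sprintf("  topK=%d, runs=%d, seed=%d\n", object@topK, object@nRuns,
              object@seed))
})

# ---- Individual / SearchHistory --------------------------------------------

#' Individual: one evaluated genome in the evolutionary record
#'
#' @slot genome The \linkS4class{ArchitectureGenome}.
#' @slot fitness Validation accuracy in [0, 1], or NA before evaluation.
#' @slot birthIndex Creation order (0-based, unique within a run).
#' @slot parentBirthIndex Parent's birth index, or NA for founders.
#' @slot mutation Mutation kind that produced this individual, or NA.
#' @export
setClass("Individual",
  representation(genome = "ArchitectureGenome", fitness = "numeric",
                 birthIndex = "integer", parentBirthIndex = "integer",
                 mutation = "character"),
  prototype(fitness = NA_real_, parentBirthIndex = NA_integer_,
            mutation = NA_character_),
  validity = function(object) {
    if (!is.na(object@fitness) &&
        (object@fitness < 0 || object@fitness > 1))
      "fitness must be in [0, 1]" else TRUE
  }
)

#' SearchHistory: append-only record of all evaluated individuals
#'
#' After a completed run the history holds exactly P + C individuals in
#' birth order; it never shrinks.
#'
#' @slot individuals List of \linkS4class{Individual}, in birth order.
#' @slot config The \linkS4class{SearchConfig} of the run.
#' @slot runId Run identifier.
#' @export
setClass("SearchHistory",
  representation(individuals = "list", config = "SearchConfig",
                 runId = "character"))

setMethod("show", "SearchHistory", function(object) {
  fit <- vapply(object@individuals, function(i) i@fitness, numeric(1))
  cat(sprintf("SearchHistory '%s': %d individuals (P=%d + C=%d)\n",
              object@runId, length(object@individuals),
              object@config@popSize, object@config@steps))
  if (length(fit))
    cat(sprintf("  fitness: best %.4f, median %.4f\n",
                max(fit, na.rm = TRUE), stats::median(fit, na.rm = TRUE)))
})

#' @describeIn SearchHistory Number of recorded individuals.
#' @param x A SearchHistory.
#' @export
setMethod("length", "SearchHistory", function(x) length(x@individuals))

#' Fitness trace of a search history
#'
#' @param history A \linkS4class{SearchHistory}.
#' @return Numeric vector of fitnesses in birth order.
#' @export
historyFitness <- function(history) {
  vapply(history@individuals, function(i) i@fitness, numeric(1))
}

#' Summarize a search history as a data.frame
#'
#' One row per individual: birth index, fitness, mutation kind and parent.
#'
#' @param history A \linkS4class{SearchHistory}.
#' @return data.frame with columns birth_index, fitness, mutation,
#'   parent_birth_index.
#' @export
historyTable <- function(history) {
  data.frame(
    birth_index = vapply(history@individuals, function(i) i@birthIndex, integer(1)),
    fitness = historyFitness(history),
    mutation = vapply(history@individuals, function(i) i@mutation, character(1)),
    parent_birth_index = vapply(history@individuals,
                                function(i) i@parentBirthIndex, integer(1)),
    stringsAsFactors = FALSE
  )
}

# ---- SubjectDataset ---------------------------------------------------------

#' SubjectDataset: subject -> slices -> class hierarchy
#'
#' Each subject record is a list with fields `subject_id`, `label` (one of
#' AL, ATTR, CTRL), `slices` (list of 2D numeric matrices, SUV-like
#' non-negative reals) and `partition` (train/val/test/unassigned).
#'
#' @slot subjects List of subject records.
#' @export
setClass("SubjectDataset",
  representation(subjects = "list"),
  validity = function(object) {
    msg <- character()
    for (s in object@subjects) {
      if (!all(c("subject_id", "label", "slices", "partition") %in% names(s))) {
        msg <- c(msg, "subject record missing fields"); next
      }
      if (!s$label %in% classLabels())
        msg <- c(msg, sprintf("subject %s: unknown label '%s'",
                              s$subject_id, s$label))
      if (!s$partition %in% c("train", "val", "test", "unassigned"))
        msg <- c(msg, sprintf("subject %s: bad partition '%s'",
                              s$subject_id, s$partition))
    }
    if (length(msg)) msg else TRUE
  }
)

#' The fixed three-class label vocabulary
#' @return c("AL", "ATTR", "CTRL")
#' @export
classLabels <- function() c("AL", "ATTR", "CTRL")

setMethod("show", "SubjectDataset", function(object) {
  lab <- vapply(object@subjects, function(s) s$label, character(1))
  prt <- vapply(object@subjects, function(s) s$partition, character(1))
  nsl <- vapply(object@subjects, function(s) length(s$slices), integer(1))
  cat(sprintf("SubjectDataset: %d subjects, %d slices\n",
              length(object@subjects), sum(nsl)))
  for (l in classLabels())
    cat(sprintf("  %s: %d subjects, %d slices\n", l, sum(lab == l),
                sum(nsl[lab == l])))
  cat("  partitions:", paste(sprintf("%s=%d", names(table(prt)), table(prt)),
                             collapse = ", "), "\n")
})

#' @describeIn SubjectDataset Number of subjects.
#' @param x A SubjectDataset.
#' @export
setMethod("length", "SubjectDataset", function(x) length(x@subjects))

#' Accessors for SubjectDataset
#'
#' `subjectIds`, `subjectLabels`, `subjectPartitions` return per-subject
#' vectors; `sliceCounts` the number of slices per subject; `datasetSlices`
#' a flat view (list of matrices plus label/subject/partition vectors).
#'
#' @param dataset A \linkS4class{SubjectDataset}.
#' @param partition Optional partition filter for `datasetSlices`.
#' @return See details.
#' @export
subjectIds <- function(dataset)
  vapply(dataset@subjects, function(s) s$subject_id, character(1))

#' @rdname subjectIds
#' @export
subjectLabels <- function(dataset)
  vapply(dataset@subjects, function(s) s$label, character(1))

#' @rdname subjectIds
#' @export
subjectPartitions <- function(dataset)
  vapply(dataset@subjects, function(s) s$partition, character(1))

#' @rdname subjectIds
#' @export
sliceCounts <- function(dataset)
  vapply(dataset@subjects, function(s) length(s$slices), integer(1))

#' @rdname subjectIds
#' @export
datasetSlices <- function(dataset, partition = NULL) {
  keep <- dataset@subjects
  if (!is.null(partition))
    keep <- Filter(function(s) s$partition %in% partition, keep)
  slices <- list(); labels <- character(); subj <- character(); part <- character()
  for (s in keep) {
    slices <- c(slices, s$slices)
    labels <- c(labels, rep(s$label, length(s$slices)))
    subj <- c(subj, rep(s$subject_id, length(s$slices)))
    part <- c(part, rep(s$partition, length(s$slices)))
  }
  list(slices = slices, labels = labels, subject_id = subj, partition = part)
}

# ---- PhantomConfig ----------------------------------------------------------

#' PhantomConfig: synthetic cardiac PET phantom generator settings
#'
#' Controls the hierarchical structure (subjects per class, slices per
#' subject), the raster geometry, and the class-dependent myocardial-ring
#' uptake model. Intensities are SUV-like non-negative reals; class effect
#' sizes are expressed relative to the pixel noise scale.
#'
#' @slot nSubjects Named integer vector: subjects per class (AL, ATTR, CTRL).
#' @slot sliceRange Integer range (min, max) of slices per subject, used when
#'   no explicit per-subject slice-count list is given.
#' @slot sliceCounts Optional named list per class of explicit per-subject
#'   slice counts (overrides sliceRange).
#' @slot imageSize Raster size (rows, cols).
#' @slot ringMean Named numeric: mean myocardial ring SUV per class.
#' @slot background Background mean intensity.
#' @slot noise Positive pixel noise scale (SD).
#' @slot subjectJitter SD of the per-subject multiplicative uptake factor.
#' @slot partitions Optional named list per class of per-subject partition
#'   assignments (parallel to sliceCounts).
#' @slot seed Base seed.
#' @export
setClass("PhantomConfig",
  representation(nSubjects = "integer", sliceRange = "integer",
                 sliceCounts = "list", imageSize = "integer",
                 ringMean = "numeric", background = "numeric",
                 noise = "numeric", subjectJitter = "numeric",
                 partitions = "list", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@noise <= 0) msg <- c(msg, "noise scale must be positive")
    if (!all(classLabels() %in% names(object@nSubjects)))
      msg <- c(msg, "nSubjects must name AL, ATTR, CTRL")
    if (!all(classLabels() %in% names(object@ringMean)))
      msg <- c(msg, "ringMean must name AL, ATTR, CTRL")
    if (length(object@sliceCounts)) {
      for (l in classLabels())
        if (length(object@sliceCounts[[l]]) != object@nSubjects[[l]])
          msg <- c(msg, sprintf("sliceCounts$%s length != nSubjects", l))
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a phantom generator configuration
#'
#' Defaults emulate the study cohort: 13 AL, 15 ATTR and 19 CTRL subjects
#' with 8-19 heart slices each on a 77 x 104 raster, with ring uptake
#' ordered AL >> ATTR > CTRL so that AL is near-perfectly separable while
#' ATTR and CTRL partially overlap.
#'
#' @param nSubjects Subjects per class.
#' @param sliceRange Range of slices per subject.
#' @param sliceCounts Optional explicit per-subject slice counts (named list
#'   of integer vectors per class).
#' @param imageSize Raster size (rows, cols).
#' @param ringMean Per-class mean ring SUV.
#' @param background Background mean intensity.
#' @param noise Pixel noise SD (must be positive).
#' @param subjectJitter SD of per-subject log-normal uptake factor.
#' @param partitions Optional explicit per-subject partitions.
#' @param seed Base seed.
#' @return A \linkS4class{PhantomConfig}.
#' @export
phantomConfig <- function(nSubjects = c(AL = 13, ATTR = 15, CTRL = 19),
                          sliceRange = c(8, 19),
                          sliceCounts = list(),
                          imageSize = c(77, 104),
                          ringMean = c(AL = 6, ATTR = 2.4, CTRL = 1.2),
                          background = 0.4, noise = 0.6,
                          subjectJitter = 0.25,
                          partitions = list(), seed = 1) {
  if (noise <= 0) stop("phantomConfig: noise scale must be positive")
  new("PhantomConfig",
      nSubjects = stats::setNames(as.integer(nSubjects), names(nSubjects)),
      sliceRange = as.integer(sliceRange),
      sliceCounts = sliceCounts,
      imageSize = as.integer(imageSize),
      ringMean = ringMean, background = background, noise = noise,
      subjectJitter = subjectJitter, partitions = partitions,
      seed = as.integer(seed))
}

#' Read a search configuration from a YAML or JSON file
#'
#' The file holds a flat mapping mirroring \code{\link{searchConfig}}'s
#' argument names (e.g. \code{popSize: 100}); omitted fields keep their
#' defaults. Unknown fields are an error, so typos do not pass silently.
#'
#' @param path Path to a .yaml/.yml or .json file.
#' @return A \linkS4class{SearchConfig}.
#' @export
readSearchConfig <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("readSearchConfig: YAML configs need the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(searchConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("readSearchConfig: unknown fields: ", paste(bad, collapse = ", "))
  do.call(searchConfig, vals)
}
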