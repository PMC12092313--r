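# evolution module: mutation operators and the aged evolutionary loop

#' Draw a mutation kind from the categorical mutation distribution
#'
#' @param probs Named probabilities over OPERATION, HIDDEN_STATE, IDENTITY;
#'   must sum to 1 (within 1e-12). Defaults to (0.475, 0.475, 0.05).
#' @return One of "OPERATION", "HIDDEN_STATE", "IDENTITY".
#' @export
#' @examples
#' set.seed(1)
#' table(replicate(1000, drawMutationKind()))
drawMutationKind <- function(probs = defaultMutationProbs()) {
  kinds <- c("OPERATION", "HIDDEN_STATE", "IDENTITY")
  if (!all(kinds %in% names(probs)))
    stop("drawMutationKind: probs must name OPERATION, HIDDEN_STATE, IDENTITY")
  probs <- probs[kinds]
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-12)
    stop("drawMutationKind: probabilities must be non-negative and sum to 1")
  kinds[sample.int(3L, 1L, prob = probs)]
}

#' Mutate an architecture genome
#'
#' Applies one randomly drawn mutation: OPERATION replaces one uniformly
#' chosen branch's operation (in a uniformly chosen cell and node) with a
#' different operation drawn uniformly from the rest of the vocabulary;
#' HIDDEN_STATE rewires one branch's source to a different valid predecessor,
#' uniformly; IDENTITY returns the parent unchanged. The child is always a
#' valid genome and the parent is never modified.
#'
#' @param parent A valid \linkS4class{ArchitectureGenome}.
#' @param probs Mutation-kind probabilities (see
#'   \code{\link{drawMutationKind}}).
#' @param vocab Operation vocabulary.
#' @return List with `child` (the mutated genome) and `kind` (the applied
#'   mutation kind).
#' @export
mutateGenome <- function(parent, probs = defaultMutationProbs(),
                         vocab = opVocabulary()) {
  kind <- drawMutationKind(probs)
  if (kind == "IDENTITY")
    return(list(child = parent, kind = "IDENTITY"))

  cellName <- c("normal", "reduction")[sample.int(2L, 1L)]
  cell <- slot(parent, cellName)
  j <- sample.int(length(cell@nodes), 1L)         # node, 1-based
  b <- sample.int(2L, 1L)                          # branch
  br <- cell@nodes[[j]][[b]]

  if (kind == "OPERATION") {
    alt <- setdiff(vocab, br$op)
    br$op <- alt[sample.int(length(alt), 1L)]
  } else {  # HIDDEN_STATE: sources 0..j are legal for 1-based node j
    alt <- setdiff(0:j, br$src)
    if (!length(alt))                              # unreachable for nOps >= 4
      return(list(child = parent, kind = "IDENTITY"))
    br$src <- alt[sample.int(length(alt), 1L)]
  }
  cell@nodes[[j]][[b]] <- br
  child <- parent
  slot(child, cellName) <- cell
  list(child = child, kind = kind)
}

#' Tournament parent selection
#'
#' Samples S individuals from the live population with replacement and
#' returns the one with the highest fitness; ties are broken in favour of
#' the larger birth index (the youngest). With S = 1 this degenerates to a
#' uniform random parent, the study's setting.
#'
#' @param population List of \linkS4class{Individual} with fitness set.
#' @param S Tournament sample size (>= 1).
#' @return The selected \linkS4class{Individual}.
#' @export
tournamentSelect <- function(population, S = 1L) {
  if (!length(population)) stop("tournamentSelect: empty population")
  if (S < 1L) stop("tournamentSelect: S must be >= 1")
  idx <- sample.int(length(population), S, replace = TRUE)
  best <- NULL
  for (i in idx) {
    cand <- population[[i]]
    if (is.na(cand@fitness))
      stop("tournamentSelect: individual ", cand@birthIndex,
           " has unset fitness")
    if (is.null(best) || cand@fitness > best@fitness ||
        (cand@fitness == best@fitness && cand@birthIndex > best@birthIndex))
      best <- cand
  }
  best
}

#' Run the aged evolutionary architecture search
#'
#' Creates P random founder genomes and evaluates each; then performs C
#' steps of: tournament-select a parent, mutate it, evaluate the child,
#' append it to the population and history, and remove the oldest member
#' (smallest birth index) so the population size stays exactly P. Evaluator
#' failures are scored 0 with a warning rather than aborting the run.
#'
#' @param cfg A \linkS4class{SearchConfig} (popSize, steps, sampleSize,
#'   nOps are used here).
#' @param evaluator Function(genome) -> fitness in [0, 1].
#' @param probs Mutation-kind probabilities.
#' @param runId Identifier stored in the history.
#' @param verbose Emit one message per step (step, parent, kind, fitness).
#' @return A \linkS4class{SearchHistory} of length P + C.
#' @export
#' @examples
#' cfg <- searchConfig(popSize = 5, steps = 10)
#' set.seed(1)
#' h <- evolve(cfg, stubEvaluator())
#' length(h)
evolve <- function(cfg, evaluator, probs = defaultMutationProbs(),
                   runId = "run1", verbose = FALSE) {
  P <- cfg@popSize; C <- cfg@steps
  history <- vector("list", P + C)

  safeEval <- function(genome) {
    fit <- tryCatch(evaluator(genome), error = function(e) {
      warning("evolve: evaluator failed (", conditionMessage(e),
              "); scoring fitness 0", call. = FALSE)
      0
    })
    if (!is.finite(fit)) fit <- 0
    min(max(fit, 0), 1)
  }

  for (i in seq_len(P)) {
    g <- randomArchitectureGenome(cfg@nOps)
    history[[i]] <- new("Individual", genome = g, fitness = safeEval(g),
                        birthIndex = i - 1L)
  }
  # the live population is the trailing window of the history
  popStart <- 1L
  for (t in seq_len(C)) {
    parent <- tournamentSelect(history[popStart:(P + t - 1L)],
                               cfg@sampleSize)
    mut <- mutateGenome(parent@genome, probs)
    child <- new("Individual", genome = mut$child,
                 fitness = safeEval(mut$child),
                 birthIndex = P + t - 1L,
                 parentBirthIndex = parent@birthIndex,
                 mutation = mut$kind)
    history[[P + t]] <- child
    popStart <- popStart + 1L   # aged removal: drop the oldest
    if (verbose)
      message(sprintf("step %d: parent %d, %s, child fitness %.4f",
                      t, parent@birthIndex, mut$kind, child@fitness))
  }
  new("SearchHistory", individuals = history, config = cfg, runId = runId)
}

#' Best-k individuals of a search history
#'
#' @param history A \linkS4class{SearchHistory} (or plain list of
#'   \linkS4class{Individual}).
#' @param k Number of individuals to return; at most the history length.
#' @return List of k distinct individuals, fitness descending; ties broken
#'   in favour of the younger (larger birth index).
#' @export
topK <- function(history, k) {
  ind <- if (is(history, "SearchHistory")) history@individuals else history
  if (!length(ind)) stop("topK: empty history")
  if (k < 1L || k > length(ind))
    stop("topK: k must be in 1..", length(ind), ", got ", k)
  fit <- vapply(ind, function(i) i@fitness, numeric(1))
  birth <- vapply(ind, function(i) i@birthIndex, integer(1))
  ord <- order(-fit, -birth)
  ind[ord[seq_len(k)]]
}

#' Deterministic stub fitness evaluators
#'
#' For structural testing of the search loop without any training:
#' `"hash"` maps each genome to a deterministic pseudo-fitness via
#' \code{\link{genomeHash}}; `"birth"` returns an increasing counter scaled
#' to (0, 1), so fitness equals creation order.
#'
#' @param kind "hash" or "birth".
#' @param scale Divisor for the "birth" counter.
#' @return Function(genome) -> fitness.
#' @export
stubEvaluator <- function(kind = c("hash", "birth"), scale = 1e6) {
  kind <- match.arg(kind)
  if (kind == "hash") return(function(genome) genomeHash(genome))
  counter <- 0
  function(genome) {
    counter <<- counter + 1
    counter / scale
  }
}
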