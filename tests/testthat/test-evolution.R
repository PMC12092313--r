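# mutation operators and the aged evolutionary loop

test_that("mutation-kind sampler validates its distribution", {
  expect_error(drawMutationKind(c(OPERATION = 0.5, HIDDEN_STATE = 0.6,
                                  IDENTITY = 0.1)), "sum to 1")
  expect_error(drawMutationKind(c(OPERATION = 1)), "must name")
  set.seed(1)
  draws <- replicate(50, drawMutationKind(c(OPERATION = 1, HIDDEN_STATE = 0,
                                            IDENTITY = 0)))
  expect_true(all(draws == "OPERATION"))
})

test_that("identity mutations leave the genome untouched", {
  set.seed(5)
  g <- randomArchitectureGenome()
  for (i in 1:20) {
    out <- mutateGenome(g, c(OPERATION = 0, HIDDEN_STATE = 0, IDENTITY = 1))
    expect_identical(out$kind, "IDENTITY")
    expect_true(genomeEqual(out$child, g))
  }
})

test_that("a mutation changes at most one branch field and keeps validity", {
  set.seed(6)
  g <- randomArchitectureGenome()
  for (i in 1:2000) {
    out <- mutateGenome(g)
    expect_length(validateGenome(out$child), 0)
    d <- genomeDiffCount(g, out$child)
    expect_lte(d, 1)
    if (out$kind == "IDENTITY") expect_equal(d, 0) else expect_equal(d, 1)
    g <- out$child   # walk the chain; validity must be closed under mutation
  }
})

test_that("operation mutation draws the new op uniformly over alternatives", {
  set.seed(8)
  base <- allIdentityGenome(4)
  probs <- c(OPERATION = 1, HIDDEN_STATE = 0, IDENTITY = 0)
  newOps <- character(0)
  for (i in 1:6000) {
    out <- mutateGenome(base, probs)
    # find the changed branch's op
    for (kind in c("normal", "reduction"))
      for (node in slot(out$child, kind)@nodes)
        for (br in node)
          if (br$op != "IDENTITY") newOps <- c(newOps, br$op)
  }
  # IDENTITY was the old op everywhere: new op uniform over the other 5
  p <- 1 / 5
  tol <- 3 * sqrt(p * (1 - p) / length(newOps))
  for (op in setdiff(opVocabulary(), "IDENTITY"))
    expect_lt(abs(mean(newOps == op) - p), tol)
  expect_false("IDENTITY" %in% newOps)   # never resamples the current op
})

test_that("hidden-state mutation rewires to a different valid source", {
  set.seed(9)
  probs <- c(OPERATION = 0, HIDDEN_STATE = 1, IDENTITY = 0)
  g <- randomArchitectureGenome(4)
  for (i in 1:500) {
    out <- mutateGenome(g, probs)
    expect_length(validateGenome(out$child), 0)
    expect_equal(genomeDiffCount(g, out$child), 1)
    expect_identical(out$kind, "HIDDEN_STATE")
  }
})

test_that("tournament selection follows the with-replacement max rule", {
  set.seed(10)
  mkInd <- function(fit, birth) new("Individual",
                                    genome = allIdentityGenome(4),
                                    fitness = fit,
                                    birthIndex = as.integer(birth))
  one <- list(mkInd(0.2, 0))
  expect_identical(tournamentSelect(one, 5)@birthIndex, 0L)
  # S = 2 over fitnesses (0.1, 0.9): the 0.9 member wins 3 of the 4
  # equally likely ordered pairs
  pop <- list(mkInd(0.1, 0), mkInd(0.9, 1))
  wins <- replicate(8000, tournamentSelect(pop, 2)@birthIndex == 1L)
  p <- 3 / 4
  expect_lt(abs(mean(wins) - p), 3 * sqrt(p * (1 - p) / 8000))
  # S = 1 ignores fitness: uniform pick
  wins1 <- replicate(8000, tournamentSelect(pop, 1)@birthIndex == 1L)
  expect_lt(abs(mean(wins1) - 0.5), 3 * sqrt(0.25 / 8000))
  # ties go to the youngest
  tied <- list(mkInd(0.5, 0), mkInd(0.5, 1))
  expect_identical(tournamentSelect(tied, 10)@birthIndex, 1L)
  # unset fitness is a state error
  expect_error(tournamentSelect(list(new("Individual",
                                         genome = allIdentityGenome(4),
                                         birthIndex = 0L)), 1),
               "unset fitness")
})

test_that("evolve keeps the aged-queue bookkeeping exact", {
  cfg <- searchConfig(popSize = 10, steps = 40, nOps = 4)
  set.seed(11)
  h <- evolve(cfg, stubEvaluator())
  expect_equal(length(h), 50)
  tb <- historyTable(h)
  expect_identical(tb$birth_index, 0:49)
  # founders have no parent or mutation record; children have both
  expect_true(all(is.na(tb$mutation[1:10])))
  expect_true(all(!is.na(tb$mutation[11:50])))
  expect_true(all(tb$parent_birth_index[11:50] >= 0))
  # every child's parent was alive (in the trailing window of size P) when
  # the child was born: birth b has population (b-P) .. (b-1)
  for (b in 11:50)
    expect_true(tb$parent_birth_index[b] >= b - 1 - 10 &&
                tb$parent_birth_index[b] <= b - 2)
})

test_that("evolve with C = 0 returns exactly the founders", {
  cfg <- searchConfig(popSize = 7, steps = 0, nOps = 4)
  set.seed(12)
  h <- evolve(cfg, stubEvaluator())
  expect_equal(length(h), 7)
  expect_true(all(is.na(historyTable(h)$mutation)))
})

test_that("with fitness = birth order the survivors are the last P created", {
  cfg <- searchConfig(popSize = 6, steps = 30, nOps = 4)
  set.seed(13)
  h <- evolve(cfg, stubEvaluator("birth"))
  tb <- historyTable(h)
  # fitness increases with creation -> monotone in birth index
  expect_true(all(diff(tb$fitness) > 0))
  # the aged queue leaves exactly the last P as the final population; their
  # children (none after the run) aside, every parent chosen at step t must
  # come from the window; the top-P by fitness are the last P born
  top <- topK(h, 6)
  expect_setequal(vapply(top, function(i) i@birthIndex, integer(1)), 30:35)
})

test_that("identity-only mutation keeps every genome equal to a founder", {
  cfg <- searchConfig(popSize = 5, steps = 25, nOps = 4)
  set.seed(14)
  h <- evolve(cfg, stubEvaluator(),
              probs = c(OPERATION = 0, HIDDEN_STATE = 0, IDENTITY = 1))
  founders <- lapply(h@individuals[1:5], function(i) i@genome)
  for (ind in h@individuals) {
    hits <- vapply(founders, function(f) genomeEqual(f, ind@genome), logical(1))
    expect_true(any(hits))
  }
})

test_that("seeded runs are exactly reproducible", {
  cfg <- searchConfig(popSize = 8, steps = 20)
  set.seed(15)
  h1 <- evolve(cfg, stubEvaluator())
  set.seed(15)
  h2 <- evolve(cfg, stubEvaluator())
  expect_identical(historyTable(h1), historyTable(h2))
  expect_true(genomeEqual(topK(h1, 1)[[1]]@genome, topK(h2, 1)[[1]]@genome))
})

test_that("evaluator failures score zero and the search continues", {
  cfg <- searchConfig(popSize = 4, steps = 6, nOps = 4)
  flaky <- local({
    n <- 0
    function(genome) {
      n <<- n + 1
      if (n %% 3 == 0) stop("boom")
      genomeHash(genome)
    }
  })
  set.seed(16)
  ws <- capture_warnings(h <- evolve(cfg, flaky))
  expect_gt(length(ws), 0)
  expect_true(all(grepl("scoring fitness 0", ws)))
  expect_equal(length(h), 10)
  expect_true(all(historyFitness(h) >= 0))
})

test_that("topK orders by fitness with youngest-first tie-breaks", {
  mk <- function(fit, birth) new("Individual", genome = allIdentityGenome(4),
                                 fitness = fit, birthIndex = as.integer(birth))
  hist <- list(mk(0.5, 0), mk(0.9, 1), mk(0.5, 2), mk(0.1, 3))
  got <- vapply(topK(hist, 4), function(i) i@birthIndex, integer(1))
  expect_identical(got, c(1L, 2L, 0L, 3L))
  expect_error(topK(hist, 5), "k must be in")
  # equal fitness everywhere: the k youngest
  tied <- list(mk(0.4, 0), mk(0.4, 1), mk(0.4, 2))
  expect_identical(vapply(topK(tied, 2), function(i) i@birthIndex, integer(1)),
                   c(2L, 1L))
})
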