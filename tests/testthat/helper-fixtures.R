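# Shared fixtures, built in code at test time.

# a small config whose networks accept small rasters (one reduction stage)
tinyConfig <- function(...) {
  searchConfig(filters = 2, nOps = 4, nLayers = 2, batchSize = 16,
               epochsPhase1 = 2, epochsPhase2 = 3, popSize = 4, steps = 6,
               topK = 2, nRuns = 2, ...)
}

# genome whose every branch is IDENTITY sourcing a cell input
allIdentityGenome <- function(nOps = 6) {
  mk <- function(kind) {
    nodes <- lapply(seq_len(nOps %/% 2), function(j)
      list(list(src = 0L, op = "IDENTITY"), list(src = 1L, op = "IDENTITY")))
    new("CellGenome", kind = kind, nodes = nodes)
  }
  new("ArchitectureGenome", normal = mk("normal"), reduction = mk("reduction"),
      nOps = as.integer(nOps))
}

# tiny separable in-memory dataset: nPer subjects per class
tinyDataset <- function(seed = 1, nPer = 2, slices = 8, size = c(12, 12)) {
  cfg <- phantomConfig(nSubjects = c(AL = nPer, ATTR = nPer, CTRL = nPer),
                       sliceRange = c(slices, slices), imageSize = size,
                       ringMean = c(AL = 12, ATTR = 4, CTRL = 1),
                       noise = 0.5, subjectJitter = 0.1, seed = seed)
  generatePhantomDataset(cfg, seed = seed)
}

# structural field-level diff count between two genomes
genomeDiffCount <- function(a, b) {
  n <- 0L
  for (kind in c("normal", "reduction")) {
    ca <- slot(a, kind)@nodes; cb <- slot(b, kind)@nodes
    for (j in seq_along(ca))
      for (br in 1:2) {
        if (ca[[j]][[br]]$src != cb[[j]][[br]]$src) n <- n + 1L
        if (ca[[j]][[br]]$op != cb[[j]][[br]]$op) n <- n + 1L
      }
  }
  n
}
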