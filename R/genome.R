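# search-space module: random genomes, validation, serialization

#' Sample a random cell genome
#'
#' Draws each branch source uniformly over the valid predecessor states
#' (node j, 0-based, may source states 0..j+1) and each operation uniformly
#' over the vocabulary. Uses the current RNG state, so results are
#' reproducible under \code{set.seed}.
#'
#' @param nOps Number of operation slots; even and >= 4. A cell with n slots
#'   has n/2 combine nodes and n-1 hidden states.
#' @param kind "normal" or "reduction".
#' @param vocab Operation vocabulary (default \code{\link{opVocabulary}}).
#' @return A \linkS4class{CellGenome}.
#' @export
#' @examples
#' set.seed(1)
#' randomCellGenome(6, "normal")
randomCellGenome <- function(nOps, kind = c("normal", "reduction"),
                             vocab = opVocabulary()) {
  kind <- match.arg(kind)
  nOps <- as.integer(nOps)
  if (nOps < 4L || nOps %% 2L != 0L)
    stop("randomCellGenome: nOps must be even and >= 4, got ", nOps)
  if (!length(vocab)) stop("randomCellGenome: empty vocabulary")
  nNodes <- nOps %/% 2L
  nodes <- vector("list", nNodes)
  for (j in seq_len(nNodes)) {
    # 0-based node j-1 may source states 0 .. j (i.e. j+1 choices)
    nodes[[j]] <- list(
      list(src = sample.int(j + 1L, 1L) - 1L, op = vocab[sample.int(length(vocab), 1L)]),
      list(src = sample.int(j + 1L, 1L) - 1L, op = vocab[sample.int(length(vocab), 1L)])
    )
  }
  new("CellGenome", kind = kind, nodes = nodes)
}

#' Sample a random architecture genome (normal + reduction cell)
#'
#' @param nOps Operation slots per cell (default 6, the study value).
#' @param vocab Operation vocabulary.
#' @return An \linkS4class{ArchitectureGenome}.
#' @export
#' @examples
#' set.seed(1)
#' g <- randomArchitectureGenome()
randomArchitectureGenome <- function(nOps = 6, vocab = opVocabulary()) {
  new("ArchitectureGenome",
      normal = randomCellGenome(nOps, "normal", vocab),
      reduction = randomCellGenome(nOps, "reduction", vocab),
      nOps = as.integer(nOps))
}

#' Validate an architecture genome against a configuration
#'
#' Reports every violated invariant (bad source index, wrong node count,
#' unknown operation code, kind mismatch) as a character vector; an empty
#' report means the genome is legal.
#'
#' @param g An \linkS4class{ArchitectureGenome}.
#' @param cfg Optional \linkS4class{SearchConfig}; when given, the genome's
#'   nOps must match cfg.
#' @return Character vector of violations (length 0 iff valid).
#' @export
validateGenome <- function(g, cfg = NULL) {
  report <- character()
  if (!is.null(cfg) && g@nOps != cfg@nOps)
    report <- c(report, sprintf("genome nOps %d != config nOps %d",
                                g@nOps, cfg@nOps))
  if (g@nOps < 4L || g@nOps %% 2L != 0L)
    report <- c(report, sprintf("nOps %d not even and >= 4", g@nOps))
  for (kind in c("normal", "reduction")) {
    cell <- slot(g, kind)
    if (cell@kind != kind)
      report <- c(report, sprintf("%s slot holds a %s cell", kind, cell@kind))
    expNodes <- g@nOps %/% 2L
    if (length(cell@nodes) != expNodes) {
      report <- c(report, sprintf("%s cell has %d nodes, expected %d",
                                  kind, length(cell@nodes), expNodes))
      next
    }
    for (j in seq_along(cell@nodes)) {
      node <- cell@nodes[[j]]
      if (length(node) != 2L) {
        report <- c(report, sprintf("%s cell node %d: needs two branches",
                                    kind, j - 1L))
        next
      }
      for (b in 1:2) {
        br <- node[[b]]
        if (!is.list(br) || is.null(br$src) || is.null(br$op)) {
          report <- c(report, sprintf("%s cell node %d branch %d: malformed",
                                      kind, j - 1L, b))
          next
        }
        if (!br$op %in% opVocabulary())
          report <- c(report, sprintf("%s cell node %d branch %d: unknown op '%s'",
                                      kind, j - 1L, b, br$op))
        if (!is.numeric(br$src) || br$src < 0 || br$src > j)
          report <- c(report, sprintf(
            "%s cell node %d branch %d: source %s outside {0..%d}",
            kind, j - 1L, b, format(br$src), j))
      }
    }
  }
  report
}

# canonical list form used for both JSON serialization and hashing
.genomeToList <- function(g) {
  cellList <- function(cell)
    lapply(cell@nodes, function(node)
      lapply(node, function(br)
        list(src = as.integer(br$src), op = br$op)))
  list(schema_version = g@schemaVersion,
       n_ops = as.integer(g@nOps),
       normal = cellList(g@normal),
       reduction = cellList(g@reduction))
}

#' Serialize an architecture genome to canonical JSON
#'
#' The document is a stable, versioned schema:
#' \code{{"schema_version", "n_ops", "normal": [[{"src","op"},{"src","op"}],
#' ...], "reduction": [...]}} with 0-based sources and operation names.
#' Structurally equal genomes serialize to byte-identical text.
#'
#' @param g An \linkS4class{ArchitectureGenome}.
#' @param file Optional path; when given the JSON is also written there.
#' @return The JSON document as a single character string.
#' @export
#' @examples
#' set.seed(1)
#' doc <- serializeGenome(randomArchitectureGenome())
serializeGenome <- function(g, file = NULL) {
  bad <- validateGenome(g)
  if (length(bad))
    stop("serializeGenome: invalid genome: ", paste(bad, collapse = "; "))
  doc <- as.character(jsonlite::toJSON(.genomeToList(g), auto_unbox = TRUE))
  if (!is.null(file)) writeLines(doc, file)
  doc
}

#' Deserialize an architecture genome from JSON
#'
#' @param doc JSON text, or a path to a file containing it.
#' @return An \linkS4class{ArchitectureGenome}.
#' @export
deserializeGenome <- function(doc) {
  if (length(doc) == 1L && !grepl("^\\s*\\{", doc) && file.exists(doc))
    doc <- paste(readLines(doc, warn = FALSE), collapse = "\n")
  parsed <- tryCatch(jsonlite::fromJSON(doc, simplifyVector = FALSE),
                     error = function(e)
                       stop("deserializeGenome: malformed JSON: ",
                            conditionMessage(e)))
  for (f in c("schema_version", "n_ops", "normal", "reduction"))
    if (is.null(parsed[[f]]))
      stop("deserializeGenome: missing field '", f, "'")
  if (!identical(parsed$schema_version, "evonas-genome/1"))
    stop("deserializeGenome: unknown schema_version '",
         parsed$schema_version, "'")
  parseCell <- function(raw, kind) {
    nodes <- lapply(seq_along(raw), function(j) {
      node <- raw[[j]]
      if (length(node) != 2L)
        stop("deserializeGenome: ", kind, " cell node ", j - 1L,
             " must have two branches")
      lapply(node, function(br) {
        if (is.null(br$src) || is.null(br$op))
          stop("deserializeGenome: branch missing 'src' or 'op' in ",
               kind, " cell node ", j - 1L)
        if (!br$op %in% opVocabulary())
          stop("deserializeGenome: unknown op '", br$op, "' in field '",
               kind, "'")
        list(src = as.integer(br$src), op = as.character(br$op))
      })
    })
    new("CellGenome", kind = kind, nodes = nodes)
  }
  g <- new("ArchitectureGenome",
           normal = parseCell(parsed$normal, "normal"),
           reduction = parseCell(parsed$reduction, "reduction"),
           nOps = as.integer(parsed$n_ops),
           schemaVersion = parsed$schema_version)
  bad <- validateGenome(g)
  if (length(bad))
    stop("deserializeGenome: invalid genome: ", paste(bad, collapse = "; "))
  g
}

#' Structural genome equality
#'
#' Two genomes are equal iff they have the same nodes, branches, sources and
#' operations in both cells (serialization-level identity).
#'
#' @param a,b \linkS4class{ArchitectureGenome} objects.
#' @return Logical.
#' @export
genomeEqual <- function(a, b) {
  identical(.genomeToList(a), .genomeToList(b))
}

#' Deterministic hash of a genome in [0, 1)
#'
#' A cheap structural fingerprint (multiplicative fold over sources and
#' operation indices); used by the stub evaluator for structural tests of
#' the search loop without any network training.
#'
#' @param g An \linkS4class{ArchitectureGenome}.
#' @return Numeric scalar in [0, 1).
#' @export
genomeHash <- function(g) {
  vocab <- opVocabulary()
  h <- 17
  m <- 2147483647
  for (kind in c("normal", "reduction")) {
    cell <- slot(g, kind)
    for (node in cell@nodes)
      for (br in node) {
        h <- (h * 31 + br$src + 1) %% m
        h <- (h * 31 + match(br$op, vocab)) %% m
      }
  }
  h / m
}
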