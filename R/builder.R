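# network_builder module: compile an ArchitectureGenome into a trainable CNN
#
# A compiled network is a flat "tape" of primitive layer entries executed in
# topological order over numbered activation buffers. Tensors are R arrays
# with dim (H, W, C, N); convolution/pooling kernels live in src/conv.cpp.

#' CompiledNetwork: executable computation graph for one genome
#'
#' @slot tape List of primitive layer entries in execution order.
#' @slot params Named list of trainable parameter arrays.
#' @slot state Named list of batch-norm running statistics (not trainable).
#' @slot shapes Per-buffer (C, H, W) shapes inferred at compile time.
#' @slot inventory data.frame of parameter names, shapes and element counts,
#'   recorded from the declared shapes at compile time.
#' @slot nBuffers Number of activation buffers.
#' @slot outBuffer Buffer id holding the class scores.
#' @slot inputShape (C, H, W) of the expected input.
#' @slot nClasses Number of output classes.
#' @export
setClass("CompiledNetwork",
  representation(tape = "list", params = "list", state = "list",
                 shapes = "list", inventory = "data.frame",
                 nBuffers = "integer", outBuffer = "integer",
                 inputShape = "integer", nClasses = "integer"))

setMethod("show", "CompiledNetwork", function(object) {
  cat(sprintf("CompiledNetwork: input (%d, %d, %d), %d classes\n",
              object@inputShape[1], object@inputShape[2], object@inputShape[3],
              object@nClasses))
  cat(sprintf("  %d tape entries, %d parameter tensors, %d parameters\n",
              length(object@tape), nrow(object@inventory),
              countParameters(object)))
})

# ---- builder state ----------------------------------------------------------

.newBuilder <- function() {
  env <- new.env(parent = emptyenv())
  env$tape <- list(); env$params <- list(); env$state <- list()
  env$shapes <- list(); env$nBuf <- 0L; env$inv <- list()
  env
}

.addBuffer <- function(env, shape) {   # shape = c(C, H, W)
  env$nBuf <- env$nBuf + 1L
  env$shapes[[env$nBuf]] <- as.integer(shape)
  env$nBuf
}

.emit <- function(env, entry) env$tape[[length(env$tape) + 1L]] <- entry

.addParam <- function(env, name, arr) {
  stopifnot(is.null(env$params[[name]]))
  env$params[[name]] <- arr
  env$inv[[length(env$inv) + 1L]] <- data.frame(
    name = name, shape = paste(dim(arr) %||% length(arr), collapse = "x"),
    n = length(arr), stringsAsFactors = FALSE)
  name
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.sameOut <- function(n, stride) as.integer(ceiling(n / stride))

# Conv(kh x kw) with "same" padding, no bias (BN supplies the shift).
.emitConv <- function(env, inBuf, cout, k, stride, dilation, groups, prefix) {
  s <- env$shapes[[inBuf]]
  cin <- s[1]
  fanIn <- k * k * (cin %/% groups)
  w <- array(rnorm(k * k * (cin %/% groups) * cout, sd = sqrt(2 / fanIn)),
             dim = c(k, k, cin %/% groups, cout))
  wid <- .addParam(env, paste0(prefix, ".w"), w)
  out <- .addBuffer(env, c(cout, .sameOut(s[2], stride), .sameOut(s[3], stride)))
  .emit(env, list(type = "conv", `in` = inBuf, out = out, w = wid,
                  stride = as.integer(stride), dilation = as.integer(dilation),
                  groups = as.integer(groups)))
  out
}

.emitReLU <- function(env, inBuf) {
  out <- .addBuffer(env, env$shapes[[inBuf]])
  .emit(env, list(type = "relu", `in` = inBuf, out = out))
  out
}

.emitBN <- function(env, inBuf, prefix) {
  C <- env$shapes[[inBuf]][1]
  gid <- .addParam(env, paste0(prefix, ".bn.gamma"), rep(1, C))
  bid <- .addParam(env, paste0(prefix, ".bn.beta"), rep(0, C))
  sid <- paste0(prefix, ".bn")
  env$state[[sid]] <- list(mean = rep(0, C), var = rep(1, C))
  out <- .addBuffer(env, env$shapes[[inBuf]])
  .emit(env, list(type = "bn", `in` = inBuf, out = out, gamma = gid,
                  beta = bid, state = sid))
  out
}

.convReluBN <- function(env, inBuf, cout, k, stride, dilation, prefix,
                        groups = 1L) {
  b <- .emitConv(env, inBuf, cout, k, stride, dilation, groups, prefix)
  b <- .emitReLU(env, b)
  .emitBN(env, b, prefix)
}

.emitPool <- function(env, inBuf, what, stride) {
  s <- env$shapes[[inBuf]]
  out <- .addBuffer(env, c(s[1], .sameOut(s[2], stride), .sameOut(s[3], stride)))
  .emit(env, list(type = what, `in` = inBuf, out = out, k = 3L,
                  stride = as.integer(stride)))
  out
}

.emitCopy <- function(env, inBuf) {
  out <- .addBuffer(env, env$shapes[[inBuf]])
  .emit(env, list(type = "copy", `in` = inBuf, out = out))
  out
}

.emitAdd <- function(env, a, b) {
  stopifnot(identical(env$shapes[[a]], env$shapes[[b]]))
  out <- .addBuffer(env, env$shapes[[a]])
  .emit(env, list(type = "add", in1 = a, in2 = b, out = out))
  out
}

.emitGAP <- function(env, inBuf) {
  s <- env$shapes[[inBuf]]
  out <- .addBuffer(env, c(s[1], 1L, 1L))
  .emit(env, list(type = "gap", `in` = inBuf, out = out))
  out
}

.emitLinear <- function(env, inBuf, cout, prefix) {
  cin <- env$shapes[[inBuf]][1]
  W <- matrix(rnorm(cout * cin, sd = sqrt(1 / cin)), cout, cin)
  wid <- .addParam(env, paste0(prefix, ".w"), W)
  bid <- .addParam(env, paste0(prefix, ".b"), rep(0, cout))
  out <- .addBuffer(env, c(cout, 1L, 1L))
  .emit(env, list(type = "linear", `in` = inBuf, out = out, w = wid, b = bid))
  out
}

# ---- operations and cells ---------------------------------------------------

#' Append one primitive operation to a builder (internal workhorse)
#'
#' Realizes one vocabulary operation: plain/dilated convolutions become a
#' single Conv(3x3)-ReLU-BN block; separable convolutions two stacked
#' depthwise+pointwise Conv-ReLU-BN blocks; pools are 3x3 with the given
#' stride, preceded by a 1x1 projection only when the channel count must
#' change; identity is a pass-through at stride 1 and a strided 1x1
#' Conv-ReLU-BN (factorized reduction) at stride 2. All spatial padding is
#' "same".
#'
#' @param env Builder environment.
#' @param inBuf Input buffer id.
#' @param op Operation code from \code{\link{opVocabulary}}.
#' @param cout Output channel count.
#' @param stride 1 or 2.
#' @param prefix Parameter name prefix.
#' @return Output buffer id.
#' @keywords internal
.buildOperation <- function(env, inBuf, op, cout, stride, prefix) {
  cin <- env$shapes[[inBuf]][1]
  switch(op,
    IDENTITY = {
      if (stride == 1L && cin == cout) .emitCopy(env, inBuf)
      else .convReluBN(env, inBuf, cout, 1L, stride, 1L,
                       paste0(prefix, ".id_reduce"))
    },
    MAX_POOL_3x3 = {
      b <- inBuf
      if (cin != cout)
        b <- .convReluBN(env, b, cout, 1L, 1L, 1L, paste0(prefix, ".proj"))
      .emitPool(env, b, "maxpool", stride)
    },
    AVG_POOL_3x3 = {
      b <- inBuf
      if (cin != cout)
        b <- .convReluBN(env, b, cout, 1L, 1L, 1L, paste0(prefix, ".proj"))
      .emitPool(env, b, "avgpool", stride)
    },
    CONV_3x3 = .convReluBN(env, inBuf, cout, 3L, stride, 1L, prefix),
    DIL_CONV_3x3 = .convReluBN(env, inBuf, cout, 3L, stride, 2L, prefix),
    SEP_CONV_3x3 = {
      # (depthwise 3x3 -> pointwise 1x1 -> ReLU -> BN) x 2; stride on block 1
      b <- .emitConv(env, inBuf, cin, 3L, stride, 1L, cin,
                     paste0(prefix, ".sep1.dw"))
      b <- .emitConv(env, b, cout, 1L, 1L, 1L, 1L, paste0(prefix, ".sep1.pw"))
      b <- .emitReLU(env, b)
      b <- .emitBN(env, b, paste0(prefix, ".sep1"))
      b <- .emitConv(env, b, cout, 3L, 1L, 1L, cout, paste0(prefix, ".sep2.dw"))
      b <- .emitConv(env, b, cout, 1L, 1L, 1L, 1L, paste0(prefix, ".sep2.pw"))
      b <- .emitReLU(env, b)
      .emitBN(env, b, paste0(prefix, ".sep2"))
    },
    stop(".buildOperation: unknown op code '", op, "'")
  )
}

#' Append one cell to a builder
#'
#' Both cell inputs are first projected by 1x1 Conv-ReLU-BN to the cell's
#' filter count (with stride 2 on c_{k-2} when it is spatially larger than
#' c_{k-1}). In a reduction cell a branch runs its operation at stride 2
#' iff its source is a cell input (state 0 or 1); branches reading
#' already-reduced intermediate states run at stride 1. Each combine node
#' sums its two branches; the cell output is the last node's state.
#'
#' @param env Builder environment.
#' @param cell A \linkS4class{CellGenome}.
#' @param buf2,buf1 Buffer ids of c_{k-2} and c_{k-1}.
#' @param fCell Filter count of this cell.
#' @param reduce Logical; TRUE for a reduction cell.
#' @param prefix Parameter name prefix.
#' @return Output buffer id.
#' @keywords internal
.buildCell <- function(env, cell, buf2, buf1, fCell, reduce, prefix) {
  s2 <- env$shapes[[buf2]]; s1 <- env$shapes[[buf1]]
  str2 <- if (s2[2] > s1[2] || s2[3] > s1[3]) 2L else 1L
  p2 <- .convReluBN(env, buf2, fCell, 1L, str2, 1L, paste0(prefix, ".pre2"))
  p1 <- .convReluBN(env, buf1, fCell, 1L, 1L, 1L, paste0(prefix, ".pre1"))
  states <- c(p2, p1)
  for (j in seq_along(cell@nodes)) {
    node <- cell@nodes[[j]]
    branches <- integer(2)
    for (b in 1:2) {
      br <- node[[b]]
      stride <- if (reduce && br$src < 2L) 2L else 1L
      branches[b] <- .buildOperation(env, states[br$src + 1L], br$op, fCell,
                                     stride,
                                     sprintf("%s.n%d.b%d", prefix, j - 1L, b))
    }
    states <- c(states, .emitAdd(env, branches[1], branches[2]))
  }
  states[length(states)]
}

# ---- whole networks ---------------------------------------------------------

#' Stage plan of the macro-architecture
#'
#' Cells alternate normal, reduction (default 4 layers: N, R, N, R); the
#' filter count starts at F and doubles at each reduction stage (the
#' reduction cell itself uses the doubled count), giving (4, 8, 8, 16) for
#' F = 4.
#'
#' @param cfg A \linkS4class{SearchConfig}.
#' @return data.frame with columns stage, kind, filters.
#' @export
macroPlan <- function(cfg) {
  kinds <- rep(c("normal", "reduction"), length.out = cfg@nLayers)
  f <- cfg@filters
  filters <- integer(cfg@nLayers)
  for (i in seq_len(cfg@nLayers)) {
    if (kinds[i] == "reduction") f <- 2L * f
    filters[i] <- f
  }
  data.frame(stage = seq_len(cfg@nLayers), kind = kinds, filters = filters,
             stringsAsFactors = FALSE)
}

#' Compile an architecture genome into a trainable network
#'
#' Macro-structure: a 1x1 convolutional stem projecting the input raster to F
#' channels; nLayers cells where cell k receives the outputs of cells k-2
#' and k-1 (the stem output stands in for both predecessors of the first
#' cell); a head of global average pooling followed by an affine map to the
#' class scores. Weight initialization draws from the current RNG state, so
#' \code{set.seed} makes compilation reproducible.
#'
#' @param g A valid \linkS4class{ArchitectureGenome}.
#' @param cfg A \linkS4class{SearchConfig}.
#' @param inputSize Raster size (rows, cols); default c(77, 104).
#' @return A \linkS4class{CompiledNetwork}.
#' @export
#' @examples
#' set.seed(1)
#' net <- buildNetwork(randomArchitectureGenome(), searchConfig(),
#'                     inputSize = c(16, 16))
#' countParameters(net)
buildNetwork <- function(g, cfg = searchConfig(), inputSize = c(77, 104)) {
  bad <- validateGenome(g, cfg)
  if (length(bad))
    stop("buildNetwork: invalid genome: ", paste(bad, collapse = "; "))
  env <- .newBuilder()
  inBuf <- .addBuffer(env, c(cfg@nChannels, inputSize[1], inputSize[2]))
  # bare linear 1x1 projection: the raster is non-negative (SUV), so a
  # rectified stem would kill every channel whose 1x1 weight draws negative
  stem <- .emitConv(env, inBuf, cfg@filters, 1L, 1L, 1L, 1L, "stem")
  plan <- macroPlan(cfg)
  prev2 <- stem; prev1 <- stem
  for (i in seq_len(nrow(plan))) {
    kind <- plan$kind[i]
    out <- .buildCell(env, slot(g, kind), prev2, prev1, plan$filters[i],
                      kind == "reduction", sprintf("cell%d", i))
    s <- env$shapes[[out]]
    if (s[2] < 4L || s[3] < 4L)
      stop(sprintf(
        "buildNetwork: stage %d (%s) output %dx%d is smaller than 4x4; input raster too small",
        i, kind, s[2], s[3]))
    prev2 <- prev1; prev1 <- out
  }
  pooled <- .emitGAP(env, prev1)
  logits <- .emitLinear(env, pooled, cfg@nClasses, "head")
  new("CompiledNetwork",
      tape = env$tape, params = env$params, state = env$state,
      shapes = env$shapes, inventory = do.call(rbind, env$inv),
      nBuffers = env$nBuf, outBuffer = logits,
      inputShape = as.integer(c(cfg@nChannels, inputSize[1], inputSize[2])),
      nClasses = cfg@nClasses)
}

#' Total count of trainable parameters
#'
#' Sums the element counts recorded in the compile-time parameter inventory
#' (batch-norm running statistics are state, not parameters, and are
#' excluded).
#'
#' @param net A \linkS4class{CompiledNetwork}.
#' @return Integer scalar.
#' @export
countParameters <- function(net) sum(net@inventory$n)

#' Stage summary table of a compiled network
#'
#' @param g An \linkS4class{ArchitectureGenome}.
#' @param cfg A \linkS4class{SearchConfig}.
#' @param inputSize Raster size (rows, cols).
#' @return data.frame with per-stage kind, filters and output size, plus the
#'   compiled network's total parameter count.
#' @export
networkSummary <- function(g, cfg = searchConfig(), inputSize = c(77, 104)) {
  plan <- macroPlan(cfg)
  h <- inputSize[1]; w <- inputSize[2]
  rows <- list()
  cum <- 0L
  for (i in seq_len(nrow(plan))) {
    if (plan$kind[i] == "reduction") { h <- ceiling(h / 2); w <- ceiling(w / 2) }
    rows[[i]] <- data.frame(stage = i, kind = plan$kind[i],
                            filters = plan$filters[i],
                            out_h = h, out_w = w)
  }
  out <- do.call(rbind, rows)
  net <- buildNetwork(g, cfg, inputSize)
  out$total_parameters <- countParameters(net)
  out
}
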