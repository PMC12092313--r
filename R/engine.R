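# Forward / backward execution of a compiled tape, softmax cross-entropy,
# and the Adam optimizer. Tensors: R arrays (H, W, C, N).

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

.relu <- function(x) { x[x < 0] <- 0; x }

# forward pass; returns buffers, per-layer caches, and (in training mode)
# updated batch-norm running statistics
.forwardTape <- function(net, x, training = FALSE) {
  if (!identical(as.integer(dim(x)[c(3, 1, 2)]), net@inputShape))
    stop("forward: input shape (", paste(dim(x), collapse = ","),
         ") does not match network input (C,H,W) = (",
         paste(net@inputShape, collapse = ","), ")")
  bufs <- vector("list", net@nBuffers)
  caches <- vector("list", length(net@tape))
  state <- net@state
  bufs[[1L]] <- x
  for (k in seq_along(net@tape)) {
    e <- net@tape[[k]]
    switch(e$type,
      conv = {
        bufs[[e$out]] <- .conv2d_fwd(bufs[[e$`in`]], net@params[[e$w]],
                                     e$stride, e$dilation, e$groups)
      },
      relu = {
        bufs[[e$out]] <- .relu(bufs[[e$`in`]])
      },
      bn = {
        xb <- bufs[[e$`in`]]
        d <- dim(xb); C <- d[3]
        gamma <- net@params[[e$gamma]]; beta <- net@params[[e$beta]]
        y <- xb
        if (training) {
          mu <- numeric(C); invstd <- numeric(C)
          st <- state[[e$state]]
          for (c in seq_len(C)) {
            xc <- xb[, , c, , drop = FALSE]
            m <- mean(xc); v <- mean(xc * xc) - m * m
            mu[c] <- m; invstd[c] <- 1 / sqrt(v + .BN_EPS)
            y[, , c, ] <- (xc - m) * (invstd[c] * gamma[c]) + beta[c]
            st$mean[c] <- (1 - .BN_MOMENTUM) * st$mean[c] + .BN_MOMENTUM * m
            nEl <- length(xc)
            vUnb <- if (nEl > 1) v * nEl / (nEl - 1) else v
            st$var[c] <- (1 - .BN_MOMENTUM) * st$var[c] + .BN_MOMENTUM * vUnb
          }
          state[[e$state]] <- st
          caches[[k]] <- list(mu = mu, invstd = invstd)
        } else {
          st <- state[[e$state]]
          for (c in seq_len(C)) {
            sc <- gamma[c] / sqrt(st$var[c] + .BN_EPS)
            y[, , c, ] <- (xb[, , c, , drop = FALSE] - st$mean[c]) * sc + beta[c]
          }
        }
        bufs[[e$out]] <- y
      },
      maxpool = {
        r <- .maxpool_fwd(bufs[[e$`in`]], e$k, e$stride)
        bufs[[e$out]] <- r$y
        caches[[k]] <- r$arg
      },
      avgpool = {
        bufs[[e$out]] <- .avgpool_fwd(bufs[[e$`in`]], e$k, e$stride)
      },
      add = {
        bufs[[e$out]] <- bufs[[e$in1]] + bufs[[e$in2]]
      },
      copy = {
        bufs[[e$out]] <- bufs[[e$`in`]]
      },
      gap = {
        xb <- bufs[[e$`in`]]; d <- dim(xb)
        bufs[[e$out]] <- t(matrix(colMeans(matrix(xb, d[1] * d[2])),
                                  d[3], d[4]))   # N x C
      },
      linear = {
        xb <- bufs[[e$`in`]]                      # N x Cin
        W <- net@params[[e$w]]; b <- net@params[[e$b]]
        bufs[[e$out]] <- xb %*% t(W) + matrix(b, nrow(xb), length(b),
                                              byrow = TRUE)
      },
      stop("forward: unknown tape entry '", e$type, "'"))
  }
  list(bufs = bufs, caches = caches, state = state)
}

# reverse-mode pass; gOut is the gradient at the output buffer (N x K)
.backwardTape <- function(net, bufs, caches, gOut) {
  gbuf <- vector("list", net@nBuffers)
  grads <- list()
  addb <- function(i, g) gbuf[[i]] <<- if (is.null(gbuf[[i]])) g else gbuf[[i]] + g
  addp <- function(n, g) grads[[n]] <<- if (is.null(grads[[n]])) g else grads[[n]] + g
  gbuf[[net@outBuffer]] <- gOut
  for (k in rev(seq_along(net@tape))) {
    e <- net@tape[[k]]
    g <- gbuf[[e$out]]
    if (is.null(g)) next
    switch(e$type,
      conv = {
        r <- .conv2d_bwd(bufs[[e$`in`]], net@params[[e$w]], g,
                         e$stride, e$dilation, e$groups)
        addb(e$`in`, r$gx)
        addp(e$w, r$gw)
      },
      relu = {
        addb(e$`in`, g * (bufs[[e$`in`]] > 0))
      },
      bn = {
        xb <- bufs[[e$`in`]]; d <- dim(xb); C <- d[3]
        cc <- caches[[k]]
        gamma <- net@params[[e$gamma]]
        gx <- xb; ggamma <- numeric(C); gbeta <- numeric(C)
        for (c in seq_len(C)) {
          xc <- xb[, , c, , drop = FALSE]
          gc <- g[, , c, , drop = FALSE]
          xhat <- (xc - cc$mu[c]) * cc$invstd[c]
          gbeta[c] <- sum(gc)
          ggamma[c] <- sum(gc * xhat)
          m <- length(gc)
          gx[, , c, ] <- (gamma[c] * cc$invstd[c]) *
            (gc - gbeta[c] / m - xhat * (ggamma[c] / m))
        }
        addb(e$`in`, gx)
        addp(e$gamma, ggamma)
        addp(e$beta, gbeta)
      },
      maxpool = {
        addb(e$`in`, .maxpool_bwd(caches[[k]], g, dim(bufs[[e$`in`]])))
      },
      avgpool = {
        addb(e$`in`, .avgpool_bwd(g, dim(bufs[[e$`in`]]), e$k, e$stride))
      },
      add = {
        addb(e$in1, g)
        addb(e$in2, g)
      },
      copy = {
        addb(e$`in`, g)
      },
      gap = {
        d <- dim(bufs[[e$`in`]])
        gx <- array(0, d)
        per <- 1 / (d[1] * d[2])
        for (c in seq_len(d[3]))
          gx[, , c, ] <- rep(g[, c] * per, each = d[1] * d[2])
        addb(e$`in`, gx)
      },
      linear = {
        xb <- bufs[[e$`in`]]
        W <- net@params[[e$w]]
        addp(e$w, t(g) %*% xb)
        addp(e$b, colSums(g))
        addb(e$`in`, g %*% W)
      })
  }
  grads
}

# softmax cross-entropy; y: integer labels 1..K; returns loss, probs, glogits
.softmaxCE <- function(logits, y) {
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  p <- ex / rowSums(ex)
  n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  onehot <- matrix(0, n, ncol(logits))
  onehot[cbind(seq_len(n), y)] <- 1
  list(loss = loss, probs = p, glogits = (p - onehot) / n)
}

.adamInit <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

.adamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  for (n in names(grads)) {
    g <- grads[[n]]
    opt$m[[n]] <- beta1 * opt$m[[n]] + (1 - beta1) * g
    opt$v[[n]] <- beta2 * opt$v[[n]] + (1 - beta2) * g * g
    mhat <- opt$m[[n]] / (1 - beta1^opt$t)
    vhat <- opt$v[[n]] / (1 - beta2^opt$t)
    params[[n]] <- params[[n]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

#' Run a compiled network forward
#'
#' @param net A \linkS4class{CompiledNetwork}.
#' @param x Input tensor, array (H, W, C, N); a single (H, W) matrix is
#'   promoted to a batch of one.
#' @param type "scores" for raw class scores (N x K matrix), "probs" for
#'   softmax probabilities, "class" for 1-based predicted labels.
#' @return See `type`. Deterministic in eval mode.
#' @export
predictNetwork <- function(net, x, type = c("scores", "probs", "class")) {
  type <- match.arg(type)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  fw <- .forwardTape(net, x, training = FALSE)
  scores <- fw$bufs[[net@outBuffer]]
  switch(type,
    scores = scores,
    probs = {
      ex <- exp(scores - apply(scores, 1, max))
      ex / rowSums(ex)
    },
    class = max.col(scores, ties.method = "first"))
}
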