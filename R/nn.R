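# Minimal dense-network engine: parameter store, forward/backward passes and
# AdamW. Hidden layers follow Linear -> LayerNorm -> Mish -> Dropout; output
# layers are plain Linear. ATAC input/output layers can be split into
# independent per-chromosome blocks. Parameters live in an environment keyed
# by layer id, so layers shared between networks (encoder tails, decoder
# heads) are stored once and accumulate gradients from every use.

LN_EPS <- 1e-5

nnInitLinear <- function(nIn, nOut) {
  list(W = matrix(stats::rnorm(nIn * nOut, sd = sqrt(2 / nIn)), nIn, nOut),
       b = numeric(nOut))
}

# Allocate hidden units to blocks proportionally to their feature counts.
blockUnitAlloc <- function(blocks, nUnits) {
  sizes <- tabulate(blocks)
  alloc <- pmax(1L, round(nUnits * sizes / sum(sizes)))
  # adjust to hit nUnits exactly
  while (sum(alloc) > nUnits) alloc[which.max(alloc)] <-
      alloc[which.max(alloc)] - 1L
  while (sum(alloc) < nUnits) alloc[which.min(alloc)] <-
      alloc[which.min(alloc)] + 1L
  alloc
}

# Layer constructors return the spec; parameters go into `store`.
newDense <- function(store, id, nIn, nOut, dropout) {
  p <- nnInitLinear(nIn, nOut)
  p$g <- rep(1, nOut); p$be <- numeric(nOut)
  store[[id]] <- p
  list(id = id, type = "dense", dropout = dropout)
}

newLinear <- function(store, id, nIn, nOut) {
  store[[id]] <- nnInitLinear(nIn, nOut)
  list(id = id, type = "linear")
}

# Block-split dense input layer: feature block k feeds its own unit slice.
newBlockDense <- function(store, id, blocks, nOut, dropout) {
  alloc <- blockUnitAlloc(blocks, nOut)
  Ws <- lapply(seq_along(alloc), function(k)
    nnInitLinear(sum(blocks == k), alloc[k])$W)
  store[[id]] <- list(Ws = Ws, b = numeric(sum(alloc)),
                      g = rep(1, sum(alloc)), be = numeric(sum(alloc)))
  list(id = id, type = "blockDense", dropout = dropout, blocks = blocks,
       alloc = alloc)
}

# Block-split linear output layer: unit slice k reconstructs feature block k.
newBlockLinear <- function(store, id, nIn, blocks) {
  alloc <- blockUnitAlloc(blocks, nIn)
  Ws <- lapply(seq_along(alloc), function(k)
    nnInitLinear(alloc[k], sum(blocks == k))$W)
  store[[id]] <- list(Ws = Ws, b = numeric(length(blocks)))
  list(id = id, type = "blockLinear", blocks = blocks, alloc = alloc)
}

# x + rowvec / x * rowvec without sweep()'s aperm overhead
rowAdd <- function(M, v) M + rep(v, each = nrow(M))
rowMul <- function(M, v) M * rep(v, each = nrow(M))

# Mish forward keeps tanh(softplus(x)) and sigmoid(x) for the backward pass.
mishFwd <- function(x) {
  tn <- tanh(log1p(exp(x)))        # overflow-safe: log1p(Inf) = Inf, tanh -> 1
  sg <- 1 / (1 + exp(-x))
  list(out = x * tn, tn = tn, sg = sg)
}

layerForward <- function(store, layer, X, train = FALSE) {
  p <- store[[layer$id]]
  cache <- list(X = X)
  if (layer$type %in% c("linear", "blockLinear")) {
    out <- if (layer$type == "linear") {
      rowAdd(X %*% p$W, p$b)
    } else {
      cols <- split(seq_along(layer$blocks), layer$blocks)
      slices <- cumsum(c(0L, layer$alloc))
      Y <- matrix(0, nrow(X), length(layer$blocks))
      for (k in seq_along(cols))
        Y[, cols[[k]]] <- X[, (slices[k] + 1):slices[k + 1], drop = FALSE] %*%
          p$Ws[[k]]
      rowAdd(Y, p$b)
    }
    return(list(out = out, cache = cache))
  }
  # dense / blockDense: linear part
  if (layer$type == "dense") {
    A <- rowAdd(X %*% p$W, p$b)
  } else {
    cols <- split(seq_along(layer$blocks), layer$blocks)
    slices <- cumsum(c(0L, layer$alloc))
    A <- matrix(0, nrow(X), sum(layer$alloc))
    for (k in seq_along(cols))
      A[, (slices[k] + 1):slices[k + 1]] <-
        X[, cols[[k]], drop = FALSE] %*% p$Ws[[k]]
    A <- rowAdd(A, p$b)
  }
  mu <- rowMeans(A)
  Ac <- A - mu
  v <- rowMeans(Ac^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- Ac * inv
  H <- rowAdd(rowMul(xhat, p$g), p$be)
  mr <- mishFwd(H)
  M <- mr$out
  if (train && layer$dropout > 0) {
    mask <- (matrix(stats::runif(length(M)), nrow(M)) >= layer$dropout) /
      (1 - layer$dropout)
    out <- M * mask
  } else {
    mask <- NULL
    out <- M
  }
  cache$xhat <- xhat; cache$inv <- inv; cache$H <- H
  cache$tn <- mr$tn; cache$sg <- mr$sg
  cache$mask <- mask
  list(out = out, cache = cache)
}

layerBackward <- function(store, grads, layer, dOut, cache) {
  p <- store[[layer$id]]
  if (layer$type %in% c("linear", "blockLinear")) {
    g <- list(b = colSums(dOut))
    if (layer$type == "linear") {
      g$W <- crossprod(cache$X, dOut)
      dX <- dOut %*% t(p$W)
    } else {
      cols <- split(seq_along(layer$blocks), layer$blocks)
      slices <- cumsum(c(0L, layer$alloc))
      g$Ws <- vector("list", length(cols))
      dX <- matrix(0, nrow(dOut), sum(layer$alloc))
      for (k in seq_along(cols)) {
        sl <- (slices[k] + 1):slices[k + 1]
        g$Ws[[k]] <- crossprod(cache$X[, sl, drop = FALSE],
                               dOut[, cols[[k]], drop = FALSE])
        dX[, sl] <- dOut[, cols[[k]], drop = FALSE] %*% t(p$Ws[[k]])
      }
    }
    gradAccum(grads, layer$id, g)
    return(dX)
  }
  # dense / blockDense
  if (!is.null(cache$mask)) dOut <- dOut * cache$mask
  dH <- dOut * (cache$tn + cache$H * (1 - cache$tn^2) * cache$sg)
  dg <- colSums(dH * cache$xhat)
  dbe <- colSums(dH)
  dXhat <- rowMul(dH, p$g)
  # layernorm backward (per row)
  m1 <- rowMeans(dXhat)
  m2 <- rowMeans(dXhat * cache$xhat)
  dA <- (dXhat - m1 - cache$xhat * m2) * cache$inv
  g <- list(b = colSums(dA), g = dg, be = dbe)
  if (layer$type == "dense") {
    g$W <- crossprod(cache$X, dA)
    dX <- dA %*% t(p$W)
  } else {
    cols <- split(seq_along(layer$blocks), layer$blocks)
    slices <- cumsum(c(0L, layer$alloc))
    g$Ws <- vector("list", length(cols))
    dX <- matrix(0, nrow(dA), length(layer$blocks))
    for (k in seq_along(cols)) {
      sl <- (slices[k] + 1):slices[k + 1]
      g$Ws[[k]] <- crossprod(cache$X[, cols[[k]], drop = FALSE],
                             dA[, sl, drop = FALSE])
      dX[, cols[[k]]] <- dA[, sl, drop = FALSE] %*% t(p$Ws[[k]])
    }
  }
  gradAccum(grads, layer$id, g)
  dX
}

gradAccum <- function(grads, id, g) {
  if (is.null(grads[[id]])) {
    grads[[id]] <- g
  } else {
    old <- grads[[id]]
    for (nm in names(g)) {
      if (nm == "Ws") {
        for (k in seq_along(g$Ws)) old$Ws[[k]] <- old$Ws[[k]] + g$Ws[[k]]
      } else old[[nm]] <- old[[nm]] + g[[nm]]
    }
    grads[[id]] <- old
  }
  invisible(NULL)
}

mlpForward <- function(store, net, X, train = FALSE) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    r <- layerForward(store, net[[i]], X, train)
    X <- r$out
    caches[[i]] <- r$cache
  }
  list(out = X, caches = caches)
}

mlpBackward <- function(store, grads, net, dOut, caches) {
  for (i in rev(seq_along(net)))
    dOut <- layerBackward(store, grads, net[[i]], dOut, caches[[i]])
  dOut
}

# AdamW update over all ids with accumulated gradients whose id matches
# `prefixes`; `scale` multiplies gradients (e.g. 1/minibatch size).
adamwStep <- function(store, grads, state, prefixes, lr, scale = 1,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weightDecay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, mstate) {
    g <- g * scale
    if (is.null(mstate)) mstate <- list(m = p * 0, v = p * 0)
    mstate$m <- beta1 * mstate$m + (1 - beta1) * g
    mstate$v <- beta2 * mstate$v + (1 - beta2) * g^2
    p <- p - lr * ((mstate$m / bc1) / (sqrt(mstate$v / bc2) + eps) +
                     weightDecay * p)
    list(p = p, s = mstate)
  }
  for (id in ls(grads)) {
    if (!any(startsWith(id, prefixes))) next
    g <- grads[[id]]
    p <- store[[id]]
    s <- state$moments[[id]]
    if (is.null(s)) s <- list()
    for (nm in names(g)) {
      if (nm == "Ws") {
        if (is.null(s$Ws)) s$Ws <- vector("list", length(g$Ws))
        for (k in seq_along(g$Ws)) {
          r <- upd(p$Ws[[k]], g$Ws[[k]], s$Ws[[k]])
          p$Ws[[k]] <- r$p; s$Ws[[k]] <- r$s
        }
      } else {
        r <- upd(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- r$p; s[[nm]] <- r$s
      }
    }
    store[[id]] <- p
    state$moments[[id]] <- s
  }
  invisible(NULL)
}

newGradEnv <- function() new.env(parent = emptyenv())
newAdamState <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e$moments <- list()
  e
}
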