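#' @include AllClasses.R nn.R
NULL

NU_MIN <- 1e-4
NU_MAX <- 1e4
# pseudo-variance of the batch expert on the c dims: effectively no
# contribution to the biological state (precision 1e-8)
BATCH_C_NU <- 1e8

#' Model architecture description
#'
#' Hyperparameters of the modular VAE. Defaults: biological-state dimension
#' 32, technical-noise dimension 2, encoder hidden sizes 1024 then 128 (the
#' 128-side tail is shared across modality encoders), mirrored decoder
#' hidden sizes 128 then 1024 (the 128-side head is shared), dropout 0.2 on
#' every hidden layer, and chromosome-block splitting of the ATAC input and
#' reconstruction layers. Batch-ID encoder/decoder and the adversarial
#' classifiers are small MLPs (classifiers: two hidden layers of 128).
#'
#' @param dC,dU latent dimensions for biological state and technical noise.
#' @param encHidden,decHidden hidden layer sizes of encoders/decoders; the
#'   first encoder layer is modality-specific, the rest are shared (and
#'   mirrored for the decoder).
#' @param dropout dropout rate for all hidden layers.
#' @param atacSplit split ATAC input/reconstruction layers by chromosome
#'   block.
#' @param clfHidden hidden sizes of the batch classifiers.
#' @param batchNetHidden hidden size of the batch-ID encoder/decoder.
#' @param scaleRates if `TRUE` (default) Poisson rates are normalized and
#'   multiplied by each cell's observed library factor; if `FALSE` the
#'   decoder emits absolute rates.
#' @return list of class `"mosaicArchitecture"`.
#' @export
mosaicArchitecture <- function(dC = 32L, dU = 2L,
                               encHidden = c(1024L, 128L),
                               decHidden = rev(encHidden),
                               dropout = 0.2, atacSplit = TRUE,
                               clfHidden = c(128L, 128L),
                               batchNetHidden = 128L,
                               scaleRates = TRUE) {
  stopifnot(dC >= 1L, dU >= 1L, all(encHidden > 0), all(decHidden > 0),
            dropout >= 0, dropout < 1)
  structure(list(dC = as.integer(dC), dU = as.integer(dU),
                 encHidden = as.integer(encHidden),
                 decHidden = as.integer(decHidden), dropout = dropout,
                 atacSplit = isTRUE(atacSplit),
                 clfHidden = as.integer(clfHidden),
                 batchNetHidden = as.integer(batchNetHidden),
                 scaleRates = isTRUE(scaleRates)),
            class = "mosaicArchitecture")
}

#' Loss weights of the training objective
#'
#' Defaults follow the published setting: modality-alignment weight
#' `alpha = 50`, technical information-bottleneck weight `betaS = 30`,
#' biological information-bottleneck weight `betaX = 4`, batch-likelihood
#' weight `gamma = 1000`, and `K = 3` classifier updates per joint update.
#'
#' @param alpha,betaS,betaX,gamma non-negative loss weights (`gamma >= 1`).
#' @param K classifier updates per iteration (`>= 1`).
#' @return list of class `"mosaicLossWeights"`.
#' @export
lossWeights <- function(alpha = 50, betaS = 30, betaX = 4, gamma = 1000,
                        K = 3L) {
  stopifnot(alpha >= 0, betaS >= 0, betaX >= 0, gamma >= 1, K >= 1)
  structure(list(alpha = alpha, betaS = betaS, betaX = betaX, gamma = gamma,
                 K = as.integer(K)), class = "mosaicLossWeights")
}

# Build all layer specs and initialize parameters for the given feature
# spaces and batch count. Returns list(store = env, nets = list).
buildNetworks <- function(featureSpaces, nBatches, arch) {
  store <- new.env(parent = emptyenv())
  dZ <- arch$dC + arch$dU
  eh <- arch$encHidden; dh <- arch$decHidden
  nets <- list(enc = list(), decOut = list(), clf = list())
  # shared encoder tail: hidden layers beyond the first, plus output head
  sharedEnc <- list()
  for (i in seq_along(eh)[-1])
    sharedEnc[[length(sharedEnc) + 1L]] <-
      newDense(store, sprintf("phi.enc.shared.%d", i), eh[i - 1], eh[i],
               arch$dropout)
  sharedEnc[[length(sharedEnc) + 1L]] <-
    newLinear(store, "phi.enc.out", eh[length(eh)], 2L * dZ)
  for (m in names(featureSpaces)) {
    fs <- featureSpaces[[m]]
    D <- length(fs@names)
    inLayer <- if (m == "ATAC" && arch$atacSplit && length(fs@blocks)) {
      newBlockDense(store, "phi.enc.in.ATAC", fs@blocks, eh[1], arch$dropout)
    } else {
      newDense(store, sprintf("phi.enc.in.%s", m), D, eh[1], arch$dropout)
    }
    nets$enc[[m]] <- c(list(inLayer), sharedEnc)
  }
  # the batch-ID expert parameterizes only the technical-noise part of z:
  # in the generative model the batch ID depends on u alone, and a batch
  # expert on c would pin the biological state to a per-batch constant
  nets$encBatch <- list(
    newDense(store, "phi.encBatch.hidden", nBatches, arch$batchNetHidden,
             arch$dropout),
    newLinear(store, "phi.encBatch.out", arch$batchNetHidden,
              2L * arch$dU))
  # shared decoder head
  sharedDec <- list(newDense(store, "theta.dec.shared.1", dZ, dh[1],
                             arch$dropout))
  for (i in seq_along(dh)[-1])
    sharedDec[[length(sharedDec) + 1L]] <-
      newDense(store, sprintf("theta.dec.shared.%d", i), dh[i - 1], dh[i],
               arch$dropout)
  nets$decShared <- sharedDec
  for (m in names(featureSpaces)) {
    fs <- featureSpaces[[m]]
    D <- length(fs@names)
    nets$decOut[[m]] <- list(
      if (m == "ATAC" && arch$atacSplit && length(fs@blocks))
        newBlockLinear(store, "theta.dec.out.ATAC", dh[length(dh)],
                       fs@blocks)
      else newLinear(store, sprintf("theta.dec.out.%s", m), dh[length(dh)],
                     D))
  }
  nets$decBatch <- list(
    newDense(store, "theta.decBatch.hidden", arch$dU, arch$batchNetHidden,
             arch$dropout),
    newLinear(store, "theta.decBatch.out", arch$batchNetHidden, nBatches))
  clfNet <- function(tag) {
    layers <- list()
    nIn <- arch$dC
    for (i in seq_along(arch$clfHidden)) {
      layers[[i]] <- newDense(store, sprintf("eta.clf.%s.%d", tag, i), nIn,
                              arch$clfHidden[i], arch$dropout)
      nIn <- arch$clfHidden[i]
    }
    layers[[length(layers) + 1L]] <-
      newLinear(store, sprintf("eta.clf.%s.out", tag), nIn, nBatches)
    layers
  }
  nets$clf$joint <- clfNet("joint")
  for (m in names(featureSpaces)) nets$clf[[m]] <- clfNet(m)
  list(store = store, nets = nets)
}

#' Initialize an untrained mosaic model
#'
#' Allocates and randomly initializes all encoder, decoder and classifier
#' parameter groups for the dataset's feature spaces and batch count.
#'
#' @param dataset a [MosaicDataset] defining feature spaces and batches.
#' @param architecture a [mosaicArchitecture()].
#' @param weights a [lossWeights()].
#' @param seed integer seed for parameter initialization.
#' @return an untrained [MosaicModel].
#' @export
initMosaicModel <- function(dataset, architecture = mosaicArchitecture(),
                            weights = lossWeights(), seed = 1L) {
  stopifnot(is(dataset, "MosaicDataset"))
  run <- localRNG(seed)
  built <- run(function()
    buildNetworks(dataset@featureSpaces, nBatches(dataset), architecture))
  libs <- libraryFactors(dataset)
  new("MosaicModel",
      params = list(store = as.list(built$store), nets = built$nets),
      architecture = unclass(architecture), lossWeights = unclass(weights),
      featureSpaces = dataset@featureSpaces,
      nBatches = nBatches(dataset),
      trainLog = data.frame(),
      config = list(libMedian = libs$median,
                    libBatchMedian = libs$batchMedian))
}

# Per-cell library factor: mean observed count per measured feature; the
# per-modality medians are kept on the model for decoding cells that lack
# the modality.
libraryFactors <- function(dataset) {
  perBatch <- list(); med <- list()
  for (m in modalities(dataset)) {
    vals <- list()
    for (b in dataset@batches) {
      if (!m %in% b@modalities) next
      mk <- b@masks[[m]]
      tot <- Matrix::rowSums(b@counts[[m]])
      vals[[as.character(b@batchId)]] <- as.numeric(tot) / max(1L, sum(mk))
    }
    perBatch[[m]] <- vals
    med[[m]] <- stats::median(unlist(vals))
  }
  list(perBatch = perBatch, median = med,
       batchMedian = lapply(perBatch, function(v)
         lapply(v, stats::median)))
}

storeEnv <- function(model) {
  e <- new.env(parent = emptyenv())
  for (nm in names(model@params$store)) e[[nm]] <- model@params$store[[nm]]
  e
}

# Encoder-side input transform: masked zeros stay zero; RNA/ADT are
# log1p-stabilized, ATAC enters binary.
encoderInput <- function(X, modality, mask = NULL) {
  X <- as.matrix(X)
  if (modality %in% c("RNA", "ADT")) X <- log1p(X)
  if (!is.null(mask)) X <- sweep(X, 2, mask, "*")
  X
}

splitMuNu <- function(out, dZ) {
  mu <- out[, seq_len(dZ), drop = FALSE]
  lv <- out[, dZ + seq_len(dZ), drop = FALSE]
  lo <- log(NU_MIN); hi <- log(NU_MAX)
  inRange <- lv > lo & lv < hi
  lv <- pmin(pmax(lv, lo), hi)
  list(mu = mu, nu = exp(lv), lvInRange = inRange)
}

#' Encode one modality into its Gaussian expert
#'
#' Runs the modality encoder on padded (and internally transformed) counts
#' and returns the diagonal-Gaussian parameters of the unnormalized expert
#' over the joint latent `z = (c, u)`. Deterministic in eval mode.
#'
#' @param model a [MosaicModel].
#' @param X cells x `D^m` padded count matrix.
#' @param modality one of the model's modalities.
#' @param mask optional 0/1 feature mask applied to the input.
#' @return list with matrices `mu` and `nu` (cells x `d_c + d_u`).
#' @export
encodeModality <- function(model, X, modality, mask = NULL) {
  if (!modality %in% names(model@params$nets$enc))
    stop("model has no encoder for modality ", modality)
  X <- encoderInput(X, modality, mask)
  if (any(!is.finite(X))) stop("NaN/Inf in encoder input")
  store <- storeEnv(model)
  out <- mlpForward(store, model@params$nets$enc[[modality]], X,
                    train = FALSE)$out
  r <- splitMuNu(out, model@architecture$dC + model@architecture$dU)
  list(mu = r$mu, nu = r$nu)
}

#' Encode batch IDs into the batch-ID Gaussian expert
#'
#' The batch expert informs only the technical-noise dimensions of the
#' latent: its biological-state part is flat (mean 0, effectively infinite
#' variance), because the generative model ties the batch ID to `u` alone.
#'
#' @param model a [MosaicModel].
#' @param s integer vector of batch IDs in `1..B`.
#' @return list with matrices `mu` and `nu` (length(s) x `d_c + d_u`).
#' @export
encodeBatch <- function(model, s) {
  B <- model@nBatches
  s <- as.integer(s)
  if (any(s < 1L | s > B)) stop("batch ID out of range 1..", B)
  X <- matrix(0, length(s), B)
  X[cbind(seq_along(s), s)] <- 1
  store <- storeEnv(model)
  out <- mlpForward(store, model@params$nets$encBatch, X, train = FALSE)$out
  r <- splitMuNu(out, model@architecture$dU)
  expandBatchExpert(r$mu, r$nu, model@architecture$dC)
}

# Lift a u-only batch expert to the full latent with a flat c part.
expandBatchExpert <- function(muU, nuU, dC) {
  n <- nrow(muU)
  list(mu = cbind(matrix(0, n, dC), muU),
       nu = cbind(matrix(BATCH_C_NU, n, dC), nuU))
}

#' Combine Gaussian experts by product of experts
#'
#' Multiplies diagonal-Gaussian densities (experts) together with the
#' implicit standard-normal prior. Precisions add:
#' `nu = (1 + sum(1/nu_i))^-1`, `mu = nu * sum(mu_i/nu_i)`. With no experts
#' the prior `(0, 1)` is returned.
#'
#' @param experts list of experts, each a list with `mu` and `nu` (equal
#'   length vectors, or matrices of matching shape); may be empty.
#' @param d latent dimension, required when `experts` is empty.
#' @return list with `mu` and `nu` in the shape of the inputs.
#' @export
poeCombine <- function(experts, d = NULL) {
  if (!length(experts)) {
    if (is.null(d)) stop("d required when no experts are given")
    return(list(mu = numeric(d), nu = rep(1, d)))
  }
  prec <- 1
  wsum <- 0
  for (e in experts) {
    if (any(e$nu <= 0)) stop("expert variances must be strictly positive")
    prec <- prec + 1 / e$nu
    wsum <- wsum + e$mu / e$nu
  }
  nu <- 1 / prec
  list(mu = wsum * nu, nu = nu)
}

# Backward through the PoE given output grads and cached inputs/outputs.
poeBackward <- function(experts, out, dMu, dNu) {
  lapply(experts, function(e) {
    list(dMu = dMu * out$nu / e$nu,
         dNu = dNu * (out$nu / e$nu)^2 +
           dMu * out$nu * (out$mu - e$mu) / e$nu^2)
  })
}

#' Decode latents into modality means and batch probabilities
#'
#' Maps biological-state and technical-noise coordinates through the shared
#' decoder head and the per-modality output layers. ATAC means pass through
#' a sigmoid into (0,1); RNA/ADT means through softplus (times a library
#' factor when the model scales rates); the batch decoder returns softmax
#' probabilities over batches.
#'
#' @param model a [MosaicModel].
#' @param cMat,uMat cells x `d_c` / `d_u` latent matrices.
#' @param libFactor optional named list of per-cell library factors per
#'   modality; defaults to the model's stored per-modality medians.
#' @return list with `lambda` (named list of cells x `D^m` mean matrices
#'   over the full unions) and `pi` (cells x B batch probabilities).
#' @export
decodeLatent <- function(model, cMat, uMat, libFactor = NULL) {
  cMat <- as.matrix(cMat); uMat <- as.matrix(uMat)
  if (any(!is.finite(cMat)) || any(!is.finite(uMat)))
    stop("NaN/Inf in latents")
  store <- storeEnv(model)
  nets <- model@params$nets
  z <- cbind(cMat, uMat)
  h <- mlpForward(store, nets$decShared, z, train = FALSE)$out
  lambda <- list()
  for (m in names(nets$decOut)) {
    a <- mlpForward(store, nets$decOut[[m]], h, train = FALSE)$out
    lambda[[m]] <- if (m == "ATAC") {
      1 / (1 + exp(-a))
    } else {
      lf <- if (!is.null(libFactor[[m]])) libFactor[[m]] else
        if (model@architecture$scaleRates) model@config$libMedian[[m]] else 1
      softplus(a) * lf
    }
    colnames(lambda[[m]]) <- model@featureSpaces[[m]]@names
  }
  oS <- mlpForward(store, nets$decBatch, uMat, train = FALSE)$out
  pi <- softmaxRows(oS)
  list(lambda = lambda, pi = pi)
}

softmaxRows <- function(o) {
  o <- o - apply(o, 1, max)
  e <- exp(o)
  e / rowSums(e)
}

#' Posterior of the latent given a subset of a cell's observations
#'
#' Combines cached expert parameters (batch-ID expert plus any subset of
#' modality experts) with the prior via [poeCombine()], without re-running
#' the encoders. With a single modality this is the unimodal posterior used
#' by the self-supervised alignment task.
#'
#' @param batchExpert list with `mu`, `nu` from [encodeBatch()].
#' @param modalityExperts list of expert lists from [encodeModality()]; may
#'   be empty (cells with only a batch ID).
#' @return list with `mu` and `nu` of the combined Gaussian posterior.
#' @export
unimodalPosterior <- function(batchExpert, modalityExperts = list()) {
  poeCombine(c(list(batchExpert), modalityExperts))
}
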