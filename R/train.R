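#' @include losses.R
NULL

# Dense, encoder-ready copies of a dataset, grouped by batch. Cells of one
# batch share the batch ID, modality set and masks, so each minibatch is
# processed in per-batch groups with one expert routing per group.
prepTrainData <- function(dataset, arch) {
  libs <- libraryFactors(dataset)
  groups <- lapply(dataset@batches, function(b) {
    raw <- list(); enc <- list(); lib <- list(); lgam <- list()
    for (m in b@modalities) {
      raw[[m]] <- as.matrix(b@counts[[m]])
      enc[[m]] <- encoderInput(raw[[m]], m, b@masks[[m]])
      lib[[m]] <- libs$perBatch[[m]][[as.character(b@batchId)]]
      if (m != "ATAC")   # constant per-cell lgamma(x+1) term of Poisson NLL
        lgam[[m]] <- as.numeric(rowMul(lgamma(raw[[m]] + 1),
                                       b@masks[[m]]) %*%
                                  rep(1, ncol(raw[[m]])))
    }
    list(s = b@batchId, mods = b@modalities, raw = raw, enc = enc,
         masks = b@masks, lib = lib, lgam = lgam, n = length(b@cellIds))
  })
  list(groups = groups, libMedian = libs$median,
       libBatchMedian = libs$batchMedian)
}

onehotRows <- function(s, n, B) {
  X <- matrix(0, n, B)
  X[, s] <- 1
  X
}

# Forward (and optionally backward) pass for the cells `rows` of one batch
# group. Accumulates parameter gradients into `grads` when given; returns
# summed (not averaged) loss components. Classifier parameters are treated
# as frozen here: their gradients accumulate but the joint update never
# applies eta-prefixed entries.
groupPass <- function(store, nets, g, rows, weights, arch, B,
                      grads = NULL, train = FALSE, scaleRates = TRUE) {
  n <- length(rows)
  dC <- arch$dC; dU <- arch$dU; dZ <- dC + dU
  cIdx <- seq_len(dC); uIdx <- dC + seq_len(dU)
  mods <- g$mods
  backprop <- !is.null(grads)

  # --- encoders -> experts
  encRes <- list(); experts <- list()
  for (m in mods) {
    r <- mlpForward(store, nets$enc[[m]], g$enc[[m]][rows, , drop = FALSE],
                    train = train)
    sp <- splitMuNu(r$out, dZ)
    encRes[[m]] <- list(caches = r$caches, lvInRange = sp$lvInRange)
    experts[[m]] <- list(mu = sp$mu, nu = sp$nu)
  }
  rB <- mlpForward(store, nets$encBatch, onehotRows(g$s, n, B),
                   train = train)
  spB <- splitMuNu(rB$out, dU)
  expertB <- expandBatchExpert(spB$mu, spB$nu, dC)

  # --- joint posterior and sample
  jointExperts <- c(list(expertB), unname(experts))
  joint <- poeCombine(jointExperts)
  epsJ <- matrix(stats::rnorm(n * dZ), n, dZ)
  zJ <- joint$mu + sqrt(joint$nu) * epsJ
  cJ <- zJ[, cIdx, drop = FALSE]; uJ <- zJ[, uIdx, drop = FALSE]

  # --- decode measured modalities
  hRes <- mlpForward(store, nets$decShared, zJ, train = train)
  recon <- 0
  dA <- list(); outRes <- list()
  for (m in mods) {
    r <- mlpForward(store, nets$decOut[[m]], hRes$out, train = train)
    outRes[[m]] <- r
    a <- r$out
    x <- g$raw[[m]][rows, , drop = FALSE]
    mk <- g$masks[[m]]
    if (m == "ATAC") {
      recon <- recon + sum(rowMul(log1p(exp(a)) - x * a, mk))
      if (backprop) dA[[m]] <- rowMul(1 / (1 + exp(-a)) - x, mk)
    } else {
      l <- if (scaleRates) g$lib[[m]][rows] else 1
      lam <- log1p(exp(a)) * l + 1e-8
      recon <- recon + sum(rowMul(lam - x * log(lam), mk)) +
        sum(g$lgam[[m]][rows])
      if (backprop)
        dA[[m]] <- rowMul((1 - x / lam) * (1 / (1 + exp(-a))) * l, mk)
    }
  }

  # --- batch decoder on u (ELBO gamma term; also reused by the joint IB)
  oRes <- mlpForward(store, nets$decBatch, uJ, train = train)
  pS <- softmaxRows(oRes$out)
  ceS <- -sum(log(pS[, g$s]))
  klJ <- 0.5 * sum(joint$mu^2 + joint$nu - log(joint$nu) - 1)
  elbo <- weights$gamma * ceS + recon + klJ

  # --- joint IB: adversarial classifier on c, KL and batch NLL on u
  rC <- mlpForward(store, nets$clf$joint, cJ, train = train)
  pC <- softmaxRows(rC$out)
  muU <- joint$mu[, uIdx, drop = FALSE]; nuU <- joint$nu[, uIdx, drop = FALSE]
  ib <- weights$betaS * sum(log(pC[, g$s])) +
    weights$betaX * 0.5 * sum(muU^2 + nuU - log(nuU) - 1) -
    weights$betaX * sum(log(pS[, g$s]))

  # --- unimodal posteriors, alignment, per-modality IB
  uni <- list()
  for (m in mods) {
    post <- poeCombine(list(expertB, experts[[m]]))
    eps <- matrix(stats::rnorm(n * dZ), n, dZ)
    uni[[m]] <- list(post = post, eps = eps,
                     z = post$mu + sqrt(post$nu) * eps,
                     dz = if (backprop) matrix(0, n, dZ))
  }
  align <- 0
  if (length(mods) >= 2L) {
    zbar <- Reduce(`+`, lapply(uni, `[[`, "z")) / length(mods)
    for (m in mods) {
      d <- uni[[m]]$z - zbar
      align <- align + weights$alpha * sum(d^2)
      if (backprop) uni[[m]]$dz <- uni[[m]]$dz + 2 * weights$alpha * d
    }
  }
  clfRes <- list(); pCm <- list(); oResM <- list(); pSm <- list()
  for (m in mods) {
    cm <- uni[[m]]$z[, cIdx, drop = FALSE]
    um <- uni[[m]]$z[, uIdx, drop = FALSE]
    rCm <- mlpForward(store, nets$clf[[m]], cm, train = train)
    pCm[[m]] <- softmaxRows(rCm$out)
    clfRes[[m]] <- rCm
    oM <- mlpForward(store, nets$decBatch, um, train = train)
    pSm[[m]] <- softmaxRows(oM$out)
    oResM[[m]] <- oM
    muUm <- uni[[m]]$post$mu[, uIdx, drop = FALSE]
    nuUm <- uni[[m]]$post$nu[, uIdx, drop = FALSE]
    ib <- ib + weights$betaS * sum(log(pCm[[m]][, g$s])) +
      weights$betaX * 0.5 * sum(muUm^2 + nuUm - log(nuUm) - 1) -
      weights$betaX * sum(log(pSm[[m]][, g$s]))
  }
  total <- elbo + align + ib
  losses <- c(total = total, elbo = elbo, align = align, ib = ib)
  if (!backprop)
    return(list(losses = losses, joint = joint, uni = uni))

  # ---------- backward ----------
  onehot <- matrix(0, n, B); onehot[, g$s] <- 1
  # reconstruction -> shared decoder -> zJ
  dH <- matrix(0, n, ncol(hRes$out))
  for (m in mods)
    dH <- dH + mlpBackward(store, grads, nets$decOut[[m]], dA[[m]],
                           outRes[[m]]$caches)
  dZJ <- mlpBackward(store, grads, nets$decShared, dH, hRes$caches)
  # batch decoder on uJ: gamma CE plus the joint IB's -betaX log p(s|u)
  dOS <- (weights$gamma + weights$betaX) * (pS - onehot)
  dUJ <- mlpBackward(store, grads, nets$decBatch, dOS, oRes$caches)
  dZJ[, uIdx] <- dZJ[, uIdx, drop = FALSE] + dUJ
  # adversarial classifier on cJ (classifier frozen, gradient flows to c)
  dOC <- weights$betaS * (onehot - pC)
  dCJ <- mlpBackward(store, grads, nets$clf$joint, dOC, rC$caches)
  dZJ[, cIdx] <- dZJ[, cIdx, drop = FALSE] + dCJ
  # KL terms on the joint posterior parameters
  dMuJ <- dZJ
  dNuJ <- dZJ * epsJ / (2 * sqrt(joint$nu))
  dMuJ <- dMuJ + joint$mu
  dNuJ <- dNuJ + 0.5 * (1 - 1 / joint$nu)
  dMuJ[, uIdx] <- dMuJ[, uIdx, drop = FALSE] +
    weights$betaX * joint$mu[, uIdx, drop = FALSE]
  dNuJ[, uIdx] <- dNuJ[, uIdx, drop = FALSE] +
    weights$betaX * 0.5 * (1 - 1 / joint$nu[, uIdx, drop = FALSE])
  expGrad <- poeBackward(jointExperts, joint, dMuJ, dNuJ)
  dExpertB <- expGrad[[1]]
  dExperts <- stats::setNames(expGrad[-1], mods)
  # unimodal paths
  for (m in mods) {
    u <- uni[[m]]
    dz <- u$dz
    dOCm <- weights$betaS * (onehot - pCm[[m]])
    dz[, cIdx] <- dz[, cIdx, drop = FALSE] +
      mlpBackward(store, grads, nets$clf[[m]], dOCm, clfRes[[m]]$caches)
    dOSm <- -weights$betaX * (onehot - pSm[[m]])
    dz[, uIdx] <- dz[, uIdx, drop = FALSE] +
      mlpBackward(store, grads, nets$decBatch, dOSm, oResM[[m]]$caches)
    dMuU <- dz
    dNuU <- dz * u$eps / (2 * sqrt(u$post$nu))
    dMuU[, uIdx] <- dMuU[, uIdx, drop = FALSE] +
      weights$betaX * u$post$mu[, uIdx, drop = FALSE]
    dNuU[, uIdx] <- dNuU[, uIdx, drop = FALSE] +
      weights$betaX * 0.5 * (1 - 1 / u$post$nu[, uIdx, drop = FALSE])
    eg <- poeBackward(list(expertB, experts[[m]]), u$post, dMuU, dNuU)
    dExpertB$dMu <- dExpertB$dMu + eg[[1]]$dMu
    dExpertB$dNu <- dExpertB$dNu + eg[[1]]$dNu
    dExperts[[m]]$dMu <- dExperts[[m]]$dMu + eg[[2]]$dMu
    dExperts[[m]]$dNu <- dExperts[[m]]$dNu + eg[[2]]$dNu
  }
  # experts -> encoders (variance head: nu = exp(clamped logvar))
  for (m in mods) {
    dOut <- cbind(dExperts[[m]]$dMu,
                  dExperts[[m]]$dNu * experts[[m]]$nu *
                    encRes[[m]]$lvInRange)
    mlpBackward(store, grads, nets$enc[[m]], dOut, encRes[[m]]$caches)
  }
  dOutB <- cbind(dExpertB$dMu[, uIdx, drop = FALSE],
                 dExpertB$dNu[, uIdx, drop = FALSE] *
                   expertB$nu[, uIdx, drop = FALSE] * spB$lvInRange)
  mlpBackward(store, grads, nets$encBatch, dOutB, rB$caches)
  list(losses = losses, joint = joint, uni = uni)
}

# Classifier phase: K AdamW steps on eta with detached latent samples.
classifierPhase <- function(store, nets, gdat, batchRows, weights, arch, B,
                            adamEta, lr, nTot) {
  dC <- arch$dC; dZ <- arch$dC + arch$dU
  cIdx <- seq_len(dC)
  samples <- list()
  for (j in seq_along(batchRows)) {
    rows <- batchRows[[j]]
    if (!length(rows)) next
    g <- gdat$groups[[j]]
    n <- length(rows)
    experts <- list()
    for (m in g$mods) {
      r <- mlpForward(store, nets$enc[[m]],
                      g$enc[[m]][rows, , drop = FALSE], train = TRUE)
      sp <- splitMuNu(r$out, dZ)
      experts[[m]] <- list(mu = sp$mu, nu = sp$nu)
    }
    rb <- mlpForward(store, nets$encBatch, onehotRows(g$s, n, B),
                     train = TRUE)
    spB <- splitMuNu(rb$out, arch$dU)
    expertB <- expandBatchExpert(spB$mu, spB$nu, dC)
    joint <- poeCombine(c(list(expertB), unname(experts)))
    cJ <- (joint$mu + sqrt(joint$nu) *
             matrix(stats::rnorm(n * dZ), n, dZ))[, cIdx, drop = FALSE]
    cms <- lapply(g$mods, function(m) {
      p <- poeCombine(list(expertB, experts[[m]]))
      (p$mu + sqrt(p$nu) *
         matrix(stats::rnorm(n * dZ), n, dZ))[, cIdx, drop = FALSE]
    })
    names(cms) <- g$mods
    samples[[j]] <- list(s = g$s, cJ = cJ, cms = cms, n = n)
  }
  lossFirst <- NA_real_
  for (k in seq_len(weights$K)) {
    grads <- newGradEnv()
    loss <- 0
    for (sm in samples) {
      if (is.null(sm)) next
      onehot <- matrix(0, sm$n, B); onehot[, sm$s] <- 1
      r <- mlpForward(store, nets$clf$joint, sm$cJ, train = TRUE)
      p <- softmaxRows(r$out)
      loss <- loss - sum(log(p[, sm$s]))
      mlpBackward(store, grads, nets$clf$joint, p - onehot, r$caches)
      for (m in names(sm$cms)) {
        rm_ <- mlpForward(store, nets$clf[[m]], sm$cms[[m]], train = TRUE)
        pm <- softmaxRows(rm_$out)
        loss <- loss - sum(log(pm[, sm$s]))
        mlpBackward(store, grads, nets$clf[[m]], pm - onehot, rm_$caches)
      }
    }
    if (k == 1L) lossFirst <- loss / nTot
    adamwStep(store, grads, adamEta, "eta.", lr, scale = 1 / nTot)
  }
  lossFirst
}

#' Train a mosaic model with the alternating adversarial schedule
#'
#' Runs the training loop: per minibatch, `K` AdamW steps update the batch
#' classifiers on detached latent samples (encoders frozen), then one AdamW
#' step updates encoders and decoders on the total objective (negative ELBO
#' plus modality-alignment and information-bottleneck losses) with the
#' classifiers frozen. Minibatches mix cells from all batches; cells with
#' different modality sets coexist via per-batch expert routing. Training
#' stops early when the validation loss has not improved for `patience`
#' epochs.
#'
#' @param dataset a [MosaicDataset].
#' @param architecture a [mosaicArchitecture()].
#' @param weights a [lossWeights()].
#' @param model optionally a pre-initialized [MosaicModel] (used by the
#'   transfer-learning heads); otherwise a fresh model is initialized.
#' @param epochs maximum number of epochs (default 2000).
#' @param lr AdamW learning rate (default 1e-4).
#' @param minibatch minibatch size (default 256).
#' @param valRatio fraction of cells held out for validation (default 0.05,
#'   batch-stratified).
#' @param patience early-stopping patience in epochs (default 10, min-delta
#'   0 on the total validation loss).
#' @param seed integer seed controlling initialization, the split,
#'   minibatch order, dropout and latent sampling; runs are reproducible.
#' @param updateFilter parameter-id prefixes updated in the joint step
#'   (default all of `theta.` and `phi.`; transfer learning restricts this).
#' @param cellWeights optional per-cell sampling weights; when given, each
#'   epoch draws cells with replacement proportionally to them (used for
#'   reference replay in reciprocal mapping).
#' @param verbose print per-epoch losses.
#' @return a trained [MosaicModel] with the per-epoch `trainingLog()`.
#' @export
trainMosaic <- function(dataset, architecture = mosaicArchitecture(),
                        weights = lossWeights(), model = NULL,
                        epochs = 2000L, lr = 1e-4, minibatch = 256L,
                        valRatio = 0.05, patience = 10L, seed = 1L,
                        updateFilter = c("theta.", "phi."),
                        cellWeights = NULL, verbose = FALSE) {
  stopifnot(is(dataset, "MosaicDataset"))
  if (is.null(model))
    model <- initMosaicModel(dataset, architecture, weights, seed = seed)
  arch <- model@architecture
  weights <- model@lossWeights
  B <- model@nBatches
  gdat <- prepTrainData(dataset, arch)
  store <- storeEnv(model)
  nets <- model@params$nets
  run <- localRNG(seed + 1L)
  sp <- splitTrainVal(dataset, 1 - valRatio, seed + 2L)
  batchOf <- cellBatch(dataset)
  localIdx <- sequence(vapply(dataset@batches, function(b)
    length(b@cellIds), integer(1)))
  adamEta <- newAdamState(); adamMain <- newAdamState()
  log <- list()
  best <- Inf; wait <- 0L
  nClf <- 0L; nJoint <- 0L
  run(function() {
    for (ep in seq_len(epochs)) {
      ord <- if (is.null(cellWeights)) sample(sp$train) else
        sample(sp$train, replace = TRUE, prob = cellWeights[sp$train])
      nIter <- ceiling(length(ord) / minibatch)
      epLoss <- c(total = 0, elbo = 0, align = 0, ib = 0)
      for (it in seq_len(nIter)) {
        idx <- ord[((it - 1) * minibatch + 1):min(it * minibatch,
                                                  length(ord))]
        rowsByBatch <- lapply(seq_len(B), function(b)
          localIdx[idx[batchOf[idx] == b]])
        nTot <- length(idx)
        # phase 1: K classifier updates, encoders frozen
        classifierPhase(store, nets, gdat, rowsByBatch, weights, arch, B,
                        adamEta, lr, nTot)
        nClf <<- nClf + weights$K
        # phase 2: one joint update, classifiers frozen
        grads <- newGradEnv()
        for (b in seq_len(B)) {
          if (!length(rowsByBatch[[b]])) next
          r <- groupPass(store, nets, gdat$groups[[b]], rowsByBatch[[b]],
                         weights, arch, B, grads = grads, train = TRUE,
                         scaleRates = arch$scaleRates)
          epLoss <- epLoss + r$losses
        }
        if (!all(is.finite(epLoss)))
          stop(sprintf("training diverged (non-finite loss) at epoch %d, iteration %d",
                       ep, it))
        adamwStep(store, grads, adamMain, updateFilter, lr,
                  scale = 1 / nTot)
        nJoint <<- nJoint + 1L
      }
      epLoss <- epLoss / length(sp$train)
      # validation loss, eval mode (no dropout), sampled expectations
      valLoss <- NA_real_
      if (length(sp$val)) {
        vRows <- lapply(seq_len(B), function(b)
          localIdx[sp$val[batchOf[sp$val] == b]])
        v <- 0
        for (b in seq_len(B)) {
          if (!length(vRows[[b]])) next
          v <- v + groupPass(store, nets, gdat$groups[[b]], vRows[[b]],
                             weights, arch, B, grads = NULL, train = FALSE,
                             scaleRates = arch$scaleRates)$losses[["total"]]
        }
        valLoss <- v / length(sp$val)
      }
      log[[ep]] <<- data.frame(epoch = ep, train_total = epLoss[["total"]],
                               train_elbo = epLoss[["elbo"]],
                               train_align = epLoss[["align"]],
                               train_ib = epLoss[["ib"]],
                               val_total = valLoss,
                               clf_updates = nClf, joint_updates = nJoint)
      if (verbose)
        message(sprintf("epoch %d: train %.3f val %.3f", ep,
                        epLoss[["total"]], valLoss))
      crit <- if (is.na(valLoss)) epLoss[["total"]] else valLoss
      if (crit < best) {
        best <<- crit
        wait <<- 0L
      } else {
        wait <<- wait + 1L
        if (wait >= patience) break
      }
    }
  })
  model@params$store <- as.list(store)
  model@trainLog <- do.call(rbind, log)
  model@config <- utils::modifyList(model@config, list(
    lr = lr, minibatch = minibatch, epochs = epochs, patience = patience,
    seed = seed, libMedian = gdat$libMedian,
    libBatchMedian = gdat$libBatchMedian))
  model
}
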