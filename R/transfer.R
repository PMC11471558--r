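#' @include tasks.R
NULL

#' Plan for transfer learning onto a query dataset
#'
#' Describes which parameter groups are reinitialized (batch-ID encoder and
#' decoder, all batch classifiers — they are batch-count specific) versus
#' fine-tuned from the pretrained state (modality encoders and decoders),
#' and the reference-replay policy for reciprocal mapping.
#'
#' @param epochs fine-tuning epochs.
#' @param lr fine-tuning learning rate.
#' @param replayFraction fraction of each reciprocal-mapping minibatch drawn
#'   from the reference dataset (in `[0, 1)`); reference cells are sampled
#'   uniformly.
#' @param minibatch minibatch size.
#' @param patience early-stopping patience.
#' @return list of class `"transferPlan"`.
#' @export
transferPlan <- function(epochs = 50L, lr = 1e-4, replayFraction = 0.5,
                         minibatch = 256L, patience = 10L) {
  stopifnot(epochs >= 0, replayFraction >= 0, replayFraction < 1)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 replayFraction = replayFraction,
                 minibatch = as.integer(minibatch),
                 patience = as.integer(patience),
                 reinitGroups = c("phi.encBatch.", "theta.decBatch.",
                                  "eta."),
                 finetuneGroups = c("phi.enc.", "theta.dec.")),
            class = "transferPlan")
}

#' Project a dataset onto a model's feature spaces
#'
#' Harmonizes a query dataset with a pretrained model by feature-name
#' intersection per modality: query features absent from the model's unions
#' are dropped (with a warning), model features unmeasured by the query get
#' mask 0. Modalities unknown to the model are dropped likewise.
#'
#' @param model a [MosaicModel].
#' @param dataset the query [MosaicDataset].
#' @return a [MosaicDataset] on the model's feature spaces.
#' @export
harmonizeFeatures <- function(model, dataset) {
  keepMods <- intersect(modalities(dataset), modalities(model))
  if (!length(keepMods)) stop("no overlapping modalities with the model")
  anyOverlap <- FALSE
  droppedCount <- integer(0)
  recs <- list()
  for (b in dataset@batches) {
    mods <- intersect(b@modalities, keepMods)
    if (!length(mods))
      stop("batch ", b@batchId, " has no modalities known to the model")
    counts <- list(); masks <- list()
    for (m in mods) {
      fs <- model@featureSpaces[[m]]
      qNames <- dataset@featureSpaces[[m]]@names
      obs <- which(b@masks[[m]] == 1L)
      common <- intersect(qNames[obs], fs@names)
      dropped <- setdiff(qNames[obs], fs@names)
      if (length(dropped))
        droppedCount[m] <- max(droppedCount[m], length(dropped),
                               na.rm = TRUE)
      if (length(common)) anyOverlap <- TRUE
      raw <- b@counts[[m]][, match(common, qNames), drop = FALSE]
      p <- padCounts(raw, common, fs)
      counts[[m]] <- p$counts
      masks[[m]] <- p$mask
    }
    recs[[b@batchId]] <- new("BatchRecord", batchId = b@batchId,
                             modalities = mods, counts = counts,
                             masks = masks, cellIds = b@cellIds)
  }
  if (!anyOverlap) stop("no overlapping features in any modality")
  for (m in names(droppedCount))
    warning(droppedCount[[m]], " ", m,
            " query features absent from the model were dropped")
  new("MosaicDataset", featureSpaces = model@featureSpaces[keepMods],
      batches = recs)
}

# Copy parameter groups whose id starts with any prefix from one store list
# to another (shapes must match).
copyParams <- function(fromStore, toStore, prefixes) {
  for (id in names(fromStore))
    if (any(startsWith(id, prefixes))) toStore[[id]] <- fromStore[[id]]
  toStore
}

#' Transfer a pretrained model to a query dataset
#'
#' Reinitializes the batch-ID encoder/decoder and the batch classifiers for
#' the query's batch count, initializes the modality encoders/decoders from
#' the pretrained state, and fine-tunes on the query with the standard
#' alternating schedule. The pretrained model is never mutated.
#'
#' @param model the pretrained [MosaicModel].
#' @param query the query [MosaicDataset] (harmonized internally).
#' @param plan a [transferPlan()]; `epochs = 0` returns the re-initialized
#'   model without fine-tuning.
#' @param seed integer seed.
#' @return a fine-tuned [MosaicModel] for the query.
#' @export
modelTransfer <- function(model, query, plan = transferPlan(), seed = 1L) {
  stopifnot(is(model, "MosaicModel"), inherits(plan, "transferPlan"))
  query <- harmonizeFeatures(model, query)
  arch <- do.call(mosaicArchitecture, model@architecture)
  w <- do.call(lossWeights, model@lossWeights)
  fresh <- initMosaicModel(query, arch, w, seed = seed)
  fresh@params$store <- copyParams(model@params$store, fresh@params$store,
                                   plan$finetuneGroups)
  if (plan$epochs == 0L) return(fresh)
  trainMosaic(query, model = fresh, epochs = plan$epochs, lr = plan$lr,
              minibatch = plan$minibatch, patience = plan$patience,
              seed = seed)
}

#' Reciprocal reference mapping
#'
#' Fine-tunes the pretrained model on reference and query jointly: the
#' combined dataset keeps the reference batches (whose batch-ID modules are
#' retained from the pretrained model) and appends the query batches with
#' freshly initialized batch-ID rows; minibatches mix query cells with a
#' `replayFraction` share of reference cells so the model neither forgets
#' the reference nor fails to generalize to the query. Both datasets are
#' then embedded with the single resulting model.
#'
#' @param model the [MosaicModel] pretrained on `reference`.
#' @param reference the reference [MosaicDataset].
#' @param query the query [MosaicDataset].
#' @param plan a [transferPlan()].
#' @param seed integer seed.
#' @return list with `model` (fine-tuned) and `latent` (joint [LatentTable]
#'   over reference cells then query cells; query batch IDs are offset by
#'   the number of reference batches).
#' @export
reciprocalMap <- function(model, reference, query, plan = transferPlan(),
                          seed = 1L) {
  stopifnot(is(model, "MosaicModel"))
  reference <- harmonizeFeatures(model, reference)
  query <- harmonizeFeatures(model, query)
  bRef <- nBatches(reference)
  combined <- concatBatches(reference, query)
  arch <- do.call(mosaicArchitecture, model@architecture)
  w <- do.call(lossWeights, model@lossWeights)
  fresh <- initMosaicModel(combined, arch, w, seed = seed)
  fresh@params$store <- copyParams(model@params$store, fresh@params$store,
                                   c("phi.enc.", "theta.dec."))
  # retain pretrained batch-ID rows/columns for the reference batches
  fresh@params$store <- graftBatchParams(model@params$store,
                                         fresh@params$store, bRef)
  nRef <- nCells(reference); nQuery <- nCells(query)
  wts <- c(rep(plan$replayFraction / max(1L, nRef), nRef),
           rep((1 - plan$replayFraction) / nQuery, nQuery))
  if (plan$replayFraction == 0) wts[seq_len(nRef)] <- 1e-12
  tuned <- if (plan$epochs > 0L)
    trainMosaic(combined, model = fresh, epochs = plan$epochs,
                lr = plan$lr, minibatch = plan$minibatch,
                patience = plan$patience, seed = seed, cellWeights = wts)
  else fresh
  list(model = tuned, latent = inferLatent(tuned, combined))
}

# Concatenate two datasets on identical feature spaces; query batch IDs are
# shifted past the reference's.
concatBatches <- function(reference, query) {
  bRef <- nBatches(reference)
  recs <- reference@batches
  for (b in query@batches)
    recs[[bRef + b@batchId]] <- new("BatchRecord",
                                    batchId = bRef + b@batchId,
                                    modalities = b@modalities,
                                    counts = b@counts, masks = b@masks,
                                    cellIds = paste0("q_", b@cellIds))
  mods <- unique(unlist(lapply(recs, function(r) r@modalities)))
  spaces <- reference@featureSpaces
  for (m in setdiff(mods, names(spaces)))
    spaces[[m]] <- query@featureSpaces[[m]]
  new("MosaicDataset", featureSpaces = spaces[intersect(MODALITIES, mods)],
      batches = recs)
}

# Keep pretrained batch-ID parameters for the first bRef batches of the
# combined model: batch one-hot input rows of the encoder, output columns of
# the batch decoder and classifiers.
graftBatchParams <- function(oldStore, newStore, bRef) {
  enc <- "phi.encBatch.hidden"
  newStore[[enc]]$W[seq_len(bRef), ] <- oldStore[[enc]]$W
  for (id in names(newStore)) {
    if (id == "theta.decBatch.out" ||
        (startsWith(id, "eta.clf.") && endsWith(id, ".out"))) {
      newStore[[id]]$W[, seq_len(bRef)] <- oldStore[[id]]$W
      newStore[[id]]$b[seq_len(bRef)] <- oldStore[[id]]$b
    }
  }
  newStore
}

# Exact Euclidean k-nearest neighbours of each row of `query` among the
# rows of `ref`; returns index matrix nq x k.
knnIndex <- function(query, ref, k) {
  q2 <- rowSums(query^2)
  r2 <- rowSums(ref^2)
  D2 <- outer(q2, r2, "+") - 2 * tcrossprod(query, ref)
  idx <- apply(D2, 1, function(d) order(d)[seq_len(k)])
  if (k == 1L) matrix(idx, ncol = 1L) else t(idx)
}

# Two-component 1-D Gaussian mixture via EM with deterministic
# initialization at the sample min/max and tolerance on the log-likelihood.
gmm2 <- function(x, tol = 1e-4, maxit = 500L) {
  mu <- c(min(x), max(x))
  if (diff(mu) < 1e-12)
    return(list(means = mu, assign = rep(1L, length(x))))
  s2 <- rep(max(stats::var(x), 1e-6), 2)
  pr <- c(0.5, 0.5)
  ll <- -Inf
  for (it in seq_len(maxit)) {
    d1 <- pr[1] * stats::dnorm(x, mu[1], sqrt(s2[1]))
    d2 <- pr[2] * stats::dnorm(x, mu[2], sqrt(s2[2]))
    tot <- d1 + d2 + 1e-300
    g <- d1 / tot
    newll <- sum(log(tot))
    mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
    s2 <- c(sum(g * (x - mu[1])^2) / sum(g),
            sum((1 - g) * (x - mu[2])^2) / sum(1 - g))
    s2 <- pmax(s2, 1e-8)
    pr <- c(mean(g), 1 - mean(g))
    if (abs(newll - ll) < tol) break
    ll <- newll
  }
  list(means = mu, assign = ifelse(g >= 0.5, 1L, 2L))
}

#' Transfer labels from reference to query embeddings
#'
#' Same-tissue mode fits a k-nearest-neighbour classifier (`k = 100`,
#' uniform weights) on the reference embedding and predicts query labels.
#' Cross-tissue mode, where the query may contain novel cell types, labels
#' all query cells `"query"`, fits the kNN classifier on reference and
#' query jointly, and computes each query cell's predicted probability of
#' the `"query"` class; a two-component 1-D Gaussian mixture (tolerance
#' 1e-4, means initialized at the probability min/max) splits those
#' probabilities, the higher-mean component becomes `"unknown"`, and the
#' rest receive the most probable non-query reference label.
#'
#' @param refEmbedding,queryEmbedding matrices with matching column count.
#' @param refLabels character/factor labels for the reference rows.
#' @param mode `"same_tissue"` or `"cross_tissue"`.
#' @param k neighbour count (shrunk with a warning if the training set is
#'   smaller).
#' @return list of class `"mosaicAnnotation"` with `labels` (per query
#'   cell), `queryProb` (cross-tissue only) and `gmmMeans`.
#' @export
transferLabels <- function(refEmbedding, refLabels, queryEmbedding,
                           mode = c("same_tissue", "cross_tissue"),
                           k = 100L) {
  mode <- match.arg(mode)
  refEmbedding <- as.matrix(refEmbedding)
  queryEmbedding <- as.matrix(queryEmbedding)
  stopifnot(ncol(refEmbedding) == ncol(queryEmbedding),
            nrow(refEmbedding) == length(refLabels))
  refLabels <- as.character(refLabels)
  if (any(table(refLabels) == 0)) stop("reference label with zero cells")
  if (mode == "same_tissue") {
    if (k > nrow(refEmbedding)) {
      warning("k reduced to the reference size ", nrow(refEmbedding))
      k <- nrow(refEmbedding)
    }
    nn <- knnIndex(queryEmbedding, refEmbedding, k)
    labels <- apply(nn, 1, function(i) {
      tab <- table(refLabels[i])
      names(tab)[which.max(tab)]
    })
    return(structure(list(labels = labels, queryProb = NULL,
                          gmmMeans = NULL), class = "mosaicAnnotation"))
  }
  # cross-tissue: train on reference + query with the query labeled "query"
  allEmb <- rbind(refEmbedding, queryEmbedding)
  allLab <- c(refLabels, rep("query", nrow(queryEmbedding)))
  if (k > nrow(allEmb) - 1L) {
    warning("k reduced to ", nrow(allEmb) - 1L)
    k <- nrow(allEmb) - 1L
  }
  q2 <- rowSums(queryEmbedding^2)
  a2 <- rowSums(allEmb^2)
  D2 <- outer(q2, a2, "+") - 2 * tcrossprod(queryEmbedding, allEmb)
  # a query cell is its own nearest neighbour in the joint training set
  D2[cbind(seq_len(nrow(queryEmbedding)),
           nrow(refEmbedding) + seq_len(nrow(queryEmbedding)))] <- Inf
  classes <- sort(unique(allLab))
  nq <- nrow(queryEmbedding)
  prob <- matrix(0, nq, length(classes), dimnames = list(NULL, classes))
  for (i in seq_len(nq)) {
    nb <- allLab[order(D2[i, ])[seq_len(k)]]
    tab <- table(factor(nb, levels = classes))
    prob[i, ] <- as.numeric(tab) / k
  }
  qp <- prob[, "query"]
  gm <- gmm2(qp, tol = 1e-4)
  hi <- which.max(gm$means)
  labels <- character(nq)
  nonQuery <- setdiff(classes, "query")
  for (i in seq_len(nq)) {
    labels[i] <- if (gm$assign[i] == hi && diff(range(gm$means)) > 1e-12)
      "unknown"
    else nonQuery[which.max(prob[i, nonQuery])]
  }
  structure(list(labels = labels, queryProb = qp, gmmMeans = gm$means),
            class = "mosaicAnnotation")
}
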