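#' @include AllClasses.R featureSpace.R
NULL

#' Simulation configuration with desk-scale defaults
#'
#' Returns the configuration driving [simulateMosaic()]. The defaults define
#' a trimodal study of 3 batches x 500 cells with 4 equally frequent cell
#' types, modest feature counts, clearly separated type centroids and
#' batch-dominated technical noise; they are the package's standard study
#' conditions for tests and examples (rationale in the methods vignette).
#'
#' @param nCellsPerBatch integer vector, cells per batch.
#' @param nTypes number of cell types.
#' @param typeProportions simplex vector of type frequencies.
#' @param nFeatures named integer vector of union sizes per modality.
#' @param dC,dU dimensions of the true biological state / technical noise.
#' @param batchShiftScale magnitude of the per-batch technical offsets on
#'   `u`; within-batch noise std is fixed at `0.1 * batchShiftScale` so `u`
#'   is batch-dominated.
#' @param typeSeparation expected Euclidean distance between type centroids
#'   in `c` space (within-type std is 0.5).
#' @param libraryScale per-modality mean-count scale for RNA (sparse, about
#'   1 count/feature) and ADT (dense, about 20 counts/feature).
#' @param mosaicPattern optional list, per batch, of modalities to retain;
#'   `NULL` keeps the full trimodal design.
#' @param featureDropout per-batch fraction of union features left
#'   unmeasured (applied per modality, seeded).
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return a list of class `"mosaicSimConfig"`.
#' @export
mosaicSimConfig <- function(nCellsPerBatch = c(500L, 500L, 500L),
                            nTypes = 4L,
                            typeProportions = rep(1 / nTypes, nTypes),
                            nFeatures = c(ATAC = 200L, RNA = 120L, ADT = 40L),
                            dC = 8L, dU = 2L,
                            batchShiftScale = 1,
                            typeSeparation = 3,
                            libraryScale = c(RNA = 1, ADT = 20),
                            mosaicPattern = NULL,
                            featureDropout = 0,
                            seed = 1L) {
  cfg <- list(nCellsPerBatch = as.integer(nCellsPerBatch),
              nTypes = as.integer(nTypes),
              typeProportions = typeProportions,
              nFeatures = nFeatures, dC = as.integer(dC),
              dU = as.integer(dU), batchShiftScale = batchShiftScale,
              typeSeparation = typeSeparation, libraryScale = libraryScale,
              mosaicPattern = mosaicPattern, featureDropout = featureDropout,
              seed = as.integer(seed))
  stopifnot(abs(sum(cfg$typeProportions) - 1) < 1e-8,
            length(cfg$typeProportions) == cfg$nTypes,
            cfg$dC >= 2L, cfg$dU >= 1L,
            cfg$batchShiftScale >= 0, cfg$typeSeparation > 0)
  class(cfg) <- "mosaicSimConfig"
  cfg
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
sigmoidFn <- function(x) 1 / (1 + exp(-x))

#' Simulate a trimodal mosaic dataset with known ground truth
#'
#' Draws biological states from a Gaussian mixture over cell types, adds a
#' batch-dominated technical-noise coordinate, maps both through fixed
#' random linear decoders, and samples Bernoulli (ATAC) and Poisson
#' (RNA/ADT) counts. The linear ground-truth maps make recovery by the model
#' exactly scoreable. The optional mosaic pattern and feature dropout are
#' applied afterwards so the retained blocks are bit-identical to the full
#' design.
#'
#' @param config a [mosaicSimConfig()].
#' @return list with `dataset` (a [MosaicDataset]) and `truth`
#'   (a [MosaicGroundTruth]); rows follow dataset cell order.
#' @export
simulateMosaic <- function(config = mosaicSimConfig()) {
  stopifnot(inherits(config, "mosaicSimConfig"))
  run <- localRNG(config$seed)
  run(function() {
    B <- length(config$nCellsPerBatch)
    N <- sum(config$nCellsPerBatch)
    K <- config$nTypes
    dC <- config$dC; dU <- config$dU; dZ <- dC + dU
    # type centroids: iid normal coordinates scaled so the expected pairwise
    # distance equals typeSeparation
    centroids <- matrix(stats::rnorm(K * dC,
                                     sd = config$typeSeparation / sqrt(2 * dC)),
                        K, dC)
    batchOffset <- matrix(stats::rnorm(B * dU, sd = config$batchShiftScale),
                          B, dU)
    batch <- rep.int(seq_len(B), config$nCellsPerBatch)
    type <- sample(K, N, replace = TRUE, prob = config$typeProportions)
    if (length(unique(type)) < K)
      stop("degenerate configuration: a cell type received zero cells")
    cTrue <- centroids[type, , drop = FALSE] +
      matrix(stats::rnorm(N * dC, sd = 0.5), N, dC)
    uTrue <- batchOffset[batch, , drop = FALSE] +
      matrix(stats::rnorm(N * dU, sd = 0.1 * config$batchShiftScale), N, dU)
    z <- cbind(cTrue, uTrue)
    featNames <- list(
      ATAC = syntheticPeakNames(config$nFeatures[["ATAC"]]),
      RNA = sprintf("gene%04d", seq_len(config$nFeatures[["RNA"]])),
      ADT = sprintf("adt%03d", seq_len(config$nFeatures[["ADT"]])))
    W <- list(); bias <- list(); lambda <- list(); X <- list()
    for (m in MODALITIES) {
      D <- config$nFeatures[[m]]
      W[[m]] <- matrix(stats::rnorm(dZ * D), dZ, D) / sqrt(dZ)
      lin <- z %*% W[[m]]
      if (m == "ATAC") {
        bias[[m]] <- rep(-1, D)
        lambda[[m]] <- sigmoidFn(sweep(lin, 2, bias[[m]], "+"))
        X[[m]] <- matrix(stats::rbinom(N * D, 1L, lambda[[m]]), N, D)
      } else {
        bias[[m]] <- rep(0.2, D)
        lambda[[m]] <- softplus(sweep(lin, 2, bias[[m]], "+")) *
          config$libraryScale[[m]]
        X[[m]] <- matrix(stats::rpois(N * D, lambda[[m]]), N, D)
      }
      colnames(lambda[[m]]) <- featNames[[m]]
      colnames(X[[m]]) <- featNames[[m]]
    }
    dropout <- config$featureDropout
    batches <- lapply(seq_len(B), function(b) {
      rows <- which(batch == b)
      counts <- list(); feats <- list()
      for (m in MODALITIES) {
        D <- config$nFeatures[[m]]
        keep <- seq_len(D)
        if (dropout > 0) {
          nKeep <- max(2L, round((1 - dropout) * D))
          keep <- sort(sample(D, nKeep))
        }
        counts[[m]] <- X[[m]][rows, keep, drop = FALSE]
        feats[[m]] <- featNames[[m]][keep]
      }
      list(counts = counts, features = feats,
           cellIds = sprintf("cell%05d", rows))
    })
    dataset <- makeMosaicDataset(batches)
    if (!is.null(config$mosaicPattern))
      dataset <- applyMosaicPattern(dataset, config$mosaicPattern)
    truth <- new("MosaicGroundTruth", cTrue = cTrue, uTrue = uTrue,
                 typeLabels = as.integer(type), lambdaTrue = lambda,
                 decoderWeights = list(W = W, bias = bias,
                                       batchOffset = batchOffset,
                                       centroids = centroids))
    list(dataset = dataset, truth = truth)
  })
}

# ATAC peak names over four pseudo-chromosomes, parseable as chrom:start-end
syntheticPeakNames <- function(D) {
  chrom <- sprintf("chr%d", as.integer(cut(seq_len(D), 4, labels = FALSE)))
  start <- 1000L + 500L * (seq_len(D) - 1L)
  sprintf("%s:%d-%d", chrom, start, start + 400L)
}

#' Remove modality blocks from a mosaic dataset
#'
#' Produces a mosaic design by dropping whole (batch, modality) blocks from
#' a dataset. Untouched blocks are bit-identical; a modality removed from
#' every batch also loses its feature space.
#'
#' @param dataset a [MosaicDataset].
#' @param pattern list, one element per batch (by position or named by batch
#'   ID), each a character vector of modalities to retain.
#' @return the reduced [MosaicDataset].
#' @export
applyMosaicPattern <- function(dataset, pattern) {
  stopifnot(is(dataset, "MosaicDataset"))
  B <- nBatches(dataset)
  ids <- if (!is.null(names(pattern))) as.integer(names(pattern))
         else seq_along(pattern)
  if (any(is.na(ids)) || any(ids < 1L) || any(ids > B))
    stop("pattern references unknown batch (dataset has ", B, " batches)")
  recs <- dataset@batches
  for (j in seq_along(pattern)) {
    b <- ids[j]
    keep <- pattern[[j]]
    if (!all(keep %in% MODALITIES))
      stop("unknown modality in pattern: ",
           paste(setdiff(keep, MODALITIES), collapse = ", "))
    keep <- intersect(recs[[b]]@modalities, keep)
    if (!length(keep))
      stop("pattern leaves batch ", b, " with no modalities")
    r <- recs[[b]]
    recs[[b]] <- new("BatchRecord", batchId = r@batchId, modalities = keep,
                     counts = r@counts[keep], masks = r@masks[keep],
                     cellIds = r@cellIds)
  }
  mods <- unique(unlist(lapply(recs, function(r) r@modalities)))
  new("MosaicDataset", featureSpaces = dataset@featureSpaces[
        intersect(MODALITIES, mods)], batches = recs)
}
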