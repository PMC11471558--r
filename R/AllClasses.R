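#' @import methods
#' @importFrom Matrix Matrix sparseMatrix readMM writeMM colSums rowSums t
NULL

#' Modalities handled by scMosaic
#'
#' Ordered character vector of the three supported molecular layers:
#' chromatin accessibility (`"ATAC"`), transcriptome (`"RNA"`) and
#' antibody-derived tags (`"ADT"`).
#'
#' @export
MODALITIES <- c("ATAC", "RNA", "ADT")

#' FeatureSpace: the feature union of one modality
#'
#' Holds the ordered union of feature identifiers observed across all batches
#' for one modality, plus (for ATAC) an optional partition of the features
#' into contiguous chromosome blocks used to split the encoder input and
#' decoder reconstruction layers.
#'
#' @slot modality one of `"ATAC"`, `"RNA"`, `"ADT"`.
#' @slot names ordered character vector of unique feature identifiers.
#' @slot blocks integer vector; either length 0 (no block structure) or one
#'   block index per feature, forming contiguous groups.
#' @export
setClass("FeatureSpace",
  representation(modality = "character", names = "character",
                 blocks = "integer"),
  prototype(blocks = integer(0)))

setValidity("FeatureSpace", function(object) {
  msg <- character(0)
  if (length(object@modality) != 1L || !object@modality %in% MODALITIES)
    msg <- c(msg, "modality must be one of ATAC, RNA, ADT")
  if (anyDuplicated(object@names))
    msg <- c(msg, paste("duplicate feature names:",
      paste(utils::head(unique(object@names[duplicated(object@names)]), 5),
            collapse = ", ")))
  if (length(object@blocks) &&
      length(object@blocks) != length(object@names))
    msg <- c(msg, "blocks must have one entry per feature")
  if (length(object@blocks) && any(diff(object@blocks) < 0))
    msg <- c(msg, "blocks must form contiguous non-decreasing groups")
  if (length(msg)) msg else TRUE
})

#' BatchRecord: one batch of a mosaic dataset
#'
#' Per-batch container of padded count matrices (cells x union features) for
#' the measured modalities, the binary feature masks marking which union
#' features this batch actually measured, and the cell barcodes.
#'
#' @slot batchId integer batch identifier in `1..B`.
#' @slot modalities character subset of [MODALITIES] measured in this batch.
#' @slot counts named list of `dgCMatrix`, one per measured modality, each
#'   `cells x D^m` padded to the union (missing features all-zero).
#' @slot masks named list of 0/1 integer vectors of length `D^m`.
#' @slot cellIds character barcodes, shared ordering across modalities.
#' @export
setClass("BatchRecord",
  representation(batchId = "integer", modalities = "character",
                 counts = "list", masks = "list", cellIds = "character"))

setValidity("BatchRecord", function(object) {
  msg <- character(0)
  if (!all(object@modalities %in% MODALITIES))
    msg <- c(msg, "unknown modality in batch")
  if (!setequal(names(object@counts), object@modalities) ||
      !setequal(names(object@masks), object@modalities))
    msg <- c(msg, "counts/masks must be named by the measured modalities")
  for (m in object@modalities) {
    cm <- object@counts[[m]]
    mk <- object@masks[[m]]
    if (nrow(cm) != length(object@cellIds))
      msg <- c(msg, sprintf("%s: row count does not match cellIds", m))
    if (ncol(cm) != length(mk))
      msg <- c(msg, sprintf("%s: mask length does not match columns", m))
    if (!all(mk %in% c(0L, 1L)))
      msg <- c(msg, sprintf("%s: mask must be binary", m))
    x <- cm@x
    if (length(x) && (any(x < 0) || any(x != round(x))))
      msg <- c(msg, sprintf("%s: counts must be non-negative integers", m))
    if (m == "ATAC" && length(x) && any(x > 1))
      msg <- c(msg, "ATAC counts must be binarized (0/1)")
    if (any(mk == 0L) && length(x)) {
      bad <- which(mk == 0L & Matrix::colSums(cm != 0) > 0)
      if (length(bad))
        msg <- c(msg, sprintf(
          "%s: masked-out columns carry nonzero counts (e.g. column %d)",
          m, bad[1]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' MosaicDataset: a mosaic multimodal single-cell dataset
#'
#' The central data container: one [FeatureSpace] per modality present
#' anywhere, and one [BatchRecord] per batch. Batches may measure different
#' modality subsets (mosaic layout) and different feature subsets of each
#' union (recorded in the masks).
#'
#' @slot featureSpaces named list of [FeatureSpace], one per modality.
#' @slot batches list of [BatchRecord] ordered by `batchId` `1..B`.
#' @export
setClass("MosaicDataset",
  representation(featureSpaces = "list", batches = "list"))

setValidity("MosaicDataset", function(object) {
  msg <- character(0)
  ids <- vapply(object@batches, function(b) b@batchId, integer(1))
  if (!identical(ids, seq_along(object@batches)))
    msg <- c(msg, "batch IDs must be 1..B without gaps, in order")
  for (b in object@batches) {
    for (m in b@modalities) {
      fs <- object@featureSpaces[[m]]
      if (is.null(fs))
        msg <- c(msg, sprintf("batch %d uses modality %s with no FeatureSpace",
                              b@batchId, m))
      else if (ncol(b@counts[[m]]) != length(fs@names))
        msg <- c(msg, sprintf(
          "batch %d %s: %d columns but union has %d features",
          b@batchId, m, ncol(b@counts[[m]]), length(fs@names)))
    }
  }
  mods <- unique(unlist(lapply(object@batches, function(b) b@modalities)))
  if (!setequal(mods, names(object@featureSpaces)))
    msg <- c(msg, "featureSpaces must cover exactly the measured modalities")
  if (length(msg)) msg else TRUE
})

#' LatentTable: per-cell posterior means and variances
#'
#' Result of [inferLatent()]: the joint product-of-experts posterior over the
#' biological state `c` and technical noise `u` for every cell. `muC` is the
#' integration embedding.
#'
#' @slot muC,nuC N x d_c posterior mean / variance of the biological state.
#' @slot muU,nuU N x d_u posterior mean / variance of the technical noise.
#' @slot batchIds integer vector of length N.
#' @slot cellIds character vector of length N.
#' @export
setClass("LatentTable",
  representation(muC = "matrix", nuC = "matrix", muU = "matrix",
                 nuU = "matrix", batchIds = "integer", cellIds = "character"))

setValidity("LatentTable", function(object) {
  n <- nrow(object@muC)
  ok <- all(vapply(list(object@nuC, object@muU, object@nuU), nrow,
                   integer(1)) == n) &&
    length(object@batchIds) == n && length(object@cellIds) == n
  if (!ok) return("row counts of slots disagree")
  if (any(object@nuC <= 0) || any(object@nuU <= 0))
    return("posterior variances must be strictly positive")
  TRUE
})

#' MosaicModel: a trained (or initialized) scMosaic model
#'
#' Encoder, decoder and adversarial-classifier parameter groups together with
#' the architecture, loss weights and the feature spaces the model was built
#' on. Parameters live in a plain list; shared encoder-tail and decoder-head
#' layers are stored once and referenced by every modality.
#'
#' @slot params named list of parameter groups (`theta`, `phi`, `eta`).
#' @slot architecture list; see [mosaicArchitecture()].
#' @slot lossWeights list; see [lossWeights()].
#' @slot featureSpaces named list of [FeatureSpace].
#' @slot nBatches integer, output dimension of the batch decoder/classifiers.
#' @slot trainLog data.frame of per-epoch losses (empty before training).
#' @slot config list of training configuration actually used.
#' @export
setClass("MosaicModel",
  representation(params = "list", architecture = "list", lossWeights = "list",
                 featureSpaces = "list", nBatches = "integer",
                 trainLog = "data.frame", config = "list"))

#' MosaicGroundTruth: simulation ground truth
#'
#' Latent variables, type labels, expected values and the linear decoder maps
#' used by [simulateMosaic()], kept so that recovery can be scored exactly.
#'
#' @slot cTrue N x d_c biological-state coordinates.
#' @slot uTrue N x d_u technical-noise coordinates.
#' @slot typeLabels integer vector of length N.
#' @slot lambdaTrue named list of N x D^m expected-value matrices.
#' @slot decoderWeights named list of the random linear maps and intercepts.
#' @export
setClass("MosaicGroundTruth",
  representation(cTrue = "matrix", uTrue = "matrix", typeLabels = "integer",
                 lambdaTrue = "list", decoderWeights = "list"))

setMethod("show", "FeatureSpace", function(object) {
  cat(sprintf("FeatureSpace<%s>: %d features%s\n", object@modality,
              length(object@names),
              if (length(object@blocks))
                sprintf(", %d blocks", max(object@blocks)) else ""))
})

setMethod("show", "MosaicDataset", function(object) {
  cat(sprintf("MosaicDataset: %d cells, %d batches, modalities {%s}\n",
              nCells(object), nBatches(object),
              paste(names(object@featureSpaces), collapse = ", ")))
  for (b in object@batches)
    cat(sprintf("  batch %d: %d cells, {%s}\n", b@batchId,
                length(b@cellIds), paste(b@modalities, collapse = ", ")))
})

setMethod("show", "LatentTable", function(object) {
  cat(sprintf("LatentTable: %d cells, d_c = %d, d_u = %d\n",
              nrow(object@muC), ncol(object@muC), ncol(object@muU)))
})

setMethod("show", "MosaicModel", function(object) {
  a <- object@architecture
  cat(sprintf(
    "MosaicModel: d_c = %d, d_u = %d, %d batches, modalities {%s}%s\n",
    a$d_c, a$d_u, object@nBatches,
    paste(names(object@featureSpaces), collapse = ", "),
    if (nrow(object@trainLog)) sprintf(", trained %d epochs",
                                       max(object@trainLog$epoch)) else
      " (untrained)"))
})

setMethod("show", "MosaicGroundTruth", function(object) {
  cat(sprintf("MosaicGroundTruth: %d cells, %d types, d_c = %d, d_u = %d\n",
              nrow(object@cTrue), length(unique(object@typeLabels)),
              ncol(object@cTrue), ncol(object@uTrue)))
})
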