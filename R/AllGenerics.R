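#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setGeneric("nBatches", function(x) standardGeneric("nBatches"))
#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("modalities", function(x) standardGeneric("modalities"))
#' @rdname accessors
#' @export
setGeneric("featureNames", function(x, modality) {
  standardGeneric("featureNames")
})
#' @rdname accessors
#' @export
setGeneric("featureMask", function(x, batch, modality) {
  standardGeneric("featureMask")
})
#' @rdname accessors
#' @export
setGeneric("assayCounts", function(x, batch, modality) {
  standardGeneric("assayCounts")
})
#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setGeneric("cellBatch", function(x) standardGeneric("cellBatch"))
#' @rdname accessors
#' @export
setGeneric("cellEmbedding", function(x) standardGeneric("cellEmbedding"))
#' @rdname accessors
#' @export
setGeneric("technicalNoise", function(x) standardGeneric("technicalNoise"))

#' Accessors for scMosaic containers
#'
#' Small read-only accessors so user code never touches slots directly:
#' `nBatches()`/`nCells()`/`modalities()` describe a [MosaicDataset];
#' `featureNames()` returns one modality's feature union; `assayCounts()`
#' and `featureMask()` return one batch's padded count matrix and its 0/1
#' measurement mask; `cellIds()`/`cellBatch()` give per-cell barcodes and
#' batch IDs; `cellEmbedding()` and `technicalNoise()` return the posterior
#' means `mu_c` (the integration embedding) and `mu_u` of a [LatentTable].
#'
#' @param x a [MosaicDataset], [LatentTable] or [MosaicModel].
#' @param batch integer batch ID.
#' @param modality one of `"ATAC"`, `"RNA"`, `"ADT"`.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
setMethod("nBatches", "MosaicDataset", function(x) length(x@batches))
#' @rdname accessors
setMethod("nCells", "MosaicDataset", function(x) {
  sum(vapply(x@batches, function(b) length(b@cellIds), integer(1)))
})
#' @rdname accessors
setMethod("modalities", "MosaicDataset", function(x) {
  intersect(MODALITIES, names(x@featureSpaces))
})
#' @rdname accessors
setMethod("modalities", "BatchRecord", function(x) x@modalities)
#' @rdname accessors
setMethod("featureNames", "MosaicDataset", function(x, modality) {
  fs <- x@featureSpaces[[modality]]
  if (is.null(fs)) stop("no such modality: ", modality)
  fs@names
})
#' @rdname accessors
setMethod("featureNames", "FeatureSpace", function(x, modality) x@names)
#' @rdname accessors
setMethod("featureMask", "MosaicDataset", function(x, batch, modality) {
  b <- batchRecord(x, batch)
  mk <- b@masks[[modality]]
  if (is.null(mk)) stop("batch ", batch, " did not measure ", modality)
  mk
})
#' @rdname accessors
setMethod("assayCounts", "MosaicDataset", function(x, batch, modality) {
  b <- batchRecord(x, batch)
  cm <- b@counts[[modality]]
  if (is.null(cm)) stop("batch ", batch, " did not measure ", modality)
  cm
})
#' @rdname accessors
setMethod("cellIds", "MosaicDataset", function(x) {
  unlist(lapply(x@batches, function(b) b@cellIds), use.names = FALSE)
})
#' @rdname accessors
setMethod("cellBatch", "MosaicDataset", function(x) {
  unlist(lapply(x@batches, function(b)
    rep.int(b@batchId, length(b@cellIds))), use.names = FALSE)
})
#' @rdname accessors
setMethod("cellIds", "LatentTable", function(x) x@cellIds)
#' @rdname accessors
setMethod("cellBatch", "LatentTable", function(x) x@batchIds)
#' @rdname accessors
setMethod("nCells", "LatentTable", function(x) nrow(x@muC))
#' @rdname accessors
setMethod("cellEmbedding", "LatentTable", function(x) x@muC)
#' @rdname accessors
setMethod("technicalNoise", "LatentTable", function(x) x@muU)
#' @rdname accessors
setMethod("modalities", "MosaicModel", function(x) {
  intersect(MODALITIES, names(x@featureSpaces))
})
#' @rdname accessors
setMethod("nBatches", "MosaicModel", function(x) x@nBatches)

#' @rdname accessors
#' @export
batchRecord <- function(x, batch) {
  stopifnot(is(x, "MosaicDataset"))
  batch <- as.integer(batch)
  if (batch < 1L || batch > length(x@batches))
    stop("no such batch: ", batch)
  x@batches[[batch]]
}

#' @rdname accessors
#' @export
trainingLog <- function(x) {
  stopifnot(is(x, "MosaicModel"))
  x@trainLog
}
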