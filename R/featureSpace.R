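#' @include AllClasses.R
NULL

#' Build per-modality feature unions across batches
#'
#' The feature union of a modality is the ordered union of the per-batch
#' feature lists, with first-seen order: batches are scanned in ascending
#' batch-ID order and each batch contributes its features in their original
#' order. The result is deterministic and idempotent, which keeps padded
#' matrices and model checkpoints compatible across runs.
#'
#' @param perBatchFeatures named list (one element per modality); each
#'   element is a list of character vectors, one per batch that measured the
#'   modality, in ascending batch-ID order.
#' @param atacBlocks fallback number of equal contiguous blocks to assign to
#'   ATAC features whose names do not parse as genomic coordinates.
#' @return named list of [FeatureSpace], one per modality.
#' @examples
#' buildFeatureUnion(list(RNA = list(c("g1", "g2"), c("g2", "g3"))))
#' @export
buildFeatureUnion <- function(perBatchFeatures, atacBlocks = 4L) {
  out <- list()
  for (m in intersect(MODALITIES, names(perBatchFeatures))) {
    lists <- perBatchFeatures[[m]]
    lists <- lists[!vapply(lists, is.null, logical(1))]
    if (!length(lists)) next
    for (i in seq_along(lists)) {
      dup <- lists[[i]][duplicated(lists[[i]])]
      if (length(dup))
        stop(sprintf("duplicate %s feature names within one batch: %s",
                     m, paste(utils::head(unique(dup), 5), collapse = ", ")))
    }
    nm <- unique(unlist(lists, use.names = FALSE))
    blocks <- if (m == "ATAC") atacChromBlocks(nm, atacBlocks) else integer(0)
    if (length(blocks)) {
      ord <- order(blocks)      # keep blocks contiguous, stable within block
      nm <- nm[ord]
      blocks <- blocks[ord]
    }
    out[[m]] <- new("FeatureSpace", modality = m, names = nm, blocks = blocks)
  }
  if (!length(out)) stop("no non-empty feature lists supplied")
  out
}

# Partition ATAC feature names into chromosome blocks. Names parsing as
# "chrom:start-end" or "chrom-start-end" are grouped by chromosome; otherwise
# all features fall back to `fallbackBlocks` equal contiguous blocks.
atacChromBlocks <- function(nm, fallbackBlocks = 4L) {
  chrom <- sub("^(.+?)[:-][0-9]+-[0-9]+$", "\\1", nm)
  parsed <- grepl("^.+?[:-][0-9]+-[0-9]+$", nm)
  if (all(parsed)) {
    as.integer(factor(chrom, levels = unique(chrom)))
  } else {
    fallbackBlocks <- max(1L, min(as.integer(fallbackBlocks), length(nm)))
    as.integer(cut(seq_along(nm), fallbackBlocks, labels = FALSE))
  }
}

#' Zero-pad raw counts onto a feature union
#'
#' Places the observed columns of a raw count matrix at their positions in
#' the modality's feature union and zero-fills the missing features. The
#' companion mask is 1 exactly on the observed columns, so downstream losses
#' and likelihoods can be restricted to measured features.
#'
#' @param rawCounts cells x length(rawFeatures) matrix (dense or sparse).
#' @param rawFeatures character vector naming the columns of `rawCounts`.
#' @param space the modality's [FeatureSpace].
#' @return list with `counts` (a `cells x D^m` sparse matrix) and `mask`
#'   (0/1 integer vector of length `D^m`).
#' @export
padCounts <- function(rawCounts, rawFeatures, space) {
  stopifnot(is(space, "FeatureSpace"))
  if (ncol(rawCounts) != length(rawFeatures))
    stop("rawFeatures length does not match rawCounts columns")
  idx <- match(rawFeatures, space@names)
  if (anyNA(idx))
    stop("raw features not in the union: ",
         paste(utils::head(rawFeatures[is.na(idx)], 5), collapse = ", "))
  D <- length(space@names)
  padded <- Matrix(0, nrow(rawCounts), D, sparse = TRUE)
  padded[, idx] <- rawCounts
  padded <- as(as(padded, "CsparseMatrix"), "generalMatrix")
  mask <- integer(D)
  mask[idx] <- 1L
  list(counts = padded, mask = mask)
}

#' Drop padded features from a vector or matrix
#'
#' Inverse of the padding step: keeps the entries whose mask is 1, in order.
#' `maskFeatures(padCounts(x, f, space)$counts, mask)` recovers `x`.
#'
#' @param padded length-`D^m` vector or `cells x D^m` matrix.
#' @param mask 0/1 vector of length `D^m`.
#' @return the observed-only vector/matrix.
#' @export
maskFeatures <- function(padded, mask) {
  D <- if (is.null(dim(padded))) length(padded) else ncol(padded)
  if (length(mask) != D)
    stop("mask length ", length(mask), " does not match width ", D)
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  keep <- which(mask == 1)
  if (is.null(dim(padded))) padded[keep] else padded[, keep, drop = FALSE]
}

#' Binarize ATAC fragment counts
#'
#' Chromatin accessibility enters the model as Bernoulli observations: any
#' positive fragment count becomes 1.
#'
#' @param counts non-negative integer matrix (dense or sparse).
#' @return matrix of the same shape with entries in \{0, 1\}.
#' @export
binarizeAtac <- function(counts) {
  vals <- if (is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (length(vals) && any(vals < 0)) stop("negative entries in ATAC counts")
  if (is(counts, "sparseMatrix")) {
    counts@x <- as.numeric(counts@x > 0)
    Matrix::drop0(counts)
  } else {
    (counts > 0) + 0L
  }
}

#' Batch-stratified train/validation split
#'
#' Splits cell indices into training and validation sets at the given ratio,
#' stratified by batch so every batch contributes proportionally to the
#' validation loss. A batch with fewer than 2 cells is placed entirely in
#' the training set with a warning.
#'
#' @param dataset a [MosaicDataset].
#' @param ratio training fraction, in (0, 1); default 0.95.
#' @param seed integer seed making the split reproducible.
#' @return list with integer index vectors `train` and `val` (global cell
#'   indices in dataset order), disjoint and exhaustive.
#' @export
splitTrainVal <- function(dataset, ratio = 0.95, seed = 1L) {
  stopifnot(is(dataset, "MosaicDataset"), ratio > 0, ratio < 1)
  batch <- cellBatch(dataset)
  train <- integer(0); val <- integer(0)
  rng <- localRNG(seed)
  for (b in seq_len(nBatches(dataset))) {
    idx <- which(batch == b)
    if (length(idx) < 2L) {
      warning("batch ", b, " has < 2 cells; placed entirely in train")
      train <- c(train, idx)
      next
    }
    nTrain <- max(1L, round(ratio * length(idx)))
    if (nTrain >= length(idx)) nTrain <- length(idx) - 1L
    pick <- rng(function() sample(idx, nTrain))
    train <- c(train, sort(pick))
    val <- c(val, sort(setdiff(idx, pick)))
  }
  list(train = sort(train), val = sort(val))
}

# Run `f` under a private RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. Returned closure evaluates thunks.
localRNG <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  state <- get(".Random.seed", envir = globalenv())
  if (had) assign(".Random.seed", old, envir = globalenv())
  function(thunk) {
    hadNow <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    oldNow <- if (hadNow) get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      if (hadNow) assign(".Random.seed", oldNow, envir = globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
    thunk()
  }
}

#' Assemble a MosaicDataset from raw per-batch matrices
#'
#' Convenience constructor used by the simulator and the MTX reader: builds
#' the per-modality feature unions, pads every batch's matrices onto them,
#' binarizes ATAC, and namespaces cell barcodes by batch to avoid collisions.
#'
#' @param batches list (in batch-ID order); each element is a list with
#'   `counts` (named list of cells x features matrices per measured
#'   modality), `features` (named list of character vectors) and optionally
#'   `cellIds`.
#' @param atacBlocks fallback ATAC block count, see [buildFeatureUnion()].
#' @return a validated [MosaicDataset].
#' @export
makeMosaicDataset <- function(batches, atacBlocks = 4L) {
  perMod <- list()
  for (m in MODALITIES) {
    lists <- lapply(batches, function(b) b$features[[m]])
    if (any(!vapply(lists, is.null, logical(1)))) perMod[[m]] <- lists
  }
  spaces <- buildFeatureUnion(perMod, atacBlocks = atacBlocks)
  recs <- vector("list", length(batches))
  for (i in seq_along(batches)) {
    b <- batches[[i]]
    mods <- intersect(MODALITIES, names(b$counts))
    counts <- list(); masks <- list()
    ncell <- nrow(b$counts[[mods[1]]])
    ids <- if (!is.null(b$cellIds)) b$cellIds else
      sprintf("cell%04d", seq_len(ncell))
    ids <- paste0("b", i, "_", ids)
    for (m in mods) {
      cm <- b$counts[[m]]
      if (m == "ATAC") cm <- binarizeAtac(cm)
      p <- padCounts(cm, b$features[[m]], spaces[[m]])
      counts[[m]] <- p$counts
      masks[[m]] <- p$mask
    }
    recs[[i]] <- new("BatchRecord", batchId = i, modalities = mods,
                     counts = counts, masks = masks, cellIds = ids)
  }
  new("MosaicDataset", featureSpaces = spaces, batches = recs)
}
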