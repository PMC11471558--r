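#' @include AllClasses.R featureSpace.R
NULL

#' Write a MosaicDataset as MTX/TSV triplets plus a manifest
#'
#' Writes, per batch and measured modality, a CellRanger-style triplet: a
#' Matrix Market coordinate matrix holding the observed (unpadded) counts, a
#' features TSV and a barcodes TSV. The per-modality feature unions (and
#' ATAC block assignment) are stored alongside so that a read reproduces the
#' dataset bit-exactly, including feature order. A YAML manifest ties the
#' files together.
#'
#' @param dataset a [MosaicDataset].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeMosaic <- function(dataset, dir) {
  stopifnot(is(dataset, "MosaicDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(format = "scMosaic/1", unions = list(), batches = list())
  for (m in modalities(dataset)) {
    fs <- dataset@featureSpaces[[m]]
    f <- sprintf("union_%s.tsv", m)
    tab <- data.frame(name = fs@names,
                      block = if (length(fs@blocks)) fs@blocks else NA)
    utils::write.table(tab, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    manifest$unions[[m]] <- f
  }
  for (b in dataset@batches) {
    entry <- list(batch_id = b@batchId, modalities = list())
    bc <- sprintf("batch%d_barcodes.tsv", b@batchId)
    writeLines(b@cellIds, file.path(dir, bc))
    entry$barcodes <- bc
    for (m in b@modalities) {
      obs <- which(b@masks[[m]] == 1L)
      raw <- b@counts[[m]][, obs, drop = FALSE]
      mtx <- sprintf("batch%d_%s_matrix.mtx", b@batchId, m)
      ftsv <- sprintf("batch%d_%s_features.tsv", b@batchId, m)
      Matrix::writeMM(as(Matrix::t(raw), "CsparseMatrix"),
                      file.path(dir, mtx))  # features x cells, 10x layout
      writeLines(dataset@featureSpaces[[m]]@names[obs], file.path(dir, ftsv))
      entry$modalities[[m]] <- list(matrix = mtx, features = ftsv)
    }
    manifest$batches[[length(manifest$batches) + 1L]] <- entry
  }
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a MosaicDataset written by writeMosaic
#'
#' @param manifest path to the `manifest.yaml` produced by [writeMosaic()].
#' @return a validated [MosaicDataset]; `readMosaic(writeMosaic(d))`
#'   reproduces `d` exactly (counts, masks, orderings, barcodes).
#' @export
readMosaic <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  dir <- dirname(manifest)
  mf <- yaml::read_yaml(manifest)
  if (!identical(mf$format, "scMosaic/1"))
    stop("unrecognized manifest format in ", manifest)
  spaces <- list()
  for (m in names(mf$unions)) {
    f <- file.path(dir, mf$unions[[m]])
    if (!file.exists(f)) stop("missing union file: ", f)
    tab <- utils::read.table(f, sep = "\t", header = TRUE,
                             colClasses = c("character", "integer"))
    blocks <- if (all(is.na(tab$block))) integer(0) else as.integer(tab$block)
    spaces[[m]] <- new("FeatureSpace", modality = m, names = tab$name,
                       blocks = blocks)
  }
  recs <- list()
  for (entry in mf$batches) {
    bid <- as.integer(entry$batch_id)
    bcf <- file.path(dir, entry$barcodes)
    if (!file.exists(bcf)) stop("missing barcodes file: ", bcf)
    ids <- readLines(bcf)
    counts <- list(); masks <- list()
    for (m in names(entry$modalities)) {
      spec <- entry$modalities[[m]]
      mtxf <- file.path(dir, spec$matrix)
      ftf <- file.path(dir, spec$features)
      for (f in c(mtxf, ftf))
        if (!file.exists(f)) stop("missing file: ", f)
      raw <- tryCatch(Matrix::readMM(mtxf),
                      error = function(e)
                        stop("corrupt MTX file ", mtxf, ": ",
                             conditionMessage(e), call. = FALSE))
      # pattern/logical MTX (e.g. all-ones binarized ATAC) -> numeric
      raw <- as(as(as(raw, "CsparseMatrix"), "generalMatrix"), "dMatrix")
      feats <- readLines(ftf)
      if (nrow(raw) != length(feats))
        stop("dimension mismatch between ", mtxf, " (", nrow(raw),
             " rows) and ", ftf, " (", length(feats), " features)")
      if (ncol(raw) != length(ids))
        stop("dimension mismatch between ", mtxf, " (", ncol(raw),
             " columns) and ", bcf, " (", length(ids), " barcodes)")
      vals <- raw@x
      if (length(vals) && any(vals != round(vals)))
        stop("non-integer values in ", mtxf)
      raw <- Matrix::t(raw)                    # back to cells x features
      p <- padCounts(raw, feats, spaces[[m]])
      counts[[m]] <- p$counts
      masks[[m]] <- p$mask
    }
    recs[[bid]] <- new("BatchRecord", batchId = bid,
                       modalities = names(entry$modalities),
                       counts = counts, masks = masks, cellIds = ids)
  }
  new("MosaicDataset", featureSpaces = spaces, batches = recs)
}
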