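#' @include train.R
NULL

#' Infer the joint latent posterior for every cell
#'
#' Runs the encoders in eval mode (dropout disabled, no sampling) and
#' combines the batch-ID expert with the experts of the requested measured
#' modalities via the product of experts. The posterior mean of the
#' biological state, `cellEmbedding()`, is the mosaic-integration embedding.
#'
#' @param model a trained [MosaicModel].
#' @param dataset a [MosaicDataset] whose feature spaces match the model.
#' @param useModalities optional character vector restricting which measured
#'   modalities contribute experts (e.g. a single modality for
#'   modality-specific embeddings); `NULL` uses all measured modalities. A
#'   cell whose batch measured none of the requested modalities falls back
#'   to prior + batch expert.
#' @return a [LatentTable].
#' @export
inferLatent <- function(model, dataset, useModalities = NULL) {
  stopifnot(is(model, "MosaicModel"), is(dataset, "MosaicDataset"))
  unknown <- setdiff(modalities(dataset), names(model@params$nets$enc))
  if (length(unknown))
    stop("dataset modalities unknown to the model: ",
         paste(unknown, collapse = ", "))
  dC <- model@architecture$dC; dU <- model@architecture$dU
  dZ <- dC + dU
  muAll <- NULL; nuAll <- NULL
  for (b in dataset@batches) {
    mods <- b@modalities
    if (!is.null(useModalities)) mods <- intersect(mods, useModalities)
    experts <- lapply(mods, function(m)
      encodeModality(model, b@counts[[m]], m, b@masks[[m]]))
    bat <- encodeBatch(model, rep.int(b@batchId, length(b@cellIds)))
    post <- poeCombine(c(list(bat), experts))
    muAll <- rbind(muAll, post$mu)
    nuAll <- rbind(nuAll, post$nu)
  }
  new("LatentTable",
      muC = muAll[, seq_len(dC), drop = FALSE],
      nuC = nuAll[, seq_len(dC), drop = FALSE],
      muU = muAll[, dC + seq_len(dU), drop = FALSE],
      nuU = nuAll[, dC + seq_len(dU), drop = FALSE],
      batchIds = cellBatch(dataset), cellIds = cellIds(dataset))
}

#' Impute counts for all modalities over the full feature unions
#'
#' Decodes each cell's posterior-mean latents into padded modality means.
#' `mode = "mean"` returns the means themselves (accessibility probabilities
#' for ATAC, Poisson rates for RNA/ADT); `mode = "sample"` draws Bernoulli /
#' Poisson counts from them with a seeded RNG.
#'
#' @param model a trained [MosaicModel].
#' @param latent a [LatentTable] from [inferLatent()].
#' @param mode `"mean"` or `"sample"`.
#' @param seed RNG seed for `mode = "sample"`.
#' @return named list of cells x `D^m` matrices, one per model modality.
#' @export
imputeCounts <- function(model, latent, mode = c("mean", "sample"),
                         seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is(latent, "LatentTable"))
  dec <- decodeLatent(model, latent@muC, latent@muU)
  lambda <- dec$lambda
  if (mode == "mean") return(lambda)
  run <- localRNG(seed)
  run(function() {
    out <- list()
    for (m in names(lambda)) {
      L <- lambda[[m]]
      out[[m]] <- if (m == "ATAC") {
        matrix(stats::rbinom(length(L), 1L, L), nrow(L), ncol(L),
               dimnames = dimnames(L))
      } else {
        matrix(stats::rpois(length(L), L), nrow(L), ncol(L),
               dimnames = dimnames(L))
      }
    }
    out
  })
}

#' Choose the reference batch for technical-noise substitution
#'
#' Given per-batch means of the technical noise, returns the batch whose
#' mean is closest (Euclidean) to the grand mean of batch means (equal
#' weight per batch). Ties break to the lowest batch ID.
#'
#' @param uMeans B x `d_u` matrix of per-batch technical-noise means.
#' @return integer batch index.
#' @export
selectReferenceBatch <- function(uMeans) {
  uMeans <- as.matrix(uMeans)
  grand <- colMeans(uMeans)
  d <- sqrt(rowSums(sweep(uMeans, 2, grand)^2))
  which.min(d)  # which.min takes the first (lowest ID) on ties
}

#' Batch-correct counts by technical-noise substitution
#'
#' Computes each batch's mean technical noise, selects the reference batch
#' whose mean is closest to the grand mean, and decodes every cell with its
#' own biological state but the reference batch's technical noise. The
#' output is simultaneously imputed (full unions) and batch-corrected;
#' Poisson rates use the reference batch's median library factor so all
#' cells share one depth.
#'
#' @param model a trained [MosaicModel].
#' @param latent a [LatentTable].
#' @return list with `counts` (named list of mean-mode matrices), `bStar`
#'   (the reference batch), `batchMeans` (B x `d_u`) and `uStar`.
#' @export
batchCorrect <- function(model, latent) {
  stopifnot(is(latent, "LatentTable"))
  bs <- sort(unique(latent@batchIds))
  uMeans <- do.call(rbind, lapply(bs, function(b)
    colMeans(latent@muU[latent@batchIds == b, , drop = FALSE])))
  bStar <- bs[selectReferenceBatch(uMeans)]
  uStar <- uMeans[match(bStar, bs), ]
  n <- nrow(latent@muC)
  uSub <- matrix(uStar, n, length(uStar), byrow = TRUE)
  lib <- lapply(model@config$libBatchMedian, function(x) {
    v <- x[[as.character(bStar)]]
    if (is.null(v)) NULL else v
  })
  dec <- decodeLatent(model, latent@muC, uSub, libFactor = lib)
  list(counts = dec$lambda, bStar = bStar, batchMeans = uMeans,
       uStar = uStar)
}
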