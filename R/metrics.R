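#' @include tasks.R
NULL

#' Exact k-nearest-neighbour graph
#'
#' Brute-force Euclidean kNN over the rows of `points`; the cell itself is
#' never its own neighbour and neighbour distances are non-decreasing.
#'
#' @param points N x d numeric matrix.
#' @param k neighbour count, `k < N`.
#' @return list of class `"neighborGraph"` with `indices` (N x k),
#'   `distances` (N x k) and `k`.
#' @export
buildKnnGraph <- function(points, k = 15L) {
  points <- as.matrix(points)
  N <- nrow(points)
  if (k >= N) stop("k must be smaller than the number of points")
  r2 <- rowSums(points^2)
  D2 <- outer(r2, r2, "+") - 2 * tcrossprod(points)
  D2[D2 < 0] <- 0
  diag(D2) <- Inf
  idx <- matrix(0L, N, k); dst <- matrix(0, N, k)
  for (i in seq_len(N)) {
    o <- order(D2[i, ])[seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- sqrt(D2[i, o])
  }
  structure(list(indices = idx, distances = dst, k = as.integer(k)),
            class = "neighborGraph")
}

# Per-cell inverse Simpson index over the neighbour label frequencies,
# averaged; uniform weights over the k nearest neighbours.
lisiRaw <- function(graph, labels) {
  labels <- as.integer(factor(labels))
  mean(apply(graph$indices, 1, function(nb) {
    p <- tabulate(labels[nb], nbins = max(labels)) / length(nb)
    1 / sum(p^2)
  }))
}

#' Graph iLISI (batch mixing) and cLISI (type separation)
#'
#' The local inverse Simpson index on the kNN graph: the effective number
#' of labels in each cell's neighbourhood, rescaled as `(LISI - 1)/(L - 1)`
#' where L is the number of labels. `graphIlisi` uses batch labels (1 =
#' perfect mixing); `graphClisi` uses type labels and is flipped so 1 =
#' perfect separation.
#'
#' @param graph a [buildKnnGraph()] result.
#' @param labels batch or type label vector.
#' @return score in `[0, 1]`.
#' @export
graphIlisi <- function(graph, labels) {
  L <- length(unique(labels))
  if (L < 2L) {
    warning("iLISI undefined with a single label; returning 1")
    return(1)
  }
  (lisiRaw(graph, labels) - 1) / (L - 1)
}

#' @rdname graphIlisi
#' @export
graphClisi <- function(graph, labels) {
  L <- length(unique(labels))
  if (L < 2L) return(1)
  1 - (lisiRaw(graph, labels) - 1) / (L - 1)
}

#' Graph connectivity of type labels
#'
#' For every label, the fraction of its cells inside the largest connected
#' component of the label-restricted kNN subgraph, averaged over labels.
#'
#' @inheritParams graphIlisi
#' @return score in `[0, 1]`.
#' @export
graphConnectivity <- function(graph, labels) {
  labels <- as.character(labels)
  scores <- vapply(unique(labels), function(lb) {
    cells <- which(labels == lb)
    if (length(cells) == 1L) return(1)
    sub <- match(graph$indices[cells, , drop = FALSE], cells)
    from <- rep(seq_along(cells), graph$k)
    keep <- !is.na(sub)
    g <- igraph::graph_from_edgelist(cbind(from[keep], sub[keep]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(cells) -
                                       igraph::vcount(g)))
    max(igraph::components(g)$csize) / length(cells)
  }, numeric(1))
  mean(scores)
}

#' kBET: local batch-composition test score
#'
#' Tests whether local batch composition matches the global one: for a
#' random subset of cells, a chi-square goodness-of-fit test compares each
#' cell's neighbourhood batch counts against the global batch proportions.
#' Rejection rates (at level 0.05) are computed per type label, averaged,
#' and subtracted from 1, so 1 indicates well-mixed batches.
#'
#' @param graph a [buildKnnGraph()] result (use neighbourhood size ~50).
#' @param batches batch labels.
#' @param typeLabels optional type labels for the label-wise adjustment.
#' @param testFraction fraction of cells tested per label (default 0.1,
#'   at least 10 cells).
#' @param level rejection level (default 0.05).
#' @param seed seed for the tested-cell subsample.
#' @return score in `[0, 1]`.
#' @export
kbet <- function(graph, batches, typeLabels = NULL, testFraction = 0.1,
                 level = 0.05, seed = 1L) {
  batches <- as.integer(factor(batches))
  B <- max(batches)
  if (B < 2L) stop("kBET needs at least 2 batches")
  if (is.null(typeLabels)) typeLabels <- rep("all", length(batches))
  typeLabels <- as.character(typeLabels)
  run <- localRNG(seed)
  rates <- c()
  for (lb in unique(typeLabels)) {
    cells <- which(typeLabels == lb)
    glob <- tabulate(batches[cells], nbins = B)
    present <- glob > 0
    if (sum(present) < 2L) {
      warning("label ", lb, " present in a single batch; skipped")
      next
    }
    nTest <- max(10L, ceiling(testFraction * length(cells)))
    nTest <- min(nTest, length(cells))
    test <- run(function() sample(cells, nTest))
    p0 <- glob[present] / sum(glob)
    rej <- vapply(test, function(i) {
      nb <- graph$indices[i, ]
      obs <- tabulate(batches[nb], nbins = B)[present]
      expd <- p0 * length(nb)
      stat <- sum((obs - expd)^2 / expd)
      stats::pchisq(stat, df = sum(present) - 1L, lower.tail = FALSE) < level
    }, logical(1))
    rates <- c(rates, mean(rej))
  }
  if (!length(rates)) return(NA_real_)
  1 - mean(rates)
}

#' Modality ASW: silhouette-based modality mixing
#'
#' Stacks per-modality embeddings of the same cells with a modality tag and
#' scores how well the modalities mix, following the batch-silhouette
#' convention: within each type label, the mean of `1 - |s|` over cells
#' (s = silhouette width for the modality grouping), averaged across
#' labels. 1 = perfect modality alignment.
#'
#' @param embeddings named list of N x d matrices, one per modality,
#'   matched rows.
#' @param typeLabels type labels of the N cells.
#' @return score in `[0, 1]`.
#' @export
modalityAsw <- function(embeddings, typeLabels) {
  stacked <- do.call(rbind, embeddings)
  tag <- rep(seq_along(embeddings),
             vapply(embeddings, nrow, integer(1)))
  labs <- rep(as.character(typeLabels), length(embeddings))
  scores <- c()
  for (lb in unique(labs)) {
    rows <- which(labs == lb)
    if (length(rows) < 2L || length(unique(tag[rows])) < 2L) next
    sil <- cluster::silhouette(tag[rows],
                               stats::dist(stacked[rows, , drop = FALSE]))
    scores <- c(scores, mean(1 - abs(sil[, "sil_width"])))
  }
  if (!length(scores)) return(NA_real_)
  mean(scores)
}

#' FOSCTTM-based modality alignment score
#'
#' Fraction of samples closer than the true match, computed for a matched
#' pair of modality embeddings in both directions, averaged, and subtracted
#' from 1 so that 1 means every cell's two profiles are mutual nearest.
#'
#' @param e1,e2 N x d embedding matrices with matched rows.
#' @return score in `[0, 1]`.
#' @export
foscttm <- function(e1, e2) {
  e1 <- as.matrix(e1); e2 <- as.matrix(e2)
  N <- nrow(e1)
  if (N < 2L || nrow(e2) != N) stop("need matched embeddings with N >= 2")
  D <- outer(rowSums(e1^2), rowSums(e2^2), "+") - 2 * tcrossprod(e1, e2)
  trueD <- diag(D)
  n1 <- rowSums(D < trueD)          # cells in e2 closer to e1_i than match
  n2 <- colSums(D < rep(trueD, each = N))  # and the reverse direction
  1 - (sum(n1 / N) + sum(n2 / N)) / (2 * N)
}

#' Label transfer F1 between modality embeddings
#'
#' For each ordered pair of modality embeddings, transfers type labels by
#' 1-nearest-neighbour from one modality to the other and scores micro-F1
#' (accuracy over all cells) against the true labels; pairs are averaged.
#'
#' @param embeddings named list of matched N x d matrices (>= 2).
#' @param typeLabels true labels.
#' @return score in `[0, 1]`.
#' @export
labelTransferF1 <- function(embeddings, typeLabels) {
  stopifnot(length(embeddings) >= 2L)
  typeLabels <- as.character(typeLabels)
  pairs <- expand.grid(from = seq_along(embeddings),
                       to = seq_along(embeddings))
  pairs <- pairs[pairs$from != pairs$to, ]
  f1 <- apply(pairs, 1, function(pr) {
    nn <- knnIndex(embeddings[[pr["to"]]], embeddings[[pr["from"]]], 1L)
    mean(typeLabels[nn[, 1]] == typeLabels)
  })
  mean(f1)
}

# Rank-based AUROC (equivalent to the Mann-Whitney statistic).
aurocVec <- function(score, truth) {
  as.numeric(suppressMessages(pROC::auc(pROC::roc(
    response = truth, predictor = score, quiet = TRUE,
    direction = "<", levels = c(0, 1)))))
}

#' Cross-modal feature recovery scores
#'
#' For each target modality, feeds every non-empty combination of the other
#' measured modalities to the model, imputes the target, and scores the
#' imputed means against the truth on observed features: AUROC for binary
#' ATAC, Pearson's r for RNA/ADT. Combinations are averaged per target.
#'
#' @param model a trained [MosaicModel].
#' @param dataset the [MosaicDataset] providing the true counts.
#' @return named numeric vector with elements `ATAC_AUROC`, `RNA_pearson`,
#'   `ADT_pearson` (entries for unmeasured targets are dropped with a
#'   warning).
#' @export
crossModalFeatureScores <- function(model, dataset) {
  mods <- modalities(dataset)
  out <- c()
  for (target in mods) {
    others <- setdiff(mods, target)
    if (!length(others)) next
    combos <- unlist(lapply(seq_along(others), function(sz)
      utils::combn(others, sz, simplify = FALSE)), recursive = FALSE)
    vals <- c()
    for (cb in combos) {
      lat <- inferLatent(model, dataset, useModalities = cb)
      imp <- imputeCounts(model, lat, mode = "mean")[[target]]
      truthM <- list(); maskM <- list()
      rowsOff <- 0
      sc <- c()
      for (b in dataset@batches) {
        n <- length(b@cellIds)
        if (target %in% b@modalities && all(cb %in% b@modalities)) {
          obs <- which(b@masks[[target]] == 1L)
          x <- as.matrix(b@counts[[target]][, obs, drop = FALSE])
          yhat <- imp[rowsOff + seq_len(n), obs, drop = FALSE]
          if (target == "ATAC") {
            sc <- c(sc, aurocVec(as.numeric(yhat), as.numeric(x)))
          } else {
            if (stats::sd(yhat) < 1e-12) {
              warning("constant imputation for ", target, "; scoring 0")
              sc <- c(sc, 0)
            } else {
              sc <- c(sc, stats::cor(as.numeric(yhat), as.numeric(x)))
            }
          }
        }
        rowsOff <- rowsOff + n
      }
      if (length(sc)) vals <- c(vals, mean(sc))
    }
    if (!length(vals)) {
      warning("target modality ", target, " never scoreable; skipped")
      next
    }
    nm <- if (target == "ATAC") "ATAC_AUROC" else paste0(target, "_pearson")
    out[nm] <- mean(vals)
  }
  out
}

# Louvain clustering on the kNN graph, sweeping resolutions and keeping the
# clustering that maximizes NMI against the given labels.
optimizedLouvain <- function(graph, labels,
                             resolutions = seq(0.1, 2, by = 0.1),
                             seed = 1L) {
  N <- nrow(graph$indices)
  edges <- cbind(rep(seq_len(N), graph$k), as.integer(graph$indices))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  run <- localRNG(seed)
  best <- NULL; bestNmi <- -1
  for (res in resolutions) {
    cl <- run(function()
      igraph::membership(igraph::cluster_louvain(g, resolution = res)))
    nmi <- igraph::compare(cl, as.integer(factor(labels)), method = "nmi")
    if (nmi > bestNmi) { bestNmi <- nmi; best <- cl }
  }
  best
}

#' Biological conservation metrics
#'
#' Clusters the kNN graph with a resolution-swept Louvain (keeping the
#' clustering that maximizes NMI against the labels), then reports NMI and
#' ARI versus the true type labels, the isolated-label F1 (labels present
#' in the fewest batches; best F1 of any single cluster against the label),
#' and graph cLISI.
#'
#' @param graph a [buildKnnGraph()] result.
#' @param typeLabels true type labels.
#' @param batches batch labels (needed for isolated labels; with one batch
#'   every label is isolated).
#' @param seed seed for the Louvain sweep.
#' @return named numeric vector `NMI`, `ARI`, `isolated_F1`, `cLISI`.
#' @export
bioConservation <- function(graph, typeLabels, batches = NULL, seed = 1L) {
  typeLabels <- as.character(typeLabels)
  cl <- optimizedLouvain(graph, typeLabels, seed = seed)
  nmi <- igraph::compare(cl, as.integer(factor(typeLabels)),
                         method = "nmi")
  ari <- igraph::compare(cl, as.integer(factor(typeLabels)),
                         method = "adjusted.rand")
  if (is.null(batches)) batches <- rep(1L, length(typeLabels))
  nb <- vapply(unique(typeLabels), function(lb)
    length(unique(batches[typeLabels == lb])), integer(1))
  isolated <- names(nb)[nb == min(nb)]
  isoF1 <- mean(vapply(isolated, function(lb) {
    truth <- typeLabels == lb
    max(vapply(unique(cl), function(k) {
      pred <- cl == k
      tp <- sum(pred & truth)
      if (tp == 0) return(0)
      prec <- tp / sum(pred); rec <- tp / sum(truth)
      2 * prec * rec / (prec + rec)
    }, numeric(1)))
  }, numeric(1)))
  c(NMI = nmi, ARI = max(0, ari), isolated_F1 = isoF1,
    cLISI = graphClisi(graph, typeLabels))
}

#' Overall integration scores
#'
#' Convex combinations of the metric groups: the single-space overall score
#' weights batch correction 0.4 and biological conservation 0.6; the
#' mosaic overall score weights batch correction 0.3 (both spaces),
#' modality alignment 0.3 and biological conservation 0.4 (both spaces).
#'
#' @param batch numeric vector of batch-correction scores.
#' @param bio numeric vector of biological-conservation scores.
#' @param modality numeric vector of modality-alignment scores (for the
#'   mosaic score).
#' @return list with `scib` (when `modality` is missing) or `scmib`.
#' @export
overallScores <- function(batch, bio, modality = NULL) {
  chk <- function(x, nm) {
    if (any(is.na(x))) stop("missing component in ", nm, " scores")
    if (any(x < -1e-9 | x > 1 + 1e-9)) stop(nm, " scores must be in [0,1]")
  }
  chk(batch, "batch"); chk(bio, "bio")
  if (is.null(modality))
    return(list(scib = 0.4 * mean(batch) + 0.6 * mean(bio)))
  chk(modality, "modality")
  list(scmib = 0.3 * mean(batch) + 0.3 * mean(modality) + 0.4 * mean(bio))
}

#' Per-cell modality contribution to the integrated neighbourhood
#'
#' The normalized consistency ratio of nearest neighbours: per cell and
#' modality, the overlap between the modality graph's and the joint graph's
#' neighbour sets divided by k, normalized across modalities to sum to 1.
#'
#' @param modalityGraphs named list of [buildKnnGraph()] results.
#' @param jointGraph the joint [buildKnnGraph()] result (same N and k).
#' @return N x length(modalityGraphs) matrix of contributions.
#' @export
modalityContribution <- function(modalityGraphs, jointGraph) {
  N <- nrow(jointGraph$indices)
  raw <- vapply(modalityGraphs, function(g) {
    stopifnot(nrow(g$indices) == N, g$k == jointGraph$k)
    vapply(seq_len(N), function(i)
      length(intersect(g$indices[i, ], jointGraph$indices[i, ])) /
        jointGraph$k, numeric(1))
  }, numeric(N))
  tot <- rowSums(raw)
  tot[tot == 0] <- 1
  sw <- raw / tot
  colnames(sw) <- names(modalityGraphs)
  sw
}

#' Feature-space similarity graph from corrected counts
#'
#' Converts imputed and batch-corrected counts into a kNN graph: each
#' modality is standardized per feature (making the graph invariant to
#' per-modality scale) and projected onto its top principal components; the
#' per-modality projections are concatenated and a Euclidean kNN graph
#' built on the concatenation.
#'
#' @param counts named list of cells x features matrices (>= 1 modality).
#' @param nComponents principal components per modality (default 32; shrunk
#'   with a warning when a modality has fewer features).
#' @param k neighbour count.
#' @return a [buildKnnGraph()] result.
#' @export
featureSpaceGraph <- function(counts, nComponents = 32L, k = 15L) {
  proj <- list()
  for (m in names(counts)) {
    X <- as.matrix(counts[[m]])
    sds <- apply(X, 2, stats::sd)
    X <- X[, sds > 1e-12, drop = FALSE]
    X <- scale(X)
    nc <- min(nComponents, ncol(X) - 1L, nrow(X) - 1L)
    if (nc < nComponents)
      warning(m, ": only ", nc, " components available")
    proj[[m]] <- stats::prcomp(X, rank. = nc, center = FALSE,
                               scale. = FALSE)$x
  }
  buildKnnGraph(do.call(cbind, proj), k = k)
}
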