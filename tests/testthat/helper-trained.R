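# Trained-model fixtures for the acceptance tests. Training is the
# expensive part, so one full-modality model and one mosaic model are fitted
# once per session (first use) and shared across test blocks.
#
# Study conditions: 3 batches x 500 cells, 4 cell types, trimodal counts
# from the package's generator defaults. The model uses a desk-scale
# architecture (d_c 16, hidden 256-64) and a desk-scale optimizer setting
# (AdamW, lr 2e-3, minibatch 256, <= 200 epochs); the methods vignette
# discusses these choices.

.trainedCache <- new.env(parent = emptyenv())

acceptanceArch <- function() {
  mosaicArchitecture(dC = 16L, dU = 2L, encHidden = c(256L, 64L),
                     decHidden = c(64L, 256L), dropout = 0.2)
}

acceptanceStudy <- function() {
  if (!is.null(.trainedCache$study)) return(.trainedCache$study)
  sim <- simulateMosaic(mosaicSimConfig())   # generator default seed
  full <- trainMosaic(sim$dataset, acceptanceArch(), lossWeights(),
                      epochs = 200L, lr = 2e-3, minibatch = 256L,
                      seed = 4L, patience = 200L)
  .trainedCache$study <- list(sim = sim, full = full)
  .trainedCache$study
}

# Paired mosaic over the same synthetic truth: every batch keeps two
# modalities and every modality pair co-occurs in some batch; batch 1 lacks
# ADT, which the imputation test holds out.
acceptanceMosaic <- function() {
  if (!is.null(.trainedCache$mosaic)) return(.trainedCache$mosaic)
  st <- acceptanceStudy()
  pattern <- list(c("ATAC", "RNA"), c("RNA", "ADT"), c("ATAC", "ADT"))
  data <- applyMosaicPattern(st$sim$dataset, pattern)
  model <- trainMosaic(data, acceptanceArch(), lossWeights(),
                       epochs = 200L, lr = 2e-3, minibatch = 256L,
                       seed = 4L, patience = 200L)
  .trainedCache$mosaic <- list(data = data, model = model)
  .trainedCache$mosaic
}

# Held-out linear probe accuracy: how well a multinomial logistic model
# predicts `labels` from `emb` on a 1/3 held-out split.
probeAccuracy <- function(emb, labels, seed = 1) {
  stopifnot(requireNamespace("nnet", quietly = TRUE))
  labels <- factor(labels)
  set.seed(seed)
  idx <- sample(length(labels))
  nTr <- floor(2 * length(labels) / 3)
  tr <- idx[seq_len(nTr)]; te <- idx[-seq_len(nTr)]
  df <- data.frame(y = labels, emb)
  fit <- nnet::multinom(y ~ ., data = df[tr, ], trace = FALSE,
                        MaxNWts = 5000)
  mean(predict(fit, newdata = df[te, ]) == labels[te])
}

kmeansAri <- function(emb, labels, centers, seed = 1) {
  set.seed(seed)
  km <- stats::kmeans(emb, centers = centers, nstart = 10)
  igraph::compare(km$cluster, as.integer(factor(labels)),
                  method = "adjusted.rand")
}
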