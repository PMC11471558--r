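# Small seeded fixtures shared across test files. Heavier trained-model
# fixtures (used by the acceptance tests) are memoized in helper-trained.R.

tinySim <- function(seed = 3, nCells = c(50, 60), ...) {
  simulateMosaic(mosaicSimConfig(
    nCellsPerBatch = nCells,
    nFeatures = c(ATAC = 40L, RNA = 30L, ADT = 10L),
    seed = seed, ...))
}

tinyModel <- function(dataset, dC = 4L, dU = 2L, seed = 2L,
                      weights = lossWeights()) {
  initMosaicModel(dataset,
                  mosaicArchitecture(dC = dC, dU = dU,
                                     encHidden = c(16L, 8L),
                                     decHidden = c(8L, 16L), dropout = 0,
                                     clfHidden = c(7L, 7L),
                                     batchNetHidden = 6L),
                  weights, seed = seed)
}

# deterministic labelled point clouds for metric tests
clusteredPoints <- function(n = 60, centers = rbind(c(0, 0), c(8, 8)),
                            sd = 0.5, seed = 1) {
  set.seed(seed)
  lab <- rep(seq_len(nrow(centers)), length.out = n)
  pts <- centers[lab, ] + matrix(rnorm(2 * n, sd = sd), n, 2)
  list(points = pts, labels = lab)
}
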