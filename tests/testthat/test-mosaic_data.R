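test_that("feature unions are deterministic first-seen unions", {
  u <- buildFeatureUnion(list(RNA = list(c("g1", "g2"), c("g2", "g3"))))
  expect_identical(u$RNA@names, c("g1", "g2", "g3"))

  single <- buildFeatureUnion(list(ADT = list(c("p3", "p1", "p2"))))
  expect_identical(single$ADT@names, c("p3", "p1", "p2"))

  # random 50%-overlapping gene sets: union size matches brute force
  set.seed(41)
  pool <- sprintf("g%03d", 1:200)
  lists <- replicate(3, sample(pool, 100), simplify = FALSE)
  u3 <- buildFeatureUnion(list(RNA = lists))
  expect_identical(length(u3$RNA@names),
                   length(Reduce(union, lists)))
  # idempotent: rebuilding from the union gives the same order
  expect_identical(
    buildFeatureUnion(list(RNA = list(u3$RNA@names)))$RNA@names,
    u3$RNA@names)

  expect_error(buildFeatureUnion(list(RNA = list(c("g1", "g1")))),
               "duplicate")
})

test_that("ATAC names parse into chromosome blocks with fallback", {
  u <- buildFeatureUnion(list(ATAC = list(
    c("chr1:100-200", "chr2:5-50", "chr1:300-400"))))
  expect_identical(max(u$ATAC@blocks), 2L)  # two chromosomes
  # blocks are contiguous after reordering
  expect_true(all(diff(u$ATAC@blocks) >= 0))
  fb <- buildFeatureUnion(list(ATAC = list(sprintf("peak%d", 1:12))),
                          atacBlocks = 3L)
  expect_identical(max(fb$ATAC@blocks), 3L)
})

test_that("padding and masking round trip exactly", {
  space <- buildFeatureUnion(list(RNA = list(c("g1", "g2", "g3"))))$RNA
  p <- padCounts(matrix(5, 1, 1), "g2", space)
  expect_equal(as.numeric(p$counts), c(0, 5, 0))
  expect_identical(p$mask, c(0L, 1L, 0L))
  expect_equal(maskFeatures(as.numeric(p$counts), p$mask), 5)

  # identity case
  raw <- matrix(1:6, 2, 3)
  pid <- padCounts(raw, c("g1", "g2", "g3"), space)
  expect_equal(as.matrix(pid$counts), raw, ignore_attr = TRUE)
  expect_identical(pid$mask, rep(1L, 3))

  # random matrix: column sums preserved, zeros elsewhere; round trip
  set.seed(7)
  pool <- sprintf("f%02d", 1:50)
  feats <- sample(pool, 30)
  raw <- matrix(rpois(20 * 30, 2), 20, 30)
  sp <- buildFeatureUnion(list(RNA = list(pool)))$RNA
  pr <- padCounts(raw, feats, sp)
  expect_equal(unname(Matrix::colSums(pr$counts)[match(feats, pool)]),
               colSums(raw))
  expect_equal(sum(pr$counts), sum(raw))
  expect_equal(as.matrix(maskFeatures(pr$counts, pr$mask))[
    , match(feats, pool[pr$mask == 1])], raw, ignore_attr = TRUE)

  expect_error(padCounts(raw, sprintf("zz%d", 1:30), sp), "not in the union")
  expect_error(maskFeatures(1:3, c(1, 0)), "length")
})

test_that("mask selection equals naive indexing on random pairs", {
  set.seed(11)
  for (i in 1:5) {
    v <- rnorm(25)
    mk <- rbinom(25, 1, 0.6)
    expect_equal(maskFeatures(v, mk), v[which(mk == 1)])
  }
  expect_equal(maskFeatures(1:4, rep(1, 4)), 1:4)
})

test_that("ATAC binarization thresholds at zero", {
  expect_equal(as.numeric(binarizeAtac(matrix(c(0, 1, 3), 1))), c(0, 1, 1))
  z <- matrix(0, 3, 4)
  expect_equal(as.matrix(binarizeAtac(z)), z, ignore_attr = TRUE)
  set.seed(5)
  x <- matrix(rpois(200, 1.5), 10, 20)
  expect_equal(as.matrix(binarizeAtac(x)), (x > 0) + 0, ignore_attr = TRUE)
  expect_error(binarizeAtac(matrix(-1)), "negative")
})

test_that("train/val split is stratified, exhaustive and reproducible", {
  sim <- tinySim(nCells = c(40, 60))
  sp <- splitTrainVal(sim$dataset, 0.95, seed = 9)
  expect_identical(sort(c(sp$train, sp$val)), 1:100)
  expect_identical(length(sp$train), 95L)
  sp2 <- splitTrainVal(sim$dataset, 0.95, seed = 9)
  expect_identical(sp, sp2)

  # per-batch proportions within 1 cell of the ratio
  big <- simulateMosaic(mosaicSimConfig(
    nCellsPerBatch = c(300, 350, 350),
    nFeatures = c(ATAC = 20L, RNA = 15L, ADT = 6L), seed = 2))
  spb <- splitTrainVal(big$dataset, 0.9, seed = 1)
  bt <- cellBatch(big$dataset)
  for (b in 1:3) {
    nb <- sum(bt == b)
    expect_lte(abs(sum(bt[spb$train] == b) - 0.9 * nb), 1)
  }

  # a batch with a single cell goes entirely to train, with a warning
  tiny <- simulateMosaic(mosaicSimConfig(
    nCellsPerBatch = c(1L, 30L), nTypes = 2L,
    nFeatures = c(ATAC = 10L, RNA = 8L, ADT = 4L), seed = 5))
  expect_warning(spt <- splitTrainVal(tiny$dataset, 0.9, seed = 1),
                 "< 2 cells")
  expect_true(1L %in% spt$train)
})

test_that("mask-0 columns are all zero and validity enforces it", {
  sim <- tinySim(featureDropout = 0.3)
  d <- sim$dataset
  for (b in seq_len(nBatches(d))) for (m in modalities(d)) {
    mk <- featureMask(d, b, m)
    cs <- Matrix::colSums(assayCounts(d, b, m))
    expect_true(all(cs[mk == 0] == 0))
  }
  # corrupting a masked column triggers the validity check
  r <- d@batches[[1]]
  bad <- which(r@masks$RNA == 0L)[1]
  r@counts$RNA[1, bad] <- 3
  expect_error(validObject(r), "masked-out")
})

test_that("MTX round trip is exact and errors name the culprit file", {
  sim <- tinySim(featureDropout = 0.2)
  d <- sim$dataset
  td <- withr::local_tempdir()
  writeMosaic(d, td)
  d2 <- readMosaic(file.path(td, "manifest.yaml"))
  expect_identical(nCells(d2), nCells(d))
  for (b in seq_len(nBatches(d))) for (m in modalities(d)) {
    expect_identical(as.matrix(assayCounts(d, b, m)),
                     as.matrix(assayCounts(d2, b, m)))
    expect_identical(featureMask(d, b, m), featureMask(d2, b, m))
  }
  expect_identical(cellIds(d), cellIds(d2))
  expect_identical(featureNames(d, "ATAC"), featureNames(d2, "ATAC"))

  # missing modality in the manifest: batch loses it
  dm <- applyMosaicPattern(d, list(c("ATAC", "ADT"),
                                   c("ATAC", "RNA", "ADT")))
  td2 <- withr::local_tempdir()
  writeMosaic(dm, td2)
  d3 <- readMosaic(file.path(td2, "manifest.yaml"))
  expect_setequal(modalities(batchRecord(d3, 1)), c("ATAC", "ADT"))

  # corrupt MTX header names the file
  mtx <- list.files(td, pattern = "RNA_matrix", full.names = TRUE)[1]
  writeLines("not a matrix market file", mtx)
  expect_error(readMosaic(file.path(td, "manifest.yaml")),
               basename(mtx))
  expect_error(readMosaic(file.path(td, "nope.yaml")), "not found")
})

test_that("mosaic patterns remove blocks and keep the rest bit-identical", {
  sim <- tinySim()
  d <- sim$dataset
  dm <- applyMosaicPattern(d, list(c("ATAC", "RNA")))
  expect_setequal(modalities(batchRecord(dm, 1)), c("ATAC", "RNA"))
  expect_identical(as.matrix(assayCounts(dm, 2, "ADT")),
                   as.matrix(assayCounts(d, 2, "ADT")))
  # identity pattern
  did <- applyMosaicPattern(d, list(MODALITIES, MODALITIES))
  expect_identical(as.matrix(assayCounts(did, 1, "RNA")),
                   as.matrix(assayCounts(d, 1, "RNA")))
  expect_error(applyMosaicPattern(d, setNames(list("RNA"), "9")),
               "unknown batch")
  expect_error(applyMosaicPattern(d, list(character(0))), "no modalities")
})
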