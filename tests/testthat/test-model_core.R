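test_that("poeCombine matches the closed form and the prior fallback", {
  expect_equal(poeCombine(list(), d = 3),
               list(mu = numeric(3), nu = rep(1, 3)))
  one <- poeCombine(list(list(mu = 1, nu = 1)))
  expect_equal(one$nu, 0.5)
  expect_equal(one$mu, 0.5)
  expect_error(poeCombine(list(list(mu = 0, nu = -1))), "positive")
})

test_that("poeCombine equals a numerically normalized density product", {
  set.seed(31)
  for (rep in 1:20) {
    experts <- lapply(seq_len(sample(1:4, 1)), function(i)
      list(mu = rnorm(1, sd = 2), nu = exp(rnorm(1))))
    out <- poeCombine(experts)
    # fine-grid product of the prior and all expert densities
    sdOut <- sqrt(out$nu)
    x <- seq(out$mu - 10 * sdOut, out$mu + 10 * sdOut,
             length.out = 20001)
    dens <- dnorm(x)
    for (e in experts) dens <- dens * dnorm(x, e$mu, sqrt(e$nu))
    w <- dens / sum(dens)
    gm <- sum(w * x)
    gv <- sum(w * (x - gm)^2)
    expect_lt(abs(gm - out$mu), 1e-6)
    expect_lt(abs(gv - out$nu), 1e-6)
  }
})

test_that("PoE variance never exceeds any expert's or the prior's", {
  set.seed(32)
  for (rep in 1:25) {
    experts <- lapply(seq_len(sample(1:5, 1)), function(i)
      list(mu = rnorm(3), nu = exp(rnorm(3, sd = 2))))
    out <- poeCombine(experts)
    expect_true(all(out$nu <= 1 + 1e-12))
    for (e in experts) expect_true(all(out$nu <= e$nu + 1e-12))
  }
})

test_that("encoders match an independently coded forward pass", {
  sim <- tinySim()
  m <- tinyModel(sim$dataset)
  st <- m@params$store
  X <- as.matrix(assayCounts(sim$dataset, 1, "RNA")[1:5, ])
  mask <- featureMask(sim$dataset, 1, "RNA")
  # hand-rolled forward: log1p -> dense+LN+mish -> dense+LN+mish -> linear
  ln <- function(A, g, be) {
    mu <- rowMeans(A); Ac <- A - mu
    xh <- Ac / sqrt(rowMeans(Ac^2) + 1e-5)
    sweep(sweep(xh, 2, g, "*"), 2, be, "+")
  }
  mi <- function(x) x * tanh(log1p(exp(x)))
  H <- log1p(X) %*% st$phi.enc.in.RNA$W
  H <- mi(ln(sweep(H, 2, st$phi.enc.in.RNA$b, "+"),
             st$phi.enc.in.RNA$g, st$phi.enc.in.RNA$be))
  H <- H %*% st$phi.enc.shared.2$W
  H <- mi(ln(sweep(H, 2, st$phi.enc.shared.2$b, "+"),
             st$phi.enc.shared.2$g, st$phi.enc.shared.2$be))
  out <- sweep(H %*% st$phi.enc.out$W, 2, st$phi.enc.out$b, "+")
  dZ <- 6L
  want <- list(mu = out[, 1:dZ], nu = exp(pmin(pmax(out[, dZ + 1:dZ],
                                                    log(1e-4)), log(1e4))))
  got <- encodeModality(m, X, "RNA", mask)
  expect_equal(got$mu, want$mu, tolerance = 1e-10)
  expect_equal(got$nu, want$nu, tolerance = 1e-10)
  # determinism in eval mode; identical cells -> identical outputs
  got2 <- encodeModality(m, X[c(1, 1), ], "RNA", mask)
  expect_equal(got2$mu[1, ], got2$mu[2, ])
  expect_error(encodeModality(m, X * NA, "RNA"), "NaN")
})

test_that("the batch expert informs only the technical-noise dims", {
  sim <- tinySim()
  m <- tinyModel(sim$dataset)
  e <- encodeBatch(m, c(1, 2, 2))
  dC <- m@architecture$dC
  expect_equal(e$mu[, 1:dC], matrix(0, 3, dC))
  expect_true(all(e$nu[, 1:dC] >= 1e7))
  expect_true(all(e$nu[, dC + 1:2] <= 1e4))
  expect_equal(e$mu[2, ], e$mu[3, ])
  expect_error(encodeBatch(m, 5), "out of range")
})

test_that("decoding produces valid supports and normalized batch
          probabilities", {
  sim <- tinySim()
  m <- tinyModel(sim$dataset)
  set.seed(2)
  dec <- decodeLatent(m, matrix(rnorm(8), 2), matrix(rnorm(4), 2))
  expect_true(all(dec$lambda$ATAC > 0 & dec$lambda$ATAC < 1))
  expect_true(all(dec$lambda$RNA > 0))
  expect_true(all(dec$lambda$ADT > 0))
  expect_equal(rowSums(dec$pi), c(1, 1))
  expect_error(decodeLatent(m, matrix(NaN, 1, 4), matrix(0, 1, 2)), "NaN")
})

test_that("loss identities hold at their closed-form points", {
  # KL zero at the prior
  post <- list(mu = rep(0, 5), nu = rep(1, 5))
  x <- list(ATAC = c(1, 0, 1))
  lam <- list(ATAC = c(1 - 1e-12, 1e-12, 1 - 1e-12))
  mk <- list(ATAC = rep(1, 3))
  pi <- c(1, 0)
  l <- elboLoss(x, lam, mk, s = 1, pi = pi, posterior = post, gamma = 7)
  expect_equal(l, 0, tolerance = 1e-9)

  # Poisson NLL at lambda = x is the self-information of the mode
  xr <- list(RNA = c(2, 0, 5))
  lamr <- list(RNA = c(2, 1e-12, 5))
  want <- -sum(dpois(c(2, 0, 5), c(2, 1e-12, 5), log = TRUE))
  l2 <- elboLoss(xr, lamr, list(RNA = rep(1, 3)), 1, c(1, 0),
                 post, gamma = 1)
  expect_equal(l2, want, tolerance = 1e-9)

  # KL > 0 away from the prior
  l3 <- elboLoss(x, lam, mk, 1, pi,
                 list(mu = rep(1, 5), nu = rep(1, 5)), gamma = 7)
  expect_gt(l3, 0)
})

test_that("elboLoss equals a direct formula evaluation on a random
          fixture", {
  set.seed(77)
  xs <- list(ATAC = rbinom(6, 1, 0.5), RNA = rpois(5, 2), ADT = rpois(4, 8))
  lam <- list(ATAC = runif(6, 0.05, 0.95), RNA = runif(5, 0.5, 4),
              ADT = runif(4, 2, 14))
  mks <- list(ATAC = rbinom(6, 1, 0.8), RNA = rep(1, 5), ADT = rbinom(4, 1, 0.7))
  mu <- rnorm(4); nu <- exp(rnorm(4)); piv <- c(0.3, 0.7)
  got <- elboLoss(xs, lam, mks, s = 2, piv, list(mu = mu, nu = nu),
                  gamma = 11)
  want <- -11 * log(0.7) -
    sum(dbinom(xs$ATAC, 1, lam$ATAC, log = TRUE) * mks$ATAC) -
    sum(dpois(xs$RNA, lam$RNA, log = TRUE) * mks$RNA) -
    sum(dpois(xs$ADT, lam$ADT, log = TRUE) * mks$ADT) +
    0.5 * sum(mu^2 + nu - log(nu) - 1)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("alignment loss measures dispersion and is zero iff samples
          coincide", {
  z <- list(c(1, 2), c(1, 2), c(1, 2))
  expect_equal(alignmentLoss(z, alpha = 50), 0)
  expect_equal(alignmentLoss(list(c(0)), alpha = 50), 0)
  expect_equal(alignmentLoss(list(c(0), c(2)), alpha = 3), 3 * 2)
  set.seed(9)
  zs <- lapply(1:3, function(i) rnorm(4))
  zbar <- Reduce(`+`, zs) / 3
  want <- 0
  for (zz in zs) for (j in 1:4) want <- want + (zz[j] - zbar[j])^2
  expect_equal(alignmentLoss(zs, alpha = 2), 2 * want)
  expect_gt(alignmentLoss(zs, alpha = 2), 0)
})

test_that("IB loss matches its uniform-classifier closed form and a random
          fixture", {
  B <- 4
  joint <- list(kappa = rep(1 / B, B), uMu = rep(0, 2), uNu = rep(1, 2),
                piU = rep(1 / B, B))
  got <- ibLoss(joint, list(), s = 2, betaS = 30, betaX = 4)
  expect_equal(got, 30 * log(1 / B) - 4 * log(1 / B))
  expect_equal(ibLoss(joint, list(joint), 2, betaS = 0, betaX = 0), 0)
  set.seed(12)
  kap <- prop.table(runif(B)); piu <- prop.table(runif(B))
  mu <- rnorm(2); nu <- exp(rnorm(2))
  t1 <- list(kappa = kap, uMu = mu, uNu = nu, piU = piu)
  want <- 30 * log(kap[3]) + 4 * 0.5 * sum(mu^2 + nu - log(nu) - 1) -
    4 * log(piu[3])
  expect_equal(ibLoss(t1, list(), 3), want)
  expect_equal(ibLoss(t1, list(t1, t1), 3), 3 * want)
  bad <- t1; bad$kappa <- c(2, 0, 0, 0.5)
  expect_error(ibLoss(bad, list(), 1), "probability")
})

test_that("classifier loss matches cross-entropy closed forms", {
  B <- 3
  perfect <- c(0, 1, 0)
  expect_equal(classifierLoss(perfect, list(), s = 2), 0)
  unif <- rep(1 / B, B)
  expect_equal(classifierLoss(unif, list(unif, unif), 1), 3 * log(B))
  set.seed(4)
  k1 <- prop.table(runif(B)); k2 <- prop.table(runif(B))
  expect_equal(classifierLoss(k1, list(k2), 2), -log(k1[2]) - log(k2[2]))
})

test_that("training losses are invariant to junk in masked-out features", {
  sim <- tinySim(featureDropout = 0.3)
  d <- sim$dataset
  arch <- mosaicArchitecture(dC = 4, dU = 2, encHidden = c(16, 8),
                             decHidden = c(8, 16), dropout = 0,
                             clfHidden = c(7, 7), batchNetHidden = 6)
  m <- initMosaicModel(d, arch, lossWeights(), seed = 2)
  gdat <- scMosaic:::prepTrainData(d, arch)
  store <- scMosaic:::storeEnv(m)
  g <- gdat$groups[[1]]
  g2 <- g
  for (mod in g$mods) {
    mask0 <- which(g$masks[[mod]] == 0L)
    if (!length(mask0)) next
    g2$raw[[mod]][, mask0] <- 99      # junk in unmeasured features
    g2$enc[[mod]] <- scMosaic:::encoderInput(g2$raw[[mod]], mod,
                                             g$masks[[mod]])
  }
  w <- do.call(lossWeights, m@lossWeights)
  set.seed(5)
  l1 <- scMosaic:::groupPass(store, m@params$nets, g, 1:10, w, arch, 2,
                             train = FALSE)$losses
  set.seed(5)
  l2 <- scMosaic:::groupPass(store, m@params$nets, g2, 1:10, w, arch, 2,
                             train = FALSE)$losses
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("short training decreases the validation loss and is
          reproducible", {
  sim <- tinySim(seed = 6, nCells = c(120, 120), nTypes = 2L)
  arch <- mosaicArchitecture(dC = 6, dU = 2, encHidden = c(32, 16),
                             decHidden = c(16, 32), dropout = 0.1)
  m1 <- trainMosaic(sim$dataset, arch, epochs = 12, lr = 2e-3,
                    minibatch = 128, seed = 3, patience = 50)
  lg <- trainingLog(m1)
  expect_lt(mean(tail(lg$val_total, 3)), mean(head(lg$val_total, 3)))
  m2 <- trainMosaic(sim$dataset, arch, epochs = 12, lr = 2e-3,
                    minibatch = 128, seed = 3, patience = 50)
  expect_equal(trainingLog(m1), trainingLog(m2), tolerance = 1e-12)
})

test_that("the schedule applies K classifier updates per joint update and
          early stopping fires on a plateau", {
  sim <- tinySim(seed = 6, nCells = c(60, 60))
  arch <- mosaicArchitecture(dC = 4, dU = 2, encHidden = c(16, 8),
                             decHidden = c(8, 16), dropout = 0)
  m <- trainMosaic(sim$dataset, arch, lossWeights(K = 3), epochs = 4,
                   lr = 1e-3, minibatch = 64, seed = 1, patience = 50)
  lg <- trainingLog(m)
  expect_equal(lg$clf_updates, 3 * lg$joint_updates)
  # lr = 0 freezes the model: loss plateaus and patience terminates training
  mp <- trainMosaic(sim$dataset, arch, epochs = 100, lr = 0,
                    minibatch = 64, seed = 1, patience = 5)
  expect_lte(nrow(trainingLog(mp)), 10)
})
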