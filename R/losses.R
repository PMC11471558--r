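#' @include network.R
NULL

# Closed-form KL between diagonal Gaussian (mu, nu) and the standard normal.
klStdNormal <- function(mu, nu) 0.5 * sum(mu^2 + nu - log(nu) - 1)

bernoulliNll <- function(x, lambda, mask = NULL) {
  ll <- x * log(lambda) + (1 - x) * log1p(-lambda)
  if (!is.null(mask)) ll <- ll * mask
  -sum(ll)
}

poissonNll <- function(x, lambda, mask = NULL) {
  ll <- x * log(lambda) - lambda - lgamma(x + 1)
  if (!is.null(mask)) ll <- ll * mask
  -sum(ll)
}

#' Negative ELBO for one cell
#'
#' The per-cell training objective's likelihood part: the weighted batch-ID
#' log-likelihood plus the masked modality log-likelihoods (Bernoulli for
#' ATAC, Poisson for RNA/ADT), negated, plus the closed-form KL between the
#' joint diagonal-Gaussian posterior and the standard-normal prior.
#' Reconstruction is computed only over the cell's observed features.
#'
#' @param x named list of padded count vectors for the measured modalities.
#' @param lambda named list of decoded mean vectors (same shape).
#' @param masks named list of 0/1 masks (same shape).
#' @param s integer batch ID of the cell.
#' @param pi probability vector over batches from the batch decoder.
#' @param posterior list with `mu` and `nu` over the joint latent `z`.
#' @param gamma batch-likelihood weight.
#' @return scalar loss.
#' @export
elboLoss <- function(x, lambda, masks, s, pi, posterior, gamma = 1000) {
  rec <- 0
  for (m in names(x)) {
    rec <- rec + if (m == "ATAC")
      bernoulliNll(x[[m]], lambda[[m]], masks[[m]])
    else poissonNll(x[[m]], lambda[[m]], masks[[m]])
  }
  -gamma * log(pi[s]) + rec + klStdNormal(posterior$mu, posterior$nu)
}

#' Self-supervised modality alignment loss
#'
#' Penalizes the dispersion of the unimodal latent samples of one cell:
#' `alpha * sum_m ||z^m - mean(z)||^2`. Zero when a single modality is
#' measured or when all samples coincide.
#'
#' @param zList list of latent sample vectors, one per measured modality.
#' @param alpha loss weight.
#' @return scalar loss (non-negative).
#' @export
alignmentLoss <- function(zList, alpha = 50) {
  if (length(zList) <= 1L) return(0)
  zbar <- Reduce(`+`, zList) / length(zList)
  alpha * sum(vapply(zList, function(z) sum((z - zbar)^2), numeric(1)))
}

#' Information-bottleneck loss for one cell
#'
#' For the joint posterior and each measured modality's unimodal posterior,
#' adds `betaS * log p(s | c)` (the adversarial classifier likelihood, so
#' minimizing removes batch information from the biological state), plus
#' `betaX * KL[q(u) || N(0, I)]`, minus `betaX * log p(s | u)` (keeping
#' batch information in the technical noise). Classifier outputs are
#' evaluated at reparameterized latent samples by the caller; classifier
#' parameters are treated as frozen.
#'
#' @param joint list with `kappa` (classifier probability vector over
#'   batches evaluated at the sampled `c`), `uMu`/`uNu` (posterior of `u`),
#'   and `piU` (batch-decoder probabilities at the sampled `u`).
#' @param perModality list of such lists, one per measured modality.
#' @param s integer batch ID.
#' @param betaS,betaX IB weights.
#' @return scalar loss.
#' @export
ibLoss <- function(joint, perModality = list(), s, betaS = 30, betaX = 4) {
  term <- function(t) {
    if (abs(sum(t$kappa) - 1) > 1e-6 || any(t$kappa < 0))
      stop("classifier output is not a probability vector")
    betaS * log(t$kappa[s]) + betaX * klStdNormal(t$uMu, t$uNu) -
      betaX * log(t$piU[s])
  }
  sum(vapply(c(list(joint), perModality), term, numeric(1)))
}

#' Adversarial classifier loss for one cell
#'
#' Negative log-likelihood of the true batch under the joint classifier at
#' the sampled `c` plus, for each measured modality, under that modality's
#' classifier at the sampled `c^m`. Latent samples are detached: encoder
#' parameters receive no gradient from this loss.
#'
#' @param kappaJoint probability vector from the joint classifier.
#' @param kappaModalities list of probability vectors, one per modality.
#' @param s integer batch ID.
#' @return scalar loss (non-negative).
#' @export
classifierLoss <- function(kappaJoint, kappaModalities = list(), s) {
  -log(kappaJoint[s]) - sum(vapply(kappaModalities,
                                   function(k) log(k[s]), numeric(1)))
}
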