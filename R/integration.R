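## cQTL-eQTL integration: sharing fraction (pi1), effect-direction
## concordance, and Bayesian colocalization from Wakefield approximate
## Bayes factors with all accumulation in log space.

#' Shared fraction of cQTLs among eQTLs (pi1)
#'
#' For each significant cQTL, one matched eQTL p-value per gene is kept
#' (at random, or the most/least significant to bracket the estimate);
#' pi0 is estimated on the matched set by the Storey estimator and
#' pi1 = 1 - pi0 is the shared fraction.
#'
#' @param eqtlPByGene named list: per gene, the numeric eQTL p-values
#'   matched to a significant cQTL.
#' @param mode `"random"`, `"most-significant"` or `"least-significant"`.
#' @param seed integer seed (random mode).
#' @return list: `pi1`, `pi0`, `mode`, `n`.
#' @export
estimateSharedFraction <- function(eqtlPByGene,
                                   mode = c("random", "most-significant",
                                            "least-significant"),
                                   seed = 1) {
  mode <- match.arg(mode)
  if (!length(eqtlPByGene)) stop("empty matched eQTL set")
  pick <- withSeed(deriveSeed(seed, "sharedfrac"),
    vapply(eqtlPByGene, function(ps) {
      ps <- ps[!is.na(ps)]
      if (!length(ps)) return(NA_real_)
      switch(mode,
             "random" = ps[sample.int(length(ps), 1L)],
             "most-significant" = min(ps),
             "least-significant" = max(ps))
    }, 1))
  pick <- pick[!is.na(pick)]
  if (!length(pick)) stop("empty matched eQTL set")
  pi0 <- storeyQvalue(pick)$pi0
  list(pi1 = 1 - pi0, pi0 = pi0, mode = mode, n = length(pick))
}

#' Effect-direction concordance between paired QTL effects
#'
#' Pairs with the same sign (for the same tested allele) are concordant;
#' an exact two-sided binomial test compares the fraction to 0.5. Pairs
#' with a zero effect are excluded and counted.
#'
#' @param effectsA,effectsB signed effects, same length and allele
#'   orientation.
#' @return list: `fraction`, `nConcordant`, `n`, `p`, `nExcluded`.
#' @export
directionConcordance <- function(effectsA, effectsB) {
  stopifnot(length(effectsA) == length(effectsB))
  ok <- is.finite(effectsA) & is.finite(effectsB) &
    effectsA != 0 & effectsB != 0
  conc <- sign(effectsA[ok]) == sign(effectsB[ok])
  n <- sum(ok)
  if (!n) return(list(fraction = NA_real_, nConcordant = 0L, n = 0L,
                      p = NA_real_, nExcluded = sum(!ok)))
  bt <- binom.test(sum(conc), n, p = 0.5)
  list(fraction = mean(conc), nConcordant = sum(conc), n = n,
       p = bt$p.value, nExcluded = sum(!ok))
}

#' Wakefield log approximate Bayes factor
#'
#' With V = se^2, r = W/(V + W) and z = beta/se:
#' log ABF = 0.5 log(1 - r) + 0.5 z^2 r. Larger values favour a true
#' association under the N(0, W) effect prior.
#'
#' @param beta,se effect estimate and standard error (se > 0).
#' @param W prior variance of the true effect (> 0).
#' @return numeric log ABF (vectorized).
#' @export
wakefieldLogABF <- function(beta, se, W) {
  if (any(!is.finite(beta) | !is.finite(se) | !is.finite(W)))
    stop("non-finite inputs")
  if (any(se <= 0) || any(W <= 0)) stop("se and W must be positive")
  V <- se^2
  r <- W / (V + W)
  z <- beta / se
  0.5 * log(1 - r) + 0.5 * z^2 * r
}

#' Colocalization posterior probabilities (H0-H4)
#'
#' Per-SNP Wakefield log ABFs for the two traits are combined over the
#' single-causal-variant configurations: H1/H2 (one trait), H3 (two
#' distinct causal SNPs) and H4 (one shared causal SNP), weighted by the
#' priors p1, p2, p12, with all sums accumulated by log-sum-exp.
#'
#' @param trait1,trait2 data.frames over the same SNPs (same order or a
#'   shared `snp` column) with columns `beta` and `se`, or `z` (then
#'   `beta = z`, `se = 1`).
#' @param p1,p2,p12 prior probabilities that a SNP is causal for trait 1
#'   only, trait 2 only, or both.
#' @param W1,W2 effect prior variances (0.15^2 for quantitative traits,
#'   0.2^2 for case-control log odds are conventional).
#' @return [ColocResult-class].
#' @export
colocPP <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                    W1 = 0.15^2, W2 = 0.15^2) {
  s1 <- normalizeTraitStats(trait1)
  s2 <- normalizeTraitStats(trait2)
  if (!is.null(s1$snp) && !is.null(s2$snp)) {
    ord <- match(s1$snp, s2$snp)
    if (anyNA(ord)) stop("trait SNP sets differ")
    s2 <- s2[ord, , drop = FALSE]
  }
  if (nrow(s1) != nrow(s2)) stop("traits must cover the same SNPs")
  if (nrow(s1) < 2L) stop("need at least two SNPs")
  l1 <- wakefieldLogABF(s1$beta, s1$se, W1)
  l2 <- wakefieldLogABF(s2$beta, s2$se, W2)
  S1 <- logSumExp(l1)
  S2 <- logSumExp(l2)
  S12 <- logSumExp(l1 + l2)
  ## sum over ordered distinct pairs = S1 + S2 minus the diagonal
  Scross <- logDiffExp(S1 + S2, S12)
  lp <- c(H0 = 0,
          H1 = log(p1) + S1,
          H2 = log(p2) + S2,
          H3 = log(p1) + log(p2) + Scross,
          H4 = log(p12) + S12)
  pp <- exp(lp - logSumExp(lp))
  methods::new("ColocResult",
               pp = setNames(pp, paste0("PP", 0:4)),
               nSnps = nrow(s1),
               priors = c(p1 = p1, p2 = p2, p12 = p12),
               labf1 = l1, labf2 = l2)
}

## z-only input follows the standardized-trait approximation
## beta = z/sqrt(N), se = 1/sqrt(N) (phenotype variance 1)
normalizeTraitStats <- function(tr, defaultN = 1e4) {
  tr <- as.data.frame(tr)
  cn <- tolower(colnames(tr))
  colnames(tr) <- ifelse(cn %in% c("z", "beta", "se", "n", "snp"),
                         cn, colnames(tr))
  if (!("beta" %in% colnames(tr)) && "z" %in% colnames(tr)) {
    n <- if ("n" %in% colnames(tr)) tr$n else defaultN
    tr$beta <- tr$z / sqrt(n)
    tr$se <- 1 / sqrt(n)
  }
  if (!all(c("beta", "se") %in% colnames(tr)))
    stop("trait stats need beta/se or z")
  tr
}
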