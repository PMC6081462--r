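## Cis chromatin-QTL mapping: nominal scan in a 5 kb window about the
## peak center, beta-approximated permutation significance per peak,
## Storey q-values across peaks, diagnosis interaction, and allelic
## imbalance validation.

## standardize columns to mean 0 / unit norm; zero-variance columns -> 0
unitCols <- function(M) {
  M <- sweep(as.matrix(M), 2L, colMeans(M))
  nrm <- sqrt(colSums(M^2))
  sweep(M, 2L, pmax(nrm, 1e-300), "/")
}

#' Nominal cis scan
#'
#' For each peak, SNPs within `window` bp of the peak center (inclusive at
#' exactly `window`) are tested by simple regression of the residualized
#' phenotype on residualized dosage (covariates regressed out once). The
#' most significant SNP is retained; ties break to the SNP nearest the
#' center, then lexicographically.
#'
#' @param pheno peaks x samples matrix of normalized accessibility (e.g.
#'   [logCPM()] rows); rownames must match peak names.
#' @param peaks GRanges with `summit` (cis anchor = summit/center).
#' @param dosages samples x SNPs matrix.
#' @param snpMap data.frame snp, chrom, pos.
#' @param window cis window (bp).
#' @param covariates samples x k matrix (e.g. phenotype PCs + ancestry
#'   PCs) or NULL.
#' @return data.frame: peak, nSnps, snp, distance, beta, se, p. Peaks with
#'   no cis SNP get NA results.
#' @export
mapCis <- function(pheno, peaks, dosages, snpMap, window = 5000,
                   covariates = NULL) {
  if (window < 0) stop("window must be >= 0")
  Y <- residualize(t(as.matrix(pheno)), covariates)  # samples x peaks
  D <- residualize(as.matrix(dosages), covariates)
  n <- nrow(Y)
  df <- n - 2L - (if (is.null(covariates)) 0L else ncol(as.matrix(covariates)))
  center <- peaks$summit %||%
    floor((GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2)
  chrom <- as.character(GenomeInfoDb::seqnames(peaks))
  out <- data.frame(peak = names(peaks), nSnps = 0L, snp = NA_character_,
                    distance = NA_integer_, beta = NA_real_,
                    se = NA_real_, p = NA_real_)
  for (i in seq_along(peaks)) {
    cis <- which(snpMap$chrom == chrom[i] &
                 abs(snpMap$pos - center[i]) <= window)
    out$nSnps[i] <- length(cis)
    if (!length(cis)) next
    y <- Y[, i]
    d <- D[, cis, drop = FALSE]
    sxx <- colSums(d^2)
    sxy <- drop(crossprod(d, y))
    beta <- sxy / pmax(sxx, 1e-300)
    rss <- sum(y^2) - beta * sxy
    se <- sqrt(pmax(rss, 0) / df / pmax(sxx, 1e-300))
    tt <- beta / se
    p <- 2 * pt(-abs(tt), df)
    dist <- abs(snpMap$pos[cis] - center[i])
    ord <- order(p, dist, snpMap$snp[cis])
    b <- ord[1L]
    out$snp[i] <- snpMap$snp[cis[b]]
    out$distance[i] <- snpMap$pos[cis[b]] - center[i]
    out$beta[i] <- beta[b]; out$se[i] <- se[b]; out$p[i] <- p[b]
  }
  out
}

## Beta(a,b) maximum likelihood on (0,1) data: method-of-moments start,
## Newton refinement on the digamma score equations.
betaMLE <- function(x, tol = 1e-8, maxIter = 100) {
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  m <- mean(x); v <- var(x)
  if (v <= 0) return(c(a = NA_real_, b = NA_real_))
  f <- m * (1 - m) / v - 1
  theta <- pmax(c(m * f, (1 - m) * f), 1e-3)
  s1 <- mean(log(x)); s2 <- mean(log1p(-x))
  for (it in seq_len(maxIter)) {
    a <- theta[1L]; b <- theta[2L]
    dga <- digamma(a + b)
    g <- c(dga - digamma(a) + s1, dga - digamma(b) + s2)
    tg <- trigamma(a + b)
    H <- matrix(c(tg - trigamma(a), tg, tg, tg - trigamma(b)), 2L)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    new <- theta - step
    if (any(new <= 0)) new <- pmax(theta - 0.5 * step, theta / 2)
    if (max(abs(new - theta)) < tol * (1 + max(abs(theta)))) {
      theta <- new; break
    }
    theta <- new
  }
  c(a = theta[1L], b = theta[2L])
}

#' Beta-approximated permutation adjustment for one peak
#'
#' Permutes the residualized phenotype `nPerm` times, records the minimum
#' nominal p across cis SNPs per permutation, fits Beta(a, b) by maximum
#' likelihood, and returns the Beta CDF evaluated at the observed minimum
#' nominal p. A degenerate permutation distribution falls back to the
#' empirical permutation p with a flag.
#'
#' @param y phenotype vector for the peak.
#' @param D samples x cis-SNPs dosage matrix (>= 1 SNP).
#' @param covariates covariate matrix or NULL.
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list: `aHat`, `bHat`, `nominalP`, `adjustedP`, `empiricalP`,
#'   `degenerate`.
#' @export
permAdjust <- function(y, D, covariates = NULL, nPerm = 1000, seed = 1) {
  if (nPerm < 100) stop("nPerm must be >= 100")
  D <- as.matrix(D)
  if (!ncol(D)) stop("need at least one cis SNP")
  yr <- drop(residualize(y, covariates))
  Dr <- residualize(D, covariates)
  n <- length(yr)
  df <- n - 2L - (if (is.null(covariates)) 0L
                  else ncol(as.matrix(covariates)))
  Du <- unitCols(Dr)
  minPOf <- function(Ymat) {
    Yu <- unitCols(Ymat)
    r <- crossprod(Du, Yu)                      # K x nCol correlations
    r2 <- pmin(r^2, 1 - 1e-12)
    tt <- sqrt(df) * abs(r) / sqrt(1 - r2)
    apply(2 * pt(-tt, df), 2L, min)
  }
  nominal <- minPOf(matrix(yr, ncol = 1L))
  perms <- withSeed(deriveSeed(seed, "permadjust"),
    vapply(seq_len(nPerm), function(i) sample(yr), yr))
  permMin <- minPOf(perms)
  empirical <- (1 + sum(permMin <= nominal)) / (1 + nPerm)
  if (sd(permMin) < 1e-12) {
    return(list(aHat = NA_real_, bHat = NA_real_, nominalP = nominal,
                adjustedP = empirical, empiricalP = empirical,
                degenerate = TRUE))
  }
  ab <- betaMLE(permMin)
  if (anyNA(ab) || any(ab <= 0)) {
    return(list(aHat = NA_real_, bHat = NA_real_, nominalP = nominal,
                adjustedP = empirical, empiricalP = empirical,
                degenerate = TRUE))
  }
  list(aHat = unname(ab["a"]), bHat = unname(ab["b"]),
       nominalP = nominal,
       adjustedP = pbeta(nominal, ab["a"], ab["b"]),
       empiricalP = empirical, degenerate = FALSE)
}

#' Full per-peak cQTL scan with permutation adjustment
#'
#' Runs [mapCis()] and [permAdjust()] for every peak with at least one cis
#' SNP, then Storey q-values across peaks.
#'
#' @inheritParams mapCis
#' @param nPerm,seed permutation controls.
#' @return data.frame: mapCis columns + aHat, bHat, adjustedP, q.
#' @export
cqtlScan <- function(pheno, peaks, dosages, snpMap, window = 5000,
                     covariates = NULL, nPerm = 1000, seed = 1) {
  nom <- mapCis(pheno, peaks, dosages, snpMap, window, covariates)
  nom$aHat <- NA_real_; nom$bHat <- NA_real_; nom$adjustedP <- NA_real_
  center <- peaks$summit %||%
    floor((GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2)
  chrom <- as.character(GenomeInfoDb::seqnames(peaks))
  Y <- t(as.matrix(pheno))
  for (i in seq_along(peaks)) {
    if (nom$nSnps[i] == 0L) next
    cis <- which(snpMap$chrom == chrom[i] &
                 abs(snpMap$pos - center[i]) <= window)
    pa <- permAdjust(Y[, i], dosages[, cis, drop = FALSE], covariates,
                     nPerm = nPerm, seed = deriveSeed(seed, i))
    nom$aHat[i] <- pa$aHat; nom$bHat[i] <- pa$bHat
    nom$adjustedP[i] <- pa$adjustedP
  }
  ok <- !is.na(nom$adjustedP)
  nom$q <- NA_real_
  if (sum(ok) >= 2L) {
    sq <- storeyQvalue(nom$adjustedP[ok])
    nom$q[ok] <- sq$q
    attr(nom, "pi0") <- sq$pi0
  }
  nom
}

#' Storey q-values
#'
#' pi0 is estimated on the lambda grid via `mean(p > lambda)/(1 - lambda)`
#' with a cubic smoothing spline extrapolated to the last grid point,
#' clipped to (0, 1]; q-values are pi0 times the BH step-up.
#'
#' @param p p-values in [0,1].
#' @param lambdaGrid grid for pi0 estimation.
#' @param pi0 optional forced pi0 (1 reproduces BH exactly).
#' @return list: `q`, `pi0`.
#' @export
storeyQvalue <- function(p, lambdaGrid = seq(0.05, 0.95, by = 0.05),
                         pi0 = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  m <- sum(!is.na(p))
  if (is.null(pi0)) {
    if (m < 100) {
      warning("fewer than 100 p-values; falling back to pi0 = 1 (BH)")
      pi0 <- 1
    } else {
      pl <- vapply(lambdaGrid, function(l)
        mean(p > l, na.rm = TRUE) / (1 - l), 1)
      fit <- smooth.spline(lambdaGrid, pl, df = 3)
      pi0 <- predict(fit, x = max(lambdaGrid))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  q <- pi0 * bhFDR(p)
  list(q = pmin(q, 1), pi0 = pi0)
}

#' Diagnosis-interaction scan at cQTL SNPs
#'
#' For each (peak, SNP) pair the model accessibility ~ dosage + diagnosis
#' + dosage:diagnosis is fit on the residualized phenotype; significance
#' of the interaction comes from permuting diagnosis labels. Exact
#' permutation p = (1 + #[|t_perm| >= |t_obs|]) / (1 + nPerm), Storey q
#' across peaks.
#'
#' @param pheno peaks x samples matrix.
#' @param peakSnp data.frame peak, snp (e.g. top SNPs from [cqtlScan()]).
#' @param dosages samples x SNPs matrix.
#' @param diagnosis character/factor with both levels present.
#' @param covariates covariate matrix or NULL.
#' @param nPerm,seed permutation controls.
#' @return data.frame: peak, snp, tObs, p, q.
#' @export
interactionScan <- function(pheno, peakSnp, dosages, diagnosis,
                            covariates = NULL, nPerm = 10000, seed = 1) {
  dx <- as.numeric(factor(diagnosis)) - 1
  if (length(unique(dx)) < 2L) stop("both diagnosis levels required")
  Y <- residualize(t(as.matrix(pheno)), covariates)
  out <- data.frame(peak = peakSnp$peak, snp = peakSnp$snp,
                    tObs = NA_real_, p = NA_real_)
  tStat <- function(y, d, g) {
    X <- cbind(1, d, g, d * g)
    qx <- qr(X)
    if (qx$rank < 4L) return(NA_real_)
    cf <- qr.coef(qx, y)
    res <- y - X %*% cf
    s2 <- sum(res^2) / (length(y) - 4L)
    XtXinv <- chol2inv(qr.R(qx))
    cf[4L] / sqrt(s2 * XtXinv[4L, 4L])
  }
  for (i in seq_len(nrow(out))) {
    if (is.na(out$snp[i])) next
    y <- Y[, match(out$peak[i], colnames(Y))]
    d <- dosages[, out$snp[i]]
    t0 <- tStat(y, d, dx)
    if (is.na(t0)) next
    perms <- withSeed(deriveSeed(seed, paste0("ixn", i)),
      vapply(seq_len(nPerm), function(k) tStat(y, d, sample(dx)), 1))
    out$tObs[i] <- t0
    out$p[i] <- (1 + sum(abs(perms) >= abs(t0), na.rm = TRUE)) / (1 + nPerm)
  }
  ok <- !is.na(out$p)
  out$q <- NA_real_
  if (sum(ok) >= 2L) out$q[ok] <- storeyQvalue(out$p[ok])$q
  out
}

#' Allelic imbalance analysis at cQTL SNPs
#'
#' Concordance: fraction of cQTL SNPs whose mean heterozygote alt-read
#' fraction deviates from 0.5 in the direction of the cQTL effect for the
#' alt allele. Distributional test: Pearson chi-squared comparing binned
#' alt-fraction histograms of cQTL versus non-cQTL heterozygote records
#' (bins right-closed on 0, 0.1, ..., 1).
#'
#' @param records data.frame snp, sample, ref, alt (one row per
#'   heterozygote x SNP).
#' @param cqtlEffects data.frame snp, beta: significant cQTLs and their
#'   alt-allele effects; SNPs absent from it count as non-cQTL.
#' @param minDepth minimum reads (ref + alt) for a record to be used.
#' @param nBins number of alt-fraction histogram bins.
#' @return list: `concordance`, `nConcordant`, `nCqtlSnps`, `chisq`, `p`,
#'   `perSnp`, `skipped`.
#' @export
alleleBiasAnalysis <- function(records, cqtlEffects, minDepth = 10,
                               nBins = 10) {
  depth <- records$ref + records$alt
  use <- records[depth >= minDepth, , drop = FALSE]
  use$frac <- use$alt / (use$ref + use$alt)
  use$isCqtl <- use$snp %in% cqtlEffects$snp
  perSnp <- do.call(rbind, lapply(split(use, use$snp), function(d)
    data.frame(snp = d$snp[1L], nHet = nrow(d),
               meanAltFrac = mean(d$frac), isCqtl = d$isCqtl[1L])))
  skipped <- sum(!cqtlEffects$snp %in% perSnp$snp)
  cq <- perSnp[perSnp$isCqtl, , drop = FALSE]
  beta <- cqtlEffects$beta[match(cq$snp, cqtlEffects$snp)]
  signal <- sign(cq$meanAltFrac - 0.5) != 0 & sign(beta) != 0
  nConc <- sum(sign(cq$meanAltFrac - 0.5) == sign(beta) & signal)
  concordance <- if (sum(signal)) nConc / sum(signal) else NA_real_
  breaks <- seq(0, 1, length.out = nBins + 1L)
  binOf <- function(f) pmax(1L, findInterval(f, breaks, left.open = TRUE,
                                             rightmost.closed = TRUE))
  tab <- table(factor(binOf(use$frac), levels = seq_len(nBins)),
               factor(use$isCqtl, levels = c(FALSE, TRUE)))
  keep <- rowSums(tab) > 0
  ct <- suppressWarnings(stats::chisq.test(tab[keep, , drop = FALSE],
                                           correct = FALSE))
  list(concordance = concordance, nConcordant = nConc,
       nCqtlSnps = sum(perSnp$isCqtl), chisq = unname(ct$statistic),
       p = unname(ct$p.value), perSnp = perSnp, skipped = skipped)
}
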