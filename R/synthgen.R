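## Synthetic study generator: every downstream stage (quantification, QC,
## covariate selection, differential accessibility, cQTL, colocalization,
## heritability partitioning) can be exercised against known ground truth
## without access to controlled cohort data.

#' Simulate a small genome layout
#'
#' Builds a toy genome with `nAutosomes` autosomes plus chrX and chrY
#' (chrY at half length), a TSS catalogue with expression-quartile labels
#' Q0..Q4, a mappability track and a blacklist. All intervals are 0-based
#' half-open internally via GRanges (1-based closed), within chromosome
#' bounds, and merged (mappable and blacklist are each non-overlapping).
#'
#' @param nAutosomes number of autosomes (>= 1).
#' @param chromLength autosome length in bp (>= 10 kb).
#' @param nTss total number of transcription start sites.
#' @param blacklistFraction fraction of the genome blacklisted, in [0, 0.5).
#' @param seed integer seed; the layout is a pure function of the arguments.
#' @return A `GenomeLayout`: list with `chromosomes` (data.frame name,
#'   length), `tss` (GRanges, strand and `quartile`), `mappable` and
#'   `blacklist` (GRanges), `seqinfo`.
#' @examples
#' gl <- simulateGenome(2, 1e6, 100, 0.02, seed = 1)
#' nrow(gl$chromosomes)  # 4: two autosomes + chrX + chrY
#' @export
simulateGenome <- function(nAutosomes = 2, chromLength = 1e6, nTss = 100,
                           blacklistFraction = 0.02, seed = 1) {
  if (nAutosomes < 1 || chromLength < 1e4 || nTss < 1)
    stop("invalid dimensions: need nAutosomes >= 1, chromLength >= 10kb, nTss >= 1")
  if (blacklistFraction < 0 || blacklistFraction >= 0.5)
    stop("blacklistFraction must lie in [0, 0.5)")
  withSeed(deriveSeed(seed, "genome"), {
    chroms <- data.frame(
      name = c(paste0("chr", seq_len(nAutosomes)), "chrX", "chrY"),
      length = c(rep(chromLength, nAutosomes), chromLength,
                 round(chromLength / 2)))
    si <- GenomeInfoDb::Seqinfo(seqnames = chroms$name,
                                 seqlengths = chroms$length)
    ## TSS: proportional to chromosome length, sorted per chromosome
    wts <- chroms$length / sum(chroms$length)
    nPer <- as.vector(stats::rmultinom(1, nTss, wts))
    tss <- do.call(c, lapply(seq_len(nrow(chroms)), function(i) {
      if (nPer[i] == 0) return(GenomicRanges::GRanges(seqinfo = si))
      pos <- sort(sample.int(chroms$length[i] - 2000L, nPer[i])) + 1000L
      GenomicRanges::GRanges(chroms$name[i],
                             IRanges::IRanges(pos, width = 1L),
                             strand = sample(c("+", "-"), nPer[i], TRUE),
                             seqinfo = si)
    }))
    tss$quartile <- paste0("Q", sample(0:4, length(tss), TRUE))
    blacklist <- randomIntervals(chroms, blacklistFraction,
                                 meanLen = 2000L, si = si)
    unmappable <- randomIntervals(chroms, 0.05, meanLen = 5000L, si = si)
    mappable <- GenomicRanges::reduce(GenomicRanges::setdiff(
      GenomicRanges::GRanges(chroms$name,
                             IRanges::IRanges(1L, chroms$length),
                             seqinfo = si),
      unmappable))
    structure(list(chromosomes = chroms, tss = sort(tss),
                   mappable = mappable, blacklist = blacklist,
                   seqinfo = si),
              class = "GenomeLayout")
  })
}

## random merged interval set covering ~`fraction` of the genome
randomIntervals <- function(chroms, fraction, meanLen, si) {
  if (fraction <= 0)
    return(GenomicRanges::GRanges(seqinfo = si))
  total <- sum(chroms$length)
  n <- max(1L, round(total * fraction / meanLen))
  wts <- chroms$length / total
  idx <- sample.int(nrow(chroms), n, TRUE, prob = wts)
  len <- pmax(100L, round(stats::rexp(n, 1 / meanLen)))
  start <- vapply(seq_len(n), function(k)
    sample.int(max(1L, chroms$length[idx[k]] - len[k]), 1L), 1L)
  gr <- GenomicRanges::GRanges(chroms$name[idx],
                               IRanges::IRanges(start, width = len),
                               seqinfo = si)
  GenomicRanges::reduce(GenomicRanges::trim(gr))
}

#' Simulate fixed-width peaks on a genome layout
#'
#' Peaks are width-bp intervals centered on a summit, non-overlapping,
#' placed inside the mappable track and outside the blacklist. A fraction
#' is placed within 2 kb of a TSS, the rest uniformly. chrY receives a
#' small share of peaks (male-specific signal downstream).
#'
#' @param layout a `GenomeLayout` from [simulateGenome()].
#' @param nPeaks number of peaks requested (collisions are dropped, so the
#'   returned set can be slightly smaller).
#' @param width peak width in bp.
#' @param fracNearTss fraction of peaks placed TSS-proximal.
#' @param seed integer seed.
#' @return GRanges with metadata columns `summit` and `support`.
#' @export
simulatePeaks <- function(layout, nPeaks = 1000, width = 300,
                          fracNearTss = 0.3, seed = 1) {
  withSeed(deriveSeed(seed, "peaks"), {
    chroms <- layout$chromosomes
    nNear <- round(nPeaks * fracNearTss)
    nFar <- nPeaks - nNear
    tssPos <- GenomicRanges::start(layout$tss)
    tssChr <- as.character(GenomeInfoDb::seqnames(layout$tss))
    iN <- sample.int(length(tssPos), nNear, replace = TRUE)
    nearSummit <- tssPos[iN] + sample(-2000:2000, nNear, TRUE)
    wts <- chroms$length / sum(chroms$length)
    iC <- sample.int(nrow(chroms), nFar, TRUE, prob = wts)
    farSummit <- vapply(iC, function(k)
      width + sample.int(chroms$length[k] - 2L * width, 1L), 1)
    summit <- c(nearSummit, farSummit)
    chr <- c(tssChr[iN], chroms$name[iC])
    ok <- summit > width & summit < chroms$length[match(chr, chroms$name)] - width
    summit <- summit[ok]; chr <- chr[ok]
    half <- floor(width / 2)
    gr <- GenomicRanges::GRanges(chr,
      IRanges::IRanges(summit - half + 1L, width = width),
      seqinfo = layout$seqinfo)
    gr$summit <- as.integer(summit)
    ## drop blacklist hits and self-overlaps (keep first of each cluster)
    gr <- gr[!IRanges::overlapsAny(gr, layout$blacklist)]
    gr <- sort(gr)
    keep <- !duplicated(GenomicRanges::findOverlaps(gr, GenomicRanges::reduce(gr),
                                                    select = "first"))
    gr <- gr[keep]
    gr$support <- sample(2:10, length(gr), TRUE)
    names(gr) <- peakIds(gr)
    gr
  })
}

#' Simulate sample metadata
#'
#' Case-control diagnosis, sex, age at death, postmortem interval, brain
#' bank batch and assay-technical covariates (GC content, RIN, enrichment
#' score) with realistic postmortem-cohort marginals.
#'
#' @param nSamples number of samples.
#' @param caseFraction fraction of schizophrenia cases.
#' @param seed integer seed.
#' @return data.frame keyed by `sample`.
#' @export
simulateMetadata <- function(nSamples = 288, caseFraction = 0.47, seed = 1) {
  withSeed(deriveSeed(seed, "metadata"), {
    nCase <- round(nSamples * caseFraction)
    dx <- sample(c(rep("case", nCase), rep("control", nSamples - nCase)))
    data.frame(
      sample = sprintf("S%03d", seq_len(nSamples)),
      diagnosis = dx,
      sex = sample(c("M", "F"), nSamples, TRUE, prob = c(0.6, 0.4)),
      age = pmin(pmax(round(rnorm(nSamples, 73, 14)), 20), 105),
      pmi = round(stats::rgamma(nSamples, shape = 4, scale = 4), 1),
      batch = sample(paste0("B", 1:4), nSamples, TRUE),
      gc_content = round(rnorm(nSamples, 41, 1.5), 2),
      rin = round(pmin(pmax(rnorm(nSamples, 7, 1), 2), 10), 1),
      enrich_score = round(stats::rlnorm(nSamples, log(2.9), 0.3), 2),
      stringsAsFactors = FALSE)
  })
}

#' Simulate genotype dosages with block LD
#'
#' Block-exchangeable latent-haplotype construction: within each block of
#' `blockSize` consecutive SNPs, each of the two haplotypes follows an
#' AR(1) latent Gaussian (autocorrelation `ar`), thresholded at the
#' allele-frequency quantile; dosage is the sum of the two haplotypes.
#' Pairwise r-squared therefore decays geometrically with SNP distance
#' within a block and is ~0 across blocks.
#'
#' @param nSamples,nSnps dimensions.
#' @param blockSize SNPs per LD block (>= 1; `blockSize = 1` gives
#'   independent SNPs).
#' @param mafLow,mafHigh per-SNP minor allele frequency range (0 < low <=
#'   high <= 0.5).
#' @param seed integer seed.
#' @param layout optional `GenomeLayout`; SNPs are spread over its
#'   autosomes. Without a layout a single pseudo-chromosome with 1 kb
#'   spacing is used.
#' @param ar within-block haplotype autocorrelation.
#' @return list with `dosage` (nSamples x nSnps matrix in [0,2]) and
#'   `map` (data.frame snp, chrom, pos, block).
#' @export
simulateGenotypes <- function(nSamples, nSnps, blockSize = 10,
                              mafLow = 0.05, mafHigh = 0.5, seed = 1,
                              layout = NULL, ar = 0.9) {
  if (mafLow <= 0 || mafLow > mafHigh || mafHigh > 0.5)
    stop("need 0 < mafLow <= mafHigh <= 0.5")
  if (blockSize < 1) stop("blockSize must be >= 1")
  if (nSnps < blockSize) stop("nSnps must be >= blockSize")
  withSeed(deriveSeed(seed, "genotypes"), {
    maf <- runif(nSnps, mafLow, mafHigh)
    thr <- qnorm(maf)
    block <- rep(seq_len(ceiling(nSnps / blockSize)),
                 each = blockSize)[seq_len(nSnps)]
    newBlock <- c(TRUE, diff(block) != 0)
    hap <- function() {
      Z <- matrix(0, nSamples, nSnps)
      for (j in seq_len(nSnps)) {
        Z[, j] <- if (newBlock[j]) rnorm(nSamples)
                  else ar * Z[, j - 1L] + sqrt(1 - ar^2) * rnorm(nSamples)
      }
      Z
    }
    dosage <- (hap() < rep(thr, each = nSamples)) +
              (hap() < rep(thr, each = nSamples))
    mode(dosage) <- "numeric"
    map <- snpPositions(nSnps, layout)
    map$block <- block
    colnames(dosage) <- map$snp
    rownames(dosage) <- sprintf("S%03d", seq_len(nSamples))
    list(dosage = dosage, map = map)
  })
}

snpPositions <- function(nSnps, layout) {
  if (is.null(layout)) {
    return(data.frame(snp = sprintf("rs%06d", seq_len(nSnps)),
                      chrom = "chr1",
                      pos = seq_len(nSnps) * 1000L))
  }
  auto <- layout$chromosomes[grepl("^chr[0-9]+$", layout$chromosomes$name), ]
  nPer <- diff(round(seq(0, nSnps, length.out = nrow(auto) + 1L)))
  chrom <- rep(auto$name, nPer)
  pos <- unlist(lapply(seq_len(nrow(auto)), function(i) {
    spacing <- max(1L, floor((auto$length[i] - 2000L) / max(nPer[i], 1L)))
    seq_len(nPer[i]) * spacing
  }), use.names = FALSE)
  data.frame(snp = sprintf("rs%06d", seq_len(nSnps)), chrom = chrom,
             pos = as.integer(pos))
}

#' Assemble a ground-truth effect set
#'
#' Assigns diagnosis log2 fold changes to `nDxPeaks` random peaks, age and
#' PMI slopes genome-wide, and a cis-cQTL effect (per alt allele, natural
#' log scale) to `nCqtlPeaks` peaks, each coupled to the SNP nearest its
#' summit within `window` bp (peaks without such a SNP are skipped).
#'
#' @param peaks GRanges of peaks (with `summit`).
#' @param snpMap SNP map from [simulateGenotypes()].
#' @param nDxPeaks,dxLog2FC number/size of case-control effects.
#' @param nCqtlPeaks,cqtlBeta number/size of cQTL effects (log per allele).
#' @param ageSlopeSD,pmiSlopeSD SDs of per-peak covariate slopes (log scale
#'   per year / per hour); 0 disables.
#' @param window cis window (bp, summit to SNP).
#' @param seed integer seed.
#' @return list: `peakEffects` (data.frame peak, dxLog2FC, ageSlope,
#'   pmiSlope), `cqtlMap` (data.frame peak, snp, beta), bookkeeping in
#'   attributes.
#' @export
simulateTruth <- function(peaks, snpMap, nDxPeaks = 0, dxLog2FC = 1.5,
                          nCqtlPeaks = 0, cqtlBeta = 0.5,
                          ageSlopeSD = 0, pmiSlopeSD = 0,
                          window = 5000, seed = 1) {
  withSeed(deriveSeed(seed, "truth"), {
    n <- length(peaks)
    pe <- data.frame(peak = names(peaks),
                     dxLog2FC = 0, ageSlope = 0, pmiSlope = 0)
    if (nDxPeaks > 0) {
      idx <- sample.int(n, min(nDxPeaks, n))
      pe$dxLog2FC[idx] <- sample(c(-1, 1), length(idx), TRUE) * dxLog2FC
    }
    if (ageSlopeSD > 0) pe$ageSlope <- rnorm(n, 0, ageSlopeSD)
    if (pmiSlopeSD > 0) pe$pmiSlope <- rnorm(n, 0, pmiSlopeSD)
    cq <- data.frame(peak = character(), snp = character(),
                     beta = numeric())
    if (nCqtlPeaks > 0) {
      cand <- sample.int(n)
      taken <- 0L
      for (i in cand) {
        if (taken >= nCqtlPeaks) break
        chr <- as.character(GenomeInfoDb::seqnames(peaks[i]))
        d <- abs(snpMap$pos - peaks$summit[i])
        d[snpMap$chrom != chr] <- Inf
        j <- which.min(d)
        if (is.finite(d[j]) && d[j] <= window) {
          cq <- rbind(cq, data.frame(peak = names(peaks)[i],
                                     snp = snpMap$snp[j],
                                     beta = sample(c(-1, 1), 1) * cqtlBeta))
          taken <- taken + 1L
        }
      }
    }
    list(peakEffects = pe, cqtlMap = cq)
  })
}

#' Simulate the peak count matrix
#'
#' Counts are negative binomial with log mean = peak baseline + sample
#' library offset + diagnosis/age/PMI effects + cQTL dosage term from the
#' truth set. chrY peaks are male-only: female chrY counts are fixed at 0.
#'
#' @param layout `GenomeLayout`.
#' @param peaks GRanges of standardized peaks.
#' @param genotypes output of [simulateGenotypes()] (or NULL when the truth
#'   has no cQTL effects).
#' @param truth output of [simulateTruth()].
#' @param metadata data.frame from [simulateMetadata()]; row order defines
#'   sample order and must match the dosage rows when genotypes are given.
#' @param dispersion NB dispersion alpha (var = mu + alpha mu^2), > 0.
#' @param meanDepth expected reads per peak per sample, > 0.
#' @param backgroundFraction fraction of each library falling outside
#'   peaks; inflates `lib_size` above the in-peak column sums.
#' @param libSizeSD SD of the per-sample log library offset; 0 gives
#'   equal offsets (the Poisson-limit setting).
#' @param seed integer seed.
#' @return [ChromAccExperiment-class] with metadata merged into colData.
#' @export
simulateCounts <- function(layout, peaks, genotypes, truth, metadata,
                           dispersion = 0.2, meanDepth = 50,
                           backgroundFraction = 0.25, libSizeSD = 0.3,
                           seed = 1) {
  if (dispersion <= 0 || meanDepth <= 0)
    stop("dispersion and meanDepth must be positive")
  pe <- truth$peakEffects
  if (!all(pe$peak %in% names(peaks)))
    stop("truth references unknown peak(s)")
  if (nrow(truth$cqtlMap)) {
    if (is.null(genotypes)) stop("cQTL truth requires genotypes")
    if (!all(truth$cqtlMap$snp %in% colnames(genotypes$dosage)))
      stop("truth references unknown SNP(s)")
  }
  withSeed(deriveSeed(seed, "counts"), {
    n <- nrow(metadata); m <- length(peaks)
    base <- rnorm(m, log(meanDepth), 0.6)
    libOff <- if (libSizeSD > 0) rnorm(n, 0, libSizeSD) else rep(0, n)
    isCase <- as.numeric(metadata$diagnosis == "case")
    ageC <- metadata$age - mean(metadata$age)
    pmiC <- metadata$pmi - mean(metadata$pmi)
    ord <- match(pe$peak, names(peaks))
    eff <- matrix(0, m, n)
    eff[ord, ] <- outer(pe$dxLog2FC * log(2), isCase) +
      outer(pe$ageSlope, ageC) + outer(pe$pmiSlope, pmiC)
    if (nrow(truth$cqtlMap)) {
      ri <- match(truth$cqtlMap$peak, names(peaks))
      D <- genotypes$dosage[, truth$cqtlMap$snp, drop = FALSE]
      eff[ri, ] <- eff[ri, ] + t(D) * truth$cqtlMap$beta
    }
    logmu <- base + eff + rep(libOff, each = m)
    mu <- exp(logmu)
    cts <- matrix(rnbinom(m * n, mu = mu, size = 1 / dispersion), m, n)
    ## male-only chrY signal
    chrY <- as.character(GenomeInfoDb::seqnames(peaks)) == "chrY"
    if (any(chrY)) cts[chrY, metadata$sex == "F"] <- 0L
    colnames(cts) <- metadata$sample
    lib <- round(colSums(cts) / (1 - backgroundFraction))
    ChromAccExperiment(cts, peaks, libSize = lib, colData = metadata)
  })
}

#' Simulate per-sample fragment placements consistent with a count matrix
#'
#' For each (peak, sample) count, fragment midpoints are drawn from a
#' triangular density peaking at the summit (center-concentrated signal);
#' background fragments (lib_size minus in-peak totals) are uniform over
#' the mappable genome.
#'
#' @param layout `GenomeLayout`.
#' @param cae [ChromAccExperiment-class] from [simulateCounts()].
#' @param fragLen emitted fragment length in bp.
#' @param seed integer seed.
#' @return named list (one per sample) of data.frames chrom/start/end
#'   (0-based half-open, BED3 convention).
#' @export
simulateFragments <- function(layout, cae, fragLen = 50, seed = 1) {
  withSeed(deriveSeed(seed, "fragments"), {
    pk <- SummarizedExperiment::rowRanges(cae)
    cts <- counts(cae)
    w <- GenomicRanges::width(pk)
    chrom <- as.character(GenomeInfoDb::seqnames(pk))
    mp <- layout$mappable
    mpw <- GenomicRanges::width(mp)
    lapply(setNames(seq_len(ncol(cts)), colnames(cts)), function(k) {
      cnt <- cts[, k]
      tot <- sum(cnt)
      idx <- rep.int(seq_along(cnt), cnt)
      ## triangular about the summit: sum of two uniforms on [-w/2, w/2]/2
      off <- round((runif(tot) + runif(tot) - 1) * w[idx] / 2)
      mid <- pk$summit[idx] + off
      nbg <- max(0L, round(libSizes(cae)[k] - tot))
      bgSeg <- sample.int(length(mp), nbg, TRUE, prob = mpw)
      bgMid <- GenomicRanges::start(mp)[bgSeg] +
        floor(runif(nbg) * mpw[bgSeg])
      start0 <- pmax(0L, c(mid, bgMid) - round(fragLen / 2))
      df <- data.frame(chrom = c(chrom[idx],
                                 as.character(GenomeInfoDb::seqnames(mp))[bgSeg]),
                       start = as.integer(start0),
                       end = as.integer(start0 + fragLen))
      df[order(df$chrom, df$start), ]
    })
  })
}

#' Simulate GWAS summary statistics under a partitioned-heritability model
#'
#' Per-SNP standardized effects are drawn with variance
#' `sum_c tau[c] * a[j,c]`; marginal z-scores are formed through the
#' reference-panel LD, `z = sqrt(N) R beta + e` with `e` having the panel's
#' LD correlation, so that `E[chi2_j] = N * sum_c tau_c l(j,c) + 1` — the
#' model the stratified regression fits.
#'
#' @param genotypes reference panel from [simulateGenotypes()].
#' @param annotations binary SNP x category matrix (include a base column
#'   of ones); row count must equal the number of SNPs.
#' @param tau named per-category per-SNP heritability coefficients (>= 0).
#' @param nGwas GWAS sample size.
#' @param windowBp LD band applied to the signal term; match the LD-score
#'   window used downstream.
#' @param seed integer seed.
#' @return data.frame SNP, CHR, BP, A1, A2, Z, N.
#' @export
simulateGWAS <- function(genotypes, annotations, tau, nGwas,
                         windowBp = 1e6, seed = 1) {
  A <- as.matrix(annotations)
  M <- ncol(genotypes$dosage)
  if (nrow(A) != M) stop("annotation/SNP mismatch")
  if (any(tau < 0) || nGwas <= 0) stop("tau must be >= 0 and nGwas > 0")
  if (length(tau) != ncol(A)) stop("tau length must match categories")
  map <- genotypes$map
  withSeed(deriveSeed(seed, "gwas"), {
    X <- scale(genotypes$dosage)
    X[is.na(X)] <- 0
    nref <- nrow(X)
    v <- as.vector(A %*% tau)
    beta <- rnorm(M, 0, sqrt(pmax(v, 0)))
    ## signal through panel LD, banded to the window so that spurious
    ## long-range sample correlations do not inflate chi2
    Rb <- numeric(M)
    chunk <- 500L
    for (chr in unique(map$chrom)) {
      idx <- which(map$chrom == chr)
      pos <- map$pos[idx]
      for (a in seq(1L, length(idx), by = chunk)) {
        b <- min(a + chunk - 1L, length(idx))
        lo <- findInterval(pos[a] - windowBp, pos) + 1L
        hi <- findInterval(pos[b] + windowBp, pos)
        J <- idx[a:b]; K <- idx[lo:hi]
        R <- crossprod(X[, J, drop = FALSE], X[, K, drop = FALSE]) / (nref - 1)
        mask <- abs(outer(pos[a:b], pos[lo:hi], "-")) <= windowBp
        R[!mask] <- 0
        Rb[J] <- drop(R %*% beta[K])
      }
    }
    eps <- as.vector(crossprod(X, rnorm(nref))) / sqrt(nref - 1)
    z <- sqrt(nGwas) * Rb + eps
    data.frame(SNP = map$snp, CHR = map$chrom, BP = map$pos,
               A1 = "A", A2 = "G", Z = z, N = nGwas)
  })
}

#' Simulate allelic read counts at peak-resident SNPs
#'
#' For every SNP lying inside a peak, each sample heterozygous at that SNP
#' contributes one record with `alt ~ Binomial(depth, p)`, where
#' `logit(p)` equals the cQTL effect for (peak, SNP) pairs in the truth
#' map and 0 (balanced) otherwise. Homozygous samples emit no record.
#'
#' @param genotypes from [simulateGenotypes()].
#' @param peaks GRanges of peaks.
#' @param cqtlTruth `cqtlMap` data.frame (peak, snp, beta); may be empty.
#' @param depth reads per heterozygote site (>= 1).
#' @param seed integer seed.
#' @return data.frame snp, sample, peak, ref, alt, isCqtl; attribute
#'   `skipped` counts truth SNPs outside any peak.
#' @export
simulateAllelicReads <- function(genotypes, peaks, cqtlTruth, depth = 50,
                                 seed = 1) {
  if (depth < 1) stop("depth must be >= 1")
  withSeed(deriveSeed(seed, "allelic"), {
    map <- genotypes$map
    snpGr <- GenomicRanges::GRanges(map$chrom,
                                    IRanges::IRanges(map$pos, width = 1L))
    hit <- GenomicRanges::findOverlaps(snpGr, peaks, select = "first")
    inPeak <- which(!is.na(hit))
    skipped <- sum(!cqtlTruth$snp %in% map$snp[inPeak])
    recs <- lapply(inPeak, function(j) {
      het <- which(round(genotypes$dosage[, j]) == 1)
      if (!length(het)) return(NULL)
      pkName <- names(peaks)[hit[j]]
      k <- which(cqtlTruth$snp == map$snp[j] & cqtlTruth$peak == pkName)
      p <- if (length(k)) stats::plogis(cqtlTruth$beta[k[1L]]) else 0.5
      alt <- rbinom(length(het), depth, p)
      data.frame(snp = map$snp[j],
                 sample = rownames(genotypes$dosage)[het],
                 peak = pkName, ref = depth - alt, alt = alt,
                 isCqtl = length(k) > 0)
    })
    out <- do.call(rbind, recs)
    if (is.null(out))
      out <- data.frame(snp = character(), sample = character(),
                        peak = character(), ref = integer(),
                        alt = integer(), isCqtl = logical())
    attr(out, "skipped") <- skipped
    if (skipped > 0) warning(skipped, " truth SNP(s) outside any peak skipped")
    out
  })
}

#' One-call synthetic study
#'
#' Bundles genome, peaks, metadata, genotypes, truth and counts with a
#' single master seed. Defaults emulate the full study scale (288 samples,
#' 5000 peaks, 20000 SNPs); tests use smaller settings.
#'
#' @param nSamples,nPeaks,nSnps scale.
#' @param nDxPeaks,dxLog2FC,nCqtlPeaks,cqtlBeta,ageSlopeSD,pmiSlopeSD truth.
#' @param dispersion,meanDepth count model.
#' @param blockSize,mafLow,mafHigh LD model.
#' @param chromLength autosome length.
#' @param seed master seed; stage seeds derive deterministically.
#' @return list: layout, peaks, metadata, genotypes, truth, cae.
#' @export
simulateStudy <- function(nSamples = 288, nPeaks = 5000, nSnps = 20000,
                          nDxPeaks = 0, dxLog2FC = 1.5,
                          nCqtlPeaks = 0, cqtlBeta = 0.5,
                          ageSlopeSD = 0, pmiSlopeSD = 0,
                          dispersion = 0.2, meanDepth = 50,
                          blockSize = 10, mafLow = 0.05, mafHigh = 0.5,
                          chromLength = 1e6, seed = 1) {
  layout <- simulateGenome(2, chromLength, max(50, round(nPeaks / 10)),
                           0.02, seed = seed)
  peaks <- simulatePeaks(layout, nPeaks, seed = seed)
  metadata <- simulateMetadata(nSamples, seed = seed)
  genotypes <- simulateGenotypes(nSamples, nSnps, blockSize = blockSize,
                                 mafLow = mafLow, mafHigh = mafHigh,
                                 seed = seed, layout = layout)
  truth <- simulateTruth(peaks, genotypes$map, nDxPeaks = nDxPeaks,
                         dxLog2FC = dxLog2FC, nCqtlPeaks = nCqtlPeaks,
                         cqtlBeta = cqtlBeta, ageSlopeSD = ageSlopeSD,
                         pmiSlopeSD = pmiSlopeSD, seed = seed)
  cae <- simulateCounts(layout, peaks, genotypes, truth, metadata,
                        dispersion = dispersion, meanDepth = meanDepth,
                        seed = seed)
  list(layout = layout, peaks = peaks, metadata = metadata,
       genotypes = genotypes, truth = truth, cae = cae)
}
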