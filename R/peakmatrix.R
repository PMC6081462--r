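## Peak-level operations: consensus merging, fragment quantification, TMM
## normalization, shuffle-null enrichment QC, replicate concordance,
## Jaccard similarity and TSS annotation.

#' Merge per-sample peak sets into a standardized consensus set
#'
#' Overlapping intervals across samples are unioned; union regions
#' supported by fewer than `minSupport` samples are dropped; each retained
#' region becomes one fixed-width peak centered on the consensus summit
#' (floor of the median of contributing summits; a .5 median rounds to the
#' lower coordinate).
#'
#' @param peakSets list of GRanges, one per sample, each with a `summit`
#'   metadata column (bp).
#' @param minSupport minimum number of samples supporting a region.
#' @param width standardized peak width (bp).
#' @return sorted GRanges with `summit` and `support`, no duplicates.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 400), summit = 250)
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 450), summit = 300)
#' mergePeaks(list(a, b), minSupport = 2)  # one 300-bp peak, summit 275
#' @export
mergePeaks <- function(peakSets, minSupport = 2, width = 300) {
  if (!length(peakSets)) return(GenomicRanges::GRanges())
  all <- suppressWarnings(do.call(c, lapply(seq_along(peakSets), function(i) {
    gr <- peakSets[[i]]
    if (length(gr) && is.null(gr$summit))
      stop("peak set ", i, " lacks a 'summit' column")
    gr$sampleIdx <- if (length(gr)) i else integer()
    gr
  })))
  if (!length(all)) return(GenomicRanges::GRanges())
  regions <- GenomicRanges::reduce(all)
  hits <- GenomicRanges::findOverlaps(all, regions)
  reg <- S4Vectors::subjectHits(hits)
  support <- vapply(split(all$sampleIdx[S4Vectors::queryHits(hits)], reg),
                    function(s) length(unique(s)), 1L)
  summit <- vapply(split(all$summit[S4Vectors::queryHits(hits)], reg),
                   function(s) floor(median(s)), 1)
  idx <- as.integer(names(support))
  keep <- support >= minSupport
  if (!any(keep)) return(GenomicRanges::GRanges())
  half <- floor(width / 2)
  out <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(regions)[idx[keep]],
    IRanges::IRanges(summit[keep] - half + 1L, width = width),
    seqinfo = GenomeInfoDb::seqinfo(regions))
  out$summit <- as.integer(summit[keep])
  out$support <- as.integer(support[keep])
  out <- sort(out)
  out <- out[!duplicated(paste(GenomeInfoDb::seqnames(out),
                               GenomicRanges::start(out)))]
  names(out) <- peakIds(out)
  out
}

fragmentsToGRanges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

#' Quantify fragments over peaks
#'
#' Each fragment is extended to `extend` bp from its start before
#' counting; a fragment contributes to every peak its extended interval
#' overlaps by at least 1 bp. Fragments on chromosomes absent from the
#' peak set are skipped with a warning.
#'
#' @param fragments named list (one per sample) of BED3-style data.frames
#'   (`chrom`, `start`, `end`, 0-based half-open) or GRanges.
#' @param peaks standardized GRanges peak set.
#' @param extend read-extension length (bp).
#' @return [ChromAccExperiment-class]; `lib_size` is the per-sample total
#'   fragment count (including out-of-peak fragments).
#' @export
quantifyPeaks <- function(fragments, peaks, extend = 300) {
  if (is.null(names(fragments)))
    names(fragments) <- paste0("S", seq_along(fragments))
  known <- GenomeInfoDb::seqlevels(peaks)
  skipped <- 0L
  cts <- vapply(fragments, function(fr) {
    gr <- if (methods::is(fr, "GRanges")) fr else fragmentsToGRanges(fr)
    bad <- !(as.character(GenomeInfoDb::seqnames(gr)) %in% known)
    skipped <<- skipped + sum(bad)
    gr <- gr[!bad]
    GenomeInfoDb::seqlevels(gr) <- known
    ext <- GenomicRanges::resize(gr, extend, fix = "start")
    GenomicRanges::countOverlaps(peaks, ext, minoverlap = 1L)
  }, numeric(length(peaks)))
  if (skipped > 0)
    warning(skipped, " fragment(s) on unknown chromosomes skipped")
  cts <- matrix(cts, nrow = length(peaks),
                dimnames = list(names(peaks), names(fragments)))
  lib <- vapply(fragments, function(fr)
    if (methods::is(fr, "GRanges")) length(fr) else nrow(fr), 1)
  ChromAccExperiment(cts, peaks, libSize = pmax(lib, colSums(cts)))
}

#' Trimmed mean of M-values normalization factors
#'
#' For each sample against a reference, M (log2 ratio of library-scaled
#' counts) and A (average log abundance) are computed over peaks positive
#' in both; the most extreme `trimM` of M and `trimA` of A are discarded;
#' the factor is 2 to the inverse-asymptotic-variance-weighted mean of the
#' remaining M. Factors are rescaled to geometric mean 1.
#'
#' @param object count matrix (peaks x samples) or
#'   [ChromAccExperiment-class].
#' @param libSize per-sample library sizes (matrix method).
#' @param trimM,trimA two-sided trim fractions.
#' @param ref `"auto"` (sample whose 75th-percentile count fraction is
#'   closest to the mean) or a sample name/index.
#' @param ... passed through from the ChromAccExperiment method.
#' @return matrix method: named numeric factors; ChromAccExperiment
#'   method: the object with `colData$tmm_factor` filled in.
#' @export
setGeneric("tmmFactors", function(object, ...) standardGeneric("tmmFactors"))

#' @rdname tmmFactors
#' @export
setMethod("tmmFactors", "matrix",
          function(object, libSize = colSums(object), trimM = 0.30,
                   trimA = 0.05, ref = "auto") {
  cts <- object
  if (ncol(cts) < 2L) stop("TMM needs at least two samples")
  frac75 <- apply(sweep(cts, 2L, libSize, "/"), 2L, quantile, 0.75)
  r <- if (identical(ref, "auto")) which.min(abs(frac75 - mean(frac75)))
       else if (is.character(ref)) match(ref, colnames(cts)) else as.integer(ref)
  if (is.na(r)) stop("unknown reference sample")
  f <- vapply(seq_len(ncol(cts)), function(k) {
    if (k == r) return(1)
    ok <- cts[, k] > 0 & cts[, r] > 0
    if (!any(ok))
      stop("sample '", colnames(cts)[k] %||% k,
           "' shares no positive peak with the reference")
    yk <- cts[ok, k]; yr <- cts[ok, r]
    Nk <- libSize[k]; Nr <- libSize[r]
    M <- log2((yk / Nk) / (yr / Nr))
    A <- 0.5 * log2((yk / Nk) * (yr / Nr))
    n <- length(M)
    loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) keep <- rep(TRUE, n)
    w <- 1 / ((Nk - yk[keep]) / (Nk * yk[keep]) +
              (Nr - yr[keep]) / (Nr * yr[keep]))
    if (!all(is.finite(w)) || sum(w) <= 0) w <- rep(1, sum(keep))
    2^(sum(w * M[keep]) / sum(w))
  }, 1)
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(cts))
})

#' @rdname tmmFactors
#' @export
setMethod("tmmFactors", "ChromAccExperiment", function(object, ...) {
  f <- tmmFactors(counts(object), libSize = libSizes(object), ...)
  SummarizedExperiment::colData(object)$tmm_factor <- unname(f)
  methods::validObject(object)
  object
})

## place `widths` non-overlapping intervals uniformly over allowed space
placeShuffled <- function(allowed, widths, maxIter = 50L) {
  segW <- GenomicRanges::width(allowed)
  if (sum(segW) < sum(widths))
    stop("insufficient allowed space for shuffled placement")
  n <- length(widths)
  placed <- GenomicRanges::GRanges()
  todo <- order(widths, decreasing = TRUE)
  for (iter in seq_len(maxIter)) {
    if (!length(todo)) break
    w <- widths[todo]
    fit <- pmax(segW - rep(w, each = length(segW)) + 1, 0)
    dim(fit) <- c(length(segW), length(w))
    seg <- vapply(seq_along(w), function(i) {
      p <- fit[, i]
      if (sum(p) <= 0) NA_integer_ else sample.int(length(segW), 1L, prob = p)
    }, 1L)
    if (anyNA(seg)) stop("insufficient allowed space for shuffled placement")
    off <- floor(runif(length(w)) * (segW[seg] - w + 1))
    cand <- GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(allowed)[seg],
      IRanges::IRanges(GenomicRanges::start(allowed)[seg] + off, width = w),
      seqinfo = GenomeInfoDb::seqinfo(allowed))
    ## accept a non-conflicting subset, retry the rest
    firstOfCluster <- !duplicated(S4Vectors::subjectHits(
      GenomicRanges::findOverlaps(cand, GenomicRanges::reduce(cand))))
    ok <- firstOfCluster & !IRanges::overlapsAny(cand, placed)
    placed <- c(placed, cand[ok])
    todo <- todo[!ok]
  }
  if (length(todo)) stop("shuffled placement did not converge")
  sort(placed)
}

#' Shuffle-null enrichment QC
#'
#' Shuffles the merged peak set to random non-overlapping positions in the
#' allowed genome (mappable minus blacklist minus `excluded`) and reports,
#' per sample, reads-in-peaks over reads-in-shuffled-peaks, and per peak
#' the observed reads over the median shuffled-peak reads (floored at 0.5
#' to keep the ratio defined at low depth).
#'
#' @param fragments as in [quantifyPeaks()].
#' @param peaks merged peak set (GRanges).
#' @param mappable,blacklist,excluded GRanges masks; `excluded` carries
#'   regions with a peak detected in any sample.
#' @param nShuffles number of independent shuffles (ratios averaged).
#' @param seed integer seed (placements are seed-reproducible).
#' @param extend read extension as in quantification.
#' @return list of class `EnrichmentReport`: `perSample` (sample, ratio),
#'   `perPeak` (peaks x samples enrichment matrix), `shuffled` (last
#'   placement), and `nEnriched(threshold)` per-sample counts.
#' @export
shuffleEnrichment <- function(fragments, peaks, mappable,
                              blacklist = GenomicRanges::GRanges(),
                              excluded = GenomicRanges::GRanges(),
                              nShuffles = 1, seed = 1, extend = 300) {
  allowed <- GenomicRanges::reduce(GenomicRanges::setdiff(
    GenomicRanges::reduce(mappable),
    GenomicRanges::reduce(c(GenomicRanges::granges(blacklist),
                            GenomicRanges::granges(excluded)))))
  if (sum(GenomicRanges::width(allowed)) < sum(GenomicRanges::width(peaks)))
    stop("insufficient allowed space for shuffled placement")
  if (is.null(names(fragments)))
    names(fragments) <- paste0("S", seq_along(fragments))
  extFrags <- lapply(fragments, function(fr) {
    gr <- if (methods::is(fr, "GRanges")) fr else fragmentsToGRanges(fr)
    GenomicRanges::resize(gr, extend, fix = "start")
  })
  obsPerPeak <- vapply(extFrags, function(gr)
    GenomicRanges::countOverlaps(peaks, gr), numeric(length(peaks)))
  obsPerPeak <- matrix(obsPerPeak, nrow = length(peaks),
                       dimnames = list(names(peaks), names(fragments)))
  obsTot <- colSums(obsPerPeak)
  shufTot <- matrix(0, nShuffles, length(fragments))
  shufMed <- matrix(0, nShuffles, length(fragments))
  shuf <- NULL
  for (s in seq_len(nShuffles)) {
    shuf <- withSeed(deriveSeed(seed, paste0("shuffle", s)),
                     placeShuffled(allowed, GenomicRanges::width(peaks)))
    perShufPeak <- vapply(extFrags, function(gr)
      GenomicRanges::countOverlaps(shuf, gr), numeric(length(shuf)))
    perShufPeak <- matrix(perShufPeak, nrow = length(shuf))
    shufTot[s, ] <- colSums(perShufPeak)
    shufMed[s, ] <- apply(perShufPeak, 2L, median)
  }
  ratio <- colMeans(matrix(obsTot, nShuffles, length(obsTot),
                           byrow = TRUE) / pmax(shufTot, 1))
  denom <- pmax(colMeans(shufMed), 0.5)
  perPeak <- sweep(obsPerPeak, 2L, denom, "/")
  out <- list(perSample = data.frame(sample = names(fragments),
                                     ratio = unname(ratio)),
              perPeak = perPeak, shuffled = shuf,
              nEnriched = function(threshold) colSums(perPeak >= threshold))
  class(out) <- "EnrichmentReport"
  out
}

#' Replicate concordance by Spearman correlation
#'
#' Tests whether replicate pairs are more correlated than unrelated
#' samples: statistic = mean within-pair Spearman minus mean between-pair
#' Spearman; the null permutes which samples form pairs.
#'
#' @param object count matrix or [ChromAccExperiment-class].
#' @param pairs two-column matrix/data.frame of sample names or indices.
#' @param nPerm permutations.
#' @param seed integer seed.
#' @return list: `withinMean`, `betweenMean`, `stat`, `p`.
#' @export
replicateConcordance <- function(object, pairs, nPerm = 10000, seed = 1) {
  cts <- if (methods::is(object, "ChromAccExperiment")) counts(object)
         else as.matrix(object)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 2L) stop("need at least two replicate pairs")
  idx <- matrix(if (is.character(pairs)) match(pairs, colnames(cts))
                else as.integer(pairs), ncol = 2L)
  if (anyNA(idx)) stop("pair references a missing sample")
  cm <- cor(cts, method = "spearman")
  statFor <- function(ix) {
    within <- cm[cbind(ix[, 1L], ix[, 2L])]
    mask <- matrix(FALSE, ncol(cts), ncol(cts))
    mask[cbind(ix[, 1L], ix[, 2L])] <- TRUE
    mask <- mask | t(mask); diag(mask) <- TRUE
    between <- cm[upper.tri(cm) & !mask]
    c(mean(within), mean(between))
  }
  obs <- statFor(idx)
  used <- as.vector(idx)
  pairKey <- function(ix) paste(sort(paste(pmin(ix[, 1L], ix[, 2L]),
                                           pmax(ix[, 1L], ix[, 2L]))),
                                collapse = ";")
  obsKey <- pairKey(idx)
  permStats <- withSeed(deriveSeed(seed, "repconc"),
    vapply(seq_len(nPerm), function(i) {
      repeat {
        ## pair membership is reassigned across all samples
        sh <- matrix(sample(ncol(cts), length(used)), ncol = 2L)
        if (pairKey(sh) != obsKey) break   # the observed pairing is not
      }                                    # part of the permutation null
      st <- statFor(sh)
      st[1L] - st[2L]
    }, 1))
  list(withinMean = obs[1L], betweenMean = obs[2L],
       stat = obs[1L] - obs[2L],
       p = (1 + sum(permStats >= obs[1L] - obs[2L])) / (1 + nPerm))
}

#' Base-pair Jaccard index of two interval sets
#'
#' @param a,b GRanges on the same genome.
#' @return intersection bp / union bp, in [0,1]; empty union gives 0.
#' @export
jaccardIndex <- function(a, b) {
  a <- GenomicRanges::reduce(GenomicRanges::granges(a))
  b <- GenomicRanges::reduce(GenomicRanges::granges(b))
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  u <- sum(GenomicRanges::width(GenomicRanges::union(a, b)))
  if (u == 0) return(0)
  sum(GenomicRanges::width(GenomicRanges::intersect(a, b))) / u
}

#' Distance of peaks to the nearest TSS
#'
#' Distance is measured peak center to nearest TSS, signed by the TSS
#' strand (positive = downstream of the TSS in transcription direction).
#' Classes (boundaries closed): `"+/-5kb"` for |d| <= 5000, `"5-25kb"`
#' for 5000 < |d| <= 25000, `">25kb"` otherwise. Peaks on a chromosome
#' without any TSS get distance +Inf and class `">25kb"`.
#'
#' @param peaks GRanges (uses `summit` when present, else the midpoint).
#' @param tss GRanges of TSS positions with strand.
#' @return data.frame peak, distance, class, orientation.
#' @export
annotateTSS <- function(peaks, tss) {
  if (!length(tss)) stop("TSS list is empty")
  center <- if (!is.null(peaks$summit)) peaks$summit
            else floor((GenomicRanges::start(peaks) +
                        GenomicRanges::end(peaks)) / 2)
  cgr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(peaks),
                                IRanges::IRanges(center, width = 1L))
  hit <- GenomicRanges::distanceToNearest(cgr, tss, ignore.strand = TRUE)
  d <- rep(Inf, length(peaks))
  q <- S4Vectors::queryHits(hit); s <- S4Vectors::subjectHits(hit)
  raw <- center[q] - GenomicRanges::start(tss)[s]
  neg <- as.character(GenomicRanges::strand(tss))[s] == "-"
  raw[neg] <- -raw[neg]
  d[q] <- raw
  cls <- ifelse(abs(d) <= 5000, "+/-5kb",
                ifelse(abs(d) <= 25000, "5-25kb", ">25kb"))
  data.frame(peak = names(peaks) %||% peakIds(peaks),
             distance = d, class = cls,
             orientation = ifelse(!is.finite(d), NA_character_,
                                  ifelse(d >= 0, "downstream", "upstream")))
}
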