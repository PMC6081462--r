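## Partitioned heritability: stratified LD scores from a reference panel,
## weighted chi-squared regression with block-jackknife uncertainty, and
## the peak-width / padding annotation experiments.

#' Banded adjusted r-squared matrix from a reference panel
#'
#' Small-sample-adjusted squared correlations
#' `r2_adj = r2 - (1 - r2)/(n - 2)` between all SNP pairs on the same
#' chromosome within `windowBp`, as a sparse symmetric band.
#'
#' @param dosages samples x SNPs reference dosages.
#' @param snpMap data.frame snp, chrom, pos (position-sorted per
#'   chromosome).
#' @param windowBp LD window in bp.
#' @param chunk column chunk size for the crossproduct.
#' @return sparse dgCMatrix (SNPs x SNPs).
#' @export
bandedR2 <- function(dosages, snpMap, windowBp = 1e6, chunk = 500L) {
  X <- scale(as.matrix(dosages))
  X[is.na(X)] <- 0
  n <- nrow(X); M <- ncol(X)
  trip <- vector("list", 0L)
  for (chr in unique(snpMap$chrom)) {
    idx <- which(snpMap$chrom == chr)
    pos <- snpMap$pos[idx]
    for (a in seq(1L, length(idx), by = chunk)) {
      b <- min(a + chunk - 1L, length(idx))
      lo <- findInterval(pos[a] - windowBp, pos) + 1L
      hi <- findInterval(pos[b] + windowBp, pos)
      J <- idx[a:b]; K <- idx[lo:hi]
      R <- crossprod(X[, J, drop = FALSE], X[, K, drop = FALSE]) / (n - 1)
      r2 <- R^2
      r2 <- r2 - (1 - r2) / (n - 2)
      mask <- abs(outer(pos[a:b], pos[lo:hi], "-")) <= windowBp
      r2[!mask] <- 0
      w <- which(r2 != 0, arr.ind = TRUE)
      trip[[length(trip) + 1L]] <-
        cbind(J[w[, 1L]], K[w[, 2L]], r2[w])
    }
  }
  tr <- do.call(rbind, trip)
  Matrix::sparseMatrix(i = tr[, 1L], j = tr[, 2L], x = tr[, 3L],
                       dims = c(M, M))
}

#' Stratified LD scores
#'
#' `l(j,c) = sum_k r2_adj(j,k) a[k,c]` over SNPs k within the window on
#' the same chromosome (self term included for k = j).
#'
#' @param dosages,snpMap,windowBp as in [bandedR2()]; alternatively pass a
#'   precomputed banded matrix via `r2` (small instances only).
#' @param annotations binary SNP x category matrix.
#' @param r2 optional precomputed [bandedR2()] output; by default the
#'   band is streamed chunk-wise without materializing it.
#' @param chunk streaming chunk size.
#' @return numeric SNP x category matrix of LD scores.
#' @export
ldScores <- function(dosages, snpMap, annotations, windowBp = 1e6,
                     r2 = NULL, chunk = 500L) {
  A <- as.matrix(annotations)
  if (!is.null(r2)) {
    if (nrow(A) != nrow(r2)) stop("annotation/SNP mismatch")
    L <- as.matrix(r2 %*% A)
    dimnames(L) <- list(snpMap$snp, colnames(A))
    return(L)
  }
  if (nrow(A) != ncol(dosages)) stop("annotation/SNP mismatch")
  if (nrow(dosages) < 50)
    warning("reference panel below 50 samples; LD scores will be noisy")
  X <- scale(as.matrix(dosages))
  X[is.na(X)] <- 0
  n <- nrow(X)
  L <- matrix(0, ncol(X), ncol(A),
              dimnames = list(snpMap$snp, colnames(A)))
  for (chr in unique(snpMap$chrom)) {
    idx <- which(snpMap$chrom == chr)
    pos <- snpMap$pos[idx]
    for (a in seq(1L, length(idx), by = chunk)) {
      b <- min(a + chunk - 1L, length(idx))
      lo <- findInterval(pos[a] - windowBp, pos) + 1L
      hi <- findInterval(pos[b] + windowBp, pos)
      J <- idx[a:b]; K <- idx[lo:hi]
      R <- crossprod(X[, J, drop = FALSE], X[, K, drop = FALSE]) / (n - 1)
      r2c <- R^2
      r2c <- r2c - (1 - r2c) / (n - 2)
      mask <- abs(outer(pos[a:b], pos[lo:hi], "-")) <= windowBp
      r2c[!mask] <- 0
      L[J, ] <- L[J, ] + r2c %*% A[K, , drop = FALSE]
    }
  }
  L
}

#' Stratified LD-score regression
#'
#' Weighted regression of chi-squared statistics on per-category LD
#' scores scaled by the GWAS sample size, with an intercept. Per-category
#' heritability shares, fold enrichments, and block-jackknife standard
#' errors over contiguous SNP blocks; the coefficient z-score is
#' tau-hat / SE_jack(tau-hat).
#'
#' @param chi2 per-SNP chi-squared statistics.
#' @param ldscores SNP x category LD-score matrix (from [ldScores()]).
#' @param annotations the matching binary annotation matrix.
#' @param nGwas GWAS sample size.
#' @param nBlocks jackknife blocks (contiguous SNP spans).
#' @param baseCol name/index of the all-SNP base category; defaults to
#'   the first column covering every SNP.
#' @return [PartitionResult-class].
#' @export
stratifiedRegression <- function(chi2, ldscores, annotations, nGwas,
                                 nBlocks = 20, baseCol = NULL) {
  L <- as.matrix(ldscores); A <- as.matrix(annotations)
  if (any(chi2 < 0)) stop("chi2 must be non-negative")
  M <- length(chi2)
  stopifnot(nrow(L) == M, nrow(A) == M, ncol(L) == ncol(A))
  if (is.null(colnames(A)))
    colnames(A) <- colnames(L) %||% paste0("C", seq_len(ncol(A)))
  if (is.null(baseCol)) {
    full <- which(colSums(A == 1) == M)
    if (!length(full)) stop("no all-SNP base category found")
    baseCol <- full[1L]
  }
  if (is.character(baseCol)) baseCol <- match(baseCol, colnames(A))
  X <- cbind(1, nGwas * L)
  if (qr(X)$rank < ncol(X))
    stop("collinear categories: ",
         paste(colnames(A), collapse = ", "))
  w <- 1 / pmax(L[, baseCol], 1)
  blocks <- cut(seq_len(M), nBlocks, labels = FALSE)
  estimate <- function(keep) {
    fit <- stats::lm.wfit(X[keep, , drop = FALSE], chi2[keep], w[keep])
    tau <- fit$coefficients[-1L]
    perSnpVar <- drop(A %*% tau)
    h2 <- sum(perSnpVar)
    propH2 <- colSums(A * perSnpVar) / h2
    list(tau = tau, h2 = h2, propH2 = propH2,
         enrichment = propH2 / (colSums(A) / M),
         intercept = fit$coefficients[1L])
  }
  full <- estimate(rep(TRUE, M))
  jk <- lapply(seq_len(nBlocks), function(b) estimate(blocks != b))
  jackSE <- function(get) {
    mat <- vapply(jk, get, numeric(length(get(full))))
    mat <- matrix(mat, ncol = nBlocks)
    mn <- rowMeans(mat)
    sqrt((nBlocks - 1) / nBlocks * rowSums((mat - mn)^2))
  }
  tauSE <- jackSE(function(e) e$tau)
  enrSE <- jackSE(function(e) e$enrichment)
  h2SE <- jackSE(function(e) e$h2)
  propSnps <- colSums(A) / M
  enrP <- 2 * pt(-abs((full$enrichment - 1) / pmax(enrSE, 1e-300)),
                 df = nBlocks - 1)
  enrP[propSnps == 1] <- NA  # base category is 1 by construction
  tb <- data.frame(category = colnames(A), propSnps = propSnps,
                   propH2 = full$propH2, tau = full$tau, tauSE = tauSE,
                   enrichment = full$enrichment, enrichmentSE = enrSE,
                   z = full$tau / pmax(tauSE, 1e-300), p = enrP,
                   row.names = NULL)
  methods::new("PartitionResult", table = tb, h2 = unname(full$h2),
               intercept = unname(full$intercept))
}

#' Fold enrichment from heritability and SNP proportions
#'
#' @param propH2 share of heritability in the annotation (any consistent
#'   unit: fraction or percent).
#' @param propSnps share of SNPs in the annotation (same unit).
#' @return propH2 / propSnps.
#' @examples
#' enrichmentStat(8.55, 1.2)  # 7.1-fold
#' @export
enrichmentStat <- function(propH2, propSnps) {
  if (any(propSnps == 0)) stop("propSnps must be positive")
  propH2 / propSnps
}

#' Build SNP annotation matrices from interval sets
#'
#' Emits, for each requested width, a peak annotation (peaks resized
#' about the summit; resizes beyond chromosome bounds are clipped and
#' counted), its +/- `pad` bp companion (padded interval minus the peak,
#' guarding the regression against boundary bias), plus conserved,
#' conserved-intersect-peak and GWA-locus membership when provided, and
#' an all-SNP base. SNPs are assigned by position.
#'
#' @param snpMap data.frame snp, chrom, pos.
#' @param peaks GRanges with `summit`.
#' @param conserved,gwaLoci optional GRanges.
#' @param widths peak widths to emit (bp).
#' @param pad companion padding (bp).
#' @return binary matrix SNPs x categories with attribute `clipped`.
#' @export
buildAnnotations <- function(snpMap, peaks, conserved = NULL,
                             gwaLoci = NULL, widths = 300, pad = 500) {
  snpGr <- GenomicRanges::GRanges(snpMap$chrom,
                                  IRanges::IRanges(snpMap$pos, width = 1L))
  M <- nrow(snpMap)
  cols <- list(base = rep(1L, M))
  clipped <- 0L
  for (w in widths) {
    half <- floor(w / 2)
    st <- peaks$summit - half + 1L
    en <- peaks$summit + (w - half)
    below <- st < 1L
    clipped <- clipped + sum(below)
    st[below] <- 1L
    sl <- GenomeInfoDb::seqlengths(peaks)
    chr <- as.character(GenomeInfoDb::seqnames(peaks))
    if (!all(is.na(sl))) {
      lim <- sl[chr]
      over <- !is.na(lim) & en > lim
      clipped <- clipped + sum(over)
      en[over] <- lim[over]
    }
    pg <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, pmax(en, st)))
    nm <- paste0("peak_w", w)
    cols[[nm]] <- as.integer(IRanges::overlapsAny(snpGr, pg))
    padded <- GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(pg),
      IRanges::IRanges(pmax(GenomicRanges::start(pg) - pad, 1L),
                       GenomicRanges::end(pg) + pad))
    companion <- GenomicRanges::setdiff(GenomicRanges::reduce(padded),
                                        GenomicRanges::reduce(pg))
    cols[[paste0(nm, "_pad", pad)]] <-
      as.integer(IRanges::overlapsAny(snpGr, companion))
    if (!is.null(conserved) && length(conserved)) {
      cols[[paste0("conserved_x_", nm)]] <-
        as.integer(IRanges::overlapsAny(
          snpGr, GenomicRanges::intersect(GenomicRanges::reduce(pg),
                                          GenomicRanges::reduce(conserved))))
    }
  }
  if (!is.null(conserved) && length(conserved))
    cols[["conserved"]] <- as.integer(IRanges::overlapsAny(snpGr, conserved))
  if (!is.null(gwaLoci) && length(gwaLoci))
    cols[["gwa_locus"]] <- as.integer(IRanges::overlapsAny(snpGr, gwaLoci))
  A <- do.call(cbind, cols)
  rownames(A) <- snpMap$snp
  attr(A, "clipped") <- clipped
  A
}

#' Heritability enrichment across peak widths
#'
#' Rebuilds the peak annotation at each width (about the summit), rescores
#' LD, reruns the stratified regression, and returns the enrichment
#' series with jackknife SEs. The banded r2 matrix is computed once.
#'
#' @param sumstats GWAS summary data.frame with `Z` (chi2 = Z^2) and `N`.
#' @param dosages,snpMap reference panel.
#' @param peaks GRanges with `summit`.
#' @param widths widths to test.
#' @param pad companion padding.
#' @param windowBp LD window.
#' @param nBlocks jackknife blocks.
#' @return data.frame width, enrichment, se, z, propSnps, propH2.
#' @export
widthExperiment <- function(sumstats, dosages, snpMap, peaks,
                            widths = c(100, 300, 1000, 2000, 5000, 10000),
                            pad = 500, windowBp = 1e6, nBlocks = 20) {
  chi2 <- sumstats$Z^2
  nGwas <- sumstats$N[1L]
  ## one streamed LD-score pass over the annotations of every width
  Aall <- buildAnnotations(snpMap, peaks, widths = widths, pad = pad)
  Lall <- ldScores(dosages, snpMap, Aall, windowBp)
  res <- lapply(widths, function(w) {
    cols <- c("base", paste0("peak_w", w), paste0("peak_w", w, "_pad", pad))
    A <- Aall[, cols, drop = FALSE]
    L <- Lall[, cols, drop = FALSE]
    pr <- stratifiedRegression(chi2, L, A, nGwas, nBlocks = nBlocks)
    i <- match(paste0("peak_w", w), pr@table$category)
    data.frame(width = w, enrichment = pr@table$enrichment[i],
               se = pr@table$enrichmentSE[i], z = pr@table$z[i],
               propSnps = pr@table$propSnps[i],
               propH2 = pr@table$propH2[i])
  })
  do.call(rbind, res)
}
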