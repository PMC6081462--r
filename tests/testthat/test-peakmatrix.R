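test_that("peak merging applies support, consensus summit and width rules", {
  a <- grP("chr1", 101, 400, 250)
  b <- grP("chr1", 151, 450, 300)
  solo <- grP("chr2", 1001, 1300, 1150)
  ## region seen in one sample only is dropped
  m <- mergePeaks(list(c(a, solo), b), minSupport = 2)
  expect_equal(length(m), 1L)
  ## consensus summit = median(250, 300) = 275; 300 bp span 125-425 (0-based)
  expect_equal(m$summit, 275L)
  expect_equal(GenomicRanges::start(m), 126L)  # 1-based closed = 0-based 125
  expect_equal(GenomicRanges::end(m), 425L)
  expect_equal(m$support, 2L)
  ## identical peak in three samples: unchanged, support 3
  p <- grP("chr1", 1001, 1300, 1150)
  m3 <- mergePeaks(list(p, p, p), minSupport = 2)
  expect_equal(GenomicRanges::start(m3), 1001L)
  expect_equal(m3$support, 3L)
  ## idempotence: merging the output with itself returns it unchanged
  st <- smallStudy()
  once <- mergePeaks(list(st$peaks), minSupport = 1)
  twice <- mergePeaks(list(once), minSupport = 1)
  expect_equal(GenomicRanges::start(once), GenomicRanges::start(twice))
  expect_equal(once$summit, twice$summit)
  expect_equal(length(mergePeaks(list())), 0L)
})

test_that("quantification extends reads and counts >=1 bp overlaps", {
  pk <- grP("chr1", 1001, 1300, 1150)
  names(pk) <- "pk1"
  ## no fragments: all-zero matrix
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer())
  expect_true(all(counts(quantifyPeaks(list(S1 = empty), pk)) == 0))
  ## fragment starting 50 bp left of the peak, extended to 300, overlaps
  frL <- data.frame(chrom = "chr1", start = 950, end = 1000)
  expect_equal(unname(counts(quantifyPeaks(list(S1 = frL), pk))[1, 1]), 1)
  ## without extension it would not overlap
  expect_equal(unname(counts(quantifyPeaks(list(S1 = frL), pk,
                                           extend = 50))[1, 1]), 0)
  ## 10 fragments inside, 1 outside: column sum 10
  fr <- data.frame(chrom = "chr1",
                   start = c(seq(1050, 1230, by = 20), 5000),
                   end = c(seq(1100, 1280, by = 20), 5050))
  q <- quantifyPeaks(list(S1 = fr), pk)
  expect_equal(sum(counts(q)), 10)
  expect_equal(unname(libSizes(q)), 11)
  ## unknown chromosome: warning + skip
  frBad <- data.frame(chrom = c("chr1", "chrUn"), start = c(1100, 1),
                      end = c(1150, 51))
  expect_warning(qb <- quantifyPeaks(list(S1 = frBad), pk), "unknown")
  expect_equal(sum(counts(qb)), 1)
})

test_that("TMM factors match hand derivations and edgeR", {
  ## identical columns: factors (1, 1)
  cts <- cbind(A = c(10, 20, 30, 40), B = c(10, 20, 30, 40))
  expect_equal(unname(tmmFactors(cts, libSize = c(100, 100))), c(1, 1))
  ## doubled column with equal lib size: raw factor 2 -> (1/sqrt2, sqrt2)
  cts2 <- cbind(A = c(10, 20, 30, 40), B = c(20, 40, 60, 80))
  f <- tmmFactors(cts2, libSize = c(1000, 1000))
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  ## brute-force trimmed weighted mean on a random matrix
  set.seed(1)
  X <- matrix(rnbinom(400, mu = 50, size = 5) + 1L, 100, 4)
  colnames(X) <- paste0("S", 1:4)
  libs <- colSums(X)
  f2 <- tmmFactors(X, libSize = libs, ref = 1)
  bf <- vapply(2:4, function(k) {
    yk <- X[, k]; yr <- X[, 1]; Nk <- libs[k]; Nr <- libs[1]
    M <- log2((yk / Nk) / (yr / Nr)); A <- 0.5 * log2((yk / Nk) * (yr / Nr))
    n <- length(M)
    keep <- rank(M) >= floor(n * .3) + 1 & rank(M) <= n - floor(n * .3) &
            rank(A) >= floor(n * .05) + 1 & rank(A) <= n - floor(n * .05)
    w <- 1 / ((Nk - yk) / (Nk * yk) + (Nr - yr) / (Nr * yr))
    2^(sum((w * M)[keep]) / sum(w[keep]))
  }, 1)
  raw <- c(1, bf)
  expect_equal(unname(f2), raw / exp(mean(log(raw))), tolerance = 1e-12)
  ## independent implementation: edgeR agrees on the doubled-column case
  skip_if_not_installed("edgeR")
  fe <- edgeR::calcNormFactors(cts2, lib.size = c(1000, 1000),
                               method = "TMM")
  expect_equal(unname(f), unname(fe), tolerance = 1e-6)
  ## scaling one sample by c scales its factor by c before rescaling:
  ## after geometric rescaling both factors move by sqrt(c)
  f3 <- tmmFactors(cbind(A = c(10, 20, 30, 40), B = 3 * c(10, 20, 30, 40)),
                   libSize = c(100, 100))
  expect_equal(unname(f3[2] / f3[1]), 3, tolerance = 1e-10)
  expect_error(tmmFactors(cbind(A = c(1, 0), B = c(0, 1)),
                          libSize = c(1, 1), ref = 1), "positive peak")
})

test_that("shuffle-null enrichment is calibrated and seed-reproducible", {
  st <- smallStudy()
  lay <- st$layout
  mkUnif <- function(n, seed) withr::with_seed(seed, {
    mp <- lay$mappable; w <- GenomicRanges::width(mp)
    seg <- sample(length(mp), n, TRUE, prob = w)
    pos <- GenomicRanges::start(mp)[seg] + floor(runif(n) * w[seg])
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(mp))[seg],
               start = pos, end = pos + 50)
  })
  unif <- list(S1 = mkUnif(8000, 1), S2 = mkUnif(8000, 2))
  en <- shuffleEnrichment(unif, st$peaks, lay$mappable, lay$blacklist,
                          nShuffles = 10, seed = 3)
  expect_true(all(abs(en$perSample$ratio - 1) < 0.35))
  ## ratio invariant to fragment order, reproducible under the same seed
  shuffledOrder <- lapply(unif, function(d) d[sample(nrow(d)), ])
  en2 <- shuffleEnrichment(shuffledOrder, st$peaks, lay$mappable,
                           lay$blacklist, nShuffles = 10, seed = 3)
  expect_equal(en$perSample$ratio, en2$perSample$ratio)
  ## construction with 3x in-peak concentration recovers ratio ~ 3
  conc <- withr::with_seed(9, {
    nIn <- 3000
    pkW <- sum(GenomicRanges::width(st$peaks))
    totW <- sum(GenomicRanges::width(lay$mappable))
    nOut <- round(nIn * (totW - pkW) / (3 * pkW))
    idx <- sample(length(st$peaks), nIn, TRUE)
    pos <- GenomicRanges::start(st$peaks)[idx] +
      floor(runif(nIn) * (GenomicRanges::width(st$peaks)[idx] - 60))
    inPk <- data.frame(chrom = as.character(
      GenomeInfoDb::seqnames(st$peaks))[idx], start = pos, end = pos + 50)
    rbind(inPk, mkUnif(nOut, 10))
  })
  en3 <- shuffleEnrichment(list(S1 = conc), st$peaks, lay$mappable,
                           lay$blacklist, nShuffles = 10, seed = 4,
                           extend = 50)
  expect_gt(en3$perSample$ratio, 2)
  expect_lt(en3$perSample$ratio, 4.5)
  ## no allowed space -> error
  expect_error(shuffleEnrichment(unif, st$peaks, lay$mappable,
                                 blacklist = lay$mappable, seed = 1),
               "insufficient")
})

test_that("replicate concordance separates true pairs from noise", {
  set.seed(5)
  base <- matrix(rnbinom(200 * 4, mu = 40, size = 3), 200, 4)
  reps <- base + matrix(rpois(200 * 4, 2), 200, 4)   # paired replicates
  noise <- matrix(rnbinom(200 * 4, mu = 40, size = 3), 200, 4)
  cts <- cbind(base, reps, noise)
  colnames(cts) <- paste0("S", 1:12)
  pairs <- cbind(paste0("S", 1:4), paste0("S", 5:8))
  rc <- replicateConcordance(cts, pairs, nPerm = 999, seed = 1)
  expect_gt(rc$withinMean, 0.9)
  expect_gt(rc$withinMean, rc$betweenMean)
  expect_equal(rc$p, 1 / 1000)
  ## independent columns: permutation p behaves like a null draw
  ps <- vapply(1:60, function(i) {
    m <- matrix(rnorm(50 * 8), 50, 8)
    colnames(m) <- paste0("S", 1:8)
    replicateConcordance(m, cbind(paste0("S", 1:2), paste0("S", 3:4)),
                         nPerm = 99, seed = i)$p
  }, 1)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_error(replicateConcordance(cts, cbind("S1", "S99")), "at least")
})

test_that("Jaccard index follows base-pair interval arithmetic", {
  a <- grP("chr1", 1, 300)
  b <- grP("chr1", 151, 450)
  expect_equal(jaccardIndex(a, a), 1)
  expect_equal(jaccardIndex(a, grP("chr2", 1, 300)), 0)
  expect_equal(jaccardIndex(a, b), 150 / 450)
  expect_equal(jaccardIndex(GenomicRanges::GRanges(),
                            GenomicRanges::GRanges()), 0)
})

test_that("TSS annotation signs distances and applies closed class bounds", {
  tss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, width = 1),
                                strand = "+")
  pkAt <- grP("chr1", 9851, 10150, 10000)
  names(pkAt) <- "p0"
  ann <- annotateTSS(pkAt, tss)
  expect_equal(ann$distance, 0)
  expect_equal(ann$class, "+/-5kb")
  ## boundary: exactly 5000 downstream stays in +/-5kb (closed)
  pk5k <- grP("chr1", 14851, 15150, 15000)
  expect_equal(annotateTSS(pk5k, tss)$class, "+/-5kb")
  expect_equal(annotateTSS(pk5k, tss)$distance, 5000)
  ## minus-strand TSS flips the sign
  tssM <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, width = 1),
                                 strand = "-")
  expect_equal(annotateTSS(pk5k, tssM)$distance, -5000)
  expect_equal(annotateTSS(pk5k, tssM)$orientation, "upstream")
  ## all peaks 30 kb away -> 100% >25kb
  far <- grP("chr1", 39851 + (0:4) * 1000, 40150 + (0:4) * 1000,
             40000 + (0:4) * 1000)
  expect_true(all(annotateTSS(far, tss)$class == ">25kb"))
  ## chromosome without TSS
  pkNo <- grP("chr9", 100, 399, 250)
  annNo <- annotateTSS(pkNo, tss)
  expect_equal(annNo$class, ">25kb")
  expect_equal(annNo$distance, Inf)
  expect_error(annotateTSS(pkAt, GenomicRanges::GRanges()), "empty")
})
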