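test_that("genome layout has the requested structure and is deterministic", {
  gl <- simulateGenome(2, 1e6, 100, 0.02, seed = 1)
  expect_equal(nrow(gl$chromosomes), 4L)  # 2 autosomes + chrX + chrY
  expect_setequal(gl$chromosomes$name, c("chr1", "chr2", "chrX", "chrY"))
  expect_equal(length(gl$tss), 100L)
  ## intervals within bounds and internally merged
  for (tr in list(gl$mappable, gl$blacklist)) {
    lens <- gl$chromosomes$length[match(
      as.character(GenomeInfoDb::seqnames(tr)), gl$chromosomes$name)]
    expect_true(all(GenomicRanges::start(tr) >= 1))
    expect_true(all(GenomicRanges::end(tr) <= lens))
    expect_true(GenomicRanges::isDisjoint(tr))
  }
  ## TSS sorted per chromosome, quartiles in Q0..Q4
  expect_true(all(gl$tss$quartile %in% paste0("Q", 0:4)))
  gl2 <- simulateGenome(2, 1e6, 100, 0.02, seed = 1)
  expect_identical(gl, gl2)
  expect_equal(length(simulateGenome(2, 1e6, 50, 0, seed = 3)$blacklist), 0L)
  expect_error(simulateGenome(0, 1e6, 10, 0.1), "invalid")
  expect_error(simulateGenome(2, 1e6, 10, 0.6), "blacklistFraction")
})

test_that("genotype generator respects MAF bounds and block LD structure", {
  gt <- simulateGenotypes(200, 500, blockSize = 10, mafLow = 0.05,
                          mafHigh = 0.5, seed = 7)
  expect_true(all(gt$dosage >= 0 & gt$dosage <= 2))
  maf <- colMeans(gt$dosage) / 2
  maf <- pmin(maf, 1 - maf)
  expect_true(all(maf >= 0 & maf <= 0.55))
  ## within-block r2 exceeds between-block r2, computed from the dosages
  r2within <- r2between <- c()
  for (b in unique(gt$map$block)[1:20]) {
    i <- which(gt$map$block == b)
    j <- which(gt$map$block == b + 1L)
    if (length(i) < 2 || !length(j)) next
    r2within <- c(r2within, cor(gt$dosage[, i[1]], gt$dosage[, i[2]])^2)
    r2between <- c(r2between, cor(gt$dosage[, i[1]], gt$dosage[, j[1]])^2)
  }
  expect_gt(mean(r2within), mean(r2between))
  ## blockSize = 1: adjacent SNPs essentially uncorrelated
  g1 <- simulateGenotypes(200, 100, blockSize = 1, seed = 3)
  rAdj <- vapply(1:99, function(k)
    cor(g1$dosage[, k], g1$dosage[, k + 1]), 1)
  expect_lt(abs(mean(rAdj)), 3 / sqrt(200 * 99))
  ## maf fixed at 0.5: mean dosage ~ 1
  g5 <- simulateGenotypes(400, 50, blockSize = 1, mafLow = 0.5,
                          mafHigh = 0.5, seed = 4)
  se <- sd(colMeans(g5$dosage)) / sqrt(50)
  expect_lt(abs(mean(g5$dosage) - 1), 3 * max(se, 0.02))
  expect_error(simulateGenotypes(10, 5, blockSize = 10), "nSnps")
  expect_error(simulateGenotypes(10, 50, mafLow = 0, mafHigh = 0.5), "maf")
  expect_identical(simulateGenotypes(20, 30, seed = 9),
                   simulateGenotypes(20, 30, seed = 9))
})

test_that("count generator hits the NB model it claims", {
  lay <- simulateGenome(2, 5e5, 20, 0, seed = 1)
  pk <- simulatePeaks(lay, 120, seed = 1)
  pk <- pk[as.character(GenomeInfoDb::seqnames(pk)) %in% c("chr1", "chr2")]
  md <- simulateMetadata(100, caseFraction = 0.5, seed = 1)
  ## Poisson limit: dispersion test non-significant for >= 95% of peaks
  tr0 <- simulateTruth(pk, data.frame(snp = "rs1", chrom = "chr1", pos = 1),
                       seed = 1)
  cae0 <- simulateCounts(lay, pk, NULL, tr0, md, dispersion = 1e-6,
                         meanDepth = 60, libSizeSD = 0, seed = 2)
  cts <- counts(cae0)
  dispP <- apply(cts, 1, function(y) {
    stat <- sum((y - mean(y))^2) / mean(y)   # chi-squared dispersion index
    pchisq(stat, df = length(y) - 1, lower.tail = FALSE)
  })
  expect_gte(mean(dispP > 0.01), 0.95)
  ## diagnosis log2FC = 2: case/control mean ratio near 4
  tr2 <- tr0
  tr2$peakEffects$dxLog2FC[1] <- 2
  cae2 <- simulateCounts(lay, pk, NULL, tr2, md, dispersion = 0.05,
                         meanDepth = 80, seed = 3)
  y <- counts(cae2)[1, ]
  ratio <- mean(y[md$diagnosis == "case"]) / mean(y[md$diagnosis == "control"])
  expect_gt(ratio, 3); expect_lt(ratio, 5.3)
  ## cQTL effect: NB mean monotone across dosage groups
  md2 <- simulateMetadata(1000, seed = 5)
  gt <- simulateGenotypes(1000, 60, blockSize = 1, mafLow = 0.3,
                          mafHigh = 0.5, seed = 5, layout = lay)
  tr3 <- simulateTruth(pk, gt$map, nCqtlPeaks = 5, cqtlBeta = 0.5, seed = 6)
  expect_gt(nrow(tr3$cqtlMap), 0)
  cae3 <- simulateCounts(lay, pk, gt, tr3, md2, dispersion = 0.1,
                         meanDepth = 60, seed = 7)
  cm <- tr3$cqtlMap[1, ]
  y <- counts(cae3)[cm$peak, ]
  g <- round(gt$dosage[, cm$snp])
  mns <- tapply(y, g, mean)
  if (cm$beta > 0) expect_true(all(diff(mns) > 0))
  else expect_true(all(diff(mns) < 0))
  ## female chrY counts are zero
  st <- smallStudy()
  chrY <- as.character(GenomeInfoDb::seqnames(st$peaks)) == "chrY"
  fem <- st$metadata$sex == "F"
  if (any(chrY) && any(fem))
    expect_true(all(counts(st$cae)[chrY, fem] == 0))
  expect_error(
    simulateCounts(lay, pk, NULL,
                   list(peakEffects = data.frame(peak = "nope", dxLog2FC = 1,
                                                 ageSlope = 0, pmiSlope = 0),
                        cqtlMap = data.frame()),
                   md, seed = 1),
    "unknown peak")
})

test_that("GWAS generator is calibrated under the null and enriched under tau", {
  lay <- simulateGenome(2, 5e6, 20, 0, seed = 2)
  gt <- simulateGenotypes(200, 6000, blockSize = 10, seed = 2, layout = lay)
  A <- cbind(base = rep(1, 6000),
             focal = as.integer(seq_len(6000) %in% sample(6000, 60)))
  ## all tau zero: mean chi2 ~ 1
  ss0 <- simulateGWAS(gt, A, c(0, 0), nGwas = 50000, seed = 3)
  chi0 <- ss0$Z^2
  ## the environmental term lives in the panel's 200-dim column space, so
  ## the effective SE of the mean chi2 is sqrt(2/n_ref), not sd/sqrt(M)
  expect_lt(abs(mean(chi0) - 1), 3 * sqrt(2 / nrow(gt$dosage)))
  ## tau concentrated in a 1% annotation: chi2 inside > outside
  ss1 <- simulateGWAS(gt, A, c(0, 5e-3), nGwas = 50000, seed = 4)
  tt <- t.test(ss1$Z[A[, 2] == 1]^2, ss1$Z[A[, 2] == 0]^2,
               alternative = "greater")
  expect_lt(tt$p.value, 0.01)
  ## determinism
  expect_identical(ss0$Z, simulateGWAS(gt, A, c(0, 0), 50000, seed = 3)$Z)
  expect_error(simulateGWAS(gt, A[1:10, ], c(0, 0), 100), "mismatch")
})

test_that("allelic read generator follows its binomial model", {
  lay <- simulateGenome(2, 5e5, 20, 0, seed = 4)
  gt <- simulateGenotypes(400, 300, blockSize = 1, mafLow = 0.3,
                          mafHigh = 0.5, seed = 4, layout = lay)
  pk <- simulatePeaks(lay, 150, seed = 4)
  snpGr <- GenomicRanges::GRanges(gt$map$chrom,
                                  IRanges::IRanges(gt$map$pos, width = 1))
  inPk <- which(IRanges::overlapsAny(snpGr, pk))
  expect_gte(length(inPk), 3)
  hit <- GenomicRanges::findOverlaps(snpGr[inPk], pk, select = "first")
  cq <- data.frame(peak = names(pk)[hit[1]], snp = gt$map$snp[inPk[1]],
                   beta = 1.5)
  rec <- simulateAllelicReads(gt, pk, cq, depth = 50, seed = 5)
  ## only heterozygotes emit records
  het <- round(gt$dosage[cbind(match(rec$sample, rownames(gt$dosage)),
                               match(rec$snp, gt$map$snp))])
  expect_true(all(het == 1))
  ## strong positive effect: mean alt fraction > 0.55
  rc <- rec[rec$snp == cq$snp, ]
  expect_gt(mean(rc$alt / (rc$alt + rc$ref)), 0.55)
  ## non-cQTL SNPs balanced at 0.5
  r0 <- rec[!rec$isCqtl, ]
  frac0 <- sum(r0$alt) / sum(r0$alt + r0$ref)
  expect_lt(abs(frac0 - 0.5), 3 * sqrt(0.25 / sum(r0$alt + r0$ref)))
})

test_that("truth set round-trips through TSV", {
  st <- smallStudy()
  f <- tempfile(fileext = ".tsv")
  write.table(st$truth$cqtlMap, f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read.table(f, sep = "\t", header = TRUE,
                     colClasses = c("character", "character", "numeric"))
  expect_equal(back, st$truth$cqtlMap, ignore_attr = TRUE)
})
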