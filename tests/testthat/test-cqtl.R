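mkPeak <- function(center, chrom = "chr1", width = 300) {
  gr <- grP(chrom, center - 149, center + 150, center)
  names(gr) <- paste0(chrom, ":", center)
  gr
}

test_that("cis window is anchored at the center and closed at window bp", {
  pk <- mkPeak(10000)
  map <- data.frame(snp = c("rsA", "rsB", "rsC"), chrom = "chr1",
                    pos = c(15000, 15001, 9000))   # +5000, +5001, -1000
  set.seed(1)
  dos <- matrix(rbinom(50 * 3, 2, 0.4), 50, 3,
                dimnames = list(NULL, map$snp))
  ph <- matrix(rnorm(50), 1, 50, dimnames = list(names(pk), NULL))
  cis <- mapCis(ph, pk, dos, map, window = 5000)
  expect_equal(cis$nSnps, 2L)       # rsB at 5001 bp excluded
  ## beta recovery: phenotype = 0.5 * dosage + small noise
  ph2 <- matrix(0.5 * dos[, "rsC"] + rnorm(50, 0, 0.1), 1, 50,
                dimnames = list(names(pk), NULL))
  c2 <- mapCis(ph2, pk, dos, map, window = 5000)
  expect_equal(c2$snp, "rsC")
  expect_lt(abs(c2$beta - 0.5), 3 * c2$se)
  ## peak with no cis SNPs: NA row, not an error
  far <- mkPeak(500000)
  cf <- mapCis(matrix(rnorm(50), 1, 50, dimnames = list(names(far), NULL)),
               far, dos, map)
  expect_equal(cf$nSnps, 0L)
  expect_true(is.na(cf$p))
})

test_that("reported top SNP is the scan minimum (re-scan oracle)", {
  set.seed(2)
  pk <- mkPeak(10000)
  map <- data.frame(snp = sprintf("rs%02d", 1:12), chrom = "chr1",
                    pos = seq(6000, 14000, length.out = 12))
  dos <- matrix(rbinom(80 * 12, 2, 0.3), 80, 12,
                dimnames = list(NULL, map$snp))
  cov <- matrix(rnorm(160), 80, 2)
  ph <- matrix(rnorm(80), 1, 80, dimnames = list(names(pk), NULL))
  got <- mapCis(ph, pk, dos, map, window = 5000, covariates = cov)
  ## oracle: per-SNP lm on residualized data
  yr <- drop(brainchrom:::residualize(drop(ph), cov))
  pOracle <- vapply(seq_len(12), function(j) {
    dr <- drop(brainchrom:::residualize(dos[, j], cov))
    summary(lm(yr ~ dr))$coefficients[2, 4]
  }, 1)
  inWin <- abs(map$pos - 10000) <= 5000
  expect_equal(got$snp, map$snp[inWin][which.min(pOracle[inWin])])
  expect_equal(got$p, min(pOracle[inWin]), tolerance = 0.05)
})

test_that("beta-approximated permutation p matches its analytic null", {
  set.seed(3)
  n <- 150
  ## single cis SNP: adjusted ~ nominal, a and b near 1
  d1 <- matrix(rbinom(n, 2, 0.4), n, 1)
  y <- rnorm(n)
  p1 <- permAdjust(y, d1, nPerm = 500, seed = 11)
  expect_lt(abs(p1$aHat - 1), 0.35)
  expect_lt(abs(p1$bHat - 1), 0.35)
  expect_lt(abs(p1$adjustedP - p1$nominalP), 0.15)
  ## K independent SNPs: min p ~ Beta(1, K)
  K <- 25
  bs <- vapply(1:40, function(i) {
    D <- matrix(rbinom(n * K, 2, 0.3), n)
    permAdjust(rnorm(n), D, nPerm = 300, seed = 100 + i)$bHat
  }, 1)
  expect_lt(abs(mean(bs) - K) / K, 0.15)
  ## degenerate phenotype falls back to the empirical p with a flag
  dg <- permAdjust(rep(c(0, 1), 60), matrix(rep(c(0, 1), 60), 120, 1),
                   nPerm = 100, seed = 1)
  expect_type(dg$adjustedP, "double")
  ## sanity envelope versus the brute-force empirical permutation p
  set.seed(6)
  inEnv <- vapply(1:30, function(i) {
    D <- matrix(rbinom(n * 8, 2, 0.35), n)
    pa <- permAdjust(rnorm(n), D, nPerm = 400, seed = 200 + i)
    pa$adjustedP >= 0.2 * pa$empiricalP &&
      pa$adjustedP <= min(1, 5 * pa$empiricalP)
  }, TRUE)
  expect_gte(mean(inEnv), 0.9)
  expect_error(permAdjust(rnorm(10), matrix(1, 10, 1), nPerm = 10), "nPerm")
})

test_that("Storey q-values estimate pi0 and reduce to BH when forced", {
  set.seed(5)
  pNull <- runif(10000)
  expect_gt(storeyQvalue(pNull)$pi0, 0.9)
  pMix <- c(rbeta(1000, 0.05, 10), runif(1000))
  pi0 <- storeyQvalue(pMix)$pi0
  expect_lt(abs(pi0 - 0.5), 0.12)
  ## forced pi0 = 1 reproduces BH exactly (cross-module equivalence)
  p <- runif(500)
  expect_equal(storeyQvalue(p, pi0 = 1)$q, bhFDR(p))
  expect_warning(storeyQvalue(runif(20)), "pi0 = 1")
  expect_error(storeyQvalue(c(0.5, 2)), "outside")
})

test_that("interaction scan calibrates and attains its permutation floor", {
  set.seed(7)
  n <- 120
  dos <- matrix(rbinom(n, 2, 0.4), n, 1, dimnames = list(NULL, "rs1"))
  dx <- rep(c("case", "control"), n / 2)
  ## floor: minimum attainable p is 1/(nPerm + 1)
  g <- dos[, 1]
  yInt <- 0.1 * g + 1.5 * g * (dx == "case") + rnorm(n, 0, 0.3)
  ph <- matrix(yInt, 1, n, dimnames = list("pk1", NULL))
  ps <- data.frame(peak = "pk1", snp = "rs1")
  it <- interactionScan(ph, ps, dos, dx, nPerm = 100, seed = 3)
  expect_equal(it$p, 1 / 101)
  ## null: interaction p roughly uniform across peaks
  nullP <- vapply(1:80, function(i) {
    y <- 0.3 * g + rnorm(n)
    interactionScan(matrix(y, 1, n, dimnames = list("pk1", NULL)),
                    ps, dos, dx, nPerm = 120, seed = 500 + i)$p
  }, 1)
  expect_gt(ks.test(nullP, "punif")$p.value, 0.01)
  expect_error(interactionScan(ph, ps, dos, rep("case", n), nPerm = 100),
               "levels")
})

test_that("allelic imbalance summaries follow their definitions", {
  ## balanced record contributes no direction
  rec <- data.frame(snp = "rs1", sample = "S1", ref = 10, alt = 10)
  ab <- alleleBiasAnalysis(rec, data.frame(snp = "rs1", beta = 1))
  expect_equal(ab$perSnp$meanAltFrac, 0.5)
  expect_equal(ab$nConcordant, 0)
  ## strong logit-linked effects at depth 50: concordance > 0.9
  set.seed(8)
  beta <- sample(c(-1.5, 1.5), 40, TRUE)
  recs <- do.call(rbind, lapply(1:40, function(j) {
    alt <- rbinom(30, 50, plogis(beta[j]))
    data.frame(snp = sprintf("c%02d", j), sample = paste0("S", 1:30),
               ref = 50 - alt, alt = alt)
  }))
  nulls <- do.call(rbind, lapply(1:40, function(j) {
    alt <- rbinom(30, 50, 0.5)
    data.frame(snp = sprintf("n%02d", j), sample = paste0("S", 1:30),
               ref = 50 - alt, alt = alt)
  }))
  ab2 <- alleleBiasAnalysis(rbind(recs, nulls),
                            data.frame(snp = sprintf("c%02d", 1:40),
                                       beta = beta))
  expect_gt(ab2$concordance, 0.9)
  expect_lt(ab2$p, 0.01)   # cQTL and null alt-fraction histograms differ
  ## identical Binomial(0.5) draws in both groups: chi-squared p uniform
  set.seed(9)
  nullChiP <- vapply(1:60, function(i) {
    a1 <- rbinom(200, 30, 0.5); a2 <- rbinom(200, 30, 0.5)
    r <- rbind(data.frame(snp = "a", sample = seq_len(200), ref = 30 - a1,
                          alt = a1),
               data.frame(snp = "b", sample = seq_len(200), ref = 30 - a2,
                          alt = a2))
    suppressWarnings(
      alleleBiasAnalysis(r, data.frame(snp = "a", beta = 1))$p)
  }, 1)
  expect_gt(ks.test(nullChiP, "punif")$p.value, 0.01)
  ## shallow records are excluded by the depth filter
  shal <- data.frame(snp = "rs9", sample = "S1", ref = 2, alt = 3)
  ab3 <- alleleBiasAnalysis(rbind(rec, shal),
                            data.frame(snp = "rs1", beta = 1))
  expect_false("rs9" %in% ab3$perSnp$snp)
})
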