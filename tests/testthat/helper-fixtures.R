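## Shared small fixtures, built once per test run.

## Table 1 cohort counts as printed in the study report: 135 cases / 137
## controls; sex 92M/43F vs 73M/64F; ethnicity (European, African-American,
## Hispanic, Asian) cases (112, 17, 5, 1), controls (98, 20, 16, 3).
cohortTable <- function() {
  data.frame(
    diagnosis = rep(c("case", "control"), c(135, 137)),
    sex = c(rep("M", 92), rep("F", 43), rep("M", 73), rep("F", 64)),
    ethnicity = c(rep(c("European", "AfricanAmerican", "Hispanic", "Asian"),
                      c(112, 17, 5, 1)),
                  rep(c("European", "AfricanAmerican", "Hispanic", "Asian"),
                      c(98, 20, 16, 3))))
}

smallStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateStudy(nSamples = 60, nPeaks = 150, nSnps = 800,
                              nDxPeaks = 8, dxLog2FC = 1.5,
                              nCqtlPeaks = 12, cqtlBeta = 0.8, seed = 42)
    cache
  }
})

grP <- function(chrom, start1, end1, summit = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1))
  if (!is.null(summit)) gr$summit <- summit
  gr
}
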