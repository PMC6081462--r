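## Orchestration: a YAML-configurable end-to-end run over the synthetic
## study, writing per-stage TSV outputs, a manifest with input hashes and
## stage seeds, and a summary report.

defaultConfig <- function() {
  list(
    seed = 1,
    out = tempfile("brainchrom_run_"),
    scale = list(nSamples = 60, nPeaks = 300, nSnps = 2000,
                 chromLength = 1e6),
    truth = list(nDxPeaks = 10, dxLog2FC = 1.5, nCqtlPeaks = 20,
                 cqtlBeta = 0.8, ageSlopeSD = 0, pmiSlopeSD = 0),
    counts = list(dispersion = 0.2, meanDepth = 50),
    cqtl = list(window = 5000, nPerm = 200),
    h2 = list(windowBp = 1e6, nBlocks = 10, nGwas = 50000,
              tauPeak = 2e-4, tauBase = 2e-5),
    stages = list(simulate = TRUE, quantify = TRUE, qc = TRUE,
                  covariates = TRUE, diffacc = TRUE, cqtl = TRUE,
                  coloc = TRUE, h2 = TRUE))
}

validateConfig <- function(config) {
  base <- defaultConfig()
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(base, config %||% list())
  stopifnot(is.numeric(config$seed), length(config$seed) == 1L)
  for (s in names(base$stages))
    if (!is.logical(config$stages[[s]] %||% TRUE))
      stop("stage toggle '", s, "' must be logical")
  if (config$cqtl$nPerm < 100) stop("cqtl nPerm must be >= 100")
  config
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Stages execute in dependency order (simulate, quantify + TMM, shuffle
#' QC, covariate selection, differential scans, cQTL scan with allelic
#' validation, colocalization demo, heritability partition). Each stage
#' writes TSV outputs under `config$out`; a manifest records stage seeds
#' and output md5 hashes. The whole run is a pure function of the master
#' seed.
#'
#' @param config a config list or path to a YAML file; see
#'   `brainchrom:::defaultConfig()` for the schema and defaults.
#' @return invisibly, a list with stage results, the run directory and
#'   the manifest.
#' @export
runPipeline <- function(config = list()) {
  cfg <- validateConfig(config)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, files = list())
  results <- list()
  logMsg <- function(...) message("[brainchrom] ", ...)

  logMsg("simulate")
  sc <- cfg$scale; tr <- cfg$truth
  study <- simulateStudy(nSamples = sc$nSamples, nPeaks = sc$nPeaks,
                         nSnps = sc$nSnps, chromLength = sc$chromLength,
                         nDxPeaks = tr$nDxPeaks, dxLog2FC = tr$dxLog2FC,
                         nCqtlPeaks = tr$nCqtlPeaks, cqtlBeta = tr$cqtlBeta,
                         ageSlopeSD = tr$ageSlopeSD,
                         pmiSlopeSD = tr$pmiSlopeSD,
                         dispersion = cfg$counts$dispersion,
                         meanDepth = cfg$counts$meanDepth,
                         seed = cfg$seed)
  results$study <- study
  if (isTRUE(cfg$stages$simulate)) {
    manifest$files$metadata <- writeTsv(study$metadata,
                                        file.path(cfg$out, "metadata.tsv"))
    manifest$files$snp_map <- writeTsv(study$genotypes$map,
                                       file.path(cfg$out, "snp_map.tsv"))
    manifest$files$truth_peaks <- writeTsv(study$truth$peakEffects,
      file.path(cfg$out, "truth_peak_effects.tsv"))
    manifest$files$truth_cqtl <- writeTsv(study$truth$cqtlMap,
      file.path(cfg$out, "truth_cqtl.tsv"))
    manifest$files$peaks <- writeTsv(grToBed(study$peaks),
                                     file.path(cfg$out, "peaks.bed"))
  }

  cae <- study$cae
  if (isTRUE(cfg$stages$quantify)) {
    logMsg("quantify + TMM")
    cae <- tmmFactors(cae)
    manifest$files$counts <- writeTsv(
      data.frame(peak = rownames(counts(cae)), counts(cae),
                 check.names = FALSE),
      file.path(cfg$out, "counts.tsv"))
    manifest$files$factors <- writeTsv(
      data.frame(sample = colnames(cae), lib_size = libSizes(cae),
                 tmm_factor = normFactors(cae)),
      file.path(cfg$out, "tmm_factors.tsv"))
  }
  results$cae <- cae

  if (isTRUE(cfg$stages$qc)) {
    logMsg("shuffle-null QC")
    frSub <- simulateFragments(study$layout,
                               cae[, seq_len(min(6L, ncol(cae)))],
                               seed = cfg$seed)
    qc <- shuffleEnrichment(frSub, study$peaks, study$layout$mappable,
                            study$layout$blacklist, seed = cfg$seed)
    results$qc <- qc
    manifest$files$qc <- writeTsv(qc$perSample,
                                  file.path(cfg$out, "qc_enrichment.tsv"))
  }

  lcpm <- logCPM(counts(cae), libSizes(cae),
                 SummarizedExperiment::colData(cae)$tmm_factor %||%
                   rep(1, ncol(cae)))
  if (isTRUE(cfg$stages$covariates)) {
    logMsg("covariate selection")
    meta <- imputeMetadata(screenMetadata(study$metadata)$table,
                           seed = cfg$seed)
    sel <- selectCovariates(lcpm, meta, nPcs = min(10, ncol(cae) - 1L),
                            technicalVars = c("gc_content", "rin",
                                              "enrich_score", "batch"))
    results$covariates <- sel
    manifest$files$covariates <- writeTsv(sel@trace,
      file.path(cfg$out, "covariate_selection.tsv"))
  }

  if (isTRUE(cfg$stages$diffacc)) {
    logMsg("differential accessibility")
    covs <- if (!is.null(results$covariates))
      results$covariates@selected else character()
    da <- differentialScan(cae, "diagnosis",
                           covariates = intersect(covs,
                             colnames(study$metadata)))
    results$diffacc <- da
    manifest$files$diffacc <- writeTsv(da,
      file.path(cfg$out, "differential_diagnosis.tsv"))
  }

  if (isTRUE(cfg$stages$cqtl)) {
    logMsg("cQTL scan")
    pcs <- prcomp(t(lcpm), rank. = min(10L, ncol(cae) - 1L))$x
    cq <- cqtlScan(lcpm, study$peaks, study$genotypes$dosage,
                   study$genotypes$map, window = cfg$cqtl$window,
                   covariates = pcs, nPerm = cfg$cqtl$nPerm,
                   seed = cfg$seed)
    results$cqtl <- cq
    manifest$files$cqtl <- writeTsv(cq, file.path(cfg$out, "cqtl.tsv"))
    reads <- simulateAllelicReads(study$genotypes, study$peaks,
                                  study$truth$cqtlMap, seed = cfg$seed)
    if (nrow(reads) && nrow(study$truth$cqtlMap)) {
      ab <- alleleBiasAnalysis(reads, study$truth$cqtlMap[, c("snp", "beta")])
      results$alleleBias <- ab
      manifest$files$allele_bias <- writeTsv(ab$perSnp,
        file.path(cfg$out, "allele_bias.tsv"))
    }
  }

  if (isTRUE(cfg$stages$coloc)) {
    logMsg("colocalization demo")
    cc <- withSeed(deriveSeed(cfg$seed, "colocdemo"), {
      nS <- 50
      z1 <- rnorm(nS); z2 <- rnorm(nS)
      z1[25] <- 8; z2[25] <- 7.5
      colocPP(data.frame(z = z1), data.frame(z = z2))
    })
    results$coloc <- cc
    manifest$files$coloc <- writeTsv(
      data.frame(hypothesis = names(cc@pp), pp = unname(cc@pp)),
      file.path(cfg$out, "coloc.tsv"))
  }

  if (isTRUE(cfg$stages$h2)) {
    logMsg("heritability partition")
    A <- buildAnnotations(study$genotypes$map, study$peaks)
    A <- A[, c("base", grep("^peak_w", colnames(A), value = TRUE)),
           drop = FALSE]
    tau <- setNames(rep(0, ncol(A)), colnames(A))
    tau["base"] <- cfg$h2$tauBase
    tau[2L] <- cfg$h2$tauPeak
    ss <- simulateGWAS(study$genotypes, A, tau, cfg$h2$nGwas,
                       seed = cfg$seed)
    L <- ldScores(study$genotypes$dosage, study$genotypes$map, A,
                  cfg$h2$windowBp)
    pr <- stratifiedRegression(ss$Z^2, L, A, cfg$h2$nGwas,
                               nBlocks = cfg$h2$nBlocks)
    results$h2 <- pr
    manifest$files$h2 <- writeTsv(pr@table,
                                  file.path(cfg$out, "h2_partition.tsv"))
    manifest$files$gwas <- writeTsv(ss, file.path(cfg$out, "gwas.tsv"))
  }

  manifest$md5 <- vapply(unlist(manifest$files), function(f)
    unname(tools::md5sum(f)), "")
  yaml::write_yaml(list(seed = cfg$seed,
                        md5 = as.list(manifest$md5)),
                   file.path(cfg$out, "manifest.yaml"))
  results$manifest <- manifest
  results$runDir <- cfg$out
  results$config <- cfg
  invisible(results)
}

grToBed <- function(gr) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = paste0("summit=", gr$summit %||% NA),
             score = gr$support %||% 0L,
             strand = ".")
}

#' Summary report over pipeline outputs
#'
#' Builds the reporting surfaces of a run: the cohort association table,
#' counts of significant peaks per scan at 5% FDR, cQTL locality
#' fractions (in own peak, within +/- 2 kb of the peak center), and the
#' heritability enrichment table. Missing stages are listed and a
#' partial report is produced.
#'
#' @param run result list from [runPipeline()].
#' @param fdr significance level on q-values.
#' @return list of report tables; `missing` names absent stages.
#' @export
pipelineReport <- function(run, fdr = 0.05) {
  rep <- list(missing = character())
  md <- run$study$metadata
  rep$cohort <- testDxAssociation(md, vars = intersect(
    c("sex", "age", "pmi", "batch"), colnames(md)))
  if (!is.null(run$diffacc)) {
    rep$nSignificantDiff <- sum(run$diffacc$q < fdr, na.rm = TRUE)
  } else rep$missing <- c(rep$missing, "diffacc")
  if (!is.null(run$cqtl)) {
    sig <- run$cqtl[!is.na(run$cqtl$q) & run$cqtl$q < fdr, , drop = FALSE]
    if (nrow(sig)) {
      half <- floor(GenomicRanges::width(run$study$peaks)[1L] / 2)
      rep$cqtl <- list(
        nSignificant = nrow(sig),
        fracInOwnPeak = mean(abs(sig$distance) <= half),
        fracWithin2kb = mean(abs(sig$distance) <= 2000))
    } else rep$cqtl <- list(nSignificant = 0L,
                            note = "no significant cQTLs")
  } else rep$missing <- c(rep$missing, "cqtl")
  if (!is.null(run$h2)) rep$h2 <- run$h2@table
  else rep$missing <- c(rep$missing, "h2")
  rep
}
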