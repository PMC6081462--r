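#' ChromAccExperiment: peaks-by-samples accessibility counts
#'
#' Container for a quantified chromatin accessibility experiment: fixed-width
#' peaks (rowRanges, with `summit` and `support` metadata columns), the raw
#' fragment counts (assay `"counts"`), per-sample total mapped fragments
#' (`colData$lib_size`) and, once computed, TMM scaling factors
#' (`colData$tmm_factor`, geometric mean 1).
#'
#' @slot .. inherits all slots from [SummarizedExperiment::RangedSummarizedExperiment].
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @export
setClass("ChromAccExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("ChromAccExperiment", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"lib_size" %in% colnames(cd))
    msg <- c(msg, "colData must contain 'lib_size'")
  else if ("counts" %in% SummarizedExperiment::assayNames(object)) {
    if (any(cd$lib_size + 1e-9 <
            colSums(SummarizedExperiment::assay(object, "counts"))))
      msg <- c(msg, "lib_size must be >= column sums of counts")
  }
  if ("tmm_factor" %in% colnames(cd)) {
    f <- cd$tmm_factor
    if (any(f <= 0)) msg <- c(msg, "tmm_factor must be positive")
    else if (abs(mean(log(f))) > 1e-9)
      msg <- c(msg, "tmm_factor must have geometric mean 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a ChromAccExperiment
#'
#' @param counts integer matrix, peaks x samples.
#' @param peaks [GenomicRanges::GRanges] of standardized peaks; metadata
#'   columns `summit` (bp) and `support` (number of contributing samples)
#'   are carried along when present.
#' @param libSize per-sample total mapped fragments; defaults to the column
#'   sums of `counts`.
#' @param colData optional extra per-sample annotation (DataFrame/data.frame).
#' @return A [ChromAccExperiment-class] object.
#' @examples
#' pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 501), width = 300))
#' cae <- ChromAccExperiment(matrix(1:4, 2), pk)
#' @export
ChromAccExperiment <- function(counts, peaks, libSize = NULL,
                               colData = NULL) {
  counts <- as.matrix(counts)
  mode(counts) <- "numeric"
  if (length(peaks) != nrow(counts))
    stop("length(peaks) must equal nrow(counts)")
  if (is.null(libSize)) libSize <- colSums(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (is.null(names(peaks)))
    names(peaks) <- peakIds(peaks)
  rownames(counts) <- names(peaks)
  cd <- S4Vectors::DataFrame(lib_size = as.numeric(libSize),
                             row.names = colnames(counts))
  if (!is.null(colData)) {
    extra <- S4Vectors::DataFrame(colData)
    cd <- cbind(cd, extra[, setdiff(colnames(extra), "lib_size"),
                          drop = FALSE])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowRanges = peaks, colData = cd)
  methods::new("ChromAccExperiment", se)
}

peakIds <- function(gr) {
  paste0(GenomeInfoDb::seqnames(gr), ":", GenomicRanges::start(gr) - 1L,
         "-", GenomicRanges::end(gr))
}

#' @describeIn ChromAccExperiment raw count matrix accessor
#' @param object,x a ChromAccExperiment
#' @importFrom BiocGenerics counts
#' @exportMethod counts
setMethod("counts", "ChromAccExperiment", function(object)
  SummarizedExperiment::assay(object, "counts"))

#' Accessors for library sizes and TMM factors
#'
#' @param object a [ChromAccExperiment-class]
#' @return numeric vector, one entry per sample. `normFactors` errors when
#'   TMM factors have not been computed yet (see [tmmFactors()]).
#' @export
libSizes <- function(object) SummarizedExperiment::colData(object)$lib_size

#' @rdname libSizes
#' @export
normFactors <- function(object) {
  f <- SummarizedExperiment::colData(object)$tmm_factor
  if (is.null(f)) stop("TMM factors not computed; run tmmFactors() first")
  f
}

setMethod("show", "ChromAccExperiment", function(object) {
  cat("ChromAccExperiment:", nrow(object), "peaks x", ncol(object),
      "samples\n")
  cat("  median lib size:", format(median(libSizes(object))), "\n")
  f <- SummarizedExperiment::colData(object)$tmm_factor
  cat("  TMM factors:", if (is.null(f)) "not computed"
      else paste0("range [", signif(min(f), 3), ", ", signif(max(f), 3), "]"),
      "\n")
})

#' Result of an iterative PC-based covariate selection
#'
#' @slot selected ordered character vector of chosen variables.
#' @slot trace per-iteration record (variable, PC, p, threshold, varExplained).
#' @slot status "converged", "max_iterations" or "collinearity".
#' @export
setClass("CovariateSelection",
         representation(selected = "character", trace = "data.frame",
                        status = "character"))

setValidity("CovariateSelection", function(object) {
  if (anyDuplicated(object@selected)) "selected variables must be unique"
  else if (nrow(object@trace) &&
           any(object@trace$p > object@trace$threshold))
    "every recorded p must be below its threshold"
  else TRUE
})

setMethod("show", "CovariateSelection", function(object) {
  cat("CovariateSelection:", length(object@selected), "variables (",
      object@status, ")\n", sep = " ")
  if (length(object@selected))
    cat("  ", paste(object@selected, collapse = " -> "), "\n")
})

#' Colocalization posterior probabilities for one region pair
#'
#' Posterior support for the five hypotheses: H0 no association, H1/H2
#' association with one trait only, H3 two distinct causal variants, H4 one
#' shared causal variant.
#'
#' @slot pp named numeric of length 5 (PP0..PP4), sums to 1.
#' @slot nSnps number of SNPs tested.
#' @slot priors p1, p2, p12.
#' @slot labf1,labf2 per-SNP log approximate Bayes factors.
#' @export
setClass("ColocResult",
         representation(pp = "numeric", nSnps = "integer",
                        priors = "numeric", labf1 = "numeric",
                        labf2 = "numeric"))

setValidity("ColocResult", function(object) {
  if (length(object@pp) != 5L) "pp must have length 5"
  else if (abs(sum(object@pp) - 1) > 1e-9) "pp must sum to 1"
  else if (any(object@pp < -1e-12 | object@pp > 1 + 1e-12))
    "pp must lie in [0,1]"
  else TRUE
})

setMethod("show", "ColocResult", function(object) {
  cat("ColocResult over", object@nSnps, "SNPs\n")
  print(round(object@pp, 4))
})

#' Stratified heritability partition result
#'
#' @slot table per-category data.frame: category, propSnps, propH2, tau,
#'   tauSE, enrichment, enrichmentSE, z, p.
#' @slot h2 total estimated (standardized-scale) SNP heritability.
#' @slot intercept regression intercept.
#' @export
setClass("PartitionResult",
         representation(table = "data.frame", h2 = "numeric",
                        intercept = "numeric"))

setValidity("PartitionResult", function(object) {
  tb <- object@table
  need <- c("category", "propSnps", "propH2", "tau", "enrichment")
  if (!all(need %in% colnames(tb))) "table is missing required columns"
  else if (any(tb$propSnps <= 0 | tb$propSnps > 1))
    "propSnps must lie in (0,1]"
  else TRUE
})

setMethod("show", "PartitionResult", function(object) {
  cat("PartitionResult: h2 =", signif(object@h2, 3),
      " intercept =", signif(object@intercept, 3), "\n")
  print(object@table[, c("category", "propSnps", "propH2", "enrichment",
                         "enrichmentSE", "z")], digits = 3)
})
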