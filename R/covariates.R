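## Metadata screening, imputation, diagnosis-association tests, iterative
## PC-based covariate selection, and genotype-concordance identity checks.

#' Screen a metadata table
#'
#' Drops variables that are invariant, have a missing fraction above
#' `maxMissing`, or are categorical with more than `maxLevels` levels.
#' `diagnosis` and `sex` are protected: the screen erroring out rather
#' than dropping them.
#'
#' @param table data.frame, one row per sample.
#' @param maxMissing maximum tolerated missing fraction.
#' @param maxLevels maximum levels for categorical variables.
#' @param protect variables that must survive.
#' @return list: `table` (reduced), `log` (data.frame variable, reason).
#' @export
screenMetadata <- function(table, maxMissing = 0.05, maxLevels = 30,
                           protect = c("diagnosis", "sex")) {
  if (!nrow(table)) stop("empty metadata table")
  drop <- character(); reason <- character()
  for (v in setdiff(colnames(table), "sample")) {
    x <- table[[v]]
    missFrac <- mean(is.na(x))
    why <- NULL
    if (missFrac > maxMissing) why <- "missing"
    else if (length(unique(x[!is.na(x)])) <= 1L) why <- "invariant"
    else if ((is.character(x) || is.factor(x)) &&
             length(unique(x[!is.na(x)])) > maxLevels) why <- "levels"
    if (!is.null(why)) {
      if (v %in% protect)
        stop("protected variable '", v, "' fails screening (", why, ")")
      drop <- c(drop, v); reason <- c(reason, why)
    }
  }
  list(table = table[, !(colnames(table) %in% drop), drop = FALSE],
       log = data.frame(variable = drop, reason = reason))
}

#' Impute missing metadata values
#'
#' Numeric variables take the median of observed values; categorical
#' variables are sampled from the observed level frequencies
#' (seed-reproducible). No missing values remain.
#'
#' @param table screened data.frame.
#' @param seed integer seed.
#' @return completed data.frame.
#' @export
imputeMetadata <- function(table, seed = 1) {
  withSeed(deriveSeed(seed, "impute"), {
    for (v in colnames(table)) {
      x <- table[[v]]
      miss <- is.na(x)
      if (!any(miss)) next
      if (all(miss)) stop("variable '", v, "' has no observed values")
      if (is.numeric(x)) x[miss] <- median(x[!miss])
      else {
        obs <- x[!miss]
        x[miss] <- sample(obs, sum(miss), replace = TRUE)
      }
      table[[v]] <- x
    }
    table
  })
}

#' Association of metadata variables with diagnosis
#'
#' Numeric variables: one-way regression on the diagnosis indicator
#' (F statistic). Categorical variables: Pearson chi-squared on the full
#' level x diagnosis contingency table, without continuity correction.
#' Bonferroni threshold is 0.05 / number of variables tested.
#'
#' @param table data.frame with a `diagnosis` column (both levels present).
#' @param vars variables to test; default all except sample/diagnosis.
#' @return data.frame variable, type, statistic, df, p, bonferroni.
#' @examples
#' tab <- data.frame(diagnosis = rep(c("case", "control"), c(135, 137)),
#'                   sex = c(rep("M", 92), rep("F", 43),
#'                           rep("M", 73), rep("F", 64)))
#' testDxAssociation(tab)$statistic  # 6.30
#' @export
testDxAssociation <- function(table, vars = NULL) {
  dx <- factor(table$diagnosis)
  if (nlevels(dx) != 2L) stop("diagnosis must have exactly two levels")
  if (is.null(vars))
    vars <- setdiff(colnames(table), c("sample", "diagnosis"))
  res <- lapply(vars, function(v) {
    x <- table[[v]]
    ok <- !is.na(x)
    if (is.numeric(x)) {
      if (stats::sd(x[ok]) == 0)
        return(data.frame(variable = v, type = "numeric", statistic = 0,
                          df = 1L, p = 1))
      fit <- stats::anova(stats::lm(x[ok] ~ dx[ok]))
      data.frame(variable = v, type = "numeric",
                 statistic = fit$`F value`[1L], df = fit$Df[1L],
                 p = fit$`Pr(>F)`[1L])
    } else {
      tabx <- table(factor(x[ok]), dx[ok])
      zero <- rowSums(tabx) == 0
      if (any(zero)) {
        warning("dropping all-zero level(s) of '", v, "'")
        tabx <- tabx[!zero, , drop = FALSE]
      }
      ct <- suppressWarnings(stats::chisq.test(tabx, correct = FALSE))
      data.frame(variable = v, type = "categorical",
                 statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p = unname(ct$p.value))
    }
  })
  out <- do.call(rbind, res)
  out$bonferroni <- out$p < 0.05 / nrow(out)
  out
}

#' Iterative PC-based covariate selection
#'
#' Repeats: PCA of the current residualized log-normalized matrix; simple
#' regression of every candidate variable on each of the top `nPcs` PCs;
#' stop when no (variable, PC) pair passes the Bonferroni threshold
#' `alpha / (n_vars * nPcs)`; otherwise pick one variable by the priority
#' rules — (1) assay-technical tag, (2) largest variance explained on its
#' best PC, (3) fewest parameters, (4) lexicographic — residualize the
#' matrix against all selected variables, and continue.
#'
#' @param logCounts log-normalized matrix, peaks x samples (see
#'   [logCPM()]); PCA runs on samples.
#' @param table complete metadata (no missing values).
#' @param nPcs number of leading PCs tested.
#' @param alpha family-wise level before Bonferroni division.
#' @param technicalVars variables tagged assay-technical (priority 1).
#' @param candidates candidate variables; default all metadata columns
#'   except `sample`.
#' @param maxIter selection-depth cap.
#' @param condCap condition-number cap on the selected design; exceeding
#'   it stops with status `"collinearity"`.
#' @return [CovariateSelection-class].
#' @export
selectCovariates <- function(logCounts, table, nPcs = 20, alpha = 0.05,
                             technicalVars = character(),
                             candidates = NULL, maxIter = 25,
                             condCap = 1e8) {
  if (is.null(candidates))
    candidates <- setdiff(colnames(table), "sample")
  X <- t(as.matrix(logCounts))          # samples x peaks
  n <- nrow(X)
  nPcs <- min(nPcs, n - 1L)
  if (n < nPcs + 1L) stop("need at least nPcs + 1 samples")
  selected <- character()
  trace <- data.frame(iteration = integer(), variable = character(),
                      pc = integer(), p = numeric(), threshold = numeric(),
                      varExplained = numeric())
  status <- "max_iterations"
  resid <- scale(X, scale = FALSE)
  for (it in seq_len(maxIter)) {
    pca <- prcomp(resid, center = TRUE, scale. = FALSE, rank. = nPcs)
    pcs <- pca$x[, seq_len(min(nPcs, ncol(pca$x))), drop = FALSE]
    cand <- setdiff(candidates, selected)
    if (!length(cand)) { status <- "converged"; break }
    thr <- alpha / (length(cand) * ncol(pcs))
    best <- NULL
    for (v in cand) {
      mm <- covariateMatrix(table, v)
      if (!ncol(mm) || qr(cbind(1, mm))$rank <= 1L) next
      for (j in seq_len(ncol(pcs))) {
        fit <- stats::lm(pcs[, j] ~ mm)
        an <- stats::anova(fit)
        p <- an$`Pr(>F)`[1L]
        r2 <- summary(fit)$r.squared *
          (pca$sdev[j]^2 / sum(pca$sdev^2))
        if (!is.na(p) && p < thr) {
          rec <- list(variable = v, pc = j, p = p, r2 = r2,
                      npar = ncol(mm),
                      tech = v %in% technicalVars)
          if (is.null(best) || priorityBefore(rec, best)) best <- rec
        }
      }
    }
    if (is.null(best)) {
      status <- "converged"
      ## candidates fully spanned by the selected design mirror the
      ## study's unresolvable covariates
      if (length(selected)) {
        des0 <- covariateMatrix(table, selected)
        spanned <- vapply(cand, function(v) {
          mm <- covariateMatrix(table, v)
          ncol(mm) > 0 &&
            sum(residualize(mm, des0)^2) < 1e-10 * max(sum(mm^2), 1e-300)
        }, TRUE)
        if (any(spanned)) status <- "collinearity"
      }
      break
    }
    selected <- c(selected, best$variable)
    trace <- rbind(trace, data.frame(
      iteration = it, variable = best$variable, pc = best$pc,
      p = best$p, threshold = thr, varExplained = best$r2))
    des <- covariateMatrix(table, selected)
    d <- svd(scale(des, scale = FALSE))$d
    if (length(d) > 1L && d[1L] / max(d[length(d)], 1e-300) > condCap) {
      status <- "collinearity"; break
    }
    resid <- residualize(X, des)
  }
  methods::new("CovariateSelection", selected = selected, trace = trace,
               status = status)
}

## priority comparison: technical tag, variance explained, parsimony, name
priorityBefore <- function(a, b) {
  if (a$tech != b$tech) return(a$tech)
  if (abs(a$r2 - b$r2) > 1e-12) return(a$r2 > b$r2)
  if (a$npar != b$npar) return(a$npar < b$npar)
  a$variable < b$variable
}

#' Genotype-concordance sample identity matching
#'
#' Concordance between two dosage matrices over shared SNPs: the fraction
#' of sites where rounded dosages agree. Flags samples whose best match is
#' not the expected pairing or whose concordance falls below `minConc`.
#'
#' @param dosagesA,dosagesB samples x SNPs dosage matrices (named rows and
#'   columns).
#' @param minSites minimum shared SNPs required.
#' @param expected named character: expected B-sample for each A-sample;
#'   default same name.
#' @param minConc concordance floor for a confident match.
#' @return list: `concordance` (A x B matrix), `bestMatch` (data.frame),
#'   `mismatches` (subset flagged).
#' @export
matchSampleIdentity <- function(dosagesA, dosagesB, minSites = 100,
                                expected = NULL, minConc = 0.8) {
  shared <- intersect(colnames(dosagesA), colnames(dosagesB))
  if (length(shared) < minSites)
    stop("only ", length(shared), " shared SNPs (< ", minSites, ")")
  A <- round(dosagesA[, shared, drop = FALSE])
  B <- round(dosagesB[, shared, drop = FALSE])
  conc <- matrix(0, nrow(A), nrow(B),
                 dimnames = list(rownames(A), rownames(B)))
  for (g in 0:2)
    conc <- conc + (A == g) %*% t(B == g)
  conc <- conc / length(shared)
  if (is.null(expected))
    expected <- setNames(rownames(A), rownames(A))
  bi <- max.col(conc, ties.method = "first")
  best <- data.frame(sampleA = rownames(A),
                     bestB = colnames(conc)[bi],
                     concordance = conc[cbind(seq_len(nrow(A)), bi)])
  best$expectedB <- unname(expected[best$sampleA])
  best$mismatch <- is.na(best$expectedB) | best$bestB != best$expectedB |
    best$concordance < minConc
  list(concordance = conc, bestMatch = best,
       mismatches = best[best$mismatch, , drop = FALSE])
}
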