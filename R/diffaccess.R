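## Negative-binomial differential accessibility with sex-chromosome-aware
## routing: autosomes use the full model, chrX is meta-analyzed across
## sex strata by inverse-variance weighting, chrY is tested in males only.

#' Negative-binomial GLM for one peak
#'
#' Maximum-likelihood NB regression with log link at fixed dispersion
#' (var = mu + dispersion * mu^2) via iteratively reweighted least
#' squares. Wald statistic is beta/se against a standard normal.
#'
#' @param y counts for one peak.
#' @param X design matrix (including intercept).
#' @param offsets per-sample log offsets (e.g. log effective library
#'   size); defaults to 0.
#' @param dispersion NB dispersion alpha; 0 gives the Poisson limit.
#' @param maxIter,tol IRLS controls.
#' @return list: `beta` (natural log), `log2Beta`, `se`, `wald`, `p`,
#'   `converged`, `cov`, `mu`. Non-convergence leaves p = NA.
#' @examples
#' X <- cbind(1, c(0, 1))
#' fitNBPeak(c(10, 40), X, dispersion = 1e-8)$log2Beta[2]  # 2
#' @export
fitNBPeak <- function(y, X, offsets = NULL, dispersion = 0,
                      maxIter = 50, tol = 1e-8) {
  X <- as.matrix(X)
  n <- length(y)
  if (is.null(offsets)) offsets <- rep(0, n)
  if (!all(is.finite(offsets))) stop("offsets must be finite")
  if (qr(X)$rank < ncol(X)) stop("design is not full rank")
  beta <- qr.coef(qr(X), log(y + 0.5) - offsets)
  beta[is.na(beta)] <- 0
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    eta <- drop(X %*% beta) + offsets
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + dispersion * mu)
    z <- (eta - offsets) + (y - mu) / mu
    fit <- lm.wfit(X, z, w)
    newBeta <- fit$coefficients
    if (anyNA(newBeta)) break
    if (max(abs(newBeta - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- newBeta; converged <- TRUE; break
    }
    beta <- newBeta
  }
  eta <- pmin(pmax(drop(X %*% beta) + offsets, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + dispersion * mu)
  XtWX <- crossprod(X * sqrt(w))
  covB <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(covB)) {
    se <- rep(NA_real_, length(beta)); converged <- FALSE
  } else se <- sqrt(pmax(diag(covB), 0))
  wald <- beta / se
  p <- if (converged) 2 * pnorm(-abs(wald)) else rep(NA_real_, length(beta))
  list(beta = beta, log2Beta = beta / log(2), se = se,
       log2Se = se / log(2), wald = wald, p = p,
       converged = converged, cov = covB, mu = mu)
}

#' Per-peak dispersion with trend shrinkage
#'
#' Method-of-moments estimate on design residuals (Poisson fitted means),
#' floored at 1e-8, then shrunk 50/50 toward a mean-dispersion lowess
#' trend fit across peaks.
#'
#' @param object [ChromAccExperiment-class] or count matrix.
#' @param design design matrix (intercept included).
#' @param offsets log offsets; defaults to log effective library size for
#'   a ChromAccExperiment with TMM factors, else log column sums.
#' @param shrink weight on the trend (0.5).
#' @return numeric per-peak dispersions.
#' @export
estimateDispersion <- function(object, design, offsets = NULL,
                               shrink = 0.5) {
  cts <- if (methods::is(object, "ChromAccExperiment")) counts(object)
         else as.matrix(object)
  if (ncol(cts) < 2L) stop("dispersion needs more than one sample")
  if (is.null(offsets)) offsets <- defaultOffsets(object)
  n <- ncol(cts); p <- ncol(design)
  if (n - p < 8L)
    warning("fewer than 8 residual degrees of freedom; estimates unstable")
  raw <- numeric(nrow(cts))
  for (g in seq_len(nrow(cts))) {
    fit <- fitNBPeak(cts[g, ], design, offsets, dispersion = 0)
    mu <- fit$mu
    num <- sum((cts[g, ] - mu)^2 - mu)
    den <- sum(mu^2)
    raw[g] <- max((num / den) * n / max(n - p, 1L), 1e-8)
  }
  mn <- rowMeans(cts)
  ok <- mn > 0 & raw > 1e-8
  if (sum(ok) >= 10) {
    tr <- lowess(log(mn[ok]), log(raw[ok]), f = 0.5)
    trend <- exp(approx(tr$x, tr$y, xout = log(pmax(mn, min(mn[ok]))),
                        rule = 2, ties = mean)$y)
  } else trend <- rep(stats::median(raw), length(raw))
  pmax((1 - shrink) * raw + shrink * trend, 1e-8)
}

defaultOffsets <- function(object) {
  if (methods::is(object, "ChromAccExperiment")) {
    f <- SummarizedExperiment::colData(object)$tmm_factor
    if (is.null(f)) f <- rep(1, ncol(object))
    log(libSizes(object) * f)
  } else log(pmax(colSums(as.matrix(object)), 1))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH with monotone enforcement; NA p-values propagate as NA and
#' do not count toward the number of tests.
#'
#' @param p numeric p-values in [0,1] (NA allowed).
#' @return q-values, same length/order.
#' @export
bhFDR <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

## inverse-variance-weighted combination of per-stratum estimates
ivwMeta <- function(betas, ses) {
  ok <- is.finite(betas) & is.finite(ses) & ses > 0
  if (!any(ok)) return(c(beta = NA_real_, se = NA_real_))
  w <- 1 / ses[ok]^2
  c(beta = sum(w * betas[ok]) / sum(w), se = 1 / sqrt(sum(w)))
}

#' Differential accessibility scan
#'
#' Per-peak NB Wald test for `variable` (diagnosis, age or pmi) adjusting
#' for the selected covariates and sex. Autosomal peaks use the full
#' model; chrX peaks are fit separately in males and females (sex dropped)
#' and combined by inverse-variance weighting; chrY peaks are tested in
#' males only. BH FDR is applied across all peaks of the scan.
#'
#' @param cae [ChromAccExperiment-class] with TMM factors.
#' @param variable one of `"diagnosis"`, `"age"`, `"pmi"` (any metadata
#'   column works; diagnosis is coded case vs control).
#' @param covariates character vector of adjustment variables (e.g. from
#'   [selectCovariates()]); sex is added automatically off the sex
#'   chromosomes.
#' @param metadata data.frame; defaults to `colData(cae)`.
#' @param dispersion per-peak dispersions; estimated when NULL.
#' @param sizeFactor `"tmm"` (log lib_size * tmm_factor offsets) or
#'   `"median-ratio"` (DESeq-style).
#' @param minStratum strata below this size degrade chrX to the other
#'   stratum alone, with a warning.
#' @return data.frame: peak, chrom, variable, beta (log2), se, stat, p, q,
#'   route, and per-stratum columns for meta-analyzed peaks.
#' @export
differentialScan <- function(cae, variable, covariates = character(),
                             metadata = NULL, dispersion = NULL,
                             sizeFactor = c("tmm", "median-ratio"),
                             minStratum = 3L) {
  sizeFactor <- match.arg(sizeFactor)
  if (is.null(metadata))
    metadata <- as.data.frame(SummarizedExperiment::colData(cae))
  cts <- counts(cae)
  offsets <- if (sizeFactor == "tmm") defaultOffsets(cae)
             else medianRatioOffsets(cts)
  chrom <- as.character(GenomeInfoDb::seqnames(
    SummarizedExperiment::rowRanges(cae)))
  covariates <- setdiff(covariates, variable)
  vTerm <- function(md) {
    if (variable == "diagnosis") as.numeric(md$diagnosis == "case")
    else as.numeric(md[[variable]])
  }
  buildDesign <- function(md, withSex) {
    vars <- covariates
    if (withSex) vars <- unique(c(vars, "sex"))
    mm <- covariateMatrix(md, vars)
    X <- cbind(`(Intercept)` = 1, mm, effect = vTerm(md))
    ## drop aliased columns (e.g. constant within a stratum)
    keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L,
                          function(c) stats::sd(c) > 0))
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    X
  }
  Xfull <- buildDesign(metadata, withSex = "sex" %in% colnames(metadata))
  if (is.null(dispersion))
    dispersion <- estimateDispersion(cts, Xfull, offsets)
  male <- which(metadata$sex == "M")
  female <- which(metadata$sex == "F")
  strata <- list(M = male, F = female)
  Xs <- lapply(strata, function(ix) buildDesign(metadata[ix, , drop = FALSE],
                                                withSex = FALSE))
  fitOne <- function(g, ix, X) {
    f <- fitNBPeak(cts[g, ix], X, offsets[ix], dispersion[g])
    j <- match("effect", colnames(X))
    c(beta = unname(f$log2Beta[j]), se = unname(f$log2Se[j]),
      p = unname(f$p[j]), conv = as.numeric(f$converged))
  }
  n <- nrow(cts)
  out <- data.frame(peak = rownames(cts), chrom = chrom,
                    variable = variable, beta = NA_real_, se = NA_real_,
                    stat = NA_real_, p = NA_real_, route = "full",
                    betaM = NA_real_, seM = NA_real_,
                    betaF = NA_real_, seF = NA_real_,
                    stringsAsFactors = FALSE)
  for (g in seq_len(n)) {
    if (chrom[g] == "chrY") {
      out$route[g] <- "chrY-male-only"
      r <- fitOne(g, male, Xs$M)
      out$beta[g] <- r["beta"]; out$se[g] <- r["se"]; out$p[g] <- r["p"]
    } else if (chrom[g] == "chrX") {
      out$route[g] <- "chrX-ivw-meta"
      rs <- lapply(c("M", "F"), function(s) {
        ix <- strata[[s]]
        if (length(ix) < minStratum) return(NULL)
        fitOne(g, ix, Xs[[s]])
      })
      names(rs) <- c("M", "F")
      okStr <- !vapply(rs, is.null, TRUE)
      if (sum(okStr) < 2L)
        warning("chrX peak ", rownames(cts)[g],
                ": single usable stratum, degraded route")
      conv <- vapply(rs[okStr], function(r) r["conv"] > 0, TRUE)
      use <- rs[okStr][conv]
      if (length(use)) {
        m <- ivwMeta(vapply(use, `[[`, 1, "beta"),
                     vapply(use, `[[`, 1, "se"))
        out$beta[g] <- m["beta"]; out$se[g] <- m["se"]
        out$p[g] <- 2 * pnorm(-abs(m["beta"] / m["se"]))
      }
      if (!is.null(rs$M)) { out$betaM[g] <- rs$M["beta"]; out$seM[g] <- rs$M["se"] }
      if (!is.null(rs$F)) { out$betaF[g] <- rs$F["beta"]; out$seF[g] <- rs$F["se"] }
    } else {
      r <- fitOne(g, seq_len(ncol(cts)), Xfull)
      out$beta[g] <- r["beta"]; out$se[g] <- r["se"]; out$p[g] <- r["p"]
    }
  }
  out$stat <- out$beta / out$se
  out$q <- bhFDR(out$p)
  out
}

medianRatioOffsets <- function(cts) {
  lg <- log(cts)
  lg[!is.finite(lg)] <- NA
  ref <- rowMeans(lg, na.rm = FALSE)
  ok <- is.finite(ref)
  sf <- apply(lg[ok, , drop = FALSE], 2L, function(col)
    exp(median(col - ref[ok], na.rm = TRUE)))
  log(sf / exp(mean(log(sf))) * mean(colSums(cts)))
}

#' Greedy matched case-control subset
#'
#' 1:1 nearest-neighbor matching within sex on the standardized Euclidean
#' distance over numeric matching variables, subject to a caliper.
#'
#' @param metadata complete data.frame with `diagnosis` and `sex`.
#' @param matchOn numeric variables to match on.
#' @param caliper maximum allowed distance for a pair.
#' @param nPairs requested number of pairs; fewer are returned (with a
#'   warning) when the caliper cannot be met.
#' @return list: `pairs` (data.frame case, control, distance), `balance`
#'   (standardized mean differences before/after).
#' @export
matchedSubset <- function(metadata, matchOn, caliper = Inf,
                          nPairs = Inf) {
  if (any(!matchOn %in% colnames(metadata)))
    stop("unknown matching variable(s)")
  Z <- scale(as.matrix(metadata[, matchOn, drop = FALSE]))
  Z[is.nan(Z)] <- 0
  pairs <- data.frame(case = character(), control = character(),
                      distance = numeric())
  for (s in unique(metadata$sex)) {
    ci <- which(metadata$diagnosis == "case" & metadata$sex == s)
    ki <- which(metadata$diagnosis == "control" & metadata$sex == s)
    while (length(ci) && length(ki) && nrow(pairs) < nPairs) {
      D <- as.matrix(stats::dist(rbind(Z[ci, , drop = FALSE],
                                       Z[ki, , drop = FALSE])))
      D <- D[seq_along(ci), length(ci) + seq_along(ki), drop = FALSE]
      m <- which(D == min(D), arr.ind = TRUE)[1L, ]
      if (D[m[1L], m[2L]] > caliper) break
      pairs <- rbind(pairs, data.frame(
        case = metadata$sample[ci[m[1L]]] %||% as.character(ci[m[1L]]),
        control = metadata$sample[ki[m[2L]]] %||% as.character(ki[m[2L]]),
        distance = D[m[1L], m[2L]]))
      ci <- ci[-m[1L]]; ki <- ki[-m[2L]]
    }
  }
  if (is.finite(nPairs) && nrow(pairs) < nPairs)
    warning("only ", nrow(pairs), " pairs within caliper")
  sel <- metadata$sample %in% c(pairs$case, pairs$control)
  smd <- vapply(matchOn, function(v) {
    x <- metadata[[v]][sel]
    d <- metadata$diagnosis[sel]
    (mean(x[d == "case"]) - mean(x[d == "control"])) /
      max(sd(x), 1e-12)
  }, 1)
  list(pairs = pairs, balance = data.frame(variable = matchOn, smd = smd))
}
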