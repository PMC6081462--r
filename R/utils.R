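#' @import methods
#' @importFrom stats lm.fit lm.wfit coef median pnorm pchisq pbeta qnorm rnorm runif
#'   rbinom rnbinom prcomp sd var cor p.adjust smooth.spline predict lowess
#'   approx ks.test dbinom pt qbeta quantile complete.cases model.matrix
#'   setNames binom.test
#' @importFrom utils head read.table write.table
NULL

## Deterministic child seeds: one master seed fans out to named stages so
## that changing one stage's draws never perturbs another's.
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 2654435761 + h * 97 + 12345) %% 2147483647)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

logSumExp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## log(exp(a) - exp(b)) for a >= b, guarded against cancellation
logDiffExp <- function(a, b) {
  if (b > a + 1e-12) stop("logDiffExp requires a >= b")
  if (!is.finite(b)) return(a)
  d <- b - a
  if (d > -1e-15) return(-Inf)
  a + log1p(-exp(d))
}

## Residualize columns of y against covariate matrix X (with intercept added).
residualize <- function(y, X = NULL) {
  y <- as.matrix(y)
  if (is.null(X) || ncol(as.matrix(X)) == 0L) X1 <- matrix(1, nrow(y), 1L)
  else X1 <- cbind(1, as.matrix(X))
  qr.resid(qr(X1), y)
}

#' log2 counts-per-million with TMM-scaled library sizes
#'
#' `log2(count / (lib_size * tmm_factor) * 1e6 + 0.5)` — the normalized
#' phenotype used for PCA, covariate selection and cQTL mapping.
#'
#' @param counts peaks x samples matrix.
#' @param libSize per-sample library sizes.
#' @param tmmFactor per-sample TMM factors (default 1).
#' @return matrix of the same shape.
#' @export
logCPM <- function(counts, libSize, tmmFactor = rep(1, length(libSize))) {
  eff <- libSize * tmmFactor
  log2(sweep(as.matrix(counts), 2L, eff / 1e6, "/") + 0.5)
}

#' Rank-based inverse normal transform
#' @param x numeric vector.
#' @return normal scores, ties averaged.
#' @export
rankNormal <- function(x) {
  qnorm((rank(x, ties.method = "average") - 0.5) / sum(!is.na(x)))
}

## model matrix from a metadata data.frame for a set of variable names;
## categoricals expand to treatment contrasts
covariateMatrix <- function(metadata, vars) {
  if (!length(vars)) return(matrix(0, nrow(metadata), 0L))
  df <- metadata[, vars, drop = FALSE]
  for (v in names(df)) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  ## variables invariant on this subset carry no information
  keep <- vapply(df, function(x) length(unique(x)) > 1L, TRUE)
  df <- df[, keep, drop = FALSE]
  if (!ncol(df)) return(matrix(0, nrow(metadata), 0L))
  mm <- model.matrix(~ ., data = df)
  mm[, -1L, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
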