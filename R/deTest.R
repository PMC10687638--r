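## Two-group negative-binomial exact test with common dispersion.
##
## The test conditions on the total count of both groups: with per-group
## sums S_A, S_B and T = S_A + S_B, the sum of n i.i.d. NB(mu, phi) counts
## is NB(n * mu, phi / n), and with equalized effective libraries the
## conditional law of S_A given T does not depend on the common mean. The
## two-sided p-value sums the probabilities of all splits no more likely
## than the observed one (minimum-likelihood method), capped at 1.
## phi = 0 degenerates to the Poisson limit, where the conditional law is
## Binomial(T, n_A / (n_A + n_B)).

.logsumexp <- function(lp) {
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

#' Exact conditional NB test for two groups of counts
#'
#' @param yA,yB numeric count vectors for the two groups (pseudo-counts
#'   equalized to a common effective library; see
#'   [equalizePseudoCounts()]). Sums are rounded to integers.
#' @param phi common NB dispersion (variance = mu + phi * mu^2); either a
#'   number or a [DispersionModel-class].
#' @return two-sided p-value in (0, 1].
#' @examples
#' nbExactTest(10, 0, phi = 0)   # binomial oracle: 2/1024
#' nbExactTest(c(5, 5), c(5, 5), phi = 0.1)  # symmetric split -> 1
#' @export
nbExactTest <- function(yA, yB, phi) {
  if (is(phi, "DispersionModel")) phi <- dispersion(phi)
  sA <- round(sum(yA)); sB <- round(sum(yB))
  tot <- sA + sB
  if (tot == 0) return(1)
  nA <- length(yA); nB <- length(yB)
  m <- tot / (nA + nB)
  s <- 0:tot
  if (phi <= 0) {
    lp <- dpois(s, nA * m, log = TRUE) + dpois(tot - s, nB * m, log = TRUE)
  } else {
    lp <- dnbinom(s, size = nA / phi, mu = nA * m, log = TRUE) +
      dnbinom(tot - s, size = nB / phi, mu = nB * m, log = TRUE)
  }
  lp <- lp - .logsumexp(lp)
  pobs <- lp[sA + 1]
  min(1, sum(exp(lp[lp <= pobs + 1e-10])))
}

## Mid-probability quantile-to-quantile map of a count from NB(muIn, phi)
## to NB(muOut, phi); phi = 0 uses the Poisson limit.
.q2q <- function(x, muIn, muOut, phi) {
  out <- numeric(length(x))
  pos <- x > 0 & muIn > 0
  if (!any(pos)) return(out)
  x <- x[pos]; muIn <- muIn[pos]; muOut <- muOut[pos]
  if (phi <= 0) {
    p <- ppois(x - 1, muIn) + 0.5 * dpois(x, muIn)
    p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
    out[pos] <- qpois(p, muOut)
  } else {
    size <- 1 / phi
    p <- pnbinom(x - 1, size = size, mu = muIn) +
      0.5 * dnbinom(x, size = size, mu = muIn)
    p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
    out[pos] <- qnbinom(p, size = size, mu = muOut)
  }
  out
}

#' Equalize effective libraries by NB quantile adjustment
#'
#' Maps each sample's counts to pseudo-counts at the geometric-mean
#' effective library: a count with null mean `lib_s * p_g` (p_g the gene's
#' pooled proportion) is carried through the NB mid-probability CDF to the
#' matching quantile at mean `L* * p_g`. Pseudo-counts are rounded so the
#' conditional enumeration of the exact test stays on the integer grid.
#'
#' @param countsMat count matrix (genes x samples).
#' @param phi common NB dispersion.
#' @param effLibSizes per-sample effective library sizes (library size
#'   times normalization factor); default column sums.
#' @return matrix of integer pseudo-counts at a common library size (given
#'   as attribute `commonLib`).
#' @export
equalizePseudoCounts <- function(countsMat, phi, effLibSizes = NULL) {
  countsMat <- as.matrix(countsMat)
  if (is.null(effLibSizes)) effLibSizes <- colSums(countsMat)
  if (any(effLibSizes <= 0)) stop("effective library sizes must be > 0")
  commonLib <- exp(mean(log(effLibSizes)))
  pg <- rowSums(countsMat) / sum(effLibSizes)
  pseudo <- countsMat
  for (j in seq_len(ncol(countsMat))) {
    pseudo[, j] <- .q2q(countsMat[, j], pg * effLibSizes[j],
      pg * commonLib, phi)
  }
  pseudo <- round(pseudo)
  attr(pseudo, "commonLib") <- commonLib
  pseudo
}

## Summed conditional NB log-likelihood of one group, as a function of phi.
## Y: genes x replicates; constant-in-phi terms dropped.
.condLogLik <- function(Y, phi) {
  r <- 1 / phi
  n <- ncol(Y)
  s <- rowSums(Y)
  sum(rowSums(lgamma(Y + r))) - nrow(Y) * n * lgamma(r) +
    nrow(Y) * lgamma(n * r) - sum(lgamma(s + n * r))
}

#' Estimate the common dispersion by conditional maximum likelihood
#'
#' After equalizing effective libraries by quantile adjustment, the common
#' dispersion phi maximizes the conditional log-likelihood of the
#' replicate counts given each gene's per-group total, summed over genes
#' and groups. The equalize/maximize cycle is run twice (the adjustment
#' itself depends on phi). The search is bounded to \[0, 10\]; identical
#' replicates give phi = 0.
#'
#' @param x a [HomeologExperiment-class] or count matrix.
#' @param groups group label per sample; defaults to `conditions(x)`.
#' @param normFactors optional per-sample normalization factors (e.g. from
#'   [tmmFactors()]); default 1.
#' @return a [DispersionModel-class].
#' @export
estimateCommonDispersion <- function(x, groups = NULL, normFactors = NULL) {
  if (is(x, "HomeologExperiment")) {
    if (is.null(groups)) groups <- conditions(x)
    x <- counts(x)
  }
  x <- as.matrix(x)
  if (is.null(groups)) stop("'groups' is required for a plain matrix")
  groups <- as.character(groups)
  libs <- colSums(x)
  if (all(x == 0)) {
    warning("all counts are zero; phi set to 0")
    return(DispersionModel(0, structure(rep(1, ncol(x)),
      names = colnames(x))))
  }
  if (is.null(normFactors)) normFactors <- rep(1, ncol(x))
  effLibs <- structure(libs * normFactors, names = colnames(x))
  gl <- split(seq_len(ncol(x)), groups)
  phi <- 0.1
  for (iter in 1:2) {
    pseudo <- equalizePseudoCounts(x, phi, effLibs)
    keep <- rowSums(pseudo) > 0
    ll <- function(p) sum(vapply(gl, function(j)
      .condLogLik(pseudo[keep, j, drop = FALSE], p), numeric(1)))
    opt <- optimize(ll, c(1e-6, 10), maximum = TRUE, tol = 1e-5)
    phi <- if (ll(1e-8) >= opt$objective) 0 else opt$maximum
    if (phi == 0) break
  }
  DispersionModel(phi, effLibs)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over `stats::p.adjust(p, "BH")`, kept as a named step of
#' the pipeline surface.
#'
#' @param p numeric p-values.
#' @return BH-adjusted q-values.
#' @export
bhAdjust <- function(p) p.adjust(p, method = "BH")

#' Call differential expression from test results
#'
#' Strict thresholds, per the printed rule: `up` needs log2FC > `lfc` and
#' p < `alpha`; `down` needs log2FC < -`lfc` and p < `alpha`; anything
#' else is `ns`. A log2FC of exactly `lfc` is `ns`.
#'
#' @param results a data.frame/DataFrame with columns `log2FC`, `pvalue`.
#' @param lfc log2 fold-change threshold (default 1).
#' @param alpha p-value threshold (default 0.01).
#' @return `results` with a `call` column added (up/down/ns).
#' @export
callDE <- function(results, lfc = 1, alpha = 0.01) {
  call <- rep("ns", nrow(results))
  call[results$log2FC > lfc & results$pvalue < alpha] <- "up"
  call[results$log2FC < -lfc & results$pvalue < alpha] <- "down"
  results$call <- call
  results
}

#' Per-gene NB exact test, cold vs control
#'
#' Runs the exact conditional test on every gene after TMM normalization
#' and quantile equalization of effective libraries. Group means are
#' normalized counts (pseudo-counts at the common library); log2FC uses a
#' pseudo-count of 0.5 on both group means so zero-count genes stay
#' finite.
#'
#' @param x a [HomeologExperiment-class] (conditions control/cold).
#' @param model optional [DispersionModel-class]; estimated by
#'   [estimateCommonDispersion()] when `NULL`.
#' @param normFactors optional TMM factors; computed when `NULL`.
#' @param lfc,alpha thresholds passed to [callDE()].
#' @param lfcPseudo pseudo-count added to group means for log2FC (0.5).
#' @return a [S4Vectors::DataFrame] with columns gene, meanControl,
#'   meanCold, log2FC, pvalue, qvalue, call.
#' @export
deTest <- function(x, model = NULL, normFactors = NULL,
                   lfc = 1, alpha = 0.01, lfcPseudo = 0.5) {
  stopifnot(is(x, "HomeologExperiment"))
  cond <- conditions(x)
  cts <- counts(x)
  if (is.null(normFactors)) normFactors <- tmmFactors(cts)
  if (is.null(model))
    model <- estimateCommonDispersion(cts, cond, normFactors)
  phi <- dispersion(model)
  pseudo <- equalizePseudoCounts(cts, phi, effectiveLibSizes(model))
  ctrl <- which(cond == "control")
  cold <- which(cond == "cold")
  pv <- vapply(seq_len(nrow(pseudo)), function(i)
    nbExactTest(pseudo[i, cold], pseudo[i, ctrl], phi), numeric(1))
  meanControl <- rowMeans(pseudo[, ctrl, drop = FALSE])
  meanCold <- rowMeans(pseudo[, cold, drop = FALSE])
  res <- DataFrame(
    gene = rownames(cts),
    meanControl = meanControl,
    meanCold = meanCold,
    log2FC = log2((meanCold + lfcPseudo) / (meanControl + lfcPseudo)),
    pvalue = pv,
    qvalue = bhAdjust(pv),
    row.names = rownames(cts))
  callDE(res, lfc = lfc, alpha = alpha)
}
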