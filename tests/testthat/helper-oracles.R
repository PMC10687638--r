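# Independent oracles and tiny fixture builders used across test files.

# Brute-force conditional split enumeration for the two-group NB exact
# test, written from the Gamma-function form of the NB pmf (no dnbinom):
# with r = 1/phi, the unnormalized weight of split (s, T - s) is
#   G(s + nA r)/(s! G(nA r)) * G(T - s + nB r)/((T-s)! G(nB r)),
# the common probability parameter cancelling under the null. phi = 0 is
# the Poisson limit with weight nA^s nB^(T-s) / (s! (T-s)!).
bruteForceExactP <- function(yA, yB, phi) {
  sA <- round(sum(yA)); sB <- round(sum(yB))
  tot <- sA + sB
  if (tot == 0) return(1)
  nA <- length(yA); nB <- length(yB)
  s <- 0:tot
  if (phi <= 0) {
    lw <- s * log(nA) + (tot - s) * log(nB) -
      lgamma(s + 1) - lgamma(tot - s + 1)
  } else {
    r <- 1 / phi
    lw <- lgamma(s + nA * r) - lgamma(s + 1) - lgamma(nA * r) +
      lgamma(tot - s + nB * r) - lgamma(tot - s + 1) - lgamma(nB * r)
  }
  lw <- lw - (max(lw) + log(sum(exp(lw - max(lw)))))
  min(1, sum(exp(lw[lw <= lw[sA + 1] + 1e-10])))
}

# A tiny two-condition experiment with known counts.
makeTinyExperiment <- function(counts, lengths = NULL) {
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  nrep <- ncol(counts) / 2
  HomeologExperiment(counts,
    condition = rep(c("control", "cold"), each = nrep),
    replicate = rep(seq_len(nrep), 2),
    lengths = lengths)
}

# Deterministic NB matrix for normalization / dispersion tests.
makeNBCounts <- function(nGenes, nSamples, mu, phi, seed) {
  set.seed(seed)
  m <- matrix(if (phi > 0) rnbinom(nGenes * nSamples, mu = mu, size = 1 / phi)
    else rpois(nGenes * nSamples, mu), nGenes, nSamples)
  dimnames(m) <- list(sprintf("g%04d", seq_len(nGenes)),
    sprintf("s%d", seq_len(nSamples)))
  m
}
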