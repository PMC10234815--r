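# The genotype-likelihood model: per-site likelihood of the observed read
# bases given a diploid genotype under independent per-base error, the
# summed log-likelihood score, its Hardy-Weinberg null moments, the
# standardized score, and normal / empirical P values.

.checkEpsilon <- function(epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon >= 0.5)
    stop("epsilon must be a single number in (0, 0.5)")
  epsilon
}

#' Per-site genotype likelihood under read error
#'
#' Probability that a diploid genotype with `g` alternative alleles
#' produced `n` read bases of which `k` match the reference allele, when
#' each base is read in error (flipped to the other allele) independently
#' with probability `epsilon`:
#' \deqn{L(g, n, k) = \frac{1}{2^n}\,[(2-g)\epsilon + g(1-\epsilon)]^{n-k}
#'   \,[g\epsilon + (2-g)(1-\epsilon)]^{k}.}
#' For a heterozygote (g = 1) this collapses to \eqn{(1/2)^n} regardless of
#' `epsilon`. Computed in log space; with `log = FALSE` the value can
#' underflow to 0 for large homozygote-discordant counts, which is why all
#' downstream scoring uses the log form.
#'
#' @param g alt-allele dosage, each 0, 1 or 2 (vectorized).
#' @param n total read bases per site, n >= 1.
#' @param k reference-allele bases per site, 0 <= k <= n.
#' @param epsilon per-base error probability in (0, 0.5); default 1e-6.
#' @param log return the natural-log likelihood.
#' @return numeric vector of (log) likelihoods.
#' @examples
#' genotypeLikelihood(1, 3, 2)              # 1/8
#' genotypeLikelihood(0, 1, 1)              # 1 - 1e-6
#' genotypeLikelihood(2, 2, 2)              # 1e-12
#' @export
genotypeLikelihood <- function(g, n, k, epsilon = 1e-6, log = FALSE) {
  .checkEpsilon(epsilon)
  if (!all(g %in% 0:2)) stop("g must be 0, 1 or 2")
  if (any(k < 0) || any(k > n) || any(n < 1))
    stop("need 0 <= k <= n and n >= 1")
  ll <- -n * base::log(2) +
    (n - k) * base::log((2 - g) * epsilon + g * (1 - epsilon)) +
    k * base::log(g * epsilon + (2 - g) * (1 - epsilon))
  if (log) ll else exp(ll)
}

# log-likelihood for all three genotypes at each site: 3 x S matrix with
# rows g = 0, 1, 2.
.logLikBySite <- function(n, k, epsilon) {
  rbind(genotypeLikelihood(0L, n, k, epsilon, log = TRUE),
        genotypeLikelihood(1L, n, k, epsilon, log = TRUE),
        genotypeLikelihood(2L, n, k, epsilon, log = TRUE))
}

#' Hardy-Weinberg genotype frequencies
#'
#' Genotype frequencies \eqn{((1-p)^2,\; 2p(1-p),\; p^2)} implied by an
#' alternative-allele frequency `p` under random mating.
#'
#' @param p allele frequency (vectorized), each in \[0, 1\].
#' @return a 3 x length(p) matrix with rows named `g0`, `g1`, `g2`.
#' @examples
#' hweGenotypeFreqs(c(0, 0.5, 0.2))
#' @export
hweGenotypeFreqs <- function(p) {
  if (any(p < 0) || any(p > 1) || anyNA(p))
    stop("allele frequencies must lie in [0, 1]")
  rbind(g0 = (1 - p)^2, g1 = 2 * p * (1 - p), g2 = p^2)
}

#' Likelihood score of one individual's genotypes for observed reads
#'
#' Sums the per-site log genotype likelihood over all sites where the
#' individual has a non-missing dosage:
#' \eqn{LS = \sum_i \log L(g_i, n_i, k_i)}. Sites with `NA` dosage are
#' skipped and excluded from the reported site and base counts.
#'
#' @param n,k per-site total and reference-allele base counts (aligned).
#' @param g per-site alt-allele dosages, 0/1/2 or NA, aligned to `n`, `k`.
#' @param epsilon per-base error probability.
#' @return list with `ls` (the score; `NA` when no usable site), `nSites`,
#'   `nBases` over the sites actually used.
#' @export
likelihoodScore <- function(n, k, g, epsilon = 1e-6) {
  use <- !is.na(g)
  if (!any(use))
    return(list(ls = NA_real_, nSites = 0L, nBases = 0L))
  ls <- sum(genotypeLikelihood(g[use], n[use], k[use], epsilon, log = TRUE))
  list(ls = ls, nSites = sum(use), nBases = as.integer(sum(n[use])))
}

#' Null moments of the likelihood score under Hardy-Weinberg genotypes
#'
#' Expectation and variance of the likelihood score when, independently at
#' each site, the genotype is drawn from the Hardy-Weinberg frequencies
#' implied by the population allele frequency:
#' \deqn{E = \sum_i \sum_g P(g, p_i)\,\log L(g, n_i, k_i), \qquad
#'   V = \sum_i \sum_g P(g, p_i)\,[\log L(g, n_i, k_i) - E_i]^2.}
#' These are the moments used to standardize an individual's score into a
#' z-score; they should be computed over exactly the site subset that
#' contributed to that individual's score (use `subset`).
#'
#' @param n,k per-site base counts.
#' @param p per-site population alternative-allele frequencies.
#' @param epsilon per-base error probability.
#' @param subset optional logical or integer index selecting the sites to
#'   include (e.g. the non-missing set of one candidate).
#' @return list with `e` and `v`.
#' @export
nullMoments <- function(n, k, p, epsilon = 1e-6, subset = NULL) {
  if (!is.null(subset)) {
    n <- n[subset]; k <- k[subset]; p <- p[subset]
  }
  if (!length(n)) return(list(e = NA_real_, v = NA_real_))
  ll <- .logLikBySite(n, k, epsilon)
  w <- hweGenotypeFreqs(p)
  ei <- colSums(w * ll)
  vi <- colSums(w * ll^2) - ei^2
  list(e = sum(ei), v = sum(pmax(vi, 0)))
}

# per-site null moments, for callers that subset repeatedly
.nullMomentsBySite <- function(n, k, p, epsilon = 1e-6) {
  ll <- .logLikBySite(n, k, epsilon)
  w <- hweGenotypeFreqs(p)
  ei <- colSums(w * ll)
  vi <- pmax(colSums(w * ll^2) - ei^2, 0)
  list(ei = ei, vi = vi)
}

#' Standardize a likelihood score and test it against the null
#'
#' Standardizes `ls` with the null moments and converts it to a one-sided
#' P value under a standard-normal null; the alternative is that the score
#' is *higher* than expected for an unrelated population member (reads and
#' genotype from the same individual inflate the score).
#'
#' @param ls likelihood score.
#' @param e,v null expectation and variance from [nullMoments()].
#' @return list with `z` and `p`; both `NA` when `v` is zero or any input
#'   is `NA` (a degenerate null never produces a spurious match).
#' @export
standardizeScore <- function(ls, e, v) {
  if (anyNA(c(ls, e, v)) || v <= 0)
    return(list(z = NA_real_, p = NA_real_))
  z <- (ls - e) / sqrt(v)
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Empirical P value by simulating genotypes from allele frequencies
#'
#' Draws `nDraws` genotype vectors with independent per-site
#' Hardy-Weinberg sampling from `p`, scores each against the observed
#' reads, and returns \eqn{(1 + \#\{LS_{sim} > ls\}) / (nDraws + 1)}.
#' Ties count toward the null (strict inequality). The default
#' `nDraws = 99999` gives a floor of 1e-5.
#'
#' @param ls observed likelihood score.
#' @param n,k,p per-site base counts and allele frequencies (the same site
#'   subset that produced `ls`).
#' @param epsilon per-base error probability.
#' @param nDraws number of simulated genotype vectors.
#' @param seed optional RNG seed for reproducibility.
#' @return empirical P value in \[1/(nDraws+1), 1\].
#' @export
empiricalPvalue <- function(ls, n, k, p, epsilon = 1e-6, nDraws = 99999L,
                            seed = NULL) {
  stopifnot(nDraws >= 1)
  S <- length(n)
  ll <- .logLikBySite(n, k, epsilon)
  .withSeed(seed, {
    exceed <- 0L
    chunk <- max(1L, min(as.integer(nDraws), as.integer(2e7 / max(S, 1L))))
    left <- as.integer(nDraws)
    while (left > 0L) {
      m <- min(chunk, left)
      gsim <- matrix(stats::rbinom(S * m, 2L, p), nrow = S)
      lssim <- colSums(matrix(ll[gsim + 1L + 3L * (seq_len(S) - 1L)],
                              nrow = S))
      exceed <- exceed + sum(lssim > ls)
      left <- left - m
    }
    (1 + exceed) / (nDraws + 1)
  })
}
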