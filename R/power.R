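# Coverage-grid power experiment: for each mean per-site depth, repeated
# simulation of a query whose true genotype sits in a candidate database,
# followed by scoring and decision evaluation.

#' Power sweep over mean per-site depth
#'
#' For each value of `lambdas` and each replicate: a query individual's
#' genotypes are drawn from the panel population, read observations are
#' simulated at that depth, and the query is matched against a candidate
#' database containing the truth plus `nCandidates - 1` unrelated
#' Hardy-Weinberg individuals. Scoring is restricted to the covered
#' sites, so the panel can be large while each replicate stays cheap.
#' Sensitivity, specificity and top-score accuracy are tabulated per
#' depth with exact binomial confidence intervals. The Bonferroni
#' denominator is `nReps * nCandidates` per cell (every query-candidate
#' pair tested in that cell) unless overridden.
#'
#' Simulated panel sites are statistically independent by construction,
#' so no clumping is applied inside the sweep.
#'
#' @param panel a [SitePanel-class] (one population used).
#' @param lambdas numeric vector of mean per-site depths (coverage
#'   proxies), e.g. `c(1e-5, 2e-5, 5e-5, 1e-4, 2e-4, 5e-4, 1e-3)`.
#' @param nCandidates candidate-database size including the truth.
#' @param nReps replicates per depth.
#' @param population frequency column to simulate from.
#' @param alpha family-wise error rate.
#' @param nTests Bonferroni denominator; default `nReps * nCandidates`.
#' @param epsilon per-base error probability (model and simulation).
#' @param contaminationFraction fraction of bases drawn from an unrelated
#'   contaminant individual (0 = none).
#' @param relatedness `"unrelated"` or `"parent"`: with `"parent"` the
#'   non-truth candidates include one parent of the query.
#' @param seed RNG seed for the whole sweep.
#' @return data.frame with one row per depth: `lambda`, `nReps`,
#'   `meanBases`, `sensitivity`, `specificity`, `topAccuracy` and 95%
#'   binomial confidence bounds for sensitivity.
#' @export
powerSweep <- function(panel, lambdas, nCandidates = 100L, nReps = 25L,
                       population = populations(panel)[1],
                       alpha = 0.05, nTests = NULL, epsilon = 1e-6,
                       contaminationFraction = 0,
                       relatedness = c("unrelated", "parent"),
                       seed = NULL) {
  relatedness <- match.arg(relatedness)
  if (is.null(nTests)) nTests <- nReps * nCandidates
  p <- alleleFreq(panel, population)
  S <- nSites(panel)
  cellSeeds <- .childSeeds(seed, length(lambdas))
  rows <- vector("list", length(lambdas))
  for (li in seq_along(lambdas)) {
    lam <- lambdas[li]
    repSeeds <- .childSeeds(cellSeeds[[li]], nReps)
    tp <- 0L; fn <- 0L; fp <- 0L; tn <- 0L; top <- 0L
    bases <- numeric(nReps)
    for (r in seq_len(nReps)) {
      res <- .withSeed(repSeeds[[r]], {
        truth <- stats::rbinom(S, 2L, p)
        n <- stats::rpois(S, lam)
        cov <- which(n > 0L)
        if (!length(cov)) NULL
        else {
          sub <- panel[cov]
          if (contaminationFraction > 0) {
            contam <- stats::rbinom(length(cov), 2L, p[cov])
            nc <- stats::rbinom(length(cov), n[cov],
                                contaminationFraction)
            k <- stats::rbinom(length(cov), n[cov] - nc,
                               .refBaseProb(truth[cov], epsilon)) +
              stats::rbinom(length(cov), nc,
                            .refBaseProb(contam, epsilon))
          } else {
            k <- stats::rbinom(length(cov), n[cov],
                               .refBaseProb(truth[cov], epsilon))
          }
          gr <- panelSites(sub)
          obs <- ObservationSet(
            as.character(GenomicRanges::seqnames(gr)),
            GenomicRanges::start(gr), gr$ref, gr$alt, n[cov], k)
          d <- matrix(stats::rbinom(length(cov) * (nCandidates - 1L),
                                    2L, p[cov]),
                      nrow = length(cov))
          if (relatedness == "parent" && nCandidates >= 2L) {
            # replace the first decoy by a parent of the query: one
            # allele identical by descent, the other population-drawn
            ibd <- stats::rbinom(length(cov), 1L, truth[cov] / 2)
            d[, 1L] <- ibd + stats::rbinom(length(cov), 1L, p[cov])
          }
          d <- cbind(truth = truth[cov], d)
          colnames(d) <- c("truth",
                           paste0("decoy", seq_len(nCandidates - 1L)))
          gs <- GenotypeSet(siteKeys(sub), d)
          runMatch(list(q = obs), gs, sub, population = population,
                   alpha = alpha, nTests = nTests, epsilon = epsilon,
                   ldRef = NULL)
        }
      })
      if (is.null(res)) {
        fn <- fn + 1L
        tn <- tn + (nCandidates - 1L)
        next
      }
      isTruth <- res$candidate == "truth"
      tp <- tp + sum(isTruth & res$significant)
      fn <- fn + sum(isTruth & !res$significant)
      fp <- fp + sum(!isTruth & res$significant)
      tn <- tn + sum(!isTruth & !res$significant)
      top <- top + as.integer(any(isTruth & res$top_score))
      bases[r] <- res$n_bases[isTruth]
    }
    ci <- stats::binom.test(tp, tp + fn)$conf.int
    rows[[li]] <- data.frame(
      lambda = lam, nReps = nReps, meanBases = mean(bases),
      sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      topAccuracy = top / nReps,
      sensLo = ci[1], sensHi = ci[2])
  }
  do.call(rbind, rows)
}
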