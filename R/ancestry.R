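# Ancestry prediction: score the observed reads against each population's
# allele frequencies by the expected likelihood score under Hardy-Weinberg
# genotypes, and predict the argmax population.

#' Expected likelihood score under one population's allele frequencies
#'
#' \deqn{E(LS_A) = \sum_i \sum_g P(g, p_{i,A}) \log L(g, n_i, k_i)}
#' i.e. the expected score of a genotype drawn from population A's
#' Hardy-Weinberg frequencies; always <= 0.
#'
#' @param n,k per-site base counts.
#' @param p per-site alternative-allele frequencies in the population.
#' @param epsilon per-base error probability.
#' @return the expected score (scalar).
#' @export
expectedPopulationScore <- function(n, k, p, epsilon = 1e-6) {
  nullMoments(n, k, p, epsilon)$e
}

#' Predict ancestry from per-population expected likelihood scores
#'
#' Every population is scored on the identical site set (sites with a
#' missing frequency in any scored population are dropped for all, so the
#' scores are comparable); the population with the highest expected score
#' is the prediction. Near-ties (relative difference < `tieTol` between
#' the best two scores) are flagged and broken lexicographically.
#'
#' @param obs an [ObservationSet-class] for one query.
#' @param panel [SitePanel-class] carrying >= 2 population frequency
#'   columns.
#' @param pops populations to score; default all panel populations.
#' @param epsilon per-base error probability.
#' @param tieTol relative tolerance declaring a tie; default 1e-9.
#' @return list with `prediction` (label, or `NA` when no usable site),
#'   `scores` (named vector of E(LS_A)), `tie` (logical), `nSites`,
#'   `nBases`.
#' @export
predictAncestry <- function(obs, panel, pops = populations(panel),
                            epsilon = 1e-6, tieTol = 1e-9) {
  stopifnot(length(pops) >= 2L)
  pi <- .matchPanel(obs, panel)
  keep <- !is.na(pi)
  obs <- obs[keep]; pi <- pi[keep]
  fr <- alleleFreq(panel)[pi, pops, drop = FALSE]
  ok <- rowSums(is.na(fr)) == 0L
  obs <- obs[ok]; fr <- fr[ok, , drop = FALSE]
  if (length(obs) == 0L)
    return(list(prediction = NA_character_,
                scores = stats::setNames(rep(NA_real_, length(pops)), pops),
                tie = NA, nSites = 0L, nBases = 0L))
  n <- totalCounts(obs); k <- refCounts(obs)
  scores <- vapply(pops, function(pp)
    expectedPopulationScore(n, k, fr[, pp], epsilon), numeric(1))
  ord <- order(scores, decreasing = TRUE)
  best <- scores[ord[1]]
  tie <- length(scores) > 1L &&
    abs(best - scores[ord[2]]) < tieTol * max(abs(best), 1e-300)
  winner <- if (tie) {
    near <- pops[abs(best - scores) < tieTol * max(abs(best), 1e-300)]
    sort(near)[1]
  } else pops[ord[1]]
  list(prediction = winner, scores = scores, tie = tie,
       nSites = length(obs), nBases = as.integer(sum(n)))
}
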