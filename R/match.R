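# Orchestration of re-identification: align observations to the panel,
# optionally restrict by MAF window, clump to approximately independent
# sites, score every query x candidate pair, standardize against the
# per-candidate Hardy-Weinberg null, and apply the two decision rules
# (top score; Bonferroni-corrected P).

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param nTests number of query x candidate tests.
#' @return `alpha / nTests`.
#' @examples
#' bonferroniThreshold(0.05, 343 * 343)   # ~4.25e-7
#' @export
bonferroniThreshold <- function(alpha, nTests) {
  stopifnot(alpha > 0, alpha < 1, nTests >= 1)
  alpha / nTests
}

#' Expected human-genome coverage of the host reads in a metagenome
#'
#' Mean coverage contributed by the human fraction of a shotgun
#' sequencing run: `totalBases * humanFraction / genomeSize`.
#'
#' @param totalBases sequenced bases (e.g. `10e9` for 10 Gbp).
#' @param humanFraction fraction of reads of human origin.
#' @param genomeSize human genome size in bases; default 3.1e9.
#' @return expected fold-coverage.
#' @examples
#' expectedHumanCoverage(10e9, 0.01)   # 0.032x
#' @export
expectedHumanCoverage <- function(totalBases, humanFraction,
                                  genomeSize = 3.1e9) {
  stopifnot(totalBases >= 0, humanFraction >= 0, humanFraction <= 1,
            genomeSize > 0)
  totalBases * humanFraction / genomeSize
}

#' Score every metagenome query against every candidate genotype
#'
#' For each query: the covered sites are intersected with the panel,
#' optionally restricted to a minor-allele-frequency window, and clumped
#' to an approximately independent subset when an LD reference is given.
#' Each candidate is then scored with [likelihoodScore()] over its
#' non-missing sites, standardized against the null moments computed over
#' exactly that site subset, and tested one-sided. The candidate with the
#' highest score is flagged `top_score`; candidates with
#' `p_normal < alpha / nTests` are flagged `significant`.
#'
#' @param obsList named list of [ObservationSet-class] (one per query), or
#'   a single `ObservationSet`.
#' @param genotypes [GenotypeSet-class] of candidates (keys matching the
#'   panel's).
#' @param panel [SitePanel-class] with the frequency column used for the
#'   null.
#' @param population population label for the null frequencies; defaults
#'   to the panel's first population.
#' @param alpha family-wise error rate for the Bonferroni rule.
#' @param nTests correction denominator; default
#'   `length(obsList) * ncol(dosages(genotypes))`.
#' @param epsilon per-base error probability.
#' @param ldRef optional [GenotypeSet-class] used as the LD reference for
#'   clumping; `NULL` skips clumping (appropriate when sites are known to
#'   be independent).
#' @param clump [clumpConfig()] used when `ldRef` is given.
#' @param mafRange optional `c(lo, hi)`: keep sites with lo < MAF <= hi.
#' @param computeEmpirical also compute [empiricalPvalue()] per pair
#'   (costly; default FALSE).
#' @param nDraws draws for the empirical P value.
#' @param seed RNG seed for the empirical P value.
#' @return data.frame with one row per query x candidate: `query`,
#'   `candidate`, `n_sites`, `n_bases`, `ls`, `e_null`, `v_null`, `z`,
#'   `p_normal`, `p_empirical`, `top_score`, `significant`.
#' @export
runMatch <- function(obsList, genotypes, panel,
                     population = populations(panel)[1],
                     alpha = 0.05, nTests = NULL, epsilon = 1e-6,
                     ldRef = NULL, clump = clumpConfig(),
                     mafRange = NULL, computeEmpirical = FALSE,
                     nDraws = 99999L, seed = NULL) {
  if (is(obsList, "ObservationSet")) obsList <- list(query = obsList)
  if (is.null(names(obsList)))
    names(obsList) <- paste0("query", seq_along(obsList))
  cand <- sampleIds(genotypes)
  nC <- length(cand)
  if (is.null(nTests)) nTests <- length(obsList) * nC
  thr <- bonferroniThreshold(alpha, nTests)
  gIdx <- match(siteKeys(genotypes), siteKeys(panel))
  seeds <- .childSeeds(seed, length(obsList))
  out <- vector("list", length(obsList))
  for (qi in seq_along(obsList)) {
    obs <- obsList[[qi]]
    qname <- names(obsList)[qi]
    res <- data.frame(query = qname, candidate = cand,
                      n_sites = 0L, n_bases = 0L,
                      ls = NA_real_, e_null = NA_real_, v_null = NA_real_,
                      z = NA_real_, p_normal = NA_real_,
                      p_empirical = NA_real_,
                      top_score = FALSE, significant = FALSE,
                      stringsAsFactors = FALSE)
    pi <- .matchPanel(obs, panel)
    keep <- !is.na(pi)
    obs <- obs[keep]; pi <- pi[keep]
    p <- alleleFreq(panel, population)[pi]
    ok <- !is.na(p)
    if (!is.null(mafRange)) {
      maf <- pmin(p, 1 - p)
      ok <- ok & maf > mafRange[1] & maf <= mafRange[2]
    }
    obs <- obs[ok]; pi <- pi[ok]; p <- p[ok]
    if (length(obs) && !is.null(ldRef)) {
      kept <- siteKeys(obs) %in%
        pruneSites(siteKeys(obs), ldRef, clump)
      obs <- obs[kept]; pi <- pi[kept]; p <- p[kept]
    }
    if (length(obs) == 0L) {
      out[[qi]] <- res
      next
    }
    n <- totalCounts(obs); k <- refCounts(obs)
    ll <- .logLikBySite(n, k, epsilon)
    mom <- .nullMomentsBySite(n, k, p, epsilon)
    G <- matrix(NA_integer_, nrow = length(obs), ncol = nC)
    gHit <- match(pi, gIdx)
    rows <- !is.na(gHit)
    G[rows, ] <- dosages(genotypes)[gHit[rows], , drop = FALSE]
    lsSite <- seq_along(n)
    for (ci in seq_len(nC)) {
      g <- G[, ci]
      use <- !is.na(g)
      if (!any(use)) next
      lsv <- ll[g[use] + 1L + 3L * (lsSite[use] - 1L)]
      res$ls[ci] <- sum(lsv)
      res$n_sites[ci] <- sum(use)
      res$n_bases[ci] <- sum(n[use])
      res$e_null[ci] <- sum(mom$ei[use])
      res$v_null[ci] <- sum(mom$vi[use])
      st <- standardizeScore(res$ls[ci], res$e_null[ci], res$v_null[ci])
      res$z[ci] <- st$z
      res$p_normal[ci] <- st$p
      if (computeEmpirical)
        res$p_empirical[ci] <- empiricalPvalue(
          res$ls[ci], n[use], k[use], p[use], epsilon, nDraws,
          seed = if (is.null(seeds[[qi]])) NULL
                 else (seeds[[qi]] + ci) %% .Machine$integer.max)
    }
    defined <- which(!is.na(res$z))
    if (length(defined))
      res$top_score[defined[which.max(res$ls[defined])]] <- TRUE
    res$significant <- !is.na(res$p_normal) & res$p_normal < thr
    out[[qi]] <- res
  }
  do.call(rbind, out)
}

#' Summarize match decisions against known truth
#'
#' @param matches result of [runMatch()].
#' @param truth named character vector mapping query name to the true
#'   candidate id; queries whose truth is absent from the candidate set
#'   (or unnamed) count as truth-absent.
#' @return list with `sensitivity` (true pairs flagged significant / true
#'   pairs), `specificity` (non-pairs not flagged / non-pairs),
#'   `topAccuracy` (queries whose top-score candidate is the truth /
#'   queries with truth present), and the underlying counts.
#' @export
evaluateDecisions <- function(matches, truth) {
  isTrue <- !is.na(truth[matches$query]) &
    matches$candidate == truth[matches$query]
  tp <- sum(isTrue & matches$significant)
  fn <- sum(isTrue & !matches$significant)
  fp <- sum(!isTrue & matches$significant)
  tn <- sum(!isTrue & !matches$significant)
  queries <- unique(matches$query)
  withTruth <- queries[!is.na(truth[queries]) &
                         truth[queries] %in% matches$candidate]
  topHit <- vapply(withTruth, function(q) {
    sub <- matches[matches$query == q & matches$top_score, , drop = FALSE]
    nrow(sub) == 1L && sub$candidate == truth[[q]]
  }, logical(1))
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
       topAccuracy = if (length(withTruth)) mean(topHit) else NA_real_,
       tp = tp, fn = fn, fp = fp, tn = tn,
       nQueriesWithTruth = length(withTruth))
}
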