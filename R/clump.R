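# Windowed pairwise-r^2 pruning of covered SNP sites, emulating PLINK's
# --indep-pairwise behaviour: within a sliding window, one site of every
# pair whose dosage correlation exceeds the threshold is removed, and the
# pass is repeated until no offending pair remains.

#' Clumping configuration
#'
#' Window and threshold for [pruneSites()]; defaults correspond to
#' PLINK's `--indep-pairwise 100 30 0.1` (window and step counted in
#' sites, not kilobases).
#'
#' @param windowSize window length in sites.
#' @param step window advance in sites.
#' @param r2Threshold squared-correlation threshold above which the later
#'   site of a pair is removed.
#' @return a list of class `ClumpConfig`.
#' @export
clumpConfig <- function(windowSize = 100L, step = 30L, r2Threshold = 0.1) {
  stopifnot(windowSize >= step, step >= 1L,
            r2Threshold > 0, r2Threshold <= 1)
  structure(list(windowSize = as.integer(windowSize),
                 step = as.integer(step),
                 r2Threshold = r2Threshold),
            class = "ClumpConfig")
}

#' Prune covered sites to an approximately independent subset
#'
#' Slides a window of `cfg$windowSize` sites (advancing by `cfg$step`)
#' along the covered sites in their given (genomic) order. Within each
#' window, pairwise r^2 is computed from the LD reference dosages (over
#' individuals with both sites non-missing); whenever a pair exceeds the
#' threshold, the later site is removed. Passes repeat over the surviving
#' sites until stable, so the retained list contains no within-window pair
#' above the threshold. Monomorphic sites have undefined correlation and
#' are treated as r^2 = 0.
#'
#' Unlike PLINK, removal always takes the later site of an offending pair
#' (PLINK's internal preference is version-dependent); results downstream
#' depend only on approximate independence of the retained set.
#'
#' @param coveredKeys character site keys in genomic order (a subset of
#'   the LD reference's keys).
#' @param ldRef [GenotypeSet-class] supplying reference dosages for LD
#'   (needs >= 2 individuals).
#' @param cfg a [clumpConfig()].
#' @return the retained keys, in input order.
#' @export
pruneSites <- function(coveredKeys, ldRef, cfg = clumpConfig()) {
  idx <- match(coveredKeys, siteKeys(ldRef))
  if (anyNA(idx))
    stop("covered site(s) absent from the LD reference")
  D <- dosages(ldRef)[idx, , drop = FALSE]
  if (ncol(D) < 2L)
    stop("LD reference must contain at least 2 individuals")
  S <- length(coveredKeys)
  keep <- rep(TRUE, S)
  repeat {
    changed <- FALSE
    alive <- which(keep)
    m <- length(alive)
    if (m < 2L) break
    starts <- seq(1L, max(m - 1L, 1L), by = cfg$step)
    for (s0 in starts) {
      win <- alive[s0:min(s0 + cfg$windowSize - 1L, m)]
      win <- win[keep[win]]
      if (length(win) < 2L) next
      C <- suppressWarnings(
        stats::cor(D[win, , drop = FALSE] |> t(),
                   use = "pairwise.complete.obs"))
      r2 <- C^2
      r2[!is.finite(r2)] <- 0
      for (jj in 2:length(win)) {
        if (!keep[win[jj]]) next
        earlier <- win[seq_len(jj - 1L)]
        earlier <- earlier[keep[earlier]]
        if (length(earlier) &&
            any(r2[match(earlier, win), jj] > cfg$r2Threshold)) {
          keep[win[jj]] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  coveredKeys[keep]
}
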