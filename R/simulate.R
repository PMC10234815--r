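# Synthetic-data generation with the statistical structure the likelihood
# model assumes: Balding-Nichols population allele frequencies,
# Hardy-Weinberg genotypes, Mendelian transmission, site-level
# ultra-low-coverage read observations with base error, contamination
# mixtures, and sex-chromosome depth profiles. Every generator takes a
# seed and is bit-reproducible under it.

#' Simulate an allele-frequency panel with population structure
#'
#' Ancestral alternative-allele frequencies are drawn from the chosen MAF
#' spectrum; each population's frequency is then drawn around the
#' ancestral value under the Balding-Nichols model,
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose mean is the ancestral frequency
#' and whose variance is `F p (1-p)`. With `F = 0` every population
#' shares the ancestral frequencies exactly. Sites are placed at distinct
#' positions on one chromosome in genomic order.
#'
#' @param nSites number of biallelic SNV sites.
#' @param pops character vector of population labels.
#' @param F Balding-Nichols divergence in \[0, 1); scalar or one value
#'   per population.
#' @param mafSpec `"uniform"` (ancestral frequency uniform on `mafRange`)
#'   or `"one_over_p"` (density proportional to 1/p on `mafRange`, the
#'   neutral-spectrum shape).
#' @param mafRange ancestral frequency range; default c(0.01, 0.5).
#' @param chrom chromosome name for the simulated sites.
#' @param seed RNG seed.
#' @return a [SitePanel-class] with one frequency column per population
#'   plus an attribute `"ancestral"` holding the ancestral frequencies
#'   (in site order).
#' @export
simulatePanel <- function(nSites, pops = "POP", F = 0,
                          mafSpec = c("uniform", "one_over_p"),
                          mafRange = c(0.01, 0.5), chrom = "1",
                          seed = NULL) {
  mafSpec <- match.arg(mafSpec)
  stopifnot(nSites >= 1, all(F >= 0), all(F < 1),
            mafRange[1] > 0, mafRange[2] <= 1, mafRange[1] < mafRange[2])
  if (length(F) == 1L) F <- rep(F, length(pops))
  stopifnot(length(F) == length(pops))
  .withSeed(seed, {
    p0 <- switch(mafSpec,
      uniform = stats::runif(nSites, mafRange[1], mafRange[2]),
      one_over_p = {
        # inverse-CDF sampling of density 1/p on [lo, hi]
        u <- stats::runif(nSites)
        exp(base::log(mafRange[1]) +
              u * (base::log(mafRange[2]) - base::log(mafRange[1])))
      })
    freq <- sapply(seq_along(pops), function(ip) {
      f <- F[ip]
      if (f == 0) p0
      else {
        x <- stats::rbeta(nSites, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
        pmin(pmax(x, 1e-6), 1 - 1e-6)
      }
    })
    colnames(freq) <- pops
    pos <- sort(sample.int(nSites * 100L, nSites))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nSites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    panel <- SitePanel(rep(chrom, nSites), pos, ref, alt, freq)
    attr(panel, "ancestral") <- p0
    panel
  })
}

#' Simulate Hardy-Weinberg genotypes from a panel
#'
#' Per site and individual, dosage ~ Binomial(2, p) independently, using
#' the allele frequencies of the chosen population.
#'
#' @param panel a [SitePanel-class].
#' @param population frequency column to draw from.
#' @param nIndividuals number of individuals.
#' @param ids optional sample ids (default `ind1..`).
#' @param seed RNG seed.
#' @return a [GenotypeSet-class] aligned to the panel.
#' @export
simulateGenotypes <- function(panel, population = populations(panel)[1],
                              nIndividuals = 1L, ids = NULL, seed = NULL) {
  p <- alleleFreq(panel, population)
  S <- length(p)
  .withSeed(seed, {
    d <- matrix(stats::rbinom(S * nIndividuals, 2L, p), nrow = S)
    colnames(d) <- ids %||% paste0("ind", seq_len(nIndividuals))
    GenotypeSet(siteKeys(panel), d)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an offspring's dosages by Mendelian transmission
#'
#' Each parent transmits one of its two alleles uniformly at random,
#' independently per site (a heterozygote transmits the alternative
#' allele with probability 1/2). A missing parental dosage makes the
#' offspring missing at that site.
#'
#' @param parent1,parent2 integer dosage vectors (0/1/2/NA), aligned.
#' @param seed RNG seed.
#' @return integer dosage vector for the offspring.
#' @export
simulateOffspring <- function(parent1, parent2, seed = NULL) {
  stopifnot(length(parent1) == length(parent2))
  .withSeed(seed, {
    S <- length(parent1)
    a1 <- stats::rbinom(S, 1L, ifelse(is.na(parent1), 0, parent1 / 2))
    a2 <- stats::rbinom(S, 1L, ifelse(is.na(parent2), 0, parent2 / 2))
    off <- as.integer(a1 + a2)
    off[is.na(parent1) | is.na(parent2)] <- NA_integer_
    off
  })
}

# P(read base = ref | dosage g): the true allele is ref with probability
# (2-g)/2 and each base is flipped with probability epsilon.
.refBaseProb <- function(g, epsilon) {
  (2 - g) / 2 * (1 - epsilon) + g / 2 * epsilon
}

#' Simulate per-site read observations at ultra-low coverage
#'
#' Per site, the read depth is Poisson(`lambda`); each base derives from
#' one of the individual's two alleles uniformly and is flipped to the
#' other allele with probability `epsilon`. Sites with zero depth (or a
#' missing dosage) are omitted. At target coverages well below 1x this
#' site-level thinning is statistically equivalent to downsampling whole
#' reads, so `lambda` plays the role of fold-coverage.
#'
#' @param dosage integer dosage vector aligned to the panel.
#' @param panel the [SitePanel-class] the dosages are aligned to.
#' @param lambda mean per-site depth (coverage proxy).
#' @param epsilon per-base error probability used in simulation.
#' @param seed RNG seed.
#' @return an [ObservationSet-class].
#' @export
simulateObservations <- function(dosage, panel, lambda, epsilon = 1e-6,
                                 seed = NULL) {
  S <- nSites(panel)
  stopifnot(length(dosage) == S, lambda >= 0)
  .withSeed(seed, {
    n <- stats::rpois(S, lambda)
    cov <- which(n > 0L & !is.na(dosage))
    k <- stats::rbinom(length(cov), n[cov],
                       .refBaseProb(dosage[cov], epsilon))
    gr <- panelSites(panel)[cov]
    ObservationSet(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr), gr$ref, gr$alt,
                   n[cov], k)
  })
}

#' Simulate observations contaminated by a second individual
#'
#' Each simulated base originates from the contaminant's genotype with
#' probability `fraction` and from the host's otherwise; counts are
#' merged per site. Base-level mixing is equivalent to read-level mixing
#' at depths at or below one read per site.
#'
#' @param hostDosage,contamDosage aligned dosage vectors.
#' @param panel the [SitePanel-class].
#' @param lambda mean per-site total depth.
#' @param fraction contaminant fraction in \[0, 1\].
#' @param epsilon per-base error probability.
#' @param seed RNG seed.
#' @return an [ObservationSet-class].
#' @export
mixContamination <- function(hostDosage, contamDosage, panel, lambda,
                             fraction, epsilon = 1e-6, seed = NULL) {
  S <- nSites(panel)
  stopifnot(length(hostDosage) == S, length(contamDosage) == S,
            fraction >= 0, fraction <= 1)
  .withSeed(seed, {
    n <- stats::rpois(S, lambda)
    cov <- which(n > 0L & !is.na(hostDosage) & !is.na(contamDosage))
    nc <- stats::rbinom(length(cov), n[cov], fraction)
    kHost <- stats::rbinom(length(cov), n[cov] - nc,
                           .refBaseProb(hostDosage[cov], epsilon))
    kCont <- stats::rbinom(length(cov), nc,
                           .refBaseProb(contamDosage[cov], epsilon))
    gr <- panelSites(panel)[cov]
    ObservationSet(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr), gr$ref, gr$alt,
                   n[cov], kHost + kCont)
  })
}

#' Simulate a per-chromosome read-count profile for one sample
#'
#' Reads are allocated multinomially across chromosomes with weights
#' proportional to copy number x length: autosomes and the female X carry
#' two copies, the male X and Y one copy each. The female Y weight is
#' `femaleYNoise` x its one-copy weight, modelling the residual
#' mismapping depth observed on Y in females (default 1%).
#'
#' @param sex `"male"` or `"female"`.
#' @param nReads total reads to allocate.
#' @param chromLengths named chromosome lengths; default
#'   [grch37ChromLengths()] without MT.
#' @param femaleYNoise female Y weight relative to one copy; default 0.01.
#' @param seed RNG seed.
#' @return named integer vector of read counts per chromosome.
#' @export
simulateDepthProfile <- function(sex = c("male", "female"), nReads,
                                 chromLengths = NULL,
                                 femaleYNoise = 0.01, seed = NULL) {
  sex <- match.arg(sex)
  if (is.null(chromLengths)) {
    chromLengths <- grch37ChromLengths()
    chromLengths <- chromLengths[names(chromLengths) != "MT"]
  }
  stopifnot(nReads >= 0, all(c("X", "Y") %in% names(chromLengths)))
  copies <- stats::setNames(rep(2, length(chromLengths)),
                            names(chromLengths))
  if (sex == "male") {
    copies["X"] <- 1
    copies["Y"] <- 1
  } else {
    copies["Y"] <- femaleYNoise
  }
  w <- copies * chromLengths
  .withSeed(seed, {
    cnt <- as.integer(stats::rmultinom(1L, nReads, w))
    stats::setNames(cnt, names(chromLengths))
  })
}
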