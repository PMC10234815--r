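#' SitePanel: biallelic SNP sites with population allele frequencies
#'
#' A `SitePanel` holds an ordered set of biallelic SNV sites together with
#' the alternative-allele frequency of each site in one or more populations.
#' Sites are stored as a [GenomicRanges::GRanges] with metadata columns
#' `ref` and `alt` (single bases); frequencies as a sites-by-populations
#' numeric matrix.
#'
#' @slot sites `GRanges` of width-1 positions with mcols `ref`, `alt`.
#' @slot freq numeric matrix, one row per site, one named column per
#'   population; all entries in \[0, 1\].
#'
#' @seealso [SitePanel()] for construction, [readFrequencyPanel()] to read
#'   a panel from VCF, [simulatePanel()] to simulate one.
#' @exportClass SitePanel
setClass("SitePanel", slots = c(sites = "GRanges", freq = "matrix"))

setValidity("SitePanel", function(object) {
  msg <- character()
  s <- object@sites
  if (nrow(object@freq) != length(s))
    msg <- c(msg, "freq must have one row per site")
  if (is.null(colnames(object@freq)))
    msg <- c(msg, "freq columns must be named by population")
  if (length(s)) {
    if (is.null(s$ref) || is.null(s$alt))
      msg <- c(msg, "sites must carry 'ref' and 'alt' metadata columns")
    else {
      bases <- c("A", "C", "G", "T")
      if (!all(s$ref %in% bases) || !all(s$alt %in% bases))
        msg <- c(msg, "ref and alt must each be one of A, C, G, T")
      if (any(s$ref == s$alt))
        msg <- c(msg, "ref and alt must differ at every site")
    }
    if (any(IRanges::width(s) != 1L))
      msg <- c(msg, "sites must be width-1 positions")
    key <- paste(as.character(GenomicRanges::seqnames(s)),
                 GenomicRanges::start(s))
    if (anyDuplicated(key))
      msg <- c(msg, "(chrom, pos) must be unique")
    if (is.unsorted(order(as.character(GenomicRanges::seqnames(s)),
                          GenomicRanges::start(s))))
      msg <- c(msg, "sites must be in genomic order")
  }
  f <- object@freq
  if (length(f) && (anyNA(f) || any(f < 0) || any(f > 1)))
    msg <- c(msg, "all frequencies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' GenotypeSet: alt-allele dosages aligned to a SitePanel
#'
#' Candidate individuals' genotypes as alt-allele counts g in \{0, 1, 2\},
#' with `NA` for missing, stored as a sites-by-individuals integer matrix.
#' Rows are identified by site keys (`"chrom:pos:ref:alt"`) so a
#' `GenotypeSet` can be checked against the panel it was aligned to.
#'
#' @slot keys character vector of site keys, one per row of `dosage`.
#' @slot dosage integer matrix (sites x individuals); entries 0, 1, 2 or NA.
#'
#' @seealso [GenotypeSet()], [readGenotypes()], [simulateGenotypes()]
#' @exportClass GenotypeSet
setClass("GenotypeSet", slots = c(keys = "character", dosage = "matrix"))

setValidity("GenotypeSet", function(object) {
  msg <- character()
  if (nrow(object@dosage) != length(object@keys))
    msg <- c(msg, "dosage must have one row per site key")
  if (is.null(colnames(object@dosage)))
    msg <- c(msg, "dosage columns must be named by individual")
  d <- object@dosage
  if (length(d) && !all(d[!is.na(d)] %in% 0:2))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (length(msg)) msg else TRUE
})

#' ObservationSet: per-site read-base counts for one query sample
#'
#' For each covered SNP site, the total number of counted read bases `n`
#' and the number matching the reference allele `k` (so `n - k` bases match
#' the alternative allele). Only sites with `n >= 1` are stored.
#'
#' @slot sites `GRanges` of width-1 positions with mcols `ref`, `alt`.
#' @slot n integer vector of total counted bases per site.
#' @slot k integer vector of reference-allele bases per site.
#'
#' @seealso [ObservationSet()], [pileupToCounts()], [readSiteCounts()],
#'   [simulateObservations()]
#' @exportClass ObservationSet
setClass("ObservationSet",
         slots = c(sites = "GRanges", n = "integer", k = "integer"))

setValidity("ObservationSet", function(object) {
  msg <- character()
  len <- length(object@sites)
  if (length(object@n) != len || length(object@k) != len)
    msg <- c(msg, "n and k must have one entry per site")
  if (len) {
    if (any(object@n < 1L)) msg <- c(msg, "every site must have n >= 1")
    if (any(object@k < 0L) || any(object@k > object@n))
      msg <- c(msg, "k must satisfy 0 <= k <= n")
    if (is.null(object@sites$ref) || is.null(object@sites$alt))
      msg <- c(msg, "sites must carry 'ref' and 'alt' metadata columns")
  }
  if (length(msg)) msg else TRUE
})

#' SexModel: logistic model on the Y/X normalized depth ratio
#'
#' A single-feature logistic regression predicting genetic sex (male = 1)
#' from the Y-to-X normalized read-depth ratio. The decision boundary
#' `thresholdRatio` is the ratio at which the predicted probability is 0.5.
#'
#' @slot intercept numeric logistic intercept.
#' @slot coefficient numeric logistic slope on the ratio; positive.
#' @slot thresholdRatio numeric ratio where P(male) = 0.5.
#'
#' @seealso [fitSexModel()], [defaultSexModel()], [predictSex()]
#' @exportClass SexModel
setClass("SexModel",
         slots = c(intercept = "numeric", coefficient = "numeric",
                   thresholdRatio = "numeric"))

setValidity("SexModel", function(object) {
  msg <- character()
  if (length(object@coefficient) != 1L || object@coefficient <= 0)
    msg <- c(msg, "coefficient must be a single positive number")
  if (length(object@intercept) != 1L)
    msg <- c(msg, "intercept must be a single number")
  tr <- -object@intercept / object@coefficient
  if (abs(tr - object@thresholdRatio) > 1e-8)
    msg <- c(msg, "thresholdRatio must equal -intercept/coefficient")
  if (length(msg)) msg else TRUE
})
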