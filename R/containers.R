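# Constructors, accessors and show methods for the core containers.

.normChrom <- function(chrom) sub("^chr", "", as.character(chrom))

.makeKeys <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

.siteGRanges <- function(chrom, pos, ref, alt) {
  gr <- GenomicRanges::GRanges(.normChrom(chrom),
                               IRanges::IRanges(pos, width = 1L))
  gr$ref <- as.character(ref)
  gr$alt <- as.character(alt)
  gr
}

.grKeys <- function(gr) {
  .makeKeys(as.character(GenomicRanges::seqnames(gr)),
            GenomicRanges::start(gr), gr$ref, gr$alt)
}

#' Construct a SitePanel
#'
#' Builds a [SitePanel-class] from parallel site vectors and a frequency
#' matrix. Sites are sorted into genomic order (chromosome as character,
#' then position); a leading `"chr"` prefix is stripped from chromosome
#' names so GRCh37- and GRCh38-style names align.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-base reference / alternative alleles.
#' @param freq numeric matrix (or vector for one population) of
#'   alternative-allele frequencies; columns named by population.
#' @return A `SitePanel`.
#' @examples
#' SitePanel("1", c(100L, 200L), c("A", "C"), c("G", "T"),
#'           freq = cbind(POP = c(0.2, 0.5)))
#' @export
SitePanel <- function(chrom, pos, ref, alt, freq) {
  if (is.null(dim(freq))) freq <- cbind(POP = as.numeric(freq))
  freq <- as.matrix(freq)
  storage.mode(freq) <- "double"
  gr <- .siteGRanges(chrom, pos, ref, alt)
  ord <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
  new("SitePanel", sites = gr[ord], freq = freq[ord, , drop = FALSE])
}

#' Construct a GenotypeSet
#'
#' @param keys character site keys (`"chrom:pos:ref:alt"`), typically
#'   `siteKeys(panel)`.
#' @param dosage integer matrix (sites x individuals) of alt-allele counts
#'   in \{0, 1, 2\} with `NA` for missing; columns named by individual.
#' @return A `GenotypeSet`.
#' @export
GenotypeSet <- function(keys, dosage) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("ind", seq_len(ncol(dosage)))
  new("GenotypeSet", keys = as.character(keys), dosage = dosage)
}

#' Construct an ObservationSet
#'
#' @param chrom,pos,ref,alt site coordinates and alleles (as in
#'   [SitePanel()]).
#' @param n integer total counted read bases per site (>= 1).
#' @param k integer reference-allele bases per site (0 <= k <= n).
#' @return An `ObservationSet`; sites are kept in the order given.
#' @export
ObservationSet <- function(chrom, pos, ref, alt, n, k) {
  new("ObservationSet", sites = .siteGRanges(chrom, pos, ref, alt),
      n = as.integer(n), k = as.integer(k))
}

## ---- SitePanel methods -----------------------------------------------

#' @rdname SitePanel-class
#' @param x a `SitePanel`
#' @export
setMethod("nSites", "SitePanel", function(x) length(x@sites))

#' @rdname SitePanel-class
#' @export
setMethod("length", "SitePanel", function(x) length(x@sites))

#' @rdname SitePanel-class
#' @export
setMethod("siteKeys", "SitePanel", function(x) .grKeys(x@sites))

#' @rdname SitePanel-class
#' @export
setMethod("panelSites", "SitePanel", function(x) x@sites)

#' @rdname SitePanel-class
#' @export
setMethod("populations", "SitePanel", function(x) colnames(x@freq))

#' @rdname SitePanel-class
#' @param population population label; must match a frequency column.
#' @export
setMethod("alleleFreq", "SitePanel", function(x, population) {
  if (missing(population)) return(x@freq)
  if (!population %in% colnames(x@freq))
    stop("unknown population label: ", population)
  x@freq[, population]
})

#' @rdname SitePanel-class
#' @param i index vector
#' @param j,drop,... unused
#' @export
setMethod("[", "SitePanel", function(x, i, j, ..., drop = FALSE) {
  new("SitePanel", sites = x@sites[i], freq = x@freq[i, , drop = FALSE])
})

setMethod("show", "SitePanel", function(object) {
  cat("SitePanel with", length(object@sites), "sites and",
      ncol(object@freq), "population(s):",
      paste(colnames(object@freq), collapse = ", "), "\n")
})

## ---- GenotypeSet methods ---------------------------------------------

#' @rdname GenotypeSet-class
#' @param x a `GenotypeSet`
#' @export
setMethod("dosages", "GenotypeSet", function(x) x@dosage)

#' @rdname GenotypeSet-class
#' @export
setMethod("sampleIds", "GenotypeSet", function(x) colnames(x@dosage))

#' @rdname GenotypeSet-class
#' @export
setMethod("siteKeys", "GenotypeSet", function(x) x@keys)

#' @rdname GenotypeSet-class
#' @export
setMethod("nSites", "GenotypeSet", function(x) length(x@keys))

#' @rdname GenotypeSet-class
#' @param i site index vector
#' @param j,drop,... unused
#' @export
setMethod("[", "GenotypeSet", function(x, i, j, ..., drop = FALSE) {
  new("GenotypeSet", keys = x@keys[i], dosage = x@dosage[i, , drop = FALSE])
})

setMethod("show", "GenotypeSet", function(object) {
  cat("GenotypeSet:", ncol(object@dosage), "individual(s) x",
      length(object@keys), "sites;",
      sum(is.na(object@dosage)), "missing dosage(s)\n")
})

## ---- ObservationSet methods ------------------------------------------

#' @rdname ObservationSet-class
#' @param x an `ObservationSet`
#' @export
setMethod("nSites", "ObservationSet", function(x) length(x@sites))

#' @rdname ObservationSet-class
#' @export
setMethod("length", "ObservationSet", function(x) length(x@sites))

#' @rdname ObservationSet-class
#' @export
setMethod("nBases", "ObservationSet", function(x) sum(x@n))

#' @rdname ObservationSet-class
#' @export
setMethod("siteKeys", "ObservationSet", function(x) .grKeys(x@sites))

#' @rdname ObservationSet-class
#' @export
setMethod("panelSites", "ObservationSet", function(x) x@sites)

#' @rdname ObservationSet-class
#' @export
setMethod("refCounts", "ObservationSet", function(x) x@k)

#' @rdname ObservationSet-class
#' @export
setMethod("totalCounts", "ObservationSet", function(x) x@n)

#' @rdname ObservationSet-class
#' @param i index vector
#' @param j,drop,... unused
#' @export
setMethod("[", "ObservationSet", function(x, i, j, ..., drop = FALSE) {
  new("ObservationSet", sites = x@sites[i], n = x@n[i], k = x@k[i])
})

setMethod("show", "ObservationSet", function(object) {
  cat("ObservationSet:", length(object@sites), "covered site(s),",
      sum(object@n), "counted base(s)\n")
})

#' Convert an ObservationSet to a data.frame
#'
#' @param x an `ObservationSet`
#' @param row.names,optional,... passed through for generic compatibility
#' @return data.frame with columns chrom, pos, ref, alt, n_ref, n_alt.
#' @export
as.data.frame.ObservationSet <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(x@sites)),
             pos = GenomicRanges::start(x@sites),
             ref = x@sites$ref, alt = x@sites$alt,
             n_ref = x@k, n_alt = x@n - x@k,
             stringsAsFactors = FALSE, row.names = row.names)
}

## ---- SexModel --------------------------------------------------------

#' Construct a SexModel
#'
#' @param intercept,coefficient logistic parameters; `coefficient` must be
#'   positive (male coded 1, higher Y/X ratio).
#' @return A [SexModel-class].
#' @export
SexModel <- function(intercept, coefficient) {
  new("SexModel", intercept = as.numeric(intercept),
      coefficient = as.numeric(coefficient),
      thresholdRatio = -intercept / coefficient)
}

setMethod("show", "SexModel", function(object) {
  cat(sprintf(
    "SexModel: logit P(male) = %.4g + %.4g * (Y/X ratio); threshold %.4g\n",
    object@intercept, object@coefficient, object@thresholdRatio))
})
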