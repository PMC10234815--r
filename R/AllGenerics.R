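#' @rdname SitePanel-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname SitePanel-class
#' @export
setGeneric("siteKeys", function(x) standardGeneric("siteKeys"))

#' @rdname SitePanel-class
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname SitePanel-class
#' @export
setGeneric("alleleFreq", function(x, population) standardGeneric("alleleFreq"))

#' @rdname GenotypeSet-class
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeSet-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname ObservationSet-class
#' @export
setGeneric("nBases", function(x) standardGeneric("nBases"))

#' @rdname ObservationSet-class
#' @export
setGeneric("refCounts", function(x) standardGeneric("refCounts"))

#' @rdname ObservationSet-class
#' @export
setGeneric("totalCounts", function(x) standardGeneric("totalCounts"))

#' @rdname SitePanel-class
#' @export
setGeneric("panelSites", function(x) standardGeneric("panelSites"))
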