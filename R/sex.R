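# Genetic-sex prediction from the Y-to-X normalized read-depth ratio over
# non-pseudo-autosomal regions, via a single-feature logistic model.

#' GRCh37 chromosome lengths
#'
#' Named vector of GRCh37 primary-assembly chromosome lengths (1-22, X,
#' Y, MT), used as the default for depth normalization.
#'
#' @return named numeric vector of lengths in bases.
#' @export
grch37ChromLengths <- function() {
  c(`1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566, X = 155270560, Y = 59373566,
    MT = 16569)
}

#' Default non-pseudo-autosomal region mask (GRCh37)
#'
#' The X and Y intervals outside the standard GRCh37 pseudo-autosomal
#' regions (PAR1/PAR2), shipped as a BED file with the package. Reads in
#' the PARs map to both sex chromosomes and would blur the copy-number
#' signal, so X/Y depths are taken over this mask.
#'
#' @return a `GRanges` mask (see [readBedMask()]).
#' @export
defaultNonParMask <- function() {
  readBedMask(system.file("extdata", "nonpar_GRCh37.bed",
                          package = "metareid", mustWork = TRUE))
}

#' Per-chromosome normalized read depth
#'
#' Two-step normalization: each chromosome's read count is divided by the
#' total read count of the sample (adjusting for library size), then by
#' the chromosome length (adjusting for target size), giving the
#' normalized depth. For X and Y the effective length should be the
#' non-PAR length; when `mask` is supplied, the masked length replaces
#' the full length for any chromosome present in the mask.
#'
#' @param counts named numeric vector of read counts per chromosome (X/Y
#'   counts restricted to non-PAR regions upstream).
#' @param totalReads total reads in the sample (>= 1).
#' @param chromLengths named vector of chromosome lengths; default
#'   [grch37ChromLengths()].
#' @param mask optional `GRanges` (e.g. [defaultNonParMask()]); its
#'   per-chromosome total width overrides `chromLengths`.
#' @return data.frame with columns `chrom`, `count`, `normCount`
#'   (count/totalReads), `normDepth` (normCount/length).
#' @export
depthProfile <- function(counts, totalReads,
                         chromLengths = grch37ChromLengths(),
                         mask = NULL) {
  stopifnot(totalReads >= 1, all(chromLengths > 0))
  chroms <- names(counts)
  if (is.null(chroms)) stop("counts must be named by chromosome")
  chroms <- .normChrom(chroms)
  len <- chromLengths[chroms]
  if (anyNA(len)) stop("missing length for chromosome(s): ",
                       paste(chroms[is.na(len)], collapse = ", "))
  if (!is.null(mask) && length(mask)) {
    mw <- tapply(IRanges::width(mask),
                 as.character(GenomicRanges::seqnames(mask)), sum)
    hit <- chroms %in% names(mw)
    len[hit] <- mw[chroms[hit]]
  }
  normCount <- as.numeric(counts) / totalReads
  data.frame(chrom = chroms, count = as.numeric(counts),
             normCount = normCount, normDepth = normCount / len,
             stringsAsFactors = FALSE)
}

#' Y-to-X normalized depth ratio
#'
#' @param profile a [depthProfile()] data.frame containing rows for X
#'   and Y.
#' @return normalized depth(Y) / normalized depth(X); `NA` with a warning
#'   when X has zero depth.
#' @export
yxRatio <- function(profile) {
  dx <- profile$normDepth[profile$chrom == "X"]
  dy <- profile$normDepth[profile$chrom == "Y"]
  if (length(dx) != 1L || length(dy) != 1L)
    stop("profile must contain exactly one X and one Y row")
  if (dx == 0) {
    warning("zero X depth; Y/X ratio undefined")
    return(NA_real_)
  }
  dy / dx
}

#' Fit the logistic sex model on Y/X depth ratios
#'
#' Maximum-likelihood logistic regression of sex (male = 1, female = 0)
#' on the scalar Y/X ratio. Because male and female ratios are usually
#' perfectly separated, a separable fit is replaced by a lightly
#' L2-penalized fit so that the decision boundary lies strictly between
#' the class extremes instead of diverging.
#'
#' @param ratios numeric Y/X depth ratios.
#' @param labels 0/1 (or logical) labels, male = 1; both classes required.
#' @param penalty L2 penalty weight used on separable data.
#' @return a [SexModel-class].
#' @export
fitSexModel <- function(ratios, labels, penalty = 1e-2) {
  labels <- as.integer(labels)
  stopifnot(length(ratios) == length(labels),
            all(labels %in% 0:1))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to fit the sex model")
  fit <- suppressWarnings(stats::glm(labels ~ ratios,
                                     family = stats::binomial()))
  cf <- stats::coef(fit)
  separable <- !fit$converged || any(abs(cf) > 1e3) ||
    any(fit$fitted.values %in% c(0, 1))
  if (separable || !is.finite(cf[2]) || cf[2] <= 0) {
    negll <- function(b) {
      eta <- b[1] + b[2] * ratios
      sum(base::log1p(exp(-(2 * labels - 1) * eta))) +
        penalty * (b[1]^2 + b[2]^2)
    }
    opt <- stats::optim(c(0, 1), negll, method = "BFGS")
    cf <- opt$par
  }
  if (cf[2] <= 0)
    stop("fitted coefficient is not positive; check label coding")
  SexModel(intercept = unname(cf[1]), coefficient = unname(cf[2]))
}

#' Reference sex model with the published decision threshold
#'
#' For use without training data: a logistic model whose decision
#' boundary is at Y/X = 0.43, the threshold obtained by logistic
#' regression on a large training cohort. The slope is nominal (it sets
#' only how fast the probability saturates away from the boundary); the
#' classification depends on the threshold alone.
#'
#' @return a [SexModel-class] with `thresholdRatio` 0.43.
#' @export
defaultSexModel <- function() {
  SexModel(intercept = -0.43 * 30, coefficient = 30)
}

#' Predict genetic sex from a Y/X depth ratio
#'
#' @param ratio Y/X normalized depth ratio(s); `NA` yields a no-call.
#' @param model a [SexModel-class]; default [defaultSexModel()].
#' @return data.frame with `ratio`, `pMale` (logistic probability), and
#'   `sex` ("male" when ratio > threshold, "female" when below, `NA`
#'   no-call at exactly the threshold or for undefined ratios).
#' @export
predictSex <- function(ratio, model = defaultSexModel()) {
  pMale <- stats::plogis(model@intercept + model@coefficient * ratio)
  sex <- ifelse(is.na(ratio), NA_character_,
                ifelse(ratio > model@thresholdRatio, "male",
                       ifelse(ratio < model@thresholdRatio, "female",
                              NA_character_)))
  data.frame(ratio = ratio, pMale = pMale, sex = sex,
             stringsAsFactors = FALSE)
}
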