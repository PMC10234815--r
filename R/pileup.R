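# Decoding samtools-style pileup text into per-site base counts, with
# base-quality filtering, and the mitochondrial non-major-allele fraction
# used as a contamination indicator. No installed R package parses the
# pileup text grammar (BAM-based pileup engines do not apply), so the
# decoder is implemented here and checked against a brute-force oracle in
# the tests.

# Decode one pileup base string together with its quality string.
# Returns list(base = character(), qual = integer()) with one entry per
# base column: "." and "," become refBase, ACGTN (any case) the upper-case
# base, "*" (deleted base) and ">"/"<" (reference skip) become NA. Read
# start ("^" + mapping-quality char), read end ("$") and indel runs
# ("+n<seq>"/"-n<seq>") are consumed without emitting a column. Qualities
# are Phred (ASCII - 33), consumed one per base column.
.decodePileupBases <- function(bases, quals, refBase) {
  bs <- strsplit(bases, "")[[1]]
  qs <- utf8ToInt(quals) - 33L
  outBase <- character(0)
  outQual <- integer(0)
  i <- 1L; j <- 1L
  nb <- length(bs)
  while (i <= nb) {
    ch <- bs[i]
    if (ch == "^") {
      i <- i + 2L
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      i <- i + 1L
      ndig <- 0L
      while (i + ndig <= nb && grepl("^[0-9]$", bs[i + ndig]))
        ndig <- ndig + 1L
      if (ndig == 0L) stop("malformed indel run in pileup base string")
      len <- as.integer(paste(bs[i:(i + ndig - 1L)], collapse = ""))
      i <- i + ndig + len
    } else {
      b <- if (ch %in% c(".", ",")) toupper(refBase)
           else if (toupper(ch) %in% c("A", "C", "G", "T", "N")) toupper(ch)
           else if (ch %in% c("*", "#", ">", "<")) NA_character_
           else stop("unexpected pileup character '", ch, "'")
      if (j > length(qs)) stop("quality string shorter than base columns")
      outBase <- c(outBase, b)
      outQual <- c(outQual, qs[j])
      j <- j + 1L
      i <- i + 1L
    }
  }
  list(base = outBase, qual = outQual)
}

.readPileupLines <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(NULL)
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 6L))
    stop("pileup line with fewer than 6 columns")
  list(chrom = .normChrom(vapply(parts, `[`, "", 1L)),
       pos = as.integer(vapply(parts, `[`, "", 2L)),
       ref = toupper(vapply(parts, `[`, "", 3L)),
       depth = as.integer(vapply(parts, `[`, "", 4L)),
       bases = vapply(parts, `[`, "", 5L),
       quals = vapply(parts, `[`, "", 6L))
}

# Decode a whole pileup file to per-position filtered base counts.
# Returns data.frame(chrom, pos, ref, A, C, G, T).
.pileupBaseCounts <- function(file, minBaseQuality = 20L) {
  pl <- .readPileupLines(file)
  if (is.null(pl))
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), A = integer(), C = integer(),
                      G = integer(), T = integer()))
  counts <- matrix(0L, nrow = length(pl$pos), ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (r in seq_along(pl$pos)) {
    dec <- .decodePileupBases(pl$bases[r], pl$quals[r], pl$ref[r])
    if (length(dec$base) != pl$depth[r])
      stop("pileup depth mismatch at ", pl$chrom[r], ":", pl$pos[r],
           " (stated ", pl$depth[r], ", decoded ", length(dec$base), ")")
    ok <- !is.na(dec$base) & dec$base %in% c("A", "C", "G", "T") &
      dec$qual >= minBaseQuality
    if (any(ok)) {
      tb <- table(factor(dec$base[ok], levels = c("A", "C", "G", "T")))
      counts[r, ] <- counts[r, ] + as.integer(tb)
    }
  }
  data.frame(chrom = pl$chrom, pos = pl$pos, ref = pl$ref,
             A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
             T = counts[, "T"], stringsAsFactors = FALSE)
}

#' Convert a pileup to per-site reference/alternative base counts
#'
#' Decodes a 6-column samtools-style pileup (chrom, pos, ref, depth,
#' bases, qualities), applies the base-quality filter, and reduces each
#' panel site to the counts `n` (bases matching the panel's ref or alt)
#' and `k` (bases matching ref). Bases matching neither allele are
#' excluded, as the likelihood model is biallelic. Positions not in the
#' panel are ignored. Mapping-quality filtering must have been applied
#' upstream when the pileup was generated (e.g. `-q 40` at pileup time);
#' pileup text carries no per-base mapping quality.
#'
#' @param file path to the pileup text.
#' @param panel [SitePanel-class] defining the sites and their alleles.
#' @param minBaseQuality minimum Phred base quality; default 20.
#' @return An [ObservationSet-class] (sites with no counted base are
#'   omitted).
#' @export
pileupToCounts <- function(file, panel, minBaseQuality = 20L) {
  bc <- .pileupBaseCounts(file, minBaseQuality)
  pk <- paste(as.character(GenomicRanges::seqnames(panel@sites)),
              GenomicRanges::start(panel@sites))
  idx <- match(paste(bc$chrom, bc$pos), pk)
  hit <- !is.na(idx)
  bc <- bc[hit, , drop = FALSE]
  idx <- idx[hit]
  if (!nrow(bc))
    return(ObservationSet(character(), integer(), character(), character(),
                          integer(), integer()))
  refA <- panel@sites$ref[idx]
  altA <- panel@sites$alt[idx]
  m <- as.matrix(bc[, c("A", "C", "G", "T")])
  k <- m[cbind(seq_len(nrow(m)), match(refA, colnames(m)))]
  na <- m[cbind(seq_len(nrow(m)), match(altA, colnames(m)))]
  n <- k + na
  keep <- n > 0L
  ObservationSet(bc$chrom[keep], bc$pos[keep], refA[keep], altA[keep],
                 n[keep], k[keep])
}

#' Per-position base counts from a pileup
#'
#' Full four-base decoding of a pileup (no panel restriction), e.g. for
#' the mitochondrial chromosome ahead of [nonmajorAlleleFraction()].
#'
#' @inheritParams pileupToCounts
#' @return data.frame with columns chrom, pos, ref, A, C, G, T.
#' @export
pileupBaseCounts <- function(file, minBaseQuality = 20L) {
  .pileupBaseCounts(file, minBaseQuality)
}

#' Non-major-allele fraction across mitochondrial positions
#'
#' Contamination indicator for a haploid chromosome: at each covered
#' position the major base is the plurality base (ties broken toward the
#' reference); the statistic is the summed count of non-major bases over
#' the summed total count. A pure single-haplotype sample gives ~0 (up to
#' sequencing error); a mixture of two haplotypes at fraction f gives ~f
#' at discordant positions.
#'
#' @param baseCounts data.frame as returned by [pileupBaseCounts()]
#'   (columns ref, A, C, G, T; one row per position).
#' @return fraction in \[0, 0.5\]; `NA` (with a warning) when there is no
#'   coverage.
#' @export
nonmajorAlleleFraction <- function(baseCounts) {
  m <- as.matrix(baseCounts[, c("A", "C", "G", "T")])
  tot <- rowSums(m)
  keep <- tot >= 1
  if (!any(keep)) {
    warning("no mitochondrial coverage; non-major fraction undefined")
    return(NA_real_)
  }
  m <- m[keep, , drop = FALSE]
  # the tie-toward-reference rule picks which base is called major, but
  # the major *count* is the row maximum either way
  mx <- apply(m, 1L, max)
  sum(rowSums(m) - mx) / sum(rowSums(m))
}
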