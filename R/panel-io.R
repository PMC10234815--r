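# Reading the standard formats: VCF frequency panels and genotypes, BED
# region masks, site-count tables; plus alignment of genotype records to a
# panel. VCF parsing is delegated to VariantAnnotation; only biallelic
# SNVs are retained anywhere.

# Extract biallelic-SNV records from a VCF read by VariantAnnotation.
# Returns list(gr = GRanges with ref/alt, keep = logical over original
# records, nIndel, nMulti).
.biallelicSnvs <- function(vcf) {
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alt)
  refc <- as.character(VariantAnnotation::ref(vcf))
  multi <- nalt != 1L
  alt1 <- rep(NA_character_, length(rr))
  alt1[!multi] <- as.character(unlist(alt[!multi]))
  snv <- !multi & nchar(refc) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    refc %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
  keep <- snv
  gr <- GenomicRanges::GRanges(
    .normChrom(as.character(GenomicRanges::seqnames(rr)[keep])),
    IRanges::IRanges(GenomicRanges::start(rr)[keep], width = 1L))
  gr$ref <- refc[keep]
  gr$alt <- alt1[keep]
  nIndel <- sum(!multi & (nchar(refc) != 1L |
                            (!is.na(alt1) & nchar(alt1) != 1L)))
  list(gr = gr, keep = keep, nIndel = nIndel, nMulti = sum(multi))
}

# "0/1", "0|1", "./." ... -> dosage 0/1/2/NA
.gtToDosage <- function(gt) {
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  d <- (a1 == "1") + (a2 == "1")
  d[!(a1 %in% c("0", "1")) | !(a2 %in% c("0", "1"))] <- NA_integer_
  as.integer(d)
}

#' Read an allele-frequency panel from VCF
#'
#' Reads a VCF, keeps only biallelic SNVs (indels and multiallelic records
#' are dropped and counted in a message), and computes per-population
#' alternative-allele frequencies from the genotype columns as alt-allele
#' count / (2 x non-missing individuals). Populations are defined by
#' `popMap`; with `popMap = NULL` all samples form one population labelled
#' `"ALL"`.
#'
#' Alternatively, with `infoFields`, frequencies are taken directly from
#' per-population INFO fields (e.g. as written by [writeFrequencyVcf()])
#' and no genotype columns are needed.
#'
#' @param file path to a VCF (plain or bgzipped).
#' @param popMap named character vector mapping sample id -> population
#'   label, or `NULL` for a single pooled population.
#' @param populations optional subset of population labels to keep; labels
#'   absent from `popMap` are an error.
#' @param infoFields optional named character vector mapping population
#'   label -> INFO key holding that population's alt-allele frequency;
#'   overrides genotype-derived frequencies.
#' @return A [SitePanel-class].
#' @export
readFrequencyPanel <- function(file, popMap = NULL, populations = NULL,
                               infoFields = NULL) {
  vcf <- VariantAnnotation::readVcf(file)
  bi <- .biallelicSnvs(vcf)
  if (length(bi$gr) == 0L)
    stop("no biallelic SNVs in ", file)
  if (bi$nIndel + bi$nMulti > 0L)
    message("dropped ", bi$nIndel, " indel and ", bi$nMulti,
            " multiallelic record(s)")
  if (!is.null(infoFields)) {
    if (is.null(names(infoFields)))
      names(infoFields) <- sub("^AF_", "", infoFields)
    inf <- VariantAnnotation::info(vcf)
    freq <- sapply(infoFields, function(key) {
      if (!key %in% colnames(inf))
        stop("INFO field not present in VCF: ", key)
      v <- inf[[key]]
      if (is.list(v) || inherits(v, "List"))
        v <- vapply(v, function(x) if (length(x)) x[1] else NA_real_,
                    numeric(1))
      as.numeric(v)[bi$keep]
    })
    if (sum(bi$keep) == 1L)
      freq <- matrix(freq, nrow = 1L,
                     dimnames = list(NULL, names(infoFields)))
    colnames(freq) <- names(infoFields)
    sk <- bi$gr
    return(SitePanel(as.character(GenomicRanges::seqnames(sk)),
                     GenomicRanges::start(sk), sk$ref, sk$alt, freq))
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field; cannot derive frequencies")
  gt <- gt[bi$keep, , drop = FALSE]
  samples <- colnames(gt)
  if (is.null(popMap)) popMap <- stats::setNames(rep("ALL", length(samples)),
                                                samples)
  pops <- unique(unname(popMap[samples[samples %in% names(popMap)]]))
  if (!is.null(populations)) {
    if (!all(populations %in% pops))
      stop("unknown population label(s): ",
           paste(setdiff(populations, pops), collapse = ", "))
    pops <- populations
  }
  if (!length(pops)) stop("no samples map to any requested population")
  freq <- sapply(pops, function(pp) {
    ids <- samples[samples %in% names(popMap) & popMap[samples] == pp]
    d <- apply(gt[, ids, drop = FALSE], 2L, .gtToDosage)
    if (length(bi$gr) == 1L) d <- matrix(d, nrow = 1L)
    nonmiss <- rowSums(!is.na(d))
    cnt <- rowSums(d, na.rm = TRUE)
    ifelse(nonmiss > 0L, cnt / (2 * nonmiss), NA_real_)
  })
  if (length(bi$gr) == 1L) freq <- matrix(freq, nrow = 1L,
                                          dimnames = list(NULL, pops))
  sk <- bi$gr
  SitePanel(as.character(GenomicRanges::seqnames(sk)),
            GenomicRanges::start(sk), sk$ref, sk$alt, freq)
}

#' Write a SitePanel as a sites-only VCF with frequency INFO fields
#'
#' Each population's frequencies are written as an INFO field
#' `AF_<population>` (with matching header definitions), one biallelic
#' SNV record per site. The file can be read back with
#' [readFrequencyPanel()] using `infoFields`.
#'
#' @param panel a [SitePanel-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeFrequencyVcf <- function(panel, file) {
  pops <- populations(panel)
  keys <- paste0("AF_", pops)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf(paste0("##INFO=<ID=%s,Number=A,Type=Float,",
                          "Description=\"Alt allele frequency (%s)\">"),
                   keys, pops),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  gr <- panelSites(panel)
  fr <- alleleFreq(panel)
  info <- apply(fr, 1L, function(v)
    paste(sprintf("%s=%.6g", keys, v), collapse = ";"))
  body <- paste(as.character(GenomicRanges::seqnames(gr)),
                GenomicRanges::start(gr), ".", gr$ref, gr$alt, ".", ".",
                info, sep = "\t")
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Write a GenotypeSet as a VCF
#'
#' One biallelic SNV record per panel site with unphased GT columns
#' (missing dosage as `./.`). Intended for serializing simulated
#' candidate sets; read back with [readGenotypes()].
#'
#' @param genotypes a [GenotypeSet-class] aligned to `panel`.
#' @param panel the [SitePanel-class] providing site coordinates.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeGenotypeVcf <- function(genotypes, panel, file) {
  stopifnot(identical(siteKeys(genotypes), siteKeys(panel)))
  gr <- panelSites(panel)
  gtCode <- c("0/0", "0/1", "1/1")
  d <- dosages(genotypes)
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gtCode[d[ok] + 1L]
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sampleIds(genotypes)),
                 collapse = "\t"))
  body <- paste(as.character(GenomicRanges::seqnames(gr)),
                GenomicRanges::start(gr), ".", gr$ref, gr$alt, ".", ".",
                ".", "GT", apply(gt, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Read candidate genotypes from VCF, aligned to a panel
#'
#' Dosages are aligned to the panel by (chrom, pos, ref, alt). Panel sites
#' absent from the VCF become missing. Records whose alleles are exactly
#' swapped relative to the panel (VCF ref = panel alt and vice versa) are
#' complemented (g -> 2 - g) and counted; records matching on position but
#' not on alleles are dropped. Phased and unphased genotypes are treated
#' identically (only the dosage is used).
#'
#' @param file path to a VCF with GT fields.
#' @param panel the [SitePanel-class] to align to.
#' @return A [GenotypeSet-class] with `siteKeys` equal to the panel's.
#' @export
readGenotypes <- function(file, panel) {
  vcf <- VariantAnnotation::readVcf(file)
  bi <- .biallelicSnvs(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  gt <- gt[bi$keep, , drop = FALSE]
  d <- apply(gt, 2L, .gtToDosage)
  if (length(bi$gr) == 1L) d <- matrix(d, nrow = 1L,
                                       dimnames = list(NULL, colnames(gt)))
  vk <- .grKeys(bi$gr)
  vkSwap <- .makeKeys(as.character(GenomicRanges::seqnames(bi$gr)),
                      GenomicRanges::start(bi$gr), bi$gr$alt, bi$gr$ref)
  pk <- siteKeys(panel)
  direct <- match(pk, vk)
  swapped <- match(pk, vkSwap)
  swapped[!is.na(direct)] <- NA_integer_
  nSwap <- sum(!is.na(swapped))
  if (nSwap > 0L)
    message(nSwap, " record(s) had ref/alt swapped; dosages complemented")
  out <- matrix(NA_integer_, nrow = length(pk), ncol = ncol(d),
                dimnames = list(NULL, colnames(gt)))
  hit <- !is.na(direct)
  out[hit, ] <- d[direct[hit], , drop = FALSE]
  hit <- !is.na(swapped)
  out[hit, ] <- 2L - d[swapped[hit], , drop = FALSE]
  if (all(is.na(out)))
    stop("no panel sites overlap the genotype VCF")
  GenotypeSet(pk, out)
}

#' Read a site-count table
#'
#' Reads the tab-separated exchange format for per-site read-base counts
#' (columns `chrom, pos, ref, alt, n_ref, n_alt`; a leading `#` on the
#' header is allowed) and matches rows against a panel. Rows at sites not
#' in the panel are skipped with a message; rows with zero total bases are
#' dropped.
#'
#' @param file path to the TSV.
#' @param panel [SitePanel-class] used to admit sites.
#' @return An [ObservationSet-class].
#' @export
readSiteCounts <- function(file, panel) {
  first <- readLines(file, n = 1L)
  hasHeader <- grepl("^#?chrom\\b", first)
  tab <- utils::read.table(file, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           col.names = c("chrom", "pos", "ref", "alt",
                                         "n_ref", "n_alt"))
  if (!hasHeader && !is.numeric(tab$pos))
    stop("malformed site-count table: non-numeric pos at line 1")
  bad <- which(!is.finite(tab$pos) | !is.finite(tab$n_ref) |
                 !is.finite(tab$n_alt) | tab$n_ref < 0 | tab$n_alt < 0)
  if (length(bad))
    stop("malformed site-count row at line ", bad[1] + hasHeader)
  tab$chrom <- .normChrom(tab$chrom)
  keys <- .makeKeys(tab$chrom, tab$pos, tab$ref, tab$alt)
  inPanel <- keys %in% siteKeys(panel)
  if (any(!inPanel))
    message("skipped ", sum(!inPanel), " row(s) at sites not in the panel")
  tab <- tab[inPanel, , drop = FALSE]
  n <- tab$n_ref + tab$n_alt
  tab <- tab[n > 0, , drop = FALSE]
  n <- n[n > 0]
  ObservationSet(tab$chrom, tab$pos, tab$ref, tab$alt, n, tab$n_ref)
}

#' Write a site-count table
#'
#' Inverse of [readSiteCounts()]: writes an [ObservationSet-class] as the
#' tab-separated exchange format with header
#' `#chrom pos ref alt n_ref n_alt`.
#'
#' @param obs an `ObservationSet`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeSiteCounts <- function(obs, file) {
  df <- as.data.frame(obs)
  writeLines("#chrom\tpos\tref\talt\tn_ref\tn_alt", file)
  utils::write.table(df, file, append = TRUE, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a BED3 region mask
#'
#' Reads a BED file of 0-based half-open intervals (e.g. non-pseudo-
#' autosomal region definitions), merging overlapping intervals on load.
#' Chromosome names are normalized by stripping a leading `"chr"`.
#'
#' @param file path to a BED file with at least 3 columns.
#' @return a reduced `GRanges` (1-based internally, as usual for
#'   `GRanges`; use `start - 1` to recover BED coordinates).
#' @export
readBedMask <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines))
    return(GenomicRanges::GRanges())
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 3L)) stop("BED line with fewer than 3 columns")
  chrom <- .normChrom(vapply(parts, `[`, "", 1L))
  s <- as.numeric(vapply(parts, `[`, "", 2L))
  e <- as.numeric(vapply(parts, `[`, "", 3L))
  if (anyNA(s) || anyNA(e) || any(s < 0)) stop("malformed BED coordinates")
  if (any(s >= e)) stop("BED interval with start >= end")
  GenomicRanges::reduce(
    GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1, e)))
}
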