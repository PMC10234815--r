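test_that("frequency panel keeps only biallelic SNVs and computes AF", {
  f <- gtVcf(c(gtRecord("1", 100, "A", "G", c("0/0", "0/1", "1/1")),
               gtRecord("1", 200, "C", "T,G", c("0/1", "0/2", "1/1")),
               gtRecord("1", 300, "A", "AT", c("0/1", "0/0", "1/1"))),
             samples = c("S1", "S2", "S3"))
  pm <- setNames(rep("EAS", 3), c("S1", "S2", "S3"))
  panel <- suppressMessages(readFrequencyPanel(f, pm))
  expect_equal(nSites(panel), 1L)
  expect_equal(unname(alleleFreq(panel, "EAS")), 0.5)  # 3 alt / 6 alleles
  expect_error(suppressMessages(readFrequencyPanel(f, pm,
                                                   populations = "EUR")),
               "unknown population")
  # only non-biallelic records -> empty-panel error
  f2 <- gtVcf(gtRecord("1", 200, "C", "T,G", c("0/1", "0/2", "1/1")),
              samples = c("S1", "S2", "S3"))
  expect_error(suppressMessages(readFrequencyPanel(f2, pm)),
               "no biallelic SNVs")
})

test_that("a synthetic thousand-record VCF is filtered to the SNV subset", {
  set.seed(5)
  nRec <- 1000
  isIndel <- sample(nRec, 50)
  bases <- c("A", "C", "G", "T")
  recs <- character(nRec)
  pos <- sort(sample.int(1e6, nRec))
  nSnv <- 0L
  for (i in seq_len(nRec)) {
    ref <- sample(bases, 1)
    if (i %in% isIndel) {
      alt <- paste0(ref, sample(bases, 1))
    } else {
      alt <- sample(setdiff(bases, ref), 1)
      nSnv <- nSnv + 1L
    }
    recs[i] <- gtRecord("2", pos[i], ref, alt, c("0/1", "0/0"))
  }
  f <- gtVcf(recs, samples = c("S1", "S2"))
  panel <- suppressMessages(readFrequencyPanel(f, NULL))
  expect_equal(nSites(panel), 950L)
  expect_equal(nSites(panel), nSnv)
})

test_that("genotype alignment handles dosage, swap complement and missing", {
  panel <- tinyPanel(c(0.2, 0.5, 0.8))          # sites 1:100/200/300 A>G
  f <- gtVcf(c(gtRecord("1", 100, "A", "G", "0/1"),
               gtRecord("1", 200, "G", "A", "1/1"),   # swapped alleles
               gtRecord("1", 300, "A", "G", "./.")),
             samples = "S1")
  gs <- suppressMessages(readGenotypes(f, panel))
  expect_identical(siteKeys(gs), siteKeys(panel))
  expect_equal(unname(dosages(gs)[, "S1"]), c(1L, 0L, NA_integer_))
  # phased GT treated as unphased; chr prefix normalized
  f2 <- gtVcf(gtRecord("chr1", 100, "A", "G", "1|1"), samples = "S1")
  gs2 <- suppressMessages(readGenotypes(f2, panel))
  expect_equal(unname(dosages(gs2)[, "S1"]), c(2L, NA_integer_, NA_integer_))
  # zero overlap is an error
  f3 <- gtVcf(gtRecord("9", 999, "A", "G", "0/1"), samples = "S1")
  expect_error(suppressMessages(readGenotypes(f3, panel)), "no panel sites")
})

test_that("site-count tables round-trip bit-exactly and filter n = 0", {
  panel <- tinyPanel(c(0.2, 0.5, 0.8))
  obs <- ObservationSet("1", c(100L, 300L), c("A", "A"), c("G", "G"),
                        n = c(3L, 5L), k = c(2L, 0L))
  f <- tempfile(fileext = ".tsv")
  writeSiteCounts(obs, f)
  back <- readSiteCounts(f, panel)
  expect_identical(as.data.frame(back), as.data.frame(obs))
  # rows outside the panel skipped; zero-total rows dropped
  lines <- c("#chrom\tpos\tref\talt\tn_ref\tn_alt",
             "1\t100\tA\tG\t2\t1",
             "1\t150\tA\tG\t4\t0",     # not a panel site
             "1\t200\tA\tG\t0\t0")     # n = 0
  f2 <- tempfile(fileext = ".tsv")
  writeLines(lines, f2)
  got <- suppressMessages(readSiteCounts(f2, panel))
  expect_equal(nSites(got), 1L)
  expect_equal(totalCounts(got), 3L)
  expect_equal(refCounts(got), 2L)
})

test_that("frequency VCF writer round-trips through the INFO reader", {
  panel <- simulatePanel(80, pops = c("EAS", "EUR"), F = 0.05, seed = 21)
  f <- tempfile(fileext = ".vcf")
  writeFrequencyVcf(panel, f)
  back <- readFrequencyPanel(f, infoFields = c(EAS = "AF_EAS",
                                               EUR = "AF_EUR"))
  expect_identical(siteKeys(back), siteKeys(panel))
  expect_equal(alleleFreq(back), alleleFreq(panel), tolerance = 1e-5)
  # genotype VCF writer round-trips through readGenotypes
  gs <- simulateGenotypes(panel, "EAS", 4, seed = 22)
  fg <- tempfile(fileext = ".vcf")
  writeGenotypeVcf(gs, panel, fg)
  gs2 <- suppressMessages(readGenotypes(fg, panel))
  expect_identical(dosages(gs2), dosages(gs))
})

test_that("BED masks load 0-based half-open and merge overlaps", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("X\t60000\t2699520"), f)
  m <- readBedMask(f)
  expect_equal(as.character(seqnames(m)), "X")
  expect_equal(start(m) - 1, 60000)   # back to BED coords
  expect_equal(end(m), 2699520)
  # empty file -> empty mask
  f2 <- tempfile(fileext = ".bed"); writeLines(character(0), f2)
  expect_equal(length(readBedMask(f2)), 0L)
  # overlapping intervals merge to their union
  f3 <- tempfile(fileext = ".bed")
  writeLines(c("1\t10\t100", "1\t50\t150", "1\t200\t300"), f3)
  m3 <- readBedMask(f3)
  expect_equal(length(m3), 2L)
  expect_equal(sum(IRanges::width(m3)), (150 - 10) + (300 - 200))
  # malformed interval
  f4 <- tempfile(fileext = ".bed"); writeLines("1\t100\t100", f4)
  expect_error(readBedMask(f4), "start >= end")
})
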