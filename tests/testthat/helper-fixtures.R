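# Fixture builders shared across test files. Everything is generated in
# code; no binary data.

# tiny deterministic panel with explicit frequencies
tinyPanel <- function(freq = c(0.2, 0.5, 0.8), pop = "POP") {
  S <- length(freq)
  SitePanel(chrom = rep("1", S), pos = seq(100L, by = 100L, length.out = S),
            ref = rep("A", S), alt = rep("G", S),
            freq = matrix(freq, ncol = 1, dimnames = list(NULL, pop)))
}

writeVcfLines <- function(lines, file = tempfile(fileext = ".vcf")) {
  writeLines(lines, file)
  file
}

# minimal genotype VCF text for given sample GT strings
gtVcf <- function(records, samples,
                  file = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeVcfLines(c(hdr, records), file)
}

gtRecord <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", ".", ".", "GT", gts),
        collapse = "\t")
}

# independent oracle: per-site loop over the likelihood definition using
# plain arithmetic on probabilities (log taken at the end per site)
oracleLogLik <- function(g, n, k, eps) {
  pAlt <- ((2 - g) * eps + g * (1 - eps)) / 2
  pRef <- (g * eps + (2 - g) * (1 - eps)) / 2
  (n - k) * log(pAlt) + k * log(pRef)
}

oracleScore <- function(g, n, k, eps) {
  tot <- 0
  for (i in seq_along(g)) {
    if (is.na(g[i])) next
    tot <- tot + oracleLogLik(g[i], n[i], k[i], eps)
  }
  tot
}

# brute-force pileup decoder: returns filtered base vector for one line
oracleDecode <- function(bases, quals, refBase, minQ) {
  bs <- strsplit(bases, "")[[1]]
  qs <- utf8ToInt(quals) - 33L
  out <- character(0)
  i <- 1; j <- 1
  while (i <= length(bs)) {
    ch <- bs[i]
    if (ch == "^") { i <- i + 2; next }
    if (ch == "$") { i <- i + 1; next }
    if (ch %in% c("+", "-")) {
      i <- i + 1
      num <- ""
      while (grepl("[0-9]", bs[i])) { num <- paste0(num, bs[i]); i <- i + 1 }
      i <- i + as.integer(num)
      next
    }
    b <- if (ch %in% c(".", ",")) toupper(refBase)
         else if (toupper(ch) %in% c("A", "C", "G", "T", "N")) toupper(ch)
         else NA_character_
    if (!is.na(b) && b != "N" && qs[j] >= minQ) out <- c(out, b)
    j <- j + 1; i <- i + 1
  }
  out
}

# random pileup base/qual string generator for property tests
randomPileupLine <- function(depth, refBase = "A") {
  cols <- character(0)
  for (d in seq_len(depth)) {
    tok <- sample(c(".", ",", "A", "C", "G", "T", "a", "g", "t", "c",
                    "N", "*"),
                  1, prob = c(8, 8, 1, 1, 1, 1, 1, 1, 1, 1, 0.3, 0.5))
    if (runif(1) < 0.15) tok <- paste0("^", intToUtf8(33 + sample(0:40, 1)),
                                       tok)
    if (runif(1) < 0.1) {
      len <- sample(1:3, 1)
      tok <- paste0(tok, "+", len,
                    paste(sample(c("A", "C", "G", "T"), len, TRUE),
                          collapse = ""))
    }
    if (runif(1) < 0.1) tok <- paste0(tok, "$")
    cols <- c(cols, tok)
  }
  quals <- paste(intToUtf8(33 + sample(0:40, depth, TRUE),
                           multiple = TRUE), collapse = "")
  list(bases = paste(cols, collapse = ""), quals = quals)
}
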