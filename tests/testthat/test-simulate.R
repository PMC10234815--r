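test_that("Balding-Nichols panel has the right moments and supports F = 0", {
  # F = 0: all populations share the ancestral frequencies
  p0 <- simulatePanel(100, pops = c("A", "B"), F = 0, seed = 81)
  expect_equal(alleleFreq(p0, "A"), alleleFreq(p0, "B"))
  expect_equal(unname(alleleFreq(p0, "A")), attr(p0, "ancestral"))
  # frequencies strictly inside (0, 1)
  pF <- simulatePanel(10000, pops = "A", F = 0.1, seed = 82)
  f <- alleleFreq(pF, "A")
  expect_true(all(f > 0 & f < 1))
  # conditional mean ~ ancestral, conditional variance ~ F p (1-p)
  anc <- attr(pF, "ancestral")
  dev <- f - anc
  expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(length(dev)))
  ratio <- var(dev) / mean(0.1 * anc * (1 - anc))
  expect_lt(abs(ratio - 1), 0.1)
  # sites are unique, ordered, with valid alleles
  ks <- siteKeys(pF)
  expect_false(anyDuplicated(ks) > 0)
})

test_that("simulated genotypes follow Hardy-Weinberg at each site", {
  S <- 5
  panel <- tinyPanel(c(0.3, 0.3, 0.3, 0.3, 0.3))
  gs <- simulateGenotypes(panel, nIndividuals = 10000, seed = 83)
  d <- dosages(gs)
  for (s in seq_len(5)) {
    obs <- table(factor(d[s, ], levels = 0:2))
    chi <- chisq.test(obs, p = c(0.49, 0.42, 0.09))
    expect_gt(chi$p.value, 1e-4)
  }
  # degenerate frequencies
  pDeg <- SitePanel("1", c(10L, 20L), c("A", "A"), c("G", "G"),
                    matrix(c(0, 1), ncol = 1, dimnames = list(NULL, "P")))
  gDeg <- simulateGenotypes(pDeg, nIndividuals = 50, seed = 84)
  expect_true(all(dosages(gDeg)[1, ] == 0))
  expect_true(all(dosages(gDeg)[2, ] == 2))
})

test_that("offspring follow Mendelian transmission", {
  expect_equal(simulateOffspring(rep(0L, 10), rep(0L, 10), seed = 1),
               rep(0L, 10))
  expect_equal(simulateOffspring(rep(2L, 10), rep(2L, 10), seed = 1),
               rep(2L, 10))
  off <- simulateOffspring(rep(1L, 40000), rep(1L, 40000), seed = 85)
  frq <- table(factor(off, levels = 0:2)) / 40000
  expect_equal(as.numeric(frq), c(0.25, 0.5, 0.25), tolerance = 0.02)
  # missing parents propagate
  expect_true(is.na(simulateOffspring(NA_integer_, 1L, seed = 1)))
})

test_that("observation simulation respects depth, error and determinism", {
  panel <- simulatePanel(100000, seed = 86)
  dos <- rep(0L, 100000)
  obs <- simulateObservations(dos, panel, lambda = 0.01, seed = 87)
  # Poisson total: ~1000 bases within 3 sqrt(1000)
  expect_lt(abs(nBases(obs) - 1000), 3 * sqrt(1000))
  # epsilon = 0 on hom-ref: k = n everywhere
  obs0 <- simulateObservations(dos, panel, lambda = 0.005, epsilon = 0 + 1e-12,
                               seed = 88)
  expect_equal(refCounts(obs0), totalCounts(obs0))
  # lambda = 0 -> empty
  expect_equal(nSites(simulateObservations(dos, panel, 0, seed = 89)), 0L)
  # fixed seed + config -> bit-identical outputs
  a <- simulateObservations(dos, panel, 0.01, seed = 90)
  b <- simulateObservations(dos, panel, 0.01, seed = 90)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("contamination mixes bases at the requested fraction", {
  S <- 30000
  panel <- SitePanel(rep("1", S), seq_len(S) * 10L, rep("A", S),
                     rep("G", S),
                     matrix(rep(0.5, S), ncol = 1,
                            dimnames = list(NULL, "P")))
  host <- rep(0L, S)     # host hom-ref everywhere
  cont <- rep(2L, S)     # contaminant hom-alt everywhere
  eps <- 1e-6
  obs <- mixContamination(host, cont, panel, lambda = 3, fraction = 0.25,
                          epsilon = eps, seed = 91)
  frac <- 1 - sum(refCounts(obs)) / sum(totalCounts(obs))
  expect_lt(abs(frac - 0.25), 0.01)
  # f = 0 equals host-only simulation with the same seed
  o0 <- mixContamination(host, cont, panel, 2, 0, eps, seed = 92)
  expect_true(all(refCounts(o0) == totalCounts(o0)))
  # f = 1 equals contaminant-only
  o1 <- mixContamination(host, cont, panel, 2, 1, eps, seed = 93)
  expect_true(all(refCounts(o1) == 0))
})

test_that("depth profiles allocate reads by copy number and length", {
  lens <- grch37ChromLengths()
  lens <- lens[names(lens) != "MT"]
  cnt <- simulateDepthProfile("female", 5e5, femaleYNoise = 0, seed = 94)
  expect_equal(cnt[["Y"]], 0L)
  cntM <- simulateDepthProfile("male", 5e5, seed = 95)
  rM <- yxRatio(depthProfile(cntM, 5e5, lens))
  expect_gt(rM, 0.43)           # male ratio ~ 1, far above the threshold
  expect_lt(abs(rM - 1), 0.15)
  # autosomal counts proportional to length (goodness of fit)
  aut <- as.character(1:22)
  pexp <- lens[aut] / sum(lens[aut])
  chi <- chisq.test(cntM[aut], p = pexp)
  expect_gt(chi$p.value, 1e-4)
})

test_that("generated data satisfy the container invariants", {
  panel <- simulatePanel(500, pops = c("A", "B"), F = 0.05, seed = 96)
  expect_true(validObject(panel))
  gs <- simulateGenotypes(panel, "B", 5, seed = 97)
  expect_true(validObject(gs))
  obs <- simulateObservations(dosages(gs)[, 1], panel, 2, seed = 98)
  expect_true(validObject(obs))
  expect_true(all(refCounts(obs) <= totalCounts(obs)))
})
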