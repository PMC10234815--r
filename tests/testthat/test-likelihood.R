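test_that("genotype likelihood matches its closed forms", {
  # heterozygote collapses to (1/2)^n independent of epsilon
  expect_equal(genotypeLikelihood(1, 3, 2), 1 / 8)
  expect_equal(genotypeLikelihood(1, 3, 2, epsilon = 0.01), 1 / 8)
  expect_equal(genotypeLikelihood(0, 1, 1), 1 - 1e-6)
  expect_equal(genotypeLikelihood(2, 2, 2), 1e-12)
  # vectorized call agrees with scalar calls
  expect_equal(genotypeLikelihood(c(0, 1, 2), c(1, 3, 2), c(1, 2, 2)),
               c(1 - 1e-6, 1 / 8, 1e-12))
  expect_error(genotypeLikelihood(3, 1, 1), "g must be")
  expect_error(genotypeLikelihood(1, 2, 3), "0 <= k <= n")
})

test_that("likelihood sums to one over read outcomes and HWE over genotypes", {
  for (eps in c(1e-6, 1e-3, 0.01)) {
    for (n in 1:12) {
      for (g in 0:2) {
        tot <- sum(choose(n, 0:n) * genotypeLikelihood(g, n, 0:n, eps))
        expect_equal(tot, 1, tolerance = 1e-12)
      }
    }
  }
  p <- runif(50)
  expect_equal(unname(colSums(hweGenotypeFreqs(p))), rep(1, 50))
  expect_equal(hweGenotypeFreqs(0)[, 1], c(g0 = 1, g1 = 0, g2 = 0))
  expect_equal(hweGenotypeFreqs(0.2)[, 1],
               c(g0 = 0.64, g1 = 0.32, g2 = 0.04))
})

test_that("likelihood score equals a per-site loop oracle and skips missing", {
  expect_equal(likelihoodScore(c(1, 1), c(0, 0), c(1, 1))$ls, 2 * log(0.5))
  r <- likelihoodScore(2, 2, 0)
  expect_equal(r$ls, 2 * log(1 - 1e-6))
  set.seed(42)
  for (rep in 1:5) {
    S <- 100
    n <- rpois(S, 2) + 1L
    k <- rbinom(S, n, runif(S))
    g <- sample(c(0:2, NA), S, replace = TRUE)
    eps <- sample(c(1e-6, 1e-3), 1)
    got <- likelihoodScore(n, k, g, eps)
    expect_equal(got$ls, oracleScore(g, n, k, eps))
    expect_equal(got$nSites, sum(!is.na(g)))
    expect_equal(got$nBases, sum(n[!is.na(g)]))
  }
  empty <- likelihoodScore(c(1, 1), c(1, 0), c(NA, NA))
  expect_true(is.na(empty$ls))
  expect_identical(empty$nSites, 0L)
})

test_that("null moments: degenerate, closed form, and Monte-Carlo oracle", {
  # p = 0 forces g = 0: zero variance, expectation is log L(0, n, k)
  m0 <- nullMoments(3, 2, 0)
  expect_equal(m0$v, 0)
  expect_equal(m0$e, genotypeLikelihood(0, 3, 2, log = TRUE))
  # closed form at p = 0.5, n = k = 1
  eps <- 1e-6
  m <- nullMoments(1, 1, 0.5, eps)
  expect_equal(m$e, 0.25 * log(1 - eps) + 0.5 * log(0.5) + 0.25 * log(eps))
  # Monte-Carlo oracle on a moderate instance
  set.seed(7)
  S <- 50
  n <- rpois(S, 1.5) + 1L
  p <- runif(S, 0.05, 0.95)
  k <- rbinom(S, n, 1 - p)
  mom <- nullMoments(n, k, p, eps)
  B <- 20000
  g <- matrix(rbinom(S * B, 2, p), nrow = S)
  ls <- colSums(matrix(genotypeLikelihood(as.vector(g), n, k, eps,
                                          log = TRUE), nrow = S))
  se <- sd(ls) / sqrt(B)
  expect_lt(abs(mean(ls) - mom$e), 4 * se)
  expect_lt(abs(var(ls) - mom$v) / mom$v, 0.1)
})

test_that("standardization and the one-sided normal test behave", {
  expect_equal(standardizeScore(-5, -5, 2), list(z = 0, p = 0.5))
  st <- standardizeScore(-2, -5, 1)
  expect_equal(st$z, 3)
  expect_equal(st$p, pnorm(3, lower.tail = FALSE))
  expect_equal(st$p, 1.3499e-3, tolerance = 1e-4)
  deg <- standardizeScore(-2, -5, 0)
  expect_true(is.na(deg$z) && is.na(deg$p))
})

test_that("empirical P value hits its formula floor and ceiling", {
  n <- c(2, 3); k <- c(2, 3); p <- c(0.5, 0.5)
  # a score above anything attainable -> floor 1/(nDraws+1)
  expect_equal(empiricalPvalue(1, n, k, p, nDraws = 999, seed = 1),
               1 / 1000)
  # a score below anything attainable -> 1
  expect_equal(empiricalPvalue(-1e9, n, k, p, nDraws = 999, seed = 1), 1)
  # identical seed reproduces identical value
  set.seed(3)
  S <- 30
  nn <- rpois(S, 1) + 1L
  pp <- runif(S, 0.1, 0.9)
  kk <- rbinom(S, nn, 1 - pp)
  ls <- nullMoments(nn, kk, pp)$e
  e1 <- empiricalPvalue(ls, nn, kk, pp, nDraws = 2000, seed = 99)
  e2 <- empiricalPvalue(ls, nn, kk, pp, nDraws = 2000, seed = 99)
  expect_identical(e1, e2)
  expect_gt(e1, 0.1)
  expect_lt(e1, 0.9)
})

test_that("scores are invariant to ref/alt relabelling", {
  set.seed(11)
  S <- 40
  n <- rpois(S, 2) + 1L
  k <- rbinom(S, n, 0.5)
  g <- sample(0:2, S, replace = TRUE)
  p <- runif(S)
  eps <- 1e-3
  a <- likelihoodScore(n, k, g, eps)$ls
  b <- likelihoodScore(n, n - k, 2 - g, eps)$ls
  expect_equal(a, b)
  ma <- nullMoments(n, k, p, eps)
  mb <- nullMoments(n, n - k, 1 - p, eps)
  expect_equal(ma$e, mb$e)
  expect_equal(ma$v, mb$v)
})
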