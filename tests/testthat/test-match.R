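test_that("Bonferroni thresholds reproduce the standard corrections", {
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(343 * 343, 117649)
  expect_equal(bonferroniThreshold(0.05, 343 * 343), 4.25e-7,
               tolerance = 0.005)
  expect_equal(bonferroniThreshold(0.05, 343 * 1e8), 1.5e-12,
               tolerance = 0.05)
  expect_error(bonferroniThreshold(1.5, 10))
})

test_that("the true individual is top-scored and significant when bases suffice", {
  panel <- simulatePanel(20000, seed = 51)
  gs <- simulateGenotypes(panel, nIndividuals = 10, seed = 52)
  truth <- dosages(gs)[, "ind4"]
  obs <- simulateObservations(truth, panel, lambda = 0.06, seed = 53)
  expect_gt(nBases(obs), 1000)
  res <- runMatch(list(q = obs), gs, panel)
  t4 <- res[res$candidate == "ind4", ]
  expect_true(t4$top_score)
  expect_true(t4$significant)
  # n_bases reported per pair covers the candidate's non-missing set
  expect_equal(t4$n_bases, nBases(obs))
  # exactly one top-score candidate
  expect_equal(sum(res$top_score), 1L)
})

test_that("queries with no usable observations give NA rows", {
  panel <- tinyPanel(c(0.2, 0.5, 0.8))
  gs <- GenotypeSet(siteKeys(panel),
                    matrix(c(0L, 1L, 2L), ncol = 1,
                           dimnames = list(NULL, "indA")))
  emptyObs <- ObservationSet(character(), integer(), character(),
                             character(), integer(), integer())
  res <- runMatch(list(q = emptyObs), gs, panel)
  expect_true(all(is.na(res$z)))
  expect_false(any(res$significant))
  expect_false(any(res$top_score))
})

test_that("a degenerate null (all p = 0) yields NA, never a match", {
  panel <- tinyPanel(c(0, 0, 0))
  gs <- GenotypeSet(siteKeys(panel),
                    matrix(0L, nrow = 3, ncol = 1,
                           dimnames = list(NULL, "indA")))
  obs <- ObservationSet("1", c(100L, 200L, 300L), rep("A", 3), rep("G", 3),
                        n = c(2L, 1L, 1L), k = c(2L, 1L, 1L))
  res <- runMatch(list(q = obs), gs, panel)
  expect_equal(res$v_null, 0)
  expect_true(is.na(res$p_normal))
  expect_false(res$significant)
})

test_that("the MAF-range filter restricts the scored sites", {
  panel <- tinyPanel(c(0.02, 0.3, 0.45))
  gs <- GenotypeSet(siteKeys(panel),
                    matrix(c(1L, 1L, 1L), ncol = 1,
                           dimnames = list(NULL, "indA")))
  obs <- ObservationSet("1", c(100L, 200L, 300L), rep("A", 3), rep("G", 3),
                        n = rep(1L, 3), k = rep(1L, 3))
  res <- runMatch(list(q = obs), gs, panel, mafRange = c(0.05, 0.4))
  expect_equal(res$n_sites, 1L)   # only the MAF 0.3 site
})

test_that("decision evaluation matches a hand-tabulated confusion matrix", {
  m <- data.frame(
    query = rep(c("q1", "q2", "q3"), each = 2),
    candidate = rep(c("c1", "c2"), 3),
    significant = c(TRUE, FALSE,  FALSE, FALSE,  TRUE, TRUE),
    top_score = c(TRUE, FALSE,  FALSE, TRUE,  FALSE, TRUE))
  truth <- c(q1 = "c1", q2 = "c2", q3 = NA)
  ev <- evaluateDecisions(m, truth)
  # true pairs: (q1,c1) sig, (q2,c2) not -> sensitivity 1/2
  expect_equal(ev$sensitivity, 0.5)
  # non-pairs: (q1,c2) ok, (q2,c1) ok, (q3,c1) called, (q3,c2) called
  expect_equal(ev$specificity, 2 / 4)
  # top accuracy over q1, q2: q1 hit, q2 hit -> 1
  expect_equal(ev$topAccuracy, 1)
  # all calls correct / no calls edge cases
  m2 <- m; m2$significant <- c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  ev2 <- evaluateDecisions(m2, truth)
  expect_equal(ev2$sensitivity, 1)
  expect_equal(ev2$specificity, 1)
  m3 <- m; m3$significant <- FALSE
  ev3 <- evaluateDecisions(m3, truth)
  expect_equal(ev3$sensitivity, 0)
  expect_equal(ev3$specificity, 1)
})

test_that("clumping inside runMatch prunes correlated covered sites", {
  set.seed(55)
  S <- 30
  base <- matrix(rbinom(S * 200, 2, 0.5), nrow = S)
  D <- rbind(base, base[S, , drop = FALSE])  # last site duplicates prior
  keys <- sprintf("1:%d:A:G", seq(100, by = 100, length.out = S + 1))
  panel <- SitePanel(rep("1", S + 1), seq(100, by = 100, length.out = S + 1),
                     rep("A", S + 1), rep("G", S + 1),
                     matrix(rep(0.5, S + 1), ncol = 1,
                            dimnames = list(NULL, "POP")))
  ld <- GenotypeSet(keys, D)
  cand <- GenotypeSet(keys, matrix(1L, nrow = S + 1, ncol = 1,
                                   dimnames = list(NULL, "indA")))
  obs <- ObservationSet(rep("1", S + 1),
                        seq(100, by = 100, length.out = S + 1),
                        rep("A", S + 1), rep("G", S + 1),
                        n = rep(1L, S + 1), k = rep(1L, S + 1))
  res <- runMatch(list(q = obs), cand, panel, ldRef = ld,
                  clump = clumpConfig(10, 5, 0.4))
  expect_equal(res$n_sites, S)   # the duplicated site was pruned
})
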