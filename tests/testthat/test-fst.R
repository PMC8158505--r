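# Weir-Cockerham estimator, multi-locus combination, resampling null and
# the complete-differentiation scan.

test_that("fixed differences give theta = 1 and identical groups give a <= 0", {
  calls <- matrix(c(2, 2, 2, 2, 2, 0, 0, 0, 0, 0), nrow = 1)
  groups <- rep(c("r", "s"), each = 5)
  comp <- fstComponents(calls, groups)
  expect_equal(comp$theta, 1)
  expect_equal(comp$b, 0)
  expect_equal(comp$c, 0)

  # same genotype counts in both groups: no among-group variance
  same <- matrix(c(0, 1, 1, 2, 2, 0, 1, 1, 2, 2), nrow = 1)
  compSame <- fstComponents(same, groups)
  expect_lte(compSame$a, 0)
  expect_lte(compSame$theta, 0)
})

test_that("components match the from-the-formulas oracle on random loci", {
  set.seed(101)
  for (i in 1:1000) {
    loc <- randomLocus(sample(5:30, 1), sample(5:30, 1))
    comp <- fstComponents(matrix(loc$calls, nrow = 1), loc$groups)
    if (!comp$informative) next
    o <- wcOracle(loc$calls, loc$groups)
    expect_equal(comp$a, o$a, tolerance = 1e-12)
    expect_equal(comp$b, o$b, tolerance = 1e-12)
    expect_equal(comp$c, o$c, tolerance = 1e-12)
    if (!is.na(comp$theta)) expect_equal(comp$theta, o$theta,
                                         tolerance = 1e-12)
  }
})

test_that("multi-locus theta is the ratio of sums and handles edge cases", {
  set.seed(202)
  n <- 20
  groups <- rep(c("a", "b"), each = n / 2)
  calls <- matrix(rbinom(100 * n, 2, runif(100, 0.1, 0.9)), nrow = 100)
  comp <- fstComponents(calls, groups)
  expect_equal(fstMultilocus(comp), wcOracleMulti(calls, groups),
               tolerance = 1e-12)

  one <- fstComponents(calls[1, , drop = FALSE], groups)
  expect_equal(fstMultilocus(one), one$theta, tolerance = 1e-12)

  fixedAll <- matrix(rep(c(rep(2, n / 2), rep(0, n / 2)), 3),
                     nrow = 3, byrow = TRUE)
  expect_equal(fstMultilocus(fstComponents(fixedAll, groups)), 1)

  mono <- matrix(0L, 2, n)
  expect_warning(out <- fstMultilocus(fstComponents(mono, groups)),
                 "undefined")
  expect_true(is.na(out))

  # a group with < 2 callable genotypes makes the locus uninformative
  sparse <- matrix(c(2, rep(NA, n / 2 - 1), rep(0, n / 2)), nrow = 1)
  expect_false(fstComponents(sparse, groups)$informative)
})

test_that("label permutation centres multi-locus theta at zero", {
  set.seed(303)
  n <- 50; nLoci <- 500
  freqs <- runif(nLoci, 0.1, 0.9)
  calls <- matrix(rbinom(nLoci * n, 2, rep(freqs, n)), nrow = nLoci)
  groups <- rep(c("a", "b"), each = n / 2)
  thetas <- replicate(200, {
    fstMultilocus(fstComponents(calls, sample(groups)))
  })
  expect_lt(abs(mean(thetas)), 0.02)
})

test_that("the estimator recovers the Balding-Nichols F parameter", {
  pops <- data.frame(name = c("g1", "g2"), cohort = c("native", "invasive"),
                     n = c(50, 50))
  spec <- simSpec(seed = 404, populations = pops, nBackgroundLoci = 5000,
                  F = 0.2, genomeExtent = c(chr1 = 1e6))
  sim <- simulateGenotypes(spec)
  groups <- sim$popmap$population
  est <- fstMultilocus(fstComponents(sim$genotypes, groups))
  expect_lt(abs(est - 0.2), 0.02)
})

test_that("empirical p arithmetic follows the exceedance definition", {
  # 7,700 of 100,000 valid replicates at or above the observed value
  nd <- new("NullDistribution", observedTheta = 0.2922,
            replicateThetas = c(rep(0.5, 7700), rep(0.1, 92300)),
            nRequested = 100000L, nValid = 100000L, nRedrawn = 0L,
            locusLength = 6053L, seed = 1L, targetInterval = "chr1:1-6053")
  expect_identical(empiricalP(nd, "plain"), 0.077)

  # observed exceeds every replicate
  nd2 <- new("NullDistribution", observedTheta = 0.9,
             replicateThetas = runif(1000, 0, 0.5),
             nRequested = 1000L, nValid = 1000L, nRedrawn = 0L,
             locusLength = 100L, seed = 1L, targetInterval = "chr1:1-100")
  expect_equal(empiricalP(nd2, "plain"), 0)
  expect_equal(empiricalP(nd2, "conservative"), 1 / 1001)
})

test_that("the resampling null is deterministic and monotone in the observed value", {
  pops <- data.frame(name = c("r", "s"), cohort = c("native", "native"),
                     n = c(15, 15))
  spec <- simSpec(seed = 505, populations = pops, nBackgroundLoci = 800,
                  F = 0.05, genomeExtent = c(chr1 = 2e5, chr2 = 1e5))
  sim <- simulateGenotypes(spec)
  groups <- sim$popmap$population
  nd1 <- resamplingNull(sim$genotypes, groups, "chr1:50001-60000",
                        c(chr1 = 2e5, chr2 = 1e5), nReps = 300, seed = 9)
  nd2 <- resamplingNull(sim$genotypes, groups, "chr1:50001-60000",
                        c(chr1 = 2e5, chr2 = 1e5), nReps = 300, seed = 9)
  expect_identical(replicateThetas(nd1), replicateThetas(nd2))
  expect_identical(observedTheta(nd1), observedTheta(nd2))
  expect_equal(nd1@nValid, 300L)

  # p_plain is non-increasing in the observed theta, all else fixed
  ps <- vapply(c(-0.05, 0, 0.05, 0.2, 0.9), function(obs) {
    nd <- nd1; nd@observedTheta <- obs
    empiricalP(nd, "plain")
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("the complete-differentiation scan finds planted sites with context", {
  set.seed(606)
  tg <- makeTinyGene(nCodons = 40, nExons = 2, intronLen = 100,
                     chromLen = 2000)
  ex <- tg$gene@cdsExons
  exonPos <- IRanges::start(ex)[1] + 5L
  intronPos <- IRanges::end(ex)[1] + 50L
  interPos <- 10L
  n <- 20
  groups <- rep(c("r", "s"), each = n / 2)
  fixedDiff <- c(rep(2L, n / 2), rep(0L, n / 2))
  shared <- rbinom(n, 2, 0.5)
  calls <- rbind(fixedDiff, fixedDiff, fixedDiff, shared)
  gm <- GenotypeMatrix(rep("chrT", 4), c(interPos, exonPos, intronPos, 500L),
                       c("A", "C", "G", "T"), c("G", "T", "A", "C"),
                       calls, samples = paste0("s", 1:n))
  scan <- completeDifferentiationScan(gm, groups,
                                      geneModels = list(tiny = tg$gene))
  expect_equal(nrow(scan), 3L)
  expect_equal(scan$context[scan$pos == exonPos], "exonic")
  expect_equal(scan$context[scan$pos == intronPos], "intronic")
  expect_equal(scan$context[scan$pos == interPos], "intergenic")

  # identical groups everywhere -> empty scan
  same <- matrix(rep(rbinom(4, 2, 0.5), n), nrow = 4)
  gmSame <- GenotypeMatrix(rep("chrT", 4), c(10L, 20L, 30L, 40L),
                           rep("A", 4), rep("G", 4), same,
                           samples = paste0("s", 1:n))
  expect_equal(nrow(completeDifferentiationScan(gmSame, groups)), 0L)
})
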