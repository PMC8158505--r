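# Catalog screening, cohort contrasts and codon spectra.

table1Screen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- table1Fixture()
      cache <<- list(fx = fx,
                     res = screen(fx$genotypes, fx$catalog, fx$geneModels,
                                  fx$popmap, fx$genome))
    }
    cache
  }
})

test_that("the worked-example fixture reproduces the published carrier table", {
  s <- table1Screen()
  z <- zygosity(s$res)
  carrierSet <- function(m) colnames(z)[!is.na(z[m, ]) & z[m, ] >= 1]

  ins2 <- carrierSet("abcc2_2bp_gc_ins")
  expect_setequal(ins2, c("PR1", "PR5", "PR12", "PR14", "PR16", "PR18",
                          "PR19", "PR27", "PR30", "PR31", "PR33"))
  het <- colnames(z)[!is.na(z["abcc2_2bp_gc_ins", ]) &
                     z["abcc2_2bp_gc_ins", ] == 1]
  expect_setequal(het, c("PR1", "PR18", "PR19", "PR27", "PR31", "PR33"))

  gy <- carrierSet("abcc2_gy_del")
  expect_setequal(gy, c("CC44", "CC69"))
  expect_true(all(z["abcc2_gy_del", gy] == 2L))     # homozygous
  expect_setequal(carrierSet("abcc2_p799kr"), c("CC44", "CC69"))

  ins12 <- carrierSet("abcc2_12bp_ins")
  expect_setequal(ins12, c("rCC25", "rCC5"))
  expect_true(all(z["abcc2_12bp_ins", ins12] == 1L)) # heterozygous

  # the unobserved mutations screen clean
  expect_equal(sum(z["abcc2_g1088d", ], na.rm = TRUE), 0L)
  expect_equal(sum(z["vgsc_l1014f", ], na.rm = TRUE), 0L)

  # all 11 2bp-insertion carriers are from Puerto Rico
  bp <- byPopulation(s$res)
  pr <- bp[bp$mutation_id == "abcc2_2bp_gc_ins" & bp$population == "PuertoRico", ]
  expect_equal(pr$carrier_count, 11L)
  expect_equal(sum(bp$carrier_count[bp$mutation_id == "abcc2_2bp_gc_ins"]), 11L)
})

test_that("zygosity classes partition the samples for every mutation", {
  s <- table1Screen()
  z <- zygosity(s$res)
  for (m in rownames(z)) {
    expect_equal(sum(z[m, ] == 0, na.rm = TRUE) +
                 sum(z[m, ] == 1, na.rm = TRUE) +
                 sum(z[m, ] == 2, na.rm = TRUE) + sum(is.na(z[m, ])),
                 ncol(z))
  }
  # cohort counts are sums of member-population counts
  bp <- byPopulation(s$res); bc <- byCohort(s$res)
  pm <- s$fx$popmap
  for (m in unique(bc$mutation_id)) for (co in c("native", "invasive")) {
    pops <- unique(pm$population[pm$cohort == co])
    expect_equal(bc$carrier_count[bc$mutation_id == m & bc$cohort == co],
                 sum(bp$carrier_count[bp$mutation_id == m &
                                      bp$population %in% pops]))
  }
})

test_that("screening is permutation-equivariant in sample order", {
  s <- table1Screen()
  fx <- s$fx
  set.seed(5)
  perm <- sample(ncol(fx$genotypes))
  st <- siteTable(fx$genotypes)
  shuffled <- GenotypeMatrix(st$chrom, st$pos, st$ref, st$alt,
                             genotypeCalls(fx$genotypes)[, perm],
                             samples = colnames(fx$genotypes)[perm])
  res2 <- screen(shuffled, fx$catalog, fx$geneModels, fx$popmap, fx$genome)
  b1 <- byPopulation(s$res); b2 <- byPopulation(res2)
  b1 <- b1[order(b1$population, b1$mutation_id), ]
  b2 <- b2[order(b2$population, b2$mutation_id), ]
  rownames(b1) <- rownames(b2) <- NULL
  expect_equal(b1, b2)
})

test_that("an empty catalog yields an empty result", {
  fx <- table1Screen()$fx
  res <- screen(fx$genotypes, emptyCatalog(), fx$geneModels, fx$popmap,
                fx$genome)
  expect_equal(nrow(zygosity(res)), 0L)
  expect_equal(nrow(byPopulation(res)), 0L)
})

test_that("planted carriers are recovered exactly (sensitivity = specificity = 1)", {
  pops <- data.frame(name = c("inv1", "inv2", "nat1"),
                     cohort = c("invasive", "invasive", "native"),
                     n = c(20, 20, 20))
  catalog <- data.frame(
    mutation_id = c("m1", "m2"), gene_id = "G",
    chrom = "chr1", pos = c(1000L, 2000L), ref = c("A", "C"),
    alt = c("G", "T"), protein_kind = "substitution", aa_ref = NA,
    codon_index = NA_integer_, aa_alt = NA, deleted_aa = NA,
    insecticide_class = "Bt", origin_population = NA,
    stringsAsFactors = FALSE)
  for (seed in c(2, 17, 23)) {
    freqs <- matrix(runif(6, 0.05, 0.6), 2, 3,
                    dimnames = list(NULL, pops$name))
    spec <- simSpec(seed = seed, populations = pops, catalog = catalog,
                    catalogFreqs = freqs, nBackgroundLoci = 30,
                    genomeExtent = c(chr1 = 1e5))
    sim <- simulateGenotypes(spec)
    res <- screen(sim$genotypes, catalog, popmap = sim$popmap)
    z <- zygosity(res)
    for (m in c("m1", "m2")) {
      found <- colnames(z)[!is.na(z[m, ]) & z[m, ] >= 1]
      expect_setequal(found, sim$truth$carriers[[m]])
    }
  }
})

test_that("cohort contrasts match the hypergeometric enumeration oracle", {
  tab <- matrix(c(61, 15, 55, 21), 2, byrow = TRUE)
  ft <- fisherExactTwoTailed(tab)
  expect_equal(ft$p, fisherEnumOracle(tab), tolerance = 1e-12)

  s <- table1Screen()
  cc <- cohortContrast(s$res, "abcc2_2bp_gc_ins")
  expect_equal(sum(cc$table), 177)
  expect_equal(unname(cc$table["native", "carrier"]), 11)
  expect_equal(cc$p, fisherEnumOracle(cc$table), tolerance = 1e-12)

  # identical proportions in both cohorts -> p = 1
  expect_equal(fisherExactTwoTailed(matrix(c(10, 30, 5, 15), 2,
                                           byrow = TRUE))$p, 1)
  # complete separation, n = 10 per cohort: the two extreme tables
  sep <- matrix(c(10, 0, 0, 10), 2, byrow = TRUE)
  expect_equal(fisherExactTwoTailed(sep)$p, 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_error(cohortContrast(s$res, "no_such"), "unknown mutation")
})

test_that("codon spectra count per-individual codons and flag ambiguity", {
  set.seed(77)
  tg <- makeTinyGene(nCodons = 40, fixedCodons = list(`10` = "GCG"))
  g <- tg$gene
  popmap <- data.frame(sample = paste0("s", 1:6),
                       population = rep(c("Benin", "Other"), each = 3),
                       cohort = rep(c("invasive", "native"), each = 3),
                       stringsAsFactors = FALSE)
  codonG <- cdsToGenomic(g, c(28L, 29L, 30L))   # codon 10

  # all hom ref -> single reference codon with count n
  gmRef <- GenotypeMatrix("chrT", codonG[3],
                          substr(tg$chrom, codonG[3], codonG[3]), "T",
                          matrix(0L, 1, 6), samples = popmap$sample)
  spRef <- codonSpectrum(gmRef, g, 10L, popmap, tg$genome)
  expect_equal(sort(unique(spRef$codon)), "GCG")
  expect_equal(sum(spRef$n_individuals), 6L)

  # three planted GCA carriers in Benin (G->A at third base)
  calls <- matrix(0L, 1, 6, dimnames = list(NULL, popmap$sample))
  calls[1, 1:2] <- 2L           # hom GCA
  calls[1, 3] <- 1L             # het carries both codons
  gmA <- GenotypeMatrix("chrT", codonG[3], "G", "A", calls,
                        samples = popmap$sample)
  sp <- codonSpectrum(gmA, g, 10L, popmap, tg$genome)
  benin <- sp[sp$population == "Benin", ]
  expect_equal(benin$n_individuals[benin$codon == "GCA"], 3L)
  expect_equal(benin$n_individuals[benin$codon == "GCG"], 1L)

  # het at two sites within the codon -> ambiguous bucket, never a guess
  calls2 <- matrix(c(1L, 1L), 2, 6, dimnames = NULL)
  colnames(calls2) <- popmap$sample
  gm2 <- GenotypeMatrix(c("chrT", "chrT"), codonG[c(1, 3)],
                        c(substr(tg$chrom, codonG[1], codonG[1]), "G"),
                        c("T", "A"), calls2, samples = popmap$sample)
  sp2 <- codonSpectrum(gm2, g, 10L, popmap, tg$genome)
  expect_true(all(sp2$codon == "ambiguous"))
  expect_equal(sum(sp2$n_individuals), 6L)
})
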