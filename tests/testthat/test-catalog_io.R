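# Readers/writers and the in-memory data model.

writeTempVcf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

vcfHeader <- function(samples)
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))

test_that("VCF GT fields map to genotype codes and sites are preserved", {
  p <- writeTempVcf(c(vcfHeader(c("s1", "s2", "s3")),
                      "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
                      "chr1\t200\t.\tT\tC\t.\tPASS\t.\tGT\t./.\t0|1\t1/1"))
  gm <- readGenotypes(p)
  expect_s4_class(gm, "GenotypeMatrix")
  expect_identical(unname(genotypeCalls(gm)[1, ]), c(0L, 1L, 2L))
  expect_identical(unname(genotypeCalls(gm)[2, ]), c(NA_integer_, 1L, 2L))
  expect_identical(siteTable(gm)$pos, c(100L, 200L))
  # no silent sample loss
  expect_identical(colnames(gm), c("s1", "s2", "s3"))
})

test_that("an insertion record keeps its +2 bp alt-ref length difference", {
  fx <- table1Fixture(dir = withr::local_tempdir())
  gm <- readGenotypes(fx$paths$vcf)
  st <- siteTable(gm)
  ins <- st[st$alt == paste0(st$ref, "GC"), ]
  expect_equal(nrow(ins), 1L)
  expect_equal(nchar(ins$alt) - nchar(ins$ref), 2L)
})

test_that("multi-allelic records split into biallelic sites at the same pos", {
  p <- writeTempVcf(c(vcfHeader(c("s1", "s2", "s3", "s4")),
                      "chr1\t500\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t1/2\t2/2\t0/0"))
  gm <- readGenotypes(p, multiallelic = "split")
  st <- siteTable(gm)
  expect_equal(nrow(st), 2L)
  expect_equal(st$pos, c(500L, 500L))
  expect_setequal(st$alt, c("G", "T"))
  # manual split: allele G counts (1,1,0,0), allele T counts (0,1,2,0)
  gRow <- which(st$alt == "G"); tRow <- which(st$alt == "T")
  expect_identical(unname(genotypeCalls(gm)[gRow, ]), c(1L, 1L, 0L, 0L))
  expect_identical(unname(genotypeCalls(gm)[tRow, ]), c(0L, 1L, 2L, 0L))
  expect_equal(S4Vectors::metadata(gm)$ingest$nSplitRecords, 1L)

  gmDrop <- readGenotypes(p, multiallelic = "drop")
  expect_equal(nrow(gmDrop), 0L)
  expect_equal(S4Vectors::metadata(gmDrop)$ingest$nDropped, 1L)
  expect_error(readGenotypes(p, multiallelic = "error"), "multi-allelic")
})

test_that("a VCF without GT is rejected as a format error", {
  p <- writeTempVcf(c(vcfHeader("s1"),
                      "chr1\t100\t.\tA\tG\t.\tPASS\t.\tDP\t13"))
  expect_error(readGenotypes(p), "GT")
})

test_that("VCF write/read round-trips the GenotypeMatrix", {
  set.seed(7)
  spec <- simSpec(seed = 7,
                  populations = data.frame(name = c("p1", "p2"),
                                           cohort = c("native", "invasive"),
                                           n = c(8, 8)),
                  nBackgroundLoci = 40, F = 0.1,
                  genomeExtent = c(chr1 = 1e5, chr2 = 5e4))
  sim <- simulateGenotypes(spec, dir = withr::local_tempdir())
  back <- readGenotypes(sim$paths$vcf)
  expect_identical(siteTable(back), siteTable(sim$genotypes))
  expect_identical(genotypeCalls(back), genotypeCalls(sim$genotypes))
})

test_that("catalog reading validates entries and counts the default 13", {
  td <- withr::local_tempdir()
  fx <- table1Fixture(dir = td)
  cat13 <- readCatalog(fx$paths$catalog, fx$geneModels)
  expect_equal(nrow(cat13), 13L)
  expect_equal(sum(cat13$gene_id == "ABCC2"), 5L)
  expect_equal(sum(cat13$gene_id == "AChE"), 3L)
  expect_equal(sum(cat13$gene_id == "VGSC"), 3L)
  expect_equal(sum(cat13$gene_id == "RyR"), 2L)

  empty <- file.path(td, "empty.json")
  writeLines("[]", empty)
  expect_warning(ec <- readCatalog(empty), "empty")
  expect_equal(nrow(ec), 0L)

  bad <- cat13
  bad$codon_index[6] <- 100000L
  badPath <- file.path(td, "bad.json")
  writeCatalog(bad, badPath)
  expect_error(readCatalog(badPath, fx$geneModels), "beyond protein length")

  # an in-frame-labelled indel whose length is not a multiple of 3
  bad2 <- cat13
  bad2$protein_kind[1] <- "in_frame_insertion"   # the 2 bp insertion
  bad2Path <- file.path(td, "bad2.json")
  writeCatalog(bad2, bad2Path)
  expect_error(readCatalog(bad2Path), "frameshift")

  # TSV round-trip
  tsv <- file.path(td, "catalog.tsv")
  writeCatalog(cat13, tsv)
  expect_equal(readCatalog(tsv, fx$geneModels)$mutation_id,
               cat13$mutation_id)
})

test_that("CNV copy numbers map by the diploid convention and round-trip", {
  td <- withr::local_tempdir()
  cn <- data.frame(sample = rep(c("a", "b"), each = 3),
                   gene = rep(c("g1", "g2", "g3"), 2),
                   copy_number = c(2, 2, 2, 4, 1, 0))
  cnvPath <- file.path(td, "cnv.tsv")
  write.table(cn, cnvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  clanPath <- file.path(td, "clans.tsv")
  write.table(data.frame(gene = c("g1", "g2"), clan = c("clan2", "clan3")),
              clanPath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(cnv <- readCnvTable(cnvPath, clanPath), "other")
  st <- cnvStates(cnv)
  expect_true(all(st[, "a"] == "neutral"))
  expect_identical(unname(st[c("g1", "g2", "g3"), "b"]),
                   c("duplicated", "deleted", "deleted"))
  expect_identical(unname(geneClans(cnv)["g3"]), "other")

  # round-trip through the writer
  spec <- simSpec(seed = 11,
                  populations = data.frame(name = c("x", "y"),
                                           cohort = c("native", "invasive"),
                                           n = c(5, 5)),
                  cnvGenes = data.frame(gene = paste0("cyp", 1:20),
                                        clan = rep(c("clan3", "clan4"), 10)),
                  cnvRates = data.frame(cohort = c("native", "invasive"),
                                        clan = "clan3",
                                        dup_rate = c(0.5, 2),
                                        del_rate = c(1, 0.2)))
  sim <- simulateCnv(spec, dir = td)
  back <- readCnvTable(sim$paths$cnv, sim$paths$clans)
  expect_identical(cnvStates(back)[rownames(cnvStates(sim$cnv)),
                                   colnames(cnvStates(sim$cnv))],
                   cnvStates(sim$cnv))
  expect_identical(geneClans(back)[names(geneClans(sim$cnv))],
                   geneClans(sim$cnv))
})

test_that("gene models round-trip through GFF3 and read from BED12", {
  td <- withr::local_tempdir()
  fx <- table1Fixture(dir = td)
  models <- readGeneModels(fx$paths$genes)
  expect_setequal(names(models), names(fx$geneModels))
  for (g in names(models)) {
    expect_identical(IRanges::start(models[[g]]@cdsExons),
                     IRanges::start(fx$geneModels[[g]]@cdsExons))
    expect_identical(models[[g]]@strand, fx$geneModels[[g]]@strand)
    expect_equal(proteinLength(models[[g]]), proteinLength(fx$geneModels[[g]]))
  }
  # BED12 (0-based half-open blocks) gives the same exon structure
  g <- fx$geneModels$ABCC2
  s <- IRanges::start(g@cdsExons); e <- IRanges::end(g@cdsExons)
  bed <- paste(g@chrom, min(s) - 1L, max(e), g@geneId, 0, g@strand,
               min(s) - 1L, max(e), "0", length(s),
               paste0(paste(e - s + 1L, collapse = ","), ","),
               paste0(paste(s - min(s), collapse = ","), ","), sep = "\t")
  bedPath <- file.path(td, "genes.bed")
  writeLines(bed, bedPath)
  fromBed <- readGeneModels(bedPath)
  expect_identical(IRanges::start(fromBed$ABCC2@cdsExons), s)
  expect_identical(IRanges::end(fromBed$ABCC2@cdsExons), e)
})

test_that("coordinate converters are inverses and validity is enforced", {
  conv <- zeroBasedToOneBased(99, 200)
  expect_equal(conv, list(start = 100L, end = 200L))
  expect_equal(oneBasedToZeroBased(conv$start, conv$end),
               list(start = 99L, end = 200L))

  expect_error(GeneModel("g", "c", "+", c(1, 10), c(12, 20)),
               "non-overlapping")
  expect_error(GeneModel("g", "c", "+", 1, 10), "divisible by 3")

  # genomic<->CDS maps invert on both strands, across exons
  set.seed(42)
  for (strand in c("+", "-")) {
    tg <- makeTinyGene(nCodons = 50, strand = strand, nExons = 3)
    L <- cdsLength(tg$gene)
    expect_identical(genomicToCds(tg$gene, cdsToGenomic(tg$gene, 1:L)), 1:L)
    # the planted CDS is recovered from the genome
    expect_identical(as.character(extractCds(tg$gene, tg$genome)), tg$cds)
  }
})

test_that("popmap reading validates cohorts and coverage mismatches are named", {
  td <- withr::local_tempdir()
  pm <- data.frame(sample = c("s1", "s2"), population = "p",
                   cohort = c("native", "invasive"))
  path <- file.path(td, "pm.tsv")
  writePopMap(pm, path)
  back <- readPopMap(path)
  expect_identical(back$sample, pm$sample)

  bad <- pm; bad$cohort[1] <- "exotic"
  writePopMap(bad, path)
  expect_error(readPopMap(path), "cohort")

  p <- writeTempVcf(c(vcfHeader(c("s1", "s2", "s3")),
                      "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1"))
  gm <- readGenotypes(p)
  expect_error(checkPopmapCoverage(gm, pm), "s3")
})

test_that("indel normalization trims and left-aligns caller variants", {
  # same deletion written two ways compares equal after normalization
  refseq <- "AAACCCTTTGGG"
  a <- normalizeVariant(3, "ACCCT", "AT", refseq)
  b <- normalizeVariant(3, "ACCC", "A", refseq)
  expect_equal(a[c("pos", "ref", "alt")], b[c("pos", "ref", "alt")])
  # left shift through a homopolymer: TTAAAAAG, one A deleted -> pos 3
  hp <- "TTAAAAAG"
  n <- normalizeVariant(6, "AA", "A", hp)
  expect_equal(n[c("pos", "ref", "alt")],
               list(pos = 3L, ref = "AA", alt = "A"))
  # SNVs untouched
  expect_equal(normalizeVariant(5, "A", "G", hp),
               list(pos = 5L, ref = "A", alt = "G"))
})
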