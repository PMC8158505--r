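# A fully synthetic but exactly specified worked example: a two-chromosome
# genome carrying synthetic gene models for the four insecticide-target
# genes (ABCC2, AChE, VGSC, RyR), the 13-entry resistance catalog with
# genomic specs derived from those models, and a VCF + population map that
# encode the published carrier table for the four observed ABCC2 mutations
# (2 bp GC insertion in Puerto Rico, GY deletion and P799K/R in the two
# susceptible Brazilian individuals, 12 bp insertion in the two resistant
# Brazilian individuals), padded with non-carrier individuals matching the
# study's cohort sizes (78 invasive, 99 native). The genome and gene
# coordinates are synthetic stand-ins — no real assembly coordinates are
# published for the catalog — so protein-level specs are the primary keys
# and the genomic specs are an overlay onto this synthetic assembly.

STOP_CODONS <- c("TAA", "TAG", "TGA")

randomNonStopCodons <- function(n) {
  all64 <- as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                 paste0), c("A","C","G","T"), paste0))
  sample(setdiff(all64, STOP_CODONS), n, replace = TRUE)
}

makeCdsSeq <- function(nCodons, fixed = list()) {
  codons <- randomNonStopCodons(nCodons - 1L)
  for (idx in names(fixed)) codons[as.integer(idx)] <- fixed[[idx]]
  paste0(paste(codons, collapse = ""), "TAA")
}

# overwrite the exon regions of a chromosome with a gene's CDS
plantCds <- function(chromSeq, gene, cdsSeq) {
  ex <- gene@cdsExons
  w <- IRanges::width(ex)
  for (i in seq_along(ex)) {
    cdsStart <- if (gene@strand == "+") {
      if (i > 1L) sum(w[seq_len(i - 1L)]) + 1L else 1L
    } else {
      if (i < length(w)) sum(w[seq(i + 1L, length(w))]) + 1L else 1L
    }
    seg <- substr(cdsSeq, cdsStart, cdsStart + w[i] - 1L)
    if (gene@strand == "-") seg <- revcompChar(seg)
    substr(chromSeq, IRanges::start(ex)[i], IRanges::end(ex)[i]) <- seg
  }
  chromSeq
}

# genomic SNV record for a CDS-level base change (handles strand)
cdsSnv <- function(gene, cdsPos, cdsRef, cdsAlt) {
  g <- cdsToGenomic(gene, cdsPos)
  if (gene@strand == "+") list(pos = g, ref = cdsRef, alt = cdsAlt)
  else list(pos = g, ref = revcompChar(cdsRef), alt = revcompChar(cdsAlt))
}

#' Build the packaged worked-example fixture
#'
#' Generates (deterministically; the caller's RNG state is untouched) a
#' synthetic genome, gene models, the 13-entry default resistance catalog
#' (5 ABCC2, 3 AChE, 3 VGSC, 2 RyR) and a 177-sample genotype set that
#' encodes the published ABCC2 carrier table exactly: the 2 bp GC
#' insertion heterozygous in PR1, PR18, PR19, PR27, PR31, PR33 and
#' homozygous in PR5, PR12, PR14, PR16, PR30; the GY deletion and the
#' P799R allele homozygous in CC44 and CC69; the 12 bp insertion
#' heterozygous in rCC25 and rCC5; every other individual carries no
#' catalog mutation.
#'
#' @param dir optional output directory; writes `genome.fa`, `genes.gff3`,
#'   `catalog.json`, `genotypes.vcf` and `popmap.tsv`.
#' @return list(genome, geneModels, catalog, genotypes, popmap, paths).
#' @export
table1Fixture <- function(dir = NULL) {
  # fixed data: use a private RNG stream and restore the caller's
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(20210468)

  genes <- list(
    ABCC2 = GeneModel("ABCC2", "chr1", "+",
                      c(10001L, 12201L, 15001L), c(11200L, 14000L, 16053L),
                      proteinId = "QGS83596"),
    AChE = GeneModel("AChE", "chr1", "+",
                     c(30001L, 32001L), c(31000L, 33103L),
                     proteinId = "XP_022819835"),
    VGSC = GeneModel("VGSC", "chr2", "-",
                     c(5001L, 8001L), c(6803L, 9500L),
                     proteinId = "KC435025"),
    RyR = GeneModel("RyR", "chr2", "+",
                    c(20001L, 27001L, 34001L), c(26000L, 33000L, 37303L),
                    proteinId = "MK226188"))

  cdsSeqs <- list(
    # ABCC2: 1351 codons; fix the codons the catalog touches
    ABCC2 = makeCdsSeq(1351L, fixed = list(
      `779` = "GCT", `780` = "GGA", `781` = "TAT", `782` = "CTT",
      `799` = "CCG", `1088` = "GGT")),
    AChE = makeCdsSeq(701L, fixed = list(
      `201` = "GCG", `209` = "TTC", `227` = "GGA")),
    VGSC = makeCdsSeq(1101L, fixed = list(
      `929` = "ACA", `932` = "CTT", `1014` = "CTT")),
    RyR = makeCdsSeq(5101L, fixed = list(
      `4734` = "ATT", `4946` = "GGA")))

  chr1 <- paste(sample(c("A", "C", "G", "T"), 50000L, replace = TRUE),
                collapse = "")
  chr2 <- paste(sample(c("A", "C", "G", "T"), 60000L, replace = TRUE),
                collapse = "")
  for (g in c("ABCC2", "AChE")) chr1 <- plantCds(chr1, genes[[g]], cdsSeqs[[g]])
  for (g in c("VGSC", "RyR")) chr2 <- plantCds(chr2, genes[[g]], cdsSeqs[[g]])
  genome <- Biostrings::DNAStringSet(c(chr1 = chr1, chr2 = chr2))

  baseAt <- function(chrom, p) substr(get(chrom), p, p)
  subAt <- function(chrom, from, to) substr(get(chrom), from, to)

  entry <- function(id, gene, kind, pos = NA, ref = NA, alt = NA,
                    aaRef = NA, codon = NA, aaAlt = NA, delAA = NA,
                    class, origin)
    data.frame(mutation_id = id, gene_id = gene@geneId,
               chrom = if (is.na(pos)) NA_character_ else gene@chrom,
               pos = as.integer(pos), ref = ref, alt = alt,
               protein_kind = kind, aa_ref = aaRef,
               codon_index = as.integer(codon), aa_alt = aaAlt,
               deleted_aa = delAA, insecticide_class = class,
               origin_population = origin, stringsAsFactors = FALSE)

  ab <- genes$ABCC2
  # 2 bp GC insertion after CDS position 2500 (codon 834)
  gIns2 <- cdsToGenomic(ab, 2500L)
  e1 <- entry("abcc2_2bp_gc_ins", ab, "frameshift", gIns2,
              baseAt("chr1", gIns2), paste0(baseAt("chr1", gIns2), "GC"),
              codon = 834L, class = "Bt", origin = "Puerto Rico")
  # GY deletion: codons 780-781, anchored at the last base of codon 779
  gDelA <- cdsToGenomic(ab, 2337L)
  e2 <- entry("abcc2_gy_del", ab, "in_frame_deletion", gDelA,
              subAt("chr1", gDelA, gDelA + 6L), baseAt("chr1", gDelA),
              codon = 780L, delAA = "GY", class = "Bt", origin = "Brazil")
  # P799K/R: the R allele is one SNV (CCG -> CGG); K matches via protein spec
  s799 <- cdsSnv(ab, 2396L, "C", "G")
  e3 <- entry("abcc2_p799kr", ab, "substitution", s799$pos, s799$ref,
              s799$alt, aaRef = "P", codon = 799L, aaAlt = "K/R",
              class = "Bt", origin = "Brazil")
  # 12 bp insertion at the codon 845/846 boundary; carries an in-frame stop
  gIns12 <- cdsToGenomic(ab, 2535L)
  e4 <- entry("abcc2_12bp_ins", ab, "in_frame_insertion", gIns12,
              baseAt("chr1", gIns12),
              paste0(baseAt("chr1", gIns12), "TAAGCAGCTGCA"),
              codon = 846L, class = "Bt", origin = "Brazil")
  s1088 <- cdsSnv(ab, 3263L, "G", "A")
  e5 <- entry("abcc2_g1088d", ab, "substitution", s1088$pos, s1088$ref,
              s1088$alt, aaRef = "G", codon = 1088L, aaAlt = "D",
              class = "Bt", origin = "Brazil")

  ac <- genes$AChE
  sF209V <- cdsSnv(ac, 625L, "T", "G")
  sA201S <- cdsSnv(ac, 601L, "G", "T")
  sG227A <- cdsSnv(ac, 680L, "G", "C")
  e6 <- entry("ache_f209v", ac, "substitution", sF209V$pos, sF209V$ref,
              sF209V$alt, "F", 209L, "V",
              class = "organophosphate/carbamate", origin = "various")
  e7 <- entry("ache_a201s", ac, "substitution", sA201S$pos, sA201S$ref,
              sA201S$alt, "A", 201L, "S",
              class = "organophosphate/carbamate", origin = "various")
  e8 <- entry("ache_g227a", ac, "substitution", sG227A$pos, sG227A$ref,
              sG227A$alt, "G", 227L, "A",
              class = "organophosphate/carbamate", origin = "various")

  vg <- genes$VGSC
  sT929I <- cdsSnv(vg, 2786L, "C", "T")
  sL932F <- cdsSnv(vg, 2794L, "C", "T")
  sL1014F <- cdsSnv(vg, 3040L, "C", "T")
  e9 <- entry("vgsc_t929i", vg, "substitution", sT929I$pos, sT929I$ref,
              sT929I$alt, "T", 929L, "I", class = "pyrethroid",
              origin = "various")
  e10 <- entry("vgsc_l932f", vg, "substitution", sL932F$pos, sL932F$ref,
               sL932F$alt, "L", 932L, "F", class = "pyrethroid",
               origin = "various")
  e11 <- entry("vgsc_l1014f", vg, "substitution", sL1014F$pos, sL1014F$ref,
               sL1014F$alt, "L", 1014L, "F", class = "pyrethroid",
               origin = "various")

  ry <- genes$RyR
  sI4734M <- cdsSnv(ry, 14202L, "T", "G")
  sG4946E <- cdsSnv(ry, 14837L, "G", "A")
  e12 <- entry("ryr_i4734m", ry, "substitution", sI4734M$pos, sI4734M$ref,
               sI4734M$alt, "I", 4734L, "M", class = "diamide",
               origin = "Brazil")
  e13 <- entry("ryr_g4946e", ry, "substitution", sG4946E$pos, sG4946E$ref,
               sG4946E$alt, "G", 4946L, "E", class = "diamide",
               origin = "Brazil")

  catalog <- rbind(e1, e2, e3, e4, e5, e6, e7, e8, e9, e10, e11, e12, e13)
  validateCatalog(catalog, genes)

  popmap <- table1Popmap()
  samples <- popmap$sample
  z <- function(het, hom) {
    v <- setNames(rep(0L, length(samples)), samples)
    v[het] <- 1L; v[hom] <- 2L
    v
  }
  carriers <- list(
    abcc2_2bp_gc_ins = z(c("PR1", "PR18", "PR19", "PR27", "PR31", "PR33"),
                         c("PR5", "PR12", "PR14", "PR16", "PR30")),
    abcc2_gy_del = z(character(0), c("CC44", "CC69")),
    abcc2_p799kr = z(character(0), c("CC44", "CC69")),
    abcc2_12bp_ins = z(c("rCC25", "rCC5"), character(0)))

  observed <- catalog[match(names(carriers), catalog$mutation_id), ]
  # emit the VCF records in normalized (left-aligned) form
  for (i in seq_len(nrow(observed))) {
    nv <- normalizeVariant(observed$pos[i], observed$ref[i], observed$alt[i],
                           genome[[observed$chrom[i]]])
    observed$pos[i] <- nv$pos; observed$ref[i] <- nv$ref
    observed$alt[i] <- nv$alt
  }
  calls <- do.call(rbind, carriers)
  gm <- GenotypeMatrix(observed$chrom, observed$pos, observed$ref,
                       observed$alt, calls, samples = samples)

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  genes = file.path(dir, "genes.gff3"),
                  catalog = file.path(dir, "catalog.json"),
                  vcf = file.path(dir, "genotypes.vcf"),
                  popmap = file.path(dir, "popmap.tsv"))
    Biostrings::writeXStringSet(genome, paths$genome)
    writeGeneModels(genes, paths$genes)
    writeCatalog(catalog, paths$catalog)
    writeGenotypesVcf(gm, paths$vcf)
    writePopMap(popmap, paths$popmap)
  }
  list(genome = genome, geneModels = genes, catalog = catalog,
       genotypes = gm, popmap = popmap, paths = paths)
}

# 177 individuals: 99 native (70 sfC + 29 sfR), 78 invasive (29 sfC + 49 sfR)
table1Popmap <- function() {
  mk <- function(prefix, n, pop, cohort)
    data.frame(sample = paste0(prefix, seq_len(n)), population = pop,
               cohort = cohort, stringsAsFactors = FALSE)
  native <- rbind(
    mk("PR", 33, "PuertoRico", "native"),
    data.frame(sample = c("CC12", "CC23", "CC31", "CC44", "CC57", "CC69",
                          "rCC5", "rCC12", "rCC25", "rCC30"),
               population = "Brazil", cohort = "native",
               stringsAsFactors = FALSE),
    mk("MS", 14, "Mississippi", "native"),
    mk("FL", 14, "Florida", "native"),
    mk("FG", 9, "FrenchGuinea", "native"),
    mk("GP", 9, "Guadeloupe", "native"),
    mk("MX", 10, "Mexico", "native"))
  invasive <- rbind(
    mk("BN", 16, "Benin", "invasive"),
    mk("MW", 16, "Malawi", "invasive"),
    mk("UG", 16, "Uganda", "invasive"),
    mk("CN", 15, "China", "invasive"),
    mk("IN", 15, "India", "invasive"))
  native$strain <- rep(c("sfC", "sfR"), c(70, 29))
  invasive$strain <- rep(c("sfC", "sfR"), c(29, 49))
  rbind(native, invasive)
}
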