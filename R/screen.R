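# Catalog screening: assign each sample a zygosity for each cataloged
# resistance mutation and summarise carrier proportions per population and
# cohort. A carrier bears at least one resistance allele (het or hom).
# Samples with a missing genotype at a mutation's site(s) are excluded from
# that mutation's denominator; denominators are always reported alongside
# proportions.

#' Screen genotypes against a resistance-mutation catalog
#'
#' Each catalog entry is matched primarily by its normalized genomic spec
#' (chrom, pos, ref, alt; both the catalog entry and the VCF sites are
#' left-aligned/trimmed, so caller representation differences do not
#' matter). Entries without a genomic spec are matched at the protein level:
#' every VCF site inside the gene is consequence-annotated and any site
#' whose consequence equals the protein spec matches (a multi-alternate
#' entry such as P799K/R matches either residue). A cataloged site with no
#' VCF record is reported absent in all samples, since a resequencing VCF
#' carries only variant sites.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param catalog validated catalog data.frame (see [readCatalog()]).
#' @param geneModels named list of [GeneModel-class] (required for
#'   protein-level matching; entries whose gene is absent are skipped with a
#'   warning).
#' @param popmap population map data.frame (see [readPopMap()]).
#' @param genome optional [Biostrings::DNAStringSet]; required for
#'   protein-level matching and used to left-align catalog indels.
#' @return A [ScreeningResult-class].
#' @export
screen <- function(genotypes, catalog, geneModels = list(), popmap,
                   genome = NULL) {
  checkPopmapCoverage(genotypes, popmap)
  st <- siteTable(genotypes)
  calls <- genotypeCalls(genotypes)
  samples <- colnames(calls)
  pm <- popmap[match(samples, popmap$sample), ]

  nMut <- nrow(catalog)
  z <- matrix(NA_integer_, nrow = nMut, ncol = length(samples),
              dimnames = list(catalog$mutation_id, samples))
  if (nMut > 0L) for (i in seq_len(nMut)) {
    entry <- catalog[i, ]
    if (!is.na(entry$pos) && !is.na(entry$ref) && !is.na(entry$alt)) {
      refseq <- if (!is.null(genome) && entry$chrom %in% names(genome))
        genome[[entry$chrom]] else NULL
      nv <- normalizeVariant(entry$pos, entry$ref, entry$alt, refseq)
      hit <- which(st$chrom == entry$chrom & st$pos == nv$pos &
                   st$ref == nv$ref & st$alt == nv$alt)
      z[i, ] <- if (length(hit)) combineSiteZygosity(calls[hit, , drop = FALSE])
                else 0L   # no record at a variant-only VCF site => no carrier
    } else {
      gm <- geneModels[[entry$gene_id]]
      if (is.null(gm) || is.null(genome)) {
        warning("catalog entry '", entry$mutation_id,
                "': gene model or genome unavailable; skipped")
        next
      }
      span <- range(c(IRanges::start(gm@cdsExons), IRanges::end(gm@cdsExons)))
      inGene <- which(st$chrom == gm@chrom & st$pos >= span[1] &
                      st$pos <= span[2])
      matching <- integer(0)
      for (k in inGene) {
        cons <- tryCatch(
          annotateConsequence(st$chrom[k], st$pos[k], st$ref[k], st$alt[k],
                              gm, genome),
          error = function(e) NULL)
        if (!is.null(cons) && consequenceMatchesSpec(cons, entry))
          matching <- c(matching, k)
      }
      z[i, ] <- if (length(matching))
        combineSiteZygosity(calls[matching, , drop = FALSE]) else 0L
    }
  }

  popSummary <- summariseCarriers(z, pm$population, "population")
  cohSummary <- summariseCarriers(z, pm$cohort, "cohort")
  new("ScreeningResult", zygosityMatrix = z, catalog = catalog,
      popmap = popmap, populationSummary = popSummary,
      cohortSummary = cohSummary)
}

# several sites can realise one mutation; a sample's zygosity is the
# maximum over sites with a call, NA only when every site is missing
combineSiteZygosity <- function(m) {
  apply(m, 2L, function(col) {
    if (all(is.na(col))) NA_integer_ else max(col, na.rm = TRUE)
  })
}

# does a Consequence satisfy a catalog protein spec?
consequenceMatchesSpec <- function(cons, entry) {
  kind <- entry$protein_kind
  if (kind == "substitution") {
    if (!cons@kind %in% c("missense", "stop_gained")) return(FALSE)
    alts <- strsplit(entry$aa_alt, "[/,]")[[1]]
    !is.na(cons@codonIndex) && cons@codonIndex == entry$codon_index &&
      identical(cons@refAA, entry$aa_ref) && cons@altAA %in% alts
  } else if (kind == "in_frame_deletion") {
    cons@kind == "in_frame_indel" && nchar(cons@ref) > nchar(cons@alt) &&
      grepl(paste0("p\\.", entry$deleted_aa, "-del"), cons@proteinChange)
  } else if (kind == "in_frame_insertion") {
    cons@kind == "in_frame_indel" && nchar(cons@alt) > nchar(cons@ref) &&
      (is.na(entry$codon_index) || cons@codonIndex == entry$codon_index)
  } else if (kind == "frameshift") {
    cons@kind == "frameshift" &&
      (is.na(entry$codon_index) || cons@codonIndex == entry$codon_index)
  } else FALSE
}

summariseCarriers <- function(z, groupOf, label) {
  groups <- unique(groupOf)
  rows <- list()
  for (m in rownames(z)) for (g in groups) {
    zz <- z[m, groupOf == g]
    n <- sum(!is.na(zz))
    carriers <- sum(zz >= 1L, na.rm = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, mutation_id = m, carrier_count = carriers,
      het_count = sum(zz == 1L, na.rm = TRUE),
      hom_count = sum(zz == 2L, na.rm = TRUE),
      n_genotyped = n,
      proportion = if (n > 0L) carriers / n else NA_real_,
      allele_frequency = if (n > 0L) sum(zz, na.rm = TRUE) / (2 * n)
                         else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(group = character(0),
                                      mutation_id = character(0),
                                      carrier_count = integer(0),
                                      het_count = integer(0),
                                      hom_count = integer(0),
                                      n_genotyped = integer(0),
                                      proportion = numeric(0),
                                      allele_frequency = numeric(0))
  names(out)[1] <- label
  out
}

#' Contrast carrier proportions between cohorts for one mutation
#'
#' Builds the 2x2 table of carriers vs non-carriers per cohort (invasive
#' row first) and applies the two-tailed exact test of
#' [fisherExactTwoTailed()].
#'
#' @param result a [ScreeningResult-class].
#' @param mutationId catalog mutation id.
#' @return list with `table` (2x2 integer matrix), `p` and `oddsRatio`.
#' @export
cohortContrast <- function(result, mutationId) {
  cs <- byCohort(result)
  cs <- cs[cs$mutation_id == mutationId, ]
  if (nrow(cs) == 0L) stop("unknown mutation: ", mutationId)
  zero <- cs$cohort[cs$n_genotyped == 0L]
  if (length(zero))
    stop("cohort with zero genotyped samples: ", paste(zero, collapse = ", "))
  ord <- order(match(cs$cohort, c("invasive", "native")))
  cs <- cs[ord, ]
  tab <- cbind(carrier = cs$carrier_count,
               non_carrier = cs$n_genotyped - cs$carrier_count)
  rownames(tab) <- cs$cohort
  ft <- fisherExactTwoTailed(tab)
  list(table = tab, p = ft$p, oddsRatio = ft$oddsRatio)
}

#' Observed codon spectrum at one codon of a gene
#'
#' Counts, per population, the distinct codon sequences carried by each
#' individual at a given codon (1-based from the initiator Met). Phasing is
#' naive: an individual homozygous at every site in the codon carries one
#' codon; heterozygous at exactly one site, both implied codons; but
#' heterozygous at two or more sites within the codon is reported in an
#' `"ambiguous"` bucket — an unphased VCF cannot resolve such haplotypes
#' and no phase is ever guessed.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param gene a [GeneModel-class].
#' @param codonIndex 1-based codon index.
#' @param popmap population map data.frame.
#' @param genome [Biostrings::DNAStringSet].
#' @return data.frame(population, codon, n_individuals); individuals missing
#'   a call at any site of the codon are excluded.
#' @export
codonSpectrum <- function(genotypes, gene, codonIndex, popmap, genome) {
  checkPopmapCoverage(genotypes, popmap)
  if (codonIndex < 1L || codonIndex > proteinLength(gene))
    stop("codonIndex out of range")
  cdsPos <- (codonIndex - 1L) * 3L + 1:3
  gpos <- cdsToGenomic(gene, cdsPos)
  cds <- extractCds(gene, genome)
  refCodon <- strsplit(as.character(Biostrings::subseq(
    cds, cdsPos[1], cdsPos[3])), "")[[1]]

  st <- siteTable(genotypes)
  calls <- genotypeCalls(genotypes)
  samples <- colnames(calls)
  pops <- popmap$population[match(samples, popmap$sample)]

  # SNVs of the matrix that fall on the codon's genomic positions
  siteIdx <- integer(0); basePos <- integer(0); altBase <- character(0)
  for (b in 1:3) {
    hit <- which(st$chrom == gene@chrom & st$pos == gpos[b] &
                 nchar(st$ref) == 1L & nchar(st$alt) == 1L)
    for (h in hit) {
      siteIdx <- c(siteIdx, h); basePos <- c(basePos, b)
      ab <- st$alt[h]
      altBase <- c(altBase, if (gene@strand == "+") ab else revcompChar(ab))
    }
  }

  rows <- list()
  for (s in seq_along(samples)) {
    g <- if (length(siteIdx)) calls[siteIdx, s] else integer(0)
    if (length(g) && anyNA(g)) next                     # excluded
    nHet <- sum(g == 1L)
    if (nHet >= 2L) {
      codons <- "ambiguous"
    } else {
      hap1 <- refCodon; hap2 <- refCodon
      for (k in seq_along(siteIdx)) {
        if (g[k] == 2L) { hap1[basePos[k]] <- altBase[k]
                          hap2[basePos[k]] <- altBase[k] }
        if (g[k] == 1L) hap2[basePos[k]] <- altBase[k]
      }
      codons <- unique(c(paste(hap1, collapse = ""),
                         paste(hap2, collapse = "")))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      population = pops[s], codon = codons, stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  if (is.null(long))
    return(data.frame(population = character(0), codon = character(0),
                      n_individuals = integer(0)))
  agg <- aggregate(list(n_individuals = rep(1L, nrow(long))),
                   by = list(population = long$population, codon = long$codon),
                   FUN = sum)
  agg[order(agg$population, -agg$n_individuals), ]
}
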