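# Synthetic-data generators with recorded ground truth. The generators
# emulate the statistical structure the pipeline assumes: Hardy-Weinberg
# diploid genotypes within populations, Balding-Nichols beta-distributed
# population allele frequencies around an ancestral frequency (explicit F
# parameter, matching the Weir-Cockerham estimand), loci placed uniformly
# over the genome (no linkage), and Poisson-distributed per-individual CNV
# events at cohort-specific rates.

#' Specification for the synthetic-data generators
#'
#' @param seed RNG seed (identical specs give byte-identical outputs).
#' @param populations data.frame(name, cohort, n) — one row per population;
#'   cohort is native or invasive.
#' @param catalog optional data.frame(mutation_id, chrom, pos, ref, alt)
#'   of resistance sites to plant.
#' @param catalogFreqs numeric matrix (mutations x populations) of planted
#'   resistance-allele frequencies.
#' @param nBackgroundLoci number of background SNPs.
#' @param F Balding-Nichols differentiation parameter in [0, 1); F = 0
#'   means every population shares the ancestral frequency exactly.
#' @param ancestralRange uniform range for ancestral background allele
#'   frequencies.
#' @param genomeExtent named numeric of chromosome lengths (bp).
#' @param cnvGenes data.frame(gene, clan) of CNV-callable genes.
#' @param cnvRates data.frame(cohort, clan, dup_rate, del_rate) of Poisson
#'   event rates per individual.
#' @return validated spec (list of class `SimSpec`).
#' @export
simSpec <- function(seed, populations,
                    catalog = NULL, catalogFreqs = NULL,
                    nBackgroundLoci = 0L, F = 0,
                    ancestralRange = c(0.05, 0.95),
                    genomeExtent = c(chr1 = 1e6, chr2 = 8e5),
                    cnvGenes = NULL, cnvRates = NULL) {
  stopifnot(is.data.frame(populations),
            all(c("name", "cohort", "n") %in% names(populations)))
  if (any(populations$n <= 0)) stop("population sizes must be positive")
  if (F < 0 || F >= 1) stop("F must be in [0, 1)")
  if (!is.null(catalogFreqs)) {
    if (any(catalogFreqs < 0 | catalogFreqs > 1))
      stop("catalog frequencies must be in [0, 1]")
    if (is.null(colnames(catalogFreqs)) ||
        !all(colnames(catalogFreqs) %in% populations$name))
      stop("catalogFreqs columns must name populations")
  }
  if (!is.null(cnvRates)) {
    if (any(cnvRates$dup_rate < 0) || any(cnvRates$del_rate < 0))
      stop("CNV rates must be non-negative")
    for (cl in unique(cnvRates$clan)) {
      avail <- sum(cnvGenes$clan == cl)
      mx <- max(cnvRates$dup_rate[cnvRates$clan == cl] +
                cnvRates$del_rate[cnvRates$clan == cl])
      if (mx > avail)
        stop("clan ", cl, ": combined event rate ", mx,
             " exceeds the ", avail, " genes available")
    }
  }
  structure(list(seed = as.integer(seed), populations = populations,
                 catalog = catalog, catalogFreqs = catalogFreqs,
                 nBackgroundLoci = as.integer(nBackgroundLoci), F = F,
                 ancestralRange = ancestralRange,
                 genomeExtent = genomeExtent,
                 cnvGenes = cnvGenes, cnvRates = cnvRates),
            class = "SimSpec")
}

simSampleNames <- function(populations)
  unlist(lapply(seq_len(nrow(populations)), function(i)
    paste0(populations$name[i], "_", seq_len(populations$n[i]))))

simPopmap <- function(populations) {
  data.frame(sample = simSampleNames(populations),
             population = rep(populations$name, populations$n),
             cohort = rep(populations$cohort, populations$n),
             strain = NA_character_, stringsAsFactors = FALSE)
}

#' Simulate multi-population diploid genotypes
#'
#' Catalog sites get Hardy-Weinberg genotypes at the planted per-population
#' frequencies. Background loci are placed uniformly over the genome with
#' ancestral frequency drawn from `ancestralRange` and per-population
#' frequencies Beta(p0(1-F)/F, (1-p0)(1-F)/F) (Balding-Nichols); genotypes
#' are Hardy-Weinberg within population. Ground truth (planted frequencies
#' and the exact carrier set of every catalog mutation) is recorded.
#'
#' @param spec a [simSpec()].
#' @param dir optional output directory; writes `genotypes.vcf`,
#'   `popmap.tsv` and `truth.json`.
#' @return list(genotypes = [GenotypeMatrix-class], popmap, truth, paths).
#' @export
simulateGenotypes <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "SimSpec"))
  set.seed(spec$seed)
  pops <- spec$populations
  popmap <- simPopmap(pops)
  samples <- popmap$sample
  popOf <- popmap$population

  chrom <- character(0); pos <- integer(0)
  ref <- character(0); alt <- character(0)
  freqMat <- NULL   # loci x populations

  nCat <- if (is.null(spec$catalog)) 0L else nrow(spec$catalog)
  if (nCat > 0L) {
    chrom <- spec$catalog$chrom; pos <- as.integer(spec$catalog$pos)
    ref <- spec$catalog$ref; alt <- spec$catalog$alt
    fm <- matrix(0, nCat, nrow(pops), dimnames = list(NULL, pops$name))
    fm[, colnames(spec$catalogFreqs)] <- spec$catalogFreqs
    freqMat <- fm
  }

  nBg <- spec$nBackgroundLoci
  if (nBg > 0L) {
    ext <- spec$genomeExtent
    bgChrom <- sample(names(ext), nBg, replace = TRUE,
                      prob = ext / sum(ext))
    bgPos <- floor(runif(nBg) * ext[bgChrom]) + 1L
    # keep site keys unique (against catalog sites and each other)
    key <- paste(bgChrom, bgPos)
    while (anyDuplicated(c(paste(chrom, pos), key))) {
      dup <- duplicated(c(paste(chrom, pos), key))[nCat + seq_len(nBg)]
      bgPos[dup] <- floor(runif(sum(dup)) * ext[bgChrom[dup]]) + 1L
      key <- paste(bgChrom, bgPos)
    }
    bases <- c("A", "C", "G", "T")
    bgRef <- sample(bases, nBg, replace = TRUE)
    bgAlt <- vapply(bgRef, function(b) sample(setdiff(bases, b), 1L),
                    character(1), USE.NAMES = FALSE)
    p0 <- runif(nBg, spec$ancestralRange[1], spec$ancestralRange[2])
    bgFreq <- matrix(NA_real_, nBg, nrow(pops),
                     dimnames = list(NULL, pops$name))
    for (j in seq_len(nrow(pops))) {
      bgFreq[, j] <- if (spec$F > 0)
        rbeta(nBg, p0 * (1 - spec$F) / spec$F,
              (1 - p0) * (1 - spec$F) / spec$F)
      else p0
    }
    chrom <- c(chrom, bgChrom); pos <- c(pos, as.integer(bgPos))
    ref <- c(ref, bgRef); alt <- c(alt, bgAlt)
    freqMat <- rbind(freqMat, bgFreq)
  }
  if (length(pos) == 0L) stop("nothing to simulate")

  calls <- matrix(NA_integer_, length(pos), length(samples),
                  dimnames = list(NULL, samples))
  for (j in seq_len(nrow(pops))) {
    cols <- which(popOf == pops$name[j])
    f <- freqMat[, pops$name[j]]
    calls[, cols] <- rbinom(length(f) * length(cols), 2L,
                            rep(f, times = length(cols)))
  }

  gm <- GenotypeMatrix(chrom, pos, ref, alt, calls, samples = samples)
  carriers <- list()
  if (nCat > 0L) for (i in seq_len(nCat))
    carriers[[spec$catalog$mutation_id[i]]] <-
      samples[which(calls[i, ] >= 1L)]
  truth <- list(seed = spec$seed, F = spec$F,
                catalogFrequencies = if (nCat > 0L)
                  as.data.frame(freqMat[seq_len(nCat), , drop = FALSE])
                else NULL,
                carriers = carriers)

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                  popmap = file.path(dir, "popmap.tsv"),
                  truth = file.path(dir, "truth.json"))
    writeGenotypesVcf(gm, paths$vcf)
    writePopMap(popmap, paths$popmap)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  list(genotypes = gm, popmap = popmap, truth = truth, paths = paths)
}

#' Simulate per-individual gene-family CNV states
#'
#' For each individual and clan, the numbers of duplicated and deleted
#' genes are Poisson at the cohort's rates and assigned to distinct genes
#' sampled without replacement. Ground truth (rates and per-individual
#' event counts) is recorded.
#'
#' @param spec a [simSpec()] with `cnvGenes` and `cnvRates`.
#' @param dir optional output directory; writes `cnv.tsv`, `clans.tsv` and
#'   `cnv_truth.json`.
#' @return list(cnv = [CnvStateTable-class], popmap, truth, paths).
#' @export
simulateCnv <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "SimSpec"))
  if (is.null(spec$cnvGenes) || is.null(spec$cnvRates))
    stop("spec lacks cnvGenes/cnvRates")
  set.seed(spec$seed)
  popmap <- simPopmap(spec$populations)
  genes <- spec$cnvGenes$gene
  clans <- setNames(spec$cnvGenes$clan, genes)
  st <- matrix("neutral", length(genes), nrow(popmap),
               dimnames = list(genes, popmap$sample))
  counts <- list()
  for (s in seq_len(nrow(popmap))) {
    co <- popmap$cohort[s]
    for (cl in unique(spec$cnvRates$clan)) {
      r <- spec$cnvRates[spec$cnvRates$cohort == co &
                         spec$cnvRates$clan == cl, ]
      if (nrow(r) == 0L) next
      clanGenes <- genes[clans[genes] == cl]
      nDup <- rpois(1L, r$dup_rate); nDel <- rpois(1L, r$del_rate)
      if (nDup + nDel > length(clanGenes))
        stop("clan ", cl, ": drew ", nDup + nDel,
             " events for ", length(clanGenes),
             " genes; lower the rates")
      pick <- sample(clanGenes, nDup + nDel)
      if (nDup > 0L) st[pick[seq_len(nDup)], s] <- "duplicated"
      if (nDel > 0L) st[pick[nDup + seq_len(nDel)], s] <- "deleted"
      counts[[length(counts) + 1L]] <- data.frame(
        sample = popmap$sample[s], cohort = co, clan = cl,
        n_dup = nDup, n_del = nDel, stringsAsFactors = FALSE)
    }
  }
  cnv <- CnvStateTable(st, clans)
  truth <- list(seed = spec$seed, rates = spec$cnvRates,
                perIndividual = do.call(rbind, counts))
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(cnv = file.path(dir, "cnv.tsv"),
                  clans = file.path(dir, "clans.tsv"),
                  truth = file.path(dir, "cnv_truth.json"))
    writeCnvTable(cnv, paths$cnv, paths$clans)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  }
  list(cnv = cnv, popmap = popmap, truth = truth, paths = paths)
}
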