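# Central S4 data containers shared by all pipeline stages.

#' GeneModel: CDS structure of a single protein-coding gene
#'
#' Holds the coding exon structure of one gene on one chromosome. Exons are
#' stored as genomic intervals (1-based, closed, ascending genomic order);
#' transcription order is derived from the strand. The total CDS length must
#' be a multiple of 3.
#'
#' @slot geneId gene identifier.
#' @slot proteinId protein accession (metadata only).
#' @slot chrom chromosome name.
#' @slot strand `"+"` or `"-"`.
#' @slot cdsExons [IRanges::IRanges] of coding exons in ascending genomic
#'   order, non-overlapping.
#'
#' @importClassesFrom IRanges IRanges
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    geneId = "character",
    proteinId = "character",
    chrom = "character",
    strand = "character",
    cdsExons = "IRanges"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@geneId) != 1L || !nzchar(object@geneId))
    msg <- c(msg, "geneId must be a single non-empty string")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  ex <- object@cdsExons
  if (length(ex) == 0L) {
    msg <- c(msg, "at least one CDS exon required")
  } else {
    s <- IRanges::start(ex); e <- IRanges::end(ex)
    if (is.unsorted(s, strictly = TRUE))
      msg <- c(msg, "CDS exons must be sorted in ascending genomic order")
    if (length(ex) > 1L && any(s[-1L] <= e[-length(e)]))
      msg <- c(msg, "CDS exons must be non-overlapping")
    if (sum(IRanges::width(ex)) %% 3L != 0L)
      msg <- c(msg, "total CDS length must be divisible by 3")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param geneId gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cdsStarts,cdsEnds 1-based inclusive genomic coordinates of the
#'   coding exons, ascending.
#' @param proteinId optional protein accession.
#' @return A [GeneModel-class] object.
#' @export
GeneModel <- function(geneId, chrom, strand, cdsStarts, cdsEnds,
                      proteinId = NA_character_) {
  new("GeneModel",
      geneId = as.character(geneId),
      proteinId = as.character(proteinId),
      chrom = as.character(chrom),
      strand = as.character(strand),
      cdsExons = IRanges::IRanges(start = as.integer(cdsStarts),
                                  end = as.integer(cdsEnds)))
}

#' @describeIn GeneModel total coding length in bp.
#' @param x a GeneModel.
#' @export
setMethod("cdsLength", "GeneModel", function(x) sum(IRanges::width(x@cdsExons)))

#' @describeIn GeneModel protein length in codons (CDS length / 3, including
#'   the terminal stop codon if annotated).
#' @export
setMethod("proteinLength", "GeneModel", function(x) cdsLength(x) %/% 3L)

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@geneId, "(", object@proteinId, ")\n")
  cat(" ", object@chrom, object@strand, "strand;",
      length(object@cdsExons), "CDS exon(s),",
      cdsLength(object), "bp,", proteinLength(object), "codons\n")
})

#' GenotypeMatrix: diploid biallelic calls at sites x samples
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose single assay
#' `"GT"` holds diploid genotype codes: 0 = hom ref, 1 = het, 2 = hom alt,
#' `NA` = missing. Row ranges carry the site coordinates with `ref`/`alt`
#' alleles in `mcols`; sites are biallelic and ordered by position within
#' chromosome.
#'
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!"GT" %in% SummarizedExperiment::assayNames(object))
    return("assay 'GT' is required")
  gt <- SummarizedExperiment::assay(object, "GT")
  if (!all(gt %in% c(0L, 1L, 2L, NA)))
    msg <- c(msg, "GT codes must be 0, 1, 2 or NA")
  rr <- SummarizedExperiment::rowRanges(object)
  mc <- S4Vectors::mcols(rr)
  if (!all(c("ref", "alt") %in% colnames(mc)))
    msg <- c(msg, "rowRanges must carry 'ref' and 'alt'")
  else {
    if (any(grepl(",", mc$alt, fixed = TRUE)))
      msg <- c(msg, "sites must be biallelic (no comma in alt)")
    if (any(!nzchar(mc$ref)) || any(!nzchar(mc$alt)))
      msg <- c(msg, "ref and alt must be non-empty")
  }
  if (length(rr) > 1L) {
    ch <- as.character(GenomicRanges::seqnames(rr))
    ps <- GenomicRanges::start(rr)
    ok <- tapply(ps, ch, function(p) !is.unsorted(p))
    if (!all(unlist(ok)))
      msg <- c(msg, "positions must be non-decreasing within chromosome")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample names must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param chrom,pos,ref,alt per-site chromosome, 1-based position, reference
#'   and alternate allele (parallel vectors).
#' @param calls integer matrix (sites x samples) of genotype codes 0/1/2/NA.
#' @param samples sample names (defaults to `colnames(calls)`).
#' @return A [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(chrom, pos, ref, alt, calls,
                           samples = colnames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(calls)))
  ord <- order(as.character(chrom), as.integer(pos))
  rr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom)[ord],
    ranges = IRanges::IRanges(start = as.integer(pos)[ord],
                              width = nchar(as.character(ref))[ord]),
    ref = as.character(ref)[ord], alt = as.character(alt)[ord])
  calls <- calls[ord, , drop = FALSE]
  dimnames(calls) <- list(NULL, samples)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(GT = calls), rowRanges = rr,
    colData = S4Vectors::DataFrame(row.names = samples))
  new("GenotypeMatrix", se)
}

#' @describeIn GenotypeMatrix data.frame of site coordinates
#'   (chrom, pos, ref, alt).
#' @param x a GenotypeMatrix.
#' @export
setMethod("siteTable", "GenotypeMatrix", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = S4Vectors::mcols(rr)$ref,
             alt = S4Vectors::mcols(rr)$alt,
             stringsAsFactors = FALSE)
})

#' @describeIn GenotypeMatrix the sites x samples genotype code matrix.
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(x)
  SummarizedExperiment::assay(x, "GT"))

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object), "sites x", ncol(object), "samples\n")
  gt <- SummarizedExperiment::assay(object, "GT")
  cat("  missing calls:", sum(is.na(gt)), "\n")
  callNextMethod()
})

#' CnvStateTable: per-gene per-sample copy-number state
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose assay `"state"` is a
#' character matrix (genes x samples) over `{"deleted","neutral",
#' "duplicated"}`; `rowData(x)$clan` maps each gene to a gene-family clan
#' (e.g. P450 clan2/clan3/clan4/other).
#'
#' @exportClass CnvStateTable
setClass("CnvStateTable", contains = "SummarizedExperiment")

setValidity("CnvStateTable", function(object) {
  msg <- character()
  if (!"state" %in% SummarizedExperiment::assayNames(object))
    return("assay 'state' is required")
  st <- SummarizedExperiment::assay(object, "state")
  if (!all(st %in% c("deleted", "neutral", "duplicated")))
    msg <- c(msg, "states must be deleted/neutral/duplicated (no missing)")
  if (!"clan" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must carry 'clan'")
  else if (anyNA(SummarizedExperiment::rowData(object)$clan))
    msg <- c(msg, "every gene needs exactly one clan")
  if (length(msg)) msg else TRUE
})

#' Construct a CnvStateTable
#'
#' @param states character matrix genes x samples with entries
#'   deleted/neutral/duplicated, or an integer copy-number matrix which is
#'   mapped by the diploid convention (<2 deleted, =2 neutral, >2 duplicated).
#' @param clans named character vector gene -> clan.
#' @return A [CnvStateTable-class].
#' @export
CnvStateTable <- function(states, clans) {
  states <- as.matrix(states)
  if (is.numeric(states)) states <- copyNumberToState(states)
  genes <- rownames(states)
  if (is.null(genes)) stop("state matrix needs gene rownames")
  clan <- unname(clans[genes])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(state = states),
    rowData = S4Vectors::DataFrame(clan = clan, row.names = genes))
  new("CnvStateTable", se)
}

#' Map integer copy numbers to trinary states (diploid convention)
#'
#' @param cn numeric matrix or vector of copy numbers.
#' @return character of the same shape over deleted/neutral/duplicated.
#' @export
copyNumberToState <- function(cn) {
  st <- ifelse(cn < 2, "deleted", ifelse(cn > 2, "duplicated", "neutral"))
  if (is.matrix(cn)) dimnames(st) <- dimnames(cn)
  st
}

#' @describeIn CnvStateTable the genes x samples state matrix.
#' @param x a CnvStateTable.
#' @export
setMethod("cnvStates", "CnvStateTable", function(x)
  SummarizedExperiment::assay(x, "state"))

#' @describeIn CnvStateTable named character vector gene -> clan.
#' @export
setMethod("geneClans", "CnvStateTable", function(x)
  setNames(SummarizedExperiment::rowData(x)$clan, rownames(x)))

setMethod("show", "CnvStateTable", function(object) {
  cat("CnvStateTable:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  clans:", paste(names(table(geneClans(object))), collapse = ", "), "\n")
  st <- cnvStates(object)
  cat("  events:", sum(st == "duplicated"), "duplicated,",
      sum(st == "deleted"), "deleted\n")
})

#' Consequence: protein-level annotation of one variant
#'
#' @slot chrom,pos,ref,alt the (normalized) genomic variant.
#' @slot geneId gene against which the consequence was called.
#' @slot kind one of synonymous, missense, in_frame_indel, frameshift,
#'   stop_gained, non_coding.
#' @slot proteinChange HGVS-like description, e.g. `p.F209V`, `p.GY-del`,
#'   `p.S833fs*12`.
#' @slot codonIndex 1-based codon index of the first affected residue
#'   (NA for non-coding).
#' @slot refAA,altAA affected reference / alternate residue string.
#' @slot prematureStopCodonIndex 1-based protein position of a premature
#'   stop introduced by the variant (NA when none; for frameshifts with no
#'   stop before the annotated CDS end this is NA and the protein change is
#'   flagged as an extension).
#'
#' @exportClass Consequence
setClass("Consequence",
  representation(
    chrom = "character", pos = "integer", ref = "character", alt = "character",
    geneId = "character", kind = "character", proteinChange = "character",
    codonIndex = "integer", refAA = "character", altAA = "character",
    prematureStopCodonIndex = "integer"
  )
)

setValidity("Consequence", function(object) {
  kinds <- c("synonymous", "missense", "in_frame_indel", "frameshift",
             "stop_gained", "non_coding")
  if (!object@kind %in% kinds)
    return(paste("kind must be one of:", paste(kinds, collapse = ", ")))
  TRUE
})

setMethod("show", "Consequence", function(object) {
  cat("Consequence:", object@kind, "in", object@geneId, "\n")
  cat(" ", object@chrom, ":", object@pos, " ", object@ref, ">", object@alt,
      "  ", object@proteinChange, "\n", sep = "")
  if (!is.na(object@prematureStopCodonIndex))
    cat("  premature stop at codon", object@prematureStopCodonIndex, "\n")
})

#' ScreeningResult: catalog screening of a cohort
#'
#' @slot zygosityMatrix integer matrix (mutations x samples): 0 absent,
#'   1 heterozygous, 2 homozygous, NA not genotyped.
#' @slot catalog the screened catalog (data.frame).
#' @slot popmap the population map used (data.frame).
#' @slot populationSummary per (population, mutation) carrier counts.
#' @slot cohortSummary per (cohort, mutation) carrier counts.
#'
#' @exportClass ScreeningResult
setClass("ScreeningResult",
  representation(
    zygosityMatrix = "matrix",
    catalog = "data.frame",
    popmap = "data.frame",
    populationSummary = "data.frame",
    cohortSummary = "data.frame"
  )
)

#' @describeIn ScreeningResult mutations x samples zygosity code matrix
#'   (0 absent, 1 het, 2 hom, NA missing).
#' @param x a ScreeningResult.
#' @export
setMethod("zygosity", "ScreeningResult", function(x) x@zygosityMatrix)

#' @describeIn ScreeningResult per-(population, mutation) carrier counts,
#'   denominators and proportions.
#' @export
setMethod("byPopulation", "ScreeningResult", function(x) x@populationSummary)

#' @describeIn ScreeningResult per-(cohort, mutation) carrier counts,
#'   denominators and proportions.
#' @export
setMethod("byCohort", "ScreeningResult", function(x) x@cohortSummary)

setMethod("show", "ScreeningResult", function(object) {
  cat("ScreeningResult:", nrow(object@zygosityMatrix), "catalog mutations x",
      ncol(object@zygosityMatrix), "samples\n")
  z <- object@zygosityMatrix
  carr <- rowSums(z >= 1, na.rm = TRUE)
  for (m in rownames(z))
    cat(sprintf("  %-28s carriers %3d (het %d / hom %d)\n", m, carr[m],
                sum(z[m, ] == 1, na.rm = TRUE), sum(z[m, ] == 2, na.rm = TRUE)))
})

#' NullDistribution: genome-resampling empirical null for multi-locus F_ST
#'
#' @slot observedTheta observed multi-locus Weir-Cockerham theta at the
#'   target interval.
#' @slot replicateThetas multi-locus theta of each valid resampled window.
#' @slot nRequested,nValid,nRedrawn replicate bookkeeping; windows with no
#'   informative SNP are redrawn and counted in `nRedrawn`.
#' @slot locusLength window length L in bp (the target interval's length).
#' @slot seed RNG seed used for the replicate draws.
#' @slot targetInterval `"chrom:start-end"` string.
#'
#' @exportClass NullDistribution
setClass("NullDistribution",
  representation(
    observedTheta = "numeric",
    replicateThetas = "numeric",
    nRequested = "integer",
    nValid = "integer",
    nRedrawn = "integer",
    locusLength = "integer",
    seed = "integer",
    targetInterval = "character"
  )
)

setValidity("NullDistribution", function(object) {
  msg <- character()
  if (object@nValid != length(object@replicateThetas))
    msg <- c(msg, "nValid must equal length(replicateThetas)")
  if (object@nValid > object@nRequested + object@nRedrawn)
    msg <- c(msg, "nValid must be <= nRequested + nRedrawn")
  if (length(msg)) msg else TRUE
})

#' @describeIn NullDistribution observed multi-locus theta.
#' @param x a NullDistribution.
#' @export
setMethod("observedTheta", "NullDistribution", function(x) x@observedTheta)

#' @describeIn NullDistribution the replicate thetas.
#' @export
setMethod("replicateThetas", "NullDistribution", function(x) x@replicateThetas)

#' @describeIn NullDistribution empirical p-values: `plain` is the fraction
#'   of valid replicates >= observed (ties at tolerance 1e-12 count);
#'   `conservative` adds the observed value to both numerator and
#'   denominator so it is never exactly zero.
#' @param type `"plain"` or `"conservative"`.
#' @export
setMethod("empiricalP", "NullDistribution",
  function(x, type = c("plain", "conservative")) {
    type <- match.arg(type)
    hits <- sum(x@replicateThetas >= x@observedTheta - 1e-12)
    if (type == "plain") hits / x@nValid else (hits + 1) / (x@nValid + 1)
  })

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution for", object@targetInterval,
      sprintf("(L = %d bp)\n", object@locusLength))
  cat(sprintf("  observed theta = %.4f\n", object@observedTheta))
  cat(sprintf("  %d valid replicates (%d requested, %d redrawn), seed %d\n",
              object@nValid, object@nRequested, object@nRedrawn, object@seed))
  cat(sprintf("  p_plain = %.4g, p_conservative = %.4g\n",
              empiricalP(object, "plain"), empiricalP(object, "conservative")))
})
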