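# Weir & Cockerham (1984) F_ST for two groups of diploids at biallelic
# sites: per-locus variance components a (among groups), b (among
# individuals within groups), c (within individuals), combined across loci
# as a ratio of sums, plus the same-length-window genome-resampling
# empirical null and the complete-differentiation scan.

#' Per-locus Weir-Cockerham variance components
#'
#' Computes, for every site of a genotype matrix, the 1984 estimator's
#' variance components for r = 2 groups of diploids from the group sample
#' sizes, allele frequencies and observed heterozygote frequencies. Missing
#' calls are dropped from that locus's group counts; a locus where either
#' group has fewer than 2 callable genotypes is flagged uninformative.
#' Per-locus theta is a/(a+b+c), left untruncated (negative estimates are
#' retained; truncation would bias the multi-locus ratio) and NA where
#' a+b+c = 0 (monomorphic).
#'
#' @param genotypes a [GenotypeMatrix-class] or an integer matrix of
#'   genotype codes (sites x samples, 0/1/2/NA).
#' @param groups character/factor of length n samples with exactly two
#'   levels (e.g. resistant vs susceptible).
#' @return data.frame with one row per locus: n1, n2, p1, p2, h1, h2,
#'   a, b, c, theta, informative.
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
fstComponents <- function(genotypes, groups) {
  calls <- if (is(genotypes, "GenotypeMatrix")) genotypeCalls(genotypes)
           else as.matrix(genotypes)
  groups <- as.character(groups)
  lv <- unique(groups[!is.na(groups)])
  if (length(lv) != 2L) stop("exactly two groups required")
  g1 <- which(groups == lv[1]); g2 <- which(groups == lv[2])

  grpStats <- function(idx) {
    m <- calls[, idx, drop = FALSE]
    n <- rowSums(!is.na(m))
    p <- rowSums(m, na.rm = TRUE) / (2 * n)
    h <- rowSums(m == 1L, na.rm = TRUE) / n
    list(n = n, p = p, h = h)
  }
  s1 <- grpStats(g1); s2 <- grpStats(g2)
  n1 <- s1$n; n2 <- s2$n; p1 <- s1$p; p2 <- s2$p; h1 <- s1$h; h2 <- s2$h

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2v <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- nbar / nc *
    (s2v - (pbar * (1 - pbar) - (r - 1) / r * s2v - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2v - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  informative <- n1 >= 2L & n2 >= 2L
  denom <- a + b + cc
  theta <- ifelse(informative & abs(denom) > 0, a / denom, NA_real_)
  a[!informative] <- NA_real_; b[!informative] <- NA_real_
  cc[!informative] <- NA_real_

  data.frame(n1 = n1, n2 = n2, p1 = p1, p2 = p2, h1 = h1, h2 = h2,
             a = a, b = b, c = cc, theta = theta, informative = informative)
}

#' Multi-locus Weir-Cockerham theta
#'
#' Combines per-locus components across informative loci. The default
#' (`method = "ratio"`) is the ratio of sums sum(a)/sum(a+b+c) — the
#' "weighted" convention of vcftools/W&C; `method = "average"` is the
#' unweighted mean of per-locus thetas, exposed for comparison only.
#'
#' @param components data.frame from [fstComponents()].
#' @param method combining rule.
#' @return multi-locus theta (NA with a warning when no informative
#'   polymorphic locus exists — never silently 0).
#' @export
fstMultilocus <- function(components, method = c("ratio", "average")) {
  method <- match.arg(method)
  ok <- components$informative & !is.na(components$a)
  if (!any(ok)) { warning("no informative locus; theta undefined")
                  return(NA_real_) }
  if (method == "ratio") {
    denom <- sum(components$a[ok] + components$b[ok] + components$c[ok])
    if (abs(denom) == 0) { warning("all loci monomorphic; theta undefined")
                           return(NA_real_) }
    sum(components$a[ok]) / denom
  } else {
    mean(components$theta[ok], na.rm = TRUE)
  }
}

#' Genome-resampling empirical null for a candidate locus
#'
#' Tests whether multi-locus F_ST at a target interval (e.g. a candidate
#' resistance gene) is unusually high by resampling windows of the same
#' length from the genome: each replicate draws a chromosome with
#' probability proportional to its placeable length (length - L + 1), then
#' a uniform start such that the window fits, and scores the multi-locus
#' theta of the SNPs inside. Windows containing no informative SNP are
#' redrawn (and counted); replicates are drawn with replacement and may
#' overlap the target unless `excludeTarget`. `p_plain` is the fraction of
#' valid replicates >= observed (ties at tolerance 1e-12 count as
#' exceedances — conservative); `p_conservative` is (hits+1)/(n+1).
#'
#' @param genotypes a [GenotypeMatrix-class] of genome-wide SNPs.
#' @param groups two-level group labels per sample.
#' @param targetInterval `"chrom:start-end"` or list(chrom,start,end).
#' @param genomeExtent named numeric of per-chromosome lengths (bp).
#' @param nReps number of replicates (the study design uses 100,000).
#' @param seed RNG seed, logged in the result.
#' @param excludeTarget redraw windows overlapping the target interval.
#' @param redrawBudgetFactor error out after `redrawBudgetFactor * nReps`
#'   redraws (advises larger windows or denser data).
#' @return A [NullDistribution-class].
#' @export
resamplingNull <- function(genotypes, groups, targetInterval, genomeExtent,
                           nReps = 100000L, seed = 1L,
                           excludeTarget = FALSE, redrawBudgetFactor = 10) {
  tgt <- parseInterval(targetInterval)
  if (!tgt$chrom %in% names(genomeExtent))
    stop("target chromosome absent from genomeExtent")
  if (tgt$end > genomeExtent[[tgt$chrom]])
    stop("target interval exceeds chromosome length")
  L <- tgt$end - tgt$start + 1L
  comp <- fstComponents(genotypes, groups)
  st <- siteTable(genotypes)

  obsIdx <- st$chrom == tgt$chrom & st$pos >= tgt$start & st$pos <= tgt$end
  if (!any(obsIdx & comp$informative))
    stop("no informative SNP in the target interval")
  observed <- fstMultilocus(comp[obsIdx, , drop = FALSE])

  # per-chromosome cumulative sums over informative loci -> O(log n) window
  # scoring by binary search
  ok <- comp$informative & !is.na(comp$a)
  chromTabs <- lapply(names(genomeExtent), function(ch) {
    idx <- which(ok & st$chrom == ch)
    idx <- idx[order(st$pos[idx])]
    list(pos = st$pos[idx],
         cumA = c(0, cumsum(comp$a[idx])),
         cumD = c(0, cumsum(comp$a[idx] + comp$b[idx] + comp$c[idx])))
  })
  names(chromTabs) <- names(genomeExtent)

  placeable <- pmax(unlist(genomeExtent) - L + 1, 0)   # keeps names
  if (sum(placeable) == 0) stop("window longer than every chromosome")

  set.seed(seed)
  reps <- numeric(0); nRedrawn <- 0L
  budget <- redrawBudgetFactor * nReps
  while (length(reps) < nReps) {
    need <- nReps - length(reps)
    chs <- sample(names(genomeExtent), need, replace = TRUE,
                  prob = placeable / sum(placeable))
    starts <- floor(runif(need) * placeable[chs]) + 1
    vals <- vapply(seq_len(need), function(i) {
      tb <- chromTabs[[chs[i]]]
      lo <- findInterval(starts[i] - 1, tb$pos)
      hi <- findInterval(starts[i] + L - 1, tb$pos)
      if (hi <= lo) return(NA_real_)
      denom <- tb$cumD[hi + 1] - tb$cumD[lo + 1]
      if (abs(denom) == 0) return(NA_real_)
      (tb$cumA[hi + 1] - tb$cumA[lo + 1]) / denom
    }, numeric(1))
    if (excludeTarget) {
      overlap <- chs == tgt$chrom & starts <= tgt$end &
        (starts + L - 1) >= tgt$start
      vals[overlap] <- NA_real_
    }
    bad <- sum(is.na(vals))
    nRedrawn <- nRedrawn + bad
    if (nRedrawn > budget)
      stop("redraw budget exhausted (", nRedrawn, " empty windows); ",
           "use larger windows or denser data")
    reps <- c(reps, vals[!is.na(vals)])
  }

  new("NullDistribution", observedTheta = observed, replicateThetas = reps,
      nRequested = as.integer(nReps), nValid = length(reps),
      nRedrawn = nRedrawn, locusLength = as.integer(L),
      seed = as.integer(seed),
      targetInterval = paste0(tgt$chrom, ":", tgt$start, "-", tgt$end))
}

#' Scan for completely differentiated SNPs
#'
#' Lists every site whose per-locus theta equals 1 (within 1e-12), i.e.
#' fixed for different alleles in the two groups with no heterozygote, and
#' labels its coding context from the gene models (exonic when inside a CDS
#' exon, intronic when inside a gene's span but not its CDS, intergenic
#' otherwise).
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param groups two-level group labels.
#' @param region optional `"chrom:start-end"` restriction.
#' @param geneModels named list of [GeneModel-class].
#' @return data.frame(chrom, pos, theta, context).
#' @export
completeDifferentiationScan <- function(genotypes, groups, region = NULL,
                                        geneModels = list()) {
  comp <- fstComponents(genotypes, groups)
  st <- siteTable(genotypes)
  keep <- comp$informative & !is.na(comp$theta) & comp$theta >= 1 - 1e-12
  if (!is.null(region)) {
    rg <- parseInterval(region)
    keep <- keep & st$chrom == rg$chrom & st$pos >= rg$start &
      st$pos <= rg$end
  }
  idx <- which(keep)
  ctx <- vapply(idx, function(i)
    codingContext(st$chrom[i], st$pos[i], geneModels), character(1))
  data.frame(chrom = st$chrom[idx], pos = st$pos[idx],
             theta = comp$theta[idx], context = ctx,
             stringsAsFactors = FALSE)
}

codingContext <- function(chrom, pos, geneModels) {
  for (g in geneModels) {
    if (g@chrom != chrom) next
    s <- IRanges::start(g@cdsExons); e <- IRanges::end(g@cdsExons)
    if (pos < min(s) || pos > max(e)) next
    if (any(pos >= s & pos <= e)) return("exonic")
    return("intronic")
  }
  "intergenic"
}
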