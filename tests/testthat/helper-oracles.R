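# Independent oracles, written directly from first principles and kept
# separate from the package's code paths.

# Weir & Cockerham (1984) variance components, transcribed from the
# published formulas with explicit per-group loops (r groups, diploid,
# biallelic). Returns a, b, c and theta for one locus.
wcOracle <- function(callsRow, groups) {
  lv <- unique(groups[!is.na(groups)])
  r <- length(lv)
  n <- p <- h <- numeric(r)
  for (i in seq_len(r)) {
    g <- callsRow[which(groups == lv[i])]
    g <- g[!is.na(g)]
    n[i] <- length(g)
    p[i] <- sum(g) / (2 * length(g))
    h[i] <- sum(g == 1) / length(g)
  }
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       theta = if (a + b + cc != 0) a / (a + b + cc) else NA_real_)
}

# multi-locus ratio of sums over a list of wcOracle results
wcOracleMulti <- function(callsMat, groups) {
  A <- D <- 0
  for (i in seq_len(nrow(callsMat))) {
    o <- wcOracle(callsMat[i, ], groups)
    A <- A + o$a
    D <- D + o$a + o$b + o$c
  }
  A / D
}

# two-tailed Fisher exact p by direct hypergeometric enumeration with
# plain choose() arithmetic (valid for small totals)
fisherEnumOracle <- function(tab) {
  m <- tab[1, 1] + tab[1, 2]; n2 <- tab[2, 1] + tab[2, 2]
  K <- tab[1, 1] + tab[2, 1]; N <- m + n2
  if (m == 0 || n2 == 0 || K == 0 || K == N) return(1)
  ks <- max(0, K - n2):min(K, m)
  probs <- choose(m, ks) * choose(n2, K - ks) / choose(N, K)
  pobs <- probs[ks == tab[1, 1]]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# random diploid genotype calls for one locus: two groups, HWE within
# group at random frequencies, sprinkled missingness
randomLocus <- function(n1, n2, missRate = 0.05) {
  p1 <- runif(1); p2 <- runif(1)
  calls <- c(rbinom(n1, 2, p1), rbinom(n2, 2, p2))
  calls[runif(n1 + n2) < missRate] <- NA
  list(calls = calls, groups = rep(c("g1", "g2"), c(n1, n2)))
}

# a tiny single-gene genome for consequence tests: random stop-free CDS
# (optionally with fixed codons), embedded in a random chromosome
makeTinyGene <- function(nCodons = 60, strand = "+", chromLen = 1200,
                         cdsOffset = 301, nExons = 1, intronLen = 50,
                         fixedCodons = list()) {
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  nonstop <- setdiff(all64, c("TAA", "TAG", "TGA"))
  codons <- sample(nonstop, nCodons - 1, replace = TRUE)
  for (i in names(fixedCodons)) codons[as.integer(i)] <- fixedCodons[[i]]
  cds <- paste0(paste(codons, collapse = ""), "TAA")
  L <- nchar(cds)
  chrom <- paste(sample(bases, chromLen, replace = TRUE), collapse = "")
  # split the CDS over nExons exons separated by introns
  cuts <- if (nExons > 1) sort(sample(seq_len(L - 1), nExons - 1)) else integer(0)
  bounds <- c(0, cuts, L)
  ws <- diff(bounds)
  # for '-' the 5' CDS segment sits in the rightmost (last) genomic exon
  ord <- if (strand == "+") seq_len(nExons) else rev(seq_len(nExons))
  starts <- ends <- integer(nExons)
  gpos <- cdsOffset
  for (j in seq_len(nExons)) {
    w <- ws[ord[j]]
    starts[j] <- gpos; ends[j] <- gpos + w - 1
    seg <- substr(cds, bounds[ord[j]] + 1, bounds[ord[j] + 1])
    if (strand == "-")
      seg <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seg)))
    substr(chrom, starts[j], ends[j]) <- seg
    gpos <- gpos + w + intronLen
  }
  gene <- GeneModel("tiny", "chrT", strand, starts, ends)
  genome <- Biostrings::DNAStringSet(c(chrT = chrom))
  list(gene = gene, genome = genome, cds = cds, chrom = chrom)
}

# independent translation via seqinr's codon machinery
seqinrTranslate <- function(dnaString) {
  paste(seqinr::translate(strsplit(tolower(dnaString), "")[[1]]),
        collapse = "")
}
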