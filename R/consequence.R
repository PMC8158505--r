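# Codon-level consequence calling: map a genomic variant onto a gene's CDS,
# rebuild the mutant coding sequence, translate, and classify. Frameshifts
# are followed in the shifted frame until the first stop codon; the scan
# never runs past the annotated CDS end (no stop there is reported as an
# extension, not a guessed stop).

#' Extract the reference CDS of a gene from chromosome sequences
#'
#' Concatenates the coding exons in transcription order; minus-strand genes
#' are reverse-complemented.
#'
#' @param gene a [GeneModel-class].
#' @param genome [Biostrings::DNAStringSet] named by chromosome.
#' @return [Biostrings::DNAString] of the coding sequence.
#' @export
extractCds <- function(gene, genome) {
  if (!gene@chrom %in% names(genome))
    stop("chromosome ", gene@chrom, " absent from genome")
  chromSeq <- genome[[gene@chrom]]
  parts <- Biostrings::DNAStringSet(Biostrings::extractAt(chromSeq,
                                                          gene@cdsExons))
  cds <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
  if (gene@strand == "-") cds <- Biostrings::reverseComplement(cds)
  cds
}

#' Convert between genomic and CDS coordinates of a gene
#'
#' `genomicToCds` returns the 1-based CDS position of a genomic position
#' (NA when the position is not coding); `cdsToGenomic` is its inverse.
#' Both count CDS positions from the first base of the initiator codon in
#' transcription order.
#'
#' @param gene a [GeneModel-class].
#' @param pos genomic position(s), 1-based.
#' @export
genomicToCds <- function(gene, pos) {
  ex <- gene@cdsExons
  s <- IRanges::start(ex); e <- IRanges::end(ex); w <- IRanges::width(ex)
  vapply(as.integer(pos), function(p) {
    i <- which(p >= s & p <= e)
    if (!length(i)) return(NA_integer_)
    if (gene@strand == "+") {
      before <- if (i > 1L) sum(w[seq_len(i - 1L)]) else 0L
      as.integer(before + (p - s[i] + 1L))
    } else {
      after <- if (i < length(w)) sum(w[seq(i + 1L, length(w))]) else 0L
      as.integer(after + (e[i] - p + 1L))
    }
  }, integer(1))
}

#' @rdname genomicToCds
#' @param cdsPos CDS position(s), 1-based.
#' @export
cdsToGenomic <- function(gene, cdsPos) {
  ex <- gene@cdsExons
  s <- IRanges::start(ex); e <- IRanges::end(ex); w <- IRanges::width(ex)
  ord <- if (gene@strand == "+") seq_along(w) else rev(seq_along(w))
  cum <- c(0L, cumsum(w[ord]))
  vapply(as.integer(cdsPos), function(cp) {
    if (is.na(cp) || cp < 1L || cp > sum(w)) return(NA_integer_)
    k <- findInterval(cp - 1L, cum, rightmost.closed = FALSE)
    i <- ord[k]
    off <- cp - cum[k]
    if (gene@strand == "+") as.integer(s[i] + off - 1L)
    else as.integer(e[i] - off + 1L)
  }, integer(1))
}

translateCds <- function(cds) {
  L <- 3L * (length(cds) %/% 3L)
  if (L == 0L) return(character(0))
  aa <- Biostrings::translate(Biostrings::subseq(cds, 1L, L),
                              if.fuzzy.codon = "X")
  strsplit(as.character(aa), "")[[1]]
}

revcompChar <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Annotate the protein-level consequence of a variant
#'
#' The variant is normalized (trimmed, left-aligned), placed on the gene's
#' CDS, the mutant CDS is rebuilt and translated under the standard genetic
#' code, and the change is classified as synonymous, missense, stop_gained,
#' in_frame_indel or frameshift. For frameshifts (and in-frame indels that
#' introduce a stop) the downstream sequence is re-read in the new frame and
#' the first stop is reported as `prematureStopCodonIndex` (1-based protein
#' position in the mutant). Variants not touching the CDS are `non_coding`;
#' variants spanning a CDS/intron boundary raise an explicit error rather
#' than being silently misannotated.
#'
#' @param chrom,pos,ref,alt the variant (VCF conventions, 1-based).
#' @param gene a [GeneModel-class].
#' @param genome [Biostrings::DNAStringSet] named by chromosome.
#' @return A [Consequence-class].
#' @export
annotateConsequence <- function(chrom, pos, ref, alt, gene, genome) {
  refseq <- if (chrom %in% names(genome)) genome[[chrom]] else NULL
  nv <- normalizeVariant(pos, ref, alt, refseq)
  pos <- nv$pos; ref <- nv$ref; alt <- nv$alt
  mk <- function(kind, proteinChange = NA_character_,
                 codonIndex = NA_integer_, refAA = NA_character_,
                 altAA = NA_character_, stopIdx = NA_integer_)
    new("Consequence", chrom = chrom, pos = as.integer(pos), ref = ref,
        alt = alt, geneId = gene@geneId, kind = kind,
        proteinChange = proteinChange, codonIndex = as.integer(codonIndex),
        refAA = refAA, altAA = altAA,
        prematureStopCodonIndex = as.integer(stopIdx))

  if (chrom != gene@chrom) return(mk("non_coding"))
  if (!is.null(refseq)) {
    obs <- toupper(as.character(Biostrings::subseq(refseq, pos,
                                                   pos + nchar(ref) - 1L)))
    if (obs != ref)
      stop("reference allele mismatch at ", chrom, ":", pos,
           " (VCF ", ref, ", genome ", obs, ")")
  }
  cds <- extractCds(gene, genome)
  cdsChars <- strsplit(as.character(cds), "")[[1]]
  refAAseq <- translateCds(cds)
  nr <- nchar(ref); na <- nchar(alt)

  if (nr == na) {
    # substitution (SNV or MNV): every affected base must be coding
    gpos <- pos:(pos + nr - 1L)
    cpos <- genomicToCds(gene, gpos)
    if (all(is.na(cpos))) return(mk("non_coding"))
    if (any(is.na(cpos)))
      stop("substitution spans a CDS boundary at ", chrom, ":", pos,
           " - unsupported")
    repl <- if (gene@strand == "+") alt else revcompChar(alt)
    cpos <- sort(cpos)
    if (!all(diff(cpos) == 1L))
      stop("substitution spans an exon junction at ", chrom, ":", pos,
           " - unsupported")
    mut <- cdsChars
    mut[cpos] <- strsplit(repl, "")[[1]]
    mutAA <- translateCds(Biostrings::DNAString(paste(mut, collapse = "")))
    changed <- which(mutAA != refAAseq[seq_along(mutAA)])
    if (!length(changed)) {
      ci <- (cpos[1] - 1L) %/% 3L + 1L
      return(mk("synonymous", paste0("p.", refAAseq[ci], ci, "="),
                ci, refAAseq[ci], refAAseq[ci]))
    }
    ci <- changed[1]
    kind <- if (mutAA[ci] == "*") "stop_gained" else "missense"
    pc <- paste0("p.", paste0(refAAseq[changed], changed, mutAA[changed],
                              collapse = ";"))
    return(mk(kind, pc, ci, paste(refAAseq[changed], collapse = ""),
              paste(mutAA[changed], collapse = ""),
              if (kind == "stop_gained") ci else
                firstPrematureStop(mutAA, refAAseq)))
  }

  # anchored indel: ref = a or a+D, alt = a or a+I (post-normalization)
  if (substr(ref, 1L, 1L) != substr(alt, 1L, 1L))
    stop("complex substitution/indel at ", chrom, ":", pos, " - unsupported")
  if (nr > na) {                         # deletion of D = ref[2..]
    delLen <- nr - na
    gdel <- (pos + 1L):(pos + delLen)
    cdel <- genomicToCds(gene, gdel)
    if (all(is.na(cdel))) return(mk("non_coding"))
    if (any(is.na(cdel)))
      stop("deletion spans a CDS boundary at ", chrom, ":", pos,
           " - unsupported")
    cdel <- sort(cdel)
    if (!all(diff(cdel) == 1L))
      stop("deletion spans an exon junction at ", chrom, ":", pos,
           " - unsupported")
    mut <- cdsChars[-cdel]
    indelLen <- delLen
    cStart <- cdel[1]
  } else {                               # insertion of I = alt[2..]
    insSeq <- substr(alt, 2L, na)
    cAnchor <- genomicToCds(gene, pos)
    cNext <- genomicToCds(gene, pos + 1L)
    if (is.na(cAnchor) && is.na(cNext)) return(mk("non_coding"))
    if (is.na(cAnchor) || is.na(cNext) || abs(cNext - cAnchor) != 1L)
      stop("insertion at a CDS boundary at ", chrom, ":", pos,
           " - unsupported")
    if (gene@strand == "+") {
      after <- cAnchor; insCds <- insSeq
    } else {
      after <- cNext; insCds <- revcompChar(insSeq)
    }
    mut <- append(cdsChars, strsplit(insCds, "")[[1]], after = after)
    indelLen <- nchar(insSeq)
    cStart <- after + 1L
  }
  mutAA <- translateCds(Biostrings::DNAString(paste(mut, collapse = "")))
  ci <- (cStart - 1L) %/% 3L + 1L
  if (indelLen %% 3L == 0L) {
    stopIdx <- firstPrematureStop(mutAA, refAAseq)
    pc <- if (nr > na) {
      delAA <- inFrameDeletedAA(refAAseq, mutAA)
      paste0("p.", delAA$aa, "-del")
    } else paste0("p.", ci, "ins", indelLen %/% 3L, "aa")
    return(mk("in_frame_indel", pc, ci,
              refAAseq[min(ci, length(refAAseq))], NA_character_, stopIdx))
  }
  stopIdx <- which(mutAA == "*")[1]
  pc <- if (is.na(stopIdx))
    paste0("p.", refAAseq[min(ci, length(refAAseq))], ci, "fs*ext")
  else
    paste0("p.", refAAseq[min(ci, length(refAAseq))], ci, "fs*",
           stopIdx - ci + 1L)
  mk("frameshift", pc, ci, refAAseq[min(ci, length(refAAseq))],
     NA_character_, stopIdx)
}

# first stop internal to the mutant protein (the terminal stop is normal)
firstPrematureStop <- function(mutAA, refAAseq) {
  s <- which(mutAA == "*")[1]
  if (is.na(s) || s >= length(mutAA)) return(NA_integer_)
  as.integer(s)
}

# aligned description of an in-frame deletion (e.g. "GY" for p.GY-del)
inFrameDeletedAA <- function(refAA, mutAA) {
  nDel <- length(refAA) - length(mutAA)
  if (nDel <= 0L) return(list(aa = "", start = NA_integer_))
  i <- 1L
  while (i <= length(mutAA) && mutAA[i] == refAA[i]) i <- i + 1L
  # deletion may be ambiguous in a repeat; report the leftmost placement
  list(aa = paste(refAA[i:(i + nDel - 1L)], collapse = ""), start = i)
}
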