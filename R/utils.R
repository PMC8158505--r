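# Coordinate and allele plumbing shared across modules.
#
# Conventions: VCF and catalog positions are 1-based; internal interval
# arithmetic on exons uses IRanges (1-based closed), converted explicitly
# where 0-based half-open input (BED) is read.

#' Normalize a variant: trim shared bases and left-align indels
#'
#' Removes the shared suffix, then the shared prefix (retaining one anchor
#' base for indels), then — when the chromosome sequence is supplied —
#' left-shifts pure insertions/deletions as far as the reference context
#' allows. Two representations of the same indel emitted by different
#' callers compare equal after this.
#'
#' @param pos 1-based position.
#' @param ref,alt allele strings.
#' @param refseq optional chromosome sequence (character or
#'   [Biostrings::DNAString]) for left-alignment.
#' @return list with elements `pos`, `ref`, `alt`.
#' @export
normalizeVariant <- function(pos, ref, alt, refseq = NULL) {
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (!is.null(refseq) && !is.character(refseq)) refseq <- as.character(refseq)
  # trim shared suffix
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # trim shared prefix, keep an anchor when an allele would empty out
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  # left-align anchored indels against the reference context
  isIndel <- nchar(ref) != nchar(alt)
  if (isIndel && !is.null(refseq)) {
    anchored <- (nchar(ref) == 1L && substr(alt, 1L, 1L) == ref) ||
                (nchar(alt) == 1L && substr(ref, 1L, 1L) == alt)
    while (anchored && pos > 1L) {
      long <- if (nchar(ref) > nchar(alt)) ref else alt
      seqIns <- substr(long, 2L, nchar(long))   # the inserted/deleted bases
      lastBase <- substr(seqIns, nchar(seqIns), nchar(seqIns))
      prevBase <- toupper(substr(refseq, pos - 1L, pos - 1L))
      if (!nzchar(prevBase) || prevBase != lastBase) break
      pos <- pos - 1L
      seqIns <- paste0(prevBase, substr(seqIns, 1L, nchar(seqIns) - 1L))
      anchor <- toupper(substr(refseq, pos, pos))
      if (nchar(ref) > nchar(alt)) {
        ref <- paste0(anchor, seqIns); alt <- anchor
      } else {
        alt <- paste0(anchor, seqIns); ref <- anchor
      }
    }
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Parse an interval string "chrom:start-end"
#'
#' @param x interval string, 1-based inclusive.
#' @return list(chrom, start, end).
#' @export
parseInterval <- function(x) {
  if (is.list(x)) return(x)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4L) stop("cannot parse interval: ", x)
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

# diploid GT string ("0/1", "1|0", "./.") -> code 0/1/2/NA
gtToCode <- function(gt) {
  gt <- sub(":.*$", "", gt)
  a <- strsplit(gt, "[/|]")
  vapply(a, function(al) {
    if (length(al) != 2L || any(al == ".") || any(al == ""))
      return(NA_integer_)
    sum(as.integer(al) > 0L)
  }, integer(1))
}

codeToGt <- function(code) {
  out <- rep("./.", length(code))
  out[!is.na(code) & code == 0L] <- "0/0"
  out[!is.na(code) & code == 1L] <- "0/1"
  out[!is.na(code) & code == 2L] <- "1/1"
  out
}

# 0-based half-open <-> 1-based closed interval converters (exact inverses)
zeroBasedToOneBased <- function(start0, end0)
  list(start = as.integer(start0) + 1L, end = as.integer(end0))

oneBasedToZeroBased <- function(start1, end1)
  list(start = as.integer(start1) - 1L, end = as.integer(end1))
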