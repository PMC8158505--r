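# Readers/writers for the external formats the pipeline consumes:
# multi-sample VCF (via vcfR), resistance-mutation catalog (JSON/TSV),
# population map (TSV), per-gene CNV tables (TSV) and gene models (GFF3
# CDS features or BED12).

#' Read a multi-sample VCF into a GenotypeMatrix
#'
#' Requires diploid GT fields. Sites are normalized (shared prefix/suffix
#' trimmed; indels left-aligned when `genome` is supplied). Multi-allelic
#' records are split into biallelic sites alt-by-alt (default), dropped, or
#' rejected, per `multiallelic`. An ingestion report (record counts, drops,
#' splits) is stored in `metadata(x)$ingest`; no sample is ever silently
#' dropped.
#'
#' @param path VCF file (v4.x, plain or bgzipped).
#' @param genome optional [Biostrings::DNAStringSet] of chromosome sequences
#'   used for indel left-alignment.
#' @param multiallelic policy for multi-allelic records.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, genome = NULL,
                          multiallelic = c("split", "drop", "error")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- v@gt
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  if (!all(grepl("(^|:)GT(:|$)", gt[, "FORMAT"])))
    stop("VCF format error: GT field required in all records")
  samples <- colnames(gt)[-1L]
  if (anyDuplicated(samples)) stop("duplicate sample names in VCF")
  gtm <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gtm))) gtm <- matrix(gtm, nrow = 1,
                                       dimnames = list(NULL, samples))

  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- toupper(fix[, "REF"]); alt <- toupper(fix[, "ALT"])
  multi <- grepl(",", alt, fixed = TRUE)
  nDropped <- 0L; nSplit <- 0L

  outChrom <- character(); outPos <- integer()
  outRef <- character(); outAlt <- character()
  outCalls <- list()

  alleleCount <- function(gtstr, allele) {
    g <- sub(":.*$", "", gtstr)
    parts <- strsplit(g, "[/|]")
    vapply(parts, function(al) {
      if (length(al) != 2L || any(al %in% c(".", "")))
        return(NA_integer_)
      sum(as.integer(al) == allele)
    }, integer(1))
  }

  for (i in seq_len(nrow(fix))) {
    if (multi[i]) {
      if (multiallelic == "error")
        stop("multi-allelic record at ", chrom[i], ":", pos[i])
      if (multiallelic == "drop") { nDropped <- nDropped + 1L; next }
      alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
      nSplit <- nSplit + 1L
      for (j in seq_along(alts)) {
        outChrom <- c(outChrom, chrom[i]); outPos <- c(outPos, pos[i])
        outRef <- c(outRef, ref[i]); outAlt <- c(outAlt, alts[j])
        outCalls[[length(outCalls) + 1L]] <- alleleCount(gtm[i, ], j)
      }
    } else {
      outChrom <- c(outChrom, chrom[i]); outPos <- c(outPos, pos[i])
      outRef <- c(outRef, ref[i]); outAlt <- c(outAlt, alt[i])
      outCalls[[length(outCalls) + 1L]] <- gtToCode(gtm[i, ])
    }
  }
  calls <- if (length(outCalls)) do.call(rbind, outCalls)
           else matrix(integer(0), 0L, length(samples))
  colnames(calls) <- samples

  for (k in seq_along(outPos)) {
    refseq <- if (!is.null(genome) && outChrom[k] %in% names(genome))
      genome[[outChrom[k]]] else NULL
    nv <- normalizeVariant(outPos[k], outRef[k], outAlt[k], refseq)
    outPos[k] <- nv$pos; outRef[k] <- nv$ref; outAlt[k] <- nv$alt
  }

  gm <- GenotypeMatrix(outChrom, outPos, outRef, outAlt, calls,
                       samples = samples)
  S4Vectors::metadata(gm)$ingest <- list(
    nRecords = nrow(fix), nSitesOut = length(outPos),
    nDropped = nDropped, nSplitRecords = nSplit,
    multiallelicPolicy = multiallelic)
  gm
}

#' Write a GenotypeMatrix as a VCF v4.2 file
#'
#' Minimal records (GT only); reading the file back with [readGenotypes()]
#' reproduces the object.
#'
#' @param x a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypesVcf <- function(x, path) {
  st <- siteTable(x)
  calls <- genotypeCalls(x)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=resistscan",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(calls)), collapse = "\t"))
  body <- vapply(seq_len(nrow(st)), function(i) {
    paste(c(st$chrom[i], st$pos[i], ".", st$ref[i], st$alt[i], ".", "PASS",
            ".", "GT", codeToGt(calls[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a population map
#'
#' TSV with header columns `sample`, `population`, `cohort`
#' (native/invasive) and optionally `strain` (sfC/sfR host form).
#'
#' @param path TSV path.
#' @return data.frame with one row per sample.
#' @export
readPopMap <- function(path) {
  pm <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "population", "cohort")
  if (!all(need %in% names(pm)))
    stop("population map needs columns: ", paste(need, collapse = ", "))
  if (!all(pm$cohort %in% c("native", "invasive")))
    stop("cohort must be 'native' or 'invasive'")
  if (anyDuplicated(pm$sample))
    stop("duplicate samples in population map")
  if (!"strain" %in% names(pm)) pm$strain <- NA_character_
  pm
}

#' @rdname readPopMap
#' @param popmap data.frame as returned by `readPopMap`.
#' @export
writePopMap <- function(popmap, path) {
  write.table(popmap, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# every genotyped sample must map; report the set difference otherwise
checkPopmapCoverage <- function(x, popmap) {
  missing <- setdiff(colnames(x), popmap$sample)
  extra <- setdiff(popmap$sample, colnames(x))
  if (length(missing))
    stop("samples in genotype data without population-map entry: ",
         paste(missing, collapse = ", "))
  invisible(list(unmapped = missing, unused = extra))
}

catalogColumns <- c("mutation_id", "gene_id", "chrom", "pos", "ref", "alt",
                    "protein_kind", "aa_ref", "codon_index", "aa_alt",
                    "deleted_aa", "insecticide_class", "origin_population")

#' Read and validate a resistance-mutation catalog
#'
#' Accepts JSON (array of objects) or TSV. Each entry carries a genomic spec
#' (`chrom`, `pos` 1-based, `ref`, `alt`; may be absent when only the
#' protein change is known) and a protein spec: `protein_kind` in
#' substitution / in_frame_deletion / in_frame_insertion / frameshift with
#' `aa_ref`, `codon_index` (1-based from the initiator Met), `aa_alt`
#' (multiple alternates separated by `/`, e.g. `K/R`), or `deleted_aa` for
#' in-frame deletions. Frameshift entries must have an indel length not
#' divisible by 3; all other indels must be in-frame.
#'
#' @param path catalog file.
#' @param geneModels optional list of [GeneModel-class]; when given,
#'   `codon_index` is checked against each gene's protein length.
#' @return data.frame of validated entries.
#' @export
readCatalog <- function(path, geneModels = NULL) {
  isJson <- grepl("\\.json$", path, ignore.case = TRUE) ||
    grepl("^\\s*\\[", readChar(path, 1024L))
  if (file.size(path) == 0L ||
      (!isJson && length(readLines(path, warn = FALSE)) <= 1L &&
       !nzchar(paste(readLines(path, warn = FALSE), collapse = "")))) {
    warning("empty catalog: ", path)
    return(emptyCatalog())
  }
  cat <- if (isJson) {
    x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(x) == 0L) { warning("empty catalog: ", path); return(emptyCatalog()) }
    as.data.frame(x, stringsAsFactors = FALSE)
  } else {
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               na.strings = c("NA", "."))
  }
  for (col in catalogColumns) if (!col %in% names(cat)) cat[[col]] <- NA
  cat <- cat[, catalogColumns]
  cat$pos <- as.integer(cat$pos)
  cat$codon_index <- as.integer(cat$codon_index)
  validateCatalog(cat, geneModels)
  cat
}

emptyCatalog <- function() {
  df <- as.data.frame(setNames(rep(list(character(0)), length(catalogColumns)),
                               catalogColumns), stringsAsFactors = FALSE)
  df$pos <- integer(0); df$codon_index <- integer(0)
  df
}

validateCatalog <- function(cat, geneModels = NULL) {
  kinds <- c("substitution", "in_frame_deletion", "in_frame_insertion",
             "frameshift")
  for (i in seq_len(nrow(cat))) {
    id <- cat$mutation_id[i]
    if (is.na(id) || !nzchar(id)) stop("catalog entry ", i, " lacks mutation_id")
    if (!cat$protein_kind[i] %in% kinds)
      stop("catalog entry '", id, "': unknown protein_kind '",
           cat$protein_kind[i], "'")
    if (!is.na(cat$ref[i]) && !is.na(cat$alt[i])) {
      d <- abs(nchar(cat$ref[i]) - nchar(cat$alt[i]))
      if (cat$protein_kind[i] == "frameshift" && d %% 3L == 0L)
        stop("catalog entry '", id, "': flagged frameshift but indel length ",
             d, " is a multiple of 3")
      if (cat$protein_kind[i] != "frameshift" && d %% 3L != 0L)
        stop("catalog entry '", id, "': indel length ", d,
             " implies a frameshift but protein_kind is '",
             cat$protein_kind[i], "'")
    }
    if (!is.null(geneModels) && !is.na(cat$codon_index[i])) {
      gm <- geneModels[[cat$gene_id[i]]]
      if (!is.null(gm) && cat$codon_index[i] > proteinLength(gm))
        stop("catalog entry '", id, "': codon_index ", cat$codon_index[i],
             " beyond protein length ", proteinLength(gm), " of ",
             cat$gene_id[i])
    }
  }
  invisible(TRUE)
}

#' @rdname readCatalog
#' @param catalog a catalog data.frame.
#' @export
writeCatalog <- function(catalog, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(catalog, path, auto_unbox = FALSE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
  }
  invisible(path)
}

#' Read a per-sample per-gene CNV table
#'
#' Long-format TSV with columns `sample`, `gene` and either `copy_number`
#' (integer; mapped by the diploid convention: <2 deleted, =2 neutral,
#' >2 duplicated) or `state`. The clan map is a TSV with columns `gene`,
#' `clan`; genes absent from it are assigned clan `"other"` with a warning.
#'
#' @param path CNV TSV.
#' @param clanMapPath gene-to-clan TSV.
#' @return A [CnvStateTable-class].
#' @export
readCnvTable <- function(path, clanMapPath) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample", "gene") %in% names(tab)))
    stop("CNV table needs columns sample, gene and copy_number or state")
  genes <- sort(unique(tab$gene)); samples <- unique(tab$sample)
  if (nrow(tab) != length(genes) * length(samples) ||
      anyDuplicated(tab[, c("sample", "gene")]))
    stop("CNV table must cover every sample x gene exactly once")
  if ("state" %in% names(tab)) {
    st <- tab$state
  } else if ("copy_number" %in% names(tab)) {
    st <- copyNumberToState(as.numeric(tab$copy_number))
  } else stop("CNV table needs a copy_number or state column")
  m <- matrix(NA_character_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(tab$gene, genes), match(tab$sample, samples))] <- st
  cm <- read.table(clanMapPath, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("gene", "clan") %in% names(cm)))
    stop("clan map needs columns gene, clan")
  clans <- setNames(cm$clan, cm$gene)
  orphan <- setdiff(genes, names(clans))
  if (length(orphan)) {
    warning("genes without clan annotation assigned 'other': ",
            paste(orphan, collapse = ", "))
    clans[orphan] <- "other"
  }
  CnvStateTable(m, clans)
}

#' @rdname readCnvTable
#' @param x a [CnvStateTable-class].
#' @param clanPath optional path for the clan map TSV.
#' @export
writeCnvTable <- function(x, path, clanPath = NULL) {
  st <- cnvStates(x)
  long <- data.frame(sample = rep(colnames(st), each = nrow(st)),
                     gene = rep(rownames(st), times = ncol(st)),
                     state = as.vector(st), stringsAsFactors = FALSE)
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(clanPath)) {
    cl <- geneClans(x)
    write.table(data.frame(gene = names(cl), clan = unname(cl)),
                clanPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read gene models from GFF3 CDS features or BED12
#'
#' GFF3: CDS features grouped by the `gene_id` attribute (falling back to
#' `Parent`/`ID`), `protein_id` kept as metadata. BED12: one record per
#' gene; blocks are the coding exons. BED's 0-based half-open coordinates
#' are converted to the 1-based closed convention used internally.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED (`.bed`) file.
#' @return named list of [GeneModel-class] objects.
#' @export
readGeneModels <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE))
    readGeneModelsBed(path) else readGeneModelsGff(path)
}

readGeneModelsGff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  if (!length(gr)) stop("no CDS features in ", path)
  mc <- S4Vectors::mcols(gr)
  gid <- if ("gene_id" %in% colnames(mc)) as.character(mc$gene_id)
         else if ("Parent" %in% colnames(mc))
           vapply(mc$Parent, function(p) as.character(p)[1], character(1))
         else as.character(mc$ID)
  prot <- if ("protein_id" %in% colnames(mc)) as.character(mc$protein_id)
          else rep(NA_character_, length(gr))
  rec <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    gene = gid, protein = prot, stringsAsFactors = FALSE)
  buildGeneModels(rec)
}

readGeneModelsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  mc <- S4Vectors::mcols(gr)
  if (!"blocks" %in% colnames(mc))
    stop("BED12 with block structure required in ", path)
  recs <- lapply(seq_along(gr), function(i) {
    bl <- mc$blocks[[i]]  # block starts are relative to the record start
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[i],
               start = GenomicRanges::start(gr)[i] + IRanges::start(bl) - 1L,
               end = GenomicRanges::start(gr)[i] + IRanges::end(bl) - 1L,
               strand = as.character(GenomicRanges::strand(gr))[i],
               gene = mc$name[i], protein = NA_character_,
               stringsAsFactors = FALSE)
  })
  buildGeneModels(do.call(rbind, recs))
}

buildGeneModels <- function(rec) {
  out <- lapply(split(rec, rec$gene), function(g) {
    g <- g[order(g$start), ]
    GeneModel(g$gene[1], g$chrom[1], g$strand[1], g$start, g$end,
              proteinId = g$protein[1])
  })
  out[unique(rec$gene)]
}

#' @rdname readGeneModels
#' @param models named list of [GeneModel-class].
#' @export
writeGeneModels <- function(models, path) {
  lines <- c("##gff-version 3")
  for (g in models) {
    ex <- g@cdsExons
    for (i in seq_along(ex)) {
      attrs <- paste0("gene_id=", g@geneId)
      if (!is.na(g@proteinId)) attrs <- paste0(attrs, ";protein_id=",
                                               g@proteinId)
      lines <- c(lines, paste(g@chrom, "resistscan", "CDS",
                              IRanges::start(ex)[i], IRanges::end(ex)[i],
                              ".", g@strand, "0", attrs, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
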