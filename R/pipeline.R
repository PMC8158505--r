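# Single entry point wiring the stages into the full analysis flow
# (screen -> F_ST/null -> CNV burden -> power) and emitting a consolidated
# JSON run report. Stages run independently: a failure in one is recorded
# in its status and never silently skips the others. Raw exact-test
# p-values are reported uncorrected (with the number of tests performed
# printed), matching the monitoring design.

#' Run the full resistance-monitoring pipeline
#'
#' @param config a list or path to a JSON file with (all optional except as
#'   noted by the stages they enable):
#'   \describe{
#'     \item{vcf, popmap, catalog, genes, genome}{input paths; enable the
#'       screening stage.}
#'     \item{fst}{list(groupBy, groups, region, nullReps, seed,
#'       genomeExtent): `groupBy` is a popmap column (e.g. population or
#'       strain), `groups` the two labels to contrast, `region` the target
#'       interval `"chrom:start-end"`; enables the F_ST/null stage.}
#'     \item{cnv, clans}{CNV table and clan map paths; enables the burden
#'       stage.}
#'     \item{power}{list(freq, n): enables the detection-power stage.}
#'   }
#' @return a `RunReport` list: tool version, config echo with input file
#'   MD5 hashes, per-stage `status` and outputs, warnings.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  report <- list(
    tool = "resistscan",
    version = as.character(packageVersion("resistscan")),
    config = config,
    inputHashes = inputHashes(config),
    nTestsPerformed = 0L,
    stages = list())

  stage <- function(fn) {
    tryCatch(c(list(status = "ok"), fn()),
             error = function(e) list(status = "error",
                                      message = conditionMessage(e)))
  }

  wantScreen <- !is.null(config$vcf) && !is.null(config$popmap) &&
    !is.null(config$catalog)
  if (wantScreen) {
    report$stages$screening <- stage(function() {
      genome <- if (!is.null(config$genome))
        Biostrings::readDNAStringSet(config$genome) else NULL
      if (!is.null(genome)) names(genome) <- sub("\\s.*$", "", names(genome))
      geneModels <- if (!is.null(config$genes))
        readGeneModels(config$genes) else list()
      gm <- readGenotypes(config$vcf, genome = genome)
      popmap <- readPopMap(config$popmap)
      catalog <- readCatalog(config$catalog, geneModels)
      res <- screen(gm, catalog, geneModels, popmap, genome)
      contrasts <- list()
      for (m in catalog$mutation_id) {
        cc <- tryCatch(cohortContrast(res, m), error = function(e) NULL)
        if (!is.null(cc))
          contrasts[[m]] <- list(table = cc$table, p = cc$p,
                                 oddsRatio = cc$oddsRatio)
      }
      report$nTestsPerformed <<- report$nTestsPerformed + length(contrasts)
      list(byPopulation = byPopulation(res), byCohort = byCohort(res),
           cohortContrasts = contrasts,
           carriers = apply(zygosity(res), 1L, function(z)
             names(z)[!is.na(z) & z >= 1L], simplify = FALSE))
    })
  }

  if (!is.null(config$fst)) {
    report$stages$fst <- stage(function() {
      fc <- config$fst
      gm <- readGenotypes(config$vcf)
      popmap <- readPopMap(config$popmap)
      groupBy <- if (!is.null(fc$groupBy)) fc$groupBy else "population"
      lab <- popmap[[groupBy]][match(colnames(gm), popmap$sample)]
      groups <- ifelse(lab %in% fc$groups, lab, NA)
      keep <- !is.na(groups)
      sub <- GenotypeMatrix(siteTable(gm)$chrom, siteTable(gm)$pos,
                            siteTable(gm)$ref, siteTable(gm)$alt,
                            genotypeCalls(gm)[, keep, drop = FALSE],
                            samples = colnames(gm)[keep])
      nd <- resamplingNull(sub, groups[keep], fc$region,
                           unlist(fc$genomeExtent),
                           nReps = if (!is.null(fc$nullReps)) fc$nullReps
                                   else 100000L,
                           seed = if (!is.null(fc$seed)) fc$seed else 1L)
      list(observedTheta = observedTheta(nd),
           pPlain = empiricalP(nd, "plain"),
           pConservative = empiricalP(nd, "conservative"),
           nValid = nd@nValid, nRedrawn = nd@nRedrawn,
           locusLength = nd@locusLength, seed = nd@seed,
           targetInterval = nd@targetInterval)
    })
  }

  if (!is.null(config$cnv) && !is.null(config$clans)) {
    report$stages$cnvBurden <- stage(function() {
      cnv <- readCnvTable(config$cnv, config$clans)
      popmap <- readPopMap(config$popmap)
      popmap <- popmap[popmap$sample %in% colnames(cnvStates(cnv)), ]
      bs <- burden(cnv, popmap)
      tests <- list()
      for (cl in setdiff(unique(bs$clan), "other")) {
        bc <- tryCatch(burdenContrast(bs, cl), error = function(e) NULL)
        if (!is.null(bc))
          tests[[cl]] <- list(table = bc$table, p = bc$p,
                              oddsRatio = bc$oddsRatio)
      }
      report$nTestsPerformed <<- report$nTestsPerformed + length(tests)
      list(summary = as.data.frame(bs), tests = tests)
    })
  }

  if (!is.null(config$power)) {
    report$stages$power <- stage(function() {
      p <- config$power$freq; N <- config$power$n
      list(freq = p, N = N, missProbability = missProbability(p, N),
           missPercent = 100 * missProbability(p, N))
    })
  }

  class(report) <- c("RunReport", class(report))
  report
}

inputHashes <- function(config) {
  paths <- unlist(config[c("vcf", "popmap", "catalog", "genes", "genome",
                           "cnv", "clans")], use.names = TRUE)
  paths <- paths[!is.na(paths) & file.exists(paths)]
  if (!length(paths)) return(list())
  as.list(tools::md5sum(paths))
}

#' Write a run report as JSON
#'
#' @param report a `RunReport` from [runPipeline()].
#' @param path output JSON path.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE,
                       dataframe = "rows")
  invisible(path)
}
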