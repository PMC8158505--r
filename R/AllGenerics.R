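#' @import methods
#' @importFrom stats rbinom rbeta rpois runif setNames uniroot aggregate
#' @importFrom utils write.table read.table packageVersion
NULL

#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))

#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @export
setGeneric("cnvStates", function(x) standardGeneric("cnvStates"))

#' @export
setGeneric("geneClans", function(x) standardGeneric("geneClans"))

#' @export
setGeneric("zygosity", function(x) standardGeneric("zygosity"))

#' @export
setGeneric("byPopulation", function(x) standardGeneric("byPopulation"))

#' @export
setGeneric("byCohort", function(x) standardGeneric("byCohort"))

#' @export
setGeneric("observedTheta", function(x) standardGeneric("observedTheta"))

#' @export
setGeneric("replicateThetas", function(x) standardGeneric("replicateThetas"))

#' @export
setGeneric("empiricalP", function(x, ...) standardGeneric("empiricalP"))

#' @export
setGeneric("cdsLength", function(x) standardGeneric("cdsLength"))

#' @export
setGeneric("proteinLength", function(x) standardGeneric("proteinLength"))
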