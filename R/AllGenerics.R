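#' @rdname GenomeLayout-class
#' @param x,object An object.
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname GenomeLayout-class
#' @export
setMethod("binSize", "GenomeLayout", function(x) x@binSize)

#' @rdname BinnedSignal-class
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))

#' @rdname BinnedSignal-class
#' @export
setMethod("stage", "BinnedSignal", function(x) x@stage)

#' @rdname AnnotationBundle-class
#' @export
setGeneric("enhancers", function(x) standardGeneric("enhancers"))
#' @rdname AnnotationBundle-class
#' @export
setMethod("enhancers", "AnnotationBundle", function(x) x@enhancers)

#' @rdname AnnotationBundle-class
#' @export
setGeneric("geneBodies", function(x) standardGeneric("geneBodies"))
#' @rdname AnnotationBundle-class
#' @export
setMethod("geneBodies", "AnnotationBundle", function(x) x@geneBodies)

#' @rdname AnnotationBundle-class
#' @export
setGeneric("denylist", function(x) standardGeneric("denylist"))
#' @rdname AnnotationBundle-class
#' @export
setMethod("denylist", "AnnotationBundle", function(x) x@denylist)

#' @rdname AnnotationBundle-class
#' @export
setGeneric("workspace", function(x) standardGeneric("workspace"))
#' @rdname AnnotationBundle-class
#' @export
setMethod("workspace", "AnnotationBundle", function(x) x@workspace)

#' @rdname AnnotationBundle-class
#' @export
setGeneric("promoterRegions", function(x) standardGeneric("promoterRegions"))
#' @rdname AnnotationBundle-class
#' @export
setMethod("promoterRegions", "AnnotationBundle", function(x) x@promoters)

#' @rdname SimulationTruth-class
#' @export
setGeneric("plantedDomains", function(x) standardGeneric("plantedDomains"))
#' @rdname SimulationTruth-class
#' @export
setMethod("plantedDomains", "SimulationTruth", function(x) x@plantedDomains)

#' @rdname SimulationTruth-class
#' @export
setGeneric("responsiveGenes", function(x) standardGeneric("responsiveGenes"))
#' @rdname SimulationTruth-class
#' @export
setMethod("responsiveGenes", "SimulationTruth", function(x) x@responsiveGenes)

#' @rdname SimulationTruth-class
#' @export
setGeneric("dependentGenes", function(x) standardGeneric("dependentGenes"))
#' @rdname SimulationTruth-class
#' @export
setMethod("dependentGenes", "SimulationTruth", function(x) x@dependentGenes)

#' @rdname DomainCallResult-class
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))
#' @rdname DomainCallResult-class
#' @export
setMethod("domains", "DomainCallResult", function(x) x@domains)

#' @rdname DomainCallResult-class
#' @export
setGeneric("binStats", function(x) standardGeneric("binStats"))
#' @rdname DomainCallResult-class
#' @export
setMethod("binStats", "DomainCallResult", function(x) x@binStats)

#' @rdname DomainCallResult-class
#' @export
setGeneric("domainSummary", function(x) standardGeneric("domainSummary"))
#' @rdname DomainCallResult-class
#' @export
setMethod("domainSummary", "DomainCallResult", function(x) x@summary)

#' @rdname EnrichmentResult-class
#' @export
setGeneric("foldEnrichment", function(x) standardGeneric("foldEnrichment"))
#' @rdname EnrichmentResult-class
#' @export
setMethod("foldEnrichment", "EnrichmentResult", function(x) x@fold)
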