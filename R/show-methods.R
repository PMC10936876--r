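#' @rdname GenomeLayout-class
#' @export
setMethod("show", "GenomeLayout", function(object) {
    sl <- seqlengths(object@seqinfo)
    cat("GenomeLayout:", length(sl), "chromosome(s),",
        format(sum(as.numeric(sl)), big.mark = ","), "bp total,",
        object@binSize, "bp bins\n")
})

#' @rdname AnnotationBundle-class
#' @export
setMethod("show", "AnnotationBundle", function(object) {
    cat("AnnotationBundle\n")
    cat("  enhancers:  ", length(object@enhancers), "\n")
    cat("  promoters:  ", length(object@promoters), "\n")
    cat("  gene bodies:", length(object@geneBodies), "\n")
    cat("  denylist:   ", length(object@denylist), "intervals (",
        sum(as.numeric(width(object@denylist))), "bp )\n")
    cat("  workspace:  ", sum(as.numeric(width(object@workspace))), "bp\n")
})

#' @rdname SimulationTruth-class
#' @export
setMethod("show", "SimulationTruth", function(object) {
    cat("SimulationTruth:", length(object@plantedDomains),
        "planted domain(s), enhancer bias", object@enhancerBias, "\n")
    cat("  responsive genes:", length(object@responsiveGenes),
        "( dependent:", length(object@dependentGenes), ")\n")
})

#' @rdname BinnedSignal-class
#' @export
setMethod("show", "BinnedSignal", function(object) {
    cat("BinnedSignal [stage:", object@stage, "]\n")
    cat(" ", nrow(object), "bins x", ncol(object), "samples (",
        sum(colData(object)$role == "target"), "target,",
        sum(colData(object)$role == "igg_control"), "IgG )\n")
})

#' @rdname DomainCallResult-class
#' @export
setMethod("show", "DomainCallResult", function(object) {
    cat("DomainCallResult:", length(object@domains), "domain(s) at",
        "adjusted p <", object@alpha, "( direction:", object@direction,
        ")\n")
    s <- object@summary
    if (length(s) && s$n_domains > 0)
        cat("  mean length:", round(s$mean_length_bp), "bp; total:",
            s$total_length_bp, "bp\n")
})

#' @rdname EnrichmentResult-class
#' @export
setMethod("show", "EnrichmentResult", function(object) {
    cat("EnrichmentResult", if (!is.na(object@category))
        paste0("[", object@category, "]"), "\n")
    cat("  observed:", object@observed, "bp; expected:",
        round(object@expected, 1), "bp; fold:",
        round(object@fold, 3), "\n")
    cat("  p(enrich):", signif(object@pEnrich, 3), "; p(deplete):",
        signif(object@pDeplete, 3), "over", object@nSim, "simulations\n")
})
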