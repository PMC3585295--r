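#' @rdname PositionFrequencyMatrix-class
#' @param object,x an object.
#' @export
setGeneric("tfId", function(object) standardGeneric("tfId"))

#' @rdname PositionFrequencyMatrix-class
#' @export
setGeneric("tfName", function(object) standardGeneric("tfName"))

#' @rdname PositionFrequencyMatrix-class
#' @export
setGeneric("tfFamily", function(object) standardGeneric("tfFamily"))

#' @rdname PositionFrequencyMatrix-class
#' @export
setGeneric("evidenceCount", function(object) standardGeneric("evidenceCount"))

#' @rdname PositionFrequencyMatrix-class
#' @export
setGeneric("matrixLength", function(object) standardGeneric("matrixLength"))

#' @rdname PositionFrequencyMatrix-class
#' @export
setGeneric("baseFrequencies", function(object, ...) standardGeneric("baseFrequencies"))

#' @rdname PositionFrequencyMatrix-class
#' @export
setGeneric("consensusSequence", function(object) standardGeneric("consensusSequence"))

#' @rdname ScoringMatrix-class
#' @param object an object.
#' @export
setGeneric("conservationVector", function(object) standardGeneric("conservationVector"))

#' @rdname ScoringMatrix-class
#' @export
setGeneric("coreWindow", function(object) standardGeneric("coreWindow"))

#' @rdname BindingCountMatrix-class
#' @param object an object.
#' @export
setGeneric("countMatrix", function(object) standardGeneric("countMatrix"))

#' @rdname BindingCountMatrix-class
#' @export
setGeneric("tfNames", function(object) standardGeneric("tfNames"))

#' @rdname BindingCountMatrix-class
#' @export
setGeneric("geneNames", function(object) standardGeneric("geneNames"))

#' Per-TF binding-site totals
#'
#' Row sums of a binding-count matrix: the total number of predicted
#' binding sites of each transcription factor across all scanned promoters.
#'
#' @param m a [BindingCountMatrix-class].
#' @return named numeric vector, one total per TF.
#' @examples
#' fx <- coreTfBindingCounts()
#' tfTotals(fx$matrix)["PPARG"]  # 76
#' @export
setGeneric("tfTotals", function(m) standardGeneric("tfTotals"))

#' @rdname PathwayMap-class
#' @param object an object.
#' @export
setGeneric("pathwayNames", function(object) standardGeneric("pathwayNames"))

#' @rdname PathwayMap-class
#' @export
setGeneric("pathwayGenes", function(object, ...) standardGeneric("pathwayGenes"))

#' @rdname RegulomeNetwork-class
#' @param object an object.
#' @export
setGeneric("networkGraph", function(object) standardGeneric("networkGraph"))
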