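#' @import methods
#' @importFrom stats pt rbinom rlnorm rnorm runif setNames var
#' @importFrom utils read.delim write.table
NULL

setOldClass("igraph")

DNA_BASES <- c("A", "C", "G", "T")

#' Position frequency matrix for a transcription factor
#'
#' A `PositionFrequencyMatrix` stores per-position nucleotide counts (or
#' frequencies) describing the binding preference of one transcription
#' factor, together with the metadata the regulome pipeline filters on:
#' the matrix family and the number of experimental evidence records
#' backing the matrix.
#'
#' @slot tfId single character, unique matrix identifier.
#' @slot tfName single character, transcription factor name.
#' @slot family single character, matrix family label.
#' @slot evidenceCount single non-negative integer, number of experimental
#'   evidence records behind the matrix.
#' @slot counts numeric L x 4 matrix of non-negative values, columns ordered
#'   A, C, G, T; every row (position) must have a strictly positive total.
#'
#' @seealso [PFM()] for the user-facing constructor, [baseFrequencies()],
#'   [informationVector()].
#' @name PositionFrequencyMatrix-class
#' @rdname PositionFrequencyMatrix-class
#' @exportClass PositionFrequencyMatrix
setClass("PositionFrequencyMatrix",
  representation(
    tfId = "character",
    tfName = "character",
    family = "character",
    evidenceCount = "integer",
    counts = "matrix"
  )
)

setValidity("PositionFrequencyMatrix", function(object) {
  msg <- character()
  if (length(object@tfId) != 1L || !nzchar(object@tfId))
    msg <- c(msg, "'tfId' must be a single non-empty string")
  if (length(object@evidenceCount) != 1L || is.na(object@evidenceCount) ||
      object@evidenceCount < 0L)
    msg <- c(msg, "'evidenceCount' must be a single non-negative integer")
  cts <- object@counts
  if (!is.numeric(cts) || ncol(cts) != 4L)
    msg <- c(msg, "'counts' must be a numeric L x 4 matrix (A,C,G,T)")
  else {
    if (nrow(cts) < 4L)
      msg <- c(msg, "matrix length must be at least 4 positions")
    if (any(cts < 0))
      msg <- c(msg, "'counts' must be non-negative")
    if (any(rowSums(cts) <= 0))
      msg <- c(msg, "every position must have a strictly positive column total")
  }
  if (length(msg)) msg else TRUE
})

#' Conservation-annotated scoring matrix
#'
#' A `ScoringMatrix` wraps a [PositionFrequencyMatrix-class] with the derived
#' quantities used by conservation-weighted similarity scoring: the
#' per-position conservation vector `ci` (0 for a uniform position, 100 for
#' an invariant one), the per-position maximum base frequency `fMax`, and the
#' contiguous core window of the most conserved positions.
#'
#' @slot pfm the underlying [PositionFrequencyMatrix-class].
#' @slot freq numeric L x 4 matrix of per-position base frequencies
#'   (rows sum to 1).
#' @slot ci numeric length-L conservation vector in \[0, 100\].
#' @slot core integer vector of consecutive 1-based core positions.
#' @slot fMax numeric length-L vector, `fMax[i] = max_b freq[i, b]`.
#'
#' @seealso [scoringMatrix()], [matrixSimilarity()], [corePositions()].
#' @name ScoringMatrix-class
#' @rdname ScoringMatrix-class
#' @exportClass ScoringMatrix
setClass("ScoringMatrix",
  representation(
    pfm = "PositionFrequencyMatrix",
    freq = "matrix",
    ci = "numeric",
    core = "integer",
    fMax = "numeric"
  )
)

setValidity("ScoringMatrix", function(object) {
  L <- nrow(object@freq)
  msg <- character()
  if (length(object@ci) != L || any(object@ci < -1e-9 | object@ci > 100 + 1e-9))
    msg <- c(msg, "'ci' must be length L with values in [0, 100]")
  if (length(object@fMax) != L)
    msg <- c(msg, "'fMax' must have one value per position")
  if (length(object@core) < 1L || length(object@core) > L)
    msg <- c(msg, "core must contain between 1 and L positions")
  else if (!all(diff(object@core) == 1L))
    msg <- c(msg, "core positions must be consecutive")
  if (any(abs(rowSums(object@freq) - 1) > 1e-9))
    msg <- c(msg, "frequency rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' TF x gene binding-site count matrix
#'
#' The central object of the regulome pipeline: an integer matrix of
#' predicted binding-site counts with transcription factors as rows and
#' target genes (biomarkers) as columns.
#'
#' @slot counts integer matrix, TFs x genes, all entries >= 0, unique
#'   row and column names.
#'
#' @seealso [bindingCountMatrix()], [tfTotals()], [pathwayCounts()],
#'   [coreTFs()].
#' @name BindingCountMatrix-class
#' @rdname BindingCountMatrix-class
#' @exportClass BindingCountMatrix
setClass("BindingCountMatrix", representation(counts = "matrix"))

setValidity("BindingCountMatrix", function(object) {
  cts <- object@counts
  msg <- character()
  if (!is.numeric(cts))
    msg <- c(msg, "'counts' must be numeric")
  else {
    if (any(cts < 0) || any(cts != round(cts)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  if (is.null(rownames(cts)) || is.null(colnames(cts)))
    msg <- c(msg, "counts must carry TF row names and gene column names")
  else {
    if (anyDuplicated(rownames(cts)))
      msg <- c(msg, "TF labels must be unique")
    if (anyDuplicated(colnames(cts)))
      msg <- c(msg, "gene labels must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Pathway membership map
#'
#' Maps pathway names to sets of biomarker gene identifiers. Genes may
#' belong to more than one pathway; every pathway set must be non-empty.
#'
#' @slot pathways named list of character vectors of gene identifiers.
#'
#' @seealso [pathwayMap()], [readGmt()], [cadPathways()].
#' @name PathwayMap-class
#' @rdname PathwayMap-class
#' @exportClass PathwayMap
setClass("PathwayMap", representation(pathways = "list"))

setValidity("PathwayMap", function(object) {
  p <- object@pathways
  msg <- character()
  if (is.null(names(p)) || any(!nzchar(names(p))) || anyDuplicated(names(p)))
    msg <- c(msg, "pathways must have unique non-empty names")
  if (!all(vapply(p, is.character, logical(1L))))
    msg <- c(msg, "each pathway must be a character vector of gene ids")
  else if (any(vapply(p, length, integer(1L)) == 0L))
    msg <- c(msg, "pathway gene sets must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Regulome summary: core, specific and combinatorial regulators
#'
#' Aggregated view of a [BindingCountMatrix-class] against a
#' [PathwayMap-class]: per-TF and per-family binding-site totals, TF x
#' pathway count matrix, per-TF pathway signatures, signature groups
#' (combinatorial regulators), and the two core-TF sets (TFs binding every
#' gene; TFs binding at least one gene of every pathway).
#'
#' @slot coreByGene character vector of TFs binding every gene.
#' @slot coreByPathway character vector of TFs whose signature covers all
#'   pathways.
#' @slot signatures named list: TF -> character vector of pathway names.
#' @slot groups named list: signature key -> character vector of TFs.
#' @slot tfTotals named numeric vector of per-TF binding-site totals.
#' @slot familyTotals named numeric vector of per-family totals.
#' @slot pathwayTotals numeric TF x pathway count matrix.
#'
#' @seealso [regulomeSummary()].
#' @name RegulomeSummary-class
#' @rdname RegulomeSummary-class
#' @exportClass RegulomeSummary
setClass("RegulomeSummary",
  representation(
    coreByGene = "character",
    coreByPathway = "character",
    signatures = "list",
    groups = "list",
    tfTotals = "numeric",
    familyTotals = "numeric",
    pathwayTotals = "matrix"
  )
)

#' TF-biomarker regulome network
#'
#' A typed graph over transcription factors and biomarkers with three edge
#' classes: `regulates` (TF -> biomarker, weight = binding-site count),
#' `co_regulates` (TF - TF, weight = Jaccard similarity of target sets) and
#' `co_targeted` (biomarker - biomarker, weight = Jaccard similarity of
#' regulator sets). Backed by an igraph object whose vertices carry a
#' `nodeType` attribute (`"TF"` or `"biomarker"`).
#'
#' @slot graph an igraph object.
#'
#' @seealso [buildRegulomeNetwork()], [extractModules()], [exportGraph()].
#' @name RegulomeNetwork-class
#' @rdname RegulomeNetwork-class
#' @exportClass RegulomeNetwork
setClass("RegulomeNetwork", representation(graph = "igraph"))
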