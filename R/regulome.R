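#' Construct a pathway map
#'
#' @param pathways named list of character vectors of gene ids.
#' @return a [PathwayMap-class].
#' @export
pathwayMap <- function(pathways) {
  new("PathwayMap", pathways = lapply(pathways, function(g) unique(as.character(g))))
}

#' @rdname PathwayMap-class
#' @export
setMethod("pathwayNames", "PathwayMap", function(object) names(object@pathways))

#' @rdname PathwayMap-class
#' @param name pathway name; omitted, the full named list is returned.
#' @param ... passed on to methods.
#' @export
setMethod("pathwayGenes", "PathwayMap", function(object, name = NULL) {
  if (is.null(name)) return(object@pathways)
  if (!name %in% names(object@pathways))
    stop("unknown pathway: ", name)
  object@pathways[[name]]
})

#' @rdname PathwayMap-class
#' @export
setMethod("length", "PathwayMap", function(x) length(x@pathways))

setMethod("show", "PathwayMap", function(object) {
  cat(sprintf("PathwayMap: %d pathways, %d genes\n",
              length(object@pathways),
              length(unique(unlist(object@pathways)))))
  for (nm in names(object@pathways))
    cat(sprintf("  %-16s %d genes\n", nm, length(object@pathways[[nm]])))
})

#' Read / write GMT pathway files
#'
#' `readGmt()` parses the standard gene-matrix-transposed format (pathway
#' name, description, tab-separated gene list per line) via
#' [fgsea::gmtPathways()]; `writeGmt()` writes a [PathwayMap-class] back out.
#'
#' @param path GMT file path.
#' @return a [PathwayMap-class].
#' @export
readGmt <- function(path) {
  pathwayMap(fgsea::gmtPathways(path))
}

#' @rdname readGmt
#' @param pmap a [PathwayMap-class].
#' @export
writeGmt <- function(pmap, path) {
  lines <- vapply(pathwayNames(pmap), function(nm) {
    paste(c(nm, nm, pathwayGenes(pmap, nm)), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname tfTotals
#' @export
setMethod("tfTotals", "BindingCountMatrix", function(m) {
  rowSums(countMatrix(m))
})

#' Binding-site totals per matrix family
#'
#' Sums the per-TF binding-site totals within each matrix family. The
#' family totals conserve the grand total:
#' `sum(aggregateFamilyCounts(m, f)) == sum(tfTotals(m))`.
#'
#' @param m a [BindingCountMatrix-class].
#' @param familyOf named character vector mapping every TF id to its family.
#' @return named numeric vector of per-family totals.
#' @export
aggregateFamilyCounts <- function(m, familyOf) {
  tfs <- tfNames(m)
  missing <- setdiff(tfs, names(familyOf))
  if (length(missing))
    stop("no family assigned for TF(s): ", paste(missing, collapse = ", "))
  tot <- tfTotals(m)
  c(tapply(tot, factor(familyOf[tfs]), sum))
}

#' TF x pathway binding-site counts
#'
#' For each TF and pathway, the total number of binding sites over the
#' pathway's member genes. A gene in several pathways contributes to each
#' of them (pathway counts are only a partition of the TF total when the
#' pathways partition the genes).
#'
#' @param m a [BindingCountMatrix-class].
#' @param pmap a [PathwayMap-class]; every pathway gene must be a matrix
#'   column.
#' @return numeric TF x pathway matrix.
#' @examples
#' fx <- coreTfBindingCounts()
#' pathwayCounts(fx$matrix, fx$pathways)["EGR1", "coagulation"]  # 21
#' @export
pathwayCounts <- function(m, pmap) {
  cts <- countMatrix(m)
  unknown <- setdiff(unique(unlist(pathwayGenes(pmap))), colnames(cts))
  if (length(unknown))
    stop("pathway gene(s) absent from the count matrix: ",
         paste(unknown, collapse = ", "))
  out <- vapply(pathwayNames(pmap), function(nm) {
    rowSums(cts[, pathwayGenes(pmap, nm), drop = FALSE])
  }, numeric(nrow(cts)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = 1L,
                  dimnames = list(rownames(cts), pathwayNames(pmap)))
  out
}

#' Pathway signature of a TF
#'
#' The set of pathways in which the TF has at least one predicted binding
#' site.
#'
#' @param m a [BindingCountMatrix-class].
#' @param pmap a [PathwayMap-class].
#' @param tf TF identifier (matrix row).
#' @return character vector of pathway names (possibly empty).
#' @export
pathwaySignature <- function(m, pmap, tf) {
  if (!tf %in% tfNames(m))
    stop("unknown TF: ", tf)
  pc <- pathwayCounts(m, pmap)
  colnames(pc)[pc[tf, ] >= 1]
}

#' Core transcription factors
#'
#' Two nested definitions of a "core" regulator:
#' * mode `"gene"`: TFs with at least one binding site in every gene
#'   (every biomarker promoter);
#' * mode `"pathway"`: TFs with at least one binding site in at least one
#'   gene of every pathway.
#' Every gene-mode core TF is also a pathway-mode core TF.
#'
#' @param m a [BindingCountMatrix-class].
#' @param pmap a [PathwayMap-class] (required for mode `"pathway"`).
#' @param mode `"gene"` or `"pathway"`.
#' @return character vector of TF ids.
#' @examples
#' fx <- coreTfBindingCounts()
#' coreTFs(fx$matrix, fx$pathways, mode = "pathway")  # "EGR1"
#' @export
coreTFs <- function(m, pmap = NULL, mode = c("gene", "pathway")) {
  mode <- match.arg(mode)
  cts <- countMatrix(m)
  if (mode == "gene")
    return(rownames(cts)[rowSums(cts >= 1) == ncol(cts)])
  if (is.null(pmap))
    stop("mode 'pathway' requires a PathwayMap")
  pc <- pathwayCounts(m, pmap)
  rownames(pc)[rowSums(pc >= 1) == ncol(pc)]
}

#' Group TFs by identical pathway signature
#'
#' Partitions all TFs of the matrix by their pathway signature; TFs sharing
#' a signature are interpreted as combinatorial regulators of that pathway
#' combination. TFs with no binding site in any pathway form an explicit
#' empty-signature group (key `"(none)"`), so no TF is silently dropped.
#'
#' @param m a [BindingCountMatrix-class].
#' @param pmap a [PathwayMap-class].
#' @return named list: signature key (pathway names joined by `"+"`,
#'   in `pathwayNames(pmap)` order) -> character vector of TF ids. Groups
#'   are disjoint and cover all TFs.
#' @export
groupBySignature <- function(m, pmap) {
  pc <- pathwayCounts(m, pmap)
  keys <- apply(pc >= 1, 1L, function(hit) {
    nm <- colnames(pc)[hit]
    if (!length(nm)) "(none)" else paste(nm, collapse = "+")
  })
  split(rownames(pc), keys)
}

#' Summarize a binding-count matrix against a pathway map
#'
#' Bundles the regulome aggregations into one [RegulomeSummary-class]:
#' per-TF and per-family totals, TF x pathway counts, pathway signatures,
#' signature groups, and the core TF sets under both definitions.
#'
#' @param m a [BindingCountMatrix-class].
#' @param pmap a [PathwayMap-class].
#' @param familyOf optional named character vector TF -> family; TFs
#'   without an entry fall into family `"unassigned"`.
#' @return a [RegulomeSummary-class].
#' @export
regulomeSummary <- function(m, pmap, familyOf = NULL) {
  tfs <- tfNames(m)
  if (is.null(familyOf))
    familyOf <- setNames(rep("unassigned", length(tfs)), tfs)
  else {
    fill <- setdiff(tfs, names(familyOf))
    familyOf <- c(familyOf, setNames(rep("unassigned", length(fill)), fill))
  }
  pc <- pathwayCounts(m, pmap)
  sigs <- lapply(setNames(tfs, tfs), function(tf) colnames(pc)[pc[tf, ] >= 1])
  new("RegulomeSummary",
      coreByGene = coreTFs(m, mode = "gene"),
      coreByPathway = coreTFs(m, pmap, mode = "pathway"),
      signatures = sigs,
      groups = groupBySignature(m, pmap),
      tfTotals = tfTotals(m),
      familyTotals = aggregateFamilyCounts(m, familyOf),
      pathwayTotals = pc)
}

setMethod("show", "RegulomeSummary", function(object) {
  cat(sprintf("RegulomeSummary: %d TFs, %d pathways\n",
              length(object@tfTotals), ncol(object@pathwayTotals)))
  cat(sprintf("  core (all genes):     %s\n",
              paste(object@coreByGene, collapse = ", ")))
  cat(sprintf("  core (all pathways):  %s\n",
              paste(object@coreByPathway, collapse = ", ")))
  cat(sprintf("  signature groups:     %d\n", length(object@groups)))
})

#' Serialize a regulome summary to JSON
#'
#' @param rs a [RegulomeSummary-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRegulomeSummary <- function(rs, path) {
  obj <- list(
    core_by_gene = rs@coreByGene,
    core_by_pathway = rs@coreByPathway,
    signatures = rs@signatures,
    groups = rs@groups,
    tf_totals = as.list(rs@tfTotals),
    family_totals = as.list(rs@familyTotals),
    pathway_totals = as.data.frame(rs@pathwayTotals)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
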