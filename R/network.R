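#' Jaccard similarity of two sets
#'
#' `|a intersect b| / |a union b|`; defined as 0 when both sets are empty.
#'
#' @param a,b vectors treated as sets.
#' @return numeric in \[0, 1\].
#' @examples
#' jaccardIndex(c("x", "y"), c("y", "z"))  # 1/3
#' @export
jaccardIndex <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Regulation edges from a binding-count matrix
#'
#' One directed TF -> biomarker edge per matrix cell with at least
#' `minCount` binding sites; the edge weight is the count.
#'
#' @param m a [BindingCountMatrix-class].
#' @param minCount minimum binding-site count for an edge (default 1).
#' @return data.frame with columns `source`, `target`, `type`
#'   (`"regulates"`), `weight`.
#' @export
buildRegulationEdges <- function(m, minCount = 1L) {
  if (minCount < 1L) stop("minCount must be >= 1")
  cts <- countMatrix(m)
  idx <- which(cts >= minCount, arr.ind = TRUE)
  df <- data.frame(source = rownames(cts)[idx[, 1L]],
                   target = colnames(cts)[idx[, 2L]],
                   type = rep("regulates", nrow(idx)),
                   weight = as.numeric(cts[idx]),
                   stringsAsFactors = FALSE)
  df[order(df$source, df$target), , drop = FALSE]
}

.pairwiseJaccardEdges <- function(sets, jaccardMin, type) {
  nms <- names(sets)
  res <- list()
  if (length(nms) >= 2L) {
    for (i in seq_len(length(nms) - 1L)) {
      for (j in (i + 1L):length(nms)) {
        if (length(sets[[i]]) == 0L && length(sets[[j]]) == 0L) next
        w <- jaccardIndex(sets[[i]], sets[[j]])
        if (w >= jaccardMin)
          res[[length(res) + 1L]] <- data.frame(
            source = nms[i], target = nms[j], type = type, weight = w,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(source = character(0L), target = character(0L),
                      type = character(0L), weight = numeric(0L),
                      stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' TF-TF co-regulation edges
#'
#' Undirected edge between two TFs whose target-gene sets (genes with at
#' least one binding site) have Jaccard similarity of at least
#' `jaccardMin`; the weight is the Jaccard value. Pairs where both target
#' sets are empty never form an edge.
#'
#' @param m a [BindingCountMatrix-class].
#' @param jaccardMin similarity threshold in \[0, 1\] (default 0.3).
#' @return edge data.frame as in [buildRegulationEdges()], type
#'   `"co_regulates"`.
#' @export
coregulationEdges <- function(m, jaccardMin = 0.3) {
  stopifnot(jaccardMin >= 0, jaccardMin <= 1)
  cts <- countMatrix(m)
  sets <- lapply(setNames(rownames(cts), rownames(cts)),
                 function(tf) colnames(cts)[cts[tf, ] >= 1])
  .pairwiseJaccardEdges(sets, jaccardMin, "co_regulates")
}

#' Biomarker-biomarker co-targeting edges
#'
#' Undirected edge between two biomarkers whose regulator sets (TFs with
#' at least one binding site in the promoter) have Jaccard similarity of
#' at least `jaccardMin`.
#'
#' @inheritParams coregulationEdges
#' @return edge data.frame, type `"co_targeted"`.
#' @export
cotargetedEdges <- function(m, jaccardMin = 0.3) {
  stopifnot(jaccardMin >= 0, jaccardMin <= 1)
  cts <- countMatrix(m)
  sets <- lapply(setNames(colnames(cts), colnames(cts)),
                 function(g) rownames(cts)[cts[, g] >= 1])
  .pairwiseJaccardEdges(sets, jaccardMin, "co_targeted")
}

#' Build the TF-biomarker regulome network
#'
#' Assembles the typed graph: `regulates` edges (TF -> biomarker, weight =
#' binding count), `co_regulates` edges (TF - TF) and `co_targeted` edges
#' (biomarker - biomarker), both weighted by Jaccard similarity. Node
#' attributes carry the TF family, the biomarker pathway membership, and
#' (when differential-expression results are supplied) the significance
#' flag and fold change.
#'
#' @param m a [BindingCountMatrix-class].
#' @param pmap optional [PathwayMap-class] used to annotate biomarker
#'   nodes.
#' @param deResults optional data.frame from [differentialExpression()].
#' @param familyOf optional named character vector TF -> family.
#' @param minCount minimum count for a `regulates` edge (default 1).
#' @param jaccardMin Jaccard threshold for the similarity edges
#'   (default 0.3).
#' @return a [RegulomeNetwork-class].
#' @export
buildRegulomeNetwork <- function(m, pmap = NULL, deResults = NULL,
                                 familyOf = NULL, minCount = 1L,
                                 jaccardMin = 0.3) {
  tfs <- tfNames(m); genes <- geneNames(m)
  edges <- rbind(buildRegulationEdges(m, minCount),
                 coregulationEdges(m, jaccardMin),
                 cotargetedEdges(m, jaccardMin))
  nodes <- data.frame(name = c(tfs, genes),
                      nodeType = c(rep("TF", length(tfs)),
                                   rep("biomarker", length(genes))),
                      stringsAsFactors = FALSE)
  nodes$family <- ""
  if (!is.null(familyOf))
    nodes$family[match(intersect(tfs, names(familyOf)), nodes$name)] <-
      familyOf[intersect(tfs, names(familyOf))]
  nodes$pathways <- ""
  if (!is.null(pmap)) {
    pw <- vapply(genes, function(g) {
      paste(pathwayNames(pmap)[vapply(pathwayGenes(pmap),
                                      function(s) g %in% s, logical(1L))],
            collapse = ";")
    }, character(1L))
    nodes$pathways[match(genes, nodes$name)] <- pw
  }
  nodes$deSignificant <- FALSE
  nodes$foldChange <- NA_real_
  if (!is.null(deResults)) {
    i <- match(nodes$name, deResults$gene_id)
    hit <- !is.na(i)
    nodes$deSignificant[hit] <- deResults$significant[i[hit]]
    nodes$foldChange[hit] <- deResults$fold_change[i[hit]]
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  new("RegulomeNetwork", graph = g)
}

#' @rdname RegulomeNetwork-class
#' @export
setMethod("networkGraph", "RegulomeNetwork", function(object) object@graph)

setMethod("show", "RegulomeNetwork", function(object) {
  g <- object@graph
  et <- igraph::edge_attr(g, "type")
  cat(sprintf("RegulomeNetwork: %d nodes (%d TFs, %d biomarkers), %d edges\n",
              igraph::vcount(g),
              sum(igraph::vertex_attr(g, "nodeType") == "TF"),
              sum(igraph::vertex_attr(g, "nodeType") == "biomarker"),
              igraph::ecount(g)))
  for (tp in c("regulates", "co_regulates", "co_targeted"))
    cat(sprintf("  %-13s %d\n", tp, sum(et == tp)))
})

#' Extract multi-pathway biomarker modules
#'
#' Modules are the connected components of the biomarker-side graph in
#' which two biomarkers are linked if they share a `co_targeted` edge or a
#' common regulating TF (a shared `regulates` neighbor). Isolated
#' biomarkers form no module. Each module is annotated with the pathways
#' its members belong to and with the TFs regulating at least half of its
#' members. Modules are ordered by decreasing size, ties broken by the
#' lexicographically smallest member.
#'
#' @param net a [RegulomeNetwork-class].
#' @return list of modules; each module is a list with `members`
#'   (sorted biomarker ids), `pathways` (sorted pathway names) and
#'   `regulators` (TFs regulating >= half the members).
#' @export
extractModules <- function(net) {
  g <- net@graph
  type <- igraph::vertex_attr(g, "nodeType")
  bios <- igraph::V(g)$name[type == "biomarker"]
  if (!length(bios)) return(list())
  et <- igraph::edge_attr(g, "type")
  ends <- igraph::as_edgelist(g)
  # regulator sets from regulates edges
  reg <- ends[et == "regulates", , drop = FALSE]
  regOf <- split(reg[, 1L], factor(reg[, 2L], levels = bios))
  # biomarker-biomarker adjacency: co_targeted or shared regulator
  adj <- matrix(FALSE, length(bios), length(bios),
                dimnames = list(bios, bios))
  ct <- ends[et == "co_targeted", , drop = FALSE]
  if (nrow(ct)) {
    adj[ct] <- TRUE
    adj[ct[, c(2L, 1L), drop = FALSE]] <- TRUE
  }
  if (length(bios) >= 2L) {
    for (i in seq_len(length(bios) - 1L)) {
      for (j in (i + 1L):length(bios)) {
        if (length(intersect(regOf[[i]], regOf[[j]])))
          adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  keep <- rowSums(adj) > 0
  if (!any(keep)) return(list())
  sub <- igraph::graph_from_adjacency_matrix(adj[keep, keep, drop = FALSE],
                                             mode = "undirected")
  comp <- igraph::components(sub)
  pathOf <- setNames(igraph::vertex_attr(g, "pathways"), igraph::V(g)$name)
  mods <- lapply(seq_len(comp$no), function(k) {
    members <- sort(names(comp$membership)[comp$membership == k])
    pws <- sort(unique(unlist(strsplit(pathOf[members], ";", fixed = TRUE))))
    pws <- pws[nzchar(pws)]
    regCount <- table(unlist(regOf[members]))
    regulators <- sort(names(regCount)[regCount >= length(members) / 2])
    list(members = members, pathways = pws, regulators = regulators)
  })
  ord <- order(-vapply(mods, function(m) length(m$members), integer(1L)),
               vapply(mods, function(m) m$members[1L], character(1L)))
  mods[ord]
}

#' Export / import a regulome network
#'
#' GraphML (via igraph) or a flat TSV with columns `source`, `target`,
#' `type`, `weight`; in the TSV form every node is written as its own row
#' (`type` `"node"`, attributes packed into `target` as
#' `nodeType|family|pathways`) so isolated nodes survive a round trip.
#' Export followed by import preserves nodes, edge types and weights
#' (weights to 1e-9).
#'
#' @param net a [RegulomeNetwork-class].
#' @param path output file.
#' @param format `"graphml"` or `"edge-tsv"`.
#' @return `path` invisibly; `importGraph()` returns a
#'   [RegulomeNetwork-class].
#' @export
exportGraph <- function(net, path, format = c("graphml", "edge-tsv")) {
  format <- match.arg(format)
  g <- net@graph
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  nodes <- data.frame(
    source = igraph::V(g)$name,
    target = paste(igraph::vertex_attr(g, "nodeType"),
                   igraph::vertex_attr(g, "family"),
                   igraph::vertex_attr(g, "pathways"), sep = "|"),
    type = "node", weight = NA_real_, stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(source = el[, 1L], target = el[, 2L],
                      type = igraph::edge_attr(g, "type"),
                      weight = igraph::edge_attr(g, "weight"),
                      stringsAsFactors = FALSE)
  write.table(rbind(nodes, edges), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname exportGraph
#' @export
importGraph <- function(path, format = c("graphml", "edge-tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(new("RegulomeNetwork", graph = g))
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  nd <- df[df$type == "node", , drop = FALSE]
  attrs <- t(vapply(strsplit(nd$target, "|", fixed = TRUE), function(v) {
    length(v) <- 3L
    ifelse(is.na(v), "", v)
  }, character(3L)))
  nodes <- data.frame(name = nd$source, nodeType = attrs[, 1L],
                      family = attrs[, 2L], pathways = attrs[, 3L],
                      stringsAsFactors = FALSE)
  edges <- df[df$type != "node", c("source", "target", "type", "weight"),
              drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  new("RegulomeNetwork", graph = g)
}
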