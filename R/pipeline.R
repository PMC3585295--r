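#' Pipeline configuration
#'
#' Holds the input paths, thresholds, flags and seed of a full regulome
#' run. A configuration round-trips unchanged through its YAML
#' serialization ([writePipelineConfig()] / [readPipelineConfig()]).
#'
#' @slot promoters,pfms,metadata,pathways,expression,groups,protein input
#'   file paths (`protein`, `expression`, `groups` may be empty strings to
#'   skip those stages).
#' @slot cssMin,mssMin scanner similarity thresholds.
#' @slot alpha differential-expression significance level.
#' @slot minEvidence minimum experimental evidence count for a matrix.
#' @slot minCount minimum binding count for a regulation edge.
#' @slot jaccardMin Jaccard threshold for similarity edges.
#' @slot log2Transform log2-transform expression values before testing.
#' @slot bhCorrection apply Benjamini-Hochberg correction in the DE stage.
#' @slot mergeOverlaps merge overlapping same-TF scanner hits.
#' @slot seed integer seed recorded with the run.
#' @slot outputDir directory for stage outputs.
#' @seealso [pipelineConfig()], [runPipeline()].
#' @name PipelineConfig-class
#' @rdname PipelineConfig-class
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(
    promoters = "character", pfms = "character", metadata = "character",
    pathways = "character", expression = "character", groups = "character",
    protein = "character",
    cssMin = "numeric", mssMin = "numeric", alpha = "numeric",
    minEvidence = "integer", minCount = "integer", jaccardMin = "numeric",
    log2Transform = "logical", bhCorrection = "logical",
    mergeOverlaps = "logical",
    seed = "integer", outputDir = "character"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  inRange <- function(x, lo, hi) length(x) == 1L && !is.na(x) &&
    x >= lo && x <= hi
  if (!inRange(object@cssMin, 0, 1)) msg <- c(msg, "cssMin must be in [0,1]")
  if (!inRange(object@mssMin, 0, 1)) msg <- c(msg, "mssMin must be in [0,1]")
  if (!inRange(object@alpha, 0, 1)) msg <- c(msg, "alpha must be in [0,1]")
  if (!inRange(object@jaccardMin, 0, 1))
    msg <- c(msg, "jaccardMin must be in [0,1]")
  if (object@minEvidence < 0L) msg <- c(msg, "minEvidence must be >= 0")
  if (object@minCount < 1L) msg <- c(msg, "minCount must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname PipelineConfig-class
#' @param promoters,pfms,metadata,pathways,expression,groups,protein input
#'   file paths ("" skips the optional expression / protein stages).
#' @param cssMin,mssMin,alpha,minEvidence,minCount,jaccardMin thresholds
#'   (defaults 0.75, 0.85, 0.05, 2, 1, 0.3).
#' @param log2Transform,bhCorrection,mergeOverlaps stage flags (defaults
#'   TRUE, FALSE, FALSE).
#' @param seed integer seed recorded with the run (default 1).
#' @param outputDir output directory (default `"regulome_out"`).
#' @export
pipelineConfig <- function(promoters, pfms, metadata = "", pathways = "",
                           expression = "", groups = "", protein = "",
                           cssMin = 0.75, mssMin = 0.85, alpha = 0.05,
                           minEvidence = 2L, minCount = 1L, jaccardMin = 0.3,
                           log2Transform = TRUE, bhCorrection = FALSE,
                           mergeOverlaps = FALSE, seed = 1L,
                           outputDir = "regulome_out") {
  new("PipelineConfig",
      promoters = promoters, pfms = pfms, metadata = metadata,
      pathways = pathways, expression = expression, groups = groups,
      protein = protein, cssMin = cssMin, mssMin = mssMin, alpha = alpha,
      minEvidence = as.integer(minEvidence), minCount = as.integer(minCount),
      jaccardMin = jaccardMin, log2Transform = log2Transform,
      bhCorrection = bhCorrection, mergeOverlaps = mergeOverlaps,
      seed = as.integer(seed), outputDir = outputDir)
}

.configSlots <- c("promoters", "pfms", "metadata", "pathways", "expression",
                  "groups", "protein", "cssMin", "mssMin", "alpha",
                  "minEvidence", "minCount", "jaccardMin", "log2Transform",
                  "bhCorrection", "mergeOverlaps", "seed", "outputDir")

#' Read / write a pipeline configuration as YAML
#'
#' @param cfg a [PipelineConfig-class].
#' @param path YAML file path.
#' @return `readPipelineConfig()` returns a [PipelineConfig-class];
#'   `writePipelineConfig()` returns `path` invisibly.
#' @export
writePipelineConfig <- function(cfg, path) {
  obj <- lapply(setNames(.configSlots, .configSlots),
                function(s) slot(cfg, s))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(pipelineConfig, obj[intersect(names(obj), .configSlots)])
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  for (s in .configSlots)
    cat(sprintf("  %-14s %s\n", s, paste(slot(object, s), collapse = " ")))
})

.stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full regulome pipeline
#'
#' Executes the workflow: matrix-library load and evidence filter,
#' both-strand promoter scan, binding-count matrix, regulome summary
#' (core / specific / combinatorial TFs), optional expression stage
#' (quantile normalization, per-gene Welch tests, expressed-TF filter and
#' an expressed-only count matrix), optional protein fold-change stage,
#' then the TF-biomarker network and its multi-pathway modules. Every
#' stage logs its input and output dimensions; stage outputs are written
#' under `outputDir(cfg)` together with a `MANIFEST` marking which stages
#' completed, and a single `report.json`.
#'
#' @param cfg a [PipelineConfig-class].
#' @return the report, invisibly: a named list with elements
#'   `n_tfs_scanned`, `core_by_gene`, `core_by_pathway`, `signatures`,
#'   `groups`, `tf_totals`, `family_totals`, `de_table` (when expression
#'   inputs are configured), `expressed_tfs`, `protein_fold_changes`,
#'   `modules` and `seed`.
#' @export
runPipeline <- function(cfg) {
  validObject(cfg)
  outDir <- cfg@outputDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  completed <- character(0L)
  manifest <- file.path(outDir, "MANIFEST")
  mark <- function(stage) {
    completed <<- c(completed, stage)
    writeLines(completed, manifest)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  report <- list(seed = cfg@seed)

  ## ---- load + evidence filter -------------------------------------------
  pfms <- stage("load_matrices", {
    md <- if (nzchar(cfg@metadata)) readTFMetadata(cfg@metadata) else NULL
    readJasparPfms(cfg@pfms, metadata = md)
  })
  promoters <- stage("load_promoters", readPromoters(cfg@promoters))
  pmap <- stage("load_pathways", readGmt(cfg@pathways))
  .stageLog("load", "%d matrices, %d promoters, %d pathways; seed %d",
            length(pfms), length(promoters), length(pmap), cfg@seed)
  kept <- stage("evidence_filter", filterByEvidence(pfms, cfg@minEvidence))
  .stageLog("evidence_filter", "%d of %d matrices kept (evidence >= %d)",
            length(kept), length(pfms), cfg@minEvidence)
  if (!length(kept))
    stop("pipeline stage 'evidence_filter' failed: no matrix passes the ",
         "evidence threshold", call. = FALSE)
  mark("evidence_filter")

  ## ---- scan + count matrix ----------------------------------------------
  hits <- stage("scan", scanPromoters(promoters, kept, cfg@cssMin,
                                      cfg@mssMin,
                                      mergeOverlaps = cfg@mergeOverlaps))
  .stageLog("scan", "%d hits at css >= %.2f, mss >= %.2f", nrow(hits),
            cfg@cssMin, cfg@mssMin)
  bcm <- stage("count_matrix",
               buildCountMatrix(hits, names(kept), names(promoters)))
  writeHits(hits, file.path(outDir, "hits.tsv"))
  writeCountMatrix(bcm, file.path(outDir, "count_matrix.tsv"))
  mark("scan")

  ## ---- regulome summary -------------------------------------------------
  familyOf <- vapply(kept, tfFamily, character(1L))
  rs <- stage("regulome", regulomeSummary(bcm, pmap, familyOf))
  writeRegulomeSummary(rs, file.path(outDir, "regulome_summary.json"))
  .stageLog("regulome", "core by gene: %d; core by pathway: %d; groups: %d",
            length(rs@coreByGene), length(rs@coreByPathway),
            length(rs@groups))
  report$n_tfs_scanned <- length(kept)
  report$core_by_gene <- rs@coreByGene
  report$core_by_pathway <- rs@coreByPathway
  report$signatures <- rs@signatures
  report$groups <- rs@groups
  report$tf_totals <- as.list(rs@tfTotals)
  report$family_totals <- as.list(rs@familyTotals)
  mark("regulome")

  ## ---- expression stage (optional) --------------------------------------
  netMatrix <- bcm
  report$expressed_tfs <- character(0L)
  if (nzchar(cfg@expression)) {
    de <- stage("expression", {
      x <- readExpressionMatrix(cfg@expression)
      groupOf <- readGroups(cfg@groups)
      if (cfg@log2Transform) {
        if (any(x <= 0))
          stop("log2 transform requires strictly positive values")
        x <- log2(x)
      }
      x <- quantileNormalize(x)
      differentialExpression(x, groupOf, alpha = cfg@alpha,
                             bhCorrection = cfg@bhCorrection)
    })
    write.table(de, file.path(outDir, "de_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ef <- expressedTfFilter(names(kept), de, alpha = cfg@alpha)
    .stageLog("expression",
              "%d genes tested; %d of %d scanned TFs expressed (%d not assayed)",
              nrow(de), length(ef$expressed), length(kept),
              length(ef$notAssayed))
    report$de_table <- de
    report$expressed_tfs <- ef$expressed
    report$not_assayed_tfs <- ef$notAssayed
    if (length(ef$expressed)) {
      netMatrix <- bindingCountMatrix(
        countMatrix(bcm)[ef$expressed, , drop = FALSE])
      writeCountMatrix(netMatrix,
                       file.path(outDir, "count_matrix_expressed.tsv"))
      rsx <- regulomeSummary(netMatrix, pmap, familyOf)
      report$core_by_pathway_expressed <- rsx@coreByPathway
    }
    mark("expression")
  }

  ## ---- protein fold changes (optional) ----------------------------------
  if (nzchar(cfg@protein)) {
    fc <- stage("protein", {
      p <- readExpressionMatrix(cfg@protein)
      groupOf <- readGroups(cfg@groups)
      grp <- groupOf[colnames(p)]
      vapply(rownames(p), function(b)
        foldChange(p[b, grp == "case"], p[b, grp == "control"])$ratio,
        numeric(1L))
    })
    report$protein_fold_changes <- as.list(fc)
    .stageLog("protein", "fold changes for %d biomarkers", length(fc))
    mark("protein")
  }

  ## ---- network + modules ------------------------------------------------
  net <- stage("network",
               buildRegulomeNetwork(netMatrix, pmap,
                                    deResults = report$de_table,
                                    familyOf = familyOf,
                                    minCount = cfg@minCount,
                                    jaccardMin = cfg@jaccardMin))
  exportGraph(net, file.path(outDir, "network.graphml"), "graphml")
  exportGraph(net, file.path(outDir, "network_edges.tsv"), "edge-tsv")
  mods <- stage("modules", extractModules(net))
  .stageLog("network", "%d nodes, %d edges, %d modules",
            igraph::vcount(networkGraph(net)),
            igraph::ecount(networkGraph(net)), length(mods))
  report$modules <- mods
  mark("network")

  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  mark("report")
  invisible(report)
}
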