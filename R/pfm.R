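#' Construct a position frequency matrix
#'
#' Builds a [PositionFrequencyMatrix-class] from per-position nucleotide
#' counts (or frequencies; the scale is irrelevant because scoring uses
#' normalized per-position frequencies).
#'
#' @param tfId unique matrix identifier.
#' @param counts numeric L x 4 matrix over columns A, C, G, T (column names
#'   optional; the A,C,G,T order is assumed); L >= 4. Every position must
#'   have a strictly positive total.
#' @param tfName transcription factor name (defaults to `tfId`).
#' @param family matrix family label.
#' @param evidenceCount non-negative integer, number of experimental
#'   evidence records supporting the matrix.
#' @return a [PositionFrequencyMatrix-class].
#' @examples
#' pfm <- PFM("T1", matrix(c(10, 0, 0, 0,
#'                           0, 10, 0, 0,
#'                           0, 0, 10, 0,
#'                           0, 0, 0, 10), 4, 4, byrow = TRUE))
#' consensusSequence(pfm)  # "ACGT"
#' @export
PFM <- function(tfId, counts, tfName = tfId, family = "unassigned",
                evidenceCount = 2L) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  colnames(counts) <- DNA_BASES
  rownames(counts) <- NULL
  new("PositionFrequencyMatrix",
      tfId = as.character(tfId), tfName = as.character(tfName),
      family = as.character(family),
      evidenceCount = as.integer(evidenceCount), counts = counts)
}

#' @rdname PositionFrequencyMatrix-class
#' @export
setMethod("tfId", "PositionFrequencyMatrix", function(object) object@tfId)

#' @rdname PositionFrequencyMatrix-class
#' @export
setMethod("tfName", "PositionFrequencyMatrix", function(object) object@tfName)

#' @rdname PositionFrequencyMatrix-class
#' @export
setMethod("tfFamily", "PositionFrequencyMatrix", function(object) object@family)

#' @rdname PositionFrequencyMatrix-class
#' @export
setMethod("evidenceCount", "PositionFrequencyMatrix",
          function(object) object@evidenceCount)

#' @rdname PositionFrequencyMatrix-class
#' @export
setMethod("matrixLength", "PositionFrequencyMatrix",
          function(object) nrow(object@counts))

#' @rdname PositionFrequencyMatrix-class
#' @param pseudocount scalar added to every count before normalization
#'   (default 0).
#' @param ... passed on to methods.
#' @export
setMethod("baseFrequencies", "PositionFrequencyMatrix",
  function(object, pseudocount = 0) {
    cts <- object@counts + pseudocount
    cts / rowSums(cts)
  })

#' @rdname PositionFrequencyMatrix-class
#' @export
setMethod("consensusSequence", "PositionFrequencyMatrix", function(object) {
  paste(DNA_BASES[apply(object@counts, 1L, which.max)], collapse = "")
})

setMethod("show", "PositionFrequencyMatrix", function(object) {
  cat(sprintf("PositionFrequencyMatrix %s (%s), family %s, L = %d, evidence = %d\n",
              object@tfId, object@tfName, object@family,
              nrow(object@counts), object@evidenceCount))
  cat("  consensus:", consensusSequence(object), "\n")
})

#' Read a JASPAR-style PFM file
#'
#' Parses a plain-text matrix file with one or more records of the form
#' \preformatted{
#' >ID NAME
#' A [ 3 10 0 ... ]
#' C [ 2  0 9 ... ]
#' G [ 0  0 1 ... ]
#' T [ 5  0 0 ... ]
#' }
#' The bracketed form without base letters and the bare whitespace-separated
#' form are also accepted. An optional metadata table supplies the family
#' and evidence-count annotation used downstream.
#'
#' @param path path to the matrix file.
#' @param metadata optional data.frame with columns `tf_id`, `family`,
#'   `evidence_count` (see [readTFMetadata()]).
#' @return list of [PositionFrequencyMatrix-class] objects, named by id.
#' @seealso [writeJasparPfms()], [filterByEvidence()]
#' @export
readJasparPfms <- function(path, metadata = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  if (!length(headers)) stop("no '>' record headers found in ", path)
  out <- list()
  bounds <- c(headers, length(lines) + 1L)
  for (k in seq_along(headers)) {
    hdr <- sub("^>\\s*", "", lines[headers[k]])
    toks <- strsplit(hdr, "\\s+")[[1L]]
    id <- toks[1L]
    name <- if (length(toks) > 1L) paste(toks[-1L], collapse = " ") else id
    body <- lines[(headers[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(body) != 4L)
      stop("record ", id, ": expected 4 base rows, found ", length(body))
    rows <- lapply(body, function(ln) {
      ln <- sub("^[ACGTacgt]\\s*", "", ln)
      ln <- gsub("[\\[\\]]", " ", ln, perl = TRUE)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1L]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("record ", id, ": base rows have unequal lengths")
    counts <- t(do.call(rbind, rows))  # L x 4, rows were A,C,G,T
    fam <- "unassigned"
    ev <- 2L
    if (!is.null(metadata)) {
      i <- match(id, metadata$tf_id)
      if (!is.na(i)) {
        fam <- as.character(metadata$family[i])
        ev <- as.integer(metadata$evidence_count[i])
      }
    }
    out[[id]] <- PFM(id, counts, tfName = name, family = fam,
                     evidenceCount = ev)
  }
  out
}

#' Write PFMs in JASPAR text format
#'
#' @param pfms list of [PositionFrequencyMatrix-class] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeJasparPfms <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    writeLines(sprintf(">%s %s", tfId(p), tfName(p)), con)
    cts <- p@counts
    for (b in seq_len(4L)) {
      writeLines(sprintf("%s [ %s ]", DNA_BASES[b],
                         paste(sprintf("%.15g", cts[, b]), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read / write the TF metadata sidecar
#'
#' Tab-separated table with columns `tf_id`, `family`, `evidence_count`.
#'
#' @param path file path.
#' @return data.frame with the three columns.
#' @export
readTFMetadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("tf_id", "family", "evidence_count")
  if (!all(need %in% names(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  md$evidence_count <- as.integer(md$evidence_count)
  md
}

#' @rdname readTFMetadata
#' @param pfms list of [PositionFrequencyMatrix-class] objects.
#' @export
writeTFMetadata <- function(pfms, path) {
  md <- data.frame(
    tf_id = vapply(pfms, tfId, character(1L)),
    family = vapply(pfms, tfFamily, character(1L)),
    evidence_count = vapply(pfms, evidenceCount, integer(1L))
  )
  write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter matrices by experimental evidence
#'
#' Keeps transcription factor matrices supported by at least `minEvidence`
#' experimental evidence records. The regulome workflow retains TFs with
#' experimental evidence of more than one record, i.e. `minEvidence = 2`.
#'
#' @param pfms list of [PositionFrequencyMatrix-class] objects.
#' @param minEvidence minimum evidence count to keep (default 2, i.e.
#'   "more than one" evidence record).
#' @return the retained sublist, names preserved.
#' @examples
#' lib <- generatePwmLibrary(nTfs = 6, nFamilies = 3, seed = 1)
#' length(filterByEvidence(lib$pfms, minEvidence = 0))  # identity
#' @export
filterByEvidence <- function(pfms, minEvidence = 2L) {
  stopifnot(minEvidence >= 0L)
  keep <- vapply(pfms, function(p) evidenceCount(p) >= minEvidence, logical(1L))
  pfms[keep]
}
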