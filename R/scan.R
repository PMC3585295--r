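#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()];
#' `N` maps to `N`. Characters outside `{A,C,G,T,N}` are rejected.
#'
#' @param seq a single DNA string.
#' @return the reverse-complemented string.
#' @examples
#' revComp("ACGT")  # "ACGT"
#' revComp("AAAN") # "NTTT"
#' @export
revComp <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bad <- !(v %in% c(DNA_BASES, "N"))
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(v[bad]), collapse = ", "))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Scores of every window of length L along an encoded sequence, for one
# strand. Numerator and denominator are accumulated position-by-position in
# the same order so a consensus window scores exactly 1.
.strandScores <- function(sm, code) {
  L <- matrixLength(sm)
  n <- length(code) - L + 1L
  if (n < 1L)
    return(list(mss = numeric(0L), css = numeric(0L)))
  ci <- sm@ci
  fMax <- sm@fMax
  inCore <- seq_len(L) %in% sm@core
  numAll <- numeric(n); denAll <- 0
  numCore <- numeric(n); denCore <- 0
  starts <- seq_len(n)
  for (i in seq_len(L)) {
    fi <- sm@freq[i, code[starts + i - 1L]]
    fi[is.na(fi)] <- 0
    numAll <- numAll + ci[i] * fi
    denAll <- denAll + ci[i] * fMax[i]
    if (inCore[i]) {
      numCore <- numCore + ci[i] * fi
      denCore <- denCore + ci[i] * fMax[i]
    }
  }
  list(mss = if (denAll == 0) rep(1, n) else numAll / denAll,
       css = if (denCore == 0) rep(1, n) else numCore / denCore)
}

.emptyHits <- function() {
  data.frame(gene_id = character(0L), start = integer(0L), end = integer(0L),
             strand = character(0L), tf_id = character(0L),
             core_sim = numeric(0L), matrix_sim = numeric(0L),
             stringsAsFactors = FALSE)
}

#' Scan one promoter with one scoring matrix
#'
#' Slides a window of the matrix length along the forward strand and along
#' the reverse complement of the promoter; every window position on each
#' strand is scored independently (no overlap suppression). A binding-site
#' hit is emitted where the core similarity reaches `cssMin` and the matrix
#' similarity reaches `mssMin`. Reverse-strand hits are reported in forward
#' coordinates (0-based, half-open, BED convention) with strand `"-"`.
#'
#' @param seq promoter sequence (single DNA string over A,C,G,T,N).
#' @param sm a [ScoringMatrix-class].
#' @param cssMin core-similarity threshold in \[0, 1\] (default 0.75).
#' @param mssMin matrix-similarity threshold in \[0, 1\] (default 0.85).
#' @param geneId gene identifier recorded with each hit.
#' @return data.frame with columns `gene_id`, `start`, `end`, `strand`,
#'   `tf_id`, `core_sim`, `matrix_sim`, sorted by (start, strand). A
#'   promoter shorter than the matrix yields zero rows.
#' @seealso [scanPromoters()] for a whole promoter set against a matrix
#'   library; [buildCountMatrix()] to tally hits.
#' @export
scanPromoter <- function(seq, sm, cssMin = 0.75, mssMin = 0.85, geneId = "gene") {
  if (!is.numeric(cssMin) || cssMin < 0 || cssMin > 1 ||
      !is.numeric(mssMin) || mssMin < 0 || mssMin > 1)
    stop("thresholds must lie in [0, 1]")
  L <- matrixLength(sm)
  slen <- nchar(seq)
  if (slen < L) return(.emptyHits())
  fwd <- .encodeDNA(seq)
  rev <- .encodeDNA(revComp(seq))
  sf <- .strandScores(sm, fwd)
  sr <- .strandScores(sm, rev)
  keepF <- which(sf$css >= cssMin & sf$mss >= mssMin)
  keepR <- which(sr$css >= cssMin & sr$mss >= mssMin)
  hits <- rbind(
    if (length(keepF))
      data.frame(gene_id = geneId, start = keepF - 1L, end = keepF - 1L + L,
                 strand = "+", tf_id = tfId(sm), core_sim = sf$css[keepF],
                 matrix_sim = sf$mss[keepF], stringsAsFactors = FALSE),
    if (length(keepR))
      data.frame(gene_id = geneId, start = slen - (keepR - 1L) - L,
                 end = slen - (keepR - 1L), strand = "-", tf_id = tfId(sm),
                 core_sim = sr$css[keepR], matrix_sim = sr$mss[keepR],
                 stringsAsFactors = FALSE)
  )
  if (is.null(hits)) return(.emptyHits())
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Merge overlapping same-TF hits
#'
#' Optional post-processing of a hit table: within each (gene, TF) pair,
#' hits whose intervals overlap (on either strand) are clustered and only
#' the best-scoring hit of each cluster is kept (highest matrix
#' similarity; ties resolved by leftmost start, then `"+"` strand). Off by
#' default in the scanner, since binding-site counting conventionally
#' counts every match.
#'
#' @param hits hit data.frame from [scanPromoter()] / [scanPromoters()].
#' @return the reduced hit data.frame, sorted by (gene, start, strand).
#' @export
mergeOverlappingHits <- function(hits) {
  if (!nrow(hits)) return(hits)
  keyOf <- paste(hits$gene_id, hits$tf_id, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(hits)), keyOf), function(idx) {
    h <- hits[idx, , drop = FALSE]
    ord <- order(h$start, h$strand)
    h <- h[ord, ]; idx <- idx[ord]
    cluster <- cumsum(c(1L, as.integer(h$start[-1L] >=
                                         cummax(h$end[-nrow(h)]))))
    vapply(split(seq_along(idx), cluster), function(ci) {
      hc <- h[ci, , drop = FALSE]
      best <- order(-hc$matrix_sim, hc$start, hc$strand)[1L]
      idx[ci[best]]
    }, integer(1L))
  }), use.names = FALSE)
  out <- hits[sort(keep), , drop = FALSE]
  out <- out[order(out$gene_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a promoter set against a matrix library
#'
#' @param promoters a named character vector or
#'   [Biostrings::DNAStringSet-class]; names are the gene ids.
#' @param sms list of [ScoringMatrix-class] objects (or
#'   [PositionFrequencyMatrix-class] objects, which are converted with
#'   default settings).
#' @param cssMin,mssMin similarity thresholds, as in [scanPromoter()].
#' @param mergeOverlaps drop overlapping same-TF hits, keeping the best
#'   per cluster (default FALSE; see [mergeOverlappingHits()]).
#' @return one hit data.frame (see [scanPromoter()]) over all
#'   (promoter, matrix) pairs.
#' @export
scanPromoters <- function(promoters, sms, cssMin = 0.75, mssMin = 0.85,
                          mergeOverlaps = FALSE) {
  if (methods::is(promoters, "DNAStringSet"))
    promoters <- setNames(as.character(promoters), names(promoters))
  if (is.null(names(promoters)) || any(!nzchar(names(promoters))))
    stop("promoters must be named by gene id")
  sms <- lapply(sms, function(s)
    if (methods::is(s, "ScoringMatrix")) s else scoringMatrix(s))
  res <- list()
  for (g in names(promoters)) {
    for (s in sms) {
      res[[length(res) + 1L]] <-
        scanPromoter(promoters[[g]], s, cssMin, mssMin, geneId = g)
    }
  }
  out <- do.call(rbind, c(res, list(.emptyHits())))
  rownames(out) <- NULL
  if (mergeOverlaps) out <- mergeOverlappingHits(out)
  out
}

#' Tally motif hits into a binding-count matrix
#'
#' @param hits hit data.frame from [scanPromoter()] / [scanPromoters()].
#' @param tfs ordered character vector of TF ids (matrix rows).
#' @param genes ordered character vector of gene ids (matrix columns).
#' @return a [BindingCountMatrix-class]; the matrix total equals
#'   `nrow(hits)`.
#' @export
buildCountMatrix <- function(hits, tfs, genes) {
  badT <- setdiff(unique(hits$tf_id), tfs)
  if (length(badT))
    stop("hits reference unknown TF id(s): ", paste(badT, collapse = ", "))
  badG <- setdiff(unique(hits$gene_id), genes)
  if (length(badG))
    stop("hits reference unknown gene id(s): ", paste(badG, collapse = ", "))
  tab <- table(factor(hits$tf_id, levels = tfs),
               factor(hits$gene_id, levels = genes))
  m <- matrix(as.integer(tab), nrow = length(tfs),
              dimnames = list(tfs, genes))
  bindingCountMatrix(m)
}

#' Construct a binding-count matrix
#'
#' @param counts integer TF x gene matrix with row and column names.
#' @return a [BindingCountMatrix-class].
#' @export
bindingCountMatrix <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  new("BindingCountMatrix", counts = counts)
}

#' @rdname BindingCountMatrix-class
#' @export
setMethod("countMatrix", "BindingCountMatrix", function(object) object@counts)

#' @rdname BindingCountMatrix-class
#' @export
setMethod("tfNames", "BindingCountMatrix",
          function(object) rownames(object@counts))

#' @rdname BindingCountMatrix-class
#' @export
setMethod("geneNames", "BindingCountMatrix",
          function(object) colnames(object@counts))

#' @rdname BindingCountMatrix-class
#' @export
setMethod("dim", "BindingCountMatrix", function(x) dim(x@counts))

setMethod("show", "BindingCountMatrix", function(object) {
  cat(sprintf("BindingCountMatrix: %d TFs x %d genes, %d binding sites\n",
              nrow(object@counts), ncol(object@counts), sum(object@counts)))
})

#' Hit and count-matrix TSV I/O
#'
#' `writeHits()`/`readHits()` exchange the BED-like hit table;
#' `writeCountMatrix()`/`readCountMatrix()` exchange the TF x gene count
#' matrix (TFs as rows), the tabular form commonly fed to matrix heatmap
#' tools.
#'
#' @param hits hit data.frame.
#' @param path file path.
#' @return the read object, or `path` invisibly for writers.
#' @export
writeHits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHits
#' @export
readHits <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname writeHits
#' @param m a [BindingCountMatrix-class].
#' @export
writeCountMatrix <- function(m, path) {
  df <- data.frame(tf_id = tfNames(m), countMatrix(m), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHits
#' @export
readCountMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  bindingCountMatrix(m)
}
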