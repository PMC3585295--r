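#' Per-position conservation (information) vector
#'
#' For each matrix position the conservation value
#' \deqn{ci(i) = \frac{100}{\ln 4}\left(\sum_b f(b,i)\ln f(b,i) + \ln 4\right)}
#' with the convention \eqn{0 \ln 0 = 0}. A uniformly distributed position
#' scores 0; a position occupied by a single base scores 100. The vector
#' weights the per-position contributions of [matrixSimilarity()] so that
#' mismatches at conserved positions are penalized most.
#'
#' @param pfm a [PositionFrequencyMatrix-class].
#' @param pseudocount optional scalar added to counts before normalization
#'   (default 0).
#' @return numeric vector of length L with values in \[0, 100\].
#' @examples
#' pfm <- PFM("T1", matrix(c(1, 1, 1, 1,
#'                           4, 0, 0, 0,
#'                           2, 2, 0, 0,
#'                           0, 0, 0, 9), 4, 4, byrow = TRUE))
#' informationVector(pfm)  # 0, 100, 50, 100
#' @export
informationVector <- function(pfm, pseudocount = 0) {
  f <- baseFrequencies(pfm, pseudocount = pseudocount)
  plogp <- ifelse(f > 0, f * log(f), 0)
  ci <- (100 / log(4)) * (rowSums(plogp) + log(4))
  pmin(pmax(ci, 0), 100)
}

#' Most conserved contiguous window of a matrix
#'
#' Returns the 1-based indices of the contiguous window of `nCore`
#' positions maximizing the summed conservation values; ties are broken by
#' the leftmost start, making the core deterministic.
#'
#' @param ci numeric conservation vector (see [informationVector()]).
#' @param nCore window width, `1 <= nCore <= length(ci)` (default 4).
#' @return integer vector of `nCore` consecutive indices.
#' @export
corePositions <- function(ci, nCore = 4L) {
  L <- length(ci)
  nCore <- as.integer(nCore)
  if (nCore < 1L || nCore > L)
    stop("nCore must be between 1 and the matrix length (", L, ")")
  sums <- vapply(seq_len(L - nCore + 1L),
                 function(s) sum(ci[s:(s + nCore - 1L)]), numeric(1L))
  best <- which.max(sums)  # which.max is leftmost on ties
  seq.int(best, best + nCore - 1L)
}

#' Build a scoring matrix from a PFM
#'
#' Derives the conservation vector, per-position maximum frequency and the
#' core window, producing the [ScoringMatrix-class] consumed by
#' [matrixSimilarity()] and [scanPromoter()].
#'
#' @param pfm a [PositionFrequencyMatrix-class].
#' @param nCore width of the core window (default 4; capped at L).
#' @param pseudocount scalar added to counts before normalization
#'   (default 0).
#' @return a [ScoringMatrix-class].
#' @export
scoringMatrix <- function(pfm, nCore = 4L, pseudocount = 0) {
  f <- baseFrequencies(pfm, pseudocount = pseudocount)
  ci <- informationVector(pfm, pseudocount = pseudocount)
  nCore <- min(as.integer(nCore), nrow(f))
  new("ScoringMatrix", pfm = pfm, freq = f, ci = ci,
      core = corePositions(ci, nCore), fMax = apply(f, 1L, max))
}

#' @rdname ScoringMatrix-class
#' @export
setMethod("conservationVector", "ScoringMatrix", function(object) object@ci)

#' @rdname ScoringMatrix-class
#' @export
setMethod("coreWindow", "ScoringMatrix", function(object) object@core)

#' @rdname ScoringMatrix-class
#' @export
setMethod("matrixLength", "ScoringMatrix",
          function(object) nrow(object@freq))

#' @rdname ScoringMatrix-class
#' @export
setMethod("tfId", "ScoringMatrix", function(object) tfId(object@pfm))

#' @rdname ScoringMatrix-class
#' @export
setMethod("consensusSequence", "ScoringMatrix",
          function(object) consensusSequence(object@pfm))

setMethod("show", "ScoringMatrix", function(object) {
  cat(sprintf("ScoringMatrix %s, L = %d, core = [%d, %d], mean ci = %.1f\n",
              tfId(object), matrixLength(object),
              min(object@core), max(object@core), mean(object@ci)))
})

# Map a DNA string to integer codes A=1, C=2, G=3, T=4; anything else
# (including N) becomes NA and contributes frequency 0 to scores.
.encodeDNA <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bad <- !(v %in% c(DNA_BASES, "N"))
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(v[bad]), collapse = ", "))
  match(v, DNA_BASES)
}

#' Conservation-weighted similarity of a window to a matrix
#'
#' Scores a DNA window of the matrix length against a [ScoringMatrix-class]:
#' \deqn{mss = \frac{\sum_i ci(i) f(w_i, i)}{\sum_i ci(i) f_{max}(i)}}
#' summed over all positions (`positions = "all"`, the matrix similarity)
#' or over the core window only (`positions = "core"`, the core
#' similarity). The score lies in \[0, 1\] and reaches 1 exactly when the
#' window carries a maximum-frequency base at every scored position with
#' positive conservation. Positions holding `N` (or any non-ACGT base)
#' contribute 0 to the numerator. A matrix with zero conservation at every
#' scored position accepts any window with score 1.
#'
#' @param sm a [ScoringMatrix-class].
#' @param window DNA string of length `matrixLength(sm)`.
#' @param positions `"all"` (matrix similarity) or `"core"` (core
#'   similarity).
#' @return a single numeric score in \[0, 1\].
#' @examples
#' sm <- scoringMatrix(PFM("T1", matrix(c(9, 0, 0, 0,
#'                                        0, 9, 0, 0,
#'                                        0, 0, 9, 0,
#'                                        0, 0, 0, 9), 4, 4, byrow = TRUE)))
#' matrixSimilarity(sm, "ACGT")  # 1
#' matrixSimilarity(sm, "ACGA") < 1
#' @export
matrixSimilarity <- function(sm, window, positions = c("all", "core")) {
  positions <- match.arg(positions)
  L <- matrixLength(sm)
  code <- .encodeDNA(window)
  if (length(code) != L)
    stop("window length ", length(code), " does not match matrix length ", L)
  idx <- if (positions == "core") sm@core else seq_len(L)
  ci <- sm@ci[idx]
  fw <- sm@freq[cbind(idx, code[idx])]
  fw[is.na(fw)] <- 0  # N or other ambiguity scores zero
  denom <- sum(ci * sm@fMax[idx])
  if (denom == 0) return(1)
  val <- sum(ci * fw) / denom
  min(max(val, 0), 1)
}
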