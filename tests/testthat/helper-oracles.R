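# Independent oracles used across the suite. These deliberately avoid the
# package's scoring/scanning code paths: scores are computed from the raw
# count matrix with plain string operations, window by window.

oracleFrequencies <- function(counts) counts / rowSums(counts)

oracleConservation <- function(counts) {
  f <- oracleFrequencies(counts)
  ci <- numeric(nrow(f))
  for (i in seq_len(nrow(f))) {
    s <- 0
    for (b in 1:4) if (f[i, b] > 0) s <- s + f[i, b] * log(f[i, b])
    ci[i] <- (100 / log(4)) * (s + log(4))
  }
  ci
}

oracleCoreWindow <- function(ci, nCore = 4L) {
  best <- -Inf; bestStart <- 1L
  for (s in seq_len(length(ci) - nCore + 1L)) {
    v <- sum(ci[s:(s + nCore - 1L)])
    if (v > best + 1e-12) { best <- v; bestStart <- s }
  }
  seq.int(bestStart, bestStart + nCore - 1L)
}

# Score one window (character string) against raw counts; positions is a
# vector of matrix positions to score over.
oracleScore <- function(counts, window, positions = seq_len(nrow(counts))) {
  f <- oracleFrequencies(counts)
  ci <- oracleConservation(counts)
  bases <- strsplit(window, "")[[1L]]
  num <- 0; den <- 0
  for (i in positions) {
    b <- match(bases[i], c("A", "C", "G", "T"))
    fw <- if (is.na(b)) 0 else f[i, b]
    num <- num + ci[i] * fw
    den <- den + ci[i] * max(f[i, ])
  }
  if (den == 0) 1 else num / den
}

oracleRevComp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1L]]]), collapse = "")
}

# Full both-strand enumeration of passing windows; returns a data.frame
# sorted like scanPromoter's output.
oracleScan <- function(seq, counts, cssMin, mssMin, nCore = 4L) {
  L <- nrow(counts)
  ci <- oracleConservation(counts)
  core <- oracleCoreWindow(ci, min(nCore, L))
  slen <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s2 <- if (strand == "+") seq else oracleRevComp(seq)
    if (slen < L) next
    for (start0 in 0:(slen - L)) {
      w <- substr(s2, start0 + 1L, start0 + L)
      mss <- oracleScore(counts, w)
      css <- oracleScore(counts, w, core)
      if (css >= cssMin && mss >= mssMin) {
        fwd <- if (strand == "+") start0 else slen - start0 - L
        rows[[length(rows) + 1L]] <-
          data.frame(start = fwd, strand = strand, core_sim = css,
                     matrix_sim = mss, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0L), strand = character(0L),
                      core_sim = numeric(0L), matrix_sim = numeric(0L)))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

randomCounts <- function(L) {
  m <- matrix(runif(L * 4L), L, 4L)
  m / rowSums(m) * 20
}

randomCountMatrixFixture <- function(nTf, nGene, maxCount = 4L) {
  m <- matrix(sample(0:maxCount, nTf * nGene, replace = TRUE,
                     prob = c(0.5, rep(0.5 / maxCount, maxCount))),
              nTf, nGene,
              dimnames = list(sprintf("T%02d", seq_len(nTf)),
                              sprintf("G%02d", seq_len(nGene))))
  bindingCountMatrix(m)
}

randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
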