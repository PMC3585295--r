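#' Generate a synthetic PWM library
#'
#' Simulates a matrix library of `nTfs` transcription factor matrices
#' assigned round-robin to `nFamilies` families. Each matrix has a unique
#' strict consensus (a single maximum-frequency base per position); the
#' consensus base receives a `sharpness` fraction of the per-position
#' counts and the remaining mass is spread evenly over the other bases.
#' Consensus strings are resampled until none is a palindrome and none is
#' contained in (or equal to) another consensus or its reverse complement,
#' so a planted consensus can only produce a perfect-score hit for its own
#' matrix. Evidence counts are sampled from \{0, 1, 2, 3\}, mimicking a
#' library in which only part of the matrices carry more than one piece of
#' experimental evidence.
#'
#' @param nTfs number of matrices.
#' @param nFamilies number of families, `<= nTfs`.
#' @param lengthRange integer length-2 vector, inclusive range of matrix
#'   lengths (default `c(8, 10)`).
#' @param sharpness consensus dominance in (0.25, 1\]; 1 gives one-hot
#'   columns with conservation 100 everywhere (default 0.9).
#' @param seed integer seed; the same seed reproduces the library exactly.
#' @return list with `pfms` (named list of
#'   [PositionFrequencyMatrix-class]), `metadata` (data.frame `tf_id`,
#'   `family`, `evidence_count`) and `consensus` (named character vector).
#' @export
generatePwmLibrary <- function(nTfs, nFamilies, lengthRange = c(8L, 10L),
                               sharpness = 0.9, seed = 1L) {
  if (nFamilies > nTfs) stop("nFamilies must not exceed nTfs")
  if (sharpness <= 0.25 || sharpness > 1)
    stop("sharpness must lie in (0.25, 1] for a strict consensus")
  if (lengthRange[1L] < 4L || lengthRange[2L] < lengthRange[1L])
    stop("invalid lengthRange")
  set.seed(seed)
  tfIds <- sprintf("TF%03d", seq_len(nTfs))
  families <- sprintf("FAM%02d", rep_len(seq_len(nFamilies), nTfs))
  lens <- sample(seq.int(lengthRange[1L], lengthRange[2L]), nTfs,
                 replace = TRUE)
  randCons <- function(L) paste(sample(DNA_BASES, L, replace = TRUE),
                                collapse = "")
  consensus <- vapply(lens, randCons, character(1L))
  ok <- function(cons) {
    rc <- vapply(cons, revComp, character(1L))
    for (i in seq_along(cons)) {
      if (cons[i] == rc[i]) return(i)  # palindrome
      for (j in seq_along(cons)) {
        if (i == j) next
        if (grepl(cons[j], cons[i], fixed = TRUE) ||
            grepl(rc[j], cons[i], fixed = TRUE)) return(max(i, j))
      }
    }
    0L
  }
  for (tries in seq_len(1000L)) {
    bad <- ok(consensus)
    if (bad == 0L) break
    consensus[bad] <- randCons(lens[bad])
  }
  if (ok(consensus) != 0L)
    stop("could not generate a collision-free consensus set; ",
         "use longer or fewer matrices")
  evidence <- sample(0:3, nTfs, replace = TRUE)
  pfms <- vector("list", nTfs)
  for (k in seq_len(nTfs)) {
    base <- match(strsplit(consensus[k], "")[[1L]], DNA_BASES)
    counts <- matrix((1 - sharpness) / 3 * 100, nrow = lens[k], ncol = 4L)
    counts[cbind(seq_len(lens[k]), base)] <- sharpness * 100
    pfms[[k]] <- PFM(tfIds[k], counts, family = families[k],
                     evidenceCount = evidence[k])
  }
  names(pfms) <- tfIds
  list(pfms = pfms,
       metadata = data.frame(tf_id = tfIds, family = families,
                             evidence_count = evidence,
                             stringsAsFactors = FALSE),
       consensus = setNames(consensus, tfIds))
}

# Sample one background sequence at the requested GC content containing no
# window with perfect matrix similarity for any library matrix, on either
# strand.
.cleanBackground <- function(len, gc, sms, maxTries = 200L) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  for (i in seq_len(maxTries)) {
    seq <- paste(sample(DNA_BASES, len, replace = TRUE, prob = probs),
                 collapse = "")
    spurious <- vapply(sms, function(s)
      nrow(scanPromoter(seq, s, cssMin = 0, mssMin = 1)) > 0, logical(1L))
    if (!any(spurious)) return(seq)
  }
  stop("failed to sample a motif-free background after ", maxTries,
       " attempts")
}

# Non-overlapping placement of planted occurrence lengths in [0, len):
# shuffle the occurrence order along the promoter, then spread the free
# space by sorted uniform cut points, so any feasible packing succeeds.
.placeOccurrences <- function(lens, promLen) {
  n <- length(lens)
  if (!n) return(integer(0L))
  if (sum(lens) > promLen) stop("planted occurrences do not fit the promoter")
  slack <- promLen - sum(lens)
  ord <- sample.int(n)
  cuts <- sort(floor(runif(n, 0, slack + 1)))
  cuts <- pmin(cuts, slack)
  starts <- integer(n)
  before <- 0L
  for (k in seq_len(n)) {
    starts[ord[k]] <- as.integer(cuts[k]) + before
    before <- before + lens[ord[k]]
  }
  starts
}

#' Generate promoters with planted motif occurrences
#'
#' Builds one promoter per gene: background bases sampled at the given GC
#' content and rejection-sampled so that no window reaches perfect matrix
#' similarity for any library matrix, then exact consensus occurrences
#' (forward or reverse-complement, strand chosen by a fair coin) spliced
#' in at uniformly drawn non-overlapping offsets according to
#' `plantedCounts`. Each assembled promoter is verified by a full scan at
#' thresholds 1.0: the recovered counts must equal the planted counts
#' exactly, otherwise the promoter is re-sampled. All planted positions
#' and strands are recorded as ground truth.
#'
#' @param genes character vector of gene ids.
#' @param pfms named list of [PositionFrequencyMatrix-class] (the library).
#' @param plantedCounts integer TF x gene matrix (dimnames required) of
#'   planted occurrence counts; missing rows/columns default to zero.
#' @param promoterLength promoter length in bp (default 500).
#' @param gc background GC content in (0, 1) (default 0.5).
#' @param seed integer seed.
#' @return list with `promoters` (named character vector), `truth` (list:
#'   `plantedCounts` full TF x gene matrix, `occurrences` data.frame with
#'   `gene_id`, `tf_id`, `start`, `strand`, and `seed`).
#' @export
generatePromoters <- function(genes, pfms, plantedCounts,
                              promoterLength = 500L, gc = 0.5, seed = 1L) {
  if (gc <= 0 || gc >= 1) stop("gc must lie in (0, 1)")
  set.seed(seed)
  tfs <- names(pfms)
  full <- matrix(0L, length(tfs), length(genes),
                 dimnames = list(tfs, genes))
  if (!is.null(plantedCounts)) {
    pc <- as.matrix(plantedCounts)
    badT <- setdiff(rownames(pc), tfs)
    if (length(badT)) stop("plantedCounts has unknown TF(s): ",
                           paste(badT, collapse = ", "))
    badG <- setdiff(colnames(pc), genes)
    if (length(badG)) stop("plantedCounts has unknown gene(s): ",
                           paste(badG, collapse = ", "))
    full[rownames(pc), colnames(pc)] <- as.integer(pc)
  }
  sms <- lapply(pfms, scoringMatrix)
  cons <- vapply(pfms, consensusSequence, character(1L))
  promoters <- setNames(character(length(genes)), genes)
  occ <- list()
  for (g in genes) {
    occTf <- rep(tfs, full[, g])
    lens <- vapply(occTf, function(tf) matrixLength(pfms[[tf]]), integer(1L))
    if (sum(lens) > promoterLength)
      stop("planted occurrences for gene ", g,
           " exceed the promoter length")
    done <- FALSE
    for (attempt in seq_len(100L)) {
      seqStr <- .cleanBackground(promoterLength, gc, sms)
      starts <- .placeOccurrences(lens, promoterLength)
      strands <- if (length(occTf))
        sample(c("+", "-"), length(occTf), replace = TRUE) else character(0L)
      chars <- strsplit(seqStr, "")[[1L]]
      for (k in seq_along(occTf)) {
        word <- if (strands[k] == "+") cons[occTf[k]] else
          revComp(cons[occTf[k]])
        chars[(starts[k] + 1L):(starts[k] + lens[k])] <-
          strsplit(word, "")[[1L]]
      }
      candidate <- paste(chars, collapse = "")
      hits <- scanPromoters(setNames(candidate, g), sms,
                            cssMin = 1, mssMin = 1)
      rec <- buildCountMatrix(hits, tfs, g)
      if (identical(as.integer(countMatrix(rec)[, g]),
                    as.integer(full[, g]))) {
        promoters[[g]] <- candidate
        if (length(occTf))
          occ[[g]] <- data.frame(gene_id = g, tf_id = occTf,
                                 start = starts, strand = strands,
                                 stringsAsFactors = FALSE)
        done <- TRUE
        break
      }
    }
    if (!done)
      stop("could not assemble a verified promoter for gene ", g)
  }
  occurrences <- if (length(occ)) do.call(rbind, c(occ, list(NULL))) else
    data.frame(gene_id = character(0L), tf_id = character(0L),
               start = integer(0L), strand = character(0L))
  rownames(occurrences) <- NULL
  list(promoters = promoters,
       truth = list(plantedCounts = full, occurrences = occurrences,
                    seed = seed))
}

#' Write / read promoters as FASTA
#'
#' @param promoters named character vector of sequences.
#' @param path FASTA path.
#' @return `path` invisibly; `readPromoters()` returns a named character
#'   vector.
#' @export
writePromoters <- function(promoters, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(promoters), path)
  invisible(path)
}

#' @rdname writePromoters
#' @export
readPromoters <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Generate a two-group expression matrix with planted DE genes
#'
#' Per-gene baselines are lognormal (normal on the log2 scale); sample
#' values add independent normal noise on the log2 scale, and case samples
#' of planted differentially expressed genes are shifted by
#' `effect * noiseSd` log2 units. The default group sizes emulate a
#' 10-case / 10-control whole-blood microarray comparison. Values are
#' returned on the linear scale.
#'
#' @param genes character vector of gene ids (TFs and/or biomarkers).
#' @param nCase,nControl group sizes (defaults 10 and 10).
#' @param deEffects named numeric vector gene -> effect size in units of
#'   `noiseSd` (positive = up in cases); empty for a null data set.
#' @param noiseSd per-sample noise standard deviation on the log2 scale
#'   (default 0.5).
#' @param baselineMean,baselineSd log2-scale mean and sd of per-gene
#'   baselines (defaults 8 and 2).
#' @param seed integer seed.
#' @return list with `matrix` (genes x samples, linear scale), `groupOf`
#'   (named vector sample -> `"case"`/`"control"`) and `truth`
#'   (`deEffects`, `noiseSd`, `seed`).
#' @export
generateExpression <- function(genes, nCase = 10L, nControl = 10L,
                               deEffects = numeric(0L), noiseSd = 0.5,
                               baselineMean = 8, baselineSd = 2, seed = 1L) {
  if (nCase < 2L || nControl < 2L)
    stop("each group needs at least two samples")
  bad <- setdiff(names(deEffects), genes)
  if (length(bad))
    stop("deEffects names not in genes: ", paste(bad, collapse = ", "))
  set.seed(seed)
  samples <- c(sprintf("case%02d", seq_len(nCase)),
               sprintf("ctrl%02d", seq_len(nControl)))
  groupOf <- setNames(rep(c("case", "control"), c(nCase, nControl)),
                      samples)
  base <- rnorm(length(genes), baselineMean, baselineSd)
  m <- matrix(rnorm(length(genes) * length(samples), 0, noiseSd),
              nrow = length(genes),
              dimnames = list(genes, samples)) + base
  if (length(deEffects)) {
    shift <- deEffects * noiseSd
    m[names(deEffects), groupOf[samples] == "case"] <-
      m[names(deEffects), groupOf[samples] == "case", drop = FALSE] + shift
  }
  list(matrix = 2^m, groupOf = groupOf,
       truth = list(deEffects = deEffects, noiseSd = noiseSd, seed = seed))
}

#' Generate two-group protein biomarker levels with planted fold changes
#'
#' Control-group concentrations are lognormal per biomarker; case-group
#' means are multiplied by the planted fold change. Measurement noise is
#' lognormal with coefficient of variation `cv`.
#'
#' @param biomarkers character vector of biomarker ids.
#' @param nCase,nControl subjects per group (defaults 413 and 413,
#'   a case-control serum panel scale).
#' @param foldChanges named numeric vector biomarker -> case/control
#'   ratio; unnamed biomarkers default to 1.
#' @param cv lognormal coefficient of variation of subject-level noise
#'   (default 0.25).
#' @param seed integer seed.
#' @return list with `matrix` (biomarkers x subjects), `groupOf` and
#'   `truth` (`foldChanges`, `seed`).
#' @export
generateProteinLevels <- function(biomarkers, nCase = 413L, nControl = 413L,
                                  foldChanges = numeric(0L), cv = 0.25,
                                  seed = 1L) {
  bad <- setdiff(names(foldChanges), biomarkers)
  if (length(bad))
    stop("foldChanges names not in biomarkers: ",
         paste(bad, collapse = ", "))
  set.seed(seed)
  fc <- setNames(rep(1, length(biomarkers)), biomarkers)
  fc[names(foldChanges)] <- foldChanges
  samples <- c(sprintf("case%03d", seq_len(nCase)),
               sprintf("ctrl%03d", seq_len(nControl)))
  groupOf <- setNames(rep(c("case", "control"), c(nCase, nControl)),
                      samples)
  ctrlMean <- rlnorm(length(biomarkers), meanlog = 2, sdlog = 1)
  sdlog <- sqrt(log(1 + cv^2))
  noise <- matrix(rlnorm(length(biomarkers) * length(samples),
                         meanlog = -sdlog^2 / 2, sdlog = sdlog),
                  nrow = length(biomarkers))
  mean <- outer(ctrlMean, rep(1, length(samples)))
  mean[, groupOf == "case"] <- mean[, groupOf == "case"] * fc
  m <- mean * noise
  dimnames(m) <- list(biomarkers, samples)
  list(matrix = m, groupOf = groupOf,
       truth = list(foldChanges = fc, seed = seed))
}
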