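#' Quantile normalization between samples
#'
#' Forces every sample (column) to share the reference distribution
#' obtained by averaging the sorted columns: after normalization the
#' sorted values of each column equal the cross-sample mean of sorted
#' values. Ties within a column receive the mean of the reference values
#' at the ranks they occupy, so tied inputs stay tied. Row and column
#' names are preserved. The transform is idempotent (up to floating-point
#' rounding) on tie-free data.
#'
#' @param x numeric genes x samples matrix, no missing values.
#' @return normalized matrix of the same dimensions and dimnames.
#' @examples
#' m <- cbind(s1 = c(1, 2), s2 = c(3, 4))
#' quantileNormalize(m)  # both columns become (2, 3)
#' @export
quantileNormalize <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values are not supported")
  if (ncol(x) < 2L) {
    warning("single sample: quantile normalization is the identity")
    return(x)
  }
  ref <- rowMeans(apply(x, 2L, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    idx <- order(x[, j])
    v <- ref
    sorted <- x[idx, j]
    runs <- rle(sorted)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$lengths > 1L)) {
      rng <- starts[k]:ends[k]
      v[rng] <- mean(ref[rng])
    }
    out[idx, j] <- v
  }
  out
}

#' Welch two-sample t test
#'
#' Unequal-variance two-sided t test: statistic
#' \eqn{t = (\bar x - \bar y)/\sqrt{s_x^2/n_x + s_y^2/n_y}} with
#' Welch-Satterthwaite degrees of freedom. When both groups are constant
#' and equal the test degenerates to `t = 0`, `p = 1`.
#'
#' @param x,y numeric vectors, each of length >= 2, finite values.
#' @return list with elements `t`, `df`, `p`.
#' @export
welchTTest <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least two observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("values must be finite")
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  delta <- mean(x) - mean(y)
  if (se2 == 0) {
    if (delta == 0) return(list(t = 0, df = nx + ny - 2, p = 1))
    return(list(t = sign(delta) * Inf, df = nx + ny - 2, p = 0))
  }
  t <- delta / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Fold change between group means
#'
#' @param caseVals,controlVals numeric vectors of case / control
#'   measurements.
#' @return list with `ratio` (= mean(case)/mean(control)) and `log2`
#'   (log2 of the ratio; `NA` when the ratio is not positive).
#' @examples
#' foldChange(c(2, 2), c(1, 1))  # ratio 2, log2 1
#' @export
foldChange <- function(caseVals, controlVals) {
  mc <- mean(caseVals); mk <- mean(controlVals)
  if (mk == 0) stop("control mean is zero; fold change undefined")
  ratio <- mc / mk
  list(ratio = ratio, log2 = if (ratio > 0) log2(ratio) else NA_real_)
}

#' Two-group differential expression
#'
#' Welch t test per gene between case and control samples of a
#' (typically quantile-normalized) expression matrix, with group means,
#' linear and log2 fold changes. No multiple-testing correction is applied
#' by default; Benjamini-Hochberg adjusted p values can be added with
#' `bhCorrection = TRUE`, in which case the significance flag uses the
#' adjusted values.
#'
#' @param x numeric genes x samples matrix.
#' @param groupOf named character vector mapping every sample (column) to
#'   `"case"` or `"control"`.
#' @param alpha significance level for the `significant` flag
#'   (default 0.05).
#' @param bhCorrection add a `p_adjusted` column (Benjamini-Hochberg) and
#'   flag significance on it (default FALSE).
#' @return data.frame, one row per gene, sorted by p value (gene id as
#'   tie-break): `gene_id`, `mean_case`, `mean_control`, `fold_change`,
#'   `log2_fold_change`, `t_stat`, `df`, `p_value`, optionally
#'   `p_adjusted`, `significant`.
#' @export
differentialExpression <- function(x, groupOf, alpha = 0.05,
                                   bhCorrection = FALSE) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) || is.null(rownames(x)))
    stop("expression matrix must carry gene row names and sample column names")
  missing <- setdiff(colnames(x), names(groupOf))
  if (length(missing))
    stop("samples without group label: ", paste(missing, collapse = ", "))
  grp <- groupOf[colnames(x)]
  if (!all(grp %in% c("case", "control")))
    stop("groups must be 'case' or 'control'")
  caseIdx <- which(grp == "case"); ctrlIdx <- which(grp == "control")
  if (length(caseIdx) < 2L || length(ctrlIdx) < 2L)
    stop("each group needs at least two samples")
  rows <- lapply(rownames(x), function(g) {
    cv <- x[g, caseIdx]; kv <- x[g, ctrlIdx]
    tt <- welchTTest(cv, kv)
    mk <- mean(kv)
    ratio <- if (mk != 0) mean(cv) / mk else NA_real_
    data.frame(gene_id = g, mean_case = mean(cv), mean_control = mk,
               fold_change = ratio,
               log2_fold_change = if (!is.na(ratio) && ratio > 0)
                 log2(ratio) else NA_real_,
               t_stat = tt$t, df = tt$df, p_value = tt$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (bhCorrection) {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- res$p_adjusted < alpha
  } else {
    res$significant <- res$p_value < alpha
  }
  res <- res[order(res$p_value, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter predicted TFs by differential-expression evidence
#'
#' Splits a set of scan-predicted TFs into those with significant
#' differential expression, those assayed but not significant, and those
#' absent from the expression matrix ("not assayed" -- reported, never
#' silently dropped into either class).
#'
#' @param tfIds character vector of predicted TF ids.
#' @param deResults data.frame from [differentialExpression()].
#' @param alpha significance level (default 0.05).
#' @return list with `expressed` (significant TFs), `notSignificant`, and
#'   `notAssayed`.
#' @export
expressedTfFilter <- function(tfIds, deResults, alpha = 0.05) {
  assayed <- intersect(tfIds, deResults$gene_id)
  notAssayed <- setdiff(tfIds, deResults$gene_id)
  sub <- deResults[match(assayed, deResults$gene_id), , drop = FALSE]
  pcol <- if ("p_adjusted" %in% names(sub)) sub$p_adjusted else sub$p_value
  expressed <- assayed[pcol < alpha]
  list(expressed = expressed,
       notSignificant = setdiff(assayed, expressed),
       notAssayed = notAssayed)
}

#' Expression matrix and group-file TSV I/O
#'
#' The expression table is genes x samples with a leading `gene_id`
#' column; the groups file has columns `sample_id` and `group`
#' (`case`/`control`).
#'
#' @param path file path.
#' @return `readExpressionMatrix()`: numeric matrix with gene rownames;
#'   `readGroups()`: named character vector sample -> group.
#' @export
readExpressionMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (anyNA(m)) stop("expression matrix contains missing values")
  m
}

#' @rdname readExpressionMatrix
#' @param x numeric genes x samples matrix.
#' @export
writeExpressionMatrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readExpressionMatrix
#' @export
readGroups <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(df$group, df$sample_id)
}

#' @rdname readExpressionMatrix
#' @param groupOf named character vector sample -> group.
#' @export
writeGroups <- function(groupOf, path) {
  write.table(data.frame(sample_id = names(groupOf), group = groupOf),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
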