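test_that("quantile normalization matches the hand-worked two-column case", {
  m <- cbind(s1 = c(1, 2), s2 = c(3, 4))
  rownames(m) <- c("g1", "g2")
  out <- quantileNormalize(m)
  expect_equal(unname(out[, "s1"]), c(2, 3))
  expect_equal(unname(out[, "s2"]), c(2, 3))
  expect_identical(dimnames(out), dimnames(m))
})

test_that("normalization equalizes distributions, preserves order, is idempotent", {
  set.seed(51)
  m <- matrix(rlnorm(200 * 6), 200, 6,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:6)))
  out <- quantileNormalize(m)
  ref <- sort(out[, 1L])
  for (j in 2:6) expect_equal(sort(out[, j]), ref, ignore_attr = TRUE)
  expect_lt(diff(range(colMeans(out))), 1e-9)
  for (j in 1:6) expect_identical(order(out[, j]), order(m[, j]))
  expect_equal(quantileNormalize(out), out, tolerance = 1e-9)
  same <- matrix(rep(sort(rnorm(50)), 3), 50, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(quantileNormalize(same), same, tolerance = 1e-12)
})

test_that("tie-free normalization matches limma and ties average the reference", {
  set.seed(52)
  m <- matrix(rnorm(120), 40, 3,
              dimnames = list(sprintf("g%02d", 1:40), c("a", "b", "c")))
  got <- quantileNormalize(m)
  want <- limma::normalizeQuantiles(m)
  expect_equal(got, want, tolerance = 1e-9, ignore_attr = TRUE)
  # tied entries take the mean of the reference values at the tied ranks
  tied <- cbind(c1 = c(1, 1, 2), c2 = c(3, 4, 5))
  ref <- c(2, 2.5, 3.5)  # mean of sorted columns
  out <- quantileNormalize(tied)
  expect_equal(unname(out[, "c1"]),
               c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
  expect_equal(unname(out[, "c2"]), ref)
  # ties stay tied within a column
  mi <- matrix(sample(1:5, 60, replace = TRUE), 20, 3)
  gi <- quantileNormalize(mi)
  expect_true(all(tapply(gi[, 1L], mi[, 1L], function(v)
    diff(range(v)) == 0)))
})

test_that("single-sample normalization warns and returns the input", {
  m <- matrix(1:4, 4, 1, dimnames = list(letters[1:4], "s1"))
  expect_warning(out <- quantileNormalize(m), "single sample")
  expect_equal(out, m, ignore_attr = TRUE)
})

test_that("Welch test matches the reference implementation and its symmetries", {
  x <- c(4.1, 5.2, 3.9, 6.0, 5.5)
  y <- c(2.0, 2.8, 3.1, 1.7)
  got <- welchTTest(x, y)
  ref <- t.test(x, y, var.equal = FALSE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-8)
  expect_equal(got$p, ref$p.value, tolerance = 1e-8)
  swapped <- welchTTest(y, x)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p, got$p)
  scaled <- welchTTest(3 * x, 3 * y)
  expect_equal(scaled$t, got$t, tolerance = 1e-12)
  expect_equal(scaled$df, got$df, tolerance = 1e-12)
  same <- welchTTest(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(welchTTest(x, x)$t, 0)
  expect_error(welchTTest(1, y), "at least two")
})

test_that("fold changes follow the mean ratio and reject a zero control mean", {
  fc <- foldChange(c(2, 2), c(1, 1))
  expect_equal(fc$ratio, 2)
  expect_equal(fc$log2, 1)
  expect_equal(foldChange(c(3, 3), c(3, 3))$ratio, 1)
  expect_equal(foldChange(c(3, 3), c(3, 3))$log2, 0)
  expect_error(foldChange(c(1, 2), c(1, -1)), "control mean is zero")
})

test_that("planted differentially expressed genes rank at the top", {
  genes <- sprintf("g%03d", 1:120)
  de <- setNames(rep(2, 10), genes[1:10])  # 2-sigma shifts
  sim <- generateExpression(genes, nCase = 10, nControl = 10,
                            deEffects = de, noiseSd = 0.5, seed = 61)
  res <- differentialExpression(quantileNormalize(log2(sim$matrix)),
                                sim$groupOf)
  top <- res$gene_id[seq_len(15L)]
  expect_gte(sum(names(de) %in% top), 8)
  expect_true(all(diff(res$p_value) >= 0))
  expect_equal(sum(differentialExpression(log2(sim$matrix), sim$groupOf,
                                          alpha = 0)$significant), 0L)
  # t sign follows the direction of the mean difference
  expect_true(all(sign(res$t_stat) ==
                    sign(res$mean_case - res$mean_control)))
})

test_that("BH correction adds an adjusted column and flags on it", {
  genes <- sprintf("g%02d", 1:50)
  sim <- generateExpression(genes, seed = 62)
  res <- differentialExpression(log2(sim$matrix), sim$groupOf,
                                bhCorrection = TRUE)
  expect_true("p_adjusted" %in% names(res))
  expect_true(all(res$p_adjusted >= res$p_value - 1e-12))
  expect_identical(res$significant, res$p_adjusted < 0.05)
})

test_that("the expressed-TF filter separates significant, assayed and missing TFs", {
  de <- data.frame(gene_id = c("T1", "T2", "T3"),
                   p_value = c(0.01, 0.2, 0.6),
                   significant = c(TRUE, FALSE, FALSE),
                   stringsAsFactors = FALSE)
  out <- expressedTfFilter(c("T1", "T2", "T3", "T9"), de, alpha = 0.05)
  expect_identical(out$expressed, "T1")
  expect_setequal(out$notSignificant, c("T2", "T3"))
  expect_identical(out$notAssayed, "T9")
  all3 <- expressedTfFilter(c("T1", "T2", "T3"), de, alpha = 1)
  expect_setequal(all3$expressed, c("T1", "T2", "T3"))
  none <- expressedTfFilter(c("X1", "X2"), de)
  expect_length(none$expressed, 0L)
  expect_setequal(none$notAssayed, c("X1", "X2"))
})

test_that("expression matrices and group files round-trip through TSV", {
  withr::with_tempdir({
    sim <- generateExpression(sprintf("g%d", 1:8), nCase = 3, nControl = 3,
                              seed = 63)
    writeExpressionMatrix(sim$matrix, "x.tsv")
    writeGroups(sim$groupOf, "g.tsv")
    expect_equal(readExpressionMatrix("x.tsv"), sim$matrix,
                 tolerance = 1e-6)
    expect_identical(readGroups("g.tsv"), sim$groupOf)
  })
})
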