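fx <- coreTfBindingCounts()

test_that("curated core-TF counts reproduce the reported totals", {
  tot <- tfTotals(fx$matrix)
  expect_equal(tot[["PPARG"]], 76)
  expect_equal(tot[["EGR1"]], 52)
  expect_equal(tot[["KLF7"]], 25)
  expect_equal(tot[["ESRRA"]], 23)
  # ETV1: per-promoter values sum to 42; the narrative total of 43 is
  # preserved as a reported discrepancy, not reconciled
  expect_equal(tot[["ETV1"]], 42)
  expect_equal(fx$claimedTotals[["ETV1"]], 43)
  expect_equal(fx$totalDiscrepancies[["ETV1"]], 1)
  expect_equal(sum(fx$totalDiscrepancies), 1)
})

test_that("curated pathway-level counts match the reported breakdown", {
  pc <- pathwayCounts(fx$matrix, fx$pathways)
  expect_equal(pc["EGR1", "coagulation"], 21)
  expect_equal(pc["ESRRA", "inflammation"], 12)
  expect_equal(pc["PPARG", "cell_adhesion"], 8)
  expect_equal(pc["ETV1", "oxidative_stress"], 4)
  expect_equal(pc["KLF7", "stress"], 3)
  # pathways partition the 31 genes, so rows conserve the TF totals
  expect_equal(rowSums(pc), tfTotals(fx$matrix))
})

test_that("only EGR1's counts cover all seven pathways", {
  expect_identical(coreTFs(fx$matrix, fx$pathways, mode = "pathway"), "EGR1")
  expect_identical(coreTFs(fx$matrix, mode = "gene"), character(0L))
  sig <- pathwaySignature(fx$matrix, fx$pathways, "PPARG")
  expect_setequal(sig, setdiff(pathwayNames(fx$pathways), "renal_function"))
})

test_that("family totals conserve the grand total and match a brute-force regroup", {
  fam <- aggregateFamilyCounts(fx$matrix, fx$familyOf)
  expect_equal(sum(fam), sum(tfTotals(fx$matrix)))
  expect_equal(fam[["nuclear_receptor"]], 76 + 23)
  set.seed(21)
  for (rep in 1:10) {
    m <- randomCountMatrixFixture(8, 6)
    fams <- setNames(sample(c("f1", "f2", "f3"), 8, replace = TRUE),
                     tfNames(m))
    got <- aggregateFamilyCounts(m, fams)
    want <- sapply(split(tfTotals(m), fams[tfNames(m)]), sum)
    expect_equal(got[names(want)], want)
    expect_equal(sum(got), sum(countMatrix(m)))
  }
  expect_error(aggregateFamilyCounts(fx$matrix, c(PPARG = "x")), "EGR1")
})

test_that("pathway counting rejects pathway genes absent from the matrix", {
  bad <- pathwayMap(list(p1 = c("CLU", "NOT_A_GENE")))
  expect_error(pathwayCounts(fx$matrix, bad), "NOT_A_GENE")
})

test_that("signatures identify specific regulators and empty rows", {
  m <- bindingCountMatrix(matrix(c(0L, 0L, 3L,
                                   0L, 0L, 0L), 2, 3, byrow = TRUE,
                                 dimnames = list(c("RFXlike", "silent"),
                                                 c("g1", "g2", "MPO"))))
  pmap <- pathwayMap(list(inflammation = c("g1", "g2"),
                          oxidative_stress = "MPO"))
  expect_identical(pathwaySignature(m, pmap, "RFXlike"), "oxidative_stress")
  expect_identical(pathwaySignature(m, pmap, "silent"), character(0L))
  expect_error(pathwaySignature(m, pmap, "nope"), "unknown TF")
})

test_that("core sets are nested and behave on planted and zero matrices", {
  genes <- sprintf("g%d", 1:6)
  pmap <- pathwayMap(list(a = genes[1:2], b = genes[3:4], c = genes[5:6]))
  m <- matrix(0L, 3, 6, dimnames = list(c("uni", "partial", "zero"), genes))
  m["uni", ] <- 1L
  m["partial", c(1, 3, 5)] <- 2L   # one gene per pathway, not all genes
  bcm <- bindingCountMatrix(m)
  expect_identical(coreTFs(bcm, mode = "gene"), "uni")
  expect_setequal(coreTFs(bcm, pmap, mode = "pathway"), c("uni", "partial"))
  expect_true(all(coreTFs(bcm, mode = "gene") %in%
                    coreTFs(bcm, pmap, mode = "pathway")))
  z <- bindingCountMatrix(matrix(0L, 2, 2,
                                 dimnames = list(c("x", "y"),
                                                 c("g1", "g2"))))
  zmap <- pathwayMap(list(p = c("g1", "g2")))
  expect_length(coreTFs(z, mode = "gene"), 0L)
  expect_length(coreTFs(z, zmap, mode = "pathway"), 0L)
})

test_that("signature groups partition all TFs including empty signatures", {
  set.seed(22)
  for (rep in 1:10) {
    m <- randomCountMatrixFixture(7, 6)
    pmap <- pathwayMap(list(p1 = geneNames(m)[1:2], p2 = geneNames(m)[3:4],
                            p3 = geneNames(m)[5:6]))
    groups <- groupBySignature(m, pmap)
    members <- unlist(groups, use.names = FALSE)
    expect_setequal(members, tfNames(m))        # cover
    expect_equal(length(members), length(tfNames(m)))  # disjoint
    # brute-force regroup from individual signatures
    for (key in names(groups)) {
      for (tf in groups[[key]]) {
        sig <- pathwaySignature(m, pmap, tf)
        wantKey <- if (!length(sig)) "(none)" else paste(sig, collapse = "+")
        expect_identical(wantKey, key)
      }
    }
  }
})

test_that("pairwise pathway intersections agree between signatures and sets", {
  set.seed(23)
  for (rep in 1:8) {
    m <- randomCountMatrixFixture(9, 6)
    pmap <- pathwayMap(list(p1 = geneNames(m)[1:3], p2 = geneNames(m)[2:5],
                            p3 = geneNames(m)[5:6]))
    pc <- pathwayCounts(m, pmap)
    tfsOf <- function(p) rownames(pc)[pc[, p] >= 1]
    sigs <- lapply(setNames(tfNames(m), tfNames(m)),
                   function(tf) pathwaySignature(m, pmap, tf))
    for (p in pathwayNames(pmap)) for (q in pathwayNames(pmap)) {
      if (p >= q) next
      fromSets <- intersect(tfsOf(p), tfsOf(q))
      fromSigs <- names(sigs)[vapply(sigs, function(s)
        all(c(p, q) %in% s), logical(1L))]
      expect_setequal(fromSets, fromSigs)
    }
  }
})

test_that("adding hits never shrinks signatures, cores or totals", {
  set.seed(24)
  m <- randomCountMatrixFixture(6, 6)
  pmap <- pathwayMap(list(p1 = geneNames(m)[1:3], p2 = geneNames(m)[4:6]))
  cts2 <- countMatrix(m)
  cell <- c(sample(nrow(cts2), 1L), sample(ncol(cts2), 1L))
  cts2[cell[1L], cell[2L]] <- cts2[cell[1L], cell[2L]] + 3L
  m2 <- bindingCountMatrix(cts2)
  expect_true(all(tfTotals(m2) >= tfTotals(m)))
  for (tf in tfNames(m))
    expect_true(all(pathwaySignature(m, pmap, tf) %in%
                      pathwaySignature(m2, pmap, tf)))
  expect_true(all(coreTFs(m, mode = "gene") %in% coreTFs(m2, mode = "gene")))
  expect_true(all(coreTFs(m, pmap, "pathway") %in%
                    coreTFs(m2, pmap, "pathway")))
})

test_that("pathway maps round-trip through GMT", {
  withr::with_tempdir({
    writeGmt(fx$pathways, "p.gmt")
    back <- readGmt("p.gmt")
    expect_identical(pathwayNames(back), pathwayNames(fx$pathways))
    for (nm in pathwayNames(back))
      expect_setequal(pathwayGenes(back, nm), pathwayGenes(fx$pathways, nm))
  })
})

test_that("regulome summaries bundle consistent components", {
  rs <- regulomeSummary(fx$matrix, fx$pathways, fx$familyOf)
  expect_identical(rs@coreByPathway, "EGR1")
  expect_equal(sum(rs@familyTotals), sum(rs@tfTotals))
  expect_equal(rowSums(rs@pathwayTotals), rs@tfTotals)
  withr::with_tempdir({
    writeRegulomeSummary(rs, "rs.json")
    parsed <- jsonlite::read_json("rs.json")
    expect_equal(parsed$tf_totals$PPARG, 76)
    expect_equal(unlist(parsed$core_by_pathway), "EGR1")
  })
})
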