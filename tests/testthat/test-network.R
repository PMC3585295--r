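test_that("Jaccard similarity covers its anchor cases", {
  expect_equal(jaccardIndex(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccardIndex(c("a"), c("b")), 0)
  expect_equal(jaccardIndex(c(1, 2), c(2, 3)), 1 / 3)
  expect_equal(jaccardIndex(character(0), character(0)), 0)
  expect_equal(jaccardIndex(c("a", "a", "b"), c("b", "a")), 1)
})

test_that("regulation edges mirror the thresholded matrix cells", {
  m <- bindingCountMatrix(matrix(c(3L, 0L, 1L, 2L), 2, 2,
                                 dimnames = list(c("T1", "T2"),
                                                 c("G1", "G2"))))
  e1 <- buildRegulationEdges(m, 1L)
  expect_equal(nrow(e1), 3L)
  expect_equal(e1$weight[e1$source == "T1" & e1$target == "G1"], 3)
  expect_equal(nrow(buildRegulationEdges(m, 4L)), 0L)
  expect_error(buildRegulationEdges(m, 0L), ">= 1")
  set.seed(71)
  for (rep in 1:8) {
    m <- randomCountMatrixFixture(5, 7)
    k <- sample(1:3, 1L)
    expect_equal(nrow(buildRegulationEdges(m, k)),
                 sum(countMatrix(m) >= k))
  }
})

test_that("similarity edges match the all-pairs oracle and the empty-set rule", {
  m <- bindingCountMatrix(matrix(c(1L, 1L, 0L,
                                   2L, 3L, 0L), 2, 3, byrow = TRUE,
                                 dimnames = list(c("T1", "T2"),
                                                 c("G1", "G2", "G3"))))
  co <- coregulationEdges(m, 0.5)
  expect_equal(nrow(co), 1L)
  expect_equal(co$weight, 1)
  empty <- bindingCountMatrix(matrix(0L, 3, 2,
                                     dimnames = list(c("a", "b", "c"),
                                                     c("g1", "g2"))))
  expect_equal(nrow(coregulationEdges(empty, 0)), 0L)
  expect_equal(nrow(cotargetedEdges(empty, 0)), 0L)
  set.seed(72)
  for (rep in 1:6) {
    m <- randomCountMatrixFixture(6, 8)
    thr <- runif(1, 0.1, 0.8)
    cts <- countMatrix(m)
    for (edges in list(coregulationEdges(m, thr))) {
      # oracle: enumerate all TF pairs
      want <- 0L
      for (i in 1:5) for (j in (i + 1):6) {
        a <- colnames(cts)[cts[i, ] >= 1]
        b <- colnames(cts)[cts[j, ] >= 1]
        if ((length(a) || length(b)) && jaccardIndex(a, b) >= thr)
          want <- want + 1L
      }
      expect_equal(nrow(edges), want)
      expect_true(all(edges$weight >= thr & edges$weight <= 1))
    }
    # raising the threshold never adds edges
    lo <- cotargetedEdges(m, 0.2)
    hi <- cotargetedEdges(m, 0.6)
    expect_true(all(paste(hi$source, hi$target) %in%
                      paste(lo$source, lo$target)))
  }
})

test_that("networks carry typed nodes and edges without self-loops", {
  fx <- coreTfBindingCounts()
  net <- buildRegulomeNetwork(fx$matrix, fx$pathways,
                              familyOf = fx$familyOf)
  g <- networkGraph(net)
  expect_equal(igraph::vcount(g), 5 + 31)
  expect_false(any(igraph::which_loop(g)))
  types <- igraph::edge_attr(g, "type")
  el <- igraph::as_edgelist(g)
  nodeType <- setNames(igraph::vertex_attr(g, "nodeType"),
                       igraph::V(g)$name)
  reg <- types == "regulates"
  expect_true(all(nodeType[el[reg, 1L]] == "TF"))
  expect_true(all(nodeType[el[reg, 2L]] == "biomarker"))
  expect_equal(sum(reg), sum(countMatrix(fx$matrix) >= 1))
  jw <- igraph::edge_attr(g, "weight")[types != "regulates"]
  expect_true(all(jw >= 0 & jw <= 1))
})

test_that("a planted universal TF yields one multi-pathway module", {
  genes <- c("b1", "b2", "b3", "b4", "b5")
  m <- matrix(0L, 3, 5, dimnames = list(c("UNI", "other", "silent"), genes))
  m["UNI", ] <- 2L
  m["other", "b1"] <- 1L
  pmap <- pathwayMap(list(pw1 = c("b1", "b2"), pw2 = c("b3", "b4"),
                          pw3 = "b5"))
  net <- buildRegulomeNetwork(bindingCountMatrix(m), pmap,
                              jaccardMin = 0.5)
  mods <- extractModules(net)
  expect_length(mods, 1L)
  expect_setequal(mods[[1L]]$members, genes)
  expect_true("UNI" %in% mods[[1L]]$regulators)
  expect_gte(length(mods[[1L]]$pathways), 2L)
})

test_that("disconnected biomarker pairs give separate modules; empty graphs none", {
  m <- matrix(0L, 2, 4, dimnames = list(c("Ta", "Tb"),
                                        c("g1", "g2", "h1", "h2")))
  m["Ta", c("g1", "g2")] <- 1L
  m["Tb", c("h1", "h2")] <- 1L
  pmap <- pathwayMap(list(pg = c("g1", "g2"), ph = c("h1", "h2")))
  mods <- extractModules(buildRegulomeNetwork(bindingCountMatrix(m), pmap,
                                              jaccardMin = 0.5))
  expect_length(mods, 2L)
  expect_setequal(mods[[1L]]$members, c("g1", "g2"))
  expect_setequal(mods[[2L]]$members, c("h1", "h2"))
  # modules partition the connected biomarkers
  expect_length(intersect(mods[[1L]]$members, mods[[2L]]$members), 0L)
  empty <- bindingCountMatrix(matrix(0L, 2, 2,
                                     dimnames = list(c("x", "y"),
                                                     c("g1", "g2"))))
  expect_length(extractModules(buildRegulomeNetwork(empty)), 0L)
})

test_that("graph export round-trips through GraphML and edge TSV", {
  withr::with_tempdir({
    set.seed(73)
    m <- randomCountMatrixFixture(4, 6)
    pmap <- pathwayMap(list(p1 = geneNames(m)[1:3], p2 = geneNames(m)[4:6]))
    net <- buildRegulomeNetwork(m, pmap, jaccardMin = 0.2)
    g <- networkGraph(net)
    for (fmt in c("graphml", "edge-tsv")) {
      f <- paste0("net.", fmt)
      exportGraph(net, f, fmt)
      back <- networkGraph(importGraph(f, fmt))
      expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
      expect_equal(igraph::ecount(back), igraph::ecount(g))
      key <- function(gr) {
        el <- igraph::as_edgelist(gr)
        ends <- t(apply(el, 1L, sort))
        ord <- order(ends[, 1L], ends[, 2L], igraph::edge_attr(gr, "type"))
        list(paste(ends[ord, 1L], ends[ord, 2L],
                   igraph::edge_attr(gr, "type")[ord]),
             igraph::edge_attr(gr, "weight")[ord])
      }
      ka <- key(g); kb <- key(back)
      expect_identical(ka[[1L]], kb[[1L]])
      expect_equal(ka[[2L]], kb[[2L]], tolerance = 1e-9)
      # node attributes survive
      expect_identical(
        sort(paste(igraph::V(back)$name,
                   igraph::vertex_attr(back, "nodeType"))),
        sort(paste(igraph::V(g)$name, igraph::vertex_attr(g, "nodeType"))))
    }
    # an empty network still exports valid files
    empty <- bindingCountMatrix(matrix(0L, 1, 1,
                                       dimnames = list("t", "g")))
    enet <- buildRegulomeNetwork(empty)
    exportGraph(enet, "empty.graphml", "graphml")
    exportGraph(enet, "empty.tsv", "edge-tsv")
    expect_equal(igraph::ecount(networkGraph(importGraph("empty.graphml"))), 0)
    expect_equal(igraph::ecount(networkGraph(
      importGraph("empty.tsv", "edge-tsv"))), 0)
    expect_error(exportGraph(net, "x.bin", "binary"))
  })
})
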