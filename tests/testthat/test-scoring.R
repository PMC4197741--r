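test_that("ISC is 100 on edge-identical subgraphs and 0 against edgeless partners", {
    nets <- list(cliqueNetwork("n1", paste0("u", 1:4), weight = 0.3),
                 cliqueNetwork("n2", paste0("v", 1:4), weight = 0.9))
    aln <- Alignment(c("n1", "n2"), cbind(paste0("u", 1:4), paste0("v", 1:4)))
    expect_equal(iscScore(aln, nets), 100)    # weights differ, edges agree

    empty <- PPINetwork("n2", data.frame(from = character(),
                                         to = character(),
                                         weight = numeric()),
                        nodes = paste0("v", 1:4))
    expect_equal(iscScore(aln, list(nets[[1]], empty)), 0)
    one <- Alignment(c("n1", "n2"), cbind("u1", "v1"))
    expect_equal(iscScore(one, nets), 0)       # undefined below 2 rows
    # both sides edgeless counts as fully conserved
    empty1 <- PPINetwork("n1", data.frame(from = character(),
                                          to = character(),
                                          weight = numeric()),
                         nodes = paste0("u", 1:4))
    expect_equal(iscScore(aln, list(empty1, empty)), 100)
})

test_that("ISC agrees exactly with a brute-force pair-counting oracle", {
    set.seed(31)
    for (i in 1:30) {
        case <- randomAlignmentCase(sample(2:4, 1), sample(2:6, 1))
        expect_equal(iscScore(case$alignment, case$networks),
                     oracleISC(case$alignment, case$networks))
    }
})

test_that("overlap fraction uses the smaller alignment as denominator", {
    big <- Alignment(c("a", "b"), cbind(paste0("x", 1:4), paste0("y", 1:4)))
    disjoint <- Alignment(c("a", "b"),
                          cbind(paste0("x", 7:9), paste0("y", 7:9)))
    contained <- Alignment(c("a", "b"), cbind(paste0("x", 1:2),
                                              paste0("y", 1:2)))
    expect_equal(overlapFraction(big, disjoint), 0)
    expect_equal(overlapFraction(big, big), 1)
    expect_equal(overlapFraction(big, contained), 1)
    expect_equal(overlapFraction(contained, big), 1)   # symmetric choice
    half <- Alignment(c("a", "b"), cbind(c("x1", "x9"), c("y1", "y9")))
    expect_equal(overlapFraction(big, half), 0.5)
})

test_that("overlap filtering keeps compatible survivors and is idempotent", {
    mk <- function(xs) Alignment(c("a", "b"),
                                 cbind(paste0("x", xs), paste0("y", xs)))
    a <- mk(1:4); b <- mk(1:3); c <- mk(7:9)
    kept <- filterByOverlap(list(a, b, c), 0.5)
    expect_true(sameAlignmentSets(kept, list(a, c)))
    expect_true(sameAlignmentSets(filterByOverlap(list(a, a), 0.5), list(a)))
    expect_true(sameAlignmentSets(filterByOverlap(kept, 0.5), kept))
    # survivors are pairwise compatible
    for (i in seq_along(kept)) for (j in seq_along(kept))
        if (i != j)
            expect_lte(overlapFraction(kept[[i]], kept[[j]]), 0.5)
})

test_that("overlap filtering matches the brute-force elimination oracle", {
    set.seed(77)
    for (rep in 1:30) {
        fam <- lapply(seq_len(sample(2:6, 1)), function(i) {
            n <- sample(2:5, 1)
            xs <- sample(1:8, n)
            Alignment(c("a", "b"), cbind(paste0("x", xs), paste0("y", xs)))
        })
        theta <- sample(c(0, 0.25, 0.5, 1), 1)
        expect_true(sameAlignmentSets(filterByOverlap(fam, theta),
                                      oracleOverlapFilter(fam, theta)))
    }
})

test_that("size filtering keeps exactly the large-enough alignments", {
    mk <- function(n) Alignment(c("a", "b"),
                                cbind(paste0("x", 1:n), paste0("y", 1:n)))
    fam <- list(mk(3), mk(5), mk(7))
    expect_equal(vapply(filterBySize(fam, 5), alignmentSize, integer(1)),
                 c(5L, 7L))
    expect_length(filterBySize(fam, 1), 3)
    expect_length(filterBySize(list(), 5), 0)
})

test_that("the alignment graph has row-wise inter-edges and banded colors", {
    ids <- c("n1", "n2", "n3")
    nets <- lapply(ids, function(id) {
        PPINetwork(id, data.frame(from = c("m1", "m2", "m3"),
                                  to = c("m2", "m3", "m4"),
                                  weight = c(0.9, 0.5, 0.2)))
    })
    aln <- Alignment(ids, matrix(rep(paste0("m", 1:4), 3), ncol = 3))
    ag <- buildAlignmentGraph(aln, nets)
    expect_s4_class(ag, "AlignmentGraph")
    expect_equal(nrow(ag@interEdges), 4 * choose(3, 2))
    expect_equal(nrow(ag@nodes), 12)
    ia <- ag@intraEdges
    key <- paste(pmin(ia$from, ia$to), pmax(ia$from, ia$to))
    expect_equal(unique(ia$color[ia$weight == 0.9]), "red")
    expect_equal(unique(ia$color[ia$weight == 0.5]), "yellow")
    expect_equal(unique(ia$color[ia$weight == 0.2]), "green")
    expect_true(all(ag@interEdges$network1 != ag@interEdges$network2))
    expect_true(all(is.na(ag@nodes$description)))

    ann <- annotationStore(descriptions = c(m1 = "subunit"),
                           terms = list(m1 = list(cc = "GO:0005737",
                                                  bp = character(),
                                                  mf = character(),
                                                  unclassified = character())))
    ag2 <- buildAlignmentGraph(aln, nets, ann)
    expect_equal(unique(ag2@nodes$description[ag2@nodes$protein == "m1"]),
                 "subunit")
    # annotations decorate nodes only; edges identical
    expect_identical(ag2@intraEdges, ag@intraEdges)
    expect_identical(ag2@interEdges, ag@interEdges)
})

test_that("GraphML export is well-formed and attribute-complete", {
    nets <- list(cliqueNetwork("n1", paste0("g", 1:3), weight = 0.8),
                 cliqueNetwork("n2", paste0("g", 1:3), weight = 0.8))
    aln <- Alignment(c("n1", "n2"), cbind(paste0("g", 1:3), paste0("g", 1:3)))
    f <- withr::local_tempfile(fileext = ".graphml")
    writeGraphML(buildAlignmentGraph(aln, nets), f)
    doc <- xml2::read_xml(f)
    ns <- xml2::xml_ns(doc)
    nodesXml <- xml2::xml_find_all(doc, ".//d1:node", ns)
    edgesXml <- xml2::xml_find_all(doc, ".//d1:edge", ns)
    expect_length(nodesXml, 6)
    expect_length(edgesXml, 3 + 3 + 3 * 1)   # intra n1 + intra n2 + inter
    kinds <- xml2::xml_text(xml2::xml_find_all(
        doc, ".//d1:edge/d1:data[@key='d_kind']", ns))
    expect_equal(sum(kinds == "inter"), 3)
    styles <- xml2::xml_text(xml2::xml_find_all(
        doc, ".//d1:edge/d1:data[@key='d_style']", ns))
    expect_true(all(styles[kinds == "inter"] == "dashed"))
    expect_true(all(styles[kinds == "intra"] == "solid"))
})
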