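test_that("candidate seed nodes are exactly the nodes of degree >= sigma", {
    path3 <- pathNetwork("p", c("A", "B", "C"))
    expect_equal(candidateSeedNodes(path3, 2), "B")
    expect_setequal(candidateSeedNodes(path3, 0), c("A", "B", "C"))
    tri <- cliqueNetwork("t", c("X", "Y", "Z"))
    expect_length(candidateSeedNodes(tri, 7), 0)
})

test_that("row similarity sums the pairwise scores over network pairs", {
    sim <- bitScoreStore(data.frame(p1 = c("a", "a", "b"),
                                    p2 = c("b", "c", "c"),
                                    score = c(10, 20, 30)))
    expect_equal(rowSimilarity(c("a", "b", "c"), sim), 60)
    expect_equal(rowSimilarity(c("a", "b"), sim), 10)
    expect_equal(rowSimilarity(c("x", "y", "z"), sim), 0)
    cog <- cogStore(list(a = c("G1", "G2"), b = "G2", c = c("G1", "G2")))
    expect_equal(rowSimilarity(c("a", "b", "c"), cog), 1 + 2 + 1)
})

test_that("seed sampling is forced by unique candidates and fails without any", {
    # in each network exactly one node reaches degree 2
    nets <- list(pathNetwork("n1", c("a1", "hub1", "a2")),
                 pathNetwork("n2", c("b1", "hub2", "b2")))
    sim <- bitScoreStore(data.frame(p1 = "hub1", p2 = "hub2", score = 5))
    for (s in 1:5) {
        set.seed(s)
        row <- gibbsSampleSeed(nets, sim, alignmentConfig(sigma = 2))
        expect_equal(unname(row), c("hub1", "hub2"))
    }
    expect_null(gibbsSampleSeed(nets, sim, alignmentConfig(sigma = 7)))
})

test_that("Gibbs seed finds a planted optimal triple among decoys", {
    # planted triple scores 100 per pair; decoys score <= 1
    ids <- c("n1", "n2", "n3")
    nets <- lapply(1:3, function(i)
        cliqueNetwork(ids[i], paste0("v", i, "_", 1:4), weight = 0.5))
    planted <- paste0("v", 1:3, "_1")
    prs <- list()
    set.seed(99)
    for (i in 1:2) for (j in seq(i + 1, 3)) {
        g <- expand.grid(p1 = nodes(nets[[i]]), p2 = nodes(nets[[j]]),
                         stringsAsFactors = FALSE)
        g$score <- stats::runif(nrow(g), 0, 1)
        g$score[g$p1 == planted[i] & g$p2 == planted[j]] <- 100
        prs[[length(prs) + 1]] <- g
    }
    sim <- bitScoreStore(do.call(rbind, prs))
    expect_equal(bruteBestSeed(nets, sim, 3), planted)
    hits <- 0
    for (s in 1:50) {
        set.seed(s)
        row <- gibbsSampleSeed(nets, sim, alignmentConfig(sigma = 3))
        hits <- hits + identical(unname(row), planted)
    }
    expect_gte(hits / 50, 0.95)
})

test_that("local density matches its definition and a brute-force oracle", {
    tri <- lapply(c("n1", "n2"), cliqueNetwork,
                  nodeNames = paste0("t", 1:3))
    aln3 <- Alignment(c("n1", "n2"), cbind(paste0("t", 1:3), paste0("t", 1:3)))
    expect_equal(localDensity(aln3, tri), 1.0)

    # one induced edge of weight 0.6 in one network, nothing in the other
    netA <- PPINetwork("a", data.frame(from = "x1", to = "x2", weight = 0.6),
                       nodes = paste0("x", 1:3))
    netB <- PPINetwork("b", data.frame(from = character(), to = character(),
                                       weight = numeric()),
                       nodes = paste0("y", 1:3))
    aln <- Alignment(c("a", "b"), cbind(paste0("x", 1:3), paste0("y", 1:3)))
    expect_equal(localDensity(aln, list(netA, netB)), (0.6 / 3 + 0) / 2)
    expect_equal(localDensity(Alignment(c("a", "b"), cbind("x1", "y1")),
                              list(netA, netB)), 0)

    set.seed(7)
    for (i in 1:20) {
        case <- randomAlignmentCase(sample(2:4, 1), sample(2:6, 1))
        expect_equal(localDensity(case$alignment, case$networks),
                     oracleDensity(case$alignment, case$networks))
    }

    # appending an isolated row strictly lowers a dense alignment's density
    netA2 <- cliqueNetwork("a", paste0("x", 1:4), weight = 0.9)
    netA2 <- PPINetwork("a", interactions(netA2), nodes = c(paste0("x", 1:4), "iso_a"))
    netB2 <- cliqueNetwork("b", paste0("y", 1:4), weight = 0.9)
    netB2 <- PPINetwork("b", interactions(netB2), nodes = c(paste0("y", 1:4), "iso_b"))
    dense <- Alignment(c("a", "b"), cbind(paste0("x", 1:4), paste0("y", 1:4)))
    grown <- Alignment(c("a", "b"), rbind(alignmentRows(dense),
                                          c("iso_a", "iso_b")))
    expect_lt(localDensity(grown, list(netA2, netB2)),
              localDensity(dense, list(netA2, netB2)))
})

test_that("extension recovers a planted conserved clique then stops", {
    # 5-clique with one weak seed edge, plus weakly attached pendants
    buildNet <- function(id) {
        nm <- paste0("a", 1:5)
        cp <- utils::combn(nm, 2)
        w <- rep(1, ncol(cp))
        w[cp[1, ] == "a1" & cp[2, ] == "a2"] <- 0.4
        edges <- data.frame(from = cp[1, ], to = cp[2, ], weight = w)
        edges <- rbind(edges, data.frame(from = "a1", to = "pend",
                                         weight = 0.1))
        PPINetwork(id, edges)
    }
    nets <- list(buildNet("n1"), buildNet("n2"))
    sim <- identityBitScores(c(paste0("a", 1:5), "pend"))
    seed <- Alignment(c("n1", "n2"), cbind(c("a1", "a2"), c("a1", "a2")))
    set.seed(3)
    ext <- extendAlignment(seed, nets, sim, alignmentConfig())
    expect_equal(rowKeys(ext),
                 sort(paste(paste0("a", 1:5), paste0("a", 1:5), sep = "\t")))
    tr <- ext@metadata$densityTrace
    expect_true(all(diff(c(0, tr)) > 0))            # strictly increasing

    # columns exhausting all nodes leave nothing to extend
    full <- Alignment(c("n1", "n2"),
                      cbind(c(paste0("a", 1:5), "pend"),
                            c(paste0("a", 1:5), "pend")))
    ext2 <- extendAlignment(full, nets, sim, alignmentConfig())
    expect_equal(rowKeys(ext2), rowKeys(full))
})

test_that("refinement leaves a perfect planted complex unchanged", {
    nets <- list(cliqueNetwork("n1", paste0("c", 1:5)),
                 cliqueNetwork("n2", paste0("c", 1:5)))
    sim <- identityBitScores(paste0("c", 1:5))
    perfect <- Alignment(c("n1", "n2"),
                         cbind(paste0("c", 1:5), paste0("c", 1:5)))
    set.seed(11)
    ref <- refineAlignment(perfect, nets, sim, alignmentConfig(refine = 10))
    expect_equal(rowKeys(ref), rowKeys(perfect))
    expect_true(all(diff(ref@metadata$refineTrace) >= -1e-9))

    ref0 <- refineAlignment(perfect, nets, sim, alignmentConfig(refine = 0))
    expect_identical(alignmentRows(ref0), alignmentRows(perfect))
})

test_that("the pipeline maps twin networks onto themselves deterministically", {
    set.seed(123)
    nm <- paste0("p", 1:10)
    cp <- utils::combn(nm, 2)
    on <- stats::runif(ncol(cp)) < 0.4
    edges <- data.frame(from = cp[1, on], to = cp[2, on],
                        weight = stats::runif(sum(on), 0.6, 1))
    nets <- list(PPINetwork("n1", edges, nodes = nm),
                 PPINetwork("n2", edges, nodes = nm))
    sim <- identityBitScores(nm)
    cfg <- alignmentConfig(sigma = 1, minComplexSize = 5, seed = 7)
    res <- alignNetworks(nets, sim, cfg)
    expect_gte(length(res), 1)
    # twin mapping: each aligned node maps to its own twin
    r1 <- alignmentRows(res[[1]])
    expect_equal(r1[, 1], r1[, 2])
    # determinism: same seed, byte-identical row sets and metadata
    res2 <- alignNetworks(nets, sim, cfg)
    expect_true(sameAlignmentSets(res, res2))
    expect_error(alignNetworks(nets[1], sim, cfg), "at least two")
    # column injectivity enforced by class validity on every result
    for (a in res) expect_true(methods::validObject(a))
})
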