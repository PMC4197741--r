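test_that("fixture generation is deterministic and leaves the RNG untouched", {
    spec <- fixtureSpec(backgroundNodes = 30, decoysPerPair = 20, seed = 4,
                        complexes = list(list(size = 5, q = 0.9,
                                              wMin = 0.7, wMax = 1)))
    set.seed(1); before <- stats::runif(1)
    set.seed(1)
    fx1 <- generateFixture(spec)
    expect_equal(stats::runif(1), before)       # caller's stream untouched
    fx2 <- generateFixture(spec)
    for (i in seq_along(fx1$networks))
        expect_identical(interactions(fx1$networks[[i]]),
                         interactions(fx2$networks[[i]]))
    expect_identical(fx1$similarity@pairs, fx2$similarity@pairs)
    expect_identical(fx1$truth, fx2$truth)
})

test_that("plantings obey the spec: cliques at q=1, bands, injective truth", {
    spec <- fixtureSpec(nNetworks = 2, backgroundNodes = 20,
                        decoysPerPair = 10, seed = 9,
                        complexes = list(list(size = 4, q = 1,
                                              wMin = 1, wMax = 1)))
    fx <- generateFixture(spec)
    for (net in fx$networks) {
        expect_true(methods::validObject(net))
        e <- interactions(net)
        planted <- startsWith(e$from, "C") & startsWith(e$to, "C")
        expect_true(all(e$weight[planted] == 1))
        expect_true(all(e$weight[!planted] >= 0.1 & e$weight[!planted] <= 0.5))
        # q = 1: each complex induces a complete clique
        members <- grep("^C1_", nodes(net), value = TRUE)
        sg <- igraph::induced_subgraph(interactionGraph(net), members)
        expect_equal(igraph::ecount(sg), choose(4, 2))
    }
    expect_true(all(apply(fx$truth, 2, anyDuplicated) == 0))
    # counterpart pairs outscore every decoy; cog store links counterparts
    expect_equal(pairScore(fx$similarity, fx$truth[1, 1], fx$truth[1, 2]), 200)
    expect_gte(pairScore(fx$cogSimilarity, fx$truth[1, 1], fx$truth[1, 2]), 1)
    expect_error(generateFixture(
        fixtureSpec(backgroundNodes = 3,
                    complexes = list(list(size = 6, q = 0.9,
                                          wMin = 0.7, wMax = 1)))),
        "do not fit")
})

test_that("background edge density matches its Erdos-Renyi rate", {
    n <- 40; p <- 0.1; reps <- 50
    edges <- 0
    for (s in seq_len(reps)) {
        fx <- generateFixture(fixtureSpec(nNetworks = 2, backgroundNodes = n,
                                          backgroundEdgeProb = p,
                                          complexes = list(),
                                          decoysPerPair = 0, seed = s))
        edges <- edges + nrow(interactions(fx$networks[[1]]))
    }
    trials <- reps * choose(n, 2)
    se <- sqrt(trials * p * (1 - p))
    expect_lt(abs(edges - trials * p), 3 * se)
})

test_that("recovery scoring counts exact planted rows", {
    truth <- cbind(net1 = paste0("a", 1:4), net2 = paste0("b", 1:4))
    exact <- list(Alignment(c("net1", "net2"), truth))
    r <- scoreRecovery(exact, truth)
    expect_equal(r$recall, 1); expect_equal(r$precision, 1)
    expect_equal(scoreRecovery(list(), truth)$recall, 0)
    half <- list(Alignment(c("net1", "net2"),
                           rbind(truth[1:2, ],
                                 cbind(paste0("j", 1:2), paste0("k", 1:2)))))
    rh <- scoreRecovery(half, truth)
    expect_equal(rh$recall, 0.5); expect_equal(rh$precision, 0.5)
    # column order of the result must not matter
    swapped <- list(Alignment(c("net2", "net1"),
                              truth[, 2:1, drop = FALSE]))
    expect_equal(scoreRecovery(swapped, truth)$recall, 1)
})

test_that("written fixture files load back through the input readers", {
    spec <- fixtureSpec(backgroundNodes = 25, decoysPerPair = 15, seed = 2,
                        complexes = list(list(size = 5, q = 0.9,
                                              wMin = 0.7, wMax = 1)))
    fx <- generateFixture(spec)
    dir <- withr::local_tempdir()
    paths <- writeFixtureFiles(fx, dir)
    expect_true(all(file.exists(paths)))
    nets <- lapply(fx$networks, function(net)
        readPPINetwork(paths[paste0("network.", networkId(net))],
                       networkId(net)))
    for (i in seq_along(nets)) {
        e0 <- interactions(fx$networks[[i]]); e1 <- interactions(nets[[i]])
        expect_equal(nrow(e0), nrow(e1))
        k0 <- paste(pmin(e0$from, e0$to), pmax(e0$from, e0$to))
        k1 <- paste(pmin(e1$from, e1$to), pmax(e1$from, e1$to))
        expect_setequal(k0, k1)
    }
    # isolated nodes are absent from reloaded edge lists, so decoy pairs
    # naming them are legitimately skipped with a warning
    sim <- suppressWarnings(readBitScores(paths["bitscores"], nets))
    expect_equal(pairScore(sim, fx$truth[1, 1], fx$truth[1, 3]), 200)
    cog <- readCogGroups(paths["cogs"])
    expect_gte(pairScore(cog, fx$truth[2, 1], fx$truth[2, 2]), 1)
    ann <- readAnnotations(paths["annotations"])
    expect_true(fx$truth[1, 1] %in% names(descriptions(ann)))
})
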