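test_that("fingerprints capture distance changes and ignore rigid motion", {
    ## 3-bead fixture, one bead moved +1 A along x in the displaced frame
    s <- makeStructure("A", 1:3, rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0)))
    x0 <- coords(s)
    xp <- x0; xp[1, 1] <- xp[1, 1] + 1
    xm <- x0; xm[1, 1] <- xm[1, 1] - 1
    tr <- frameTrajectory(s, list(xm, x0, xp))
    fp <- computeFingerprint(tr, system = "S")
    ## hand-computed distance changes
    d12 <- sqrt(sum((xp[1, ] - xp[2, ])^2)) - 4        # 3 - 4 = -1
    d13 <- sqrt(sum((xp[1, ] - xp[3, ])^2)) - 4        # sqrt(17) - 4
    expect_equal(fp@delta[1, 2], d12, tolerance = 1e-12)
    expect_equal(fp@delta[1, 3], d13, tolerance = 1e-12)
    expect_equal(fp@delta[2, 3], 0)

    ## rigid translation: all distances unchanged
    trT <- frameTrajectory(s, list(sweep(x0, 2, c(1, 1, 1), "+"), x0,
                                   sweep(x0, 2, c(-2, 0.5, 3), "+")))
    fpT <- computeFingerprint(trT)
    expect_true(all(fpT@delta == 0))

    ## zero-amplitude trajectory
    tr0 <- frameTrajectory(s, list(x0, x0, x0))
    expect_true(all(computeFingerprint(tr0)@delta == 0))
})

test_that("mantel identity and negation reach +1 and -1", {
    f <- randomFingerprint(10, seed = 1)
    expect_equal(mantelTest(f, f)@r, 1.0)
    fneg <- matFingerprint(-f@delta)
    expect_equal(mantelTest(f, fneg)@r, -1.0)
})

test_that("zero-variance fingerprints are rejected", {
    s <- makeStructure("A", 1:3, rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0)))
    x0 <- coords(s)
    tr0 <- frameTrajectory(s, list(x0, x0, x0))
    fp0 <- computeFingerprint(tr0)
    expect_error(mantelTest(fp0, fp0), "undefined")
})

test_that("exhaustive p equals the enumeration fraction and sampling converges to it", {
    fA <- randomFingerprint(5, seed = 11)
    fB <- randomFingerprint(5, seed = 12)
    res <- mantelTest(fA, fB)
    expect_identical(res@scheme, "exhaustive")
    expect_identical(res@nPermutations, 119L)   # 5! - 1 non-identity

    ## independent oracle: direct enumeration over all 120 permutations
    perms <- MotionDissect:::.allPermutations(5)
    ut <- upper.tri(matrix(0, 5, 5))
    a <- fA@delta[ut]
    r <- cor(a, fB@delta[ut])
    rstar <- vapply(perms, function(p) {
        cor(a, fB@delta[p, p][ut])
    }, numeric(1))
    pExact <- mean(abs(rstar) >= abs(r) - 1e-12)
    expect_equal(res@pValue, pExact)

    ## sampled scheme on an 8x8 instance agrees with its own exhaustive
    ## fraction within 3 binomial standard errors
    gA <- randomFingerprint(8, seed = 21)
    gB8 <- gA@delta + MotionDissect:::.withSeed(31, {
        z <- matrix(rnorm(64, sd = 2), 8, 8); z + t(z)
    })
    gB <- matFingerprint(gB8)
    sampled <- mantelTest(gA, gB, nPermutations = 4999, seed = 5)
    expect_identical(sampled@scheme, "sampled")
    ## oracle: large independent resample of the permutation null
    ut8 <- upper.tri(matrix(0, 8, 8))
    a8 <- gA@delta[ut8]
    r8 <- cor(a8, gB@delta[ut8])
    pRef <- MotionDissect:::.withSeed(99, {
        hits <- sum(replicate(20000, {
            p <- sample.int(8)
            abs(cor(a8, gB@delta[p, p][ut8])) >= abs(r8) - 1e-12
        }))
        (1 + hits) / (1 + 20000)
    })
    se <- sqrt(pRef * (1 - pRef) / 4999)
    expect_lt(abs(sampled@pValue - pRef), 3 * se + 1e-4)
})

test_that("mantel r is symmetric and permutation-equivariant", {
    fA <- randomFingerprint(7, seed = 41)
    fB <- randomFingerprint(7, seed = 42)
    rAB <- mantelTest(fA, fB)
    rBA <- mantelTest(fB, fA)
    expect_equal(rAB@r, rBA@r)
    expect_equal(rAB@pValue, rBA@pValue)   # exhaustive: exactly symmetric
    ## applying one permutation to both sides leaves r unchanged
    p <- c(3, 1, 7, 2, 6, 4, 5)
    fAp <- matFingerprint(fA@delta[p, p])
    fBp <- matFingerprint(fB@delta[p, p])
    expect_equal(mantelTest(fAp, fBp)@r, rAB@r, tolerance = 1e-12)
})

test_that("our mantel statistic matches the vegan implementation", {
    skip_if_not_installed("vegan")
    fA <- randomFingerprint(12, seed = 51)
    fB <- randomFingerprint(12, seed = 52)
    ours <- mantelTest(fA, fB, nPermutations = 999, seed = 3)
    ref <- vegan::mantel(fA@delta, fB@delta, permutations = 999)
    expect_equal(ours@r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("similarity graph applies both thresholds and keeps the full r matrix", {
    fps <- list(randomFingerprint(12, seed = 1, system = "X", label = 7L),
                randomFingerprint(12, seed = 2, system = "X", label = 8L),
                randomFingerprint(12, seed = 1, system = "Y", label = 7L),
                randomFingerprint(12, seed = 2, system = "Y", label = 8L))
    g <- buildSimilarityGraph(fps, nPermutations = 1999, seed = 7)
    ## twins across systems are identical -> connected with r = 1
    R <- similarityMatrix(g)
    expect_equal(R["X:7", "Y:7"], 1)
    expect_equal(R["X:8", "Y:8"], 1)
    e <- graphEdges(g)
    pairKey <- function(i, j) paste(sort(c(i, j)), collapse = "-")
    got <- mapply(pairKey, e$from, e$to)
    expect_true(pairKey(1, 3) %in% got && pairKey(2, 4) %in% got)
    expect_true(all(abs(e$r) >= 0.6 & e$p < 0.001))

    ## an impossible threshold empties the edge set
    g2 <- buildSimilarityGraph(fps, rThreshold = 1.01, nPermutations = 99)
    expect_identical(nrow(graphEdges(g2)), 0L)
})

test_that("orthogonal motions of one structure fall below the edge threshold", {
    fix <- beadCloud(n = 25, seed = 13)
    m <- computeNormalModes(buildEnmHessian(fix$structure,
                                            topology = fix$topology),
                            particleMasses(fix$structure), nModes = 6)
    trs <- lapply(modeLabels(m), function(l)
        generateModeTrajectory(fix$structure, m, l, nFrames = 5))
    fps <- lapply(trs, computeFingerprint, system = "S")
    ## distinct low modes of a generic cloud describe different motions
    rs <- vapply(2:6, function(i)
        abs(cor(fps[[1]]@delta[upper.tri(fps[[1]]@delta)],
                fps[[i]]@delta[upper.tri(fps[[i]]@delta)])), numeric(1))
    expect_true(any(rs < 0.6))
})

test_that("classification separates shared and unique components", {
    ## engineered: systems P and Q share modes 7 and 8, differ in mode 9
    shared7 <- randomFingerprint(10, seed = 61)
    shared8 <- randomFingerprint(10, seed = 62)
    mk <- function(fp, sys, lab) matFingerprint(fp@delta, sys, lab)
    fps <- list(mk(shared7, "P", 7L), mk(shared8, "P", 8L),
                randomFingerprint(10, seed = 63, system = "P", label = 9L),
                mk(shared7, "Q", 7L), mk(shared8, "Q", 8L),
                randomFingerprint(10, seed = 64, system = "Q", label = 9L))
    g <- buildSimilarityGraph(fps, nPermutations = 1999, seed = 11)
    cls <- classifyMotions(g, phenotypes = list(P = c("alpha", "beta"),
                                                Q = c("alpha")))
    tab <- classTable(cls)
    expect_identical(tab$class[tab$system == "P" & tab$mode %in% 7:8],
                     c("shared", "shared"))
    expect_identical(tab$class[tab$system == "P" & tab$mode == 9], "unique")
    expect_identical(tab$classLabel[tab$system == "P" & tab$mode == 9],
                     "unique_to_P")
    ## semantic tags: shared -> common outcome; P-unique -> distinguishing one
    expect_identical(unique(tab$tag[tab$class == "shared"]), "alpha")
    expect_identical(tab$tag[tab$system == "P" & tab$mode == 9], "beta")
    expect_identical(tab$tag[tab$system == "Q" & tab$mode == 9], "novel")

    ## classification order-invariance
    g2 <- buildSimilarityGraph(fps[c(4:6, 1:3)], nPermutations = 1999,
                               seed = 11)
    cls2 <- classifyMotions(g2, phenotypes = list(P = c("alpha", "beta"),
                                                  Q = c("alpha")))
    t2 <- classTable(cls2)
    key <- function(d) d[order(d$system, d$mode), c("system", "mode", "class",
                                                    "classLabel", "tag")]
    expect_identical(key(t2), key(tab), ignore_attr = TRUE)
})

test_that("degenerate classification inputs behave as specified", {
    fps <- list(randomFingerprint(8, seed = 71, system = "P", label = 7L),
                randomFingerprint(8, seed = 71, system = "P", label = 8L))
    g <- buildSimilarityGraph(fps, nPermutations = 1999)
    expect_error(classifyMotions(g, list(P = "alpha")), "two systems")
    red <- redundancyReport(g)
    expect_equal(unname(red$component), c(1, 1))   # identical modes cluster

    ## all modes mutually similar -> a single shared component
    f <- randomFingerprint(8, seed = 72)
    fps2 <- list(matFingerprint(f@delta, "P", 7L),
                 matFingerprint(f@delta, "P", 8L),
                 matFingerprint(f@delta, "Q", 7L))
    g2 <- buildSimilarityGraph(fps2, nPermutations = 1999)
    cls2 <- classTable(classifyMotions(g2, list(P = "a", Q = "a")))
    expect_true(all(cls2$class == "shared"))

    ## no cross-system similarity at all -> everything unique
    fps3 <- list(randomFingerprint(8, seed = 73, system = "P", label = 7L),
                 randomFingerprint(8, seed = 74, system = "Q", label = 7L))
    g3 <- buildSimilarityGraph(fps3, nPermutations = 1999)
    cls3 <- classTable(classifyMotions(g3, list(P = "a", Q = "a")))
    expect_true(all(cls3$class == "unique"))
})
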