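# Hand-assembled DCCM + frames for exact network-rule checks.
networkFixture <- function() {
    ## 6 beads on a line, 4 A apart -> beads within 2 steps are inside 10 A
    s <- makeStructure("A", 1:6, cbind(4 * (0:5), 0, 0))
    x0 <- coords(s)
    ## frames: static geometry (contact fraction 1 for all close pairs)
    frames <- list(x0, x0, x0, x0)
    C <- diag(6)
    set <- function(M, i, j, v) { M[i, j] <- M[j, i] <- v; M }
    C <- set(C, 1, 2, 0.7)     # boundary: exactly at threshold -> edge
    C <- set(C, 2, 3, 0.9)
    C <- set(C, 3, 4, 0.95)
    C <- set(C, 4, 5, 0.75)
    C <- set(C, 5, 6, 0.85)
    C <- set(C, 1, 3, 0.65)    # below |C| threshold -> no edge
    C <- set(C, 1, 6, 0.99)    # 20 A apart -> fails contact rule
    C <- set(C, 2, 4, -0.8)    # negative but |C| >= 0.7 -> edge
    dccm <- new("CrossCorrelationMatrix", corr = C,
                keys = paste0("A:", 1:6), nFrames = 4L, sources = 7L)
    list(structure = s, dccm = dccm,
         trajectory = frameTrajectory(s, frames, label = 7L))
}

test_that("network edges obey the correlation AND contact conjunction", {
    fx <- networkFixture()
    net <- buildNetwork(fx$dccm, fx$trajectory)
    g <- net@graph
    el <- apply(igraph::as_edgelist(g), 1, paste, collapse = "|")
    expect_setequal(el, c("A:1|A:2", "A:2|A:3", "A:3|A:4", "A:4|A:5",
                          "A:5|A:6", "A:2|A:4"))
    ## weights are -log|C|; the boundary |C| = 0.7 edge is included
    w <- igraph::E(g)$weight[match("A:1|A:2", el)]
    expect_equal(w, -log(0.7), tolerance = 1e-12)
    wNeg <- igraph::E(g)$weight[match("A:2|A:4", el)]
    expect_equal(wNeg, -log(0.8), tolerance = 1e-12)
    expect_true(all(igraph::E(g)$weight > 0))
    expect_identical(length(net@keys), 6L)   # isolated nodes retained
    expect_error(buildNetwork(fx$dccm, fx$trajectory, corrThreshold = 1.5),
                 "corrThreshold")
    expect_error(buildNetwork(fx$dccm, fx$trajectory, distThreshold = -1),
                 "positive")
})

test_that("contact fraction below threshold suppresses a high-|C| edge", {
    s <- makeStructure("A", 1:2, rbind(c(0, 0, 0), c(5, 0, 0)))
    near <- coords(s)
    far <- near; far[2, 1] <- 20
    ## contact in exactly half the frames, |C| = 0.9
    frames <- list(near, far, near, far)
    C <- matrix(c(1, 0.9, 0.9, 1), 2, 2)
    dccm <- new("CrossCorrelationMatrix", corr = C, keys = c("A:1", "A:2"),
                nFrames = 4L, sources = 7L)
    tr <- frameTrajectory(s, frames)
    net75 <- buildNetwork(dccm, tr, frameFraction = 0.75)
    expect_equal(as.integer(igraph::ecount(net75@graph)), 0L)
    net50 <- buildNetwork(dccm, tr, frameFraction = 0.5)
    expect_equal(as.integer(igraph::ecount(net50@graph)), 1L)
})

test_that("barbell graph splits at the bridge, within tolerance of the brute-force optimum", {
    g <- generateReferenceGraph("barbell", list(n1 = 12, n2 = 12))
    net <- asDynamicalNetwork(g)
    part <- detectCommunities(net, minSize = 10)
    memb <- communityMembership(part)
    expect_identical(part@nCommunities, 2L)
    expect_identical(unname(memb[1]), unname(memb[12]))
    expect_identical(unname(memb[13]), unname(memb[24]))
    expect_false(memb[[1]] == memb[[13]])

    ## brute-force oracle over all bipartitions of a 14-node barbell
    g14 <- generateReferenceGraph("barbell", list(n1 = 7, n2 = 7))
    net14 <- asDynamicalNetwork(g14)
    part14 <- detectCommunities(net14, minSize = 1)
    g14 <- net14@graph                      # carries the |C| strengths
    strength <- abs(igraph::E(g14)$C)
    best <- -Inf
    for (mask in 0:(2^13 - 1)) {
        memb14 <- c(1L, as.integer(intToBits(mask))[1:13] + 1L)
        q <- igraph::modularity(g14, memb14, weights = strength)
        if (q > best) best <- q
    }
    expect_gte(part14@modularity, best - 0.05)
})

test_that("community edge cases: complete graph, pruning, edgeless network", {
    full <- igraph::make_full_graph(12)
    igraph::E(full)$weight <- 1
    p1 <- detectCommunities(asDynamicalNetwork(full), minSize = 1)
    expect_identical(p1@nCommunities, 1L)

    ## two bridged 4-cliques with minSize 10: everything pruned
    g2 <- generateReferenceGraph("barbell", list(n1 = 4, n2 = 4))
    p2 <- detectCommunities(asDynamicalNetwork(g2), minSize = 10)
    expect_identical(p2@nCommunities, 0L)
    expect_length(p2@pruned, 8)

    ## edgeless network: warning, all unassigned
    s <- makeStructure("A", 1:3, rbind(c(0, 0, 0), c(30, 0, 0), c(60, 0, 0)))
    C <- diag(3)
    dccm <- new("CrossCorrelationMatrix", corr = C,
                keys = paste0("A:", 1:3), nFrames = 2L, sources = 7L)
    tr <- frameTrajectory(s, list(coords(s), coords(s), coords(s)))
    net <- buildNetwork(dccm, tr)
    expect_warning(p3 <- detectCommunities(net), "edgeless")
    expect_true(all(is.na(communityMembership(p3))))
})

test_that("community detection is invariant under node relabeling", {
    g <- generateReferenceGraph("barbell", list(n1 = 6, n2 = 6))
    p1 <- detectCommunities(asDynamicalNetwork(g), minSize = 1)
    perm <- c(7:12, 1:6)
    g2 <- igraph::permute(g, perm)
    p2 <- detectCommunities(asDynamicalNetwork(g2), minSize = 1)
    m1 <- communityMembership(p1)
    m2 <- communityMembership(p2)
    ## same partition up to community ids: compare co-membership of pairs
    co <- function(m) outer(m, m, "==")
    expect_identical(co(m2[names(m1)]), co(m1))
})

test_that("betweenness matches hand enumeration and the closed star form", {
    gp <- generateReferenceGraph("path", list(n = 4))
    b <- nodeBetweenness(asDynamicalNetwork(gp))
    expect_equal(unname(b), c(0, 2, 2, 0))
    gs <- generateReferenceGraph("star", list(n = 8))
    bs <- nodeBetweenness(asDynamicalNetwork(gs))
    expect_equal(unname(bs[1]), choose(7, 2))
    expect_true(all(bs[-1] == 0))
})

test_that("betweenness agrees with a brute-force shortest-path count", {
    g <- generateReferenceGraph("random", list(n = 9, p = 0.5), seed = 7)
    net <- asDynamicalNetwork(g)
    b <- nodeBetweenness(net)
    ## oracle: enumerate all simple paths per pair, count the shortest ones
    n <- igraph::vcount(g)
    acc <- stats::setNames(rep(0, n), igraph::V(g)$name)
    for (s in seq_len(n - 1)) {
        for (t in (s + 1):n) {
            ap <- igraph::all_simple_paths(g, from = s, to = t)
            lens <- vapply(ap, function(p) {
                ep <- igraph::E(g, path = p)
                sum(igraph::E(g)$weight[as.integer(ep)])
            }, numeric(1))
            sh <- which(abs(lens - min(lens)) < 1e-12)
            for (pi in sh) {
                inner <- setdiff(as.integer(ap[[pi]]), c(s, t))
                nm <- igraph::V(g)$name[inner]
                acc[nm] <- acc[nm] + 1 / length(sh)
            }
        }
    }
    expect_equal(b, acc, tolerance = 1e-9)
})

test_that("suboptimal paths equal exhaustive enumeration on small graphs", {
    g <- generateReferenceGraph("random", list(n = 8, p = 0.5), seed = 3)
    net <- asDynamicalNetwork(g)
    pe <- suboptimalPaths(net, "1", "8", k = 10)
    ## oracle: all simple paths sorted by summed weight then lexicographically
    ap <- igraph::all_simple_paths(g, from = "1", to = "8")
    lens <- vapply(ap, function(p) {
        ep <- igraph::E(g, path = p)
        sum(igraph::E(g)$weight[as.integer(ep)])
    }, numeric(1))
    seqs <- lapply(ap, function(p) igraph::V(g)$name[as.integer(p)])
    ord <- order(lens, vapply(seqs, paste, character(1), collapse = "\r"))
    expectPaths <- seqs[ord][1:10]
    expectLens <- lens[ord][1:10]
    expect_equal(pe@lengths, expectLens, tolerance = 1e-12)
    expect_identical(pathList(pe), expectPaths)
    ## optimal path equals the single-source shortest path
    sp <- igraph::shortest_paths(g, from = "1", to = "8",
                                 weights = igraph::E(g)$weight)
    expect_identical(pathList(pe)[[1]],
                     igraph::V(g)$name[as.integer(sp$vpath[[1]])])
    ## degeneracy bounds and endpoints
    deg <- nodeDegeneracy(pe)
    expect_equal(unname(deg[c("1", "8")]), c(1, 1))
    expect_true(all(deg >= 0 & deg <= 1))
})

test_that("path exhaustion, disconnection and histogram behave as specified", {
    ## a graph with exactly 3 simple source-sink paths
    g <- igraph::graph_from_edgelist(
        matrix(c("s", "a", "s", "b", "a", "t", "b", "t", "s", "t"),
               ncol = 2, byrow = TRUE), directed = FALSE)
    igraph::E(g)$weight <- c(1, 2, 1, 2, 5)
    net <- asDynamicalNetwork(g)
    pe <- suboptimalPaths(net, "s", "t", k = 500)
    expect_length(pathList(pe), 3)
    expect_equal(pe@lengths, c(2, 4, 5))

    ## disconnected pair: explicit empty result
    g2 <- igraph::make_graph(~ a - b, c - d)
    igraph::E(g2)$weight <- 1
    pe2 <- suboptimalPaths(asDynamicalNetwork(g2), "a", "c")
    expect_false(pe2@reachable)
    expect_length(pathList(pe2), 0)
    expect_error(suboptimalPaths(net, "s", "s"), "differ")

    ## histogram counts
    h <- pathLengthHistogram(pe, binWidth = 1)
    expect_identical(sum(h$count), 3L)
    hOne <- pathLengthHistogram(pe, binWidth = 100)
    expect_identical(nrow(hOne), 1L)
    expect_identical(hOne$count, 3L)
    ## equal-length ensemble lands in a single bin
    pe3 <- new("PathEnsemble", source = "s", sink = "t",
               paths = list(c("s", "t"), c("s", "a", "t"), c("s", "b", "t")),
               lengths = c(3, 3, 3), k = 3L,
               degeneracy = c(s = 1, t = 1, a = 1 / 3, b = 1 / 3),
               reachable = TRUE)
    h3 <- pathLengthHistogram(pe3, binWidth = 0.5)
    expect_identical(nrow(h3), 1L)
    expect_identical(h3$count, 3L)
})
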