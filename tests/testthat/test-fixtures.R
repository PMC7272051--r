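test_that("complex generation is pure, connected and PDB-writable", {
    spec <- fixtureSpec(nChains = 4, beadsPerChain = 30, seed = 1)
    cx <- generateComplex(spec)
    expect_identical(nResidues(cx$structure), 120L)
    expect_identical(unique(atoms(cx$structure)$chain), c("A", "B", "C", "D"))
    expect_true(MotionDissect:::.topologyConnected(cx$topology, 120L))
    ## bit-reproducible given the spec
    cx2 <- generateComplex(fixtureSpec(nChains = 4, beadsPerChain = 30,
                                       seed = 1))
    expect_identical(coords(cx$structure), coords(cx2$structure))
    ## a different seed moves the beads
    cx3 <- generateComplex(fixtureSpec(seed = 2))
    expect_false(identical(coords(cx$structure), coords(cx3$structure)))
    ## passes all structure invariants and survives PDB round-trip
    expect_true(validObject(cx$structure))
    f <- withr::local_tempfile(fileext = ".pdb")
    writeStructure(cx$structure, f)
    expect_identical(nResidues(readStructure(f)), 120L)
})

test_that("an edgeless request yields extra trivial modes downstream", {
    spec <- fixtureSpec(nChains = 2, beadsPerChain = 4, cutoff = 0,
                        requireConnected = FALSE)
    cx <- generateComplex(spec)
    expect_identical(nrow(cx$topology), 0L)
    H <- buildEnmHessian(cx$structure, topology = cx$topology)
    ## every mode is trivial: there is nothing left to analyse
    expect_error(computeNormalModes(H, particleMasses(cx$structure),
                                    nModes = 1), "exceeds")
})

test_that("variant pairs perturb springs locally and flag the mutation", {
    pair <- generateVariantPair(fixtureSpec())
    expect_lt(nrow(pair$var$topology), nrow(pair$wt$topology))
    ## coordinates are shared; only the network differs
    expect_identical(coords(pair$wt$structure), coords(pair$var$structure))
    expect_identical(sum(pair$mapping@pairs$mutation), 1L)
    expect_identical(pair$mapping@pairs$keyA[pair$mapping@pairs$mutation],
                     pair$site)
    ## every deleted spring touches the neighbourhood of the site
    site <- which(atoms(pair$wt$structure)$chain == "B" &
                  atoms(pair$wt$structure)$resno == 15)
    xyz <- coords(pair$wt$structure)
    near <- which(sqrt(rowSums(sweep(xyz, 2, xyz[site, ])^2)) <= 8)
    del <- pair$wt$topology[pair$perturbedSprings, ]
    expect_true(all(del$i %in% near | del$j %in% near))

    ## null perturbation is rejected; disconnection is flagged
    expect_error(generateVariantPair(fixtureSpec(),
                                     perturbation = list(chain = "B",
                                                         resno = 15,
                                                         fraction = 0)),
                 "at least one spring")
    expect_error(generateVariantPair(fixtureSpec(nChains = 2,
                                                 beadsPerChain = 4,
                                                 cutoff = 4.2,
                                                 requireConnected = FALSE),
                                     perturbation = list(chain = "A",
                                                         resno = 2,
                                                         radius = 20,
                                                         fraction = 1)),
                 "disconnects")
})

test_that("a null perturbation leaves every mode shared with r = 1", {
    spec <- fixtureSpec(nChains = 2, beadsPerChain = 10)
    cx <- generateComplex(spec)
    m <- computeNormalModes(buildEnmHessian(cx$structure,
                                            topology = cx$topology),
                            particleMasses(cx$structure), nModes = 4)
    mkFps <- function(sysId) lapply(modeLabels(m), function(l)
        computeFingerprint(generateModeTrajectory(cx$structure, m, l,
                                                  nFrames = 5),
                           system = sysId))
    fps <- c(mkFps("WT"), mkFps("TWIN"))
    g <- buildSimilarityGraph(fps, nPermutations = 1999, seed = 3)
    R <- similarityMatrix(g)
    for (l in modeLabels(m))
        expect_equal(R[paste0("WT:", l), paste0("TWIN:", l)], 1)
    cls <- classTable(classifyMotions(g, list(WT = "a", TWIN = "a")))
    expect_true(all(cls$class == "shared"))
})

test_that("reference graphs are deterministic with known shapes", {
    b <- generateReferenceGraph("barbell", list(n1 = 12, n2 = 12))
    expect_equal(as.integer(igraph::vcount(b)), 24L)
    expect_equal(as.integer(igraph::ecount(b)), 2 * choose(12, 2) + 1L)
    p <- generateReferenceGraph("path", list(n = 4))
    expect_equal(as.integer(igraph::ecount(p)), 3L)
    r1 <- generateReferenceGraph("random", list(n = 9), seed = 7)
    r2 <- generateReferenceGraph("random", list(n = 9), seed = 7)
    expect_identical(igraph::as_edgelist(r1), igraph::as_edgelist(r2))
    expect_identical(igraph::E(r1)$weight, igraph::E(r2)$weight)
})

test_that("topology JSON round-trips", {
    cx <- generateComplex(fixtureSpec(nChains = 2, beadsPerChain = 6))
    f <- withr::local_tempfile(fileext = ".json")
    exportTopology(cx$topology, f)
    back <- importTopology(f)
    expect_equal(back, cx$topology, ignore_attr = TRUE)
})
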