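test_that("two-body oscillator reproduces the analytic eigenvalue 2k/m", {
    s <- makeStructure("A", 1:2, rbind(c(0, 0, 0), c(3, 0, 0)), mass = 10)
    H <- buildEnmHessian(s, cutoff = 5, springConstant = 1)
    expect_equal(H, t(H))
    ## translational invariance: uniform translations are in the null space
    for (axis in 1:3) {
        t3 <- rep(0, 3); t3[axis] <- 1
        expect_equal(as.vector(H %*% rep(t3, 2)), rep(0, 6),
                     tolerance = 1e-12)
    }
    m <- computeNormalModes(H, particleMasses(s), nModes = 1)
    expect_equal(eigenvalues(m), 2 * 1 / 10, tolerance = 1e-8)
})

test_that("ENM Hessian matches a central finite-difference of the ENM energy", {
    fix <- beadCloud(n = 20, seed = 7)
    H <- buildEnmHessian(fix$structure, topology = fix$topology)
    xyz <- coords(fix$structure)
    n <- nrow(xyz)
    h <- 1e-4
    ## independent oracle: numerical second derivatives of the spring energy
    Hfd <- matrix(0, 3 * n, 3 * n)
    en <- function(x) MotionDissect:::enmEnergy(x, fix$topology)
    for (a in seq_len(3 * n)) {
        for (b in a:(3 * n)) {
            xpp <- xpm <- xmp <- xmm <- xyz
            ia <- (a - 1) %/% 3 + 1; ca <- (a - 1) %% 3 + 1
            ib <- (b - 1) %/% 3 + 1; cb <- (b - 1) %% 3 + 1
            xpp[ia, ca] <- xpp[ia, ca] + h; xpp[ib, cb] <- xpp[ib, cb] + h
            xpm[ia, ca] <- xpm[ia, ca] + h; xpm[ib, cb] <- xpm[ib, cb] - h
            xmp[ia, ca] <- xmp[ia, ca] - h; xmp[ib, cb] <- xmp[ib, cb] + h
            xmm[ia, ca] <- xmm[ia, ca] - h; xmm[ib, cb] <- xmm[ib, cb] - h
            Hfd[a, b] <- Hfd[b, a] <-
                (en(xpp) - en(xpm) - en(xmp) + en(xmm)) / (4 * h * h)
        }
    }
    expect_lt(max(abs(H - Hfd)), 1e-5)
})

test_that("zero-distance particle pairs are rejected", {
    s <- makeStructure("A", 1:2, rbind(c(0, 0, 0), c(0, 0, 0)))
    expect_error(enmTopology(s, cutoff = 5), "zero distance")
})

test_that("connected 3-D fixtures yield exactly six trivial modes", {
    fix <- beadCloud(n = 10, seed = 3)
    H <- buildEnmHessian(fix$structure, topology = fix$topology)
    m <- computeNormalModes(H, particleMasses(fix$structure), nModes = 5)
    expect_identical(nTrivial(m), 6L)
    expect_identical(modeLabels(m), 7:11)
    expect_length(m@trivialValues, 6)
})

test_that("an isolated particle adds trivial modes beyond six", {
    fix <- beadCloud(n = 8, seed = 5)
    far <- makeStructure("A", 1:9,
                         rbind(coords(fix$structure), c(500, 500, 500)),
                         mass = 12)
    H <- buildEnmHessian(far, cutoff = 8)
    ## the isolated bead's rows are zero
    expect_true(all(H[25:27, ] == 0))
    m <- computeNormalModes(H, particleMasses(far), nModes = 3)
    expect_gt(nTrivial(m), 6L)
})

test_that("eigenpairs satisfy the generalized eigenproblem", {
    fix <- beadCloud(n = 20, seed = 7)
    H <- buildEnmHessian(fix$structure, topology = fix$topology)
    masses <- particleMasses(fix$structure)
    m <- computeNormalModes(H, masses, nModes = 10)
    Mdof <- rep(masses, each = 3)
    for (c in seq_len(nModes(m))) {
        v <- modeVectors(m)[, c]
        resid <- H %*% v - eigenvalues(m)[c] * (Mdof * v)
        expect_lt(sqrt(sum(resid^2)), 1e-8)
    }
    expect_error(computeNormalModes(H, masses, nModes = 100), "exceeds")
})

test_that("non-trivial spectrum is invariant under rigid translation", {
    fix <- beadCloud(n = 12, seed = 11)
    m1 <- computeNormalModes(buildEnmHessian(fix$structure,
                                             topology = fix$topology),
                             particleMasses(fix$structure), nModes = 6)
    shifted <- makeStructure("A", 1:12,
                             sweep(coords(fix$structure), 2, c(5, -3, 2), "+"),
                             mass = 12)
    m2 <- computeNormalModes(buildEnmHessian(shifted,
                                             topology = enmTopology(shifted, 8)),
                             particleMasses(shifted), nModes = 6)
    expect_equal(eigenvalues(m1), eigenvalues(m2), tolerance = 1e-8)
})

test_that("mode computation is reproducible including eigenvector signs", {
    fix <- beadCloud(n = 15, seed = 2)
    H <- buildEnmHessian(fix$structure, topology = fix$topology)
    m1 <- computeNormalModes(H, particleMasses(fix$structure), nModes = 8)
    m2 <- computeNormalModes(H, particleMasses(fix$structure), nModes = 8)
    expect_identical(modeVectors(m1), modeVectors(m2))
    ## sign convention: the largest-magnitude component is positive
    for (c in seq_len(8))
        expect_gt(modeVectors(m1)[which.max(abs(modeVectors(m1)[, c])), c], 0)
})

test_that("mode set JSON round-trips", {
    fix <- beadCloud(n = 8, seed = 9)
    m <- computeNormalModes(buildEnmHessian(fix$structure,
                                            topology = fix$topology),
                            particleMasses(fix$structure), nModes = 4)
    f <- withr::local_tempfile(fileext = ".json")
    exportModeSet(m, f)
    m2 <- importModeSet(f)
    expect_equal(eigenvalues(m2), eigenvalues(m))
    expect_equal(modeVectors(m2), modeVectors(m), tolerance = 1e-12)
    expect_identical(nTrivial(m2), nTrivial(m))
})

test_that("unrelaxed trajectories hit their MRMS targets and are antisymmetric", {
    fix <- beadCloud(n = 10, seed = 3)
    m <- computeNormalModes(buildEnmHessian(fix$structure,
                                            topology = fix$topology),
                            particleMasses(fix$structure), nModes = 4)
    tr <- generateModeTrajectory(fix$structure, m, 8, amplitude = 1,
                                 nFrames = 11, relax = FALSE)
    expect_identical(nFrames(tr), 11L)
    expect_lt(max(abs(tr@achieved - abs(tr@targets))), 1e-6)
    x0 <- coords(fix$structure)
    expect_identical(coords(tr, frame = 6), x0)   # centre frame == reference
    for (f in 1:5) {
        dPlus <- tr@frames[[12 - f]] - x0
        dMinus <- tr@frames[[f]] - x0
        expect_equal(dPlus, -dMinus, tolerance = 1e-12)
    }
    expect_error(generateModeTrajectory(fix$structure, m, 8, nFrames = 10),
                 "odd")
    expect_error(generateModeTrajectory(fix$structure, m, 99), "not in ModeSet")
})

test_that("relaxed frames never exceed the harmonic frame's ENM energy", {
    fix <- beadCloud(n = 20, seed = 7)
    m <- computeNormalModes(buildEnmHessian(fix$structure,
                                            topology = fix$topology),
                            particleMasses(fix$structure), nModes = 3)
    lab <- modeLabels(m)[1]
    hard <- generateModeTrajectory(fix$structure, m, lab, amplitude = 1.5,
                                   nFrames = 5, relax = FALSE)
    soft <- generateModeTrajectory(fix$structure, m, lab, amplitude = 1.5,
                                   nFrames = 5, relax = TRUE,
                                   topology = fix$topology)
    for (f in seq_len(5)) {
        eHard <- MotionDissect:::enmEnergy(hard@frames[[f]], fix$topology)
        eSoft <- MotionDissect:::enmEnergy(soft@frames[[f]], fix$topology)
        expect_lte(eSoft, eHard + 1e-9)
    }
    ## the reference frame stays put under relaxation
    expect_equal(soft@frames[[3]], coords(fix$structure))
})

test_that("trajectory export writes one MODEL per frame", {
    fix <- beadCloud(n = 6, seed = 1)
    m <- computeNormalModes(buildEnmHessian(fix$structure,
                                            topology = fix$topology),
                            particleMasses(fix$structure), nModes = 2)
    tr <- generateModeTrajectory(fix$structure, m, 7, nFrames = 5)
    f <- withr::local_tempfile(fileext = ".pdb")
    writeStructure(tr, f)
    lines <- readLines(f)
    expect_identical(sum(grepl("^MODEL", lines)), 5L)
    back <- readStructure(f, model = 3)
    expect_equal(coords(back), coords(fix$structure), tolerance = 1e-3)
})
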