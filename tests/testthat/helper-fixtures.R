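# Shared fixtures for the suite: built in code, deterministic.

# Small connected bead cloud with ENM topology (n beads, ~4 A spacing).
beadCloud <- function(n = 10, seed = 42, cutoff = 8) {
    xyz <- MotionDissect:::.withSeed(seed, {
        x <- matrix(runif(n * 3, 0, 4 + n / 2), ncol = 3)
        # nudge apart any close pair so the network is well-conditioned
        repeat {
            D <- as.matrix(dist(x))
            diag(D) <- Inf
            if (min(D) > 2) break
            i <- which(D == min(D), arr.ind = TRUE)[1, ]
            x[i[1], ] <- x[i[1], ] + runif(3, 0.5, 1)
        }
        x
    })
    s <- makeStructure("A", seq_len(n), xyz, mass = 12)
    ## widen the cutoff if needed so the network is connected and the
    ## trivial-mode count is exactly six
    repeat {
        topo <- enmTopology(s, cutoff = cutoff)
        if (MotionDissect:::.topologyConnected(topo, n)) break
        cutoff <- cutoff * 1.3
    }
    list(structure = s, topology = topo, cutoff = cutoff)
}

# A tiny two-chain peptide-like PDB text fixture (3 residues, full names).
writeMiniPdb <- function(path) {
    lines <- c(
        "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
        "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
        "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
        "ATOM      4  N   GLY A   2       3.300   1.500   0.100  1.00  0.00           N",
        "ATOM      5  CA  GLY A   2       4.100   2.700   0.200  1.00  0.00           C",
        "ATOM      6  C   GLY A   2       5.500   2.500   0.700  1.00  0.00           C",
        "ATOM      7  N   SER A   3       6.300   3.500   0.900  1.00  0.00           N",
        "ATOM      8  CA  SER A   3       7.700   3.400   1.400  1.00  0.00           C",
        "ATOM      9  OG  SER A   3       8.400   4.600   1.200  1.00  0.00           O",
        "END")
    writeLines(lines, path)
    path
}

# Symmetric zero-diagonal matrix wrapped as a fingerprint.
matFingerprint <- function(m, system = "S", label = 7L) {
    m <- as.matrix(m)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    dimnames(m) <- NULL
    new("MotionFingerprint", system = system, modeLabel = as.integer(label),
        delta = m, keys = paste0("A:", seq_len(nrow(m))),
        minusSimilarity = NA_real_)
}

# Random symmetric fingerprint of dimension n.
randomFingerprint <- function(n, seed, system = "S", label = 7L) {
    m <- MotionDissect:::.withSeed(seed, matrix(rnorm(n * n), n, n))
    matFingerprint(m + t(m), system, label)
}

# Trajectory object assembled directly from a list of coordinate frames.
frameTrajectory <- function(structure, frames, label = 7L) {
    nf <- length(frames)
    targets <- seq(-1, 1, length.out = nf)
    if (nf %% 2L == 1L) targets[(nf + 1L) %/% 2L] <- 0
    new("ModeTrajectory", modeLabel = as.integer(label),
        reference = structure, frames = frames, targets = targets,
        achieved = rep(0, nf), relaxed = FALSE, converged = rep(TRUE, nf))
}
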