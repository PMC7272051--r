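# Hand-placed polar geometries: a serine-like O-H donor and a backbone
# carbonyl O acceptor whose separation we control per frame.
hbondSystem <- function(dOA, bend = 0) {
    ## donor O at origin, H on the x axis, acceptor O beyond it, optionally
    ## bent by `bend` degrees out of the O-H line
    th <- bend * pi / 180
    xyz <- rbind(c(0, 0, 0),                              # OG  (donor)
                 c(0.96, 0, 0),                           # HG
                 c(0.96 + (dOA - 0.96) * cos(th),
                   (dOA - 0.96) * sin(th), 0),            # O (acceptor)
                 c(10, 10, 10))                           # spectator CA
    atoms <- data.frame(
        serial = 1:4, name = c("OG", "HG", "O", "CA"),
        element = c("O", "H", "O", "C"),
        mass = c(15.999, 1.008, 15.999, 12.011),
        chain = "A", resno = c(1L, 1L, 2L, 3L), insert = "",
        resid = c("SER", "SER", "GLY", "GLY"),
        stringsAsFactors = FALSE)
    new("MolecularStructure", atoms = atoms, xyz = xyz)
}

# Asp/Lys side-chain pair with a controllable O-N distance.
saltSystem <- function(dON) {
    xyz <- rbind(c(0, 0, 0), c(dON, 0, 0), c(8, 8, 8))
    atoms <- data.frame(
        serial = 1:3, name = c("OD1", "NZ", "CA"),
        element = c("O", "N", "C"), mass = c(15.999, 14.007, 12.011),
        chain = "A", resno = c(1L, 2L, 3L), insert = "",
        resid = c("ASP", "LYS", "GLY"), stringsAsFactors = FALSE)
    new("MolecularStructure", atoms = atoms, xyz = xyz)
}

# A deliberately small run configuration so the orchestration logic can be
# exercised quickly; the full-size study conditions are covered by the
# acceptance suite.
smallPairConfig <- function(seed = 1L, relax = FALSE) {
    pair <- generateVariantPair(
        fixtureSpec(nChains = 2, beadsPerChain = 10, seed = 5),
        perturbation = list(chain = "A", resno = 5, radius = 8,
                            fraction = 0.4))
    makeRunConfig(
        systems = list(
            list(id = "WT", structure = pair$wt$structure,
                 topologyTable = pair$wt$topology,
                 phenotypes = c("alpha", "beta")),
            list(id = "VAR", structure = pair$var$structure,
                 topologyTable = pair$var$topology,
                 phenotypes = "alpha")),
        seed = seed,
        nma = list(nModes = 4L, nFrames = 5L, relax = relax),
        similarity = list(nPermutations = 1999L),
        network = list(minCommunitySize = 3L, kPaths = 20L))
}
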