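#' @describeIn MolecularStructure number of atoms
#' @param x,object a `MolecularStructure`
#' @export
setMethod("nAtoms", "MolecularStructure", function(x) nrow(x@atoms))

#' @describeIn MolecularStructure number of residues
#' @export
setMethod("nResidues", "MolecularStructure", function(x)
    length(unique(.atomResidueKeys(x@atoms))))

#' @describeIn MolecularStructure residue keys in structure order
#' @export
setMethod("residueKeys", "MolecularStructure", function(x) {
    k <- .atomResidueKeys(x@atoms)
    k[!duplicated(k)]
})

#' @describeIn MolecularStructure coordinate matrix (n x 3)
#' @param ... unused
#' @export
setMethod("coords", "MolecularStructure", function(x, ...) x@xyz)

#' @describeIn MolecularStructure atom table
#' @export
setMethod("atoms", "MolecularStructure", function(x) x@atoms)

#' @describeIn MolecularStructure per-atom masses (amu)
#' @export
setMethod("particleMasses", "MolecularStructure", function(x) x@atoms$mass)

setMethod("show", "MolecularStructure", function(object) {
    ch <- unique(object@atoms$chain)
    cat("MolecularStructure:", nAtoms(object), "atoms,",
        nResidues(object), "residues,", length(ch), "chain(s)",
        if (length(ch)) paste0("[", paste(ch, collapse = ","), "]"), "\n")
})

#' @describeIn ModeSet number of kept (non-trivial) modes
#' @param x,object a `ModeSet`
#' @export
setMethod("nModes", "ModeSet", function(x) length(x@values))

#' @describeIn ModeSet eigenvalues, ascending
#' @export
setMethod("eigenvalues", "ModeSet", function(x) x@values)

#' @describeIn ModeSet mode displacement vectors (3N x m)
#' @export
setMethod("modeVectors", "ModeSet", function(x) x@vectors)

#' @describeIn ModeSet mode labels
#' @export
setMethod("modeLabels", "ModeSet", function(x) x@labels)

#' @describeIn ModeSet number of trivial modes
#' @export
setMethod("nTrivial", "ModeSet", function(x) x@nTrivial)

#' @describeIn ModeSet per-particle masses
#' @export
setMethod("particleMasses", "ModeSet", function(x) x@masses)

setMethod("show", "ModeSet", function(object) {
    cat("ModeSet:", nModes(object), "non-trivial modes (labels",
        if (nModes(object)) paste0(min(object@labels), "-", max(object@labels))
        else "none", "),", object@nTrivial, "trivial modes excluded\n")
})

#' @describeIn ModeTrajectory number of frames
#' @param x,object a `ModeTrajectory`
#' @export
setMethod("nFrames", "ModeTrajectory", function(x) length(x@frames))

#' @describeIn ModeTrajectory mode label of the source mode
#' @export
setMethod("modeLabels", "ModeTrajectory", function(x) x@modeLabel)

#' @describeIn ModeTrajectory coordinates of one frame
#' @param frame frame index (1-based)
#' @param ... unused
#' @export
setMethod("coords", "ModeTrajectory", function(x, frame = 1L, ...)
    x@frames[[frame]])

#' @describeIn ModeTrajectory atoms of the reference structure
#' @export
setMethod("nAtoms", "ModeTrajectory", function(x) nAtoms(x@reference))

setMethod("show", "ModeTrajectory", function(object) {
    cat("ModeTrajectory: mode", object@modeLabel, "-", nFrames(object),
        "frames, MRMS", min(object@targets), "to", max(object@targets),
        "A,", if (object@relaxed) "relaxed" else "harmonic", "\n")
})

#' @describeIn MotionFingerprint fingerprint matrix
#' @param x,object a `MotionFingerprint`
#' @export
setMethod("fingerprintMatrix", "MotionFingerprint", function(x) x@delta)

#' @describeIn MotionFingerprint residue keys
#' @export
setMethod("residueKeys", "MotionFingerprint", function(x) x@keys)

#' @describeIn MotionFingerprint source mode label
#' @export
setMethod("modeLabels", "MotionFingerprint", function(x) x@modeLabel)

setMethod("show", "MotionFingerprint", function(object) {
    cat("MotionFingerprint:", object@system, "mode", object@modeLabel,
        "-", nrow(object@delta), "C-alpha positions; cor(M+, M-) =",
        signif(object@minusSimilarity, 3), "\n")
})

setMethod("show", "MantelResult", function(object) {
    cat(sprintf("MantelResult: r = %.4f, p = %.4g (%s, %d permutations)\n",
                object@r, object@pValue, object@scheme, object@nPermutations))
})

#' @describeIn ModeSimilarityGraph full Mantel r matrix
#' @param x,object a `ModeSimilarityGraph`
#' @export
setMethod("similarityMatrix", "ModeSimilarityGraph", function(x) x@rMatrix)

#' @describeIn ModeSimilarityGraph edge table
#' @export
setMethod("graphEdges", "ModeSimilarityGraph", function(x) x@edges)

setMethod("show", "ModeSimilarityGraph", function(object) {
    cat("ModeSimilarityGraph:", nrow(object@nodes), "modes over",
        length(unique(object@nodes$system)), "system(s),",
        nrow(object@edges), "edges (|r| >=", object@rThreshold,
        ", p <", object@pThreshold, ")\n")
})

#' @describeIn MotionClassification classification table
#' @param x,object a `MotionClassification`
#' @export
setMethod("classTable", "MotionClassification", function(x) x@classes)

setMethod("show", "MotionClassification", function(object) {
    tab <- table(object@classes$classLabel)
    cat("MotionClassification:", nrow(object@classes), "modes in",
        length(object@components), "components\n")
    for (nm in names(tab)) cat(" ", nm, ":", tab[[nm]], "\n")
})

#' @describeIn CrossCorrelationMatrix correlation matrix
#' @param x,object a `CrossCorrelationMatrix`
#' @export
setMethod("correlationMatrix", "CrossCorrelationMatrix", function(x) x@corr)

#' @describeIn CrossCorrelationMatrix residue keys
#' @export
setMethod("residueKeys", "CrossCorrelationMatrix", function(x) x@keys)

setMethod("show", "CrossCorrelationMatrix", function(object) {
    cat("CrossCorrelationMatrix:", nrow(object@corr), "x", ncol(object@corr),
        "over", object@nFrames, "frames (modes",
        paste(object@sources, collapse = ","), ")\n")
})

setMethod("show", "FlexibilityProfile", function(object) {
    cat("FlexibilityProfile:", object@groupId, "-", length(object@values),
        "residues, mean rmsf", signif(mean(object@values), 3), "A\n")
})

#' @describeIn DynamicalNetwork residue keys of all nodes
#' @param x,object a `DynamicalNetwork`
#' @export
setMethod("residueKeys", "DynamicalNetwork", function(x) x@keys)

setMethod("show", "DynamicalNetwork", function(object) {
    cat("DynamicalNetwork:", length(object@keys), "nodes,",
        igraph::ecount(object@graph), "edges (|C| >=",
        object@params$corrThreshold, ", d <=", object@params$distThreshold,
        "A in >=", object@params$frameFraction * 100, "% of frames)\n")
})

#' @describeIn CommunityPartition membership vector (NA = pruned)
#' @param x,object a `CommunityPartition`
#' @export
setMethod("communityMembership", "CommunityPartition", function(x) x@membership)

setMethod("show", "CommunityPartition", function(object) {
    cat("CommunityPartition:", object@nCommunities, "communities, modularity",
        signif(object@modularity, 4), "(max", signif(object@maxModularity, 4),
        "),", length(object@pruned), "nodes pruned\n")
})

#' @describeIn PathEnsemble path list
#' @param x,object a `PathEnsemble`
#' @export
setMethod("pathList", "PathEnsemble", function(x) x@paths)

#' @describeIn PathEnsemble node degeneracy
#' @export
setMethod("nodeDegeneracy", "PathEnsemble", function(x) x@degeneracy)

setMethod("show", "PathEnsemble", function(object) {
    if (!object@reachable) {
        cat("PathEnsemble:", object@source, "->", object@sink,
            "- no path (disconnected)\n")
    } else {
        cat("PathEnsemble:", object@source, "->", object@sink, "-",
            length(object@paths), "paths, lengths",
            signif(min(object@lengths), 4), "to",
            signif(max(object@lengths), 4), "\n")
    }
})
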