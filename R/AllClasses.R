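#' @import methods
NULL

#' MolecularStructure: atoms, residues and chains with coordinates
#'
#' Container for a (possibly coarse-grained) molecular structure.  Atoms are
#' rows of the `atoms` data.frame (serial, name, element, mass, chain, resno,
#' insert, resid) and coordinates live in the `xyz` matrix (one row per atom,
#' Angstrom).  Residue identity follows author numbering: a residue is keyed
#' by `(chain, resno, insert)` and rendered as `"chain:resno"` or
#' `"chain:resno^insert"`.
#'
#' @slot atoms data.frame with columns `serial`, `name`, `element`, `mass`,
#'   `chain`, `resno`, `insert`, `resid`.
#' @slot xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @exportClass MolecularStructure
setClass("MolecularStructure",
    representation(atoms = "data.frame", xyz = "matrix"))

setValidity("MolecularStructure", function(object) {
    a <- object@atoms
    need <- c("serial", "name", "element", "mass", "chain", "resno",
              "insert", "resid")
    if (!all(need %in% names(a)))
        return(paste("atoms must have columns:", paste(need, collapse = ", ")))
    if (nrow(a) != nrow(object@xyz) || ncol(object@xyz) != 3L)
        return("xyz must be an n_atoms x 3 matrix")
    if (nrow(a) > 0 && !all(is.finite(object@xyz)))
        return("coordinates must be finite")
    if (nrow(a) > 0 && !all(a$mass > 0))
        return("masses must be strictly positive")
    ## residue ordering within a chain strictly increasing by (resno, insert)
    if (nrow(a) > 0) {
        key <- paste(a$chain, a$resno, a$insert, sep = "\r")
        res <- !duplicated(key)
        rk <- data.frame(chain = a$chain[res], resno = a$resno[res],
                         insert = a$insert[res], stringsAsFactors = FALSE)
        for (ch in unique(rk$chain)) {
            sub <- rk[rk$chain == ch, ]
            o <- order(sub$resno, sub$insert)
            if (!identical(o, seq_len(nrow(sub))))
                return(sprintf("residues in chain %s not in increasing order", ch))
            if (anyDuplicated(paste(sub$resno, sub$insert)))
                return(sprintf("duplicate residue key in chain %s", ch))
        }
    }
    TRUE
})

#' ResidueMapping: residue correspondence between two structures
#'
#' Pairs residues of two systems by `(chain, resno, insert)`.  Substitutions
#' (same key, different residue name) are retained and flagged as mutations.
#'
#' @slot pairs data.frame with columns `keyA`, `keyB`, `residA`, `residB`,
#'   `mutation` (logical).
#' @slot unmappedA,unmappedB character vectors of residue keys present in
#'   only one structure.
#' @exportClass ResidueMapping
setClass("ResidueMapping",
    representation(pairs = "data.frame", unmappedA = "character",
                   unmappedB = "character"))

setValidity("ResidueMapping", function(object) {
    p <- object@pairs
    if (anyDuplicated(p$keyA) || anyDuplicated(p$keyB))
        return("mapping must be injective on both sides")
    TRUE
})

#' ModeSet: eigenpairs of the mass-weighted Hessian
#'
#' Solutions of the generalised eigenproblem H v = lambda M v.  Eigenvectors
#' are stored as Cartesian displacement directions, orthonormal under the
#' mass metric (t(v) M v = I).  Trivial (rigid-body) modes are excluded from
#' the stored set but counted, and mode labels follow the convention of the
#' field: with 6 rigid-body modes the first internal mode is mode 7.
#'
#' @slot values non-trivial eigenvalues kept, ascending.
#' @slot vectors 3N x m matrix of mass-metric-orthonormal displacement
#'   directions, one column per kept mode.
#' @slot masses per-particle masses (amu).
#' @slot nTrivial number of near-zero modes excluded from analysis numbering.
#' @slot labels integer mode labels, `nTrivial + 1` upward.
#' @slot trivialValues eigenvalues of the excluded near-zero modes.
#' @exportClass ModeSet
setClass("ModeSet",
    representation(values = "numeric", vectors = "matrix",
                   masses = "numeric", nTrivial = "integer",
                   labels = "integer", trivialValues = "numeric"))

setValidity("ModeSet", function(object) {
    m <- ncol(object@vectors)
    if (length(object@values) != m || length(object@labels) != m)
        return("values/labels length must match number of mode vectors")
    if (m > 1 && any(diff(object@values) < -1e-10))
        return("eigenvalues must be non-decreasing")
    if (nrow(object@vectors) != 3L * length(object@masses))
        return("vectors must have 3N rows")
    if (m > 0) {
        mdof <- rep(object@masses, each = 3L)
        G <- crossprod(object@vectors * mdof, object@vectors)
        if (max(abs(G - diag(m))) > 1e-8)
            return("eigenvectors must be orthonormal under the mass metric")
    }
    TRUE
})

#' ModeTrajectory: frames displaced along one normal mode
#'
#' Pseudo-trajectory obtained by displacing a reference structure along one
#' mode at equally spaced mass-weighted RMS (MRMS) targets in [-A, +A],
#' optionally relaxed under the elastic-network energy with a harmonic
#' restraint on the MRMS coordinate.
#'
#' @slot modeLabel label of the source mode.
#' @slot reference the reference [MolecularStructure-class].
#' @slot frames list of n_atoms x 3 coordinate matrices, one per frame.
#' @slot targets signed MRMS targets (Angstrom), ascending, containing 0.
#' @slot achieved achieved (unsigned) MRMS displacement per frame.
#' @slot relaxed logical scalar: were frames energy-relaxed?
#' @slot converged per-frame convergence flag (all TRUE when relaxed=FALSE).
#' @exportClass ModeTrajectory
setClass("ModeTrajectory",
    representation(modeLabel = "integer", reference = "MolecularStructure",
                   frames = "list", targets = "numeric",
                   achieved = "numeric", relaxed = "logical",
                   converged = "logical"))

setValidity("ModeTrajectory", function(object) {
    nf <- length(object@frames)
    if (length(object@targets) != nf || length(object@achieved) != nf ||
        length(object@converged) != nf)
        return("targets/achieved/converged must be one per frame")
    n <- nrow(object@reference@xyz)
    if (nf > 0 && !all(vapply(object@frames, function(f)
            is.matrix(f) && nrow(f) == n && ncol(f) == 3L, logical(1))))
        return("every frame must share atom count and ordering with reference")
    TRUE
})

#' MotionFingerprint: distance-difference signature of one motion
#'
#' The C-alpha distance-difference matrix `M+ - Mx` where `Mx` is the
#' reference-structure distance matrix and `M+` the distance matrix of the
#' frame displaced at +A MRMS along the mode.  Isometry-invariant, so a pure
#' rigid-body motion fingerprints as zero.
#'
#' @slot system system identifier.
#' @slot modeLabel mode label.
#' @slot delta symmetric distance-difference matrix (Angstrom), zero diagonal.
#' @slot keys residue keys defining row/column order.
#' @slot minusSimilarity Pearson r between the `M+ - Mx` and `M- - Mx`
#'   matrices (reported; only the plus matrix is kept).
#' @exportClass MotionFingerprint
setClass("MotionFingerprint",
    representation(system = "character", modeLabel = "integer",
                   delta = "matrix", keys = "character",
                   minusSimilarity = "numeric"))

setValidity("MotionFingerprint", function(object) {
    d <- object@delta
    if (nrow(d) != ncol(d) || nrow(d) != length(object@keys))
        return("delta dimensions must match residue key list")
    if (nrow(d) > 0) {
        if (max(abs(d - t(d))) > 1e-9) return("delta must be symmetric")
        if (max(abs(diag(d))) > 1e-9) return("delta must have zero diagonal")
    }
    TRUE
})

#' MantelResult: permutation-test comparison of two fingerprints
#'
#' @slot r Pearson correlation of the vectorised upper triangles.
#' @slot pValue permutation p-value (never 0; exhaustive p >= 1/n!).
#' @slot nPermutations permutations used (n! - 1 non-identity ones when
#'   exhaustive).
#' @slot scheme "exhaustive" or "sampled".
#' @slot seed RNG seed used for the sampled scheme (NA when exhaustive).
#' @exportClass MantelResult
setClass("MantelResult",
    representation(r = "numeric", pValue = "numeric",
                   nPermutations = "integer", scheme = "character",
                   seed = "integer"))

setValidity("MantelResult", function(object) {
    if (!is.na(object@r) && (object@r < -1 - 1e-12 || object@r > 1 + 1e-12))
        return("r must lie in [-1, 1]")
    if (object@pValue <= 0 || object@pValue > 1)
        return("p-value must lie in (0, 1]")
    if (!object@scheme %in% c("exhaustive", "sampled"))
        return("scheme must be 'exhaustive' or 'sampled'")
    TRUE
})

#' ModeSimilarityGraph: Mantel similarity graph over (system, mode) nodes
#'
#' Nodes are analysed modes of every system; edges connect mode pairs whose
#' fingerprints satisfy |r| >= rThreshold and p < pThreshold.  The full r
#' matrix over all pairs is retained for reporting; p-values are computed
#' for pairs passing the |r| screen (NA elsewhere).
#'
#' @slot nodes data.frame(system, mode).
#' @slot edges data.frame(from, to, r, p) with node indices.
#' @slot rMatrix,pMatrix square matrices over nodes.
#' @slot rThreshold,pThreshold,nPermutations parameters used.
#' @exportClass ModeSimilarityGraph
setClass("ModeSimilarityGraph",
    representation(nodes = "data.frame", edges = "data.frame",
                   rMatrix = "matrix", pMatrix = "matrix",
                   rThreshold = "numeric", pThreshold = "numeric",
                   nPermutations = "integer"))

setValidity("ModeSimilarityGraph", function(object) {
    e <- object@edges
    if (nrow(e) > 0) {
        if (any(e$from == e$to)) return("no self-edges allowed")
        if (any(abs(e$r) < object@rThreshold - 1e-12))
            return("every edge must satisfy the |r| threshold")
        if (any(e$p >= object@pThreshold))
            return("every edge must satisfy the p threshold")
    }
    TRUE
})

#' MotionClassification: shared / system-unique labels for analysed modes
#'
#' Connected components of the similarity graph, labelled by the systems
#' they span and tagged with the signaling outcomes those systems support.
#' A component spanning several systems is a shared motion (tagged with the
#' outcomes common to its systems); a component confined to one system is
#' unique to it (tagged with the outcomes that distinguish that system, or
#' "novel" when none do).
#'
#' @slot classes data.frame(system, mode, component, class, classLabel, tag).
#' @slot components list of node index vectors, one per component.
#' @slot phenotypes named list: system -> character vector of outcomes.
#' @exportClass MotionClassification
setClass("MotionClassification",
    representation(classes = "data.frame", components = "list",
                   phenotypes = "list"))

#' CrossCorrelationMatrix: dynamic cross-correlation map
#'
#' Normalised covariance of atomic displacements about the ensemble mean,
#' over the concatenated frames of a group of mode trajectories.  Entries in
#' [-1, 1]; atoms with zero fluctuation carry NA rows (undefined, not 0).
#'
#' @slot corr symmetric correlation matrix over the selection.
#' @slot keys residue keys for rows/columns.
#' @slot nFrames number of frames pooled.
#' @slot sources mode labels of the contributing trajectories.
#' @exportClass CrossCorrelationMatrix
setClass("CrossCorrelationMatrix",
    representation(corr = "matrix", keys = "character", nFrames = "integer",
                   sources = "integer"))

setValidity("CrossCorrelationMatrix", function(object) {
    C <- object@corr
    ok <- !is.na(C)
    if (any(abs(C[ok]) > 1 + 1e-9)) return("correlations must lie in [-1, 1]")
    if (nrow(C) > 0 && max(abs(C[ok & t(ok)] - t(C)[ok & t(ok)])) > 1e-9)
        return("C must be symmetric")
    TRUE
})

#' FlexibilityProfile: per-residue RMSF of a mode group
#'
#' @slot values per-C-alpha root-mean-square fluctuation (Angstrom), named
#'   by residue key.
#' @slot groupId identifier of the mode group.
#' @slot modes member mode labels.
#' @exportClass FlexibilityProfile
setClass("FlexibilityProfile",
    representation(values = "numeric", groupId = "character",
                   modes = "integer"))

setValidity("FlexibilityProfile", function(object) {
    if (any(object@values < 0)) return("rmsf must be non-negative")
    TRUE
})

#' DynamicalNetwork: weighted residue interaction graph
#'
#' Undirected graph over C-alpha nodes.  An edge (i, j) exists when
#' |C(i,j)| >= corrThreshold and the C-alpha pair is within distThreshold
#' for at least frameFraction of the pooled frames; its weight is
#' -log(|C(i,j)|), so stronger correlation means shorter network distance.
#'
#' @slot graph the underlying igraph object (vertex names = residue keys;
#'   edge attributes `C`, `contactFraction`, `weight`).
#' @slot keys residue keys (all nodes, including isolated ones).
#' @slot params construction parameters.
#' @exportClass DynamicalNetwork
setClass("DynamicalNetwork",
    representation(graph = "ANY", keys = "character", params = "list"))

#' CommunityPartition: Girvan-Newman communities of a dynamical network
#'
#' Partition chosen among the Girvan-Newman dendrogram cuts whose modularity
#' is within a tolerance of the maximum, preferring fewer communities;
#' communities below a minimum size are pruned (members unassigned).
#'
#' @slot membership integer community id per node (NA = pruned/unassigned),
#'   named by residue key.
#' @slot modularity modularity of the selected partition (before pruning).
#' @slot maxModularity maximum modularity over all dendrogram cuts.
#' @slot nCommunities number of communities after pruning.
#' @slot pruned residue keys of pruned nodes.
#' @slot coupling symmetric matrix of inter-community coupling strengths
#'   (summed |C| over crossing edges, normalised by the largest such sum).
#' @exportClass CommunityPartition
setClass("CommunityPartition",
    representation(membership = "integer", modularity = "numeric",
                   maxModularity = "numeric", nCommunities = "integer",
                   pruned = "character", coupling = "matrix"))

#' PathEnsemble: optimal and suboptimal communication paths
#'
#' The k lowest-total-weight simple paths between a source and sink node,
#' sorted by non-decreasing length (ties broken lexicographically on the
#' node sequence), with the fraction of paths visiting each node (node
#' degeneracy).
#'
#' @slot source,sink residue keys of the endpoints.
#' @slot paths list of residue-key sequences, optimal first.
#' @slot lengths summed edge weights per path, non-decreasing.
#' @slot k number of paths requested.
#' @slot degeneracy named fraction of paths through each visited node.
#' @slot reachable FALSE when source and sink are disconnected.
#' @exportClass PathEnsemble
setClass("PathEnsemble",
    representation(source = "character", sink = "character",
                   paths = "list", lengths = "numeric", k = "integer",
                   degeneracy = "numeric", reachable = "logical"))

setValidity("PathEnsemble", function(object) {
    if (length(object@lengths) != length(object@paths))
        return("one length per path")
    if (length(object@lengths) > 1 && any(diff(object@lengths) < -1e-12))
        return("paths must be sorted by non-decreasing length")
    if (length(object@degeneracy) &&
        (any(object@degeneracy < 0) || any(object@degeneracy > 1 + 1e-12)))
        return("degeneracy must lie in [0, 1]")
    if (length(object@paths)) {
        if (abs(object@degeneracy[[object@source]] - 1) > 1e-12 ||
            abs(object@degeneracy[[object@sink]] - 1) > 1e-12)
            return("source and sink degeneracy must equal 1")
    }
    TRUE
})
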