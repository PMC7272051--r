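#' Number of atoms in a structure
#' @param x a [MolecularStructure-class] or [ModeTrajectory-class]
#' @return integer scalar
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Number of residues
#' @param x a [MolecularStructure-class]
#' @return integer scalar
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Residue keys ("chain:resno" with optional "^insert"), in structure order
#' @param x an object with residue identity
#' @return character vector
#' @export
setGeneric("residueKeys", function(x) standardGeneric("residueKeys"))

#' Atomic coordinates
#' @param x an object carrying coordinates
#' @param ... further arguments for methods
#' @return numeric matrix (n x 3, Angstrom)
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' Atom table
#' @param x a [MolecularStructure-class]
#' @return data.frame of atoms
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Per-particle masses (amu)
#' @param x an object carrying masses
#' @return numeric vector
#' @export
setGeneric("particleMasses", function(x) standardGeneric("particleMasses"))

#' Number of (non-trivial) modes kept
#' @param x a [ModeSet-class]
#' @return integer scalar
#' @export
setGeneric("nModes", function(x) standardGeneric("nModes"))

#' Eigenvalues of the kept modes (mass-weighted Hessian units, ascending)
#' @param x a [ModeSet-class]
#' @return numeric vector
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' Mode displacement vectors (3N x m, mass-metric orthonormal)
#' @param x a [ModeSet-class]
#' @return numeric matrix
#' @export
setGeneric("modeVectors", function(x) standardGeneric("modeVectors"))

#' Mode labels (first non-trivial mode is nTrivial + 1, conventionally 7)
#' @param x a [ModeSet-class] or trajectory/fingerprint
#' @return integer vector
#' @export
setGeneric("modeLabels", function(x) standardGeneric("modeLabels"))

#' Number of trivial (rigid-body) modes detected
#' @param x a [ModeSet-class]
#' @return integer scalar
#' @export
setGeneric("nTrivial", function(x) standardGeneric("nTrivial"))

#' Number of frames
#' @param x a [ModeTrajectory-class]
#' @return integer scalar
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Fingerprint matrix (M+ - Mx)
#' @param x a [MotionFingerprint-class]
#' @return symmetric numeric matrix
#' @export
setGeneric("fingerprintMatrix", function(x) standardGeneric("fingerprintMatrix"))

#' Similarity (Mantel r) matrix over all analysed mode pairs
#' @param x a [ModeSimilarityGraph-class]
#' @return numeric matrix with dimnames "system:mode"
#' @export
setGeneric("similarityMatrix", function(x) standardGeneric("similarityMatrix"))

#' Edge table of a similarity graph
#' @param x a [ModeSimilarityGraph-class]
#' @return data.frame(from, to, r, p)
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' Classification table
#' @param x a [MotionClassification-class]
#' @return data.frame(system, mode, component, class, classLabel, tag)
#' @export
setGeneric("classTable", function(x) standardGeneric("classTable"))

#' Correlation matrix of a DCCM
#' @param x a [CrossCorrelationMatrix-class]
#' @return numeric matrix
#' @export
setGeneric("correlationMatrix", function(x) standardGeneric("correlationMatrix"))

#' Community membership (NA = pruned)
#' @param x a [CommunityPartition-class]
#' @return named integer vector
#' @export
setGeneric("communityMembership",
           function(x) standardGeneric("communityMembership"))

#' Paths of an ensemble
#' @param x a [PathEnsemble-class]
#' @return list of residue-key vectors
#' @export
setGeneric("pathList", function(x) standardGeneric("pathList"))

#' Node degeneracy (fraction of ensemble paths through each node)
#' @param x a [PathEnsemble-class]
#' @return named numeric vector in [0, 1]
#' @export
setGeneric("nodeDegeneracy", function(x) standardGeneric("nodeDegeneracy"))
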