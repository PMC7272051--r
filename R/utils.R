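# Internal helpers shared across modules.

# Residue key rendering: "chain:resno" plus "^insert" when present.
.atomResidueKeys <- function(atoms) {
    ins <- ifelse(is.na(atoms$insert) | atoms$insert == "", "",
                  paste0("^", atoms$insert))
    paste0(atoms$chain, ":", atoms$resno, ins)
}

.makeResidueKey <- function(chain, resno, insert = "") {
    ins <- ifelse(is.na(insert) | insert == "", "", paste0("^", insert))
    paste0(chain, ":", resno, ins)
}

# Evaluate expr with a locally-set RNG seed, restoring global RNG state.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(if (exists(".Random.seed", envir = globalenv(),
                           inherits = FALSE))
                    rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# Least-squares (Kabsch) superposition of coordinate matrix X onto Y using
# the rows in `fit`; the returned transform is applied to all rows of X.
.superpose <- function(X, Y, fit = seq_len(nrow(X))) {
    cx <- colMeans(X[fit, , drop = FALSE])
    cy <- colMeans(Y[fit, , drop = FALSE])
    A <- crossprod(sweep(X[fit, , drop = FALSE], 2, cx),
                   sweep(Y[fit, , drop = FALSE], 2, cy))
    sv <- svd(A)
    d <- sign(det(tcrossprod(sv$v, sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    sweep(sweep(X, 2, cx) %*% t(R), 2, cy, "+")
}

# Upper-triangle (i < j) index pair matrix for an n x n matrix.
.upperIdx <- function(n) {
    which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

# All permutations of 1..n (n small; used for exhaustive Mantel p).
.allPermutations <- function(n) {
    if (n == 1L) return(list(1L))
    sub <- .allPermutations(n - 1L)
    out <- vector("list", n * length(sub))
    k <- 0L
    for (i in seq_len(n)) {
        for (p in sub) {
            q <- integer(n)
            q[i] <- n
            q[-i] <- p
            k <- k + 1L
            out[[k]] <- q
        }
    }
    out
}

# Pairwise Euclidean distance matrix of an n x 3 coordinate block.
.distMatrix <- function(xyz) {
    as.matrix(stats::dist(xyz))
}

# Atomic masses (amu) for elements seen in protein PDB files; bead models
# fall back to the pseudo-atom mass set at generation time.
.elementMasses <- c(
    H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
    P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
    "NA" = 22.990, K = 39.098, MG = 24.305, CA = 40.078, MN = 54.938,
    FE = 55.845, CO = 58.933, NI = 58.693, CU = 63.546, ZN = 65.38,
    SE = 78.971
)

.massForElement <- function(element, name) {
    el <- toupper(trimws(element))
    m <- unname(.elementMasses[el])
    miss <- is.na(m)
    if (any(miss)) {
        # guess from the first alphabetic character of the atom name
        guess <- toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", name[miss]))
        m[miss] <- unname(.elementMasses[guess])
        m[is.na(m)] <- 12.011
    }
    m
}

.standardAminoAcids <- c(
    "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
    "MSE", "HSD", "HSE", "HSP"
)

.waterNames <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "DOD")
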