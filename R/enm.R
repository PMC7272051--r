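#' Elastic-network topology of a structure
#'
#' Lists the harmonic springs of an anisotropic network model: one spring of
#' stiffness `springConstant` per particle pair within `cutoff`, with
#' equilibrium length equal to the pair's distance in the input structure.
#' The topology is the pluggable part of the Hessian: springs may be
#' deleted, added or re-weighted (this is how the fixture generator encodes
#' a point mutation) before building the Hessian or relaxing frames.
#'
#' @param structure a [MolecularStructure-class].
#' @param cutoff contact cutoff in Angstrom (default 10).
#' @param springConstant uniform spring stiffness (default 1, arbitrary
#'   energy units / A^2).
#' @return data.frame with columns `i`, `j` (atom indices, i < j), `k`
#'   (stiffness) and `r0` (equilibrium length, A).
#' @export
enmTopology <- function(structure, cutoff = 10, springConstant = 1) {
    stopifnot(cutoff > 0, springConstant > 0)
    xyz <- coords(structure)
    n <- nrow(xyz)
    if (n < 2L) stop("need at least 2 particles for an elastic network")
    D <- .distMatrix(xyz)
    ij <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)
    if (nrow(ij) > 0 && any(D[ij] < 1e-6))
        stop("particle pair at zero distance; cannot build elastic network")
    data.frame(i = ij[, 1], j = ij[, 2], k = springConstant, r0 = D[ij])
}

#' Build the anisotropic-network Hessian
#'
#' Standard ANM Hessian at the reference coordinates: for each spring (i,j)
#' the off-diagonal 3x3 superblock is `-k * rhat %*% t(rhat)` (rhat the unit
#' inter-particle vector) and diagonal superblocks are minus the sum of the
#' row's off-diagonal blocks, which enforces translational invariance
#' exactly.
#'
#' @param structure a [MolecularStructure-class].
#' @param cutoff,springConstant passed to [enmTopology()] when `topology`
#'   is not supplied.
#' @param topology optional explicit spring table (see [enmTopology()]),
#'   allowing perturbed or non-cutoff networks.
#' @return symmetric 3N x 3N numeric matrix.
#' @examples
#' s <- makeStructure("A", 1:2, rbind(c(0, 0, 0), c(3, 0, 0)), mass = 10)
#' H <- buildEnmHessian(s, cutoff = 5)
#' range(eigen(H, symmetric = TRUE)$values)
#' @export
buildEnmHessian <- function(structure, cutoff = 10, springConstant = 1,
                            topology = NULL) {
    xyz <- coords(structure)
    n <- nrow(xyz)
    if (is.null(topology))
        topology <- enmTopology(structure, cutoff, springConstant)
    H <- matrix(0, 3L * n, 3L * n)
    for (s in seq_len(nrow(topology))) {
        i <- topology$i[s]; j <- topology$j[s]; k <- topology$k[s]
        d <- xyz[j, ] - xyz[i, ]
        r <- sqrt(sum(d * d))
        if (r < 1e-6)
            stop("particle pair at zero distance; cannot build elastic network")
        rh <- d / r
        B <- -k * tcrossprod(rh)
        ii <- (3L * (i - 1L) + 1L):(3L * i)
        jj <- (3L * (j - 1L) + 1L):(3L * j)
        H[ii, jj] <- H[ii, jj] + B
        H[jj, ii] <- H[jj, ii] + B
        H[ii, ii] <- H[ii, ii] - B
        H[jj, jj] <- H[jj, jj] - B
    }
    H
}

# ENM potential energy: sum over springs of 0.5 k (|r_ij| - r0)^2.
# Zero at the reference coordinates by construction.
enmEnergy <- function(xyz, topology) {
    d <- xyz[topology$j, , drop = FALSE] - xyz[topology$i, , drop = FALSE]
    r <- sqrt(rowSums(d * d))
    sum(0.5 * topology$k * (r - topology$r0)^2)
}

# Analytic gradient of enmEnergy, n x 3.
enmGradient <- function(xyz, topology) {
    d <- xyz[topology$j, , drop = FALSE] - xyz[topology$i, , drop = FALSE]
    r <- sqrt(rowSums(d * d))
    r <- pmax(r, 1e-12)
    f <- topology$k * (r - topology$r0) / r   # (dE/dr) / r
    fd <- d * f
    acc <- rowsum(rbind(fd, -fd), group = c(topology$j, topology$i))
    g <- matrix(0, nrow(xyz), 3L)
    g[as.integer(rownames(acc)), ] <- acc
    g
}
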