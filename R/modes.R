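#' Compute normal modes from a Hessian and particle masses
#'
#' Solves the mass-weighted eigenproblem `H v = lambda M v` by symmetric
#' diagonalisation of `M^(-1/2) H M^(-1/2)`.  Near-zero (rigid-body)
#' eigenvalues are counted as trivial and excluded from the returned set: a
#' connected 3-D network of at least three non-collinear particles has
#' exactly six of them, so the first analysed mode carries label 7 by the
#' usual convention.  Eigenvector sign is fixed so the largest-magnitude
#' component of each displacement vector is positive, which makes the
#' decomposition bit-reproducible.
#'
#' @param hessian symmetric 3N x 3N matrix (see [buildEnmHessian()], or any
#'   user-supplied Hessian).
#' @param masses per-particle masses, length N, strictly positive.
#' @param nModes number of non-trivial modes to keep (default 20; the
#'   computed pool may be anything up to `3N - nTrivial`).
#' @param zeroTol relative tolerance: eigenvalues below
#'   `zeroTol * max(eigenvalue)` count as trivial (default 1e-8).
#' @return a [ModeSet-class]
#' @examples
#' s <- makeStructure("A", 1:2, rbind(c(0, 0, 0), c(3, 0, 0)), mass = 10)
#' m <- computeNormalModes(buildEnmHessian(s, cutoff = 5), particleMasses(s),
#'                         nModes = 1)
#' eigenvalues(m)  # 2k/m = 0.2 for the two-body oscillator
#' @export
computeNormalModes <- function(hessian, masses, nModes = 20L,
                               zeroTol = 1e-8) {
    n <- length(masses)
    stopifnot(nrow(hessian) == 3L * n, ncol(hessian) == 3L * n)
    if (any(masses <= 0)) stop("masses must be strictly positive")
    if (max(abs(hessian - t(hessian))) > 1e-8)
        stop("hessian must be symmetric")
    w <- rep(1 / sqrt(masses), each = 3L)
    Ht <- hessian * tcrossprod(w)           # M^{-1/2} H M^{-1/2}
    eig <- eigen(Ht, symmetric = TRUE)
    vals <- rev(eig$values)                 # ascending
    vecs <- eig$vectors[, rev(seq_len(3L * n)), drop = FALSE]
    tol <- zeroTol * max(abs(vals))
    trivial <- vals <= tol
    nTriv <- sum(trivial)
    nAvail <- 3L * n - nTriv
    if (nModes > nAvail)
        stop("nModes (", nModes, ") exceeds available non-trivial modes (",
             nAvail, ")")
    keep <- which(!trivial)[seq_len(nModes)]
    V <- vecs[, keep, drop = FALSE] * w     # back to Cartesian displacements
    ## sign convention: largest-|component| entry positive (first on ties)
    for (c in seq_len(ncol(V))) {
        imax <- which.max(abs(V[, c]))
        if (V[imax, c] < 0) V[, c] <- -V[, c]
    }
    new("ModeSet",
        values = vals[keep], vectors = V, masses = as.numeric(masses),
        nTrivial = as.integer(nTriv),
        labels = as.integer(nTriv + seq_len(nModes)),
        trivialValues = vals[trivial])
}

#' Export a ModeSet to a plain-text JSON file
#'
#' Writes eigenvalues, labels, trivial-mode bookkeeping, masses and the
#' displacement vectors so a mode set can be archived or re-loaded without
#' recomputation.
#'
#' @param modes a [ModeSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportModeSet <- function(modes, path) {
    obj <- list(
        eigenvalues = modes@values,
        labels = modes@labels,
        nTrivial = modes@nTrivial,
        trivialEigenvalues = modes@trivialValues,
        masses = modes@masses,
        vectors = apply(modes@vectors, 2, identity, simplify = FALSE))
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' Read a ModeSet written by [exportModeSet()]
#' @param path JSON file.
#' @return a [ModeSet-class]
#' @export
importModeSet <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    vecs <- if (is.matrix(obj$vectors)) t(obj$vectors)
        else do.call(cbind, lapply(obj$vectors, as.numeric))
    new("ModeSet",
        values = as.numeric(obj$eigenvalues),
        vectors = vecs,
        masses = as.numeric(obj$masses),
        nTrivial = as.integer(obj$nTrivial),
        labels = as.integer(obj$labels),
        trivialValues = as.numeric(obj$trivialEigenvalues))
}
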