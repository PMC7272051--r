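#' Generate a pseudo-trajectory displaced along one normal mode
#'
#' Frames are produced at equally spaced mass-weighted RMS (MRMS) targets in
#' `[-amplitude, +amplitude]`.  With `relax = FALSE` each frame is the pure
#' harmonic displacement `x = x0 + s * v` scaled so its MRMS equals the
#' target exactly.  With `relax = TRUE` each frame is quasi-Newton
#' relaxed under the elastic-network energy plus a harmonic restraint on the
#' signed MRMS coordinate along the mode, which lets the structure escape
#' strict harmonicity (side contacts re-form, local distortions relax) while
#' staying at the prescribed displacement.
#'
#' @param structure the reference [MolecularStructure-class].
#' @param modes a [ModeSet-class] computed for `structure`.
#' @param modeLabel label of the mode to displace along (see
#'   [modeLabels()]); ignored when `direction` is supplied.
#' @param amplitude maximum MRMS displacement in Angstrom (default 1.0).
#' @param nFrames number of frames, odd so displacement 0 is included
#'   (default 21).
#' @param relax relax frames under the ENM energy? Default `FALSE`.
#' @param topology spring table for relaxation (defaults to
#'   `enmTopology(structure, cutoff, springConstant)`).
#' @param cutoff,springConstant ENM parameters used when `topology` is NULL.
#' @param restraintWeight stiffness of the harmonic restraint tying the
#'   frame to its MRMS target (energy units / A^2; default 50).
#' @param maxIter,gradTol relaxation stopping controls (iteration cap and
#'   projected-gradient tolerance).
#' @param direction optional explicit 3N displacement direction (overrides
#'   `modeLabel`; used by [transferModeTrajectory()]).
#' @return a [ModeTrajectory-class]
#' @export
generateModeTrajectory <- function(structure, modes, modeLabel,
                                   amplitude = 1.0, nFrames = 21L,
                                   relax = FALSE, topology = NULL,
                                   cutoff = 10, springConstant = 1,
                                   restraintWeight = 50, maxIter = 2000L,
                                   gradTol = 1e-5, direction = NULL) {
    if (nFrames %% 2L != 1L)
        stop("nFrames must be odd so that displacement 0 is included")
    masses <- particleMasses(structure)
    n <- length(masses)
    if (is.null(direction)) {
        pos <- match(modeLabel, modeLabels(modes))
        if (is.na(pos)) stop("mode label ", modeLabel, " not in ModeSet")
        v <- modes@vectors[, pos]
        lab <- as.integer(modeLabel)
    } else {
        stopifnot(length(direction) == 3L * n)
        v <- direction
        nrm <- sqrt(sum(rep(masses, each = 3L) * v^2))
        if (nrm < 1e-12) stop("displacement direction is identically zero")
        v <- v / nrm                        # mass-metric unit vector
        lab <- as.integer(if (missing(modeLabel)) NA else modeLabel)
    }
    x0 <- coords(structure)
    mdof <- rep(masses, each = 3L)
    Mtot <- sum(masses)
    targets <- seq(-amplitude, amplitude, length.out = nFrames)
    targets[(nFrames + 1L) %/% 2L] <- 0     # exact zero at the centre
    V <- matrix(v, ncol = 3L, byrow = TRUE) # per-atom direction
    if (relax && is.null(topology))
        topology <- enmTopology(structure, cutoff, springConstant)

    frames <- vector("list", nFrames)
    achieved <- numeric(nFrames)
    converged <- rep(TRUE, nFrames)
    for (f in seq_len(nFrames)) {
        ## harmonic displacement; with relax = TRUE this is the start point
        x <- x0 + targets[f] * sqrt(Mtot) * V
        if (relax && targets[f] != 0) {
            res <- .relaxFrame(x, x0, V, mdof, Mtot, topology,
                               targets[f], restraintWeight, maxIter,
                               gradTol)
            x <- res$x
            converged[f] <- res$converged
        }
        frames[[f]] <- x
        d <- x - x0
        achieved[f] <- sqrt(sum(mdof * as.vector(t(d))^2) / Mtot)
    }
    if (!all(converged))
        warning(sum(!converged), " frame(s) of mode ", lab,
                " did not reach the relaxation gradient tolerance ",
                "(flagged, not fatal)", call. = FALSE)
    new("ModeTrajectory", modeLabel = lab, reference = structure,
        frames = frames, targets = targets, achieved = achieved,
        relaxed = relax, converged = converged)
}

# Quasi-Newton (L-BFGS-B) minimisation with analytic gradient of
#   E_enm(x) + w/2 (c(x) - target)^2,  c(x) = sum(m * d * v) / sqrt(Mtot)
# (c is the signed MRMS coordinate along the mode direction).
.relaxFrame <- function(x, x0, V, mdof, Mtot, topology, target, w,
                        maxIter, gradTol) {
    mV <- matrix(mdof, ncol = 3L, byrow = TRUE) * V
    sq <- sqrt(Mtot)
    fn <- function(p) {
        xm <- matrix(p, ncol = 3L, byrow = TRUE)
        cc <- sum(mV * (xm - x0)) / sq
        enmEnergy(xm, topology) + 0.5 * w * (cc - target)^2
    }
    gr <- function(p) {
        xm <- matrix(p, ncol = 3L, byrow = TRUE)
        cc <- sum(mV * (xm - x0)) / sq
        g <- enmGradient(xm, topology) + (w * (cc - target) / sq) * mV
        as.vector(t(g))
    }
    o <- stats::optim(as.vector(t(x)), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxIter, pgtol = gradTol,
                                     factr = 1e5))
    list(x = matrix(o$par, ncol = 3L, byrow = TRUE),
         converged = o$convergence == 0L)
}

#' Transfer a mode of one system onto another structure
#'
#' Re-indexes system A's C-alpha-restricted mode displacement onto system
#' B via a residue mapping (unmapped B positions get zero displacement),
#' renormalises it in B's mass metric, and generates a trajectory on B along
#' that direction -- relaxed under B's own elastic network when
#' `relax = TRUE`.  This tests whether B's topology supports A's motion.
#'
#' @param modes [ModeSet-class] of the donor system A.
#' @param structureA donor reference structure (used to locate A's
#'   C-alpha positions).
#' @param structureB acceptor structure.
#' @param mapping a [ResidueMapping-class] from A to B.
#' @param modeLabel donor mode label.
#' @param coverage minimum fraction of B's C-alpha positions that must be
#'   mapped (default 0.9).
#' @param ... passed to [generateModeTrajectory()] (`amplitude`, `nFrames`,
#'   `relax`, `topology` for B, ...).
#' @return a [ModeTrajectory-class] on B
#' @export
transferModeTrajectory <- function(modes, structureA, structureB, mapping,
                                   modeLabel, coverage = 0.9, ...) {
    pos <- match(modeLabel, modeLabels(modes))
    if (is.na(pos)) stop("mode label ", modeLabel, " not in donor ModeSet")
    caA <- selectCalpha(structureA)
    caB <- selectCalpha(structureB)
    keyToA <- stats::setNames(caA, names(caA))
    mapped <- mapping@pairs[mapping@pairs$keyA %in% names(caA) &
                            mapping@pairs$keyB %in% names(caB), , drop = FALSE]
    cov <- nrow(mapped) / length(caB)
    if (cov < coverage)
        stop(sprintf("mapping covers %.1f%% of acceptor C-alpha positions (need >= %.1f%%)",
                     100 * cov, 100 * coverage))
    vA <- matrix(modes@vectors[, pos], ncol = 3L, byrow = TRUE)
    nB <- nAtoms(structureB)
    dB <- matrix(0, nB, 3L)
    ia <- keyToA[mapped$keyA]
    ib <- caB[mapped$keyB]
    dB[ib, ] <- vA[ia, , drop = FALSE]
    generateModeTrajectory(structureB, modes = NULL, modeLabel = modeLabel,
                           direction = as.vector(t(dB)), ...)
}
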