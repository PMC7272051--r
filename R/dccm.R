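#' Dynamic cross-correlation matrix of a mode group
#'
#' Pools the frames of one or more mode trajectories (a motion class) and
#' computes the normalised covariance of C-alpha displacements about the
#' ensemble mean:
#' `C(i,j) = <dr_i . dr_j> / (<|dr_i|^2>^(1/2) <|dr_j|^2>^(1/2))`.
#' Fully correlated motion gives +1, fully anti-correlated motion -1.
#' Frames are least-squares superposed onto the reference over the selection
#' before the covariance is taken (a no-op for unrelaxed trajectories, a
#' safeguard for relaxed ones).  Atoms with zero fluctuation get NA rows
#' (undefined, not zero).
#'
#' @param trajectories a [ModeTrajectory-class] or list of them sharing one
#'   reference structure.
#' @param selection C-alpha selection (default from the reference).
#' @param superpose superpose frames onto the reference first? Default TRUE.
#' @return a [CrossCorrelationMatrix-class]
#' @export
computeDccm <- function(trajectories, selection = NULL, superpose = TRUE) {
    trajectories <- .asTrajectoryList(trajectories)
    ref <- trajectories[[1]]@reference
    if (is.null(selection)) selection <- selectCalpha(ref)
    frames <- .pooledFrames(trajectories, selection, superpose)
    nF <- length(frames)
    if (nF < 2L) stop("need at least 2 frames for a cross-correlation matrix")
    n <- length(selection)
    X <- array(unlist(frames), dim = c(n, 3L, nF))
    mu <- apply(X, c(1, 2), mean)
    D <- X - as.vector(mu)                 # deviations about ensemble mean
    Sdot <- matrix(0, n, n)
    for (c in 1:3) {
        Dc <- matrix(D[, c, ], n, nF)
        Sdot <- Sdot + tcrossprod(Dc)
    }
    Sdot <- Sdot / nF
    v <- diag(Sdot)
    zero <- v < 1e-20
    denom <- sqrt(outer(v, v))
    C <- Sdot / denom
    C[zero, ] <- NA_real_
    C[, zero] <- NA_real_
    diag(C)[!zero] <- 1
    dimnames(C) <- NULL
    new("CrossCorrelationMatrix", corr = C, keys = names(selection),
        nFrames = as.integer(nF),
        sources = vapply(trajectories, function(t) t@modeLabel, integer(1)))
}

#' Group flexibility profile (per-residue RMSF of a mode group)
#'
#' For a group `s` of `n_s` similar modes, the per-atom root-mean-square
#' fluctuation is the square root of the squared deviation from the initial
#' structure, averaged over each mode's frames, over the atom's three
#' degrees of freedom, and over the group's modes.  Duplicating a group
#' member leaves the profile unchanged.
#'
#' @param trajectories a [ModeTrajectory-class] or list of them sharing one
#'   reference structure (the mode group).
#' @param selection C-alpha selection (default from the reference).
#' @param groupId identifier stored with the profile.
#' @param superpose superpose frames onto the reference first? Default FALSE:
#'   mode displacements carry no net rigid motion by construction, and
#'   skipping superposition keeps the profile an exact evaluation of the
#'   definition.
#' @return a [FlexibilityProfile-class]
#' @export
computeGroupRmsf <- function(trajectories, selection = NULL,
                             groupId = "group", superpose = FALSE) {
    trajectories <- .asTrajectoryList(trajectories)
    ref <- trajectories[[1]]@reference
    if (is.null(selection)) selection <- selectCalpha(ref)
    x0 <- coords(ref)[selection, , drop = FALSE]
    msd <- matrix(0, length(selection), length(trajectories))
    for (q in seq_along(trajectories)) {
        tr <- trajectories[[q]]
        if (!isTRUE(all.equal(coords(tr@reference), coords(ref),
                              tolerance = 1e-9)))
            stop("all group members must share the same reference structure")
        frames <- .pooledFrames(list(tr), selection, superpose)
        dev <- vapply(frames, function(f) rowSums((f - x0)^2), numeric(nrow(x0)))
        msd[, q] <- rowMeans(matrix(dev, nrow = nrow(x0))) / 3
    }
    vals <- sqrt(rowMeans(msd))
    names(vals) <- names(selection)
    new("FlexibilityProfile", values = vals, groupId = groupId,
        modes = vapply(trajectories, function(t) t@modeLabel, integer(1)))
}

.asTrajectoryList <- function(trajectories) {
    if (is(trajectories, "ModeTrajectory")) trajectories <- list(trajectories)
    if (!length(trajectories)) stop("empty trajectory group")
    stopifnot(all(vapply(trajectories, is, logical(1), "ModeTrajectory")))
    n <- vapply(trajectories, nAtoms, integer(1))
    if (length(unique(n)) != 1L)
        stop("trajectories must share atom count and ordering")
    trajectories
}

# Selection-restricted coordinates of all frames of all trajectories,
# optionally superposed onto the first trajectory's reference.
.pooledFrames <- function(trajectories, selection, superpose) {
    refXyz <- coords(trajectories[[1]]@reference)
    out <- list()
    for (tr in trajectories) {
        for (f in tr@frames) {
            x <- if (superpose) .superpose(f, refXyz, fit = selection) else f
            out[[length(out) + 1L]] <- x[selection, , drop = FALSE]
        }
    }
    out
}

#' Export a DCCM as CSV
#' @param dccm a [CrossCorrelationMatrix-class].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
exportDccm <- function(dccm, path) {
    C <- dccm@corr
    dimnames(C) <- list(dccm@keys, dccm@keys)
    utils::write.csv(C, path)
    invisible(path)
}

#' Render a DCCM heatmap
#'
#' Blue-white-red image of the correlation matrix (undefined entries grey),
#' either to the active device or to a PNG file.
#'
#' @param dccm a [CrossCorrelationMatrix-class].
#' @param path optional PNG output path; default plots to the active device.
#' @param main plot title.
#' @return `path` (or NULL), invisibly.
#' @export
plotDccm <- function(dccm, path = NULL, main = "dynamic cross-correlation") {
    C <- dccm@corr
    n <- nrow(C)
    if (!is.null(path)) {
        grDevices::png(path, width = 900, height = 800)
        on.exit(grDevices::dev.off())
    }
    pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
    graphics::image(seq_len(n), seq_len(n), t(C[n:1, , drop = FALSE]),
                    zlim = c(-1, 1), col = pal, useRaster = TRUE,
                    xlab = "residue index", ylab = "residue index",
                    main = main)
    invisible(path)
}

#' Export a flexibility profile as two-column TSV (residue key, Angstrom)
#' @param profile a [FlexibilityProfile-class].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
exportRmsf <- function(profile, path) {
    utils::write.table(
        data.frame(residue = names(profile@values), rmsf = profile@values),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
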