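#' Detect hydrogen bonds across trajectory frames
#'
#' Geometric criterion per frame: donor--acceptor heavy-atom distance at
#' most `distCutoff` and D-H...A deviation from linearity at most
#' `angleCutoff` degrees (the angle at the hydrogen between the H->D and
#' H->A directions is within `angleCutoff` of 180 degrees).  Donors are N/O
#' heavy atoms with at least one covalently attached hydrogen (assigned by
#' distance < 1.25 A in the reference frame); acceptors are N/O atoms.  For
#' hydrogen-free structures (C-alpha bead models, unprotonated PDBs) the
#' angle test is skipped and detection falls back to the distance criterion
#' alone, flagged in the output.
#'
#' Occupancy is the exact fraction of frames in which the bond is present.
#'
#' @param trajectories a [ModeTrajectory-class] or list of them (a motion
#'   class); frames are pooled.
#' @param distCutoff donor-acceptor distance cutoff in Angstrom (default 3.0).
#' @param angleCutoff deviation-from-linearity cutoff in degrees (default 20).
#' @param minOccupancy drop interactions below this occupancy (default 0,
#'   i.e. keep all; the conventional high-occupancy screen is 0.5,
#'   inclusive).
#' @return data.frame with columns `kind`, `donorAtom`, `donorKey`,
#'   `acceptorAtom`, `acceptorKey`, `occupancy`, `intraResidue`,
#'   `heavyOnly`.
#' @export
detectHydrogenBonds <- function(trajectories, distCutoff = 3.0,
                                angleCutoff = 20, minOccupancy = 0) {
    trajectories <- .asTrajectoryList(trajectories)
    ref <- trajectories[[1]]@reference
    a <- ref@atoms
    keys <- .atomResidueKeys(a)
    isH <- a$element %in% c("H", "D")
    polar <- which(a$element %in% c("N", "O"))
    if (!length(polar)) {
        warning("no N/O donors or acceptors found")
        return(.emptyInteractionTable())
    }
    heavyOnly <- !any(isH)
    refXyz <- coords(ref)
    ## hydrogens attached to each polar heavy atom (reference geometry)
    attachedH <- list()
    if (!heavyOnly) {
        hIdx <- which(isH)
        for (d in polar) {
            dd <- sqrt(rowSums((refXyz[hIdx, , drop = FALSE] -
                                matrix(refXyz[d, ], length(hIdx), 3,
                                       byrow = TRUE))^2))
            attachedH[[as.character(d)]] <- hIdx[dd < 1.25]
        }
        donors <- polar[vapply(as.character(polar),
                               function(k) length(attachedH[[k]]) > 0,
                               logical(1))]
    } else {
        donors <- polar
    }
    acceptors <- polar
    cand <- expand.grid(d = donors, acc = acceptors)
    cand <- cand[cand$d != cand$acc, , drop = FALSE]
    if (!nrow(cand)) return(.emptyInteractionTable())
    frames <- .allFrames(trajectories)
    nF <- length(frames)
    hits <- numeric(nrow(cand))
    for (x in frames) {
        dv <- x[cand$acc, , drop = FALSE] - x[cand$d, , drop = FALSE]
        dist <- sqrt(rowSums(dv * dv))
        present <- dist <= distCutoff
        if (!heavyOnly) {
            for (ii in which(present)) {
                hs <- attachedH[[as.character(cand$d[ii])]]
                okAngle <- FALSE
                for (h in hs) {
                    v1 <- x[cand$d[ii], ] - x[h, ]
                    v2 <- x[cand$acc[ii], ] - x[h, ]
                    ct <- sum(v1 * v2) /
                        sqrt(sum(v1 * v1) * sum(v2 * v2))
                    theta <- acos(pmin(pmax(ct, -1), 1)) * 180 / pi
                    if (180 - theta <= angleCutoff) { okAngle <- TRUE; break }
                }
                present[ii] <- okAngle
            }
        }
        hits <- hits + present
    }
    occ <- hits / nF
    keep <- occ > 0 & occ >= minOccupancy
    if (!any(keep)) return(.emptyInteractionTable())
    out <- data.frame(
        kind = "hbond",
        donorAtom = a$name[cand$d[keep]],
        donorKey = keys[cand$d[keep]],
        acceptorAtom = a$name[cand$acc[keep]],
        acceptorKey = keys[cand$acc[keep]],
        occupancy = occ[keep],
        intraResidue = keys[cand$d[keep]] == keys[cand$acc[keep]],
        heavyOnly = heavyOnly,
        stringsAsFactors = FALSE)
    out[order(-out$occupancy, out$donorKey, out$acceptorKey), ,
        drop = FALSE]
}

#' Detect salt bridges across trajectory frames
#'
#' Anionic side-chain oxygens (Asp OD1/OD2, Glu OE1/OE2, plus C-terminal
#' OXT) against cationic side-chain nitrogens (Lys NZ, Arg NE/NH1/NH2, His
#' ND1/NE2) within `cutoff` Angstrom, per frame, aggregated to occupancy.
#'
#' @param trajectories a [ModeTrajectory-class] or list of them.
#' @param cutoff oxygen-nitrogen distance cutoff in Angstrom (default 3.2).
#' @param minOccupancy drop interactions below this occupancy (default 0).
#' @return data.frame as in [detectHydrogenBonds()] with `kind =
#'   "salt_bridge"` (donor = cation, acceptor = anion).
#' @export
detectSaltBridges <- function(trajectories, cutoff = 3.2, minOccupancy = 0) {
    trajectories <- .asTrajectoryList(trajectories)
    ref <- trajectories[[1]]@reference
    a <- ref@atoms
    keys <- .atomResidueKeys(a)
    anions <- which((a$resid == "ASP" & a$name %in% c("OD1", "OD2")) |
                    (a$resid == "GLU" & a$name %in% c("OE1", "OE2")) |
                    a$name == "OXT")
    cations <- which((a$resid == "LYS" & a$name == "NZ") |
                     (a$resid == "ARG" & a$name %in% c("NE", "NH1", "NH2")) |
                     (a$resid %in% c("HIS", "HSP") &
                          a$name %in% c("ND1", "NE2")))
    if (!length(anions) || !length(cations))
        return(.emptyInteractionTable())
    cand <- expand.grid(d = cations, acc = anions)
    frames <- .allFrames(trajectories)
    hits <- numeric(nrow(cand))
    for (x in frames) {
        dv <- x[cand$acc, , drop = FALSE] - x[cand$d, , drop = FALSE]
        hits <- hits + (sqrt(rowSums(dv * dv)) <= cutoff)
    }
    occ <- hits / length(frames)
    keep <- occ > 0 & occ >= minOccupancy
    if (!any(keep)) return(.emptyInteractionTable())
    out <- data.frame(
        kind = "salt_bridge",
        donorAtom = a$name[cand$d[keep]],
        donorKey = keys[cand$d[keep]],
        acceptorAtom = a$name[cand$acc[keep]],
        acceptorKey = keys[cand$acc[keep]],
        occupancy = occ[keep],
        intraResidue = keys[cand$d[keep]] == keys[cand$acc[keep]],
        heavyOnly = FALSE,
        stringsAsFactors = FALSE)
    out[order(-out$occupancy, out$donorKey, out$acceptorKey), ,
        drop = FALSE]
}

.emptyInteractionTable <- function() {
    data.frame(kind = character(0), donorAtom = character(0),
               donorKey = character(0), acceptorAtom = character(0),
               acceptorKey = character(0), occupancy = numeric(0),
               intraResidue = logical(0), heavyOnly = logical(0),
               stringsAsFactors = FALSE)
}

#' Diff high-occupancy interaction sets between two systems or classes
#'
#' Interactions at or above the occupancy threshold (the conventional
#' screen is 50%, inclusive) are keyed by kind and unordered residue pair;
#' the diff lists pairs present only in A (`lost`, absent in B), only in B
#' (`gained`) and in both (`kept`).
#'
#' @param recordsA,recordsB interaction tables from
#'   [detectHydrogenBonds()] / [detectSaltBridges()] (may be rbind-ed).
#' @param threshold minimum occupancy, inclusive (default 0.5).
#' @param mapping optional [ResidueMapping-class] translating B's residue
#'   keys into A's.
#' @return list of data.frames `gained`, `lost`, `kept` with columns
#'   `kind`, `pair`, and the occupancies observed in each input.
#' @export
diffInteractions <- function(recordsA, recordsB, threshold = 0.5,
                             mapping = NULL) {
    keySet <- function(rec, translate = NULL) {
        rec <- rec[rec$occupancy >= threshold & !rec$intraResidue, ,
                   drop = FALSE]
        dk <- rec$donorKey; ak <- rec$acceptorKey
        if (!is.null(translate)) {
            tr <- stats::setNames(translate@pairs$keyA, translate@pairs$keyB)
            dk <- ifelse(dk %in% names(tr), tr[dk], dk)
            ak <- ifelse(ak %in% names(tr), tr[ak], ak)
        }
        pair <- ifelse(dk < ak, paste(dk, ak, sep = "--"),
                       paste(ak, dk, sep = "--"))
        id <- paste(rec$kind, pair)
        occ <- tapply(rec$occupancy, id, max)
        kind <- tapply(rec$kind, id, function(z) z[1])
        pairTab <- tapply(pair, id, function(z) z[1])
        data.frame(id = names(occ), kind = as.character(kind),
                   pair = as.character(pairTab),
                   occupancy = as.numeric(occ), stringsAsFactors = FALSE)
    }
    sa <- keySet(recordsA)
    sb <- keySet(recordsB, mapping)
    lost <- sa[!sa$id %in% sb$id, c("kind", "pair", "occupancy")]
    gained <- sb[!sb$id %in% sa$id, c("kind", "pair", "occupancy")]
    keptIds <- intersect(sa$id, sb$id)
    kept <- data.frame(
        kind = sa$kind[match(keptIds, sa$id)],
        pair = sa$pair[match(keptIds, sa$id)],
        occupancyA = sa$occupancy[match(keptIds, sa$id)],
        occupancyB = sb$occupancy[match(keptIds, sb$id)],
        stringsAsFactors = FALSE)
    rownames(lost) <- rownames(gained) <- rownames(kept) <- NULL
    list(gained = gained, lost = lost, kept = kept)
}

.allFrames <- function(trajectories) {
    unlist(lapply(trajectories, function(tr) tr@frames), recursive = FALSE)
}
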