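#' Build the weighted residue dynamical network
#'
#' Nodes are the C-alpha positions of the selection.  Two nodes are
#' connected when `|C(i,j)| >= corrThreshold` and their C-alpha distance is
#' at most `distThreshold` in at least `frameFraction` of the pooled frames
#' (the same concatenated frame set used for the class DCCM).  The edge
#' weight is `-log(|C(i,j)|)` (|C| capped just below 1 to keep weights
#' positive and finite), so strongly correlated contacts are short network
#' distances and path lengths decrease as correlations increase.  Isolated
#' nodes are retained.
#'
#' @param dccm a [CrossCorrelationMatrix-class].
#' @param trajectories the trajectories the DCCM was computed from (used for
#'   the contact-fraction rule).
#' @param corrThreshold minimum |C| (default 0.7).
#' @param distThreshold contact distance in Angstrom (default 10).
#' @param frameFraction minimum fraction of frames in contact (default 0.75).
#' @param selection C-alpha selection (default from the reference).
#' @return a [DynamicalNetwork-class]
#' @export
buildNetwork <- function(dccm, trajectories, corrThreshold = 0.7,
                         distThreshold = 10, frameFraction = 0.75,
                         selection = NULL) {
    if (corrThreshold <= 0 || corrThreshold > 1)
        stop("corrThreshold must lie in (0, 1]")
    if (frameFraction <= 0 || frameFraction > 1)
        stop("frameFraction must lie in (0, 1]")
    if (distThreshold <= 0) stop("distThreshold must be positive")
    trajectories <- .asTrajectoryList(trajectories)
    ref <- trajectories[[1]]@reference
    if (is.null(selection)) selection <- selectCalpha(ref)
    keys <- names(selection)
    n <- length(selection)
    stopifnot(n == nrow(dccm@corr))
    frames <- .pooledFrames(trajectories, selection, superpose = FALSE)
    contact <- matrix(0, n, n)
    for (f in frames)
        contact <- contact + (.distMatrix(f) <= distThreshold)
    contact <- contact / length(frames)
    C <- dccm@corr
    absC <- abs(C)
    ok <- !is.na(absC) & absC >= corrThreshold & contact >= frameFraction
    ok[lower.tri(ok, diag = TRUE)] <- FALSE
    ij <- which(ok, arr.ind = TRUE)
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    igraph::V(g)$name <- keys
    if (nrow(ij)) {
        g <- igraph::add_edges(g, rbind(ij[, 1], ij[, 2]))
        cvals <- C[ij]
        igraph::E(g)$C <- cvals
        igraph::E(g)$contactFraction <- contact[ij]
        igraph::E(g)$weight <- -log(pmin(abs(cvals), 1 - 1e-12))
    }
    new("DynamicalNetwork", graph = g, keys = keys,
        params = list(corrThreshold = corrThreshold,
                      distThreshold = distThreshold,
                      frameFraction = frameFraction))
}

#' Girvan-Newman communities with a modularity correction
#'
#' Divisive edge-betweenness clustering (edge weights treated as distances).
#' Among all dendrogram cuts whose modularity is within
#' `modularityTolerance` of the maximum, the cut with the fewest communities
#' is returned --- this avoids the over-fragmentation that strict modularity
#' maximisation can produce.  Modularity is evaluated with |C| edge
#' strengths.  Communities smaller than `minSize` are pruned: their members
#' are reported unassigned.
#'
#' @param network a [DynamicalNetwork-class].
#' @param modularityTolerance tolerance below the maximum modularity
#'   (default 0.05).
#' @param minSize minimum community size (default 10).
#' @return a [CommunityPartition-class]
#' @export
detectCommunities <- function(network, modularityTolerance = 0.05,
                              minSize = 10L) {
    g <- network@graph
    n <- igraph::vcount(g)
    if (igraph::ecount(g) == 0L) {
        warning("edgeless network: every node unassigned")
        return(new("CommunityPartition",
                   membership = stats::setNames(rep(NA_integer_, n),
                                                network@keys),
                   modularity = NA_real_, maxModularity = NA_real_,
                   nCommunities = 0L, pruned = network@keys,
                   coupling = matrix(numeric(0), 0, 0)))
    }
    strength <- abs(igraph::E(g)$C)
    gn <- igraph::cluster_edge_betweenness(
        g, weights = igraph::E(g)$weight, modularity = FALSE,
        membership = FALSE)
    nComp <- igraph::count_components(g)
    cuts <- seq(from = nComp, to = n)
    mods <- vapply(cuts, function(k) {
        memb <- igraph::cut_at(gn, no = k)
        igraph::modularity(g, memb, weights = strength)
    }, numeric(1))
    maxMod <- max(mods)
    candidates <- cuts[mods >= maxMod - modularityTolerance]
    kSel <- min(candidates)                 # fewest communities
    membership <- igraph::cut_at(gn, no = kSel)
    modSel <- mods[match(kSel, cuts)]
    ## prune small communities
    sizes <- table(membership)
    small <- as.integer(names(sizes)[sizes < minSize])
    memb <- as.integer(membership)
    memb[memb %in% small] <- NA_integer_
    keep <- sort(unique(memb[!is.na(memb)]))
    memb <- match(memb, keep)               # compact ids, NA preserved
    names(memb) <- network@keys
    pruned <- network@keys[is.na(memb)]
    nComm <- length(keep)
    ## inter-community coupling: summed |C| over crossing edges, normalised
    coupling <- matrix(0, nComm, nComm)
    if (nComm > 0) {
        el <- igraph::as_edgelist(g, names = FALSE)
        ci <- memb[el[, 1]]; cj <- memb[el[, 2]]
        cross <- !is.na(ci) & !is.na(cj) & ci != cj
        if (any(cross)) {
            for (e in which(cross)) {
                a <- ci[e]; b <- cj[e]
                coupling[a, b] <- coupling[a, b] + strength[e]
                coupling[b, a] <- coupling[a, b]
            }
            coupling <- coupling / max(coupling)
        }
        dimnames(coupling) <- list(paste0("community", seq_len(nComm)),
                                   paste0("community", seq_len(nComm)))
    }
    new("CommunityPartition", membership = memb, modularity = modSel,
        maxModularity = maxMod, nCommunities = as.integer(nComm),
        pruned = pruned, coupling = coupling)
}

#' Weighted betweenness centrality of network nodes
#'
#' Number of weighted shortest paths between pairs of other nodes running
#' through each node (unnormalised, per connected component).
#'
#' @param network a [DynamicalNetwork-class].
#' @return named numeric vector over residue keys.
#' @export
nodeBetweenness <- function(network) {
    g <- network@graph
    b <- igraph::betweenness(
        g, directed = FALSE,
        weights = if (igraph::ecount(g)) igraph::E(g)$weight else NULL,
        normalized = FALSE)
    stats::setNames(as.numeric(b), network@keys)
}

#' Optimal and suboptimal communication paths
#'
#' The `k` lowest-total-weight simple paths between two nodes (Yen-style
#' enumeration; fewer if the graph has fewer simple paths), sorted by
#' non-decreasing length with equal-length ties broken lexicographically on
#' the node sequence.  Node degeneracy is the fraction of returned paths
#' visiting each node; source and sink always have degeneracy 1.
#'
#' @param network a [DynamicalNetwork-class].
#' @param source,sink residue keys of the endpoints.
#' @param k number of paths requested (default 500).
#' @return a [PathEnsemble-class]; when source and sink are disconnected an
#'   empty ensemble with `reachable = FALSE`.
#' @export
suboptimalPaths <- function(network, source, sink, k = 500L) {
    g <- network@graph
    if (identical(source, sink)) stop("source and sink must differ")
    if (!source %in% network@keys || !sink %in% network@keys)
        stop("source/sink must be residue keys of the network")
    d <- igraph::distances(g, v = source, to = sink,
                           weights = igraph::E(g)$weight)
    if (!is.finite(d[1, 1]))
        return(new("PathEnsemble", source = source, sink = sink,
                   paths = list(), lengths = numeric(0), k = as.integer(k),
                   degeneracy = numeric(0), reachable = FALSE))
    ksp <- igraph::k_shortest_paths(g, from = source, to = sink, k = k,
                                    weights = igraph::E(g)$weight)
    paths <- lapply(ksp$vpaths, function(vp) igraph::V(g)$name[as.integer(vp)])
    w <- igraph::E(g)$weight
    lengths <- vapply(ksp$epaths, function(ep) sum(w[as.integer(ep)]),
                      numeric(1))
    ord <- order(lengths, vapply(paths, paste, character(1), collapse = "\r"))
    paths <- paths[ord]
    lengths <- lengths[ord]
    visits <- table(factor(unlist(lapply(paths, unique)),
                           levels = network@keys))
    deg <- as.numeric(visits) / length(paths)
    names(deg) <- network@keys
    deg <- deg[deg > 0]
    new("PathEnsemble", source = source, sink = sink, paths = paths,
        lengths = lengths, k = as.integer(k), degeneracy = deg,
        reachable = TRUE)
}

#' Histogram of path lengths in an ensemble
#'
#' @param ensemble a [PathEnsemble-class] with at least one path.
#' @param binWidth bin width in weight units.
#' @return data.frame(binStart, binEnd, count); counts sum to the ensemble
#'   size.
#' @export
pathLengthHistogram <- function(ensemble, binWidth) {
    if (!length(ensemble@paths)) stop("empty path ensemble")
    stopifnot(binWidth > 0)
    l <- ensemble@lengths
    lo <- min(l)
    bin <- floor((l - lo) / binWidth)
    tab <- table(bin)
    idx <- as.integer(names(tab))
    data.frame(binStart = lo + idx * binWidth,
               binEnd = lo + (idx + 1) * binWidth,
               count = as.integer(tab))
}

#' Export a dynamical network as GraphML
#' @param network a [DynamicalNetwork-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(network, path) {
    igraph::write_graph(network@graph, path, format = "graphml")
    invisible(path)
}

#' Export a community partition as TSV (residue key, community id)
#' @param partition a [CommunityPartition-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportCommunities <- function(partition, path) {
    utils::write.table(
        data.frame(residue = names(partition@membership),
                   community = partition@membership),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export a path ensemble as JSON
#' @param ensemble a [PathEnsemble-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportPathEnsemble <- function(ensemble, path) {
    obj <- list(source = ensemble@source, sink = ensemble@sink,
                k = ensemble@k, reachable = ensemble@reachable,
                lengths = ensemble@lengths, paths = ensemble@paths,
                degeneracy = as.list(ensemble@degeneracy))
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}
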