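#' Fingerprint a mode's motion as a distance-difference matrix
#'
#' Computes `deltaM = M+ - Mx`: the C-alpha pairwise-distance matrix of the
#' frame displaced at +A MRMS minus that of the reference structure.  Being
#' built from internal distances, the fingerprint is invariant to rigid-body
#' motion.  The mirror matrix `M- - Mx` is also computed and its plain
#' correlation with `deltaM` is reported (`minusSimilarity`), but only the
#' plus matrix is kept.
#'
#' @param trajectory a [ModeTrajectory-class] containing the reference and
#'   the extreme displaced frames.
#' @param system system identifier stored with the fingerprint.
#' @param selection optional C-alpha atom selection (default
#'   `selectCalpha(reference)`).
#' @return a [MotionFingerprint-class]
#' @export
computeFingerprint <- function(trajectory, system = "system",
                               selection = NULL) {
    ref <- trajectory@reference
    if (is.null(selection)) selection <- selectCalpha(ref)
    if (length(selection) < 3L)
        stop("need at least 3 C-alpha positions to fingerprint a motion")
    iRef <- which(trajectory@targets == 0)[1]
    iPlus <- which.max(trajectory@targets)
    iMinus <- which.min(trajectory@targets)
    if (is.na(iRef)) stop("trajectory lacks the zero-displacement frame")
    Dx <- .distMatrix(trajectory@frames[[iRef]][selection, , drop = FALSE])
    Dp <- .distMatrix(trajectory@frames[[iPlus]][selection, , drop = FALSE])
    Dm <- .distMatrix(trajectory@frames[[iMinus]][selection, , drop = FALSE])
    delta <- Dp - Dx
    deltaMinus <- Dm - Dx
    ut <- upper.tri(delta)
    minusSim <- if (stats::sd(delta[ut]) == 0 || stats::sd(deltaMinus[ut]) == 0)
        NA_real_ else stats::cor(delta[ut], deltaMinus[ut])
    dimnames(delta) <- NULL
    new("MotionFingerprint", system = system,
        modeLabel = trajectory@modeLabel, delta = delta,
        keys = names(selection), minusSimilarity = minusSim)
}

# Align two fingerprints on common residue keys (optionally translating B's
# keys through a ResidueMapping) and return their matrices and key set.
.alignFingerprints <- function(fpA, fpB, mapping = NULL) {
    keysB <- fpB@keys
    if (!is.null(mapping)) {
        tr <- stats::setNames(mapping@pairs$keyA, mapping@pairs$keyB)
        keysB <- ifelse(keysB %in% names(tr), tr[keysB], NA_character_)
    }
    common <- intersect(fpA@keys, keysB[!is.na(keysB)])
    if (length(common) < 3L)
        stop("fewer than 3 common C-alpha positions between fingerprints")
    ia <- match(common, fpA@keys)
    ib <- match(common, keysB)
    list(A = fpA@delta[ia, ia, drop = FALSE],
         B = fpB@delta[ib, ib, drop = FALSE],
         keys = common)
}

#' Mantel permutation test between two motion fingerprints
#'
#' `r` is the Pearson correlation of the vectorised upper triangles.  The
#' permutation null applies the same random permutation to rows and columns
#' of the second matrix; significance is two-sided on |r|.  For matrices of
#' dimension <= 7 all `n!` permutations are enumerated and the p-value is
#' the exact fraction with `|r*| >= |r|` (the identity is included, so
#' p >= 1/n!).  Otherwise `nPermutations` random permutations are drawn and
#' `p = (1 + #{|r*| >= |r|}) / (1 + nPermutations)`.
#'
#' @param fpA,fpB [MotionFingerprint-class] objects (or plain symmetric
#'   matrices, in which case `keys` are taken as row indices).
#' @param nPermutations random permutations for the sampled scheme
#'   (default 9999).
#' @param seed RNG seed for the sampled scheme.
#' @param mapping optional [ResidueMapping-class] translating B's residue
#'   keys into A's when the systems differ.
#' @param scheme `"auto"` (exhaustive for dimension <= 7, sampled above),
#'   or force `"exhaustive"` / `"sampled"`.
#' @return a [MantelResult-class]
#' @examples
#' m <- matrix(rnorm(25), 5, 5); m <- m + t(m); diag(m) <- 0
#' f <- new("MotionFingerprint", system = "s", modeLabel = 7L, delta = m,
#'          keys = paste0("A:", 1:5), minusSimilarity = 1)
#' mantelTest(f, f)@r   # 1
#' @export
mantelTest <- function(fpA, fpB, nPermutations = 9999L, seed = 1L,
                       mapping = NULL,
                       scheme = c("auto", "exhaustive", "sampled")) {
    scheme <- match.arg(scheme)
    if (is.matrix(fpA)) fpA <- .matrixFingerprint(fpA)
    if (is.matrix(fpB)) fpB <- .matrixFingerprint(fpB)
    al <- .alignFingerprints(fpA, fpB, mapping)
    n <- nrow(al$A)
    ut <- .upperIdx(n)
    a <- al$A[ut]
    b <- al$B[ut]
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
        stop("zero-variance fingerprint: Mantel r is undefined")
    r <- stats::cor(a, b)
    B <- al$B
    lin <- function(p) B[(p[ut[, 2]] - 1) * n + p[ut[, 1]]]
    exhaustive <- switch(scheme, auto = n <= 7L, exhaustive = TRUE,
                         sampled = FALSE)
    if (exhaustive) {
        perms <- .allPermutations(n)
        rstar <- vapply(perms, function(p) stats::cor(a, lin(p)), numeric(1))
        p <- mean(abs(rstar) >= abs(r) - 1e-12)
        new("MantelResult", r = r, pValue = p,
            nPermutations = length(perms) - 1L, scheme = "exhaustive",
            seed = NA_integer_)
    } else {
        count <- .withSeed(seed, {
            cnt <- 0L
            for (i in seq_len(nPermutations)) {
                p <- sample.int(n)
                if (abs(stats::cor(a, lin(p))) >= abs(r) - 1e-12)
                    cnt <- cnt + 1L
            }
            cnt
        })
        p <- (1 + count) / (1 + nPermutations)
        new("MantelResult", r = r, pValue = p,
            nPermutations = as.integer(nPermutations), scheme = "sampled",
            seed = as.integer(seed))
    }
}

.matrixFingerprint <- function(m, system = "matrix", label = 0L) {
    dimnames(m) <- NULL
    new("MotionFingerprint", system = system, modeLabel = as.integer(label),
        delta = m, keys = as.character(seq_len(nrow(m))),
        minusSimilarity = NA_real_)
}

#' Build the Mantel similarity graph over all mode fingerprints
#'
#' Computes the full pairwise Mantel r matrix (within and across systems).
#' An edge connects two modes when `|r| >= rThreshold` and the permutation
#' p-value is below `pThreshold`.  Because the p-value cannot rescue a pair
#' that fails the |r| screen, permutation tests are run only for pairs with
#' `|r| >= rThreshold`; other pairs report `p = NA`.  Per-pair permutation
#' seeds are derived as `seed + pair index` so results do not depend on
#' evaluation order.
#'
#' @param fingerprints list of [MotionFingerprint-class] objects.
#' @param rThreshold similarity threshold on |r| (default 0.6).
#' @param pThreshold significance threshold (default 0.001).
#' @param nPermutations permutations per test (default 9999).
#' @param seed base RNG seed.
#' @param mappings optional named list of [ResidueMapping-class] objects,
#'   keyed `"systemA|systemB"`, used to align cross-system fingerprints;
#'   by default common residue keys are used directly.
#' @return a [ModeSimilarityGraph-class]
#' @export
buildSimilarityGraph <- function(fingerprints, rThreshold = 0.6,
                                 pThreshold = 0.001, nPermutations = 9999L,
                                 seed = 1L, mappings = NULL) {
    if (length(fingerprints) < 2L)
        stop("need at least 2 fingerprints")
    nodes <- data.frame(
        system = vapply(fingerprints, function(f) f@system, character(1)),
        mode = vapply(fingerprints, function(f) f@modeLabel, integer(1)),
        stringsAsFactors = FALSE)
    nn <- nrow(nodes)
    nodeNames <- paste0(nodes$system, ":", nodes$mode)
    R <- matrix(NA_real_, nn, nn, dimnames = list(nodeNames, nodeNames))
    P <- matrix(NA_real_, nn, nn, dimnames = list(nodeNames, nodeNames))
    diag(R) <- 1
    getMapping <- function(sa, sb) {
        if (is.null(mappings)) return(NULL)
        mappings[[paste0(sa, "|", sb)]]
    }
    edges <- list()
    pairIndex <- 0L
    for (i in seq_len(nn - 1L)) {
        for (j in (i + 1L):nn) {
            pairIndex <- pairIndex + 1L
            map <- getMapping(nodes$system[i], nodes$system[j])
            al <- .alignFingerprints(fingerprints[[i]], fingerprints[[j]], map)
            ut <- upper.tri(al$A)
            a <- al$A[ut]; b <- al$B[ut]
            if (stats::sd(a) == 0 || stats::sd(b) == 0) {
                R[i, j] <- R[j, i] <- NA_real_
                next
            }
            r <- stats::cor(a, b)
            R[i, j] <- R[j, i] <- r
            if (abs(r) >= rThreshold) {
                mt <- mantelTest(fingerprints[[i]], fingerprints[[j]],
                                 nPermutations = nPermutations,
                                 seed = seed + pairIndex, mapping = map)
                P[i, j] <- P[j, i] <- mt@pValue
                if (mt@pValue < pThreshold)
                    edges[[length(edges) + 1L]] <-
                        data.frame(from = i, to = j, r = r, p = mt@pValue)
            }
        }
    }
    edges <- if (length(edges)) do.call(rbind, edges)
        else data.frame(from = integer(0), to = integer(0),
                        r = numeric(0), p = numeric(0))
    new("ModeSimilarityGraph", nodes = nodes, edges = edges,
        rMatrix = R, pMatrix = P, rThreshold = rThreshold,
        pThreshold = pThreshold, nPermutations = as.integer(nPermutations))
}

#' Classify motions as shared or system-unique
#'
#' Clusters the similarity graph into connected components.  Components
#' containing modes of more than one system are shared motions, tagged with
#' the signaling outcomes common to those systems; components confined to
#' one system are unique to it, tagged with the outcomes that distinguish
#' that system from the rest (or `"novel"` when no outcome does --- the
#' variant-only situation).
#'
#' @param graph a [ModeSimilarityGraph-class] over >= 2 systems.
#' @param phenotypes named list: system id -> character vector of supported
#'   signaling outcomes.
#' @return a [MotionClassification-class]
#' @export
classifyMotions <- function(graph, phenotypes) {
    nodes <- graph@nodes
    systems <- unique(nodes$system)
    if (length(systems) < 2L)
        stop("classification requires at least two systems; ",
             "only intra-system redundancy can be reported for one system")
    if (!all(systems %in% names(phenotypes)))
        stop("phenotype map must cover all systems: missing ",
             paste(setdiff(systems, names(phenotypes)), collapse = ", "))
    g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
    if (nrow(graph@edges))
        g <- igraph::add_edges(g, rbind(graph@edges$from, graph@edges$to))
    comp <- igraph::components(g)
    commonAll <- Reduce(intersect, phenotypes[systems])
    classes <- nodes
    classes$component <- comp$membership
    classes$class <- NA_character_
    classes$classLabel <- NA_character_
    classes$tag <- NA_character_
    components <- vector("list", comp$no)
    for (cid in seq_len(comp$no)) {
        members <- which(comp$membership == cid)
        components[[cid]] <- members
        sys <- unique(nodes$system[members])
        if (length(sys) > 1L) {
            shared <- Reduce(intersect, phenotypes[sys])
            classes$class[members] <- "shared"
            classes$classLabel[members] <- "shared"
            classes$tag[members] <- if (length(shared))
                paste(shared, collapse = "+") else "none"
        } else {
            distinct <- setdiff(phenotypes[[sys]], commonAll)
            classes$class[members] <- "unique"
            classes$classLabel[members] <- paste0("unique_to_", sys)
            classes$tag[members] <- if (length(distinct))
                paste(distinct, collapse = "+") else "novel"
        }
    }
    new("MotionClassification", classes = classes, components = components,
        phenotypes = phenotypes[systems])
}

#' Report intra-system motion redundancy (single-system fallback)
#'
#' When only one system is analysed, cross-system classification is not
#' defined; this reports which of the system's own modes describe the same
#' motion (connected components of the within-system similarity graph).
#'
#' @param graph a [ModeSimilarityGraph-class].
#' @return data.frame(system, mode, component)
#' @export
redundancyReport <- function(graph) {
    nodes <- graph@nodes
    g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
    if (nrow(graph@edges))
        g <- igraph::add_edges(g, rbind(graph@edges$from, graph@edges$to))
    nodes$component <- igraph::components(g)$membership
    nodes
}

#' Export a similarity graph
#'
#' @param graph a [ModeSimilarityGraph-class].
#' @param rPath optional CSV path for the full r matrix (rows/columns
#'   labelled `system:mode`, mirroring the usual mode-similarity tables).
#' @param graphmlPath optional GraphML path for the thresholded graph.
#' @return invisibly, NULL
#' @export
exportSimilarityGraph <- function(graph, rPath = NULL, graphmlPath = NULL) {
    if (!is.null(rPath))
        utils::write.csv(graph@rMatrix, rPath)
    if (!is.null(graphmlPath)) {
        nodeNames <- paste0(graph@nodes$system, ":", graph@nodes$mode)
        g <- igraph::make_empty_graph(n = nrow(graph@nodes), directed = FALSE)
        igraph::V(g)$name <- nodeNames
        igraph::V(g)$system <- graph@nodes$system
        igraph::V(g)$mode <- graph@nodes$mode
        if (nrow(graph@edges)) {
            g <- igraph::add_edges(g, rbind(graph@edges$from, graph@edges$to))
            igraph::E(g)$r <- graph@edges$r
            igraph::E(g)$p <- graph@edges$p
        }
        igraph::write_graph(g, graphmlPath, format = "graphml")
    }
    invisible(NULL)
}
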