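#' Assemble a run configuration
#'
#' Central parameter container for the end-to-end workflow.  Defaults equal
#' the study's stated operating point: 20 lowest non-trivial modes analysed,
#' +-1.0 A MRMS displacement, Mantel edge rule |r| >= 0.6 with p < 0.001,
#' network rule |C| >= 0.7 with a 10 A contact held in >= 75% of frames,
#' modularity correction 0.05 with communities under 10 nodes pruned, 500
#' suboptimal paths, hydrogen bonds at 3.0 A / 20 degrees, salt bridges at
#' 3.2 A, 50% occupancy screen.
#'
#' @param systems list of system entries; each a list with `id`,
#'   `structure` (PDB path), optional `topology` (JSON spring table,
#'   see [exportTopology()]) and `phenotypes` (character vector of
#'   supported signaling outcomes).
#' @param seed global seed; per-stage seeds are derived as documented in
#'   the methods vignette (`seed + 1000` for the similarity stage, `seed +
#'   2000` for transfer comparisons).
#' @param nma,similarity,network,paths,interactions named lists overriding
#'   individual defaults.
#' @return a list of class `"RunConfig"`
#' @export
makeRunConfig <- function(systems, seed = 1L, nma = list(),
                          similarity = list(), network = list(),
                          paths = list(), interactions = list()) {
    cfg <- list(
        seed = as.integer(seed),
        systems = systems,
        nma = utils::modifyList(
            list(cutoff = 10, springConstant = 1, nModes = 20L,
                 amplitude = 1.0, nFrames = 21L, relax = TRUE,
                 restraintWeight = 50, maxIter = 2000L, gradTol = 1e-5),
            nma),
        similarity = utils::modifyList(
            list(rThreshold = 0.6, pThreshold = 0.001,
                 nPermutations = 9999L),
            similarity),
        network = utils::modifyList(
            list(corrThreshold = 0.7, distThreshold = 10,
                 frameFraction = 0.75, modularityTolerance = 0.05,
                 minCommunitySize = 10L, kPaths = 500L),
            network),
        paths = utils::modifyList(list(endpoints = NULL), paths),
        interactions = utils::modifyList(
            list(hbondDist = 3.0, hbondAngle = 20, saltBridgeDist = 3.2,
                 occupancy = 0.5),
            interactions))
    .validateRunConfig(cfg)
    class(cfg) <- "RunConfig"
    cfg
}

#' Read a run configuration from a YAML file
#' @param path YAML file with the fields of [makeRunConfig()].
#' @return a `"RunConfig"` list
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    if (is.null(y$systems)) stop("config must list systems")
    makeRunConfig(systems = y$systems,
                  seed = y$seed %||% 1L,
                  nma = y$nma %||% list(),
                  similarity = y$similarity %||% list(),
                  network = y$network %||% list(),
                  paths = y$paths %||% list(),
                  interactions = y$interactions %||% list())
}

.validateRunConfig <- function(cfg) {
    s <- cfg$similarity; n <- cfg$network
    stopifnot(s$rThreshold > 0, s$rThreshold <= 1.01,
              s$pThreshold > 0, s$pThreshold <= 1,
              n$corrThreshold > 0, n$corrThreshold <= 1,
              n$frameFraction > 0, n$frameFraction <= 1,
              n$distThreshold > 0,
              cfg$nma$nFrames %% 2L == 1L,
              cfg$nma$amplitude > 0)
    ids <- vapply(cfg$systems, function(x) x$id, character(1))
    if (anyDuplicated(ids)) stop("duplicate system ids in config")
    invisible(TRUE)
}

# Analyse one system: structure -> modes -> trajectories -> fingerprints.
.analyzeSystem <- function(sys, nmaCfg) {
    structure <- if (is(sys$structure, "MolecularStructure")) sys$structure
        else readStructure(sys$structure)
    topology <- if (!is.null(sys$topologyTable)) sys$topologyTable
        else if (!is.null(sys$topology)) importTopology(sys$topology)
        else enmTopology(structure, nmaCfg$cutoff, nmaCfg$springConstant)
    H <- buildEnmHessian(structure, topology = topology)
    modes <- computeNormalModes(H, particleMasses(structure),
                                nModes = nmaCfg$nModes)
    trajectories <- lapply(modeLabels(modes), function(lab)
        generateModeTrajectory(structure, modes, lab,
                               amplitude = nmaCfg$amplitude,
                               nFrames = nmaCfg$nFrames,
                               relax = nmaCfg$relax, topology = topology,
                               restraintWeight = nmaCfg$restraintWeight,
                               maxIter = nmaCfg$maxIter,
                               gradTol = nmaCfg$gradTol))
    names(trajectories) <- as.character(modeLabels(modes))
    fingerprints <- lapply(trajectories, computeFingerprint, system = sys$id)
    list(id = sys$id, structure = structure, topology = topology,
         modes = modes, trajectories = trajectories,
         fingerprints = fingerprints)
}

#' Run the end-to-end motion-dissection pipeline
#'
#' Structures -> normal modes -> mode trajectories -> fingerprints ->
#' Mantel similarity graph -> motion classification -> per-class DCCM,
#' flexibility profile, dynamical network (communities, betweenness,
#' suboptimal paths, degeneracy table) and interaction occupancy tables
#' with cross-system diffs.  Every stage writes its artifact into `outDir`
#' and the run closes with a manifest (config echo, seeds, output hashes,
#' warnings).  Identical config and seed produce byte-identical numeric
#' outputs.
#'
#' With a single system, classification is refused and an intra-system
#' redundancy report is produced instead; downstream per-class analyses
#' then use one group holding all modes.
#'
#' @param config a `"RunConfig"` (see [makeRunConfig()] /
#'   [readRunConfig()]).
#' @param outDir output directory (created if needed).
#' @param stages which stages to execute, a prefix of
#'   `c("modes", "fingerprints", "similarity", "classify", "dccm",
#'   "network", "paths", "interactions")`; prerequisites of the last
#'   requested stage always run.
#' @return invisibly, a list with all in-memory stage results.
#' @export
runPipeline <- function(config, outDir,
                        stages = c("modes", "fingerprints", "similarity",
                                   "classify", "dccm", "network", "paths",
                                   "interactions")) {
    allStages <- c("modes", "fingerprints", "similarity", "classify",
                   "dccm", "network", "paths", "interactions")
    stages <- match.arg(stages, allStages, several.ok = TRUE)
    last <- max(match(stages, allStages))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logCon <- file(file.path(outDir, "log.jsonl"), "w")
    on.exit(close(logCon), add = TRUE)
    warnings <- character(0)
    log <- function(stage, msg) {
        message("[", stage, "] ", msg)
        writeLines(jsonlite::toJSON(list(stage = stage, message = msg),
                                    auto_unbox = TRUE), logCon)
    }
    fail <- function(stage, e) {
        .writeManifest(config, outDir,
                       warnings = c(warnings, paste0("FAILED at stage ",
                                                     stage, ": ",
                                                     conditionMessage(e))))
        stop("pipeline failed at stage '", stage, "': ",
             conditionMessage(e), call. = FALSE)
    }
    res <- list(config = config)

    ## --- modes / trajectories / fingerprints -------------------------
    log("modes", paste("analysing", length(config$systems), "system(s)"))
    res$systems <- tryCatch(
        lapply(config$systems, .analyzeSystem, nmaCfg = config$nma),
        error = function(e) fail("modes", e))
    names(res$systems) <- vapply(res$systems, `[[`, character(1), "id")
    for (sys in res$systems) {
        exportModeSet(sys$modes,
                      file.path(outDir, paste0("modes_", sys$id, ".json")))
    }
    if (last < 3L) { .writeManifest(config, outDir, warnings); return(invisible(res)) }

    ## --- similarity graph -------------------------------------------
    log("similarity", "pairwise Mantel comparison of mode fingerprints")
    fps <- unlist(lapply(res$systems, `[[`, "fingerprints"),
                  use.names = FALSE)
    res$graph <- tryCatch(
        buildSimilarityGraph(fps,
                             rThreshold = config$similarity$rThreshold,
                             pThreshold = config$similarity$pThreshold,
                             nPermutations = config$similarity$nPermutations,
                             seed = config$seed + 1000L),
        error = function(e) fail("similarity", e))
    exportSimilarityGraph(res$graph,
                          rPath = file.path(outDir, "similarity_r.csv"),
                          graphmlPath = file.path(outDir,
                                                  "similarity_graph.graphml"))
    if (last < 4L) { .writeManifest(config, outDir, warnings); return(invisible(res)) }

    ## --- classification ---------------------------------------------
    phenotypes <- stats::setNames(
        lapply(config$systems, function(s) as.character(s$phenotypes %||%
                                                            character(0))),
        vapply(config$systems, `[[`, character(1), "id"))
    if (length(res$systems) >= 2L) {
        log("classify", "classifying motions as shared / unique")
        res$classification <- tryCatch(
            classifyMotions(res$graph, phenotypes),
            error = function(e) fail("classify", e))
        cls <- classTable(res$classification)
        jsonlite::write_json(
            list(classes = cls,
                 components = lapply(res$classification@components,
                                     function(m)
                                         paste0(res$graph@nodes$system[m], ":",
                                                res$graph@nodes$mode[m])),
                 edges = res$graph@edges),
            file.path(outDir, "classification.json"), digits = NA,
            auto_unbox = TRUE)
        groups <- split(seq_len(nrow(cls)),
                        paste0(cls$system, ".", cls$classLabel))
        groupTable <- data.frame(
            group = names(groups),
            system = vapply(groups, function(i) cls$system[i[1]], character(1)),
            stringsAsFactors = FALSE)
        groupModes <- lapply(groups, function(i) cls$mode[i])
    } else {
        log("classify", "single system: writing redundancy report instead")
        warnings <- c(warnings,
                      "single system: classification refused, redundancy report produced")
        red <- redundancyReport(res$graph)
        res$redundancy <- red
        jsonlite::write_json(red, file.path(outDir, "redundancy.json"),
                             digits = NA, auto_unbox = TRUE)
        id <- res$systems[[1]]$id
        groupTable <- data.frame(group = paste0(id, ".all"), system = id,
                                 stringsAsFactors = FALSE)
        groupModes <- list(modeLabels(res$systems[[1]]$modes))
        names(groupModes) <- groupTable$group
    }
    res$groups <- groupTable
    if (last < 5L) { .writeManifest(config, outDir, warnings); return(invisible(res)) }

    ## --- per-group DCCM / rmsf / network / paths / interactions ------
    res$dccm <- res$rmsf <- res$network <- res$communities <-
        res$betweenness <- res$pathEnsembles <- res$interactions <- list()
    for (gi in seq_len(nrow(groupTable))) {
        gname <- groupTable$group[gi]
        sys <- res$systems[[groupTable$system[gi]]]
        trajs <- sys$trajectories[as.character(groupModes[[gname]])]
        log("dccm", paste("group", gname, "-", length(trajs), "mode(s)"))
        dccm <- tryCatch(computeDccm(trajs), error = function(e)
            fail("dccm", e))
        res$dccm[[gname]] <- dccm
        exportDccm(dccm, file.path(outDir, paste0("dccm_", gname, ".csv")))
        prof <- computeGroupRmsf(trajs, groupId = gname)
        res$rmsf[[gname]] <- prof
        exportRmsf(prof, file.path(outDir, paste0("rmsf_", gname, ".tsv")))
        if (last < 6L) next
        log("network", paste("group", gname))
        net <- tryCatch(
            buildNetwork(dccm, trajs,
                         corrThreshold = config$network$corrThreshold,
                         distThreshold = config$network$distThreshold,
                         frameFraction = config$network$frameFraction),
            error = function(e) fail("network", e))
        res$network[[gname]] <- net
        exportNetwork(net, file.path(outDir, paste0("network_", gname,
                                                    ".graphml")))
        comm <- withCallingHandlers(
            detectCommunities(net,
                              modularityTolerance =
                                  config$network$modularityTolerance,
                              minSize = config$network$minCommunitySize),
            warning = function(w) {
                warnings <<- c(warnings, conditionMessage(w))
                invokeRestart("muffleWarning")
            })
        res$communities[[gname]] <- comm
        exportCommunities(comm, file.path(outDir, paste0("communities_",
                                                         gname, ".tsv")))
        btw <- nodeBetweenness(net)
        res$betweenness[[gname]] <- btw
        utils::write.table(
            data.frame(residue = names(btw), betweenness = btw),
            file.path(outDir, paste0("betweenness_", gname, ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
        if (last >= 7L) {
            eps <- config$paths$endpoints
            if (is.null(eps)) {
                ord <- names(sort(btw, decreasing = TRUE))
                eps <- list(c(ord[1], ord[2]))
            }
            for (ep in eps) {
                log("paths", paste(gname, ":", ep[1], "->", ep[2]))
                pe <- suboptimalPaths(net, ep[1], ep[2],
                                      k = config$network$kPaths)
                pname <- paste0(gname, "_", gsub("[:^]", "-", ep[1]), "_",
                                gsub("[:^]", "-", ep[2]))
                res$pathEnsembles[[pname]] <- pe
                exportPathEnsemble(pe, file.path(outDir, paste0("paths_",
                                                                pname,
                                                                ".json")))
                if (pe@reachable && length(pe@lengths) > 1) {
                    h <- pathLengthHistogram(
                        pe, binWidth = max(diff(range(pe@lengths)) / 20,
                                           1e-6))
                    utils::write.table(h,
                        file.path(outDir, paste0("path_hist_", pname,
                                                 ".tsv")),
                        sep = "\t", quote = FALSE, row.names = FALSE)
                }
            }
        }
        if (last >= 8L) {
            log("interactions", paste("group", gname))
            rec <- rbind(
                detectHydrogenBonds(trajs,
                                    distCutoff = config$interactions$hbondDist,
                                    angleCutoff = config$interactions$hbondAngle),
                detectSaltBridges(trajs,
                                  cutoff = config$interactions$saltBridgeDist))
            res$interactions[[gname]] <- rec
            utils::write.table(rec,
                file.path(outDir, paste0("interactions_", gname, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
        }
    }
    ## degeneracy table mirroring the supplementary layout: one column per
    ## group network, rows = nodes visited by any ensemble
    if (last >= 7L && length(res$pathEnsembles)) {
        degs <- lapply(res$pathEnsembles, nodeDegeneracy)
        nodesAll <- sort(unique(unlist(lapply(degs, names))))
        tab <- data.frame(node = nodesAll, stringsAsFactors = FALSE)
        for (nm in names(degs))
            tab[[nm]] <- ifelse(nodesAll %in% names(degs[[nm]]),
                                degs[[nm]][nodesAll], 0)
        utils::write.table(tab, file.path(outDir, "degeneracy.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        res$degeneracy <- tab
    }
    ## cross-system interaction diffs (same class label, different system)
    if (last >= 8L && length(res$interactions) > 1L) {
        diffs <- list()
        gnames <- names(res$interactions)
        for (i in seq_along(gnames)) {
            for (j in seq_along(gnames)) {
                if (i >= j) next
                si <- groupTable$system[match(gnames[i], groupTable$group)]
                sj <- groupTable$system[match(gnames[j], groupTable$group)]
                if (si == sj) next
                d <- diffInteractions(res$interactions[[gnames[i]]],
                                      res$interactions[[gnames[j]]],
                                      threshold = config$interactions$occupancy)
                diffs[[paste0(gnames[i], "_vs_", gnames[j])]] <- d
            }
        }
        res$interactionDiffs <- diffs
        jsonlite::write_json(diffs,
                             file.path(outDir, "interaction_diff.json"),
                             digits = NA, auto_unbox = TRUE)
    }
    .writeManifest(config, outDir, warnings)
    invisible(res)
}

.writeManifest <- function(config, outDir, warnings = character(0)) {
    files <- setdiff(list.files(outDir), c("manifest.json", "log.jsonl"))
    hashes <- if (length(files))
        as.list(tools::md5sum(file.path(outDir, files))) else list()
    names(hashes) <- files
    cfg <- unclass(config)
    cfg$systems <- lapply(cfg$systems, function(s) {
        if (is(s$structure, "MolecularStructure"))
            s$structure <- paste0("<in-memory structure: ",
                                  nAtoms(s$structure), " atoms>")
        s$topologyTable <- NULL
        s
    })
    jsonlite::write_json(
        list(package = "MotionDissect",
             version = as.character(utils::packageVersion("MotionDissect")),
             seed = config$seed, config = cfg, outputs = hashes,
             warnings = warnings),
        file.path(outDir, "manifest.json"), digits = NA, auto_unbox = TRUE)
    invisible(NULL)
}

#' Transfer a donor system's motion class onto an acceptor structure
#'
#' For each donor mode in the class, the mode direction is re-indexed onto
#' the acceptor via the residue mapping, a trajectory is generated on the
#' acceptor (relaxed under the acceptor's own elastic network when the
#' config requests relaxation), fingerprinted, and compared by Mantel test
#' against the original donor fingerprint.  A mode is preserved when the
#' comparison passes the similarity edge rule.  This asks whether the
#' acceptor's topology still supports the donor's motion.
#'
#' @param config a `"RunConfig"` containing both systems.
#' @param donor,acceptor system ids.
#' @param classLabel class of donor modes to transfer (default
#'   `"unique_to_<donor>"`); requires >= 2 systems for classification, or
#'   pass `modes` directly.
#' @param modes optional explicit donor mode labels, bypassing
#'   classification.
#' @param analysis optional precomputed result of [runPipeline()] (saves
#'   re-analysis).
#' @return list with `report` (data.frame: mode, r, p, preserved),
#'   `nPreserved`, `nLost`, `classLabel`.
#' @export
runTransferExperiment <- function(config, donor, acceptor,
                                  classLabel = NULL, modes = NULL,
                                  analysis = NULL) {
    if (is.null(analysis))
        analysis <- runPipeline(config, outDir = tempfile("transfer_run_"),
                                stages = "classify")
    if (!donor %in% names(analysis$systems) ||
        !acceptor %in% names(analysis$systems))
        stop("donor/acceptor must be analysed systems")
    dsys <- analysis$systems[[donor]]
    asys <- analysis$systems[[acceptor]]
    if (is.null(modes)) {
        if (is.null(classLabel)) classLabel <- paste0("unique_to_", donor)
        cls <- classTable(analysis$classification)
        modes <- cls$mode[cls$system == donor & cls$classLabel == classLabel]
    } else {
        classLabel <- classLabel %||% "explicit"
    }
    if (!length(modes)) {
        return(list(report = data.frame(mode = integer(0), r = numeric(0),
                                        p = numeric(0),
                                        preserved = logical(0)),
                    nPreserved = 0L, nLost = 0L, classLabel = classLabel))
    }
    mapping <- mapResidues(dsys$structure, asys$structure)
    sim <- config$similarity
    rows <- lapply(seq_along(modes), function(mi) {
        lab <- modes[mi]
        tr <- transferModeTrajectory(
            dsys$modes, dsys$structure, asys$structure, mapping, lab,
            amplitude = config$nma$amplitude, nFrames = config$nma$nFrames,
            relax = config$nma$relax, topology = asys$topology,
            restraintWeight = config$nma$restraintWeight,
            maxIter = config$nma$maxIter, gradTol = config$nma$gradTol)
        fpH <- computeFingerprint(tr, system = paste0("h_", donor))
        mt <- mantelTest(dsys$fingerprints[[as.character(lab)]], fpH,
                         nPermutations = sim$nPermutations,
                         seed = config$seed + 2000L + mi,
                         mapping = mapping)
        data.frame(mode = lab, r = mt@r, p = mt@pValue,
                   preserved = abs(mt@r) >= sim$rThreshold &
                       mt@pValue < sim$pThreshold)
    })
    report <- do.call(rbind, rows)
    list(report = report, nPreserved = sum(report$preserved),
         nLost = sum(!report$preserved), classLabel = classLabel)
}
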