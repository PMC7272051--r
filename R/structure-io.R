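#' Read a molecular structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) into a
#' [MolecularStructure-class].  Author residue numbering is kept as the
#' public coordinate system; insertion codes participate in residue
#' identity.  For alternate locations, the highest-occupancy conformer is
#' kept.  Atomic masses come from a bundled element table; unknown elements
#' fall back to a guess from the atom name.
#'
#' @param path path to a PDB file.
#' @param model model index to read (for multi-MODEL files); default 1.
#' @param keepWaters keep water molecules? Default `FALSE`.
#' @param keepHetero keep non-water HETATM groups? Default `TRUE` (they are
#'   excluded from C-alpha analyses by [selectCalpha()] but usable for
#'   interaction analysis).
#' @return a [MolecularStructure-class]
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeStructure(generateComplex(fixtureSpec(nChains = 2, beadsPerChain = 5,
#'                                            seed = 1))$structure, pdb)
#' s <- readStructure(pdb)
#' nResidues(s)
#' @export
readStructure <- function(path, model = 1L, keepWaters = FALSE,
                          keepHetero = TRUE) {
    if (!file.exists(path))
        stop("structure file not found: ", path)
    pdb <- tryCatch(
        suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
        error = function(e) stop("cannot parse PDB file ", path, ": ",
                                 conditionMessage(e)))
    at <- pdb$atom
    if (is.null(at) || nrow(at) == 0L)
        stop("no ATOM/HETATM records in ", path)
    nModels <- nrow(pdb$xyz)
    if (model < 1L || model > nModels)
        stop("model index ", model, " out of range (file has ", nModels,
             " model(s))")
    xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)

    chain <- ifelse(is.na(at$chain), " ", at$chain)
    insert <- ifelse(is.na(at$insert), "", at$insert)
    ## duplicate residue keys: same (chain,resno,insert) with two names
    rkey0 <- paste(chain, at$resno, insert, sep = "\r")
    clash <- tapply(at$resid, rkey0, function(z) length(unique(z)) > 1)
    if (any(clash)) {
        bad <- names(which(clash))[1]
        parts <- strsplit(bad, "\r")[[1]]
        stop("duplicate residue key (two residue names at the same position): ",
             .makeResidueKey(parts[1], parts[2],
                             if (length(parts) > 2) parts[3] else ""))
    }
    keep <- rep(TRUE, nrow(at))
    if (!keepWaters) keep <- keep & !(at$resid %in% .waterNames)
    if (!keepHetero)
        keep <- keep & (at$type == "ATOM" | at$resid %in% .waterNames == FALSE &
                            at$type == "ATOM")
    ## altLoc: keep the highest-occupancy conformer per (chain,res,atom name)
    occ <- ifelse(is.na(at$o), 1, at$o)
    atomKey <- paste(chain, at$resno, insert, at$elety, sep = "\r")
    ord <- order(atomKey, -occ, ifelse(is.na(at$alt), "", at$alt))
    dupAfter <- duplicated(atomKey[ord])
    keepAlt <- logical(nrow(at))
    keepAlt[ord] <- !dupAfter
    keep <- keep & keepAlt

    at <- at[keep, , drop = FALSE]
    xyz <- xyz[keep, , drop = FALSE]
    chain <- chain[keep]
    insert <- insert[keep]
    if (nrow(at) == 0L) stop("no atoms left after filtering in ", path)

    element <- if ("elesy" %in% names(at)) at$elesy else NA_character_
    element <- ifelse(is.na(element) | element == "",
                      toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", at$elety)),
                      element)
    atoms <- data.frame(
        serial = as.integer(at$eleno),
        name = at$elety,
        element = element,
        mass = .massForElement(element, at$elety),
        chain = chain,
        resno = as.integer(at$resno),
        insert = insert,
        resid = at$resid,
        stringsAsFactors = FALSE)
    dimnames(xyz) <- NULL
    new("MolecularStructure", atoms = atoms, xyz = xyz)
}

#' Write a structure (or a mode trajectory) to a PDB file
#'
#' Writes ATOM records at standard PDB precision (3 decimals).  For a
#' [ModeTrajectory-class], frames are written as consecutive MODEL blocks.
#'
#' @param x a [MolecularStructure-class] or [ModeTrajectory-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(x, path) {
    if (is(x, "ModeTrajectory")) {
        ref <- x@reference
        con <- file(path, "w")
        on.exit(close(con))
        for (f in seq_along(x@frames)) {
            writeLines(sprintf("MODEL     %4d", f), con)
            writeLines(.pdbAtomLines(ref@atoms, x@frames[[f]]), con)
            writeLines("ENDMDL", con)
        }
        writeLines("END", con)
        return(invisible(path))
    }
    stopifnot(is(x, "MolecularStructure"))
    writeLines(c(.pdbAtomLines(x@atoms, x@xyz), "END"), path)
    invisible(path)
}

# Fixed-width PDB ATOM records.
.pdbAtomLines <- function(atoms, xyz) {
    name <- atoms$name
    # PDB atom-name column convention: left-pad short names by one space
    name4 <- ifelse(nchar(name) >= 4, substr(name, 1, 4),
                    sprintf(" %-3s", name))
    sprintf("ATOM  %5d %s%s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            atoms$serial %% 100000L, name4, " ", atoms$resid,
            substr(atoms$chain, 1, 1), atoms$resno %% 10000L,
            ifelse(atoms$insert == "", " ", atoms$insert),
            xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
            substr(atoms$element, 1, 2))
}

#' Select C-alpha atoms of standard amino-acid residues
#'
#' Returns one atom index per residue containing an atom named `CA`
#' (bead models in which every particle is a `CA` pseudo-atom are handled
#' naturally).  Waters and hetero groups are excluded.  Residues lacking a
#' CA atom are reported in the `"missing"` attribute.
#'
#' @param structure a [MolecularStructure-class].
#' @return integer vector of atom indices in residue order, named by residue
#'   key, with attribute `missing` (residue keys lacking a CA atom).
#' @export
selectCalpha <- function(structure) {
    a <- structure@atoms
    keys <- .atomResidueKeys(a)
    isAA <- a$resid %in% .standardAminoAcids & !(a$resid %in% .waterNames)
    resKeys <- keys[isAA]
    resKeys <- resKeys[!duplicated(resKeys)]
    idx <- integer(0)
    missing <- character(0)
    for (k in resKeys) {
        i <- which(keys == k & a$name == "CA" & isAA)
        if (length(i) == 0L) missing <- c(missing, k)
        else idx <- c(idx, i[1])
    }
    names(idx) <- keys[idx]
    attr(idx, "missing") <- missing
    idx
}

#' Map residues between two structures
#'
#' Residues are paired by `(chain, resno, insert)`.  Positions where the
#' residue name differs (substitutions) are mapped and flagged as mutations.
#'
#' @param structureA,structureB [MolecularStructure-class] objects.
#' @return a [ResidueMapping-class]
#' @export
mapResidues <- function(structureA, structureB) {
    ra <- .residueTable(structureA)
    rb <- .residueTable(structureB)
    if (length(intersect(unique(ra$chain), unique(rb$chain))) == 0L)
        stop("chain sets of the two structures are disjoint; cannot map")
    common <- intersect(ra$key, rb$key)
    pa <- ra[match(common, ra$key), ]
    pb <- rb[match(common, rb$key), ]
    pairs <- data.frame(keyA = pa$key, keyB = pb$key,
                        residA = pa$resid, residB = pb$resid,
                        mutation = pa$resid != pb$resid,
                        stringsAsFactors = FALSE)
    new("ResidueMapping", pairs = pairs,
        unmappedA = setdiff(ra$key, common),
        unmappedB = setdiff(rb$key, common))
}

.residueTable <- function(structure) {
    a <- structure@atoms
    keys <- .atomResidueKeys(a)
    first <- !duplicated(keys)
    data.frame(key = keys[first], chain = a$chain[first],
               resno = a$resno[first], insert = a$insert[first],
               resid = a$resid[first], stringsAsFactors = FALSE)
}

#' Construct a MolecularStructure from raw vectors
#'
#' Mostly used by the fixture generator and by tests; validates all
#' structure invariants on construction.
#'
#' @param chain,resno,insert,resid per-atom residue identity vectors.
#' @param name,element per-atom name and element.
#' @param mass per-atom mass (amu); defaults from the element table.
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param serial atom serial numbers; default sequential.
#' @return a [MolecularStructure-class]
#' @export
makeStructure <- function(chain, resno, xyz, name = "CA", element = "C",
                          resid = "GLY", insert = "", mass = NULL,
                          serial = NULL) {
    n <- nrow(xyz)
    atoms <- data.frame(
        serial = if (is.null(serial)) seq_len(n) else as.integer(serial),
        name = rep_len(name, n), element = rep_len(element, n),
        mass = if (is.null(mass))
                   .massForElement(rep_len(element, n), rep_len(name, n))
               else rep_len(mass, n),
        chain = rep_len(chain, n), resno = as.integer(rep_len(resno, n)),
        insert = rep_len(insert, n), resid = rep_len(resid, n),
        stringsAsFactors = FALSE)
    xyz <- as.matrix(xyz)
    dimnames(xyz) <- NULL
    new("MolecularStructure", atoms = atoms, xyz = xyz)
}
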