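WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

# common monoatomic ions seen as het groups in lysosomal-enzyme structures
ION_NAMES <- c("NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "CU", "NI",
               "CO", "CD", "HG", "BR", "IOD", "SO4", "PO4")

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records, optionally restricting to one chain.
#' Alternate locations are resolved to a single conformer per atom: the
#' highest-occupancy altloc is kept, with ties broken toward altloc "A".
#' Hydrogens are retained but flagged via the `is_heavy` column so that all
#' distance-based computations can exclude them.
#'
#' @param path path to a PDB-format text file.
#' @param chain optional single chain identifier to restrict to.
#' @return a [ProteinStructure-class].
#' @examples
#' pdb <- makeStructure(n_residues = 6, geometry = "extended")
#' tf <- tempfile(fileext = ".pdb")
#' writeLines(pdb$pdb_text, tf)
#' s <- readPDB(tf)
#' @export
readPDB <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop("no ATOM/HETATM records parsed from '", path,
         "': not PDB-format text?")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- ""
  at$elesy[is.na(at$elesy)] <- ""

  if (!is.null(chain)) {
    avail <- sort(unique(at$chain))
    if (!chain %in% avail)
      stop("chain '", chain, "' not found; available chains: ",
           paste(avail, collapse = ", "))
    at <- at[at$chain == chain, , drop = FALSE]
  }

  # altloc resolution: highest occupancy, ties toward "A" (blank sorts first,
  # which is correct: a blank altloc is the sole conformer)
  key <- paste(at$type, at$chain, at$resno, at$insert, at$resid, at$elety)
  if (anyDuplicated(key) > 0) {
    o <- at$o
    o[is.na(o)] <- 1
    ord <- order(key, -o, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(key[ord]), , drop = FALSE]
    at <- at[order(at$eleno), , drop = FALSE]
  }

  if (any(!is.finite(as.matrix(at[, c("x", "y", "z")]))))
    stop("non-finite coordinates in '", path, "'")
  if (any(is.na(at$b)) || any(at$b < 0, na.rm = TRUE))
    warning("missing or negative B-factors in '", path, "'")

  elesy <- toupper(trimws(at$elesy))
  guess <- toupper(substr(trimws(at$elety), 1, 1))
  elesy[elesy == ""] <- guess[elesy == ""]
  at$elesy <- elesy
  at$is_heavy <- !(elesy %in% c("H", "D"))

  keep <- c("type", "eleno", "elety", "resid", "chain", "resno", "insert",
            "x", "y", "z", "o", "b", "elesy", "is_heavy")
  rownames(at) <- NULL
  new("ProteinStructure", atoms = at[, keep], source = path)
}

#' Write a ProteinStructure back to PDB text
#'
#' Emits fixed-column ATOM/HETATM records for the (altloc-resolved) atoms of
#' the structure; used for round-trip checks and synthetic fixtures.
#'
#' @param structure a [ProteinStructure-class].
#' @param path optional output path; when `NULL` the lines are returned.
#' @return character vector of PDB lines, invisibly when written to `path`.
#' @export
writePDB <- function(structure, path = NULL) {
  a <- atomTable(structure)
  lines <- sprintf(
    "%-6s%5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$type, a$eleno, formatAtomName(a$elety, a$elesy), a$resid,
    ifelse(a$chain == "", " ", a$chain), a$resno,
    ifelse(a$insert == "", " ", a$insert),
    a$x, a$y, a$z, ifelse(is.na(a$o), 1, a$o), ifelse(is.na(a$b), 0, a$b),
    a$elesy)
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

# PDB column 13-16 convention: 1-2 char elements start in col 13, others 14
formatAtomName <- function(elety, elesy) {
  ifelse(nchar(elesy) >= 2 | nchar(elety) >= 4,
         sprintf("%-4s", elety), sprintf(" %-3s", elety))
}

polymerAtoms <- function(structure) {
  a <- atomTable(structure)
  a[a$type == "ATOM", , drop = FALSE]
}

hetAtoms <- function(structure, exclude_waters = TRUE, exclude_ions = TRUE) {
  a <- atomTable(structure)
  a <- a[a$type == "HETATM", , drop = FALSE]
  if (exclude_waters) a <- a[!(a$resid %in% WATER_NAMES), , drop = FALSE]
  if (exclude_ions) a <- a[!(a$resid %in% ION_NAMES), , drop = FALSE]
  a
}

#' Per-residue alpha-carbon B-factor
#'
#' Returns the crystallographic temperature factor of the CA atom of the
#' requested residue, a proxy for local flexibility used as a variant
#' feature.
#'
#' @param structure a [ProteinStructure-class].
#' @param residue author residue number (integer) of a polymer residue.
#' @param chain optional chain restriction when the structure has several.
#' @return numeric B-factor in square angstroms, or `NA_real_` (with a
#'   warning) when the residue lacks a CA atom.
#' @export
caBFactor <- function(structure, residue, chain = NULL) {
  a <- polymerAtoms(structure)
  if (!is.null(chain)) a <- a[a$chain == chain, , drop = FALSE]
  a <- a[a$resno == residue, , drop = FALSE]
  if (nrow(a) == 0) stop("residue ", residue, " not found in structure")
  ca <- a[a$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) {
    warning("residue ", residue, " has no CA atom; returning NA")
    return(NA_real_)
  }
  ca$b[1]
}

#' Heavy atoms of a ligand (het group)
#'
#' Selects all het groups matching a residue-name selector and returns their
#' heavy atoms. Waters never match; monoatomic ions are excluded by default.
#'
#' @param structure a [ProteinStructure-class].
#' @param ligand_selector residue name of the het group, e.g. `"NND"`, or
#'   `NULL` to take every non-water, non-ion het group.
#' @param include_ions logical, allow ion het groups to match.
#' @return data.frame of heavy atoms (same columns as [atomTable()]).
#' @export
ligandAtoms <- function(structure, ligand_selector = NULL,
                        include_ions = FALSE) {
  het <- hetAtoms(structure, exclude_waters = TRUE,
                  exclude_ions = !include_ions)
  avail <- sort(unique(het$resid))
  if (!is.null(ligand_selector)) {
    if (ligand_selector %in% WATER_NAMES)
      stop("waters ('", ligand_selector, "') are never ligand candidates")
    het <- het[het$resid == ligand_selector, , drop = FALSE]
    if (nrow(het) == 0)
      stop("no het group named '", ligand_selector, "'; available: ",
           if (length(avail) > 0) paste(avail, collapse = ", ") else "(none)")
  } else if (nrow(het) == 0) {
    stop("structure has no non-water het groups")
  }
  het[het$is_heavy, , drop = FALSE]
}
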