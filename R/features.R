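AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

aa3to1 <- function(x) {
  out <- AA1[match(toupper(x), AA3)]
  out[is.na(out)] <- "other"
  out
}

#' Is a residue within a distance cutoff of the ligand?
#'
#' TRUE when any heavy atom of the residue lies within `cutoff` angstroms
#' (inclusive) of any heavy atom of the selected ligand het group(s) — the
#' standard active-site proximity feature (default 5 angstroms).
#'
#' @param structure a [ProteinStructure-class].
#' @param residue author residue number of a polymer residue.
#' @param ligand_selector het residue name; see [ligandAtoms()].
#' @param cutoff distance cutoff in angstroms, boundary inclusive.
#' @param chain optional chain restriction for the residue.
#' @return logical.
#' @export
bindsLigand <- function(structure, residue, ligand_selector = NULL,
                        cutoff = 5.0, chain = NULL) {
  a <- polymerAtoms(structure)
  if (!is.null(chain)) a <- a[a$chain == chain, , drop = FALSE]
  ra <- a[a$resno == residue & a$is_heavy, , drop = FALSE]
  if (nrow(ra) == 0) stop("residue ", residue, " not found in structure")
  lig <- ligandAtoms(structure, ligand_selector)
  d2 <- outer(rowSums(ra[, c("x", "y", "z")]^2),
              rowSums(lig[, c("x", "y", "z")]^2), "+") -
    2 * as.matrix(ra[, c("x", "y", "z")]) %*%
        t(as.matrix(lig[, c("x", "y", "z")]))
  min(d2) <= cutoff^2 + 1e-9
}

#' Catalytic-domain membership
#'
#' @param catalytic_ranges data.frame (or 2-column matrix) of inclusive
#'   residue-number intervals `start`, `end` delimiting the catalytic domain;
#'   domain boundaries are user configuration, typically taken from a domain
#'   database for the protein at hand.
#' @param residue residue number.
#' @return logical, TRUE when the position falls inside any range
#'   (inclusive ends).
#' @export
inCatalyticDomain <- function(catalytic_ranges, residue) {
  r <- as.data.frame(catalytic_ranges)
  if (nrow(r) == 0) stop("no catalytic ranges configured")
  names(r)[1:2] <- c("start", "end")
  if (any(r$start > r$end)) stop("malformed range: start > end")
  r <- r[order(r$start), , drop = FALSE]
  if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)]))
    stop("catalytic ranges overlap")
  any(residue >= r$start & residue <= r$end)
}

#' Residue-type profile of a residue's contact partners
#'
#' Counts the contacting residues of each standard amino-acid type; the
#' profile sums to the residue's contact count. Non-standard partners fall
#' in an `"other"` bin with a warning.
#'
#' @param structure a [ProteinStructure-class].
#' @param cmap a [ContactMap-class] computed from that structure.
#' @param residue residue number.
#' @return named integer vector over the 20 standard one-letter codes plus
#'   `"other"`.
#' @export
contactProfile <- function(structure, cmap, residue) {
  a <- polymerAtoms(structure)
  if (!residue %in% a$resno)
    stop("residue ", residue, " not found in structure")
  ct <- contactTable(cmap)
  partners <- unique(c(ct$j[ct$i == residue], ct$i[ct$j == residue]))
  prof <- stats::setNames(integer(21), c(AA1, "other"))
  for (p in partners) {
    aa <- aa3to1(a$resid[a$resno == p][1])
    prof[aa] <- prof[aa] + 1L
  }
  if (prof["other"] > 0)
    warning("non-standard residue(s) among contact partners of ", residue)
  prof
}

#' Parse variant names like "N370S"
#'
#' Accepts plain one-letter substitution names with an optional HGVS-style
#' `p.` prefix.
#'
#' @param x character vector of variant names.
#' @return data.frame with columns `wt_aa`, `position`, `mut_aa`.
#' @export
parseVariant <- function(x) {
  x0 <- sub("^p\\.", "", trimws(x))
  m <- regmatches(x0, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x0))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad))
    stop("cannot parse variant name(s): ", paste(x[bad], collapse = ", "))
  out <- data.frame(
    wt_aa = toupper(vapply(m, `[`, "", 2)),
    position = as.integer(vapply(m, `[`, "", 3)),
    mut_aa = toupper(vapply(m, `[`, "", 4)))
  if (any(out$wt_aa == out$mut_aa))
    stop("wild-type and mutant residue identical in: ",
         paste(x[out$wt_aa == out$mut_aa], collapse = ", "))
  out
}

#' Read a variant table from CSV/TSV
#'
#' Expects columns `protein_id`, `variant` (e.g. "N370S" or "p.N370S"),
#' `ddg` (kcal/mol, externally computed) and optionally `label`
#' (responsive yes/no) plus any precomputed feature columns, which are
#' passed through.
#'
#' @param path CSV or TSV file.
#' @return data.frame of variant records with parsed `wt_aa`, `position`,
#'   `mut_aa` columns added.
#' @export
readVariants <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  v <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE)
  if (!"variant" %in% names(v)) stop("variant column missing in ", path)
  cbind(v, parseVariant(v$variant))
}

#' Assemble the per-variant feature table
#'
#' Builds the feature table consumed by the decision tree and by downstream
#' machine learning: stability change `ddg` (always externally supplied),
#' ligand proximity, contact count, catalytic-domain flag, local
#' circuit-topology counts, CA B-factor, the contacting-residue-type
#' profile, and an optional PSSM row. Feature columns already present in
#' `variants` (e.g. from a published table) are passed through unchanged;
#' the rest are computed when the needed structural inputs are supplied and
#' are explicit `NA` otherwise — never silent zeros.
#'
#' @param variants data.frame with columns `variant` (or `wt_aa`,
#'   `position`, `mut_aa`), `ddg`, optional `label`/`responsive` and
#'   optional precomputed feature columns `binds_ligand`, `n_contacts`,
#'   `catalytic_domain`, `p_inv`, `p_par`, `series`, `cross`, `ca_b_factor`.
#' @param structure optional [ProteinStructure-class].
#' @param cmap optional [ContactMap-class]; computed from `structure` with
#'   default parameters when structural features are needed and `cmap` is
#'   missing.
#' @param ligand_selector optional het residue name for [bindsLigand()].
#' @param domain_config optional range table for [inCatalyticDomain()].
#' @param pssm optional matrix from [readPSSM()].
#' @param unresolved what to do when a variant position is absent from the
#'   structure: `"error"` or `"skip"` (drops the row with a warning).
#' @return data.frame, one row per variant, with documented feature columns;
#'   `contact_profile` columns are prefixed `cp_`, PSSM columns `pssm_`.
#' @export
buildFeatureTable <- function(variants, structure = NULL, cmap = NULL,
                              ligand_selector = NULL, domain_config = NULL,
                              pssm = NULL,
                              unresolved = c("error", "skip")) {
  unresolved <- match.arg(unresolved)
  v <- as.data.frame(variants)
  if (!all(c("wt_aa", "position", "mut_aa") %in% names(v))) {
    if (!"variant" %in% names(v))
      stop("variants need a 'variant' column or wt_aa/position/mut_aa")
    v <- cbind(v, parseVariant(v$variant))
  }
  if (!"variant" %in% names(v))
    v$variant <- paste0(v$wt_aa, v$position, v$mut_aa)
  if (!"ddg" %in% names(v)) stop("variants need a 'ddg' column")
  n <- nrow(v)
  if (n == 0) {
    out <- data.frame(variant = character(), wt_aa = character(),
                      position = integer(), mut_aa = character(),
                      ddg = numeric(), binds_ligand = logical(),
                      n_contacts = integer(), catalytic_domain = logical(),
                      p_inv = integer(), p_par = integer(),
                      series = integer(), cross = integer(),
                      ca_b_factor = numeric())
    return(out)
  }

  have_struct <- !is.null(structure)
  if (have_struct) {
    pol <- polymerAtoms(structure)
    if (unresolved == "skip") {
      missing_pos <- !(v$position %in% pol$resno)
      if (any(missing_pos)) {
        warning("skipping variant(s) at unresolved positions: ",
                paste(v$variant[missing_pos], collapse = ", "))
        v <- v[!missing_pos, , drop = FALSE]
        n <- nrow(v)
      }
    }
    # wild-type identity check against the structure sequence
    for (k in seq_len(n)) {
      ra <- pol$resid[pol$resno == v$position[k]]
      if (length(ra) == 0)
        stop("variant ", v$variant[k], ": position not in structure")
      found <- aa3to1(ra[1])
      if (found != "other" && found != v$wt_aa[k])
        stop("variant ", v$variant[k], ": structure has ", found,
             " at position ", v$position[k])
    }
    need_cmap <- !all(c("n_contacts", "p_inv", "p_par", "series", "cross")
                      %in% names(v))
    if (is.null(cmap) && need_cmap) cmap <- computeContacts(structure)
  }

  # feature columns present in the input pass through; otherwise compute
  # per position when possible, else explicit NA
  getcol <- function(col, fn, proto) {
    if (col %in% names(v)) return(v[[col]])
    if (is.null(fn)) return(rep(proto, n))
    out <- rep(proto, n)
    for (k in seq_len(n)) out[k] <- fn(v$position[k])
    out
  }

  binds <- getcol("binds_ligand",
    if (have_struct && !is.null(ligand_selector))
      function(p) bindsLigand(structure, p, ligand_selector) else NULL,
    NA)
  ncon <- getcol("n_contacts",
    if (have_struct) function(p) contactCount(cmap, p) else NULL,
    NA_integer_)
  catdom <- getcol("catalytic_domain",
    if (!is.null(domain_config))
      function(p) inCatalyticDomain(domain_config, p) else NULL,
    NA)
  topo_fn <- function(field) {
    if (!have_struct) return(NULL)
    function(p) localTopology(cmap, p)[[field]]
  }
  p_inv <- getcol("p_inv", topo_fn("inverse_parallel"), NA_integer_)
  p_par <- getcol("p_par", topo_fn("parallel"), NA_integer_)
  srs <- getcol("series", topo_fn("series"), NA_integer_)
  crs <- getcol("cross", topo_fn("cross"), NA_integer_)
  bfac <- getcol("ca_b_factor",
    if (have_struct)
      function(p) suppressWarnings(caBFactor(structure, p)) else NULL,
    NA_real_)

  out <- data.frame(variant = v$variant, wt_aa = v$wt_aa,
                    position = v$position, mut_aa = v$mut_aa,
                    ddg = as.numeric(v$ddg),
                    binds_ligand = normalizeYesNo(binds),
                    n_contacts = as.integer(ncon),
                    catalytic_domain = normalizeYesNo(catdom),
                    p_inv = as.integer(p_inv), p_par = as.integer(p_par),
                    series = as.integer(srs), cross = as.integer(crs),
                    ca_b_factor = as.numeric(bfac))
  if ("label" %in% names(v)) out$responsive <- normalizeYesNo(v$label)
  if ("responsive" %in% names(v)) out$responsive <- normalizeYesNo(v$responsive)
  if ("label_source" %in% names(v)) out$label_source <- v$label_source

  if (have_struct && !is.null(cmap)) {
    prof <- t(vapply(v$position, function(p)
      suppressWarnings(contactProfile(structure, cmap, p)), integer(21)))
    colnames(prof) <- paste0("cp_", colnames(prof))
    out <- cbind(out, prof)
  }
  if (!is.null(pssm)) {
    pr <- matrix(NA_integer_, n, 20, dimnames = list(NULL, paste0("pssm_", AA1)))
    ok <- v$position >= 1 & v$position <= nrow(pssm)
    pr[ok, ] <- as.matrix(pssm[v$position[ok], AA1, drop = FALSE])
    out <- cbind(out, pr)
  }
  rownames(out) <- NULL
  out
}

# tolerant yes/no/TRUE/FALSE -> logical (NA preserved)
normalizeYesNo <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("yes", "y", "true", "1", "responsive")] <- TRUE
  out[s %in% c("no", "n", "false", "0", "non-responsive", "nonresponsive")] <- FALSE
  out
}
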