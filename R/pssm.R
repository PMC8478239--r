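#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the standard two-matrix ASCII layout written by PSI-BLAST
#' (`-out_ascii_pssm`): a header line naming the 40 amino-acid columns,
#' then one row per query position carrying the position, the query residue,
#' 20 integer log-odds scores and 20 weighted-percentage columns, followed
#' by a trailing statistics block which is ignored. Only the first (log-odds)
#' matrix is consumed.
#'
#' @param path path to the ASCII PSSM file.
#' @return integer matrix with one row per query position (rownames the
#'   query residues as `"<pos> <aa>"` attribute-free; positions are row
#'   indices) and the 20 standard one-letter amino-acid columns in the
#'   file's column order.
#' @export
readPSSM <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*A\\s+R\\s+N\\s+D", lines)
  if (length(hdr) == 0)
    stop("not a PSI-BLAST ASCII PSSM (no amino-acid header line): ", path)
  hdr <- hdr[1]
  cols <- strsplit(trimws(lines[hdr]), "\\s+")[[1]]
  if (length(cols) < 20)
    stop("PSSM header at line ", hdr, " has ", length(cols),
         " columns; expected >= 20")
  aa_cols <- cols[1:20]

  rows <- list()
  query <- character(0)
  for (k in seq(hdr + 1, length(lines))) {
    ln <- trimws(lines[k])
    if (ln == "") break  # blank line ends the matrix; statistics block follows
    f <- strsplit(ln, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", f[1])) break  # e.g. "Lambda" footer
    if (length(f) < 22)
      stop("truncated PSSM row at line ", k, ": ", length(f),
           " fields, expected >= 22")
    sc <- suppressWarnings(as.integer(f[3:22]))
    if (any(is.na(sc)))
      stop("non-integer score in PSSM row at line ", k)
    pos <- as.integer(f[1])
    if (pos != length(rows) + 1L)
      stop("non-consecutive position ", pos, " at line ", k)
    rows[[pos]] <- sc
    query <- c(query, f[2])
  }
  if (length(rows) == 0) stop("PSSM contains no score rows: ", path)
  m <- do.call(rbind, rows)
  colnames(m) <- aa_cols
  attr(m, "query") <- query
  m
}
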