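#' Read a molecule from PDB-format content
#'
#' Parses ATOM/HETATM records (via bio3d), assigns van der Waals radii by
#' element from a radius table, and applies the standard acceptance policy:
#' waters (residue HOH) are excluded unless `include_waters = TRUE`, altLoc
#' codes other than blank or 'A' are dropped, and only the first NMR model is
#' used. Unknown elements get the table's fallback radius with a warning.
#'
#' @param x path to a PDB file, or a character scalar/vector of PDB text.
#' @param include_waters keep HOH residues? Default FALSE (cavities are
#'   computed against solvent).
#' @param rtable radius table from [radius_table()].
#' @param name molecule name (default: file basename or "pdb").
#' @return A preprocessed [molecule()].
#' @export
read_pdb <- function(x, include_waters = FALSE, rtable = radius_table(),
                     name = NULL) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    path <- x
    if (is.null(name)) name <- sub("\\.(pdb|ent)$", "", basename(path))
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(paste(x, collapse = "\n"), "\n")), path)
    if (is.null(name)) name <- "pdb"
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("no parsable ATOM/HETATM records: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("no parsable ATOM/HETATM records")
  keep <- at$alt %in% c("", "A", NA)
  if (!include_waters) keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no atoms accepted (only waters / alternate locations present)")
  el <- at$elesy
  miss <- is.na(el) | trimws(el) == ""
  # fall back to first letter of the atom name when the element column is blank
  el[miss] <- sub("^[0-9]*([A-Za-z]).*", "\\1", at$elety[miss])
  r <- lookup_radii(el, rtable)
  preprocess_molecule(molecule(cbind(at$x, at$y, at$z), r,
                               serial = at$eleno, element = toupper(trimws(el)),
                               resid = at$resid, chain = at$chain, name = name))
}
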