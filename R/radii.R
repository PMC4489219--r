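#' Van der Waals radius table
#'
#' Bondi-style set used to assign radii to PDB atoms by element. No single
#' table is canonical; this bundled default (C 1.70, N 1.55, O 1.52,
#' S 1.80, H 1.20, P 1.80 Angstrom, plus common ions) can be overridden by
#' a plain-text config file of `ELEMENT radius` lines.
#'
#' @param file optional path to a whitespace-separated `element radius` file;
#'   entries override or extend the default table.
#' @param default fallback radius (Angstrom) for unknown elements.
#' @return A list with `radii` (named numeric) and `default`.
#' @export
radius_table <- function(file = NULL, default = 1.70) {
  radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
             F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
             ZN = 1.39, FE = 1.40, MG = 1.73, CA = 2.31, "NA" = 2.27,
             K = 2.75, MN = 1.40, CU = 1.40, NI = 1.40, CO = 1.40)
  if (!is.null(file)) {
    tab <- utils::read.table(file, header = FALSE, col.names = c("el", "r"),
                             stringsAsFactors = FALSE)
    if (any(tab$r <= 0)) stop("radius table entries must be positive")
    radii[toupper(tab$el)] <- tab$r
  }
  if (default <= 0) stop("default radius must be positive")
  list(radii = radii, default = default)
}

# vectorized lookup with fallback + warning on unknown elements
lookup_radii <- function(elements, table) {
  el <- toupper(trimws(elements))
  r <- unname(table$radii[el])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning(sprintf("unknown element(s) %s: using fallback radius %.2f A",
                    paste(unique(el[unknown]), collapse = ", "),
                    table$default))
    r[unknown] <- table$default
  }
  r
}
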