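#' Write / read the quasi-triangulation cache file (QTF dialect)
#'
#' A plain-text cache of the quasi-triangulation so repeated analyses of the
#' same structure (different probe radii, voids vs channels) skip the dual
#' construction. The format is a self-contained dialect: a `QTF/1` version
#' line, a header with the simplex counts, an atom section (serial, center,
#' radius, element), then edge/face/cell sections carrying atom ids, probe
#' thresholds and anomaly markers, and per-cell neighbor lists (-1 for an
#' unbounded boundary side). Coordinates are written with 17 significant
#' digits so write-read round trips are stable.
#'
#' @param qt a `vc_qt` from [dualize()].
#' @param path optional file path; when `NULL` the document is returned as a
#'   character vector of lines.
#' @return `write_qtf`: the lines, invisibly when written to a file.
#'   `read_qtf`: a `vc_qt` (molecule rebuilt from the atom section).
#' @export
write_qtf <- function(qt, path = NULL) {
  stopifnot(inherits(qt, "vc_qt"))
  mol <- qt$molecule
  num <- function(x) formatC(x, digits = 17, format = "g")
  ln <- c("QTF/1",
          paste("molecule", mol$name),
          paste("counts", nrow(qt$vertices), nrow(qt$edges),
                nrow(qt$faces), nrow(qt$cells)),
          "atoms")
  ln <- c(ln, vapply(seq_len(n_atoms(mol)), function(i)
    paste(mol$serial[i], num(mol$centers[i, 1]), num(mol$centers[i, 2]),
          num(mol$centers[i, 3]), num(mol$radii[i]),
          ifelse(is.na(mol$element[i]), ".", mol$element[i])),
    character(1)))
  ln <- c(ln, "edges")
  if (nrow(qt$edges) > 0)
    ln <- c(ln, paste(qt$edges$id, qt$edges$a1, qt$edges$a2,
                      num(qt$edges$rho)))
  ln <- c(ln, "faces")
  if (nrow(qt$faces) > 0)
    ln <- c(ln, paste(qt$faces$id, qt$faces$a1, qt$faces$a2, qt$faces$a3,
                      num(qt$faces$rho), as.integer(qt$faces$anomaly)))
  ln <- c(ln, "cells")
  if (nrow(qt$cells) > 0)
    ln <- c(ln, vapply(seq_len(nrow(qt$cells)), function(i) {
      at <- qt$cells$atoms[[i]]
      nb <- qt$cell_neighbors[[i]]
      paste(qt$cells$id[i], length(at), paste(at, collapse = " "),
            num(qt$cells$rho[i]), as.integer(qt$cells$anomaly[i]),
            length(nb), paste(nb, collapse = " "))
    }, character(1)))
  if (!is.null(path)) {
    writeLines(ln, path)
    return(invisible(ln))
  }
  ln
}

#' @rdname write_qtf
#' @param x path to a QTF file, or the document as a character vector.
#' @export
read_qtf <- function(x) {
  ln <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x) else unlist(strsplit(x, "\n"))
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) < 4L || ln[1] != "QTF/1")
    stop("QTF parse error in header: missing QTF/1 version line")
  name <- sub("^molecule ", "", ln[2])
  cnt <- as.integer(strsplit(ln[3], "\\s+")[[1]][-1])
  if (length(cnt) != 4L || anyNA(cnt))
    stop("QTF parse error in header: bad counts line")
  secs <- split_sections(ln[-(1:3)], c("atoms", "edges", "faces", "cells"))
  for (nm in c("atoms", "edges", "faces", "cells")) {
    need <- c(atoms = cnt[1], edges = cnt[2], faces = cnt[3],
              cells = cnt[4])[[nm]]
    if (length(secs[[nm]]) != need)
      stop(sprintf("QTF parse error in section '%s': header declares %d, found %d",
                   nm, need, length(secs[[nm]])))
  }
  at <- do.call(rbind, strsplit(secs$atoms, "\\s+"))
  mol <- molecule(matrix(as.numeric(at[, 2:4]), ncol = 3),
                  as.numeric(at[, 5]), serial = as.integer(at[, 1]),
                  element = ifelse(at[, 6] == ".", NA, at[, 6]), name = name)
  n <- n_atoms(mol)
  vertices <- data.frame(id = seq_len(n), atom = seq_len(n),
                         rho = -mol$radii, dual_cell = seq_len(n))
  parse_num <- function(rows, k) {
    if (length(rows) == 0L) return(matrix(numeric(0), 0, k))
    m <- do.call(rbind, strsplit(rows, "\\s+"))
    if (ncol(m) != k) stop("QTF parse error: malformed record '",
                           rows[which(sapply(strsplit(rows, "\\s+"),
                                             length) != k)[1]], "'")
    m
  }
  em <- parse_num(secs$edges, 4L)
  edges <- data.frame(id = as.integer(em[, 1]), a1 = as.integer(em[, 2]),
                      a2 = as.integer(em[, 3]), rho = as.numeric(em[, 4]),
                      dual_face = as.integer(em[, 1]))
  fm <- parse_num(secs$faces, 6L)
  faces <- data.frame(id = as.integer(fm[, 1]), a1 = as.integer(fm[, 2]),
                      a2 = as.integer(fm[, 3]), a3 = as.integer(fm[, 4]),
                      rho = as.numeric(fm[, 5]), dual_edge = as.integer(fm[, 1]),
                      anomaly = fm[, 6] == "1")
  cl <- lapply(secs$cells, function(row) {
    f <- strsplit(row, "\\s+")[[1]]
    na <- as.integer(f[2])
    at <- as.integer(f[3:(2 + na)])
    rho <- as.numeric(f[3 + na]); anom <- f[4 + na] == "1"
    nn <- as.integer(f[5 + na])
    nb <- if (nn > 0) as.integer(f[(6 + na):(5 + na + nn)]) else integer(0)
    if (anyNA(c(at, rho, nn, nb))) stop("QTF parse error in section 'cells'")
    list(id = as.integer(f[1]), atoms = at, rho = rho, anom = anom, nb = nb)
  })
  cells <- data.frame(id = vapply(cl, `[[`, integer(1), "id"),
                      rho = vapply(cl, `[[`, numeric(1), "rho"),
                      dual_vertex = vapply(cl, `[[`, integer(1), "id"),
                      anomaly = vapply(cl, `[[`, logical(1), "anom"))
  cells$atoms <- lapply(cl, `[[`, "atoms")
  nbrs <- lapply(cl, `[[`, "nb")
  # neighbor symmetry check
  for (i in seq_along(nbrs)) for (j in nbrs[[i]]) if (j > 0)
    if (!(i %in% nbrs[[j]]))
      stop("QTF parse error in section 'cells': asymmetric neighbor relation")
  structure(list(molecule = mol, vertices = vertices, edges = edges,
                 faces = faces, cells = cells, cell_neighbors = nbrs),
            class = "vc_qt")
}

split_sections <- function(ln, names) {
  idx <- match(names, ln)
  if (anyNA(idx) || is.unsorted(idx))
    stop("QTF parse error: missing or misordered section header(s) ",
         paste(names[is.na(idx)], collapse = ", "))
  out <- list()
  bounds <- c(idx, length(ln) + 1L)
  for (k in seq_along(names)) {
    rows <- if (bounds[k] + 1L > bounds[k + 1L] - 1L) character(0)
            else ln[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    out[[names[k]]] <- rows
  }
  out
}
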