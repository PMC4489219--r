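#' Dualize a Voronoi diagram into its quasi-triangulation
#'
#' The quasi-triangulation is the dual simplicial structure of the additively
#' weighted Voronoi diagram: one QT vertex per atom (Voronoi cell), one QT
#' edge per Voronoi face (atom pair), one QT triangular face per Voronoi edge
#' (atom triple) and one QT cell per Voronoi vertex (atom quadruple). Unlike
#' the Delaunay triangulation the quasi-triangulation need not be a simplicial
#' complex: the same atom triple can appear as several QT faces (its
#' equidistant curve can carry several Voronoi edges) and degenerate
#' cospherical configurations yield cells with more than four atoms. Such
#' simplexes are flagged `anomaly` and handled through incidence lists, never
#' assumed manifold.
#'
#' Each simplex stores its probe threshold rho: the minimum clearance over
#' the closed dual Voronoi entity (vertex tangent radius for a cell, minimum
#' clearance along the dual Voronoi edge for a face, minimum clearance over
#' the dual Voronoi face for an edge, -r_i for an atom vertex). A probe of
#' radius beta passes through the simplex iff beta < rho, which is what the
#' beta-complex extraction consumes.
#'
#' @param vd a `vc_vd` from [compute_awvd()].
#' @return An object of class `vc_qt` with data.frames `vertices`, `edges`,
#'   `faces`, `cells` (cells carry their atom sets in list column `atoms`),
#'   back-references to the dual Voronoi entity ids, and the source molecule.
#' @examples
#' qt <- dualize(compute_awvd(make_fixture("tetra_cage")))
#' nrow(qt$cells)   # 1 cell dual to the single Voronoi vertex
#' @export
dualize <- function(vd) {
  stopifnot(inherits(vd, "vc_vd"))
  mol <- vd$molecule
  n <- n_atoms(mol)
  vertices <- data.frame(id = seq_len(n), atom = seq_len(n),
                         rho = -mol$radii, dual_cell = seq_len(n))
  edges <- data.frame(id = seq_len(nrow(vd$faces)),
                      a1 = vd$faces$a1, a2 = vd$faces$a2,
                      rho = vd$faces$rho_min, dual_face = vd$faces$id)
  tri_key <- paste(vd$edges$a1, vd$edges$a2, vd$edges$a3)
  faces <- data.frame(id = seq_len(nrow(vd$edges)),
                      a1 = vd$edges$a1, a2 = vd$edges$a2, a3 = vd$edges$a3,
                      rho = vd$edges$rho_min, dual_edge = vd$edges$id,
                      anomaly = duplicated(tri_key) |
                        duplicated(tri_key, fromLast = TRUE))
  nc <- nrow(vd$vertices)
  cells <- data.frame(id = seq_len(nc), rho = vd$vertices$rho,
                      dual_vertex = vd$vertices$id,
                      anomaly = vd$vertices$degenerate)
  cells$atoms <- if (nc > 0) vd$vertex_atoms else list()
  # neighbor cells through shared QT faces (dual: Voronoi edges between
  # vertices); -1 marks an unbounded dual edge end (boundary of the complex)
  nbrs <- vector("list", nc)
  if (nc > 0) {
    for (i in seq_len(nc)) nbrs[[i]] <- integer(0)
    for (ei in seq_len(nrow(vd$edges))) {
      v1 <- vd$edges$v1[ei]; v2 <- vd$edges$v2[ei]
      if (!is.na(v1)) nbrs[[v1]] <- c(nbrs[[v1]],
                                      if (is.na(v2)) -1L else v2)
      if (!is.na(v2)) nbrs[[v2]] <- c(nbrs[[v2]],
                                      if (is.na(v1)) -1L else v1)
    }
  }
  structure(list(molecule = mol, vertices = vertices, edges = edges,
                 faces = faces, cells = cells, cell_neighbors = nbrs),
            class = "vc_qt")
}

#' @export
print.vc_qt <- function(x, ...) {
  cat(sprintf("<vc_qt> %s: %d vertices, %d edges, %d faces, %d cells",
              x$molecule$name, nrow(x$vertices), nrow(x$edges),
              nrow(x$faces), nrow(x$cells)),
      sprintf("(%d anomalous)\n",
              sum(x$faces$anomaly) + sum(x$cells$anomaly)))
  invisible(x)
}
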