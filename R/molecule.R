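#' Molecule objects
#'
#' A molecule is an ordered set of spherical atoms a_i = (c_i, r_i) with a
#' center and a van der Waals radius, plus per-atom metadata (PDB serial,
#' element symbol, residue and chain). All geometry downstream (Voronoi
#' diagram, beta-complex, cavities) is driven by centers and radii only.
#'
#' @param centers numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param radii positive numeric vector of van der Waals radii (Angstrom).
#' @param serial integer identifiers echoed in reports (defaults to 1..n).
#' @param element character element symbols (optional metadata).
#' @param resid,chain character residue / chain metadata (optional).
#' @param name molecule name used in reports.
#' @return An object of class `vc_molecule`.
#' @export
molecule <- function(centers, radii, serial = NULL, element = NULL,
                     resid = NULL, chain = NULL, name = "molecule") {
  centers <- as.matrix(centers)
  if (ncol(centers) != 3L) stop("centers must be an n x 3 matrix")
  storage.mode(centers) <- "double"
  n <- nrow(centers)
  if (n < 1L) stop("a molecule needs at least one atom")
  radii <- as.numeric(radii)
  if (length(radii) == 1L) radii <- rep(radii, n)
  if (length(radii) != n) stop("length(radii) must match nrow(centers)")
  if (!all(is.finite(centers)) || !all(is.finite(radii)))
    stop("atom coordinates and radii must be finite")
  if (any(radii <= 0)) stop("all radii must be positive")
  if (is.null(serial)) serial <- seq_len(n)
  if (is.null(element)) element <- rep(NA_character_, n)
  if (is.null(resid)) resid <- rep(NA_character_, n)
  if (is.null(chain)) chain <- rep(NA_character_, n)
  structure(list(
    centers = unname(centers), radii = unname(radii),
    serial = as.integer(serial), element = as.character(element),
    resid = as.character(resid), chain = as.character(chain),
    name = as.character(name)[1]
  ), class = "vc_molecule")
}

#' @export
print.vc_molecule <- function(x, ...) {
  cat(sprintf("<vc_molecule> %s: %d atoms, radii %.2f-%.2f A\n",
              x$name, n_atoms(x), min(x$radii), max(x$radii)))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `vc_molecule`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$centers)

#' Remove atoms entirely contained in another atom
#'
#' Atom j is contained in atom i when d(c_i, c_j) + r_j <= r_i + tol: every
#' point of ball j lies inside ball i, so j cannot contribute a Voronoi cell
#' with interior and is dropped before any diagram computation. The operation
#' is idempotent. Removed serials are attached as attribute `removed` and
#' reported via a message.
#'
#' @param mol a `vc_molecule`.
#' @param tol containment slack in Angstrom.
#' @return The preprocessed `vc_molecule`.
#' @export
preprocess_molecule <- function(mol, tol = 1e-9) {
  n <- n_atoms(mol)
  if (n == 1L) {
    attr(mol, "removed") <- integer(0)
    return(mol)
  }
  d <- as.matrix(stats::dist(mol$centers))
  contained <- rep(FALSE, n)
  for (j in seq_len(n)) {
    # contained in any i with larger radius; ties broken by lower index so
    # exactly one of two coincident equal atoms survives
    inside <- d[, j] + mol$radii[j] <= mol$radii + tol
    inside[j] <- FALSE
    inside <- inside & !contained            # survivors only
    if (any(inside & (mol$radii > mol$radii[j] |
                      (mol$radii == mol$radii[j] & seq_len(n) < j))))
      contained[j] <- TRUE
  }
  removed <- mol$serial[contained]
  if (any(contained)) {
    keep <- !contained
    mol <- molecule(mol$centers[keep, , drop = FALSE], mol$radii[keep],
                    mol$serial[keep], mol$element[keep], mol$resid[keep],
                    mol$chain[keep], mol$name)
    message(sprintf("preprocess_molecule: removed %d contained atom(s): %s",
                    length(removed), paste(removed, collapse = ", ")))
  }
  attr(mol, "removed") <- removed
  mol
}

#' Additively weighted clearance of points
#'
#' Clearance of a point x is min_i (d(x, c_i) - r_i): the radius of the
#' largest ball centered at x that touches no atom; negative inside an atom.
#'
#' @param pts numeric matrix (m x 3) or length-3 vector.
#' @param mol a `vc_molecule`.
#' @return numeric vector of clearances (Angstrom).
#' @export
clearance <- function(pts, mol) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  cw <- weighted_dists(pts, mol)
  do.call(pmin, as.data.frame(cw))
}

# m x n matrix of weighted distances d(x, c_i) - r_i
weighted_dists <- function(pts, mol) {
  cx <- mol$centers
  d2 <- outer(rowSums(pts^2), rep(1, nrow(cx))) +
    outer(rep(1, nrow(pts)), rowSums(cx^2)) - 2 * pts %*% t(cx)
  sqrt(pmax(d2, 0)) - rep(mol$radii, each = nrow(pts))
}

# index of nearest atom(s) within tol of the minimum, for a single point
nearest_atoms <- function(x, mol, tol = 1e-7) {
  w <- sqrt(colSums((t(mol$centers) - x)^2)) - mol$radii
  which(w <= min(w) + tol)
}
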