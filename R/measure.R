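#' Van der Waals volume and area of a molecule (union of balls)
#'
#' Two computation paths behind one contract:
#'
#' * analytic (tag `"analytic"`): when no three balls share volume and no
#'   two spherical caps on any one sphere overlap, the union volume is
#'   sum of ball volumes minus the exact two-sphere lens terms, and the area
#'   is sum of sphere areas minus the exact cap terms.
#' * adaptive (tag `"adaptive"`): otherwise, exact radial ray casting over
#'   the Voronoi cells. Cells partition space and within its own cell an
#'   atom is nearest, so the union is the disjoint union over atoms of
#'   (cell_i intersect ball_i); along a ray from c_i the cell is left at a
#'   closed-form parameter, giving per-direction volume and boundary terms
#'   integrated over a deterministic spherical quadrature. The reported
#'   error bound is the observed change under quadrature refinement.
#'
#' @param mol a preprocessed [molecule()].
#' @param n_dirs directions per atom for the adaptive quadrature.
#' @return A list: `volume`, `area` (Angstrom^3 / Angstrom^2), `method`,
#'   `error` (absolute bound estimate).
#' @examples
#' vdw_volume_area(molecule(matrix(c(0, 0, 0), 1), 1))  # 4*pi/3, 4*pi
#' @export
vdw_volume_area <- function(mol, n_dirs = 40000L) {
  stopifnot(inherits(mol, "vc_molecule"))
  n <- n_atoms(mol)
  ctr <- mol$centers; rad <- mol$radii
  d <- as.matrix(stats::dist(ctr))
  if (analytic_union_ok(ctr, rad, d)) {
    vol <- sum(4 / 3 * pi * rad^3)
    area <- sum(4 * pi * rad^2)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      dd <- d[i, j]
      if (dd >= rad[i] + rad[j]) next
      vol <- vol - lens_volume(rad[i], rad[j], dd)
      area <- area - cap_area(rad[i], rad[j], dd) -
        cap_area(rad[j], rad[i], dd)
    }
    return(list(volume = vol, area = area, method = "analytic",
                error = max(1e-6, 1e-6 * vol)))
  }
  f1 <- union_raycast(mol, n_dirs)
  f2 <- union_raycast(mol, n_dirs %/% 4L)
  list(volume = f1$volume, area = f1$area, method = "adaptive",
       error = max(abs(f1$volume - f2$volume), abs(f1$area - f2$area), 1e-9))
}

# no common volume among any three balls and no overlapping caps on a sphere
analytic_union_ok <- function(ctr, rad, d) {
  n <- nrow(ctr)
  if (n <= 1L) return(TRUE)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < rad[i] + rad + 1e-12 & seq_len(n) != i)
    if (length(nb) < 2L) next
    # cap of j on sphere i: angular radius around the center-line direction
    cosr <- (d[i, nb]^2 + rad[i]^2 - rad[nb]^2) / (2 * d[i, nb] * rad[i])
    if (any(abs(cosr) > 1)) return(FALSE)   # one ball swallows the cap
    angr <- acos(pmin(1, pmax(-1, cosr)))
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (b <= a) next
      u <- (ctr[nb[a], ] - ctr[i, ]) / d[i, nb[a]]
      v <- (ctr[nb[b], ] - ctr[i, ]) / d[i, nb[b]]
      gap <- acos(pmin(1, pmax(-1, sum(u * v))))
      if (gap < angr[a] + angr[b]) return(FALSE)
    }
  }
  TRUE
}

# exact two-sphere lens volume for centers dd apart (dd < r1 + r2)
lens_volume <- function(r1, r2, dd) {
  pi * (r1 + r2 - dd)^2 *
    (dd^2 + 2 * dd * r2 - 3 * r2^2 + 2 * dd * r1 + 6 * r2 * r1 - 3 * r1^2) /
    (12 * dd)
}

# area of the cap that sphere (r1) loses to a neighbor (r2) at distance dd
cap_area <- function(r1, r2, dd) {
  cosr <- (dd^2 + r1^2 - r2^2) / (2 * dd * r1)
  2 * pi * r1^2 * (1 - cosr)
}

# closed-form exit parameter of the ray c_i + t*w out of cell i past the
# bisector with atom j; Inf when the bisector is not crossed forward
ray_cell_exit <- function(mol, i, dirs) {
  ctr <- mol$centers; rad <- mol$radii
  n <- n_atoms(mol)
  tmin <- rep(Inf, nrow(dirs))
  for (j in seq_len(n)) {
    if (j == i) next
    dv <- ctr[j, ] - ctr[i, ]
    dr <- rad[j] - rad[i]
    num <- sum(dv^2) - dr^2
    den <- 2 * (dirs %*% dv + dr)
    t <- ifelse(den > 1e-14, num / den, Inf)
    t[t < 0] <- Inf
    # reject mirror roots of the squared bisector equation
    t[t + dr < 0] <- Inf
    tmin <- pmin(tmin, t)
  }
  tmin
}

union_raycast <- function(mol, n_dirs) {
  dirs <- fibonacci_directions(n_dirs)
  dOmega <- 4 * pi / n_dirs
  vol <- 0; area <- 0
  for (i in seq_len(n_atoms(mol))) {
    texit <- ray_cell_exit(mol, i, dirs)
    vol <- vol + sum(pmin(mol$radii[i], texit)^3) / 3 * dOmega
    area <- area + mol$radii[i]^2 * sum(texit > mol$radii[i]) * dOmega
  }
  list(volume = vol, area = area)
}

#' Monte-Carlo volume of an arbitrary region (test oracle)
#'
#' Unbiased hit-or-miss estimator over an axis-aligned box, used as the
#' independent cross-check for the analytic and ray-cast volumes.
#'
#' @param predicate function taking an m x 3 matrix, returning logical m.
#' @param box 2 x 3 matrix: rows are lower and upper corners.
#' @param n sample count (>= 1000).
#' @param seed integer seed; the estimate is reproducible.
#' @return list(`estimate`, `se`) with `se` the standard error
#'   box_volume * sqrt(p(1-p)/n).
#' @export
mc_region_volume <- function(predicate, box, n = 1e6, seed = 1L) {
  stopifnot(n >= 1000)
  box <- as.matrix(box)
  vb <- prod(box[2, ] - box[1, ])
  hits <- with_local_seed(seed, {
    pts <- cbind(stats::runif(n, box[1, 1], box[2, 1]),
                 stats::runif(n, box[1, 2], box[2, 2]),
                 stats::runif(n, box[1, 3], box[2, 3]))
    sum(predicate(pts))
  })
  p <- hits / n
  list(estimate = vb * p, se = vb * sqrt(p * (1 - p) / n))
}

#' Volume, boundary area and contributing atoms of a cavity
#'
#' For a void: the cavity region is the set of points with clearance > delta
#' belonging to the void's complement component. It is measured by exact
#' radial ray casting over the Voronoi cells of the contributing atoms:
#' along a ray from atom center c_i, clearance grows monotonically inside
#' cell i, so the accessible interval is (r_i + delta, t_exit); the exit
#' face portion's component label (from the trimmed complement) decides
#' whether the interval belongs to this void. Boundary area is the matching
#' portion of the offset (Lee-Richards) surface; the vdW-facing ("buried")
#' area is the same solid angle on the van der Waals spheres.
#'
#' For a channel: the volume of the radius-varying ball swept along the
#' spine (the standard channel visualization), estimated by seeded
#' Monte-Carlo over the spine's bounding box; areas count the offset/vdW
#' surface patches facing the swept region.
#'
#' @param cavity a `vc_cavity` (void from [classify_voids()], channel from
#'   [detect_channels()]).
#' @param vc the `vc_complement` the cavity came from.
#' @param n_dirs quadrature directions per contributing atom.
#' @return A list: `volume`, `boundary_area` (offset surface),
#'   `buried_area` (vdW surface), `atoms` (serials), `method`, `error`.
#' @export
cavity_metrics <- function(cavity, vc, n_dirs = 40000L) {
  stopifnot(inherits(cavity, "vc_cavity"), inherits(vc, "vc_complement"))
  mol <- vc$vd$molecule
  if (cavity$kind == "void") {
    f1 <- void_raycast(cavity, vc, n_dirs)
    f2 <- void_raycast(cavity, vc, n_dirs %/% 4L)
    err <- max(abs(f1$volume - f2$volume), 1e-9)
    return(list(volume = f1$volume, boundary_area = f1$boundary_area,
                buried_area = f1$buried_area,
                atoms = mol$serial[cavity$atoms], method = "adaptive",
                error = err))
  }
  channel_metrics(cavity, vc)
}

void_raycast <- function(cavity, vc, n_dirs) {
  vd <- vc$vd; mol <- vd$molecule
  delta <- vc$delta
  dirs <- fibonacci_directions(n_dirs)
  dOmega <- 4 * pi / n_dirs
  vol <- 0; ba <- 0; bu <- 0
  comp <- cavity$component$id
  for (i in cavity$atoms) {
    lim <- mol$radii[i] + delta
    texit <- ray_cell_exit(mol, i, dirs)
    open_dir <- which(is.finite(texit) & texit > lim)
    if (length(open_dir) == 0L) next
    pts <- mol$centers[rep(i, length(open_dir)), , drop = FALSE] +
      dirs[open_dir, , drop = FALSE] * texit[open_dir]
    lab <- exit_component(vc, i, pts)
    member <- which(lab == comp)
    if (length(member) == 0L) next
    vol <- vol + sum(texit[open_dir][member]^3 - lim^3) / 3 * dOmega
    ba <- ba + lim^2 * length(member) * dOmega
    bu <- bu + mol$radii[i]^2 * length(member) * dOmega
  }
  list(volume = vol, boundary_area = ba, buried_area = bu)
}

# component label of cell-exit points: find the face the exit crossed and
# look the point up in that face portion's grid labels
exit_component <- function(vc, i, pts) {
  vd <- vc$vd
  out <- rep(NA_integer_, nrow(pts))
  fids <- which(vd$faces$a1 == i | vd$faces$a2 == i)
  if (length(fids) == 0L) return(out)
  fports_by_face <- split(seq_along(vc$face_portions),
                          vapply(vc$face_portions, `[[`, numeric(1), "face"))
  W <- weighted_dists(pts, vd$molecule)
  for (fi in fids) {
    j <- if (vd$faces$a1[fi] == i) vd$faces$a2[fi] else vd$faces$a1[fi]
    # exit points on this bisector: i and j (weakly) tie for nearest
    on <- which(abs(W[, j] - W[, i]) <= 1e-6 * (1 + abs(W[, i])))
    on <- on[is.na(out[on])]
    if (length(on) == 0L) next
    for (pi in fports_by_face[[as.character(vd$faces$id[fi])]] %||%
           integer(0)) {
      fp <- vc$face_portions[[pi]]
      hit <- face_portion_contains(fp, pts[on, , drop = FALSE], slack = 1L)
      out[on[hit]] <- fp$component
      on <- on[!hit]
      if (length(on) == 0L) break
    }
  }
  out
}

channel_metrics <- function(cavity, vc, n_mc = 2e5, seed = 20260922L) {
  mol <- vc$vd$molecule
  sp <- cavity$spine
  if (is.null(sp) || length(sp) == 0L)
    return(list(volume = NA_real_, boundary_area = NA_real_,
                buried_area = NA_real_, atoms = mol$serial[cavity$atoms],
                method = "adaptive", error = NA_real_))
  pts <- do.call(rbind, lapply(sp, `[[`, "points"))
  sw <- unlist(lapply(sp, `[[`, "sweep_radius"))
  box <- rbind(apply(pts - sw, 2, min), apply(pts + sw, 2, max))
  pred <- function(x) {
    inside <- rep(FALSE, nrow(x))
    for (k in seq_len(nrow(pts)))
      inside <- inside | rowSums(sweep(x, 2, pts[k, ])^2) <= sw[k]^2
    inside
  }
  mc <- mc_region_volume(pred, box, n = n_mc, seed = seed)
  # offset / vdW surface patches facing the swept region
  dirs <- fibonacci_directions(2000L)
  ba <- 0; bu <- 0
  dOmega <- 4 * pi / 2000L
  for (i in cavity$atoms) {
    lim <- mol$radii[i] + vc$delta
    texit <- ray_cell_exit(mol, i, dirs)
    surf <- mol$centers[rep(i, nrow(dirs)), ] + dirs * lim
    face_ok <- texit > lim & pred(surf)
    ba <- ba + lim^2 * sum(face_ok) * dOmega
    bu <- bu + mol$radii[i]^2 * sum(face_ok) * dOmega
  }
  list(volume = mc$estimate, boundary_area = ba, buried_area = bu,
       atoms = mol$serial[cavity$atoms], method = "adaptive",
       error = 3 * mc$se)
}
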