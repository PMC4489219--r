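#' Additively weighted Voronoi diagram of a molecule
#'
#' Computes the Voronoi diagram of spherical atoms under the additively
#' weighted distance d(x, c_i) - r_i: vertices (empty tangent spheres of
#' atom quadruples), edges (portions of three-atom equidistant curves on
#' which the triple is nearest), faces (two-atom bisector portions) and
#' cells, with full mutual incidence. The diagram is offset invariant:
#' growing every radius by the same amount leaves it unchanged.
#'
#' Vertices are found by solving the Apollonius problem for atom quadruples
#' and keeping empty tangent spheres; coincident tangent spheres of
#' cospherical configurations (e.g. symmetric cages) are merged into a single
#' degenerate vertex carrying all defining atoms. Every atom triple's
#' equidistant curve is then examined: it splits at the vertices lying on it,
#' and each arc on which the triple is nearest (checked by an empty-sphere
#' test, which can only change at a vertex) becomes a Voronoi edge. Closed
#' loop edges without vertices are caught by the same per-triple scan.
#' Unbounded edges are kept symbolically and clipped at a bounding sphere
#' (molecule bounding sphere + max radius + 10 A margin) only for sampling.
#'
#' Because each edge is parametrized in a plane whose first coordinate is the
#' clearance itself, minimum clearance along an edge and probe clip points
#' are closed form.
#'
#' @param mol a preprocessed [molecule()].
#' @param tol relative tolerance for the algebraic solves.
#' @param max_atoms guard for the quadruple enumeration (the package targets
#'   desk-scale structures; the enumeration is quartic in atom count).
#' @return An object of class `vc_vd`; see Details for the fields.
#' @examples
#' vd <- compute_awvd(make_fixture("tetra_cage"))
#' nrow(vd$vertices)   # 1 vertex, tangent radius sqrt(6)/2 - 1
#' @export
compute_awvd <- function(mol, tol = 1e-9, max_atoms = 120L) {
  stopifnot(inherits(mol, "vc_molecule"))
  n <- n_atoms(mol)
  if (n > max_atoms)
    stop(sprintf(paste0("compute_awvd: %d atoms exceeds max_atoms = %d; ",
                        "the full diagram enumeration targets desk-scale ",
                        "structures"), n, max_atoms))
  ctr <- mol$centers; rad <- mol$radii
  cc <- colMeans(ctr)
  spread <- max(sqrt(colSums((t(ctr) - cc)^2)))
  Rclip <- spread + max(rad) + 10
  # component-inclusion radius: depends on radii only through max-min, so the
  # retained combinatorics are offset invariant
  Rg <- spread + (max(rad) - min(rad)) + 10
  rho_high <- Rg + spread + max(rad)   # clearance bound inside the Rg sphere
  vx <- awvd_vertices(mol, tol = tol)
  if (nrow(vx$df) > 0 && max(vx$df$residual) > 1e-6)
    stop("compute_awvd: tangency residual above 1e-6 after refinement; ",
         "input too degenerate (max residual ",
         format(max(vx$df$residual)), ")")
  # triple -> vertex lookup (degenerate vertices register all their triples)
  vlookup <- new.env(hash = TRUE, parent = emptyenv())
  for (vi in seq_len(nrow(vx$df))) {
    at <- vx$atoms[[vi]]
    tr <- utils::combn(sort(at), 3L)
    for (k in seq_len(ncol(tr))) {
      key <- paste(tr[, k], collapse = "_")
      assign(key, c(vlookup[[key]] %||% integer(0), vi), envir = vlookup)
    }
  }
  edges <- list(); conics <- list()
  if (n >= 3L) {
    triples <- utils::combn(n, 3L)
    for (k in seq_len(ncol(triples))) {
      ijk <- triples[, k]
      key <- paste(ijk, collapse = "_")
      cn <- triple_conic(ctr, rad, ijk)
      if (is.null(cn)) next
      vids <- vlookup[[key]] %||% integer(0)
      es <- triple_edges(cn, vids, vx, mol, cc, Rg, rho_high, tol)
      if (length(es) > 0L) {
        conics[[key]] <- cn
        edges <- c(edges, es)
      }
    }
  }
  edges_df <- if (length(edges) > 0L) {
    df <- do.call(rbind, lapply(edges, as.data.frame))
    df$id <- seq_len(nrow(df)); df
  } else empty_edges_df()
  faces <- awvd_faces(mol, edges_df, tol)
  vd <- structure(list(
    molecule = mol, tol = tol,
    clip = list(center = cc, R = Rclip),
    vertices = vx$df, vertex_atoms = vx$atoms,
    edges = edges_df, conics = conics,
    faces = faces$df, face_edges = faces$edge_ids,
    cells = seq_len(n)
  ), class = "vc_vd")
  vd
}

#' @export
print.vc_vd <- function(x, ...) {
  cat(sprintf(paste0("<vc_vd> %s: %d vertices, %d edges, %d faces, ",
                     "%d cells (clip R = %.1f A)\n"),
              x$molecule$name, nrow(x$vertices), nrow(x$edges),
              nrow(x$faces), length(x$cells), x$clip$R))
  invisible(x)
}

empty_edges_df <- function() data.frame(
  id = integer(0), key = character(0), a1 = integer(0), a2 = integer(0),
  a3 = integer(0), comp = integer(0), t1 = numeric(0), t2 = numeric(0),
  cyclic = logical(0), v1 = integer(0), v2 = integer(0), unb1 = logical(0),
  unb2 = logical(0), rho_min = numeric(0), rho_max = numeric(0),
  t_min = numeric(0))

# --- vertices ---------------------------------------------------------------

# All empty tangent spheres; coincident spheres merged into degenerate
# vertices. Returns list(df = data.frame(id,x,y,z,rho,degenerate,residual),
# atoms = list of defining atom index vectors).
awvd_vertices <- function(mol, tol = 1e-9, merge_tol = 1e-6) {
  n <- n_atoms(mol)
  empty <- list(df = data.frame(id = integer(0), x = numeric(0),
                                y = numeric(0), z = numeric(0),
                                rho = numeric(0), degenerate = logical(0),
                                residual = numeric(0)),
                atoms = list())
  if (n < 4L) return(empty)
  quads <- t(utils::combn(n, 4L))
  # offset-invariant inclusion sphere (see compute_awvd): vertices of
  # near-degenerate quadruples blow up to arbitrarily distant positions where
  # relative tolerances lose meaning; they cannot matter within the model
  cc <- colMeans(mol$centers)
  spread <- max(sqrt(colSums((t(mol$centers) - cc)^2)))
  Rg <- spread + (max(mol$radii) - min(mol$radii)) + 10
  sol <- apollonius_batch(mol$centers, mol$radii, quads, tol = tol,
                          cc = cc, Rg = Rg)$solutions
  if (nrow(sol) == 0L) return(empty)
  pts <- cbind(sol$x, sol$y, sol$z)
  wmin <- apply(weighted_dists(pts, mol), 1L, min)
  keep <- wmin >= sol$rho - 1e-7 * (1 + abs(sol$rho))
  sol <- sol[keep, , drop = FALSE]; pts <- pts[keep, , drop = FALSE]
  if (nrow(sol) == 0L) return(empty)
  grp <- if (nrow(sol) == 1L) 1L else
    stats::cutree(stats::hclust(stats::dist(pts), method = "single"),
                  h = merge_tol)
  ids <- sort(unique(grp))
  atoms <- vector("list", length(ids))
  df <- data.frame(id = seq_along(ids), x = 0, y = 0, z = 0, rho = 0,
                   degenerate = FALSE, residual = 0)
  for (g in seq_along(ids)) {
    m <- which(grp == ids[g])
    df$x[g] <- mean(sol$x[m]); df$y[g] <- mean(sol$y[m])
    df$z[g] <- mean(sol$z[m]); df$rho[g] <- mean(sol$rho[m])
    df$residual[g] <- max(sol$residual[m])
    atoms[[g]] <- sort(unique(as.vector(quads[sol$quad[m], ])))
    df$degenerate[g] <- length(atoms[[g]]) > 4L
  }
  list(df = df, atoms = atoms)
}

# --- edges ------------------------------------------------------------------

# Arcs of one triple curve on which the triple is nearest.
triple_edges <- function(cn, vids, vx, mol, cc, Rg, rho_high, tol) {
  out <- list()
  key <- paste(cn$atoms, collapse = "_")
  # locate this triple's vertices on the curve
  locs <- lapply(vids, function(vi)
    c(list(vid = vi),
      conic_locate(cn, c(vx$df$x[vi], vx$df$y[vi], vx$df$z[vi]),
                   vx$df$rho[vi])))
  locs <- Filter(function(l) !is.null(l$comp) && l$err < 1e-5 * (1 + Rg),
                 locs)
  rho_low <- -min(cn$r) + 1e-9
  # offset-invariant inclusion: keep a component iff its minimum-clearance
  # point lies within the Rg sphere (the curve geometry does not change under
  # a uniform radius offset, so this test is identical for A and A^O) or a
  # retained vertex lies on it
  comp_included <- function(ci) {
    if (any(vapply(locs, function(l) l$comp == ci, logical(1))))
      return(TRUE)
    cp <- cn$comps[[ci]]
    t0 <- switch(cp$type, loop = 1, fold = 0, branch = NULL)
    if (is.null(t0)) return(TRUE)        # branch: low end sits at the atoms
    sqrt(sum((drop(conic_point(cn, ci, t0)) - cc)^2)) <= Rg
  }
  for (ci in seq_along(cn$comps)) {
    cp <- cn$comps[[ci]]
    if (!comp_included(ci)) next
    lv <- Filter(function(l) l$comp == ci, locs)
    tv <- vapply(lv, `[[`, numeric(1), "t")
    vv <- vapply(lv, `[[`, integer(1), "vid")
    o <- order(tv); tv <- tv[o]; vv <- vv[o]
    segs <- list()
    if (cp$type == "loop") {
      if (length(tv) == 0L) {
        ts <- seq(0, 2, length.out = 9L)[-9L]
        if (arc_is_voronoi(cn, ci, ts, mol, tol))
          segs[[1]] <- list(t1 = 0, t2 = 2, cyclic = TRUE,
                            v1 = NA_integer_, v2 = NA_integer_,
                            unb1 = FALSE, unb2 = FALSE)
      } else {
        for (i in seq_along(tv)) {
          t1 <- tv[i]
          t2 <- if (i < length(tv)) tv[i + 1L] else tv[1L] + 2
          if (t2 - t1 < 1e-12) next
          segs[[length(segs) + 1L]] <- list(
            t1 = t1, t2 = t2, cyclic = FALSE,
            v1 = vv[i], v2 = vv[if (i < length(tv)) i + 1L else 1L],
            unb1 = FALSE, unb2 = FALSE)
        }
        if (length(tv) == 1L && length(segs) == 1L)
          segs[[1]]$cyclic <- TRUE       # single vertex: arc closes on itself
      }
    } else {
      # finite parameter window covering rho <= rho_high and rho >= rho_low,
      # widened to cover any vertex sitting on this component
      rh <- rho_high
      if (length(tv) > 0)
        rh <- max(rh, max(vx$df$rho[vv]) + 1)
      bounds <- comp_bounds(cn, ci, rho_low, rh)
      if (is.null(bounds)) next
      tlo <- bounds$tlo; thi <- bounds$thi
      unb_lo <- bounds$unb_lo; unb_hi <- bounds$unb_hi
      cuts <- c(tlo, tv[tv > tlo + 1e-12 & tv < thi - 1e-12], thi)
      vcut <- c(NA_integer_, vv[tv > tlo + 1e-12 & tv < thi - 1e-12],
                NA_integer_)
      for (i in seq_len(length(cuts) - 1L)) {
        segs[[length(segs) + 1L]] <- list(
          t1 = cuts[i], t2 = cuts[i + 1L], cyclic = FALSE,
          v1 = vcut[i], v2 = vcut[i + 1L],
          unb1 = (i == 1L) && unb_lo,
          unb2 = (i == length(cuts) - 1L) && unb_hi)
      }
    }
    for (sg in segs) {
      ts <- seg_test_params(sg)
      if (!arc_is_voronoi(cn, ci, ts, mol, tol)) next
      rr <- arc_rho_extrema(cn, ci, sg)
      out[[length(out) + 1L]] <- list(
        key = key, a1 = cn$atoms[1], a2 = cn$atoms[2], a3 = cn$atoms[3],
        comp = ci, t1 = sg$t1, t2 = sg$t2, cyclic = sg$cyclic,
        v1 = sg$v1, v2 = sg$v2, unb1 = sg$unb1, unb2 = sg$unb2,
        rho_min = rr$min, rho_max = rr$max, t_min = rr$t_min)
    }
  }
  out
}

# parameter window of a fold/branch component between clearance cutoffs
comp_bounds <- function(cn, ci, rho_low, rho_high) {
  cp <- cn$comps[[ci]]
  if (cp$type == "fold") {
    if (cp$dir > 0) {
      if (cp$rho0 > rho_high) return(NULL)
      Tm <- sqrt(rho_high - cp$rho0)
      list(tlo = -Tm, thi = Tm, unb_lo = TRUE, unb_hi = TRUE)
    } else {
      if (cp$rho0 < rho_low) return(NULL)
      Tm <- sqrt(cp$rho0 - rho_low)
      list(tlo = -Tm, thi = Tm, unb_lo = FALSE, unb_hi = FALSE)
    }
  } else {                               # branch: t = rho
    if (rho_low > rho_high) return(NULL)
    list(tlo = rho_low, thi = rho_high, unb_lo = FALSE, unb_hi = TRUE)
  }
}

seg_test_params <- function(sg) {
  t1 <- sg$t1; t2 <- sg$t2
  t1 + c(0.25, 0.5, 0.75) * (t2 - t1)
}

# is the arc (sampled at ts) a real Voronoi edge: points valid and empty
arc_is_voronoi <- function(cn, ci, ts, mol, tol) {
  rho <- conic_rho(cn, ci, ts)
  pts <- conic_point(cn, ci, ts)
  if (!all(conic_valid(cn, pts, rho, tol = 1e-6))) return(FALSE)
  wmin <- apply(weighted_dists(pts, mol), 1L, min)
  all(wmin >= rho - 1e-7 * (1 + abs(rho)))
}

# exact clearance extrema over an arc
arc_rho_extrema <- function(cn, ci, sg) {
  cp <- cn$comps[[ci]]
  if (cp$type == "loop") {
    if (sg$cyclic && is.na(sg$v1))
      return(list(min = cp$rho1, max = cp$rho2, t_min = 1))
    t1 <- sg$t1; t2 <- sg$t2
    cand_t <- c(t1, t2)
    for (textr in c(0, 1, 2, 3)) {       # rho extrema at t = 0,1 (mod 2)
      if (textr > t1 && textr < t2) cand_t <- c(cand_t, textr)
    }
    rho <- conic_rho(cn, ci, cand_t)
    list(min = min(rho), max = max(rho), t_min = cand_t[which.min(rho)])
  } else if (cp$type == "fold") {
    cand_t <- c(sg$t1, sg$t2)
    if (sg$t1 < 0 && sg$t2 > 0) cand_t <- c(cand_t, 0)
    rho <- conic_rho(cn, ci, cand_t)
    mx <- if (sg$unb1 || sg$unb2) Inf else max(rho)
    list(min = min(rho), max = mx, t_min = cand_t[which.min(rho)])
  } else {
    rho <- c(sg$t1, sg$t2)
    mx <- if (sg$unb2) Inf else max(rho)
    list(min = min(rho), max = mx, t_min = sg$t1)
  }
}

# --- faces ------------------------------------------------------------------

awvd_faces <- function(mol, edges_df, tol) {
  n <- n_atoms(mol)
  ctr <- mol$centers; rad <- mol$radii
  pair_edges <- new.env(hash = TRUE, parent = emptyenv())
  for (ei in seq_len(nrow(edges_df))) {
    at <- sort(c(edges_df$a1[ei], edges_df$a2[ei], edges_df$a3[ei]))
    for (pr in list(at[c(1, 2)], at[c(1, 3)], at[c(2, 3)])) {
      key <- paste(pr, collapse = "_")
      assign(key, c(pair_edges[[key]] %||% integer(0), edges_df$id[ei]),
             envir = pair_edges)
    }
  }
  rows <- list(); eids <- list()
  if (n >= 2L) {
    prs <- utils::combn(n, 2L)
    for (k in seq_len(ncol(prs))) {
      i <- prs[1, k]; j <- prs[2, k]
      d <- sqrt(sum((ctr[j, ] - ctr[i, ])^2))
      ti <- (d + rad[i] - rad[j]) / 2
      ax <- ctr[i, ] + (ti / d) * (ctr[j, ] - ctr[i, ])
      arho <- (d - rad[i] - rad[j]) / 2
      wd <- drop(weighted_dists(matrix(ax, ncol = 3), mol))
      axis_empty <- min(wd) >= arho - 1e-7 * (1 + abs(arho))
      # a non-pair atom tying at the closest bisector point marks a
      # degenerate (measure-zero) face of a symmetric configuration
      axis_tie <- axis_empty && n > 2L &&
        min(wd[-c(i, j)]) <= arho + 1e-7 * (1 + abs(arho))
      key <- paste(c(i, j), collapse = "_")
      be <- pair_edges[[key]] %||% integer(0)
      if (!axis_empty && length(be) == 0L) next
      rho_min <- if (axis_empty) arho else
        min(edges_df$rho_min[match(be, edges_df$id)])
      rows[[length(rows) + 1L]] <- data.frame(
        a1 = i, a2 = j, axis_empty = axis_empty, axis_tie = axis_tie,
        axis_rho = arho,
        ax_x = ax[1], ax_y = ax[2], ax_z = ax[3], rho_min = rho_min)
      eids[[length(rows)]] <- be
    }
  }
  df <- if (length(rows) > 0L) {
    d <- do.call(rbind, rows); d$id <- seq_len(nrow(d)); d
  } else data.frame(a1 = integer(0), a2 = integer(0), axis_empty = logical(0),
                    axis_tie = logical(0), axis_rho = numeric(0),
                    ax_x = numeric(0), ax_y = numeric(0), ax_z = numeric(0),
                    rho_min = numeric(0), id = integer(0))
  list(df = df, edge_ids = eids)
}

# --- geometry helpers used downstream --------------------------------------

# sample m points along edge ei (rows of a matrix), with clearances
edge_samples <- function(vd, ei, m = 33L) {
  e <- vd$edges[ei, ]
  cn <- vd$conics[[e$key]]
  ts <- seq(e$t1, e$t2, length.out = m)
  list(t = ts, pts = conic_point(cn, e$comp, ts),
       rho = conic_rho(cn, e$comp, ts))
}

# parameters t in [t1,t2] where rho(t) = delta (exact, per component type)
edge_clip_params <- function(vd, ei, delta) {
  e <- vd$edges[ei, ]
  cn <- vd$conics[[e$key]]
  cp <- cn$comps[[e$comp]]
  ts <- switch(cp$type,
    loop = {
      if (abs(cp$rhoamp) < 1e-300 || delta < cp$rho1 || delta > cp$rho2)
        numeric(0)
      else {
        th <- acos(min(1, max(-1, (delta - cp$rhoc) / cp$rhoamp))) / pi
        cand <- c(th, 2 - th, th + 2, 2 - th + 2, th - 2)
        cand
      }
    },
    fold = {
      if (cp$dir * (delta - cp$rho0) < 0) numeric(0)
      else { tt <- sqrt(cp$dir * (delta - cp$rho0)); c(-tt, tt) }
    },
    branch = delta)
  sort(ts[ts >= e$t1 - 1e-12 & ts <= e$t2 + 1e-12])
}

#' Find one Voronoi vertex of a molecule
#'
#' Returns a vertex whose tangent sphere is empty with respect to all atoms
#' (the seed from which a diagram traversal could start), or `NULL` when the
#' molecule admits no Voronoi vertex (fewer than 4 atoms, or all quadruples
#' degenerate).
#'
#' @param mol a [molecule()].
#' @return A one-row data.frame (position, tangent radius, defining atoms as
#'   attribute) or `NULL` for a vertex-free diagram.
#' @export
find_initial_vertex <- function(mol) {
  vx <- awvd_vertices(mol)
  if (nrow(vx$df) == 0L) {
    message("find_initial_vertex: vertex-free diagram")
    return(NULL)
  }
  i <- order(vx$df$rho, vx$df$id)[1]
  out <- vx$df[i, , drop = FALSE]
  attr(out, "atoms") <- vx$atoms[[i]]
  out
}
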