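#' Voronoi complement: the diagram outside the offset model
#'
#' Trims the (V, E, F) part of the Voronoi diagram against the offset model
#' A^O (all radii grown by the probe radius delta, whose boundary is the
#' Lee-Richards solvent accessible surface): only entity portions with
#' clearance > delta are retained. The retained portions, glued along their
#' shared boundaries (edge ends at vertices, edges on face boundaries, all
#' unbounded portions joined at infinity), are homotopy equivalent to the
#' probe-accessible exterior space, so their connected components classify
#' the space: the unique component touching infinity is the exterior, every
#' other component is a void.
#'
#' Edge portions are exact: clearance is a closed-form coordinate of the edge
#' parametrization, so clip points with clearance exactly delta are solved,
#' not searched. Face portions are resolved on a per-face 2-D grid in
#' (off-axis distance h, azimuth phi) coordinates of the bisector sheet,
#' where clearance depends on h alone and increases with it; the grid masks
#' points where the face's atom pair is nearest, labels connected regions,
#' and doubles as the lookup structure that the volume integrator uses to
#' attribute space to components.
#'
#' @param vd a `vc_vd` from [compute_awvd()].
#' @param delta probe radius (offset amount), `delta >= 0`.
#' @param nh,nphi per-face grid resolution (radial x azimuthal).
#' @return An object of class `vc_complement`: retained vertices, edge
#'   portions (with end types among vertex / clip / infinity / cusp), face
#'   portions with their grids, the connectivity graph, and a `components`
#'   data.frame with an `unbounded` flag.
#' @export
trim_complement <- function(vd, delta, nh = 48L, nphi = 60L) {
  stopifnot(inherits(vd, "vc_vd"))
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0)
    stop("delta must be a single non-negative probe radius")
  mol <- vd$molecule
  crit <- c(vd$vertices$rho, vd$edges$rho_min, vd$faces$rho_min)
  if (any(abs(crit - delta) < 1e-6))
    warning("trim_complement: delta within 1e-6 of a critical clearance; ",
            "classification is unstable at this probe radius")
  vkeep <- vd$vertices$id[vd$vertices$rho > delta]
  eports <- complement_edge_portions(vd, delta)
  fports <- complement_face_portions(vd, delta, nh, nphi)
  gr <- complement_graph(vd, vkeep, eports, fports)
  comp_of <- igraph::components(gr$g)$membership
  labs <- sort(unique(comp_of))
  inf_comp <- if ("INF" %in% names(comp_of)) comp_of[["INF"]] else NA_integer_
  comps <- data.frame(id = seq_along(labs), label = labs,
                      unbounded = labs == inf_comp)
  # map graph component labels onto entities
  vcomp <- if (length(vkeep) > 0) comp_of[paste0("V", vkeep)] else integer(0)
  ecomp <- if (nrow(eports) > 0) comp_of[paste0("E", seq_len(nrow(eports)))]
           else integer(0)
  fcomp <- vapply(fports, function(fp) {
    nm <- paste0("F", fp$uid)
    if (nm %in% names(comp_of)) comp_of[[nm]] else NA_integer_
  }, numeric(1))
  remap <- function(x) comps$id[match(x, comps$label)]
  eports$component <- if (nrow(eports) > 0) remap(ecomp) else integer(0)
  for (k in seq_along(fports)) fports[[k]]$component <- remap(fcomp[k])
  structure(list(
    vd = vd, delta = delta,
    vertices = data.frame(id = vkeep,
                          component = if (length(vkeep)) remap(vcomp)
                                      else integer(0)),
    edge_portions = eports,
    face_portions = fports,
    graph = gr$g,
    components = comps
  ), class = "vc_complement")
}

#' @export
print.vc_complement <- function(x, ...) {
  nb <- sum(!x$components$unbounded)
  cat(sprintf(paste0("<vc_complement> delta = %.3f A: %d vertices, ",
                     "%d edge portions, %d face portions; %d component(s), ",
                     "%d bounded\n"),
              x$delta, nrow(x$vertices), nrow(x$edge_portions),
              length(x$face_portions), nrow(x$components), nb))
  invisible(x)
}

# --- edge portions ----------------------------------------------------------

# sub-arcs of every Voronoi edge with clearance > delta
complement_edge_portions <- function(vd, delta) {
  rows <- list()
  for (ei in seq_len(nrow(vd$edges))) {
    e <- vd$edges[ei, ]
    if (e$rho_min > delta && e$cyclic) {
      rows[[length(rows) + 1L]] <- data.frame(
        edge = e$id, t1 = e$t1, t2 = e$t2, cyclic = TRUE,
        end1 = "closed", ref1 = NA_integer_, end2 = "closed",
        ref2 = NA_integer_, rho_min = e$rho_min, crossing = FALSE)
      next
    }
    cuts <- edge_clip_params(vd, e$id, delta)
    bounds <- c(e$t1, cuts, e$t2)
    cn <- vd$conics[[e$key]]
    for (k in seq_len(length(bounds) - 1L)) {
      ta <- bounds[k]; tb <- bounds[k + 1L]
      if (tb - ta < 1e-12) next
      if (conic_rho(cn, e$comp, (ta + tb) / 2) <= delta) next
      end_of <- function(at_t, side) {
        if (abs(at_t - e$t1) < 1e-12) {
          if (!is.na(e$v1)) list(type = "vertex", ref = e$v1)
          else if (e$unb1) list(type = "inf", ref = NA_integer_)
          else list(type = "cusp", ref = NA_integer_)
        } else if (abs(at_t - e$t2) < 1e-12) {
          if (!is.na(e$v2)) list(type = "vertex", ref = e$v2)
          else if (e$unb2) list(type = "inf", ref = NA_integer_)
          else list(type = "cusp", ref = NA_integer_)
        } else list(type = "clip", ref = NA_integer_)
      }
      e1 <- end_of(ta, 1L); e2 <- end_of(tb, 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        edge = e$id, t1 = ta, t2 = tb, cyclic = FALSE,
        end1 = e1$type, ref1 = e1$ref, end2 = e2$type, ref2 = e2$ref,
        rho_min = min(conic_rho(cn, e$comp, c(ta, tb)),
                      if (e$t_min > ta && e$t_min < tb)
                        conic_rho(cn, e$comp, e$t_min) else Inf),
        crossing = e1$type == "clip" || e2$type == "clip")
    }
  }
  if (length(rows) == 0L)
    return(data.frame(edge = integer(0), t1 = numeric(0), t2 = numeric(0),
                      cyclic = logical(0), end1 = character(0),
                      ref1 = integer(0), end2 = character(0),
                      ref2 = integer(0), rho_min = numeric(0),
                      crossing = logical(0), component = integer(0)))
  out <- do.call(rbind, rows)
  out$uid <- seq_len(nrow(out))
  out
}

# --- face geometry ----------------------------------------------------------

face_frame <- function(vd, fi) {
  f <- vd$faces[fi, ]
  mol <- vd$molecule
  ci <- mol$centers[f$a1, ]; cj <- mol$centers[f$a2, ]
  d <- sqrt(sum((cj - ci)^2))
  u <- (cj - ci) / d
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(a1 = f$a1, a2 = f$a2, ci = ci, cj = cj, d = d, u = u, e1 = e1,
       e2 = e2, ri = mol$radii[f$a1], rj = mol$radii[f$a2])
}

# The bisector point at off-axis distance h sits on the intersection circle
# of spheres of radius R1 = ri + rho and R2 = rj + rho around the two
# centers, which gives closed forms both ways (e = rj - ri, c0 = d^2 - e^2):
#   R1(h) = (-e + sqrt(e^2 + c0 + 4 d^2 h^2 / c0)) / 2
#   tau(h) = (c0 - 2 e R1) / (2 d),  rho(h) = R1 - ri
face_R1 <- function(fr, h) {
  e <- fr$rj - fr$ri
  c0 <- fr$d^2 - e^2
  (-e + sqrt(e^2 + c0 + 4 * fr$d^2 * h^2 / c0)) / 2
}

face_tau <- function(fr, h) {
  e <- fr$rj - fr$ri
  (fr$d^2 - e^2 - 2 * e * face_R1(fr, h)) / (2 * fr$d)
}

face_rho_of_h <- function(fr, h) face_R1(fr, h) - fr$ri

face_h_of_rho <- function(fr, rho) {
  R1 <- fr$ri + rho; R2 <- fr$rj + rho
  tau <- (fr$d^2 + R1^2 - R2^2) / (2 * fr$d)
  sqrt(pmax(R1^2 - tau^2, 0))
}

face_point <- function(fr, h, phi, tau = NULL) {
  if (is.null(tau)) tau <- face_tau(fr, h)
  t(fr$ci + outer(fr$u, tau)) +
    outer(h * cos(phi), fr$e1) + outer(h * sin(phi), fr$e2)
}

# (h, phi) coordinates of points known to lie on the face
face_coords <- function(fr, pts) {
  rel <- sweep(pts, 2, fr$ci)
  ax <- drop(rel %*% fr$u)
  p1 <- drop(rel %*% fr$e1); p2 <- drop(rel %*% fr$e2)
  list(h = sqrt(p1^2 + p2^2), phi = atan2(p2, p1) %% (2 * pi), tau = ax)
}

# --- face portions ----------------------------------------------------------

complement_face_portions <- function(vd, delta, nh, nphi) {
  mol <- vd$molecule
  # the clearance maximum of any bounded complement component is attained at
  # a Voronoi vertex, so face regions reaching beyond every vertex clearance
  # belong to the exterior: the radial grid may stop just past that level,
  # marking anything that touches the last ring as unbounded
  vmax <- if (nrow(vd$vertices) > 0) max(vd$vertices$rho) else 0
  rho_cap <- max(delta, vmax) + max(mol$radii) + 1
  out <- list(); uid <- 0L
  for (fi in seq_len(nrow(vd$faces))) {
    # degenerate point-faces (symmetric ties) without bounding edges carry no
    # 2-D portion and would only produce tolerance-width slivers
    if (isTRUE(vd$faces$axis_tie[fi]) &&
        length(vd$face_edges[[fi]] %||% integer(0)) == 0L) next
    fr <- face_frame(vd, fi)
    h_lo <- if (vd$faces$axis_rho[fi] > delta) 0 else face_h_of_rho(fr, delta)
    h_hi <- face_h_of_rho(fr, rho_cap)
    if (h_hi <= h_lo + 1e-12) next
    # radial grid concentrated near the clip circle where topology decides
    uu <- seq(0, 1, length.out = nh)
    hs <- h_lo + (h_hi - h_lo) * uu^2
    hs[1] <- h_lo + 1e-9 * (1 + h_lo)
    phis <- seq(0, 2 * pi, length.out = nphi + 1L)[-(nphi + 1L)]
    taus <- face_tau(fr, hs)
    rhos <- sqrt(taus^2 + hs^2) - fr$ri
    # in-face mask: the pair must be (weakly) nearest
    hh <- rep(hs, nphi); pp <- rep(phis, each = nh)
    pts <- face_point(fr, hh, pp, tau = rep(taus, nphi))
    W <- weighted_dists(pts, mol)
    wmin <- do.call(pmin, as.data.frame(W))
    mask <- matrix(wmin >= rep(rhos, nphi) - 1e-7 * (1 + abs(rep(rhos, nphi))),
                   nh, nphi)
    if (!any(mask)) next
    lab <- grid_label(mask, wrap_cols = TRUE,
                      join_first_row = h_lo == 0)
    for (pc in sort(unique(lab[lab > 0]))) {
      sel <- lab == pc
      uid <- uid + 1L
      touches_lo <- any(sel[1, ])
      out[[uid]] <- list(
        uid = uid, face = vd$faces$id[fi], fr = fr,
        h = hs, phi = phis, tau = taus, rho = rhos,
        cells = sel,
        crossing = h_lo > 0 && touches_lo,
        unbounded = any(sel[nh, ]),
        component = NA_integer_)
    }
    # stash labels for point lookup: one matrix per face
    attr(out, "noop") <- NULL
  }
  out
}

# connected labeling of a logical grid, 4-connectivity, optional column wrap
# (phi) and optional merging of the whole first row (degenerate axis point)
grid_label <- function(mask, wrap_cols = TRUE, join_first_row = FALSE) {
  nr <- nrow(mask); nc <- ncol(mask)
  id <- matrix(seq_len(nr * nc), nr, nc)
  parent <- seq_len(nr * nc)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  un <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  for (j in seq_len(nc)) {
    cm <- mask[, j]
    up <- which(cm[-1] & cm[-nr])
    for (i in up) un(id[i, j], id[i + 1L, j])
  }
  for (j in seq_len(nc - 1L)) {
    both <- which(mask[, j] & mask[, j + 1L])
    for (i in both) un(id[i, j], id[i, j + 1L])
  }
  if (wrap_cols && nc > 2L) {
    both <- which(mask[, nc] & mask[, 1L])
    for (i in both) un(id[i, nc], id[i, 1L])
  }
  if (join_first_row) {
    on <- which(mask[1L, ])
    if (length(on) > 1L) for (j in on[-1]) un(id[1L, on[1]], id[1L, j])
  }
  lab <- matrix(0L, nr, nc)
  roots <- integer(0)
  for (k in which(mask)) {
    r <- find(k)
    m <- match(r, roots)
    if (is.na(m)) { roots <- c(roots, r); m <- length(roots) }
    lab[k] <- m
  }
  lab
}

# --- connectivity graph -----------------------------------------------------

complement_graph <- function(vd, vkeep, eports, fports) {
  edges <- character(0)
  nodes <- c(if (length(vkeep) > 0) paste0("V", vkeep),
             if (nrow(eports) > 0) paste0("E", eports$uid),
             vapply(fports, function(fp) paste0("F", fp$uid), character(1)),
             "INF")
  add <- function(a, b) edges <<- c(edges, a, b)
  if (nrow(eports) > 0) {
    for (k in seq_len(nrow(eports))) {
      ep <- eports[k, ]
      for (side in 1:2) {
        ty <- ep[[paste0("end", side)]]; rf <- ep[[paste0("ref", side)]]
        if (ty == "vertex" && rf %in% vkeep) add(paste0("E", ep$uid),
                                                paste0("V", rf))
        if (ty == "inf") add(paste0("E", ep$uid), "INF")
      }
    }
  }
  # edge portion <-> face portion adjacency by sampling
  fp_by_face <- split(seq_along(fports),
                      vapply(fports, `[[`, numeric(1), "face"))
  if (nrow(eports) > 0 && length(fports) > 0) {
    for (k in seq_len(nrow(eports))) {
      ep <- eports[k, ]
      e <- vd$edges[vd$edges$id == ep$edge, ]
      cn <- vd$conics[[e$key]]
      ts <- seq(ep$t1, ep$t2, length.out = 9L)[2:8]
      pts <- conic_point(cn, e$comp, ts)
      tri <- sort(c(e$a1, e$a2, e$a3))
      for (pr in list(tri[c(1, 2)], tri[c(1, 3)], tri[c(2, 3)])) {
        fid <- vd$faces$id[vd$faces$a1 == pr[1] & vd$faces$a2 == pr[2]]
        if (length(fid) == 0L) next
        for (pi in fp_by_face[[as.character(fid)]] %||% integer(0)) {
          fp <- fports[[pi]]
          hits <- face_portion_contains(fp, pts, slack = 2L)
          if (any(hits)) add(paste0("E", ep$uid), paste0("F", fp$uid))
        }
      }
    }
  }
  for (fp in fports) if (fp$unbounded) add(paste0("F", fp$uid), "INF")
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(edges) > 0) g <- igraph::add_edges(g, match(edges, nodes))
  list(g = g)
}

# do points (on the portion's face) fall in / next to the portion's cells?
face_portion_contains <- function(fp, pts, slack = 1L) {
  co <- face_coords(fp$fr, pts)
  ih <- findInterval(co$h, fp$h, all.inside = TRUE)
  dphi <- 2 * pi / length(fp$phi)
  ip <- (round(co$phi / dphi) %% length(fp$phi)) + 1L
  nh <- length(fp$h); np <- length(fp$phi)
  vapply(seq_along(ih), function(q) {
    ii <- max(1L, ih[q] - slack):min(nh, ih[q] + slack + 1L)
    jj <- ((ip[q] - 1L + (-slack:slack)) %% np) + 1L
    any(fp$cells[ii, jj])
  }, logical(1))
}

#' Connected components of a Voronoi complement
#'
#' @param vc a `vc_complement` from [trim_complement()].
#' @return A list of components; each is a list with `id`, `unbounded`,
#'   `vertex_ids`, `edge_portions` (row indices), `face_portions` (indices),
#'   and the contributing `atoms`.
#' @export
complement_components <- function(vc) {
  lapply(seq_len(nrow(vc$components)), function(ci) {
    vids <- vc$vertices$id[vc$vertices$component == ci]
    eps <- which(vc$edge_portions$component == ci)
    fps <- which(vapply(vc$face_portions, `[[`, numeric(1),
                        "component") == ci)
    atoms <- integer(0)
    vd <- vc$vd
    for (v in vids) atoms <- c(atoms, vd$vertex_atoms[[match(v, vd$vertices$id)]])
    for (k in eps) {
      e <- vd$edges[vd$edges$id == vc$edge_portions$edge[k], ]
      atoms <- c(atoms, e$a1, e$a2, e$a3)
    }
    for (k in fps) atoms <- c(atoms, vc$face_portions[[k]]$fr$a1,
                              vc$face_portions[[k]]$fr$a2)
    list(id = ci, unbounded = vc$components$unbounded[ci],
         vertex_ids = vids, edge_portions = eps, face_portions = fps,
         atoms = sort(unique(atoms)))
  })
}

#' Classify bounded complement components as voids
#'
#' Every bounded component of the Voronoi complement corresponds to one void
#' of the offset model (the component homotopy-represents the enclosed
#' probe-accessible pocket of space). A genuine void carries its maximum
#' clearance at a Voronoi vertex (or, for symmetric toroidal voids, along a
#' closed edge), so bounded "components" consisting solely of face-grid
#' cells are tolerance slivers and are discarded.
#'
#' @param vc a `vc_complement`.
#' @return A list of `vc_cavity` objects of kind `"void"`.
#' @export
classify_voids <- function(vc) {
  comps <- complement_components(vc)
  out <- list()
  for (cp in comps) {
    if (cp$unbounded) next
    if (length(cp$vertex_ids) == 0L && length(cp$edge_portions) == 0L) next
    out[[length(out) + 1L]] <- structure(
      list(kind = "void", component = cp, delta = vc$delta,
           atoms = cp$atoms, openings = list(), handles = NA_integer_,
           spine = NULL, bottleneck = NULL),
      class = "vc_cavity")
  }
  out
}

#' @export
print.vc_cavity <- function(x, ...) {
  cat(sprintf("<vc_cavity> %s (delta = %.3f A): %d contributing atoms",
              x$kind, x$delta, length(x$atoms)))
  if (x$kind == "channel")
    cat(sprintf(", %d openings, %d handles, bottleneck %.3f A",
                length(x$openings), x$handles,
                if (!is.null(x$bottleneck)) x$bottleneck$radius else NA))
  cat("\n")
  invisible(x)
}
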