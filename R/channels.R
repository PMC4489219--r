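#' Channel recognition in the unbounded complement component
#'
#' A channel is a passage through the molecular body with two or more
#' openings through which the probe can pass. Operationally: take the
#' Voronoi graph of the unbounded complement component with all
#' surface-intersecting entities removed (only whole entities with clearance
#' > delta survive), intersect it with the molecular envelope -- the convex
#' hull of the offset model A^O -- and examine each connected interior
#' subgraph. Points where the subgraph pierces the envelope boundary are its
#' openings (crossings closer than one probe diameter are merged into a
#' single mouth); subgraphs with at least two openings are channels,
#' subgraphs with exactly one are pockets (computed, reported separately,
#' excluded from channel statistics). The beta-shape was considered as the
#' delimiting solid but is degenerate (measure zero) exactly for thin
#' ring-like structures whose through-holes matter most, so the envelope is
#' used; see the methods vignette.
#'
#' For each channel the spine is the union of widest (maximum bottleneck)
#' paths between its opening pairs, swept with the exact clearance radius;
#' the bottleneck is the global minimum clearance along the spine with its
#' attained position (ties broken toward the lexicographically smallest
#' position); handles is the cycle rank of the interior subgraph corrected
#' by its retained disk faces.
#'
#' @param vc a `vc_complement` from [trim_complement()].
#' @param opening_merge merge radius for opening clusters (default
#'   `max(2 * delta, 0.01)` Angstrom).
#' @param n_support number of support directions for the envelope test.
#' @return A list of `vc_cavity` objects of kind `"channel"`, with attribute
#'   `pockets` (the 1-opening subgraphs).
#' @export
detect_channels <- function(vc, opening_merge = NULL, n_support = 4000L) {
  stopifnot(inherits(vc, "vc_complement"))
  delta <- vc$delta
  if (is.null(opening_merge)) opening_merge <- max(2 * delta, 0.01)
  unb <- vc$components$id[vc$components$unbounded]
  if (length(unb) == 0L) return(structure(list(), pockets = list()))
  vg <- build_voronoi_graph(vc, unb[1], include_crossing = FALSE)
  env <- envelope_model(vc$vd$molecule, delta, n_support)
  ig <- interior_graph(vc, vg, env)
  if (igraph::ecount(ig$g) == 0L) return(structure(list(), pockets = list()))
  comp <- igraph::components(ig$g)
  groups <- merge_by_shared_faces(vc, ig, comp)
  groups <- merge_by_shared_mouths(ig, comp, groups, opening_merge)
  channels <- list(); pockets <- list()
  for (grp in groups) {
    nodes <- names(comp$membership)[comp$membership %in% grp]
    xnodes <- nodes[startsWith(nodes, "X")]
    if (length(xnodes) == 0L) next
    xpos <- t(vapply(xnodes, function(nm) ig$node_pos[[nm]], numeric(3)))
    cl <- if (length(xnodes) == 1L) 1L else
      stats::cutree(stats::hclust(stats::dist(xpos), method = "single"),
                    h = opening_merge)
    sg <- igraph::induced_subgraph(ig$g, nodes)
    openings <- lapply(sort(unique(cl)), function(k) {
      sel <- which(cl == k)
      list(position = colMeans(xpos[sel, , drop = FALSE]),
           clearance = mean(vapply(xnodes[sel], function(nm)
             ig$node_rho[[nm]], numeric(1))),
           crossings = xnodes[sel])
    })
    cav <- structure(list(
      kind = if (length(openings) >= 2L) "channel" else "pocket",
      component = unb[1], delta = delta,
      atoms = interior_atoms(vc, ig, nodes),
      openings = openings,
      handles = channel_handles(vg, ig, sg),
      graph = sg, igraph_data = ig,
      spine = NULL, bottleneck = NULL), class = "vc_cavity")
    if (length(openings) >= 2L) {
      sp <- channel_spine(vc, ig, sg, openings)
      cav$spine <- sp$paths
      cav$bottleneck <- sp$bottleneck
      channels[[length(channels) + 1L]] <- cav
    } else pockets[[length(pockets) + 1L]] <- cav
  }
  structure(channels, pockets = pockets)
}

# Interior subgraphs whose sub-arcs touch the same retained (non-crossing)
# face portion are connected through that face's interior in the complement,
# so they form one passage even when the 1-skeleton misses the link (e.g.
# braided near-degenerate edge bundles). Returns a list of component-id
# groups.
merge_by_shared_faces <- function(vc, ig, comp) {
  nc <- comp$no
  parent <- seq_len(nc)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  el <- igraph::as_edgelist(ig$g)
  face_of <- list()
  for (q in seq_len(nrow(el))) {
    ci <- comp$membership[[el[q, 1]]]
    a <- ig$eattr[[q]]
    ename <- paste0("E", vc$edge_portions$uid[a$portion])
    if (!ename %in% igraph::V(vc$graph)$name) next
    for (nb in igraph::neighbors(vc$graph, ename)$name) {
      if (!startsWith(nb, "F")) next
      fp <- vc$face_portions[[as.integer(sub("^F", "", nb))]]
      if (fp$crossing) next
      prev <- face_of[[nb]]
      if (is.null(prev)) face_of[[nb]] <- ci
      else {
        ra <- find(prev); rb <- find(ci)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(nc), find, integer(1))
  unname(split(seq_len(nc), roots))
}

# Interior subgraphs whose envelope crossings coincide pierce the envelope
# at the same mouth and belong to one passage (braided strands cross the
# boundary at indistinguishable loci); merge their groups.
merge_by_shared_mouths <- function(ig, comp, groups, opening_merge) {
  xn <- names(comp$membership)[startsWith(names(comp$membership), "X")]
  if (length(xn) < 2L) return(groups)
  xpos <- t(vapply(xn, function(nm) ig$node_pos[[nm]], numeric(3)))
  cl <- stats::cutree(stats::hclust(stats::dist(xpos), "single"),
                      h = opening_merge)
  grp_of_comp <- integer(0)
  for (gi in seq_along(groups)) grp_of_comp[groups[[gi]]] <- gi
  parent <- seq_along(groups)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in sort(unique(cl))) {
    gs <- unique(grp_of_comp[comp$membership[xn[cl == k]]])
    gs <- gs[!is.na(gs)]
    if (length(gs) > 1L) for (g in gs[-1]) {
      ra <- find(gs[1]); rb <- find(g)
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(groups), find, integer(1))
  lapply(unname(split(seq_along(groups), roots)),
         function(gs) unlist(groups[gs]))
}

# --- envelope: convex hull of the offset model via support directions ------

envelope_model <- function(mol, delta, k = 4000L) {
  D <- fibonacci_directions(k)
  s <- apply(D %*% t(mol$centers) +
               rep(mol$radii + delta, each = k), 1L, max)
  list(D = D, s = s)
}

fibonacci_directions <- function(k) {
  i <- seq_len(k) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / k
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

envelope_contains <- function(env, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  # x inside iff x . d <= s(d) for every support direction
  proj <- pts %*% t(env$D)
  rowSums(proj > rep(env$s, each = nrow(pts)) + 1e-9) == 0L
}

# --- interior subgraph: graph cap envelope, split at crossings -------------

interior_graph <- function(vc, vg, env, m = 65L) {
  vd <- vc$vd
  node_pos <- list(); node_rho <- list()
  for (nm in igraph::V(vg$g)$name) {
    node_pos[[nm]] <- c(igraph::V(vg$g)[nm]$x, igraph::V(vg$g)[nm]$y,
                        igraph::V(vg$g)[nm]$z)
    node_rho[[nm]] <- igraph::V(vg$g)[nm]$rho
  }
  nodes_in <- vapply(igraph::V(vg$g)$name, function(nm) {
    p <- node_pos[[nm]]
    !anyNA(p) && envelope_contains(env, p)
  }, logical(1))
  names(nodes_in) <- igraph::V(vg$g)$name
  edges <- character(0); weights <- numeric(0); eattr <- list()
  xcount <- 0L
  el <- igraph::as_edgelist(vg$g)
  for (q in seq_len(nrow(vg$edges_df))) {
    k <- vg$edges_df$portion[q]
    ep <- vc$edge_portions[k, ]
    e <- vd$edges[vd$edges$id == ep$edge, ]
    cn <- vd$conics[[e$key]]
    ts <- seq(ep$t1, ep$t2, length.out = m)
    pts <- conic_point(cn, e$comp, ts)
    ins <- envelope_contains(env, pts)
    ends <- el[q, ]
    # boundary events along the arc
    cuts <- numeric(0)
    for (j in seq_len(m - 1L)) if (ins[j] != ins[j + 1L])
      cuts <- c(cuts, env_cross_param(cn, e$comp, env, ts[j], ts[j + 1L]))
    bounds <- c(ts[1], cuts, ts[m])
    bnodes <- character(length(bounds))
    bnodes[1] <- ends[1]; bnodes[length(bounds)] <- ends[2]
    if (length(cuts) > 0) for (j in seq_along(cuts)) {
      xcount <- xcount + 1L
      nm <- paste0("X", xcount)
      bnodes[j + 1L] <- nm
      node_pos[[nm]] <- drop(conic_point(cn, e$comp, cuts[j]))
      node_rho[[nm]] <- conic_rho(cn, e$comp, cuts[j])
    }
    for (j in seq_len(length(bounds) - 1L)) {
      tm <- (bounds[j] + bounds[j + 1L]) / 2
      if (!envelope_contains(env, conic_point(cn, e$comp, tm))) next
      n1 <- bnodes[j]; n2 <- bnodes[j + 1L]
      if (!startsWith(n1, "X") && !isTRUE(nodes_in[[n1]])) next
      if (!startsWith(n2, "X") && !isTRUE(nodes_in[[n2]])) next
      rr <- sub_arc_rho(cn, e$comp, bounds[j], bounds[j + 1L])
      edges <- c(edges, n1, n2)
      weights <- c(weights, rr$min)
      eattr[[length(weights)]] <- list(portion = k, t1 = bounds[j],
                                       t2 = bounds[j + 1L],
                                       rho_min = rr$min, t_min = rr$t_min,
                                       edge = ep$edge)
    }
  }
  used <- unique(edges)
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(used), name = used)
  if (length(edges) > 0)
    g <- igraph::add_edges(g, match(edges, used), weight = weights)
  list(g = g, node_pos = node_pos, node_rho = node_rho, eattr = eattr,
       vg = vg)
}

env_cross_param <- function(cn, comp, env, t_in, t_out) {
  for (it in 1:50) {
    tm <- (t_in + t_out) / 2
    if (envelope_contains(env, conic_point(cn, comp, tm)))
      t_in <- tm else t_out <- tm
  }
  (t_in + t_out) / 2
}

# exact clearance minimum over a sub-arc
sub_arc_rho <- function(cn, ci, ta, tb) {
  cp <- cn$comps[[ci]]
  cand <- c(ta, tb)
  extr <- switch(cp$type, loop = c(0, 1, 2, 3), fold = 0, branch = numeric(0))
  cand <- c(cand, extr[extr > ta & extr < tb])
  rho <- conic_rho(cn, ci, cand)
  list(min = min(rho), t_min = cand[which.min(rho)])
}

# atoms whose surface the channel's sweep balls touch: at every sample of
# every interior sub-arc, atoms within `slack` of the local clearance
interior_atoms <- function(vc, ig, nodes, slack = 0.05) {
  vd <- vc$vd; mol <- vd$molecule
  atoms <- integer(0)
  el <- igraph::as_edgelist(ig$g)
  for (q in seq_len(nrow(el))) {
    if (!(el[q, 1] %in% nodes) || !(el[q, 2] %in% nodes)) next
    a <- ig$eattr[[q]]
    ep <- vc$edge_portions[a$portion, ]
    e <- vd$edges[vd$edges$id == ep$edge, ]
    cn <- vd$conics[[e$key]]
    ts <- seq(a$t1, a$t2, length.out = 9L)
    pts <- conic_point(cn, e$comp, ts)
    W <- weighted_dists(pts, mol)
    sw <- do.call(pmin, as.data.frame(W))
    atoms <- c(atoms, unique(which(colSums(W <= sw + slack) > 0)))
  }
  sort(unique(atoms))
}

# Handles of a channel: the number of geometrically substantial independent
# cycles of its interior subgraph. Near-degenerate configurations (jittered
# symmetric rings) braid the skeleton into micro-separated parallel strands
# whose cycles are bounded by face slivers below grid resolution; such
# cycles are thin: every node of the fundamental cycle lies within `tube_h`
# of the chord closing it. Each non-tree edge (w.r.t. a spanning forest)
# whose fundamental cycle escapes the tube counts as one handle; genuinely
# distinct passages reconnecting have well-separated interiors and are
# counted, braid artifacts are not.
channel_handles <- function(vg, ig, sg, tube_h = 0.05) {
  if (igraph::ecount(sg) == 0L) return(0L)
  mst <- igraph::mst(sg, weights = rep(1, igraph::ecount(sg)))
  mel <- igraph::as_edgelist(mst)
  mkey <- paste(pmin(mel[, 1], mel[, 2]), pmax(mel[, 1], mel[, 2]))
  el <- igraph::as_edgelist(sg)
  ekey <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  seen_tree <- rep(FALSE, length(mkey))
  handles <- 0L
  for (q in seq_len(nrow(el))) {
    m <- match(ekey[q], mkey)
    if (!is.na(m) && !seen_tree[m]) { seen_tree[m] <- TRUE; next }
    u <- el[q, 1]; v <- el[q, 2]
    if (u == v) next                    # self-loop: zero-extent cycle
    sp <- igraph::shortest_paths(mst, u, v, output = "vpath")$vpath[[1]]$name
    P <- t(vapply(sp, function(nm) ig$node_pos[[nm]], numeric(3)))
    if (cycle_thickness(P) > tube_h) handles <- handles + 1L
  }
  handles
}

# transverse extent of a node loop: maximum distance from the best-fit line
# (first principal axis); a cycle bounding a real handle encloses area and
# escapes every line, a degeneracy braid hugs one
cycle_thickness <- function(P) {
  if (nrow(P) < 3L) return(0)
  Pc <- sweep(P, 2, colMeans(P))
  sv <- svd(Pc, nu = 0, nv = 3)
  u1 <- sv$v[, 1]
  res <- Pc - outer(drop(Pc %*% u1), u1)
  sqrt(max(rowSums(res^2)))
}

# --- spine and bottleneck ---------------------------------------------------

channel_spine <- function(vc, ig, sg, openings) {
  vd <- vc$vd
  # widest (maximum-bottleneck) paths live on the maximum spanning tree
  mst <- igraph::mst(sg, weights = -igraph::E(sg)$weight)
  memb <- igraph::components(mst)$membership
  # per opening pair, pick crossing representatives sharing a 1-skeleton
  # component (merged braid strands cross the envelope as separate nodes)
  pick_pair <- function(oi, oj) {
    for (a in oi$crossings) for (b in oj$crossings)
      if (memb[[a]] == memb[[b]]) return(c(a, b))
    NULL
  }
  paths <- list(); bn_rho <- Inf; bn_pos <- NULL
  el <- igraph::as_edgelist(ig$g)
  eattr_of <- function(n1, n2) {
    for (q in seq_len(nrow(el))) {
      if ((el[q, 1] == n1 && el[q, 2] == n2) ||
          (el[q, 1] == n2 && el[q, 2] == n1)) return(ig$eattr[[q]])
    }
    NULL
  }
  mol <- vd$molecule
  for (i in seq_along(openings)) for (j in seq_along(openings)) {
    if (j <= i) next
    pr <- pick_pair(openings[[i]], openings[[j]])
    if (is.null(pr)) next
    sp <- tryCatch(igraph::shortest_paths(mst, pr[1], pr[2],
                                          output = "vpath"),
                   warning = function(w) NULL, error = function(e) NULL)
    if (is.null(sp) || length(sp$vpath[[1]]) == 0L) next
    vp <- sp$vpath[[1]]$name
    pts <- NULL; sweep <- NULL
    for (q in seq_len(length(vp) - 1L)) {
      a <- eattr_of(vp[q], vp[q + 1L])
      if (is.null(a)) next
      ep <- vc$edge_portions[a$portion, ]
      e <- vd$edges[vd$edges$id == ep$edge, ]
      cn <- vd$conics[[e$key]]
      ts <- seq(a$t1, a$t2, length.out = 17L)
      pp <- conic_point(cn, e$comp, ts)
      # orient the sampled arc to continue from the previous point
      p_node <- ig$node_pos[[vp[q]]]
      if (sum((pp[1, ] - p_node)^2) > sum((pp[17, ] - p_node)^2)) {
        pp <- pp[17:1, , drop = FALSE]; ts <- rev(ts)
      }
      sw <- clearance(pp, mol)
      pts <- rbind(pts, pp); sweep <- c(sweep, sw)
      if (a$rho_min < bn_rho - 1e-12 ||
          (abs(a$rho_min - bn_rho) <= 1e-12 && !is.null(bn_pos) &&
           lex_less(drop(conic_point(cn, e$comp, a$t_min)), bn_pos))) {
        bn_rho <- a$rho_min
        bn_pos <- drop(conic_point(cn, e$comp, a$t_min))
      }
    }
    if (!is.null(pts))
      paths[[length(paths) + 1L]] <- list(
        from = i, to = j, points = pts, sweep_radius = sweep)
  }
  list(paths = paths,
       bottleneck = list(radius = bn_rho, position = bn_pos))
}

lex_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k] - 1e-12) return(TRUE)
    if (a[k] > b[k] + 1e-12) return(FALSE)
  }
  FALSE
}

#' Bottleneck of a channel
#'
#' @param cavity a `vc_cavity` of kind `"channel"`.
#' @return A list with `radius` (minimum clearance along the spine, Angstrom)
#'   and `position`.
#' @export
bottleneck <- function(cavity) {
  stopifnot(inherits(cavity, "vc_cavity"))
  if (cavity$kind != "channel")
    stop("bottleneck() is defined for channels, not ", cavity$kind)
  cavity$bottleneck
}

#' Spine of a channel
#'
#' @param cavity a `vc_cavity` of kind `"channel"`.
#' @return A list of polylines; each has `points` (matrix) and
#'   `sweep_radius` (clearance at each sample, the radius of the ball swept
#'   along the spine).
#' @export
spine <- function(cavity) {
  stopifnot(inherits(cavity, "vc_cavity"))
  if (cavity$kind != "channel")
    stop("spine() is defined for channels, not ", cavity$kind)
  cavity$spine
}
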