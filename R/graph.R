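#' Voronoi graph of a complement component
#'
#' Reduces one connected component of the Voronoi complement to a graph:
#' vertices are retained Voronoi vertices plus clip points (where an edge
#' portion meets the offset surface) plus a single node for infinity; graph
#' edges are the retained edge portions, each annotated with its exact
#' minimum clearance. Faces are carried along as boundary relations and used
#' to correct the cycle rank (a disk face makes its boundary cycle
#' contractible), realizing the face-onto-edge contraction: the returned
#' `handles` equals the first Betti number of the retained 2-complex.
#'
#' For channel analysis (`include_crossing = FALSE`, the trimming rule for
#' the unbounded component) entities that intersect the offset surface are
#' removed entirely, leaving only whole entities with clearance > delta
#' everywhere.
#'
#' @param vc a `vc_complement`.
#' @param component component id (row of `vc$components`).
#' @param include_crossing keep clipped (surface-intersecting) portions?
#' @return An object of class `vc_vgraph`: an igraph `g` (nodes carry
#'   positions and clearances), `edges_df` mapping graph edges to diagram
#'   edge sub-arcs, `face_boundaries`, and `handles`.
#' @export
build_voronoi_graph <- function(vc, component, include_crossing = TRUE) {
  stopifnot(inherits(vc, "vc_complement"))
  vd <- vc$vd
  eports <- vc$edge_portions
  sel <- which(eports$component == component &
                 (include_crossing | !eports$crossing))
  fsel <- which(vapply(vc$face_portions, `[[`, numeric(1),
                       "component") == component &
                  (include_crossing |
                     !vapply(vc$face_portions, `[[`, logical(1), "crossing")))
  vids <- vc$vertices$id[vc$vertices$component == component]
  nodes <- c(if (length(vids) > 0) paste0("V", vids), "INF")
  pos <- rbind(if (length(vids) > 0)
    as.matrix(vd$vertices[match(vids, vd$vertices$id), c("x", "y", "z")]),
    c(NA, NA, NA))
  rho <- c(vd$vertices$rho[match(vids, vd$vertices$id)], Inf)
  ename <- character(0); gedges <- character(0); erow <- integer(0)
  add_node <- function(nm, p, r) {
    nodes <<- c(nodes, nm); pos <<- rbind(pos, p); rho <<- c(rho, r)
  }
  for (k in sel) {
    ep <- eports[k, ]
    e <- vd$edges[vd$edges$id == ep$edge, ]
    cn <- vd$conics[[e$key]]
    endpoint <- function(side) {
      ty <- ep[[paste0("end", side)]]
      tt <- if (side == 1) ep$t1 else ep$t2
      if (ty == "vertex") paste0("V", ep[[paste0("ref", side)]])
      else if (ty == "inf") "INF"
      else {
        nm <- sprintf("C%d_%d", ep$uid, side)
        add_node(nm, drop(conic_point(cn, e$comp, tt)),
                 conic_rho(cn, e$comp, tt))
        nm
      }
    }
    if (ep$cyclic) {
      nm <- sprintf("L%d", ep$uid)
      add_node(nm, drop(conic_point(cn, e$comp, ep$t1)),
               conic_rho(cn, e$comp, ep$t1))
      n1 <- n2 <- nm
    } else {
      n1 <- endpoint(1); n2 <- endpoint(2)
    }
    gedges <- c(gedges, n1, n2)
    erow <- c(erow, k)
    ename <- c(ename, paste0("E", ep$uid))
  }
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(gedges) > 0)
    g <- igraph::add_edges(g, match(gedges, nodes), name = ename,
                           weight = eports$rho_min[erow])
  igraph::V(g)$x <- pos[, 1]; igraph::V(g)$y <- pos[, 2]
  igraph::V(g)$z <- pos[, 3]; igraph::V(g)$rho <- rho
  # drop isolated INF when nothing reaches it (bounded components)
  if (igraph::degree(g, "INF") == 0)
    g <- igraph::delete_vertices(g, "INF")
  # face boundary relations: graph edges adjacent to each retained face
  # portion (via the complement connectivity graph built at trim time). A
  # face with part of its boundary removed is a flap: it collapses freely
  # and must not contribute a cycle relation, so only faces whose entire
  # adjacent edge set survives are kept.
  ends_of <- stats::setNames(split(gedges, rep(seq_along(ename), each = 2)),
                             ename)
  fb <- lapply(fsel, function(fi) {
    fp <- vc$face_portions[[fi]]
    nb <- igraph::neighbors(vc$graph, paste0("F", fp$uid))$name
    enb <- nb[startsWith(nb, "E")]
    if (!all(enb %in% ename)) return(character(0))
    if (!edges_form_cycle(enb, ends_of)) return(character(0))
    enb
  })
  handles <- graph_cycle_rank(g) - face_relation_rank(fb, ename)
  structure(list(g = g, component = component,
                 edges_df = data.frame(name = ename, portion = erow,
                                       stringsAsFactors = FALSE),
                 face_boundaries = fb, handles = handles),
            class = "vc_vgraph")
}

#' @export
print.vc_vgraph <- function(x, ...) {
  cat(sprintf("<vc_vgraph> component %d: V=%d E=%d, handles=%d\n",
              x$component, igraph::vcount(x$g), igraph::ecount(x$g),
              x$handles))
  invisible(x)
}

# is a set of edges an even-degree (cycle-space) subgraph? A face glued
# along a path is a flap (collapses), only closed boundaries kill cycles
edges_form_cycle <- function(enb, ends_of) {
  vs <- unlist(ends_of[enb], use.names = FALSE)
  if (length(vs) == 0L) return(FALSE)
  all(table(vs) %% 2L == 0L)
}

# cycle rank E - V + C of a graph
graph_cycle_rank <- function(g) {
  igraph::ecount(g) - igraph::vcount(g) + igraph::components(g)$no
}

# GF(2) rank of the face-boundary relations in the edge space: each retained
# disk face contributes the set of graph edges on its boundary; independent
# relations kill independent cycles
face_relation_rank <- function(face_bounds, edge_names) {
  fb <- Filter(length, face_bounds)
  if (length(fb) == 0L || length(edge_names) == 0L) return(0L)
  M <- matrix(FALSE, length(fb), length(edge_names))
  for (i in seq_along(fb))
    M[i, match(fb[[i]], edge_names)] <- TRUE
  rank <- 0L; row <- 1L
  for (col in seq_len(ncol(M))) {
    piv <- which(M[row:nrow(M), col])[1]
    if (is.na(piv)) next
    piv <- piv + row - 1L
    tmp <- M[row, ]; M[row, ] <- M[piv, ]; M[piv, ] <- tmp
    for (r in seq_len(nrow(M))) if (r != row && M[r, col])
      M[r, ] <- xor(M[r, ], M[row, ])
    rank <- rank + 1L; row <- row + 1L
    if (row > nrow(M)) break
  }
  rank
}

#' Euler-Poincare summary of a graph
#'
#' @param graph a `vc_vgraph`, or any igraph object.
#' @return A list with `components` and `handles` (cycle rank
#'   E - V + components of the 1-skeleton).
#' @examples
#' g <- igraph::make_graph(~ a-b, b-c, c-d, d-e)   # path: 1 component, 0 cycles
#' euler_poincare(g)
#' @export
euler_poincare <- function(graph) {
  g <- if (inherits(graph, "vc_vgraph")) graph$g else graph
  list(components = igraph::components(g)$no, handles = graph_cycle_rank(g))
}
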