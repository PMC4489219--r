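# Independent oracles used across the suite. These deliberately avoid the
# package's conic/complement machinery: flood fill on a voxel grid (C++),
# brute-force circumsphere enumeration, and multi-start Newton solving.

# voids by 0.05-A flood fill of clearance > delta space (26-connectivity)
flood_void_count <- function(mol, delta, step = 0.05) {
  pad <- max(mol$radii) + delta + 5 * step
  lo <- apply(mol$centers, 2, min) - pad
  hi <- apply(mol$centers, 2, max) + pad
  dims <- as.integer(ceiling((hi - lo) / step)) + 1L
  vorocav:::flood_voids_cpp(mol$centers, mol$radii, lo, dims, 0.05, delta)
}

# Ordinary Voronoi diagram of points by O(n^5) empty-circumsphere search.
# The production diagram clips entities beyond its inclusion sphere, so the
# comparison is restricted to vertices within `rmax` of the centroid. Edge
# triples are detected locally: from each retained vertex, step a small eps
# along each of its triples' equidistant lines; an empty probe point marks a
# Voronoi edge leaving the vertex.
ordinary_voronoi_oracle <- function(ctr, tol = 1e-7, rmax = NULL,
                                    eps = 1e-3) {
  n <- nrow(ctr)
  cc0 <- colMeans(ctr)
  if (is.null(rmax))
    rmax <- max(sqrt(rowSums(sweep(ctr, 2, cc0)^2))) + 10
  verts <- list()
  for (q in utils::combn(n, 4L, simplify = FALSE)) {
    A <- 2 * sweep(ctr[q[2:4], , drop = FALSE], 2, ctr[q[1], ])
    if (abs(det(A)) < 1e-9) next
    b <- rowSums(ctr[q[2:4], , drop = FALSE]^2) - sum(ctr[q[1], ]^2)
    cc <- solve(A, b)
    if (sqrt(sum((cc - cc0)^2)) > rmax) next
    R0 <- sqrt(sum((cc - ctr[q[1], ])^2))
    dd <- sqrt(rowSums(sweep(ctr, 2, cc)^2))
    if (min(dd) >= R0 - tol)
      verts[[length(verts) + 1L]] <- list(atoms = q, center = cc, R = R0)
  }
  # merge cospherical duplicates
  if (length(verts) > 1L) {
    pos <- do.call(rbind, lapply(verts, `[[`, "center"))
    grp <- stats::cutree(stats::hclust(stats::dist(pos), "single"), h = 1e-6)
    verts <- lapply(sort(unique(grp)), function(g) {
      m <- which(grp == g)
      list(atoms = sort(unique(unlist(lapply(verts[m], `[[`, "atoms")))),
           center = colMeans(pos[m, , drop = FALSE]),
           R = mean(vapply(verts[m], `[[`, numeric(1), "R")))
    })
  }
  vkeys <- vapply(verts, function(v) paste(v$atoms, collapse = "_"),
                  character(1))
  edge_triples <- character(0)
  for (v in verts) {
    for (tr in utils::combn(sort(v$atoms), 3L, simplify = FALSE)) {
      u <- pracma_cross(ctr[tr[2], ] - ctr[tr[1], ],
                        ctr[tr[3], ] - ctr[tr[1], ])
      nu <- sqrt(sum(u^2))
      if (nu < 1e-9) next
      u <- u / nu
      for (sgn in c(-1, 1)) {
        x <- v$center + sgn * eps * u
        dd <- sqrt(rowSums(sweep(ctr, 2, x)^2))
        if (min(dd) >= dd[tr[1]] - tol) {
          edge_triples <- c(edge_triples, paste(tr, collapse = "_"))
          break
        }
      }
    }
  }
  list(vertices = verts, vertex_keys = sort(vkeys),
       edge_triples = sort(unique(edge_triples)))
}

# Agreement of the production void count with the flood-fill oracle, with a
# principled exclusion of near-critical probe radii: if the counts differ,
# the case is excluded when the production count is unstable within +/-0.02 A
# of delta (delta sits at a topology change) or the oracle count is
# resolution-limited (changes under grid refinement).
compare_void_counts <- function(mol, vd, delta) {
  nv <- length(classify_voids(suppressWarnings(trim_complement(vd, delta))))
  no <- flood_void_count(mol, delta)$n_voids
  if (nv == no) return("agree")
  n_lo <- length(classify_voids(suppressWarnings(
    trim_complement(vd, delta - 0.02))))
  n_hi <- length(classify_voids(suppressWarnings(
    trim_complement(vd, delta + 0.02))))
  if (n_lo != n_hi) return("excluded")
  if (flood_void_count(mol, delta, step = 0.04)$n_voids != no)
    return("excluded")
  "mismatch"
}

pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

# multi-start Newton oracle for the 4-atom tangent-sphere problem: counts
# distinct real solutions with rho >= 0, independently of the closed form
apollonius_newton_oracle <- function(centers, radii, n_starts = 200L,
                                     seed = 1L) {
  sols <- list()
  set.seed(seed)
  span <- max(dist(centers)) + max(radii)
  mid <- colMeans(centers)
  for (s in seq_len(n_starts)) {
    x <- mid + stats::rnorm(3, sd = span / 2)
    rho <- stats::runif(1, 0, span)
    ok <- FALSE
    for (it in 1:60) {
      dd <- sqrt(colSums((t(centers) - x)^2))
      f <- dd - radii - rho
      if (max(abs(f)) < 1e-10) { ok <- TRUE; break }
      J <- cbind(sweep(-(centers - rep(x, each = 4)), 1, pmax(dd, 1e-12),
                       "/"), -1)
      upd <- tryCatch(solve(J, f), error = function(e) NULL)
      if (is.null(upd) || anyNA(upd)) break
      step <- pmin(1, span / (1e-9 + sqrt(sum(upd^2))))
      x <- x - step * upd[1:3]; rho <- rho - step * upd[4]
    }
    if (ok && rho >= -1e-9)
      sols[[length(sols) + 1L]] <- c(x, max(rho, 0))
  }
  if (length(sols) == 0L) return(matrix(numeric(0), 0, 4))
  m <- do.call(rbind, sols)
  if (nrow(m) > 1L) {
    grp <- stats::cutree(stats::hclust(stats::dist(m), "single"), h = 1e-4)
    m <- do.call(rbind, lapply(sort(unique(grp)), function(g)
      colMeans(m[grp == g, , drop = FALSE])))
  }
  m[m[, 4] >= -1e-9, , drop = FALSE]
}

# brute-force threshold of an equal-radius simplex: minimum clearance of an
# empty sphere tangent to the simplex atoms, by dense search over the
# equidistant locus plus local refinement
alpha_threshold_oracle <- function(mol, atoms, ngrid = 400L) {
  ctr <- mol$centers; r <- mol$radii[1]
  stopifnot(length(unique(mol$radii)) == 1L)
  span <- max(stats::dist(ctr)) + 2 * r + 3
  all_dists <- function(pts) {
    d2 <- outer(rowSums(pts^2), rep(1, nrow(ctr))) +
      outer(rep(1, nrow(pts)), rowSums(ctr^2)) - 2 * pts %*% t(ctr)
    sqrt(pmax(d2, 0))
  }
  if (length(atoms) == 2L) {
    # bisector plane grid
    mid <- colMeans(ctr[atoms, , drop = FALSE])
    u <- ctr[atoms[2], ] - ctr[atoms[1], ]; u <- u / sqrt(sum(u^2))
    e1 <- if (abs(u[1]) < 0.9) pracma_cross(u, c(1, 0, 0)) else
      pracma_cross(u, c(0, 1, 0))
    e1 <- e1 / sqrt(sum(e1^2)); e2 <- pracma_cross(u, e1)
    g <- seq(-span, span, length.out = ngrid)
    pts <- t(mid + outer(e1, rep(g, each = ngrid)) +
               outer(e2, rep(g, ngrid)))
    dd <- all_dists(pts)
    dd1 <- dd[, atoms[1]]
    okv <- apply(dd, 1, min) >= dd1 - 1e-9
    if (!any(okv)) Inf else min(dd1[okv]) - r
  } else {
    # equidistant line of the triple
    A <- 2 * rbind(ctr[atoms[2], ] - ctr[atoms[1], ],
                   ctr[atoms[3], ] - ctr[atoms[1], ])
    b <- c(sum(ctr[atoms[2], ]^2) - sum(ctr[atoms[1], ]^2),
           sum(ctr[atoms[3], ]^2) - sum(ctr[atoms[1], ]^2))
    x0 <- drop(t(A) %*% solve(A %*% t(A), b))
    u <- pracma_cross(ctr[atoms[2], ] - ctr[atoms[1], ],
                      ctr[atoms[3], ] - ctr[atoms[1], ])
    u <- u / sqrt(sum(u^2))
    ts <- seq(-span, span, length.out = 20L * ngrid)
    pts <- t(x0 + outer(u, ts))
    dd <- all_dists(pts)
    dd1 <- dd[, atoms[1]]
    okv <- apply(dd, 1, min) >= dd1 - 1e-9
    if (!any(okv)) Inf else min(dd1[okv]) - r
  }
}
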