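#' Tangent spheres of four atoms (Apollonius problem)
#'
#' Finds every sphere simultaneously tangent (externally) to four given
#' atoms: center x and radius rho with |x - c_i| = r_i + rho for all i.
#' Subtracting pairs of tangency equations linearizes the system, giving
#' x = a + rho * b; substituting back yields a quadratic in rho, so there are
#' 0, 1 or 2 real solutions. Solutions are polished by Newton iteration when
#' the closed form leaves a residual above tolerance, and returned only when
#' the relative tangency residual is below `tol`.
#'
#' @param centers 4 x 3 matrix of atom centers.
#' @param radii length-4 vector of atom radii.
#' @param tol relative tangency tolerance.
#' @param min_radius minimum returned radius (default 0; pass `-Inf` to keep
#'   negative-clearance solutions, used internally for overlapping atoms).
#' @return A data.frame with columns x, y, z, rho, residual; zero rows when no
#'   tangent sphere exists. Degenerate (coplanar-center) quadruples yield zero
#'   rows with attribute `degenerate = TRUE`.
#' @examples
#' m <- make_fixture("tetra_cage")
#' solve_apollonius(m$centers, m$radii)  # one sphere, rho = sqrt(6)/2 - 1
#' @export
solve_apollonius <- function(centers, radii, tol = 1e-9, min_radius = 0) {
  stopifnot(nrow(centers) == 4L, length(radii) == 4L)
  sol <- apollonius_batch(centers, radii, matrix(1:4, nrow = 1L), tol = tol)
  out <- sol$solutions[sol$solutions$rho >= min_radius, , drop = FALSE]
  rownames(out) <- NULL
  structure(out[, c("x", "y", "z", "rho", "residual")],
            degenerate = sol$degenerate[1])
}

# Batch tangent-sphere solver.
# centers: n x 3, radii: n, quads: Q x 4 index matrix.
# Optional inclusion sphere (cc, Rg): solutions outside are dropped before
# polishing (near-degenerate quadruples produce arbitrarily distant spheres).
# Returns list(solutions = data.frame(quad, x, y, z, rho, residual),
#              degenerate = logical(Q)).
apollonius_batch <- function(centers, radii, quads, tol = 1e-9,
                             cc = NULL, Rg = Inf) {
  Q <- nrow(quads)
  c1 <- centers[quads[, 1], , drop = FALSE]
  m <- lapply(2:4, function(k) 2 * (centers[quads[, k], , drop = FALSE] - c1))
  sq <- rowSums(centers^2)
  g <- vapply(2:4, function(k)
    sq[quads[, k]] - sq[quads[, 1]] + radii[quads[, 1]]^2 - radii[quads[, k]]^2,
    numeric(Q))
  h <- vapply(2:4, function(k)
    2 * (radii[quads[, 1]] - radii[quads[, k]]), numeric(Q))
  g <- matrix(g, nrow = Q); h <- matrix(h, nrow = Q)
  cross3 <- function(u, v)
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  adj1 <- cross3(m[[2]], m[[3]])
  adj2 <- cross3(m[[3]], m[[1]])
  adj3 <- cross3(m[[1]], m[[2]])
  det <- rowSums(m[[1]] * adj1)
  scale <- pmax(sqrt(rowSums(m[[1]]^2)) * sqrt(rowSums(m[[2]]^2)) *
                  sqrt(rowSums(m[[3]]^2)), .Machine$double.eps)
  degen <- abs(det) <= 1e-9 * scale
  a <- (g[, 1] * adj1 + g[, 2] * adj2 + g[, 3] * adj3) / det
  b <- (h[, 1] * adj1 + h[, 2] * adj2 + h[, 3] * adj3) / det
  w <- a - c1
  r1 <- radii[quads[, 1]]
  qa <- rowSums(b^2) - 1
  qb <- 2 * (rowSums(w * b) - r1)
  qc <- rowSums(w^2) - r1^2
  qa[degen] <- NA_real_
  disc <- qb^2 - 4 * qa * qc
  lin <- !degen & abs(qa) < 1e-14
  sols <- list()
  for (sgn in c(1, -1)) {
    rho <- rep(NA_real_, Q)
    quadr <- !degen & !lin & !is.na(disc) & disc >= 0
    rho[quadr] <- (-qb[quadr] + sgn * sqrt(disc[quadr])) / (2 * qa[quadr])
    if (sgn > 0) {
      linok <- lin & abs(qb) > 1e-14
      rho[linok] <- -qc[linok] / qb[linok]
    }
    idx <- which(is.finite(rho))
    if (length(idx) == 0L) next
    x <- a[idx, , drop = FALSE] + rho[idx] * b[idx, , drop = FALSE]
    sols[[length(sols) + 1L]] <-
      data.frame(quad = idx, x = x[, 1], y = x[, 2], z = x[, 3],
                 rho = rho[idx])
  }
  if (length(sols) == 0L)
    return(list(solutions = data.frame(quad = integer(0), x = numeric(0),
                                       y = numeric(0), z = numeric(0),
                                       rho = numeric(0), residual = numeric(0)),
                degenerate = degen))
  sol <- do.call(rbind, sols)
  if (!is.null(cc)) {
    inside <- (sol$x - cc[1])^2 + (sol$y - cc[2])^2 + (sol$z - cc[3])^2 <=
      Rg^2
    sol <- sol[inside, , drop = FALSE]
    if (nrow(sol) == 0L)
      return(list(solutions = cbind(sol, residual = numeric(0)),
                  degenerate = degen))
  }
  res <- apollonius_residual(sol, centers, radii, quads)
  # polish only near-miss roots: clean closed-form roots sit at ~1e-12,
  # mirror roots of the squared system at O(1) and cannot be rescued
  bad <- which(res > tol * (1 + abs(sol$rho)) &
                 res < 1e-3 * (1 + abs(sol$rho)))
  for (i in bad) {   # Newton polish on the full 4x4 tangency system
    qd <- quads[sol$quad[i], ]
    xx <- c(sol$x[i], sol$y[i], sol$z[i]); rho <- sol$rho[i]
    for (it in 1:8) {
      dd <- sqrt(colSums((t(centers[qd, , drop = FALSE]) - xx)^2))
      f <- dd - radii[qd] - rho
      if (max(abs(f)) < tol * (1 + abs(rho)) / 4) break
      J <- cbind(sweep(-(centers[qd, , drop = FALSE] - rep(xx, each = 4)), 1,
                       pmax(dd, 1e-12), "/"), -1)
      upd <- tryCatch(solve(J, f), error = function(e) NULL)
      if (is.null(upd)) break
      xx <- xx - upd[1:3]; rho <- rho - upd[4]
    }
    sol$x[i] <- xx[1]; sol$y[i] <- xx[2]; sol$z[i] <- xx[3]; sol$rho[i] <- rho
  }
  sol$residual <- apollonius_residual(sol, centers, radii, quads)
  keep <- sol$residual <= tol * (1 + abs(sol$rho))
  if (!is.null(cc))   # Newton polishing may push junk roots far out again
    keep <- keep & (sol$x - cc[1])^2 + (sol$y - cc[2])^2 +
      (sol$z - cc[3])^2 <= Rg^2
  # drop duplicate double roots (disc == 0 returns the same sphere twice)
  sol <- sol[keep, , drop = FALSE]
  if (nrow(sol) > 1L) {
    key <- paste(sol$quad, round(sol$x, 9), round(sol$y, 9), round(sol$z, 9),
                 round(sol$rho, 9))
    sol <- sol[!duplicated(key), , drop = FALSE]
  }
  rownames(sol) <- NULL
  list(solutions = sol, degenerate = degen)
}

apollonius_residual <- function(sol, centers, radii, quads) {
  if (nrow(sol) == 0L) return(numeric(0))
  res <- rep(0, nrow(sol))
  for (k in 1:4) {
    idx <- quads[sol$quad, k]
    dd <- sqrt((centers[idx, 1] - sol$x)^2 + (centers[idx, 2] - sol$y)^2 +
                 (centers[idx, 3] - sol$z)^2)
    res <- pmax(res, abs(dd - radii[idx] - sol$rho))
  }
  res
}
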