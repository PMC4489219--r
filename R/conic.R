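# Equidistant curve of three atoms ("triple curve").
#
# Points x additively equidistant from atoms (c1,r1), (c2,r2), (c3,r3) at
# weighted distance rho satisfy two linear equations in (x, rho), so
# x = a + rho*b + s*u with u normal to the plane of the two bisector
# gradients. Substituting into |x - c1|^2 = (r1 + rho)^2 gives a conic
# C(rho, s) = A2 rho^2 + B2 rho s + s^2 + D2 rho + E2 s + F2 = 0
# whose s^2 coefficient is always 1. For fixed rho the two roots
# s = (-(B2 rho + E2) +/- sqrt(Disc(rho))) / 2 are the two curve points at
# clearance rho; Disc(rho) = Da rho^2 + Db rho + Dc. The real curve therefore
# decomposes into components classified by Da:
#   Da < 0            -> one closed loop over rho in [rho1, rho2]
#   Da > 0, real roots-> two "fold" components (rho >= rho2 and rho <= rho1)
#   Da > 0, no roots  -> two monotone "branch" components over all rho
#   Da ~ 0            -> one fold (linear Disc) or two branches (constant)
# Each component gets a 1-D parameter t under which rho(t) is closed form:
#   loop:   t in [0,2) cyclic, rho = rhoc + rhoamp*cos(pi*t), s-branch by t<1
#   fold:   t in R, rho = rho0 + dir*t^2, s-branch = sign(t)
#   branch: t = rho, fixed s-branch
# Because rho is a parameter coordinate, minimum clearance along an edge and
# clip points rho(t) = delta are exact, not sampled.
#
# Squaring the tangency equation introduces mirror solutions with
# r_i + rho < 0; conic_valid() filters them by checking the true weighted
# distances.

triple_conic <- function(centers, radii, ijk, degen_tol = 1e-9) {
  c1 <- centers[ijk[1], ]; c2 <- centers[ijk[2], ]; c3 <- centers[ijk[3], ]
  r <- radii[ijk]
  A <- rbind(2 * (c2 - c1), 2 * (c3 - c1))
  un <- c(A[1, 2] * A[2, 3] - A[1, 3] * A[2, 2],
          A[1, 3] * A[2, 1] - A[1, 1] * A[2, 3],
          A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1])
  nu <- sqrt(sum(un^2))
  if (nu <= degen_tol * sqrt(sum(A[1, ]^2)) * sqrt(sum(A[2, ]^2)))
    return(NULL)                       # collinear centers: no 1-D curve
  u <- un / nu
  g <- c(sum(c2^2) - sum(c1^2) + r[1]^2 - r[2]^2,
         sum(c3^2) - sum(c1^2) + r[1]^2 - r[3]^2)
  h <- c(2 * (r[1] - r[2]), 2 * (r[1] - r[3]))
  # minimum-norm particular solutions of A x = g and A x = h
  AAt <- A %*% t(A)
  a <- drop(t(A) %*% solve(AAt, g))
  b <- drop(t(A) %*% solve(AAt, h))
  w <- a - c1
  A2 <- sum(b^2) - 1
  B2 <- 2 * sum(b * u)
  D2 <- 2 * (sum(w * b) - r[1])
  E2 <- 2 * sum(w * u)
  F2 <- sum(w^2) - r[1]^2
  Da <- B2^2 - 4 * A2
  Db <- 2 * B2 * E2 - 4 * D2
  Dc <- E2^2 - 4 * F2
  comps <- list()
  push <- function(type, ...) comps[[length(comps) + 1L]] <<-
    c(list(type = type), list(...))
  eps <- 1e-12 * max(1, abs(Da), abs(Db), abs(Dc))
  if (abs(Da) < eps) {
    if (abs(Db) < eps) {
      if (Dc > 0) { push("branch", sigma = 1); push("branch", sigma = -1) }
    } else {
      push("fold", rho0 = -Dc / Db, dir = sign(Db))
    }
  } else {
    dd <- Db^2 - 4 * Da * Dc
    if (Da < 0) {
      if (dd > 0) {
        rr <- sort(c((-Db - sqrt(dd)) / (2 * Da), (-Db + sqrt(dd)) / (2 * Da)))
        push("loop", rho1 = rr[1], rho2 = rr[2],
             rhoc = mean(rr), rhoamp = diff(rr) / 2)
      }
    } else {
      if (dd < 0) {
        push("branch", sigma = 1); push("branch", sigma = -1)
      } else {
        rr <- sort(c((-Db - sqrt(dd)) / (2 * Da), (-Db + sqrt(dd)) / (2 * Da)))
        push("fold", rho0 = rr[2], dir = 1)
        push("fold", rho0 = rr[1], dir = -1)
      }
    }
  }
  list(atoms = ijk, a = a, b = b, u = u, c1 = c1, c2 = c2, c3 = c3, r = r,
       A2 = A2, B2 = B2, D2 = D2, E2 = E2, F2 = F2,
       Da = Da, Db = Db, Dc = Dc, comps = comps)
}

# rho along component at parameter t (vectorized over t)
conic_rho <- function(cn, ci, t) {
  cp <- cn$comps[[ci]]
  switch(cp$type,
         loop = cp$rhoc + cp$rhoamp * cos(pi * (t %% 2)),
         fold = cp$rho0 + cp$dir * t^2,
         branch = t)
}

conic_sigma <- function(cp, t) {
  switch(cp$type,
         loop = ifelse(t %% 2 < 1, 1, -1),
         fold = ifelse(t >= 0, 1, -1),
         branch = rep(cp$sigma, length(t)))
}

# 3-D points along component at parameters t (matrix length(t) x 3)
conic_point <- function(cn, ci, t) {
  cp <- cn$comps[[ci]]
  rho <- conic_rho(cn, ci, t)
  sig <- conic_sigma(cp, t)
  disc <- pmax(cn$Da * rho^2 + cn$Db * rho + cn$Dc, 0)
  s <- (-(cn$B2 * rho + cn$E2) + sig * sqrt(disc)) / 2
  cbind(cn$a[1] + rho * cn$b[1] + s * cn$u[1],
        cn$a[2] + rho * cn$b[2] + s * cn$u[2],
        cn$a[3] + rho * cn$b[3] + s * cn$u[3])
}

# does the parametrized point actually realize weighted distance rho to all
# three defining atoms (filters mirror solutions of the squared system)?
conic_valid <- function(cn, pts, rho, tol = 1e-6) {
  ok <- rep(TRUE, length(rho))
  slack <- tol * (1 + abs(rho))
  ctrs <- list(cn$c1, cn$c2, cn$c3)
  for (k in 1:3) {
    ck <- ctrs[[k]]
    dk <- sqrt((pts[, 1] - ck[1])^2 + (pts[, 2] - ck[2])^2 +
                 (pts[, 3] - ck[3])^2) - cn$r[k]
    ok <- ok & abs(dk - rho) <= slack
  }
  ok
}

# map a known on-curve point (x, rho) to (component index, t)
conic_locate <- function(cn, x, rho) {
  s <- sum(cn$u * (x - cn$a - rho * cn$b))
  disc <- max(cn$Da * rho^2 + cn$Db * rho + cn$Dc, 0)
  mid <- -(cn$B2 * rho + cn$E2) / 2
  best <- NULL
  for (ci in seq_along(cn$comps)) {
    cp <- cn$comps[[ci]]
    inr <- switch(cp$type,
                  loop = rho >= cp$rho1 - 1e-9 && rho <= cp$rho2 + 1e-9,
                  fold = if (cp$dir > 0) rho >= cp$rho0 - 1e-9
                         else rho <= cp$rho0 + 1e-9,
                  branch = TRUE)
    if (!inr) next
    for (sig in if (cp$type == "branch") cp$sigma else c(1, -1)) {
      sp <- mid + sig * sqrt(disc) / 2
      err <- abs(sp - s)
      if (is.null(best) || err < best$err) {
        t <- switch(cp$type,
          loop = {
            cth <- min(1, max(-1, (rho - cp$rhoc) / max(cp$rhoamp, 1e-300)))
            th <- acos(cth) / pi           # in [0,1]
            if (sig > 0) th else 2 - th
          },
          fold = sig * sqrt(max(0, cp$dir * (rho - cp$rho0))),
          branch = rho)
        best <- list(comp = ci, t = t, err = err)
      }
    }
  }
  best
}

# finite parameter value on a component at clearance rho_target (for tails);
# side = +1 upper-s branch end, -1 lower. Returns NA when unreachable.
conic_t_at_rho <- function(cn, ci, rho_target, side) {
  cp <- cn$comps[[ci]]
  switch(cp$type,
    loop = NA_real_,                       # loops are bounded; no tails
    fold = if (cp$dir * (rho_target - cp$rho0) >= 0)
             side * sqrt(cp$dir * (rho_target - cp$rho0)) else NA_real_,
    branch = rho_target)
}
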