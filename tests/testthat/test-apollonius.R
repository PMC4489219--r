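test_that("regular tetrahedron has the closed-form central tangent sphere", {
  m <- make_fixture("tetra_cage", r = 1, edge = 2)
  s <- solve_apollonius(m$centers, m$radii)
  expect_equal(nrow(s), 1L)
  expect_equal(s$rho, sqrt(6) / 2 - 1, tolerance = 1e-9)
  expect_equal(c(s$x, s$y, s$z), c(0, 0, 0), tolerance = 1e-9)
})

test_that("equal radii reduce to the circumsphere of the centers", {
  set.seed(21)
  for (rep in 1:5) {
    C <- matrix(rnorm(12, sd = 2), 4)
    r <- runif(1, 0.5, 1.5)
    s <- solve_apollonius(C, rep(r, 4), min_radius = -Inf)
    A <- 2 * sweep(C[2:4, ], 2, C[1, ])
    if (abs(det(A)) < 1e-6) next
    cc <- solve(A, rowSums(C[2:4, ]^2) - sum(C[1, ]^2))
    R0 <- sqrt(sum((cc - C[1, ])^2))
    expect_equal(nrow(s), 1L)
    expect_equal(c(s$x, s$y, s$z), unname(cc), tolerance = 1e-8)
    expect_equal(s$rho, R0 - r, tolerance = 1e-8)
  }
})

test_that("random mixed-radius quadruples satisfy tangency and match the
           multi-start Newton oracle count", {
  set.seed(5)
  for (rep in 1:6) {
    C <- matrix(rnorm(12, sd = 2.5), 4)
    r <- runif(4, 0.6, 1.8)
    if (any(dist(C) < 0.8)) next
    s <- solve_apollonius(C, r)
    for (i in seq_len(nrow(s))) {
      d <- sqrt(colSums((t(C) - c(s$x[i], s$y[i], s$z[i]))^2))
      expect_lt(max(abs(d - r - s$rho[i])), 1e-9 * (1 + s$rho[i]))
    }
    oracle <- apollonius_newton_oracle(C, r, seed = rep)
    expect_equal(nrow(s), nrow(oracle))
  }
})

test_that("coplanar-center quadruples are flagged degenerate", {
  C <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0))
  s <- solve_apollonius(C, rep(1, 4))
  expect_true(attr(s, "degenerate"))
  expect_equal(nrow(s), 0L)
})

test_that("find_initial_vertex seeds tracing or signals vertex-free", {
  v <- find_initial_vertex(make_fixture("tetra_cage"))
  expect_equal(v$rho, sqrt(6) / 2 - 1, tolerance = 1e-9)
  expect_message(v2 <- find_initial_vertex(molecule(rbind(c(0, 0, 0),
                                                          c(4, 0, 0)),
                                                    c(1, 1))),
                 "vertex-free")
  expect_null(v2)
  expect_message(v3 <- find_initial_vertex(make_fixture("chain")),
                 "vertex-free")
  expect_null(v3)
})

test_that("every vertex of a random equal-radius blob appears in the
           brute-force empty-circumsphere enumeration", {
  mol <- make_fixture("random_blob", n = 20, r = 1.4, seed = 3)
  v <- find_initial_vertex(mol)
  oracle <- ordinary_voronoi_oracle(mol$centers)
  pos <- do.call(rbind, lapply(oracle$vertices, `[[`, "center"))
  dmin <- min(sqrt(rowSums(sweep(pos, 2, c(v$x, v$y, v$z))^2)))
  expect_lt(dmin, 1e-6)
})
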