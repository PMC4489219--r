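test_that("two-generator diagram is a single bisector sheet", {
  vd <- compute_awvd(molecule(rbind(c(0, 0, 0), c(5, 0, 0)), c(1, 2)))
  expect_equal(nrow(vd$vertices), 0L)
  expect_equal(nrow(vd$edges), 0L)
  expect_equal(nrow(vd$faces), 1L)
  expect_equal(length(vd$cells), 2L)
  # bisector crosses the center line where surface clearances agree: x = 2
  expect_equal(vd$faces$ax_x, 2, tolerance = 1e-12)
  expect_equal(vd$faces$axis_rho, 1, tolerance = 1e-12)
})

test_that("equal-radius diagram equals the ordinary Voronoi diagram of the
           centers, combinatorially and geometrically", {
  mol <- make_fixture("random_blob", n = 14, r = 1.4, seed = 3)
  vd <- compute_awvd(mol)
  oracle <- ordinary_voronoi_oracle(mol$centers)
  akeys <- vapply(vd$vertex_atoms, function(a) paste(a, collapse = "_"),
                  character(1))
  okeys <- vapply(oracle$vertices, function(v) paste(v$atoms, collapse = "_"),
                  character(1))
  expect_identical(sort(akeys), sort(okeys))
  ov <- do.call(rbind, lapply(oracle$vertices, `[[`, "center"))
  av <- as.matrix(vd$vertices[, c("x", "y", "z")])
  expect_equal(av[match(okeys, akeys), ], ov, tolerance = 1e-6,
               ignore_attr = TRUE)
  # vertex-incident edges (the oracle detects edges locally at vertices;
  # vertex-free far lines are clipped on both sides)
  ve <- !is.na(vd$edges$v1) | !is.na(vd$edges$v2)
  etr <- sort(unique(paste(vd$edges$a1, vd$edges$a2,
                           vd$edges$a3, sep = "_")[ve]))
  expect_identical(etr, oracle$edge_triples)
})

test_that("vertex tangent spheres and sampled edge points are empty and
           equidistant", {
  mol <- make_fixture("random_blob", n = 20, seed = 11)
  vd <- compute_awvd(mol)
  W <- vorocav:::weighted_dists(as.matrix(vd$vertices[, c("x", "y", "z")]),
                                mol)
  expect_true(all(apply(W, 1, min) >= vd$vertices$rho - 1e-6))
  for (ei in vd$edges$id) {
    s <- vorocav:::edge_samples(vd, ei, 9)
    W <- vorocav:::weighted_dists(s$pts, mol)
    tri <- unlist(vd$edges[vd$edges$id == ei, c("a1", "a2", "a3")])
    expect_lt(max(abs(W[, tri] - s$rho)), 1e-6)
    expect_true(all(apply(W, 1, min) >= s$rho - 1e-6 * (1 + abs(s$rho))))
  }
})

test_that("a uniform radius offset leaves combinatorics and geometry fixed", {
  mol <- make_fixture("random_blob", n = 14, seed = 3, r = 1.4)
  vd <- compute_awvd(mol)
  for (delta in c(0.5, 1.4)) {
    mo <- mol; mo$radii <- mol$radii + delta
    vo <- compute_awvd(mo)
    expect_equal(nrow(vo$vertices), nrow(vd$vertices))
    expect_equal(sort(paste(vo$edges$a1, vo$edges$a2, vo$edges$a3, vo$edges$comp)),
                 sort(paste(vd$edges$a1, vd$edges$a2, vd$edges$a3, vd$edges$comp)))
    expect_equal(sort(paste(vo$faces$a1, vo$faces$a2)),
                 sort(paste(vd$faces$a1, vd$faces$a2)))
    expect_equal(as.matrix(vo$vertices[, c("x", "y", "z")]),
                 as.matrix(vd$vertices[, c("x", "y", "z")]),
                 tolerance = 1e-8)
    expect_equal(vo$vertices$rho, vd$vertices$rho - delta, tolerance = 1e-8)
  }
})

test_that("radial-edge style incidence closes: vertices have >= 4 incident
           edges, edge triples bound exactly the three pair faces", {
  mol <- make_fixture("random_blob", n = 15, seed = 9)
  vd <- compute_awvd(mol)
  inc <- table(factor(c(vd$edges$v1, vd$edges$v2),
                      levels = vd$vertices$id))
  expect_true(all(inc >= 4))
  fkey <- paste(vd$faces$a1, vd$faces$a2)
  for (ei in seq_len(nrow(vd$edges))) {
    tri <- sort(unlist(vd$edges[ei, c("a1", "a2", "a3")]))
    prs <- c(paste(tri[1], tri[2]), paste(tri[1], tri[3]),
             paste(tri[2], tri[3]))
    expect_true(all(prs %in% fkey))
  }
  # face edge lists point back to edges carrying the pair
  for (fi in seq_len(nrow(vd$faces))) {
    for (ei in vd$face_edges[[fi]]) {
      tri <- unlist(vd$edges[vd$edges$id == ei, c("a1", "a2", "a3")])
      expect_true(all(c(vd$faces$a1[fi], vd$faces$a2[fi]) %in% tri))
    }
  }
})

test_that("symmetric cages resolve their degenerate vertices", {
  vd <- compute_awvd(make_fixture("octa_cage"))
  expect_equal(nrow(vd$vertices), 1L)
  expect_true(vd$vertices$degenerate)
  expect_equal(vd$vertices$rho, 1, tolerance = 1e-9)
  expect_length(vd$vertex_atoms[[1]], 6L)
  expect_equal(nrow(vd$edges), 8L)   # one spoke per octahedron face
  expect_equal(unique(round(vd$edges$rho_min, 9)),
               round(2 * sqrt(6) / 3 - 1, 9))
})

test_that("oversized inputs are rejected with a clear message", {
  big <- molecule(matrix(rnorm(3 * 121, sd = 20), ncol = 3), 1)
  expect_error(compute_awvd(big), "max_atoms")
})
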