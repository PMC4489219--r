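test_that("pair, triple and cell thresholds match their closed forms", {
  # two radius-1 atoms 4 A apart: the probe passes at (4 - 2)/2 = 1
  qt2 <- dualize(compute_awvd(molecule(rbind(c(0, 0, 0), c(4, 0, 0)),
                                       c(1, 1))))
  expect_equal(beta_threshold(qt2, "edge", 1L), 1, tolerance = 1e-9)
  # equilateral triple side 4: minimum clearance along the dual Voronoi edge
  # is at the centroid, circumradius 4/sqrt(3) minus radius
  m3 <- molecule(rbind(c(0, 0, 0), c(4, 0, 0), c(2, 2 * sqrt(3), 0)),
                 c(1, 1, 1))
  qt3 <- dualize(compute_awvd(m3))
  expect_equal(qt3$faces$rho, 4 / sqrt(3) - 1, tolerance = 1e-9)
  # tetra cage cell: the dual vertex tangent radius
  qt4 <- dualize(compute_awvd(make_fixture("tetra_cage")))
  expect_equal(qt4$cells$rho, sqrt(6) / 2 - 1, tolerance = 1e-9)
})

test_that("overlapping atoms have a negative threshold and stay members at
           beta = 0", {
  qt <- dualize(compute_awvd(molecule(rbind(c(0, 0, 0), c(1, 0, 0)),
                                      c(1, 1))))
  expect_equal(qt$edges$rho, -0.5, tolerance = 1e-9)
  bc <- extract_beta_complex(qt, 0)
  expect_true(all(bc$edge_in))
})

test_that("the whole quasi-triangulation is recovered at huge beta and
           negative beta errors", {
  qt <- dualize(compute_awvd(make_fixture("random_blob", n = 15, seed = 4)))
  bc <- extract_beta_complex(qt, 1e6)
  expect_true(all(bc$edge_in) && all(bc$face_in) && all(bc$cell_in))
  expect_error(extract_beta_complex(qt, -0.1), "non-negative")
})

test_that("ring at beta = 1.4 keeps the wall edges and drops the
           hole-spanning faces", {
  mol <- make_fixture("ring", n = 8, R = 3, r = 1)
  qt <- dualize(compute_awvd(mol))
  bc <- extract_beta_complex(qt, 1.4)
  # consecutive-pair gaps: clearance 3*sin(pi/8) - 1, far below the probe
  consec <- abs(qt$edges$a1 - qt$edges$a2) %in% c(1, 7)
  expect_equal(sort(unique(round(qt$edges$rho[consec], 3))),
               round(3 * sin(pi / 8) - 1, 3))
  expect_true(all(bc$edge_in[consec]))
  # every face spans the hole: minimum clearance ~ R - r = 2 > 1.4
  expect_true(all(qt$faces$rho > 1.9))
  expect_false(any(bc$face_in))
})

test_that("membership is nested along a beta sweep", {
  qt <- dualize(compute_awvd(make_fixture("random_blob", n = 30, seed = 6)))
  prev <- NULL
  for (b in seq(0, 3, by = 0.1)) {
    bc <- extract_beta_complex(qt, b)
    cur <- c(bc$vertex_in, bc$edge_in, bc$face_in, bc$cell_in)
    if (!is.null(prev)) expect_false(any(prev & !cur))
    prev <- cur
  }
})

test_that("equal-radius membership agrees with a brute-force alpha-complex
           oracle", {
  mol <- make_fixture("random_blob", n = 9, r = 1.3, seed = 8,
                      extent = 2.6)
  qt <- dualize(compute_awvd(mol))
  # oracle thresholds by dense search over the equidistant loci
  for (k in seq_len(min(6, nrow(qt$edges)))) {
    rho_o <- alpha_threshold_oracle(mol, c(qt$edges$a1[k], qt$edges$a2[k]))
    expect_equal(qt$edges$rho[k], rho_o, tolerance = 0.05)
  }
  for (k in seq_len(min(4, nrow(qt$faces)))) {
    rho_o <- alpha_threshold_oracle(mol, unlist(qt$faces[k, c("a1", "a2",
                                                              "a3")]))
    expect_equal(qt$faces$rho[k], rho_o, tolerance = 0.05)
  }
  # membership at probe values away from any threshold
  for (b in c(0.4, 1.1, 2.3)) {
    bc <- extract_beta_complex(qt, b)
    margin <- 0.06
    for (k in seq_len(min(6, nrow(qt$edges)))) {
      if (abs(qt$edges$rho[k] - b) < margin) next
      rho_o <- alpha_threshold_oracle(mol, c(qt$edges$a1[k], qt$edges$a2[k]))
      expect_equal(bc$edge_in[k], b >= rho_o)
    }
  }
})

test_that("cage boundary is watertight once beta exceeds the face
           thresholds", {
  qt <- dualize(compute_awvd(make_fixture("octa_cage")))
  bc <- extract_beta_complex(qt, 0.8)   # faces at 0.633 all members
  expect_equal(length(bc$boundary_faces), 8L)
  # each boundary edge (atom pair on the boundary) borders an even number of
  # boundary triangles
  prs <- rbind(bc$boundary_triplets[, c(1, 2)],
               bc$boundary_triplets[, c(1, 3)],
               bc$boundary_triplets[, c(2, 3)])
  cnt <- table(paste(pmin(prs[, 1], prs[, 2]), pmax(prs[, 1], prs[, 2])))
  expect_true(all(cnt %% 2 == 0))
})
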