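test_that("trimming keeps exactly the bisector portions beyond the probe", {
  mol <- molecule(rbind(c(0, 0, 0), c(4, 0, 0)), c(1, 1))
  vd <- compute_awvd(mol)
  # delta = 0.5: the face midpoint (clearance 1.0) survives
  vc <- trim_complement(vd, 0.5)
  fp <- vc$face_portions[[1]]
  expect_equal(length(vc$face_portions), 1L)
  expect_false(fp$crossing)
  expect_true(fp$unbounded)
  # delta = 1.2: retained portion starts at the closed-form clip circle
  # h with sqrt(2^2 + h^2) - 1 = 1.2 (equal radii: tau = d/2)
  vc2 <- trim_complement(vd, 1.2)
  fp2 <- vc2$face_portions[[1]]
  expect_true(fp2$crossing)
  h_expect <- sqrt(2.2^2 - 2^2)
  expect_equal(min(fp2$h), h_expect, tolerance = 1e-6)
})

test_that("octa cage classifies by probe size with the analytic escape
           bottleneck", {
  vd <- compute_awvd(make_fixture("octa_cage"))
  # escape bottleneck through a triangular face: 2*sqrt(6)/3 - 1
  expect_equal(unique(round(vd$edges$rho_min, 9)),
               round(2 * sqrt(6) / 3 - 1, 9))
  vc8 <- trim_complement(vd, 0.8)
  expect_equal(sum(!vc8$components$unbounded), 1L)
  expect_equal(sum(vc8$components$unbounded), 1L)
  voids <- classify_voids(vc8)
  expect_length(voids, 1L)
  expect_equal(voids[[1]]$atoms, 1:6)
  vc5 <- trim_complement(vd, 0.5)
  expect_equal(nrow(vc5$components), 1L)
  expect_length(classify_voids(vc5), 0L)
})

test_that("probe growth can only create or merge voids on the cage", {
  vd <- compute_awvd(make_fixture("octa_cage"))
  n5 <- length(classify_voids(trim_complement(vd, 0.5)))
  n8 <- length(classify_voids(trim_complement(vd, 0.8)))
  expect_gte(n8, n5)
  expect_equal(c(n5, n8), c(0L, 1L))
})

test_that("a chain encloses nothing at any probe below the spacing", {
  vd <- compute_awvd(make_fixture("chain"))
  for (delta in c(0.3, 0.9, 1.4)) {
    vc <- trim_complement(vd, delta)
    expect_equal(nrow(vc$components), 1L)
    expect_true(all(vc$components$unbounded))
  }
})

test_that("near-critical probe radii trigger an instability warning", {
  vd <- compute_awvd(make_fixture("octa_cage"))
  expect_warning(trim_complement(vd, 2 * sqrt(6) / 3 - 1 + 1e-8),
                 "unstable")
})

test_that("void counts match the flood-fill oracle on seeded blobs away
           from critical radii", {
  checked <- 0L
  for (s in c(4, 9, 17)) {
    mol <- make_fixture("random_blob", n = 30, seed = s)
    vd <- compute_awvd(mol)
    for (delta in c(0.5, 1.0)) {
      res <- compare_void_counts(mol, vd, delta)
      expect_true(res != "mismatch",
                  label = sprintf("seed %d delta %.1f: %s", s, delta, res))
      if (res == "agree") checked <- checked + 1L
    }
  }
  expect_gt(checked, 3L)
})

test_that("voronoi graph of a star component is a tree and euler_poincare
           matches hand counts", {
  to8 <- trim_complement(compute_awvd(make_fixture("octa_cage")), 0.8)
  void_id <- to8$components$id[!to8$components$unbounded]
  vg <- build_voronoi_graph(to8, void_id)
  ep <- euler_poincare(vg)
  expect_equal(ep$components, 1L)
  expect_equal(vg$handles, 0L)
  # pure graph examples
  path <- igraph::make_graph(~ a - b, b - c, c - d, d - e)
  expect_equal(euler_poincare(path), list(components = 1L, handles = 0L))
  theta <- igraph::make_graph(c(1, 2, 1, 2, 1, 2), directed = FALSE)
  expect_equal(euler_poincare(theta), list(components = 1L, handles = 2L))
})

test_that("ring at delta = 1.4 carries one channel through the hole", {
  vd <- compute_awvd(make_fixture("ring", n = 8, R = 3, r = 1))
  vc <- trim_complement(vd, 1.4)
  ch <- detect_channels(vc)
  expect_length(ch, 1L)
  cv <- ch[[1]]
  expect_equal(length(cv$openings), 2L)   # mirror-symmetric: even count
  expect_equal(cv$handles, 0L)
  bn <- bottleneck(cv)
  expect_equal(bn$radius, 2.0, tolerance = 1e-3)   # closed form R - r
  expect_lt(max(abs(bn$position)), 0.01)
  # openings sit near the two mouths of the hole, on opposite sides
  zs <- vapply(cv$openings, function(o) o$position[3], numeric(1))
  expect_true(prod(sign(zs)) < 0)
  expect_equal(cv$atoms, 1:8)
})

test_that("scaled ring scales its bottleneck: R = 5 gives 4.0", {
  vd <- compute_awvd(make_fixture("ring", n = 8, R = 5, r = 1))
  vc <- trim_complement(vd, 1.4)
  ch <- detect_channels(vc)
  expect_length(ch, 1L)
  expect_equal(bottleneck(ch[[1]])$radius, 4.0, tolerance = 1e-3)
})

test_that("chain has no channels and bottleneck/spine refuse voids", {
  vc <- trim_complement(compute_awvd(make_fixture("chain")), 1.4)
  expect_length(detect_channels(vc), 0L)
  void <- classify_voids(trim_complement(compute_awvd(
    make_fixture("octa_cage")), 0.8))[[1]]
  expect_error(bottleneck(void), "channel")
  expect_error(spine(void), "channel")
})

test_that("spine sweep radii equal the exhaustive nearest-atom distance", {
  mol <- make_fixture("ring", n = 8, R = 3, r = 1)
  vc <- trim_complement(compute_awvd(mol), 1.4)
  cv <- detect_channels(vc)[[1]]
  for (p in spine(cv)) {
    d <- vorocav:::weighted_dists(p$points, mol)
    expect_lt(max(abs(apply(d, 1, min) - p$sweep_radius)), 1e-9)
    expect_true(all(p$sweep_radius >= vc$delta - 1e-9))
  }
  # the spine threads the hole along the axis
  expect_gt(diff(range(vapply(spine(cv), function(p)
    range(p$points[, 3]), numeric(2)))), 3)
})

test_that("interior subgraph cycle rank matches an independent recount", {
  vc <- trim_complement(compute_awvd(make_fixture("ring")), 1.4)
  cv <- detect_channels(vc)[[1]]
  g <- cv$graph
  expect_equal(igraph::ecount(g) - igraph::vcount(g) +
                 igraph::components(g)$no,
               vorocav:::graph_cycle_rank(g))
})
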