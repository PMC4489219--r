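test_that("union volume and area closed forms for one and two spheres", {
  v1 <- vdw_volume_area(molecule(matrix(c(0, 0, 0), 1), 1))
  expect_equal(v1$volume, 4 * pi / 3, tolerance = 1e-6)
  expect_equal(v1$area, 4 * pi, tolerance = 1e-6)
  expect_equal(v1$method, "analytic")
  # two unit spheres 1 A apart: lens 5*pi/12, caps of height 1/2
  v2 <- vdw_volume_area(molecule(rbind(c(0, 0, 0), c(1, 0, 0)), 1))
  expect_equal(v2$volume, 9 * pi / 4, tolerance = 1e-6)
  expect_equal(v2$area, 6 * pi, tolerance = 1e-6)
  v3 <- vdw_volume_area(molecule(rbind(c(0, 0, 0), c(10, 0, 0)), 1))
  expect_equal(v3$volume, 8 * pi / 3, tolerance = 1e-6)
  expect_equal(v3$area, 8 * pi, tolerance = 1e-6)
})

test_that("the adaptive ray-cast path agrees with closed forms and reports
           its error", {
  # force the adaptive path on an overlapping triple (caps overlap)
  mol <- molecule(rbind(c(0, 0, 0), c(1.2, 0, 0), c(0.6, 1.0, 0)), 1)
  va <- vdw_volume_area(mol, n_dirs = 60000L)
  expect_equal(va$method, "adaptive")
  mc <- mc_region_volume(function(p) {
    inb <- rep(FALSE, nrow(p))
    for (i in 1:3) inb <- inb |
        rowSums(sweep(p, 2, mol$centers[i, ])^2) <= 1
    inb
  }, rbind(c(-1.1, -1.1, -1.1), c(2.3, 2.1, 1.1)), n = 2e5, seed = 3)
  expect_lt(abs(va$volume - mc$estimate), 3 * mc$se + va$error)
})

test_that("Monte-Carlo oracle behaves: unit ball, empty set, half-space", {
  mc <- mc_region_volume(function(p) rowSums(p^2) <= 1,
                         rbind(c(-1, -1, -1), c(1, 1, 1)), n = 1e6, seed = 4)
  expect_lt(abs(mc$estimate - 4 * pi / 3), 3 * mc$se)
  z <- mc_region_volume(function(p) rep(FALSE, nrow(p)),
                        rbind(c(0, 0, 0), c(1, 1, 1)), n = 1000, seed = 1)
  expect_equal(z$estimate, 0)
  expect_equal(z$se, 0)
  hs <- mc_region_volume(function(p) p[, 1] <= 0.5,
                         rbind(c(0, 0, 0), c(1, 1, 1)), n = 1e5, seed = 2)
  expect_lt(abs(hs$estimate - 0.5), 3 * hs$se)
  expect_error(mc_region_volume(function(p) TRUE,
                                rbind(c(0, 0, 0), c(1, 1, 1)), n = 10), "n")
  # reproducible under a fixed seed
  expect_identical(mc_region_volume(function(p) rowSums(p^2) <= 1,
                                    rbind(c(-1, -1, -1), c(1, 1, 1)),
                                    n = 1e4, seed = 9),
                   mc_region_volume(function(p) rowSums(p^2) <= 1,
                                    rbind(c(-1, -1, -1), c(1, 1, 1)),
                                    n = 1e4, seed = 9))
})

test_that("octa void volume agrees with the Monte-Carlo oracle within 3 SE", {
  mol <- make_fixture("octa_cage")
  vc <- trim_complement(compute_awvd(mol), 0.8)
  cav <- classify_voids(vc)[[1]]
  met <- cavity_metrics(cav, vc)
  mc <- mc_region_volume(function(p) clearance(p, mol) > 0.8,
                         rbind(rep(-0.45, 3), rep(0.45, 3)),
                         n = 1e6, seed = 7)
  expect_lt(abs(met$volume - mc$estimate), 3 * mc$se + met$error)
  expect_equal(met$atoms, 1:6)
  expect_gt(met$boundary_area, 0)
  expect_gt(met$buried_area, 0)
  expect_lt(met$buried_area, met$boundary_area)  # r^2 < (r + delta)^2 patches
})

test_that("void volume strictly decreases as the probe grows", {
  vd <- compute_awvd(make_fixture("octa_cage"))
  vols <- vapply(c(0.70, 0.80, 0.90, 0.95), function(delta) {
    vc <- trim_complement(vd, delta)
    cavity_metrics(classify_voids(vc)[[1]], vc, n_dirs = 20000L)$volume
  }, numeric(1))
  expect_true(all(diff(vols) < 0))
})

test_that("uniform scaling multiplies volumes by s^3 and areas by s^2", {
  s <- 2
  mol <- make_fixture("octa_cage")
  mols <- molecule(mol$centers * s, mol$radii * s, name = "octa_x2")
  vc1 <- trim_complement(compute_awvd(mol), 0.8)
  vc2 <- trim_complement(compute_awvd(mols), 0.8 * s)
  m1 <- cavity_metrics(classify_voids(vc1)[[1]], vc1)
  m2 <- cavity_metrics(classify_voids(vc2)[[1]], vc2)
  expect_equal(m2$volume, s^3 * m1$volume, tolerance = 1e-3)
  expect_equal(m2$boundary_area, s^2 * m1$boundary_area, tolerance = 1e-3)
  v1 <- vdw_volume_area(mol); v2 <- vdw_volume_area(mols)
  expect_equal(v2$volume, s^3 * v1$volume, tolerance = 1e-9)
  expect_equal(v2$area, s^2 * v1$area, tolerance = 1e-9)
})

test_that("vdW metrics are additive for far-apart sub-molecules", {
  m1 <- make_fixture("random_blob", n = 6, seed = 2)
  m2 <- make_fixture("random_blob", n = 5, seed = 3)
  shifted <- m2$centers + 60
  joint <- molecule(rbind(m1$centers, shifted), c(m1$radii, m2$radii))
  vj <- vdw_volume_area(joint, n_dirs = 60000L)
  va <- vdw_volume_area(m1, n_dirs = 60000L)
  vb <- vdw_volume_area(molecule(shifted, m2$radii), n_dirs = 60000L)
  tol <- va$error + vb$error + vj$error + 1e-3
  expect_lt(abs(vj$volume - (va$volume + vb$volume)), tol)
  expect_lt(abs(vj$area - (va$area + vb$area)), tol)
})
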