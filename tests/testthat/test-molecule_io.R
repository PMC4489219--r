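pdb_line <- function(serial, name, resn, resi, x, y, z, el,
                     record = "ATOM", alt = " ") {
  sprintf("%-6s%5d %-4s%s%-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, name, alt, resn, resi, x, y, z, el)
}

test_that("read_pdb accepts well-formed records and assigns table radii", {
  txt <- c(pdb_line(1, "N", "ALA", 1, 0, 0, 0, "N"),
           pdb_line(2, "CA", "ALA", 1, 1.5, 0, 0, "C"),
           pdb_line(3, "O", "ALA", 1, 3.0, 0, 0, "O"))
  mol <- read_pdb(txt)
  expect_s3_class(mol, "vc_molecule")
  expect_equal(n_atoms(mol), 3L)
  rt <- radius_table()
  expect_equal(mol$radii, unname(rt$radii[c("N", "C", "O")]))
  expect_equal(mol$serial, 1:3)
})

test_that("waters are excluded by default and retained on request", {
  txt <- c(pdb_line(1, "C1", "LIG", 1, 0, 0, 0, "C", record = "HETATM"),
           pdb_line(2, "O", "HOH", 2, 5, 0, 0, "O", record = "HETATM"))
  expect_equal(n_atoms(read_pdb(txt)), 1L)
  expect_equal(n_atoms(read_pdb(txt, include_waters = TRUE)), 2L)
  only_water <- pdb_line(1, "O", "HOH", 1, 0, 0, 0, "O", record = "HETATM")
  expect_error(read_pdb(only_water), "no atoms accepted|no parsable")
})

test_that("alternate locations other than blank/A are dropped", {
  txt <- c(pdb_line(1, "CA", "ALA", 1, 0, 0, 0, "C", alt = "A"),
           pdb_line(2, "CA", "ALA", 1, 0.2, 0, 0, "C", alt = "B"),
           pdb_line(3, "CB", "ALA", 1, 4, 0, 0, "C"))
  mol <- read_pdb(txt)
  expect_equal(mol$serial, c(1L, 3L))
})

test_that("unknown elements fall back with a warning", {
  txt <- c(pdb_line(1, "X1", "LIG", 1, 0, 0, 0, "XX"),
           pdb_line(2, "C1", "LIG", 1, 4, 0, 0, "C"))
  expect_warning(mol <- read_pdb(txt), "unknown element")
  expect_equal(mol$radii[1], radius_table()$default)
})

test_that("radius table file overrides and rejects bad entries", {
  f <- withr::local_tempfile(lines = c("C 1.90", "QQ 1.10"))
  rt <- radius_table(f)
  expect_equal(unname(rt$radii["C"]), 1.90)
  expect_equal(unname(rt$radii["QQ"]), 1.10)
  bad <- withr::local_tempfile(lines = "C -1")
  expect_error(radius_table(bad), "positive")
})

test_that("fixtures have their stated closed-form geometry", {
  mo <- make_fixture("octa_cage", r = 1, d = 2)
  expect_equal(n_atoms(mo), 6L)
  expect_setequal(rowSums(abs(mo$centers)), rep(2, 6))
  expect_equal(mo$radii, rep(1, 6))
  mr <- make_fixture("ring", n = 8, R = 3, r = 1, jitter = 0)
  expect_equal(n_atoms(mr), 8L)
  expect_equal(sqrt(rowSums(mr$centers^2)), rep(3, 8))
  mt <- make_fixture("tetra_cage", r = 1, edge = 2)
  d <- as.matrix(dist(mt$centers))
  expect_equal(unname(d[upper.tri(d)]), rep(2, 6))
})

test_that("fixtures are deterministic under a fixed seed", {
  expect_identical(make_fixture("random_blob", n = 30, seed = 7),
                   make_fixture("random_blob", n = 30, seed = 7))
  expect_false(identical(make_fixture("random_blob", n = 30, seed = 7),
                         make_fixture("random_blob", n = 30, seed = 8)))
  expect_identical(make_fixture("ring", seed = 5), make_fixture("ring", seed = 5))
})

test_that("jittered ring centers stay within 10x jitter of the ideal circle", {
  mr <- make_fixture("ring", n = 8, R = 3, r = 1, jitter = 1e-4)
  dev <- abs(sqrt(mr$centers[, 1]^2 + mr$centers[, 2]^2) - 3)
  expect_lt(max(c(dev, abs(mr$centers[, 3]))), 10 * 1e-4)
})

test_that("containment preprocessing removes engulfed atoms idempotently", {
  mol <- molecule(rbind(c(0, 0, 0), c(0.2, 0, 0), c(5, 0, 0)),
                  c(2, 0.5, 1))
  expect_message(m1 <- preprocess_molecule(mol), "removed 1")
  expect_equal(n_atoms(m1), 2L)
  expect_equal(attr(m1, "removed"), 2L)
  m2 <- preprocess_molecule(m1)
  expect_equal(m2$centers, m1$centers)
  expect_length(attr(m2, "removed"), 0L)
})

test_that("invalid fixture parameters error", {
  expect_error(make_fixture("ring", n = 2), "n >= 3")
  expect_error(make_fixture("octa_cage", r = -1), "positive")
  expect_error(molecule(matrix(0, 1, 3), -1), "positive")
})
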