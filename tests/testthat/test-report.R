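test_that("octa cage voids-only run reports the void and omits channels", {
  rep <- run_analysis(list(fixture = list(kind = "octa_cage"), probe = 0.8,
                           channels = FALSE))
  expect_s3_class(rep, "vc_report")
  expect_length(rep$voids, 1L)
  expect_null(rep$channels)
  expect_equal(rep$voids[[1]]$atoms, 1:6)
  expect_equal(rep$header$n_atoms, 6L)
  expect_equal(rep$header$probe, 0.8)
  txt <- render_text(rep)
  expect_true(any(grepl("^voids: 1$", txt)))
  expect_false(any(grepl("^channels:", txt)))
})

test_that("ring channels-only run reports openings, handles, bottleneck", {
  rep <- run_analysis(list(fixture = list(kind = "ring"), probe = 1.4,
                           voids = FALSE))
  expect_length(rep$channels, 1L)
  ch <- rep$channels[[1]]
  expect_equal(ch$n_openings, 2L)
  expect_equal(ch$handles, 0L)
  expect_equal(ch$bottleneck_radius, 2.0, tolerance = 1e-3)
  expect_true(all(unlist(ch$boundary_triplets) %in% 1:8))
  txt <- render_text(rep)
  expect_true(any(grepl("^channels: 1$", txt)))
})

test_that("invalid configurations are rejected", {
  expect_error(run_analysis(list(fixture = list(kind = "chain"),
                                 probe = -1)), ">= 0")
  expect_error(run_analysis(list(fixture = list(kind = "chain"),
                                 voids = FALSE, channels = FALSE)),
               "at least one")
  expect_error(run_analysis(list(probe = 1)), "input.*fixture")
})

test_that("empty-cavity runs render zero counts in both sections", {
  rep <- run_analysis(list(fixture = list(kind = "chain"), probe = 1.4))
  txt <- render_text(rep)
  expect_true(any(grepl("^voids: 0$", txt)))
  expect_true(any(grepl("^channels: 0$", txt)))
})

test_that("structured output parses back and re-renders byte-identically", {
  for (fx in list(list(kind = "octa_cage"), list(kind = "ring"))) {
    rep <- run_analysis(list(fixture = fx, probe = if (fx$kind == "ring")
      1.4 else 0.8))
    rt <- parse_structured(render_structured(rep))
    expect_identical(render_text(rep), render_text(rt))
  }
})

test_that("equal-volume cavities order by smallest contributing serial", {
  oc <- make_fixture("octa_cage")
  two <- molecule(rbind(oc$centers + 40, oc$centers), rep(1, 12),
                  name = "two_cages")
  vd <- compute_awvd(two)
  vc <- trim_complement(vd, 0.8)
  voids <- classify_voids(vc)
  expect_length(voids, 2L)
  mets <- lapply(voids, cavity_metrics, vc = vc)
  expect_equal(mets[[1]]$volume, mets[[2]]$volume, tolerance = 1e-6)
  # the report ordering rule: volume descending, tie by smallest serial
  vols <- vapply(mets, `[[`, numeric(1), "volume")
  first <- vapply(mets, function(m) min(m$atoms), numeric(1))
  ord <- order(-round(vols, 9), first)
  expect_equal(min(mets[[ord[1]]]$atoms), 1)
})

test_that("QTF cache reruns render identical reports", {
  qtf <- withr::local_tempfile(fileext = ".qtf")
  cfg <- list(fixture = list(kind = "octa_cage"), probe = 0.8, qtf = qtf)
  r1 <- run_analysis(cfg)
  expect_true(file.exists(qtf))
  r2 <- run_analysis(cfg)   # second run consumes the cache
  expect_identical(render_text(r1), render_text(r2))
  expect_identical(render_structured(r1), render_structured(r2))
})

test_that("fixture specs parse and the CLI main returns proper statuses", {
  fx <- vorocav:::parse_fixture_spec("ring(n=8,R=3,r=1)")
  expect_equal(fx, list(kind = "ring", n = 8, R = 3, r = 1))
  expect_error(vorocav:::parse_fixture_spec("Ring[3]"), "cannot parse")
  skip_if_not_installed("optparse")
  out <- withr::local_tempfile(fileext = ".txt")
  st <- cli_main(c("--fixture", "tetra_cage", "--probe", "0.2", "--voids",
                   "--quiet", "--out", out))
  expect_equal(st, 0L)
  expect_true(any(grepl("^voids: 1$", readLines(out))))
  expect_equal(suppressMessages(cli_main(c("--probe", "1.4"))), 1L)
  expect_equal(suppressMessages(cli_main(c("--fixture", "chain", "--probe",
                                           "-2"))), 1L)
})
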