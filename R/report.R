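#' Run the full cavity analysis pipeline
#'
#' Executes kernel (Voronoi diagram, quasi-triangulation, beta-complex),
#' trimmer (Voronoi complement at the probe radius), classifier (voids and
#' channels from the complement components and the Voronoi graph) and
#' evaluator (volumes and areas) in order, and assembles a report. A probe
#' radius of zero yields van der Waals cavities, a positive radius
#' Lee-Richards (solvent accessible) cavities.
#'
#' @param config a list: `input` (PDB path or text) or `fixture` (list with
#'   `kind`, parameters, `seed`); `probe` radius in Angstrom (default 1.4);
#'   `voids`, `channels` logical flags (at least one `TRUE`); `qtf` optional
#'   cache path (read when present, written otherwise); `radii` optional
#'   radius-table file; `name` optional molecule name; `seed` integer.
#' @return An object of class `vc_report`.
#' @export
run_analysis <- function(config) {
  t_start <- proc.time()[["elapsed"]]
  cfg <- config
  cfg$probe <- cfg$probe %||% 1.4
  cfg$voids <- cfg$voids %||% TRUE
  cfg$channels <- cfg$channels %||% TRUE
  if (!is.numeric(cfg$probe) || cfg$probe < 0)
    stop("probe radius must be >= 0")
  if (!isTRUE(cfg$voids) && !isTRUE(cfg$channels))
    stop("at least one of voids/channels must be requested")
  warnings_seen <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  mol <- if (!is.null(cfg$fixture)) {
    fx <- cfg$fixture
    do.call(make_fixture, c(list(kind = fx$kind,
                                 seed = fx$seed %||% cfg$seed %||% 1L),
                            fx[setdiff(names(fx), c("kind", "seed"))]))
  } else if (!is.null(cfg$input)) {
    rt <- if (!is.null(cfg$radii)) radius_table(cfg$radii) else radius_table()
    collect(read_pdb(cfg$input, rtable = rt, name = cfg$name))
  } else stop("config needs either $input (PDB) or $fixture")
  t0 <- proc.time()[["elapsed"]]
  vd <- collect(compute_awvd(mol))
  qt <- NULL
  if (!is.null(cfg$qtf) && file.exists(cfg$qtf)) {
    qt <- tryCatch(read_qtf(cfg$qtf), error = function(e) NULL)
    if (!is.null(qt) &&
        !isTRUE(all.equal(qt$molecule$centers, mol$centers,
                          tolerance = 1e-9)))
      qt <- NULL                      # stale cache: recompute
  }
  if (is.null(qt)) {
    qt <- dualize(vd)
    if (!is.null(cfg$qtf)) write_qtf(qt, cfg$qtf)
  }
  bc <- extract_beta_complex(qt, cfg$probe)
  t_kernel <- proc.time()[["elapsed"]] - t0
  t0 <- proc.time()[["elapsed"]]
  vc <- collect(trim_complement(vd, cfg$probe))
  t_trim <- proc.time()[["elapsed"]] - t0
  t0 <- proc.time()[["elapsed"]]
  voids <- list(); channels <- list(); pockets <- list()
  if (isTRUE(cfg$voids)) voids <- classify_voids(vc)
  if (isTRUE(cfg$channels)) {
    channels <- collect(detect_channels(vc))
    pockets <- attr(channels, "pockets") %||% list()
  }
  t_classify <- proc.time()[["elapsed"]] - t0
  t0 <- proc.time()[["elapsed"]]
  vdw <- vdw_volume_area(mol)
  void_entries <- lapply(voids, function(cv) {
    met <- cavity_metrics(cv, vc)
    list(kind = "void", volume = met$volume,
         boundary_area = met$boundary_area, buried_area = met$buried_area,
         atoms = sort(met$atoms), n_atoms = length(met$atoms),
         method = met$method, error = met$error)
  })
  chan_entries <- lapply(channels, function(cv) {
    met <- cavity_metrics(cv, vc)
    trip <- bc$boundary_triplets
    if (length(trip) > 0) {
      sel <- apply(matrix(trip %in% cv$atoms, nrow(trip)), 1L, all)
      trip <- matrix(mol$serial[trip[sel, , drop = FALSE]], ncol = 3)
    } else trip <- matrix(integer(0), 0, 3)
    list(kind = "channel",
         openings = lapply(cv$openings, function(o)
           list(position = zap_negzero(round(unname(o$position), 4)),
                clearance = o$clearance)),
         n_openings = length(cv$openings), handles = cv$handles,
         bottleneck_radius = cv$bottleneck$radius,
         bottleneck_position = zap_negzero(round(unname(cv$bottleneck$position), 4)),
         spine = lapply(cv$spine, function(p)
           list(points = unname(p$points), sweep_radius = p$sweep_radius)),
         boundary_triplets = trip,
         volume = met$volume, boundary_area = met$boundary_area,
         buried_area = met$buried_area, atoms = sort(met$atoms),
         n_atoms = length(met$atoms), method = met$method, error = met$error)
  })
  t_measure <- proc.time()[["elapsed"]] - t0
  # deterministic report order: volume descending, ties by smallest serial
  ord <- function(entries) {
    if (length(entries) == 0L) return(entries)
    vols <- vapply(entries, function(e) -e$volume, numeric(1))
    first <- vapply(entries, function(e) min(e$atoms), numeric(1))
    entries[order(vols, first)]
  }
  structure(list(
    schema = "vorocav-report/1",
    header = list(
      molecule = mol$name, n_atoms = n_atoms(mol), probe = cfg$probe,
      mode = if (cfg$probe == 0) "van der Waals" else "Lee-Richards",
      vdw_volume = vdw$volume, vdw_area = vdw$area,
      vdw_method = vdw$method,
      timings = list(kernel = t_kernel, trim = t_trim,
                     classify = t_classify, measure = t_measure,
                     total = proc.time()[["elapsed"]] - t_start)),
    voids = if (isTRUE(cfg$voids)) ord(void_entries) else NULL,
    channels = if (isTRUE(cfg$channels)) ord(chan_entries) else NULL,
    n_pockets = length(pockets),
    warnings = warnings_seen
  ), class = "vc_report")
}

#' @export
print.vc_report <- function(x, ...) {
  cat(render_text(x), sep = "\n")
  invisible(x)
}

zap_negzero <- function(x) { x[x == 0] <- 0; x }

#' Render a report as fixed-order text
#'
#' Section order is header, voids, channels; cavities are pre-sorted by
#' volume (descending, ties by smallest contributing serial). Timings are
#' excluded so cached and uncached runs render identically.
#'
#' @param report a `vc_report`.
#' @param timings include the timing lines?
#' @return character vector of lines.
#' @export
render_text <- function(report, timings = FALSE) {
  h <- report$header
  ln <- c("vorocav report (schema vorocav-report/1)",
          sprintf("molecule: %s", h$molecule),
          sprintf("atoms: %d", h$n_atoms),
          sprintf("probe radius: %.3f A (%s mode)", h$probe, h$mode),
          sprintf("vdW volume: %.4f A^3 (%s)", h$vdw_volume, h$vdw_method),
          sprintf("vdW area: %.4f A^2", h$vdw_area))
  if (timings)
    ln <- c(ln, sprintf("time: %.2f s (kernel %.2f, trim %.2f, classify %.2f, measure %.2f)",
                        h$timings$total, h$timings$kernel, h$timings$trim,
                        h$timings$classify, h$timings$measure))
  fmt_cav <- function(e, i) {
    out <- c(sprintf("  %s %d:", e$kind, i),
             sprintf("    volume: %.4f A^3 (+/- %.2g)", e$volume, e$error),
             sprintf("    boundary area: %.4f A^2", e$boundary_area),
             sprintf("    buried area: %.4f A^2", e$buried_area),
             sprintf("    contributing atoms (%d): %s", e$n_atoms,
                     paste(e$atoms, collapse = " ")))
    if (e$kind == "channel") {
      out <- c(out,
               sprintf("    openings: %d", e$n_openings),
               vapply(e$openings, function(o)
                 sprintf("      at (%.3f, %.3f, %.3f), clearance %.3f A",
                         o$position[1], o$position[2], o$position[3],
                         o$clearance), character(1)),
               sprintf("    handles: %d", e$handles),
               sprintf("    bottleneck: %.4f A at (%.3f, %.3f, %.3f)",
                       e$bottleneck_radius, e$bottleneck_position[1],
                       e$bottleneck_position[2], e$bottleneck_position[3]),
               sprintf("    spine: %d path(s), %d samples",
                       length(e$spine),
                       sum(vapply(e$spine, function(p) nrow(p$points),
                                  numeric(1)))),
               sprintf("    boundary triplets: %d", nrow(e$boundary_triplets)))
    }
    out
  }
  if (!is.null(report$voids)) {
    ln <- c(ln, sprintf("voids: %d", length(report$voids)))
    for (i in seq_along(report$voids))
      ln <- c(ln, fmt_cav(report$voids[[i]], i))
  }
  if (!is.null(report$channels)) {
    ln <- c(ln, sprintf("channels: %d", length(report$channels)))
    for (i in seq_along(report$channels))
      ln <- c(ln, fmt_cav(report$channels[[i]], i))
    ln <- c(ln, sprintf("pockets (1 opening, not channels): %d",
                        report$n_pockets))
  }
  if (length(report$warnings) > 0)
    ln <- c(ln, "warnings:", paste0("  ", report$warnings))
  ln
}

#' Render / parse the machine-readable report
#'
#' The structured document mirrors the report exactly (minus timings) and
#' parses back to an equivalent object, so text re-rendered from the parsed
#' document is byte-identical.
#'
#' @param report a `vc_report`.
#' @return `render_structured`: a JSON string. `parse_structured`: a
#'   `vc_report`.
#' @export
render_structured <- function(report) {
  x <- unclass(report)
  x$header$timings <- NULL
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname render_structured
#' @param json a JSON string or path produced by [render_structured()].
#' @export
parse_structured <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  fix_cav <- function(e) {
    e$atoms <- as.integer(unlist(e$atoms))
    if (!is.null(e$boundary_triplets)) {
      bt <- e$boundary_triplets
      if (is.list(bt)) bt <- do.call(rbind, bt)
      if (is.null(bt)) bt <- matrix(integer(0), 0, 3)
      e$boundary_triplets <- matrix(as.integer(bt), ncol = 3)
    }
    if (!is.null(e$spine))
      e$spine <- lapply(e$spine, function(p) {
        p$points <- matrix(unlist(p$points), ncol = 3,
                           byrow = !is.matrix(p$points))
        p
      })
    e
  }
  if (!is.null(x$voids)) x$voids <- lapply(x$voids, fix_cav)
  if (!is.null(x$channels)) x$channels <- lapply(x$channels, fix_cav)
  x$header$timings <- list(total = NA_real_)
  x$warnings <- as.character(unlist(x$warnings))
  structure(x, class = "vc_report")
}
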