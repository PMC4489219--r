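#' Synthetic sphere-set fixtures with known cavity geometry
#'
#' Deterministic generators used throughout the test-suite and the worked
#' examples. Each kind has closed-form geometry:
#'
#' * `tetra_cage`: 4 atoms of radius `r` at the vertices of a regular
#'   tetrahedron of edge `edge`; the central tangent sphere has radius
#'   `edge * sqrt(6)/4 - r` (0.2247 for the defaults).
#' * `octa_cage`: 6 atoms of radius `r` at `(+/-d,0,0), (0,+/-d,0), (0,0,+/-d)`;
#'   center clearance `d - r`, escape bottleneck through a triangular face
#'   `2*d/sqrt(6)*... = d*sqrt(2/3)*sqrt(2) ...` (0.633 for d=2, r=1).
#' * `ring`: `n` atoms of radius `r` equally spaced on a circle of radius `R`
#'   in the z=0 plane; the through-hole along z has bottleneck clearance
#'   `R - r`. A seeded positional `jitter` (default 1e-4 A) breaks the exact
#'   cocircular degeneracy.
#' * `chain`: `n` collinear atoms of radius `r` spaced `spacing` along x;
#'   encloses nothing.
#' * `random_blob`: `n` atoms with centers drawn uniformly in a ball of radius
#'   `extent` (minimum center separation `min_sep`, rejection sampling) and
#'   radii uniform in `rrange`; fully determined by `seed`.
#'
#' @param kind one of `"tetra_cage"`, `"octa_cage"`, `"ring"`, `"chain"`,
#'   `"random_blob"`.
#' @param ... kind-specific parameters, see Details above.
#' @param seed integer seed controlling all randomness (jitter, blob draws).
#' @return A [molecule()].
#' @examples
#' make_fixture("octa_cage")
#' make_fixture("ring", n = 8, R = 3, r = 1)
#' @export
make_fixture <- function(kind = c("tetra_cage", "octa_cage", "ring", "chain",
                                  "random_blob"), ..., seed = 1L) {
  kind <- match.arg(kind)
  p <- list(...)
  with_local_seed(seed, switch(kind,
    tetra_cage = fixture_tetra(p), octa_cage = fixture_octa(p),
    ring = fixture_ring(p), chain = fixture_chain(p),
    random_blob = fixture_blob(p)))
}

# run expr under a temporary RNG state so fixtures never disturb user RNG
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  force(expr)
}

fixture_tetra <- function(p) {
  r <- p$r %||% 1; edge <- p$edge %||% 2
  if (r <= 0 || edge <= 0) stop("tetra_cage: r and edge must be positive")
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  molecule(v * edge / (2 * sqrt(2)), r, name = "tetra_cage")
}

fixture_octa <- function(p) {
  r <- p$r %||% 1; d <- p$d %||% 2
  if (r <= 0 || d <= 0) stop("octa_cage: r and d must be positive")
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
             c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  molecule(v * d, r, name = "octa_cage")
}

fixture_ring <- function(p) {
  n <- p$n %||% 8L; R <- p$R %||% 3; r <- p$r %||% 1
  jitter <- p$jitter %||% 1e-4
  if (n < 3L) stop("ring: need n >= 3 atoms")
  if (R <= 0 || r <= 0 || jitter < 0) stop("ring: invalid parameters")
  th <- 2 * pi * (seq_len(n) - 1L) / n
  ctr <- cbind(R * cos(th), R * sin(th), 0)
  if (jitter > 0)
    ctr <- ctr + matrix(stats::runif(3L * n, -jitter, jitter), ncol = 3L)
  molecule(ctr, r, name = "ring")
}

fixture_chain <- function(p) {
  n <- p$n %||% 6L; spacing <- p$spacing %||% 2.5; r <- p$r %||% 1
  if (n < 2L) stop("chain: need n >= 2 atoms")
  if (spacing <= 0 || r <= 0) stop("chain: invalid parameters")
  molecule(cbind(spacing * (seq_len(n) - (n + 1) / 2), 0, 0), r,
           name = "chain")
}

fixture_blob <- function(p) {
  n <- p$n %||% 30L; extent <- p$extent %||% 3.5
  rrange <- p$rrange %||% c(1.2, 1.9); min_sep <- p$min_sep %||% 0.8
  if (!is.null(p$r)) rrange <- c(p$r, p$r)   # equal-radius blobs
  if (n < 1L || extent <= 0 || any(rrange <= 0))
    stop("random_blob: invalid parameters")
  ctr <- matrix(NA_real_, n, 3L)
  placed <- 0L; tries <- 0L
  while (placed < n) {
    x <- stats::runif(3, -extent, extent)
    if (sum(x^2) <= extent^2 &&
        (placed == 0L ||
         min(rowSums((ctr[seq_len(placed), , drop = FALSE] -
                      rep(x, each = placed))^2)) >= min_sep^2)) {
      placed <- placed + 1L
      ctr[placed, ] <- x
    }
    tries <- tries + 1L
    if (tries > 200000L) stop("random_blob: cannot place atoms; lower n")
  }
  radii <- stats::runif(n, rrange[1], rrange[2])
  preprocess_molecule(molecule(ctr, radii, name = "random_blob"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
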