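#' Deterministic toy epithelia
#'
#' Small constructed tissues used throughout the test suite and examples:
#' `hex_patch` (concentric hexagonal rings of equal cells around a center
#' cell: sizes 1, 7, 19, 37, ...), `strip` (a single row of equally spaced
#' cells along x), and `ring_unit` (one center cell plus its 6 contact
#' neighbours, i.e. `hex_patch` with one ring).
#'
#' @param kind One of `"hex_patch"`, `"strip"`, `"ring_unit"`.
#' @param size Number of cells (`hex_patch` rounds up to a full ring
#'   count; `ring_unit` ignores it and always builds 7).
#' @param cell_radius Radius of every cell (world units).
#' @param jitter Uniform positional jitter amplitude as a fraction of the
#'   radius (default 0: exact lattice).
#' @param seed Seed for the jitter draw.
#' @return An `epithelium`.
#' @examples
#' ep <- make_fixture("hex_patch", 7)
#' neighbors(ep, ep$id[1], mode = "contact")
#' @export
make_fixture <- function(kind = c("hex_patch", "strip", "ring_unit"),
                         size = 7L, cell_radius = 10, jitter = 0, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(size >= 1L, size <= 1000L, cell_radius > 0)
  s <- 2 * cell_radius
  if (kind == "ring_unit") { kind <- "hex_patch"; size <- 7L }
  if (kind == "hex_patch") {
    pts <- matrix(c(0, 0), ncol = 2)
    ring <- 1L
    while (nrow(pts) < size) {
      # ring k: 6k points on the hexagon of circumradius k*s
      corners <- ring * s * cbind(cos(seq(0, 5) * pi / 3), sin(seq(0, 5) * pi / 3))
      for (c0 in seq_len(6)) {
        a <- corners[c0, ]; b <- corners[c0 %% 6 + 1, ]
        frac <- (seq_len(ring) - 1L) / ring
        pts <- rbind(pts, cbind(a[1] + frac * (b[1] - a[1]),
                                a[2] + frac * (b[2] - a[2])))
      }
      ring <- ring + 1L
    }
    x <- pts[, 1]; y <- pts[, 2]
  } else { # strip
    x <- (seq_len(size) - 1L) * s
    y <- rep(0, size)
  }
  if (jitter > 0) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(restore_global_seed(old))
    set.seed(as.integer(seed))
    x <- x + runif(length(x), -jitter, jitter) * cell_radius
    y <- y + runif(length(y), -jitter, jitter) * cell_radius
  }
  pad <- 2 * s
  domain <- c(min(x) - pad, max(x) + pad, min(y) - pad, max(y) + pad)
  n <- length(x)
  new_epithelium(id = seq_len(n), x = x, y = y,
                 r = rep(cell_radius, n), fate = rep(FATE_PRECURSOR, n),
                 target = rep(cell_radius, n), unit = rep(NA_integer_, n),
                 domain = domain, avg_cell_size = cell_radius)
}
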