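#' @title The precursor epithelium
#' @description
#' The epithelium is an off-lattice sheet of circular cells on a fixed
#' axis-aligned rectangular domain. Internally it is a column-store: parallel
#' vectors of id, position, radius, fate, growth target and unit membership,
#' which keeps per-cycle updates vectorized. Use [as.data.frame.epithelium()]
#' for a tidy cell table.
#' @name epithelium
NULL

new_epithelium <- function(id, x, y, r, fate, target, unit,
                           domain, avg_cell_size, next_id = max(id, 0L) + 1L) {
  structure(list(id = as.integer(id), x = as.numeric(x), y = as.numeric(y),
                 r = as.numeric(r), fate = as.integer(fate),
                 target = as.numeric(target), unit = as.integer(unit),
                 evmask = integer(length(id)),
                 domain = as.numeric(domain), avg_cell_size = avg_cell_size,
                 next_id = as.integer(next_id)),
            class = "epithelium")
}

n_cells <- function(ep) length(ep$id)

#' Generate a relaxed precursor epithelium
#'
#' Seeds `min_cell_count` undifferentiated circular cells on a jittered
#' square grid sized to hold them at the mean radius, samples radii from a
#' normal distribution truncated below at `0.2 * avg_cell_size`, and relaxes
#' the packing (see [relax_epithelium()]) until pairwise overlaps fall below
#' tolerance. Identical `(seed, parameters)` give identical output.
#'
#' @param min_cell_count Positive integer number of cells.
#' @param avg_cell_size Mean cell radius in world units (> 0).
#' @param cell_size_variance Standard deviation of cell radii (>= 0).
#' @param seed Integer seed for the radius and jitter draws.
#' @param relax_iters Maximum relaxation iterations (stops early once the
#'   overlap tolerance is met).
#' @param overlap_tolerance Maximum allowed pairwise overlap depth after
#'   relaxation; defaults to 5% of `avg_cell_size`.
#' @return An object of class `epithelium`.
#' @examples
#' ep <- generate_epithelium(50, 10, 2, seed = 1)
#' summary(ep)
#' @export
generate_epithelium <- function(min_cell_count, avg_cell_size,
                                cell_size_variance, seed = 1L,
                                relax_iters = 2000L,
                                overlap_tolerance = 0.05 * avg_cell_size) {
  if (!is.numeric(min_cell_count) || length(min_cell_count) != 1L ||
      is.na(min_cell_count) || min_cell_count < 1 ||
      min_cell_count != round(min_cell_count))
    stop("generate_epithelium: 'min_cell_count' must be a positive integer",
         call. = FALSE)
  if (!is.numeric(avg_cell_size) || length(avg_cell_size) != 1L ||
      is.na(avg_cell_size) || avg_cell_size <= 0)
    stop("generate_epithelium: 'avg_cell_size' must be > 0", call. = FALSE)
  if (!is.numeric(cell_size_variance) || length(cell_size_variance) != 1L ||
      is.na(cell_size_variance) || cell_size_variance < 0)
    stop("generate_epithelium: 'cell_size_variance' must be >= 0", call. = FALSE)

  n <- as.integer(min_cell_count)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_global_seed(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)

  r <- pmax(rnorm(n, avg_cell_size, cell_size_variance), 0.2 * avg_cell_size)
  # 5% headroom over one mean diameter: a jammed exact-contact grid cannot
  # relax its size jitter away inside hard walls
  spacing <- 2.1 * avg_cell_size
  ncol <- ceiling(sqrt(n))
  nrow <- ceiling(n / ncol)
  domain <- c(0, ncol * spacing, 0, nrow * spacing)
  if (n == 1L) {
    x <- mean(domain[1:2]); y <- mean(domain[3:4])
  } else {
    ix <- (seq_len(n) - 1L) %% ncol
    iy <- (seq_len(n) - 1L) %/% ncol
    x <- (ix + 0.5) * spacing + runif(n, -0.25, 0.25) * avg_cell_size
    y <- (iy + 0.5) * spacing + runif(n, -0.25, 0.25) * avg_cell_size
  }
  ep <- new_epithelium(id = seq_len(n), x = x, y = y, r = r,
                       fate = rep(FATE_PRECURSOR, n), target = r,
                       unit = rep(NA_integer_, n),
                       domain = domain, avg_cell_size = avg_cell_size)
  relax_epithelium(ep, max_iters = relax_iters,
                   overlap_tolerance = overlap_tolerance)
}

#' Relax cell positions by pairwise repulsion and weak attraction
#'
#' Iteratively displaces cells: overlapping pairs repel along their center
#' line proportionally to overlap depth (spring constant `k_rep`, split
#' between the partners), while nearby pairs whose gap exceeds
#' `gap_threshold` attract weakly (`k_att`). Cells are clamped inside the
#' rectangular domain. Iteration stops when the maximum pairwise overlap
#' depth falls below `overlap_tolerance` or after `max_iters` iterations;
#' non-convergence is reported in the attached diagnostics, not raised.
#'
#' @param ep An `epithelium`.
#' @param max_iters Maximum number of iterations.
#' @param overlap_tolerance Stop once max overlap depth <= this (world units).
#' @param k_rep,k_att Repulsion/attraction spring constants.
#' @param gap_threshold Gap beyond which weak attraction acts; defaults to
#'   half the average cell size.
#' @param attract_range Maximum gap at which attraction is considered;
#'   defaults to one average cell size.
#' @param clamp If `TRUE` (the default, used while packing the initial
#'   sheet), cells are clamped inside the rectangular domain. If `FALSE`
#'   (used during the developmental sweep, when growing eye units
#'   legitimately push the tissue outward), cells move freely; the domain is
#'   kept unchanged as the fixed reference frame of the tissue.
#' @return The relaxed `epithelium`, with an attribute `"relax_info"`
#'   (list: `iters`, `max_overlap`, `converged`, per-iteration total
#'   `displacement`).
#' @export
relax_epithelium <- function(ep, max_iters = 200L,
                             overlap_tolerance = 0.05 * ep$avg_cell_size,
                             k_rep = 0.5, k_att = 0.01,
                             gap_threshold = 0.5 * ep$avg_cell_size,
                             attract_range = ep$avg_cell_size,
                             clamp = TRUE) {
  stopifnot(inherits(ep, "epithelium"))
  if (n_cells(ep) == 0L) stop("relax_epithelium: empty epithelium", call. = FALSE)
  res <- relax_cpp(ep$x, ep$y, ep$r, ep$domain, k_rep, k_att,
                   gap_threshold, attract_range, overlap_tolerance,
                   as.integer(max_iters), isTRUE(clamp))
  ep$x <- res$x
  ep$y <- res$y
  attr(ep, "relax_info") <- list(iters = res$iters,
                                 max_overlap = res$max_overlap,
                                 converged = res$max_overlap <= overlap_tolerance,
                                 displacement = res$displacement)
  ep
}

#' Grow cells for one cycle, dividing oversized precursors
#'
#' Each cycle a cell closes a fraction `cell_growth_rate` of the gap to its
#' growth ceiling: undifferentiated precursors grow toward `cell_max_size`,
#' specified cells toward their own `target_radius`. A precursor that
#' reaches `cell_max_size` divides into two daughters of radius
#' `cell_max_size / sqrt(2)` (the daughters' areas sum to the parent's),
#' displaced along a random axis; at the small per-cycle fractions typical
#' of a sweep the approach is asymptotic and cells do not divide — division
#' kicks in at larger growth rates, or for cells seeded at the ceiling.
#' Specified cells never divide. With `rate = 0` the tissue is static.
#'
#' @param ep An `epithelium`.
#' @param cell_growth_rate Per-cycle growth fraction (>= 0).
#' @param cell_max_size Division size for precursors (> 0).
#' @param streams Optional RNG stream environment (see the simulation loop);
#'   when `NULL`, the current RNG is used for division axes.
#' @return A list with components `epithelium` and `divided_ids` (ids of the
#'   precursors that divided this cycle; each division adds one cell).
#' @export
grow_step <- function(ep, cell_growth_rate, cell_max_size, streams = NULL) {
  stopifnot(inherits(ep, "epithelium"))
  if (!is.numeric(cell_growth_rate) || cell_growth_rate < 0)
    stop("grow_step: 'cell_growth_rate' must be >= 0", call. = FALSE)
  if (!is.numeric(cell_max_size) || cell_max_size <= 0)
    stop("grow_step: 'cell_max_size' must be > 0", call. = FALSE)
  if (cell_growth_rate == 0)
    return(list(epithelium = ep, divided_ids = integer(0)))
  frac <- min(cell_growth_rate, 1)

  prec <- ep$fate == FATE_PRECURSOR
  ep$r[prec] <- ep$r[prec] + frac * pmax(cell_max_size - ep$r[prec], 0)
  spec <- !prec & ep$r < ep$target
  ep$r[spec] <- ep$r[spec] + frac * (ep$target[spec] - ep$r[spec])

  div <- which(prec & ep$r >= cell_max_size * (1 - 1e-3))
  divided_ids <- ep$id[div]
  if (length(div)) {
    nd <- length(div)
    theta <- if (is.null(streams)) runif(nd, 0, 2 * pi) else
      with_stream(streams, "growth", runif(nd, 0, 2 * pi))
    rd <- cell_max_size / sqrt(2)
    off <- 0.5 * rd
    dx <- off * cos(theta); dy <- off * sin(theta)
    new_ids <- ep$next_id + seq_len(nd) - 1L
    # parent keeps its id and shifts one way; the new daughter takes the other
    ep$id <- c(ep$id, new_ids)
    ep$x <- c(ep$x, ep$x[div] - dx); ep$x[div] <- ep$x[div] + dx
    ep$y <- c(ep$y, ep$y[div] - dy); ep$y[div] <- ep$y[div] + dy
    ep$r[div] <- rd
    ep$r <- c(ep$r, rep(rd, nd))
    ep$fate <- c(ep$fate, rep(FATE_PRECURSOR, nd))
    ep$target <- c(ep$target, rep(rd, nd))
    ep$unit <- c(ep$unit, rep(NA_integer_, nd))
    ep$evmask <- c(ep$evmask, ep$evmask[div])
    ep$next_id <- ep$next_id + nd
  }
  list(epithelium = ep, divided_ids = divided_ids)
}

#' Neighbouring cells
#'
#' @param ep An `epithelium`.
#' @param cell_id Id of the focal cell.
#' @param mode `"contact"` (center distance <= sum of radii + `contact_slack`),
#'   `"delaunay"` (Delaunay triangulation neighbours, via \pkg{deldir}), or
#'   `"radius"` (centers within `radius` of the focal center).
#' @param radius Search radius for `mode = "radius"`.
#' @param contact_slack Extra tolerance for contact detection; defaults to
#'   10% of the average cell size.
#' @return Integer vector of neighbouring cell ids (sorted; symmetric in the
#'   sense that `b` is a neighbour of `a` iff `a` is a neighbour of `b`).
#' @export
neighbors <- function(ep, cell_id,
                      mode = c("contact", "delaunay", "radius"),
                      radius = NULL, contact_slack = 0.1 * ep$avg_cell_size) {
  stopifnot(inherits(ep, "epithelium"))
  mode <- match.arg(mode)
  i <- match(cell_id, ep$id)
  if (is.na(i)) stop("neighbors: unknown cell id ", cell_id, call. = FALSE)
  if (mode == "contact") {
    prs <- contact_pairs_cpp(ep$x, ep$y, ep$r, i, contact_slack)
    return(sort(ep$id[prs[, 2]]))
  }
  if (mode == "radius") {
    if (is.null(radius) || !is.numeric(radius) || radius < 0)
      stop("neighbors: 'radius' must be a non-negative number", call. = FALSE)
    idx <- within_radius_cpp(ep$x, ep$y, ep$x[i], ep$y[i], radius)
    return(sort(ep$id[setdiff(idx, i)]))
  }
  # delaunay
  if (!requireNamespace("deldir", quietly = TRUE))
    stop("neighbors: mode 'delaunay' requires the deldir package", call. = FALSE)
  if (n_cells(ep) < 2L) return(integer(0))
  dd <- deldir::deldir(ep$x, ep$y, suppressMsge = TRUE)
  sg <- dd$delsgs
  nb <- c(sg$ind2[sg$ind1 == i], sg$ind1[sg$ind2 == i])
  sort(ep$id[unique(nb)])
}

#' Write an epithelium to a versioned plain-text cell table
#'
#' Format: one magic line `#OMMATID-EPITHELIUM v1 {json}` carrying the
#' domain, average cell size and id counter, then a CSV table with columns
#' `id,x,y,radius,fate,target_radius,unit_id,alive`. Numeric fields use 17
#' significant digits so that a save/load round trip is bit-exact.
#'
#' @param ep An `epithelium`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_epithelium <- function(ep, path) {
  stopifnot(inherits(ep, "epithelium"))
  # %.17g so doubles survive the round trip bit-exactly
  hdr <- sprintf(
    '{"domain":[%.17g,%.17g,%.17g,%.17g],"avg_cell_size":%.17g,"next_id":%d}',
    ep$domain[1], ep$domain[2], ep$domain[3], ep$domain[4],
    ep$avg_cell_size, ep$next_id)
  fate_chr <- FATE_LEVELS[ep$fate]
  unit_chr <- ifelse(is.na(ep$unit), "", as.character(ep$unit))
  rows <- sprintf("%d,%.17g,%.17g,%.17g,%s,%.17g,%s,TRUE",
                  ep$id, ep$x, ep$y, ep$r, fate_chr, ep$target, unit_chr)
  writeLines(c(paste0("#OMMATID-EPITHELIUM v1 ", hdr),
               "id,x,y,radius,fate,target_radius,unit_id,alive", rows), path)
  invisible(path)
}

#' Read an epithelium written by [write_epithelium()]
#'
#' @param path File path.
#' @return An `epithelium`.
#' @export
read_epithelium <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1], "#OMMATID-EPITHELIUM v1 "))
    stop("read_epithelium: '", path,
         "': line 1 is not an '#OMMATID-EPITHELIUM v1' header", call. = FALSE)
  hdr <- jsonlite::fromJSON(sub("^#OMMATID-EPITHELIUM v1 ", "", lines[1]))
  hdr$domain <- as.numeric(hdr$domain)
  hdr$avg_cell_size <- as.numeric(hdr$avg_cell_size)
  tab <- read.csv(text = lines[-1], stringsAsFactors = FALSE)
  needed <- c("id", "x", "y", "radius", "fate", "target_radius", "unit_id", "alive")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("read_epithelium: '", path, "': missing column(s) ",
         paste(missing, collapse = ", "), " in the cell table (line 2)",
         call. = FALSE)
  fate <- match(tab$fate, FATE_LEVELS)
  if (anyNA(fate)) {
    bad <- which(is.na(fate))[1]
    stop("read_epithelium: '", path, "': unknown fate '", tab$fate[bad],
         "' at table row ", bad, call. = FALSE)
  }
  unit <- suppressWarnings(as.integer(tab$unit_id))
  ep <- new_epithelium(id = tab$id, x = tab$x, y = tab$y, r = tab$radius,
                       fate = fate, target = tab$target_radius, unit = unit,
                       domain = hdr$domain, avg_cell_size = hdr$avg_cell_size,
                       next_id = hdr$next_id)
  ep
}

#' @export
as.data.frame.epithelium <- function(x, ...) {
  data.frame(id = x$id, x = x$x, y = x$y, radius = x$r,
             fate = FATE_LEVELS[x$fate], target_radius = x$target,
             unit_id = x$unit, alive = TRUE, stringsAsFactors = FALSE)
}

#' @export
print.epithelium <- function(x, ...) {
  cat(sprintf("<epithelium: %d cells, domain [%g, %g] x [%g, %g], avg cell size %g>\n",
              n_cells(x), x$domain[1], x$domain[2], x$domain[3], x$domain[4],
              x$avg_cell_size))
  invisible(x)
}

#' @export
summary.epithelium <- function(object, ...) {
  tab <- table(factor(FATE_LEVELS[object$fate], levels = FATE_LEVELS))
  out <- list(n = n_cells(object), domain = object$domain,
              avg_cell_size = object$avg_cell_size, fates = tab,
              mean_radius = mean(object$r),
              max_overlap = max_overlap_cpp(object$x, object$y, object$r))
  class(out) <- "summary.epithelium"
  out
}

#' @export
print.summary.epithelium <- function(x, ...) {
  cat(sprintf("Epithelium: %d cells on [%g, %g] x [%g, %g]\n",
              x$n, x$domain[1], x$domain[2], x$domain[3], x$domain[4]))
  cat(sprintf("  mean radius %.3g (generation mean %.3g); max pairwise overlap %.3g\n",
              x$mean_radius, x$avg_cell_size, x$max_overlap))
  cat("  fates:", paste(sprintf("%s=%d", names(x$fates), x$fates), collapse = " "),
      "\n")
  invisible(x)
}
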