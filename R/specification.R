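#' @title Differentiation events
#' @description
#' The four distance-gated differentiation events fired behind the furrow:
#' greedy founder (R8) selection under an exclusion radius, nearest-neighbour
#' photoreceptor wave recruitment, contact-layer border recruitment, and
#' apoptosis of undifferentiated precursors. Each exported function is a pure
#' decision procedure on the epithelium; the simulation loop applies the
#' resulting fate changes and logs them.
#' @name specification
NULL

# distance from a set of points to the nearest domain edge
edge_distance <- function(x, y, domain) {
  pmin(x - domain[1], domain[2] - x, y - domain[3], domain[4] - y)
}

#' Select new founder (R8) cells from a furrow band
#'
#' A band precursor is eligible if its center is at least
#' `exclusion_radius` average cell diameters from every existing founder and
#' at least `min_distance_from_edge` diameters from every domain edge.
#' Selection is greedy: while eligible candidates remain, the candidate whose
#' minimum distance to the current founder set is smallest is selected (ties
#' broken by lowest id), so new units form as close to existing ones as the
#' exclusion allows. If no founder exists yet, the eligible cell nearest the
#' right (posterior) domain edge seeds the first unit.
#'
#' @param ep An `epithelium`.
#' @param band_ids Ids of the candidate precursor cells (typically one
#'   furrow band).
#' @param founder_ids Ids of all existing founders (possibly empty).
#' @param fp A [founder_params()] object.
#' @return Integer vector of newly selected founder ids, in selection order
#'   (possibly empty).
#' @export
select_founders <- function(ep, band_ids, founder_ids, fp) {
  stopifnot(inherits(ep, "epithelium"), inherits(fp, "founder_params"))
  excl <- diam_units(fp$exclusion_radius, ep$avg_cell_size)
  margin <- diam_units(fp$min_distance_from_edge, ep$avg_cell_size)

  idx <- match(band_ids, ep$id)
  idx <- idx[!is.na(idx)]
  idx <- idx[ep$fate[idx] == FATE_PRECURSOR]
  if (!length(idx)) return(integer(0))
  idx <- idx[edge_distance(ep$x[idx], ep$y[idx], ep$domain) >= margin]
  if (!length(idx)) return(integer(0))
  # order candidates by id so all ties resolve to the lowest id
  idx <- idx[order(ep$id[idx])]
  cx <- ep$x[idx]; cy <- ep$y[idx]; cid <- ep$id[idx]

  fidx <- match(founder_ids, ep$id)
  fidx <- fidx[!is.na(fidx)]
  # running minimum distance from each candidate to the founder set
  mind <- rep(Inf, length(idx))
  for (j in fidx) {
    mind <- pmin(mind, sqrt((cx - ep$x[j])^2 + (cy - ep$y[j])^2))
  }

  selected <- integer(0)
  taken <- rep(FALSE, length(idx))
  if (!length(fidx)) {
    # seed with the eligible cell nearest the right domain edge
    k <- which.max(cx)  # ids ascending, so which.max ties -> lowest id
    selected <- cid[k]
    taken[k] <- TRUE
    mind <- pmin(mind, sqrt((cx - cx[k])^2 + (cy - cy[k])^2))
  }
  repeat {
    ok <- !taken & mind >= excl
    if (!any(ok)) break
    k <- which(ok)[which.min(mind[which(ok)])]
    selected <- c(selected, cid[k])
    taken[k] <- TRUE
    mind <- pmin(mind, sqrt((cx - cx[k])^2 + (cy - cy[k])^2))
  }
  selected
}

#' Recruit one photoreceptor wave for a unit
#'
#' Candidates are undifferentiated precursors whose center lies within
#' `max_distance_from_r8` average cell diameters of the unit's founder;
#' the `selection_count` nearest (ties by lowest id) are recruited. Fewer are
#' recruited when the pool is smaller.
#'
#' @param ep An `epithelium`.
#' @param founder_id Id of the unit's founder cell.
#' @param wp A [wave_params()] object.
#' @param candidates Optional id subset to restrict the pool (used by the
#'   simulation loop to give contested cells to the nearest founder).
#' @return Integer vector of recruited cell ids (possibly empty).
#' @export
recruit_wave <- function(ep, founder_id, wp, candidates = NULL) {
  stopifnot(inherits(ep, "epithelium"), inherits(wp, "wave_params"))
  fi <- match(founder_id, ep$id)
  if (is.na(fi)) stop("recruit_wave: unknown founder id ", founder_id, call. = FALSE)
  if (wp$selection_count == 0L) return(integer(0))
  maxd <- diam_units(wp$max_distance_from_r8, ep$avg_cell_size)
  idx <- within_radius_cpp(ep$x, ep$y, ep$x[fi], ep$y[fi], maxd)
  idx <- idx[ep$fate[idx] == FATE_PRECURSOR]
  if (!is.null(candidates)) idx <- idx[ep$id[idx] %in% candidates]
  if (!length(idx)) return(integer(0))
  d <- sqrt((ep$x[idx] - ep$x[fi])^2 + (ep$y[idx] - ep$y[fi])^2)
  ord <- order(d, ep$id[idx])
  ep$id[idx[ord[seq_len(min(wp$selection_count, length(ord)))]]]
}

#' Recruit border-cell layers around a unit
#'
#' Layer 1 consists of the undifferentiated contact neighbours of the given
#' seed cells (the unit's specified photoreceptors); layer `k` of the contact
#' neighbours of layer `k - 1`. `n_layers` layers are returned.
#'
#' @param ep An `epithelium`.
#' @param seed_ids Ids of the unit's specified cells.
#' @param n_layers Number of layers (`border_radius`).
#' @param contact_slack Contact tolerance, defaulting to 10% of the average
#'   cell size.
#' @param exclude Ids never to recruit (cells contested away to another
#'   unit).
#' @return A list of integer vectors, one per layer, innermost first.
#' @export
recruit_border <- function(ep, seed_ids, n_layers,
                           contact_slack = 0.1 * ep$avg_cell_size,
                           exclude = integer(0)) {
  stopifnot(inherits(ep, "epithelium"))
  n_layers <- as.integer(n_layers)
  layers <- vector("list", max(n_layers, 0L))
  if (n_layers <= 0L) return(layers)
  frontier <- match(seed_ids, ep$id)
  frontier <- frontier[!is.na(frontier)]
  claimed <- ep$id[frontier]
  for (k in seq_len(n_layers)) {
    if (!length(frontier)) { layers[[k]] <- integer(0); next }
    prs <- contact_pairs_cpp(ep$x, ep$y, ep$r, frontier, contact_slack)
    nb <- unique(prs[, 2])
    nb <- nb[ep$fate[nb] == FATE_PRECURSOR]
    ids <- setdiff(ep$id[nb], c(claimed, exclude))
    layers[[k]] <- sort(ids)
    claimed <- c(claimed, ids)
    frontier <- match(ids, ep$id)
  }
  layers
}

#' Apply one cycle of apoptosis behind the furrow
#'
#' Every undifferentiated precursor whose center lies at or beyond
#' `distance_from_furrow` behind the furrow line dies independently with
#' probability `death_chance / 100`. Specified cells are never removed.
#'
#' @param ep An `epithelium`.
#' @param furrow_x Current furrow x position (world units).
#' @param dp A [death_params()] object.
#' @param streams Optional RNG stream environment; when `NULL` the current
#'   RNG is used.
#' @param eligible_ids Optional id subset (used for one-shot band semantics).
#' @return A list with `epithelium` (survivors) and `removed_ids`.
#' @export
apoptosis_step <- function(ep, furrow_x, dp, streams = NULL,
                           eligible_ids = NULL) {
  stopifnot(inherits(ep, "epithelium"), inherits(dp, "death_params"))
  behind <- ep$fate == FATE_PRECURSOR & ep$x >= furrow_x + dp$distance_from_furrow
  if (!is.null(eligible_ids)) behind <- behind & ep$id %in% eligible_ids
  idx <- which(behind)
  if (!length(idx) || dp$death_chance == 0)
    return(list(epithelium = ep, removed_ids = integer(0)))
  u <- if (is.null(streams)) runif(length(idx)) else
    with_stream(streams, "death", runif(length(idx)))
  kill <- idx[u < dp$death_chance / 100]
  removed <- ep$id[kill]
  if (length(kill)) {
    keep <- setdiff(seq_len(n_cells(ep)), kill)
    for (f in c("id", "x", "y", "r", "fate", "target", "unit", "evmask"))
      ep[[f]] <- ep[[f]][keep]
  }
  list(epithelium = ep, removed_ids = removed)
}

# Apply a specification fate to cells (internal; keeps transitions monotone).
specify_cells <- function(ep, ids, fate, target_radius, unit_id) {
  idx <- match(ids, ep$id)
  stopifnot(!anyNA(idx))
  if (any(ep$fate[idx] != FATE_PRECURSOR))
    stop("specify_cells: attempt to respecify a non-precursor cell", call. = FALSE)
  ep$fate[idx] <- fate
  ep$target[idx] <- pmax(target_radius, ep$r[idx])
  ep$unit[idx] <- unit_id
  ep
}
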