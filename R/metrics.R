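#' @title Layout metrics
#' @description
#' Quantitative summaries of a simulated eye layout: per-unit censuses,
#' founder spacing statistics, radial wave profiles, and a spatial
#' autocorrelation score of photoreceptor wave labels that separates
#' concentric ("expansion") from interleaved ("fusion") retinas.
#' @name metrics
NULL

# Rebuild a minimal simulation state from a bare cell table (e.g. a loaded
# epithelium file): unit membership and founders are recovered from the
# fate and unit_id columns. Enough for census/spacing/rendering; the event
# log is empty.
state_from_epithelium <- function(ep) {
  stopifnot(inherits(ep, "epithelium"))
  uids <- sort(unique(ep$unit[!is.na(ep$unit)]))
  units <- lapply(uids, function(u) {
    sel <- which(!is.na(ep$unit) & ep$unit == u)
    fid <- ep$id[sel[ep$fate[sel] == FATE_R8]]
    list(unit_id = u,
         founder_id = if (length(fid)) fid[1] else NA_integer_,
         founder_x0 = if (length(fid)) ep$x[match(fid[1], ep$id)] else NA_real_,
         members = list(WAVE1 = ep$id[sel[ep$fate[sel] == FATE_WAVE1]],
                        WAVE2 = ep$id[sel[ep$fate[sel] == FATE_WAVE2]],
                        WAVE3 = ep$id[sel[ep$fate[sel] == FATE_WAVE3]]),
         border_ids = ep$id[sel[ep$fate[sel] == FATE_BORDER]])
  })
  structure(list(epithelium = ep, units = units,
                 founder_ids = ep$id[ep$fate == FATE_R8],
                 furrow = furrow_state(ep$domain[1] - 1, 0, ep$domain[1]),
                 log = new_log(), initial_n = n_cells(ep),
                 divisions = 0L, deaths = 0L),
            class = "eye_sim")
}

#' Per-unit census
#'
#' One row per eye unit: fate counts, founder position, member centroid and
#' unit radius (maximum member distance to the founder).
#'
#' @param state An `eye_sim` object.
#' @return A data.frame with columns `unit_id`, `founder_id`, `n_wave1`,
#'   `n_wave2`, `n_wave3`, `n_border`, `founder_x`, `founder_y`,
#'   `centroid_x`, `centroid_y`, `unit_radius`. Zero rows when no units
#'   exist.
#' @export
census <- function(state) {
  stopifnot(inherits(state, "eye_sim"))
  ep <- state$epithelium
  rows <- lapply(state$units, function(u) {
    fi <- match(u$founder_id, ep$id)
    mem <- c(u$founder_id, unlist(u$members, use.names = FALSE), u$border_ids)
    mi <- match(mem, ep$id)
    d <- sqrt((ep$x[mi] - ep$x[fi])^2 + (ep$y[mi] - ep$y[fi])^2)
    data.frame(unit_id = u$unit_id, founder_id = u$founder_id,
               n_wave1 = length(u$members$WAVE1),
               n_wave2 = length(u$members$WAVE2),
               n_wave3 = length(u$members$WAVE3),
               n_border = length(u$border_ids),
               founder_x = ep$x[fi], founder_y = ep$y[fi],
               centroid_x = mean(ep$x[mi]), centroid_y = mean(ep$y[mi]),
               unit_radius = max(d))
  })
  if (!length(rows))
    return(data.frame(unit_id = integer(0), founder_id = integer(0),
                      n_wave1 = integer(0), n_wave2 = integer(0),
                      n_wave3 = integer(0), n_border = integer(0),
                      founder_x = numeric(0), founder_y = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      unit_radius = numeric(0)))
  do.call(rbind, rows)
}

#' Number of eye units
#'
#' @param state An `eye_sim` object.
#' @return Integer count of eye units (equivalently, of founders).
#' @export
unit_count <- function(state) {
  stopifnot(inherits(state, "eye_sim"))
  length(state$units)
}

#' Founder spacing statistics
#'
#' Pairwise and nearest-neighbour center distances among founder cells, in
#' world units. The nearest-neighbour coefficient of variation (`nn_cv`,
#' sd/mean) is the lattice regularity score: 0 for a perfect lattice,
#' larger for irregular seeding. With exactly two founders `nn_cv` is 0 by
#' convention; with fewer than two founders the statistics are `NA` (not an
#' error).
#'
#' @param state An `eye_sim` object, or an `epithelium` (founders taken from
#'   cell fates).
#' @return A list: `n` founders, `min`, `mean` (pairwise), `nn_mean`,
#'   `nn_cv`.
#' @export
founder_spacing <- function(state) {
  if (inherits(state, "eye_sim")) {
    ep <- state$epithelium
    fidx <- match(state$founder_ids, ep$id)
  } else {
    stopifnot(inherits(state, "epithelium"))
    ep <- state
    fidx <- which(ep$fate == FATE_R8)
  }
  n <- length(fidx)
  if (n < 2L)
    return(list(n = n, min = NA_real_, mean = NA_real_,
                nn_mean = NA_real_, nn_cv = NA_real_))
  d <- as.matrix(dist(cbind(ep$x[fidx], ep$y[fidx])))
  pw <- d[upper.tri(d)]
  diag(d) <- Inf
  nn <- apply(d, 1L, min)
  nn_cv <- if (n == 2L) 0 else sd(nn) / mean(nn)
  list(n = n, min = min(pw), mean = mean(pw), nn_mean = mean(nn),
       nn_cv = nn_cv)
}

#' Radial profile of photoreceptor waves within a unit
#'
#' Mean member center distance to the founder, per recruitment wave. In an
#' expansion-type (single-founder) eye the three waves form concentric
#' shells, so the means increase strictly from wave 1 to wave 3.
#'
#' @param state An `eye_sim` object.
#' @param unit_id Unit to profile.
#' @return Named numeric vector with entries `PR_WAVE1`, `PR_WAVE2`,
#'   `PR_WAVE3`; waves with no members are dropped.
#' @export
wave_radial_profile <- function(state, unit_id) {
  stopifnot(inherits(state, "eye_sim"))
  if (!is.numeric(unit_id) || length(unit_id) != 1L ||
      unit_id < 1 || unit_id > length(state$units))
    stop("wave_radial_profile: unknown unit ", unit_id, call. = FALSE)
  u <- state$units[[unit_id]]
  ep <- state$epithelium
  fi <- match(u$founder_id, ep$id)
  out <- c(PR_WAVE1 = NA_real_, PR_WAVE2 = NA_real_, PR_WAVE3 = NA_real_)
  for (k in 1:3) {
    mem <- u$members[[paste0("WAVE", k)]]
    if (length(mem)) {
      mi <- match(mem, ep$id)
      out[k] <- mean(sqrt((ep$x[mi] - ep$x[fi])^2 + (ep$y[mi] - ep$y[fi])^2))
    }
  }
  out[!is.na(out)]
}

#' Spatial autocorrelation of photoreceptor wave labels
#'
#' Moran's I of the wave index (1, 2, 3) over the k-nearest-neighbour graph
#' of all wave-recruited photoreceptors. Near 1 when wave types form
#' spatially coherent blocks (concentric expansion retinas); near 0 when
#' types are interleaved through a fused mosaic.
#'
#' @param state An `eye_sim` object.
#' @param k Number of nearest neighbours per cell (default 6, the contact
#'   number of a hexagonal packing).
#' @return Moran's I, or `NA` if fewer than `k + 2` wave cells exist or the
#'   labels are constant.
#' @export
wave_label_moran <- function(state, k = 6L) {
  stopifnot(inherits(state, "eye_sim"))
  ep <- state$epithelium
  idx <- which(ep$fate %in% c(FATE_WAVE1, FATE_WAVE2, FATE_WAVE3))
  m <- length(idx)
  if (m < k + 2L) return(NA_real_)
  z <- (ep$fate[idx] - FATE_WAVE1 + 1L)
  if (sd(z) == 0) return(NA_real_)
  z <- z - mean(z)
  d <- as.matrix(dist(cbind(ep$x[idx], ep$y[idx])))
  diag(d) <- Inf
  num <- 0
  for (i in seq_len(m)) {
    nb <- order(d[i, ])[seq_len(k)]
    num <- num + z[i] * sum(z[nb])
  }
  (m / (m * k)) * num / sum(z^2) * 1
}

#' Check cell-count conservation against the event log
#'
#' The census identity: initial count + logged divisions - logged deaths
#' must equal the final cell count, and every logged death must be of an
#' undifferentiated precursor (specified cells never die).
#'
#' @param state An `eye_sim` object.
#' @return `TRUE` invisibly; stops with a message if the ledger does not
#'   reconcile.
#' @export
check_conservation <- function(state) {
  stopifnot(inherits(state, "eye_sim"))
  recs <- event_log(state)
  kinds <- vapply(recs, `[[`, character(1), "kind")
  ndiv <- sum(lengths(lapply(recs[kinds == "DIVISION"], `[[`, "cell_ids")))
  ndeath <- sum(lengths(lapply(recs[kinds == "DEATH"], `[[`, "cell_ids")))
  expected <- state$initial_n + ndiv - ndeath
  if (expected != n_cells(state$epithelium))
    stop(sprintf("conservation violated: %d + %d - %d != %d",
                 state$initial_n, ndiv, ndeath, n_cells(state$epithelium)),
         call. = FALSE)
  # no specified cell may ever appear among removals
  dead <- unlist(lapply(recs[kinds == "DEATH"], `[[`, "cell_ids"))
  specified <- unlist(lapply(recs[kinds %in% c("FOUNDER", "WAVE1", "WAVE2",
                                               "WAVE3", "BORDER")],
                             `[[`, "cell_ids"))
  if (length(intersect(dead, specified)))
    stop("conservation: a specified cell appears among apoptosis removals",
         call. = FALSE)
  invisible(TRUE)
}

#' Export run metrics
#'
#' Writes the per-unit census as a tidy CSV and a run-level summary (unit
#' count, founder spacing, cell ledger, wave-label Moran's I) as JSON.
#'
#' @param state An `eye_sim` object.
#' @param census_path CSV output path.
#' @param summary_path Optional JSON output path.
#' @return `census_path`, invisibly.
#' @export
write_metrics <- function(state, census_path, summary_path = NULL) {
  cen <- census(state)
  utils::write.csv(cen, census_path, row.names = FALSE)
  if (!is.null(summary_path)) {
    sp <- founder_spacing(state)
    s <- list(n_cells = n_cells(state$epithelium),
              initial_n = state$initial_n,
              divisions = state$divisions, deaths = state$deaths,
              n_units = unit_count(state), cycles = state$furrow$cycle,
              founder_spacing = sp,
              wave_label_moran = wave_label_moran(state))
    jsonlite::write_json(s, summary_path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  invisible(census_path)
}
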