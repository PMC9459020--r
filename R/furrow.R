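#' @title The morphogenetic furrow sweep
#' @description
#' The furrow is a vertical line sweeping the epithelium right-to-left at a
#' fixed velocity. Each cycle, the tissue grows one step, the furrow
#' advances, and every scheduled event fires on the vertical band of cells
#' its offset swept this cycle, in ascending-offset order (founder selection
#' first at offset 0, apoptosis last). Recruitment events reach each cell at
#' most once per run; apoptosis is a per-cycle hazard on everything behind
#' its threshold.
#' @name furrow
NULL

#' Create a furrow state
#'
#' @param x Starting x position (world units), normally the right domain
#'   edge.
#' @param velocity World units moved (rightward-to-left) per cycle.
#' @param finish_x The furrow is finished once `x < finish_x`; normally
#'   `xmin - max(event offsets)`, so every event clears the left edge.
#' @return An object of class `furrow_state`.
#' @export
furrow_state <- function(x, velocity, finish_x = -Inf) {
  stopifnot(is.numeric(x), is.numeric(velocity), velocity >= 0)
  structure(list(x = x, velocity = velocity, cycle = 0L,
                 finish_x = finish_x, finished = x < finish_x),
            class = "furrow_state")
}

#' Advance the furrow by one cycle
#'
#' Moves the furrow left by its velocity and increments the cycle counter.
#' The furrow becomes finished once its trailing-most event offset has
#' cleared the left domain edge (`x < finish_x`); advancing a finished
#' furrow is an error.
#'
#' @param fs A `furrow_state`.
#' @return The updated `furrow_state`.
#' @export
advance_furrow <- function(fs) {
  stopifnot(inherits(fs, "furrow_state"))
  if (fs$finished) stop("advance_furrow: furrow already finished", call. = FALSE)
  fs$x <- fs$x - fs$velocity
  fs$cycle <- fs$cycle + 1L
  if (fs$x < fs$finish_x) fs$finished <- TRUE
  fs
}

#' Cells in the band an event swept this cycle
#'
#' After the furrow advances, the band for an event at offset `d` is
#' `[x + d, x + d + velocity)`: the vertical slice that crossed the event's
#' trigger line during this cycle. Cells that already received this event
#' kind are excluded, so over a run each cell receives each recruitment
#' event kind at most once.
#'
#' @param ep An `epithelium`.
#' @param fs A `furrow_state` (already advanced this cycle).
#' @param spec A list with fields `kind` (one of `"FOUNDER"`, `"WAVE1"`,
#'   `"WAVE2"`, `"WAVE3"`, `"BORDER"`, `"DEATH"`) and `distance_from_furrow`.
#' @return Integer vector of cell ids in the band.
#' @export
cells_in_band <- function(ep, fs, spec) {
  stopifnot(inherits(ep, "epithelium"), inherits(fs, "furrow_state"))
  bit <- event_bit(spec$kind)
  lo <- fs$x + spec$distance_from_furrow
  hi <- lo + fs$velocity
  idx <- which(ep$x >= lo & ep$x < hi & bitwAnd(ep$evmask, bit) == 0L)
  ep$id[idx]
}

# The event schedule implied by a parameter set, ascending by offset with
# the canonical kind order breaking ties.
build_schedule <- function(params) {
  ev <- list(
    list(kind = "FOUNDER", distance_from_furrow = params$founder$distance_from_furrow,
         params = params$founder),
    list(kind = "WAVE1", distance_from_furrow = params$wave1$distance_from_furrow,
         params = params$wave1),
    list(kind = "WAVE2", distance_from_furrow = params$wave2$distance_from_furrow,
         params = params$wave2),
    list(kind = "WAVE3", distance_from_furrow = params$wave3$distance_from_furrow,
         params = params$wave3),
    list(kind = "BORDER", distance_from_furrow = params$border$distance_from_furrow,
         params = params$border),
    list(kind = "DEATH", distance_from_furrow = params$death$distance_from_furrow,
         params = params$death))
  off <- vapply(ev, `[[`, numeric(1), "distance_from_furrow")
  ev[order(off, seq_along(ev))]
}

new_log <- function() {
  env <- new.env(parent = emptyenv())
  env$records <- vector("list", 256L)
  env$n <- 0L
  env
}

log_event <- function(log, cycle, kind, cell_ids, unit_id = NA_integer_) {
  if (log$n == length(log$records))
    length(log$records) <- 2L * length(log$records)
  log$n <- log$n + 1L
  log$records[[log$n]] <- list(cycle = cycle, kind = kind,
                               cell_ids = as.integer(cell_ids),
                               unit_id = unit_id)
  invisible(log)
}

#' Event log of a simulation
#'
#' @param state An `eye_sim` object.
#' @return A list of records, each with `cycle`, `kind`, `cell_ids` and
#'   `unit_id`.
#' @export
event_log <- function(state) {
  stopifnot(inherits(state, "eye_sim"))
  state$log$records[seq_len(state$log$n)]
}

#' Write the event log as JSON lines
#'
#' One JSON object per mutation: `{cycle, kind, cell_ids, unit_id}`.
#'
#' @param state An `eye_sim` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(state, path) {
  recs <- event_log(state)
  lines <- vapply(recs, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- per-cycle event dispatch ----------------------------------------------

dispatch_founder <- function(state, spec) {
  ep <- state$epithelium
  band <- cells_in_band(ep, state$furrow, spec)
  if (!length(band)) return(state)
  bit <- event_bit("FOUNDER")
  idx <- match(band, ep$id)
  ep$evmask[idx] <- bitwOr(ep$evmask[idx], bit)
  new_f <- select_founders(ep, band, state$founder_ids, spec$params)
  for (id in new_f) {
    uid <- length(state$units) + 1L
    ep <- specify_cells(ep, id, FATE_R8, spec$params$target_radius, uid)
    state$units[[uid]] <- list(unit_id = uid, founder_id = id,
                               founder_x0 = ep$x[match(id, ep$id)],
                               members = list(WAVE1 = integer(0),
                                              WAVE2 = integer(0),
                                              WAVE3 = integer(0)),
                               border_ids = integer(0))
    state$founder_ids <- c(state$founder_ids, id)
    state$unit_x0 <- c(state$unit_x0, state$units[[uid]]$founder_x0)
    for (k in names(state$unit_done))
      state$unit_done[[k]] <- c(state$unit_done[[k]], FALSE)
    log_event(state$log, state$furrow$cycle, "FOUNDER", id, uid)
  }
  state$epithelium <- ep
  state
}

# Units whose founder (at its founding position) has fallen at least
# `offset` behind the furrow and that have not yet run this event. Keying on
# the founding position rather than the live one makes event delivery
# exactly-once and immune to cells drifting during relaxation.
units_due <- function(state, kind, offset) {
  which(!state$unit_done[[kind]] & state$unit_x0 >= state$furrow$x + offset)
}

dispatch_wave <- function(state, spec) {
  ep <- state$epithelium
  uids <- units_due(state, spec$kind, spec$distance_from_furrow)
  if (!length(uids)) return(state)
  wp <- spec$params
  fate <- c(WAVE1 = FATE_WAVE1, WAVE2 = FATE_WAVE2, WAVE3 = FATE_WAVE3)[[spec$kind]]

  assigned <- NULL
  if (length(uids) > 1L && wp$selection_count > 0L) {
    # cells in range of several same-cycle founders go to the nearest one
    maxd <- diam_units(wp$max_distance_from_r8, ep$avg_cell_size)
    pool_unit <- integer(0); pool_id <- integer(0); pool_d <- numeric(0)
    for (uid in uids) {
      fi <- match(state$units[[uid]]$founder_id, ep$id)
      cand <- within_radius_cpp(ep$x, ep$y, ep$x[fi], ep$y[fi], maxd)
      cand <- cand[ep$fate[cand] == FATE_PRECURSOR]
      if (!length(cand)) next
      d <- sqrt((ep$x[cand] - ep$x[fi])^2 + (ep$y[cand] - ep$y[fi])^2)
      pool_unit <- c(pool_unit, rep(uid, length(cand)))
      pool_id <- c(pool_id, ep$id[cand]); pool_d <- c(pool_d, d)
    }
    if (length(pool_id)) {
      ord <- order(pool_id, pool_d, pool_unit)
      first <- !duplicated(pool_id[ord])
      assigned <- split(pool_id[ord][first], pool_unit[ord][first])
    }
  }
  for (uid in uids) {
    cand <- if (is.null(assigned)) NULL else assigned[[as.character(uid)]]
    if (!is.null(assigned) && is.null(cand)) cand <- integer(0)
    rec <- recruit_wave(ep, state$units[[uid]]$founder_id, wp, candidates = cand)
    if (length(rec)) {
      ep <- specify_cells(ep, rec, fate, wp$target_radius, uid)
      state$units[[uid]]$members[[spec$kind]] <- rec
    }
    state$unit_done[[spec$kind]][uid] <- TRUE
    log_event(state$log, state$furrow$cycle, spec$kind, rec, uid)
  }
  state$epithelium <- ep
  state
}

dispatch_border <- function(state, spec) {
  ep <- state$epithelium
  uids <- units_due(state, "BORDER", spec$distance_from_furrow)
  if (!length(uids)) return(state)
  bp <- spec$params
  if (bp$border_radius < 1L) {
    for (uid in uids) {
      state$unit_done[["BORDER"]][uid] <- TRUE
      log_event(state$log, state$furrow$cycle, "BORDER", integer(0), uid)
    }
    return(state)
  }
  slack <- 0.1 * ep$avg_cell_size
  frontiers <- lapply(uids, function(uid) {
    u <- state$units[[uid]]
    c(u$founder_id, unlist(u$members, use.names = FALSE))
  })
  names(frontiers) <- as.character(uids)
  recruited <- setNames(vector("list", length(uids)), as.character(uids))
  for (k in seq_len(bp$border_radius)) {
    # gather candidate layer cells for every unit, then give contested
    # precursors to the unit with the nearer founder (ties: lower unit id)
    cand_unit <- integer(0); cand_id <- integer(0); cand_d <- numeric(0)
    for (uid in uids) {
      fr <- match(frontiers[[as.character(uid)]], ep$id)
      fr <- fr[!is.na(fr)]
      if (!length(fr)) next
      prs <- contact_pairs_cpp(ep$x, ep$y, ep$r, fr, slack)
      nb <- unique(prs[, 2])
      nb <- nb[ep$fate[nb] == FATE_PRECURSOR]
      if (!length(nb)) next
      fi <- match(state$units[[uid]]$founder_id, ep$id)
      d <- sqrt((ep$x[nb] - ep$x[fi])^2 + (ep$y[nb] - ep$y[fi])^2)
      cand_unit <- c(cand_unit, rep(uid, length(nb)))
      cand_id <- c(cand_id, ep$id[nb]); cand_d <- c(cand_d, d)
    }
    if (!length(cand_id)) break
    ord <- order(cand_id, cand_d, cand_unit)
    first <- !duplicated(cand_id[ord])
    winner <- split(cand_id[ord][first], cand_unit[ord][first])
    for (uid in uids) {
      ids <- winner[[as.character(uid)]]
      if (is.null(ids) || !length(ids)) { frontiers[[as.character(uid)]] <- integer(0); next }
      ids <- sort(ids)
      ep <- specify_cells(ep, ids, FATE_BORDER, bp$target_radius, uid)
      recruited[[as.character(uid)]] <- c(recruited[[as.character(uid)]], ids)
      frontiers[[as.character(uid)]] <- ids
    }
  }
  for (uid in uids) {
    ids <- recruited[[as.character(uid)]]
    if (is.null(ids)) ids <- integer(0)
    state$units[[uid]]$border_ids <- ids
    state$unit_done[["BORDER"]][uid] <- TRUE
    log_event(state$log, state$furrow$cycle, "BORDER", ids, uid)
  }
  state$epithelium <- ep
  state
}

dispatch_death <- function(state, spec) {
  dp <- spec$params
  eligible <- NULL
  if (dp$one_shot) {
    eligible <- cells_in_band(state$epithelium, state$furrow, spec)
    if (length(eligible)) {
      idx <- match(eligible, state$epithelium$id)
      state$epithelium$evmask[idx] <-
        bitwOr(state$epithelium$evmask[idx], event_bit("DEATH"))
    } else return(state)
  }
  res <- apoptosis_step(state$epithelium, state$furrow$x, dp,
                        streams = state$streams, eligible_ids = eligible)
  if (length(res$removed_ids)) {
    state$deaths <- state$deaths + length(res$removed_ids)
    log_event(state$log, state$furrow$cycle, "DEATH", res$removed_ids)
  }
  state$epithelium <- res$epithelium
  state
}

#' Run one simulation cycle
#'
#' Executes, in order: one growth step (with divisions), one furrow advance,
#' then every scheduled event in ascending-offset order, then a short
#' relaxation so growing cells push their neighbours apart. All mutations
#' are logged. A pure function of (state, RNG streams).
#'
#' @param state An `eye_sim` object with an unfinished furrow.
#' @return The updated `eye_sim`.
#' @export
run_cycle <- function(state) {
  stopifnot(inherits(state, "eye_sim"))
  if (state$furrow$finished)
    stop("run_cycle: furrow already finished", call. = FALSE)
  p <- state$params
  gs <- grow_step(state$epithelium, p$cell_growth_rate, p$cell_max_size,
                  streams = state$streams)
  state$epithelium <- gs$epithelium
  if (length(gs$divided_ids)) {
    state$divisions <- state$divisions + length(gs$divided_ids)
    log_event(state$log, state$furrow$cycle + 1L, "DIVISION", gs$divided_ids)
  }
  state$furrow <- advance_furrow(state$furrow)
  for (spec in state$schedule) {
    state <- switch(spec$kind,
                    FOUNDER = dispatch_founder(state, spec),
                    WAVE1 = , WAVE2 = , WAVE3 = dispatch_wave(state, spec),
                    BORDER = dispatch_border(state, spec),
                    DEATH = dispatch_death(state, spec))
  }
  if (state$control$relax_iters_per_cycle > 0L && n_cells(state$epithelium) > 1L)
    state$epithelium <- relax_epithelium(
      state$epithelium,
      max_iters = state$control$relax_iters_per_cycle,
      overlap_tolerance = state$control$overlap_tolerance,
      k_att = state$control$relax_k_att, clamp = FALSE)
  state
}

#' Run a full eye development simulation
#'
#' Initializes the furrow at the right domain edge and runs cycles until the
#' trailing-most event offset has cleared the left edge; then continues
#' growth-only cycles (specified cells growing toward their target radii,
#' interleaved with relaxation) until cell growth completes. Precursor
#' growth and division stop with the furrow, so the post-furrow phase
#' terminates.
#'
#' @param params A [sim_params()] object.
#' @param epithelium An `epithelium` to develop, or `NULL` to generate one
#'   from `params` and `seed` (the reload feature: one saved epithelium can
#'   be developed under many parameter sets).
#' @param seed Integer root seed; spawns independent per-purpose RNG streams
#'   (generation, division axes, death draws).
#' @param control List of loop controls: `relax_iters_per_cycle` (default 8),
#'   `overlap_tolerance` (default 5% of the average cell size),
#'   `max_post_cycles` (default 400), `generate_relax_iters` (default 200).
#' @return An object of class `eye_sim`: the final epithelium, furrow state,
#'   eye units, schedule, parameters and event log.
#' @examples
#' p <- load_preset("lepidoptera_larva")
#' sim <- run_simulation(p, seed = 1)
#' unit_count(sim)
#' @export
run_simulation <- function(params, epithelium = NULL, seed = 1L,
                           control = list()) {
  stopifnot(inherits(params, "sim_params"))
  ctl <- list(relax_iters_per_cycle = 8L,
              overlap_tolerance = 0.05 * params$avg_cell_size,
              max_post_cycles = 400L,
              generate_relax_iters = 2000L,
              final_relax_iters = 20000L,
              settle_k_rep = 0.9,
              # cohesive attraction is a feature of initial sheet packing;
              # once differentiation starts, cells only push (units that
              # apoptosis has separated must not re-aggregate)
              relax_k_att = 0)
  ctl[names(control)] <- control
  if (params$furrow_velocity <= 0)
    stop("run_simulation: 'furrow_velocity' must be > 0", call. = FALSE)
  streams <- make_streams(seed)
  if (is.null(epithelium)) {
    gen_seed <- with_stream(streams, "generate",
                            sample.int(.Machine$integer.max - 1L, 1L))
    epithelium <- generate_epithelium(params$min_cell_count,
                                      params$avg_cell_size,
                                      params$cell_size_variance,
                                      seed = gen_seed,
                                      relax_iters = ctl$generate_relax_iters)
  }
  stopifnot(inherits(epithelium, "epithelium"))
  if (n_cells(epithelium) == 0L)
    stop("run_simulation: empty epithelium", call. = FALSE)
  schedule <- build_schedule(params)
  max_off <- max(vapply(schedule, `[[`, numeric(1), "distance_from_furrow"))
  fs <- furrow_state(x = epithelium$domain[2],
                     velocity = params$furrow_velocity,
                     finish_x = epithelium$domain[1] - max_off)
  state <- structure(list(epithelium = epithelium, furrow = fs,
                          units = list(), founder_ids = integer(0),
                          unit_x0 = numeric(0),
                          unit_done = list(WAVE1 = logical(0),
                                           WAVE2 = logical(0),
                                           WAVE3 = logical(0),
                                           BORDER = logical(0)),
                          schedule = schedule, params = params,
                          streams = streams, log = new_log(),
                          control = ctl, seed = seed, max_offset = max_off,
                          initial_n = n_cells(epithelium),
                          divisions = 0L, deaths = 0L),
                     class = "eye_sim")
  guard <- ceiling((epithelium$domain[2] - epithelium$domain[1] + max_off) /
                     params$furrow_velocity) + 4L
  while (!state$furrow$finished && guard > 0L) {
    state <- run_cycle(state)
    guard <- guard - 1L
  }
  # post-furrow growth completion: specified cells finish growing to within
  # 1% of their targets (the gap-law approach is asymptotic), with
  # relaxation interleaved so the expansion stays tracked
  rate <- min(params$cell_growth_rate, 1)
  if (rate > 0) {
    for (i in seq_len(ctl$max_post_cycles)) {
      ep <- state$epithelium
      growing <- ep$fate != FATE_PRECURSOR & ep$r < ep$target * 0.99
      if (!any(growing)) break
      ep$r[growing] <- ep$r[growing] +
        rate * (ep$target[growing] - ep$r[growing])
      state$epithelium <- ep
      if (ctl$relax_iters_per_cycle > 0L && n_cells(ep) > 1L)
        state$epithelium <- relax_epithelium(
          state$epithelium, max_iters = ctl$relax_iters_per_cycle,
          overlap_tolerance = ctl$overlap_tolerance,
          k_att = ctl$relax_k_att, clamp = FALSE)
    }
  }
  # settle: growth stopped, give the packing time to decompress fully; a
  # near-full overlap projection converges faster than the gentle in-cycle
  # constant once no new area is being added
  if (ctl$final_relax_iters > 0L && n_cells(state$epithelium) > 1L)
    state$epithelium <- relax_epithelium(
      state$epithelium, max_iters = ctl$final_relax_iters,
      overlap_tolerance = ctl$overlap_tolerance, k_rep = ctl$settle_k_rep,
      k_att = ctl$relax_k_att, clamp = FALSE)
  state
}

#' Run a bundled preset end to end
#'
#' Convenience wrapper: load a preset, optionally rescale the epithelium, and
#' run the simulation.
#'
#' @param name Preset name (see [preset_names()]).
#' @param seed Integer seed.
#' @param cells Optional override of the preset's `min_cell_count` (e.g. for
#'   scaled-down exploratory runs).
#' @param fusion_variant Passed to [load_preset()].
#' @param epithelium Optional pre-generated starting epithelium.
#' @param control Passed to [run_simulation()].
#' @return An `eye_sim` object.
#' @export
run_preset <- function(name, seed = 1L, cells = NULL,
                       fusion_variant = c("late", "early"),
                       epithelium = NULL, control = list()) {
  p <- load_preset(name, fusion_variant = match.arg(fusion_variant))
  if (!is.null(cells)) p$min_cell_count <- as.integer(cells)
  run_simulation(p, epithelium = epithelium, seed = seed, control = control)
}

#' @export
print.eye_sim <- function(x, ...) {
  cat(sprintf("<eye_sim: %d cells, %d eye units, cycle %d, furrow %s>\n",
              n_cells(x$epithelium), length(x$units), x$furrow$cycle,
              if (x$furrow$finished) "finished" else
                sprintf("at x = %g", x$furrow$x)))
  invisible(x)
}

#' @export
summary.eye_sim <- function(object, ...) {
  cen <- census(object)
  out <- list(n_cells = n_cells(object$epithelium),
              initial_n = object$initial_n,
              divisions = object$divisions, deaths = object$deaths,
              n_units = length(object$units),
              cycles = object$furrow$cycle,
              spacing = founder_spacing(object),
              census = cen)
  class(out) <- "summary.eye_sim"
  out
}

#' @export
print.summary.eye_sim <- function(x, ...) {
  cat(sprintf("Eye development simulation: %d cycles, %d eye units\n",
              x$cycles, x$n_units))
  cat(sprintf("  cells: %d initial + %d divisions - %d deaths = %d final\n",
              x$initial_n, x$divisions, x$deaths, x$n_cells))
  if (x$n_units >= 2)
    cat(sprintf("  founder spacing: min %.1f, mean %.1f (nn cv %.3f)\n",
                x$spacing$min, x$spacing$mean, x$spacing$nn_cv))
  if (nrow(x$census)) {
    cat("  per-unit census (first units):\n")
    print(utils::head(x$census[, c("unit_id", "n_wave1", "n_wave2",
                                   "n_wave3", "n_border")], 8L),
          row.names = FALSE)
  }
  invisible(x)
}
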