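#' Founder-cell (R8) selection parameters
#'
#' Parameters controlling where eye-unit founder cells are specified behind
#' the morphogenetic furrow. Distances that describe cell-scale geometry
#' (`exclusion_radius`, `min_distance_from_edge`) are expressed in units of
#' one average cell diameter (`2 * avg_cell_size`); `distance_from_furrow` is
#' in raw world units, the same scale as cell coordinates.
#'
#' @param exclusion_radius Minimal spacing between founder cells, in average
#'   cell diameters. Larger values space eye units further apart.
#' @param target_radius Radius (world units) the founder grows toward once
#'   specified.
#' @param min_distance_from_edge Minimal distance of a founder center from
#'   every domain edge, in average cell diameters. Keeps enough precursors
#'   around a founder to complete its unit.
#' @param distance_from_furrow Offset (world units) behind the furrow at
#'   which founder selection acts.
#' @return An object of class `founder_params`.
#' @export
founder_params <- function(exclusion_radius, target_radius,
                           min_distance_from_edge, distance_from_furrow = 0) {
  p <- list(exclusion_radius = exclusion_radius,
            target_radius = target_radius,
            min_distance_from_edge = min_distance_from_edge,
            distance_from_furrow = distance_from_furrow)
  for (f in names(p)) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || is.na(p[[f]]) || p[[f]] < 0)
      stop("founder_params: '", f, "' must be a single non-negative number",
           call. = FALSE)
  }
  structure(p, class = "founder_params")
}

#' Photoreceptor wave recruitment parameters
#'
#' One set per recruitment wave (the R2/R5-, R3/R4- and R1/R6-like pairs of
#' the fly, generalized to arbitrary counts). `max_distance_from_r8` is in
#' average cell diameters; `distance_from_furrow` in world units.
#'
#' @param selection_count Number of precursors recruited per unit in this
#'   wave (fewer if the pool is smaller).
#' @param target_radius Radius the recruited cells grow toward (world units).
#' @param max_distance_from_r8 Maximum center distance from the founder at
#'   which precursors can be recruited, in average cell diameters.
#' @param distance_from_furrow Offset behind the furrow at which this wave
#'   fires for a unit (world units).
#' @return An object of class `wave_params`.
#' @export
wave_params <- function(selection_count, target_radius,
                        max_distance_from_r8, distance_from_furrow) {
  p <- list(selection_count = selection_count,
            target_radius = target_radius,
            max_distance_from_r8 = max_distance_from_r8,
            distance_from_furrow = distance_from_furrow)
  for (f in names(p)) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || is.na(p[[f]]) || p[[f]] < 0)
      stop("wave_params: '", f, "' must be a single non-negative number",
           call. = FALSE)
  }
  if (p$selection_count != round(p$selection_count))
    stop("wave_params: 'selection_count' must be an integer", call. = FALSE)
  p$selection_count <- as.integer(p$selection_count)
  structure(p, class = "wave_params")
}

#' Border-cell recruitment parameters
#'
#' @param border_radius Integer number of contact layers of precursors
#'   recruited as border (pigment/support) cells around each unit.
#' @param target_radius Radius border cells grow toward (world units).
#' @param distance_from_furrow Offset behind the furrow (world units).
#' @return An object of class `border_params`.
#' @export
border_params <- function(border_radius, target_radius, distance_from_furrow) {
  p <- list(border_radius = border_radius, target_radius = target_radius,
            distance_from_furrow = distance_from_furrow)
  for (f in names(p)) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || is.na(p[[f]]) || p[[f]] < 0)
      stop("border_params: '", f, "' must be a single non-negative number",
           call. = FALSE)
  }
  if (p$border_radius != round(p$border_radius))
    stop("border_params: 'border_radius' must be an integer layer count",
         call. = FALSE)
  p$border_radius <- as.integer(p$border_radius)
  structure(p, class = "border_params")
}

#' Apoptosis parameters
#'
#' Each simulation cycle, every undifferentiated precursor further behind the
#' furrow than `distance_from_furrow` dies independently with probability
#' `death_chance / 100`. Specified cells never die.
#'
#' @param death_chance Percent chance of death per cycle, in \[0, 100\].
#' @param distance_from_furrow Offset behind the furrow (world units).
#' @param one_shot If `TRUE`, the hazard is applied to each cell once (the
#'   cycle its band is swept) instead of every cycle.
#' @return An object of class `death_params`.
#' @export
death_params <- function(death_chance, distance_from_furrow, one_shot = FALSE) {
  if (!is.numeric(death_chance) || length(death_chance) != 1L ||
      is.na(death_chance) || death_chance < 0 || death_chance > 100)
    stop("death_params: 'death_chance' must be a percent in [0, 100]",
         call. = FALSE)
  if (!is.numeric(distance_from_furrow) || length(distance_from_furrow) != 1L ||
      is.na(distance_from_furrow) || distance_from_furrow < 0)
    stop("death_params: 'distance_from_furrow' must be a single non-negative number",
         call. = FALSE)
  structure(list(death_chance = death_chance,
                 distance_from_furrow = distance_from_furrow,
                 one_shot = isTRUE(one_shot)),
            class = "death_params")
}

#' Full simulation parameter set
#'
#' Bundles every tunable of the simulator: epithelium generation, growth,
#' furrow motion, and the per-event parameter blocks. See the individual
#' constructors for units. `simulation_speed` (display cycles per second in
#' an interactive setting) is carried for completeness but has no effect on
#' headless runs.
#'
#' @param min_cell_count Number of precursor cells generated.
#' @param avg_cell_size Mean precursor radius (world units).
#' @param cell_size_variance Standard deviation of precursor radii.
#' @param cell_max_size Radius at which an undifferentiated precursor divides.
#' @param cell_growth_rate Per-cycle multiplicative radius growth fraction.
#' @param furrow_velocity World units the furrow advances per cycle.
#' @param simulation_speed Ignored in headless runs.
#' @param founder A [founder_params()] object.
#' @param wave1,wave2,wave3 [wave_params()] objects for the three waves.
#' @param border A [border_params()] object.
#' @param death A [death_params()] object.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(min_cell_count, avg_cell_size, cell_size_variance,
                       cell_max_size, cell_growth_rate, furrow_velocity,
                       simulation_speed = 100,
                       founder, wave1, wave2, wave3, border, death) {
  num1 <- function(v, f, min = 0, strict = FALSE) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        (strict && v <= min) || (!strict && v < min))
      stop("sim_params: '", f, "' must be a single number ",
           if (strict) "> " else ">= ", min, call. = FALSE)
    v
  }
  num1(min_cell_count, "min_cell_count", 1)
  if (min_cell_count != round(min_cell_count))
    stop("sim_params: 'min_cell_count' must be an integer", call. = FALSE)
  num1(avg_cell_size, "avg_cell_size", 0, strict = TRUE)
  num1(cell_size_variance, "cell_size_variance", 0)
  num1(cell_max_size, "cell_max_size", 0, strict = TRUE)
  num1(cell_growth_rate, "cell_growth_rate", 0)
  num1(furrow_velocity, "furrow_velocity", 0)
  stopifnot(inherits(founder, "founder_params"),
            inherits(wave1, "wave_params"), inherits(wave2, "wave_params"),
            inherits(wave3, "wave_params"), inherits(border, "border_params"),
            inherits(death, "death_params"))
  structure(list(min_cell_count = as.integer(min_cell_count),
                 avg_cell_size = avg_cell_size,
                 cell_size_variance = cell_size_variance,
                 cell_max_size = cell_max_size,
                 cell_growth_rate = cell_growth_rate,
                 furrow_velocity = furrow_velocity,
                 simulation_speed = simulation_speed,
                 founder = founder, wave1 = wave1, wave2 = wave2,
                 wave3 = wave3, border = border, death = death),
            class = "sim_params")
}

# cell-scale parameter -> world units: one unit is one average cell diameter
diam_units <- function(v, avg_cell_size) v * 2 * avg_cell_size

#' @export
print.sim_params <- function(x, ...) {
  cat("Eye development simulation parameters\n")
  cat(sprintf("  epithelium: %d cells, radius %g +/- %g (max %g)\n",
              x$min_cell_count, x$avg_cell_size, x$cell_size_variance,
              x$cell_max_size))
  cat(sprintf("  growth rate %g per cycle; furrow velocity %g\n",
              x$cell_growth_rate, x$furrow_velocity))
  cat(sprintf("  founder: exclusion %g diam, edge margin %g diam, target r %g\n",
              x$founder$exclusion_radius, x$founder$min_distance_from_edge,
              x$founder$target_radius))
  for (w in c("wave1", "wave2", "wave3"))
    cat(sprintf("  %s: %d cells within %g diam of R8, target r %g, offset %g\n",
                w, x[[w]]$selection_count, x[[w]]$max_distance_from_r8,
                x[[w]]$target_radius, x[[w]]$distance_from_furrow))
  cat(sprintf("  border: %d layer(s), target r %g, offset %g\n",
              x$border$border_radius, x$border$target_radius,
              x$border$distance_from_furrow))
  cat(sprintf("  death: %g%% per cycle beyond offset %g\n",
              x$death$death_chance, x$death$distance_from_furrow))
  invisible(x)
}

#' Load a named eye-layout preset
#'
#' Returns the parameter set for one of the seven bundled eye-layout presets:
#' a fly-like compound eye (`drosophila`), the large spaced image-forming
#' units of twisted-wing insects (`strepsiptera`), widely spaced larval
#' stemmata (`lepidoptera_larva`), clustered image-forming larval eyes
#' (`diving_beetle`), the median simple eyes of adult insects (`ocelli`), and
#' two single-chamber routes: one founder recruiting concentric photoreceptor
#' layers (`one_eye_expansion`) and many tightly packed units merging into a
#' mosaic retina (`one_eye_fusion`).
#'
#' @param name One of the seven preset names.
#' @param fusion_variant For `one_eye_fusion` only: `"late"` (founders one
#'   cell diameter apart; photoreceptor types interleave through the mosaic)
#'   or `"early"` (0.8 diameters; late types pushed to the periphery).
#' @return A [sim_params()] object.
#' @export
load_preset <- function(name, fusion_variant = c("late", "early")) {
  valid <- preset_names()
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("unknown preset '", paste(name, collapse = ","), "'; valid presets: ",
         paste(valid, collapse = ", "), call. = FALSE)
  path <- system.file("presets", paste0(name, ".yaml"), package = "ommatid")
  y <- yaml::read_yaml(path)
  f <- y$founder
  if (name == "one_eye_fusion") {
    fusion_variant <- match.arg(fusion_variant)
    f$exclusion_radius <- f[[paste0("exclusion_radius_", fusion_variant)]]
    f$exclusion_radius_early <- NULL
    f$exclusion_radius_late <- NULL
  }
  sim_params(min_cell_count = y$min_cell_count,
             avg_cell_size = y$avg_cell_size,
             cell_size_variance = y$cell_size_variance,
             cell_max_size = y$cell_max_size,
             cell_growth_rate = y$cell_growth_rate,
             furrow_velocity = y$furrow_velocity,
             simulation_speed = y$simulation_speed,
             founder = do.call(founder_params, f),
             wave1 = do.call(wave_params, y$wave1),
             wave2 = do.call(wave_params, y$wave2),
             wave3 = do.call(wave_params, y$wave3),
             border = do.call(border_params, y$border),
             death = do.call(death_params, y$death))
}

#' @rdname load_preset
#' @export
preset_names <- function() {
  c("drosophila", "strepsiptera", "lepidoptera_larva", "diving_beetle",
    "ocelli", "one_eye_expansion", "one_eye_fusion")
}

#' Read simulation parameters from a YAML config file
#'
#' The file mirrors the [sim_params()] field names, with nested blocks
#' `founder`, `wave1`..`wave3`, `border`, `death` (the same layout as the
#' bundled preset files).
#'
#' @param path Path to a YAML file.
#' @return A [sim_params()] object.
#' @export
read_params <- function(path) {
  y <- yaml::read_yaml(path)
  sim_params(min_cell_count = y$min_cell_count,
             avg_cell_size = y$avg_cell_size,
             cell_size_variance = y$cell_size_variance,
             cell_max_size = y$cell_max_size,
             cell_growth_rate = y$cell_growth_rate,
             furrow_velocity = y$furrow_velocity,
             simulation_speed = if (is.null(y$simulation_speed)) 100 else y$simulation_speed,
             founder = do.call(founder_params, y$founder),
             wave1 = do.call(wave_params, y$wave1),
             wave2 = do.call(wave_params, y$wave2),
             wave3 = do.call(wave_params, y$wave3),
             border = do.call(border_params, y$border),
             death = do.call(death_params, y$death))
}
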