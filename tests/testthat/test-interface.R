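# Reference copy of the preset parameter table, written out independently of
# the YAML preset files (the fusion preset's paired exclusion variants are
# covered in their own test below).
reference_presets <- function() {
  w <- function(n, t, m, d) list(selection_count = n, target_radius = t,
                                 max_distance_from_r8 = m, distance_from_furrow = d)
  f <- function(e, t, m) list(exclusion_radius = e, target_radius = t,
                              min_distance_from_edge = m, distance_from_furrow = 0)
  list(
    drosophila = list(n = 10000, avg = 8, var = 0.1, max = 15, rate = 0.005,
                      vel = 20, f = f(2, 20, 3),
                      w1 = w(2, 20, 2, 100), w2 = w(2, 20, 2, 150),
                      w3 = w(2, 25, 4, 200),
                      b = list(1, 20, 1000), d = list(30, 1200)),
    strepsiptera = list(n = 7000, avg = 10, var = 2, max = 15, rate = 0.005,
                        vel = 20, f = f(10, 10, 10),
                        w1 = w(35, 20, 50, 100), w2 = w(35, 20, 50, 200),
                        w3 = w(35, 20, 50, 300),
                        b = list(2, 20, 400), d = list(20, 1000)),
    lepidoptera_larva = list(n = 1000, avg = 10, var = 2, max = 15,
                             rate = 0.005, vel = 20, f = f(10, 10, 4),
                             w1 = w(2, 20, 2, 100), w2 = w(2, 25, 2, 200),
                             w3 = w(2, 25, 4, 300),
                             b = list(1, 20, 400), d = list(20, 1000)),
    diving_beetle = list(n = 7000, avg = 10, var = 2, max = 15, rate = 0.005,
                         vel = 20, f = f(25, 10, 13),
                         w1 = w(50, 20, 50, 200), w2 = w(100, 18, 50, 400),
                         w3 = w(50, 20, 80, 600),
                         b = list(2, 20, 800), d = list(20, 1000)),
    ocelli = list(n = 10000, avg = 10, var = 2, max = 25, rate = 0.01,
                  vel = 10, f = f(28, 20, 25),
                  w1 = w(150, 30, 200, 100), w2 = w(150, 30, 200, 150),
                  w3 = w(150, 30, 200, 200),
                  b = list(5, 15, 550), d = list(10, 600)),
    one_eye_expansion = list(n = 5000, avg = 10, var = 2, max = 15,
                             rate = 0.005, vel = 20, f = f(40, 10, 30),
                             w1 = w(800, 20, 600, 400), w2 = w(800, 25, 500, 800),
                             w3 = w(800, 25, 600, 1000),
                             b = list(1, 20, 2000), d = list(20, 2200)))
}

test_that("every preset matches the reference parameter table field by field", {
  ref <- reference_presets()
  for (nm in names(ref)) {
    p <- load_preset(nm)
    r <- ref[[nm]]
    expect_equal(p$min_cell_count, r$n, info = nm)
    expect_equal(p$avg_cell_size, r$avg, info = nm)
    expect_equal(p$cell_size_variance, r$var, info = nm)
    expect_equal(p$cell_max_size, r$max, info = nm)
    expect_equal(p$cell_growth_rate, r$rate, info = nm)
    expect_equal(p$furrow_velocity, r$vel, info = nm)
    expect_equal(unclass(p$founder)[names(r$f)], r$f, info = nm)
    for (wk in c("w1", "w2", "w3")) {
      w <- p[[sub("w", "wave", wk)]]
      expect_equal(w$selection_count, as.integer(r[[wk]]$selection_count), info = nm)
      expect_equal(w$target_radius, r[[wk]]$target_radius, info = nm)
      expect_equal(w$max_distance_from_r8, r[[wk]]$max_distance_from_r8, info = nm)
      expect_equal(w$distance_from_furrow, r[[wk]]$distance_from_furrow, info = nm)
    }
    expect_equal(p$border$border_radius, as.integer(r$b[[1]]), info = nm)
    expect_equal(p$border$target_radius, r$b[[2]], info = nm)
    expect_equal(p$border$distance_from_furrow, r$b[[3]], info = nm)
    expect_equal(p$death$death_chance, r$d[[1]], info = nm)
    expect_equal(p$death$distance_from_furrow, r$d[[2]], info = nm)
  }
})

test_that("the fusion preset exposes both exclusion variants", {
  late <- load_preset("one_eye_fusion", fusion_variant = "late")
  early <- load_preset("one_eye_fusion", fusion_variant = "early")
  expect_equal(late$founder$exclusion_radius, 1)
  expect_equal(early$founder$exclusion_radius, 0.8)
  expect_equal(late$founder$min_distance_from_edge, 8)
  expect_equal(late$wave1$selection_count, 2L)
  expect_equal(late$death$death_chance, 20)
})

test_that("unknown presets produce an error listing the valid names", {
  err <- tryCatch(load_preset("spider"), error = conditionMessage)
  expect_match(err, "spider")
  for (nm in preset_names()) expect_match(err, nm, fixed = TRUE)
  expect_length(preset_names(), 7)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(wave_params(2.5, 10, 1, 0), "integer")
  expect_error(border_params(1.5, 10, 0), "integer")
  expect_error(founder_params(-1, 10, 0), "exclusion_radius")
  expect_error(sim_params(0, 10, 1, 15, 0.005, 20,
                          founder = founder_params(2, 20, 3),
                          wave1 = wave_params(2, 20, 2, 100),
                          wave2 = wave_params(2, 20, 2, 150),
                          wave3 = wave_params(2, 25, 4, 200),
                          border = border_params(1, 20, 1000),
                          death = death_params(30, 1200)),
               "min_cell_count")
})

test_that("YAML config files round-trip through read_params", {
  p <- load_preset("drosophila")
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- list(min_cell_count = p$min_cell_count,
              avg_cell_size = p$avg_cell_size,
              cell_size_variance = p$cell_size_variance,
              cell_max_size = p$cell_max_size,
              cell_growth_rate = p$cell_growth_rate,
              furrow_velocity = p$furrow_velocity,
              founder = unclass(p$founder), wave1 = unclass(p$wave1),
              wave2 = unclass(p$wave2), wave3 = unclass(p$wave3),
              border = unclass(p$border),
              death = unclass(p$death)[c("death_chance", "distance_from_furrow")])
  yaml::write_yaml(cfg, path)
  q <- read_params(path)
  expect_equal(q$founder$exclusion_radius, 2)
  expect_equal(q$wave3$target_radius, 25)
  expect_equal(q$death$death_chance, 30)
})

test_that("fixtures have the advertised geometry", {
  hex <- make_fixture("hex_patch", 7, cell_radius = 8)
  expect_length(hex$id, 7)
  d <- sqrt((hex$x[-1] - hex$x[1])^2 + (hex$y[-1] - hex$y[1])^2)
  expect_equal(d, rep(16, 6), tolerance = 1e-9)
  strip <- make_fixture("strip", 100, cell_radius = 5)
  expect_equal(diff(strip$x), rep(10, 99))
  expect_true(all(strip$y == strip$y[1]))
  ring <- make_fixture("ring_unit")
  expect_length(ring$id, 7)
  expect_identical(neighbors(ring, 1L, "contact"), 2:7)
})

test_that("SVG snapshots encode the fate palette and the furrow line", {
  st <- local({
    p <- load_preset("lepidoptera_larva")
    p$min_cell_count <- 150L
    run_simulation(p, seed = 1)
  })
  path <- withr::local_tempfile(fileext = ".svg")
  render_snapshot(st, path, format = "svg")
  svg <- readLines(path)
  expect_match(svg[1], "^<svg ")
  # founders drawn dark purple, borders green; finished furrow -> no line
  expect_true(any(grepl('fill="#4B0082".*class="R8"', svg)))
  expect_true(any(grepl('fill="#2E8B57".*class="BORDER"', svg)))
  expect_false(any(grepl('class="furrow"', svg)))
  # precursors are outline-only
  expect_true(any(grepl('fill="none".*class="PRECURSOR"', svg)) ||
                !any(grepl('class="PRECURSOR"', svg)))
  # an unfinished state draws the dashed furrow line
  ep <- make_fixture("hex_patch", 19)
  st2 <- structure(list(epithelium = ep,
                        furrow = furrow_state(0, 10, finish_x = -1000),
                        units = list(), founder_ids = integer(0)),
                   class = "eye_sim")
  path2 <- withr::local_tempfile(fileext = ".svg")
  render_snapshot(st2, path2, format = "svg")
  expect_true(any(grepl('class="furrow"', readLines(path2))))
})

test_that("the command-line interface round-trips generate/run/metrics", {
  cli <- system.file("cli", "ommatid.R", package = "ommatid")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  epf <- file.path(dir, "ep.csv")
  # child Rscript must resolve the same library the tests run against
  withr::local_envvar(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep))
  run1 <- function(...) {
    system2("Rscript", c(cli, ...), stdout = TRUE, stderr = TRUE)
  }
  run1("generate", "--cells", "120", "--avg-size", "10", "--variance", "2",
       "--seed", "3", "--out", epf)
  expect_true(file.exists(epf))
  expect_length(read_epithelium(epf)$id, 120)

  outd <- file.path(dir, "run1")
  run1("run", "--preset", "lepidoptera_larva", "--cells", "120",
       "--epithelium", epf, "--seed", "1", "--out", outd)
  for (f in c("cells.csv", "events.jsonl", "metrics.csv", "summary.json",
              "manifest.json", "final.svg"))
    expect_true(file.exists(file.path(outd, f)), info = f)
  man <- jsonlite::fromJSON(file.path(outd, "manifest.json"))
  expect_equal(man$seed, 1)
  expect_equal(man$params$min_cell_count, 120)

  # same preset + seed + starting tissue: byte-identical cell tables
  outd2 <- file.path(dir, "run2")
  run1("run", "--preset", "lepidoptera_larva", "--cells", "120",
       "--epithelium", epf, "--seed", "1", "--out", outd2)
  expect_identical(readLines(file.path(outd, "cells.csv")),
                   readLines(file.path(outd2, "cells.csv")))

  mtd <- file.path(dir, "m")
  run1("metrics", "--cells-file", file.path(outd, "cells.csv"), "--out", mtd)
  expect_true(file.exists(file.path(mtd, "metrics.csv")))

  # bad arguments exit with status 2
  st <- system2("Rscript", c(cli, "run"), stdout = FALSE, stderr = FALSE)
  expect_equal(st, 2)
  st <- system2("Rscript", c(cli, "frobnicate"), stdout = FALSE, stderr = FALSE)
  expect_equal(st, 2)
})

test_that("an empty epithelium still renders a valid domain rectangle", {
  ep <- make_fixture("strip", 1)
  ep$id <- integer(0); ep$x <- numeric(0); ep$y <- numeric(0)
  ep$r <- numeric(0); ep$fate <- integer(0); ep$target <- numeric(0)
  ep$unit <- integer(0); ep$evmask <- integer(0)
  path <- withr::local_tempfile(fileext = ".svg")
  render_snapshot(ep, path, format = "svg")
  svg <- readLines(path)
  expect_match(svg[2], "<rect")
  expect_match(svg[length(svg)], "</svg>")
})
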