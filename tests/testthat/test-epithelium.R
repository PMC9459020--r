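test_that("generation returns the requested count with sane radii and packing", {
  ep <- generate_epithelium(200, 10, 2, seed = 7)
  expect_s3_class(ep, "epithelium")
  expect_length(ep$id, 200)
  expect_true(all(ep$fate == 1L))  # all precursors
  # sample mean radius within 3 standard errors of the target
  expect_lt(abs(mean(ep$r) - 10), 3 * 2 / sqrt(200))
  expect_true(all(ep$r > 0))
  # overlap invariant, verified by brute-force O(n^2) scan
  expect_lte(brute_max_overlap(ep), 0.05 * 10 + 1e-9)
  # centers inside the domain
  expect_true(all(ep$x >= ep$domain[1] & ep$x <= ep$domain[2]))
  expect_true(all(ep$y >= ep$domain[3] & ep$y <= ep$domain[4]))
})

test_that("a single cell with zero variance sits at the domain center with exact radius", {
  ep <- generate_epithelium(1, 10, 0, seed = 3)
  expect_equal(ep$r, 10)
  expect_equal(ep$x, mean(ep$domain[1:2]))
  expect_equal(ep$y, mean(ep$domain[3:4]))
})

test_that("generation is deterministic in (seed, params) and rejects bad input", {
  a <- generate_epithelium(80, 8, 1, seed = 42)
  b <- generate_epithelium(80, 8, 1, seed = 42)
  expect_identical(a$x, b$x)
  expect_identical(a$r, b$r)
  c <- generate_epithelium(80, 8, 1, seed = 43)
  expect_false(identical(a$x, c$x))
  expect_error(generate_epithelium(0, 8, 1), "min_cell_count")
  expect_error(generate_epithelium(10, -1, 1), "avg_cell_size")
  expect_error(generate_epithelium(10, 8, -1), "cell_size_variance")
})

test_that("two-body relaxation separates an overlapping pair toward contact", {
  r <- 10
  ep <- make_fixture("strip", 2, cell_radius = r)
  # overlap them: center distance r
  ep$x[2] <- ep$x[1] + r
  out <- relax_epithelium(ep, max_iters = 200, overlap_tolerance = 0.01)
  d <- abs(out$x[2] - out$x[1])
  expect_gte(d, 2 * r - 0.01 - 1e-9)
  # closed-form check of one iteration of the update rule: the pair
  # separation grows by k_rep * overlap = 0.5 * r, split between partners
  one <- relax_epithelium(ep, max_iters = 1, overlap_tolerance = 0)
  expect_equal(abs(one$x[2] - one$x[1]), r + 0.5 * r, tolerance = 1e-12)
})

test_that("a single cell does not move during relaxation", {
  ep <- make_fixture("strip", 1, cell_radius = 5)
  out <- relax_epithelium(ep, max_iters = 50)
  expect_identical(out$x, ep$x)
  expect_identical(out$y, ep$y)
})

test_that("summed overlap depth is non-increasing across relaxation iterations", {
  ep <- random_epithelium(50, avg = 10, sv = 1, side = 150, seed = 2)
  s_prev <- brute_overlap_sum(ep)
  for (i in 1:30) {
    ep <- relax_epithelium(ep, max_iters = 1, overlap_tolerance = 0)
    s <- brute_overlap_sum(ep)
    expect_lte(s, s_prev + 1e-9)
    s_prev <- s
  }
  expect_lt(s_prev, brute_overlap_sum(random_epithelium(50, 10, 1, 150, 2)))
})

test_that("grid max-overlap agrees with the brute-force scan", {
  for (seed in 1:3) {
    ep <- random_epithelium(120, avg = 8, sv = 2, seed = seed)
    expect_equal(max_overlap_cpp(ep$x, ep$y, ep$r), brute_max_overlap(ep),
                 tolerance = 1e-12)
  }
})

test_that("growth at rate zero is a no-op", {
  ep <- make_fixture("hex_patch", 19, cell_radius = 10)
  out <- grow_step(ep, 0, 15)
  expect_identical(out$epithelium$r, ep$r)
  expect_length(out$divided_ids, 0)
})

test_that("a precursor at max size divides into two area-conserving daughters", {
  ep <- make_fixture("strip", 1, cell_radius = 15)
  set.seed(1)
  out <- grow_step(ep, 0.01, 15)
  ep2 <- out$epithelium
  expect_length(ep2$id, 2)
  expect_identical(out$divided_ids, 1L)
  expect_equal(sum(ep2$r^2), 15^2, tolerance = 1e-9)  # pi cancels
  expect_equal(ep2$r[1], ep2$r[2])
  expect_true(all(ep2$fate == 1L))
})

test_that("specified cells grow toward target and never divide", {
  ep <- make_fixture("strip", 1, cell_radius = 10)
  ep$fate <- 6L  # border
  ep$target <- 30
  out <- grow_step(ep, 0.5, 15)  # half the gap to target per cycle
  expect_length(out$divided_ids, 0)
  expect_length(out$epithelium$id, 1)
  expect_equal(out$epithelium$r, 20)  # 10 + 0.5 * (30 - 10), past max size
  # a full-fraction step lands exactly on the cell's own target
  out2 <- grow_step(out$epithelium, 5, 15)
  expect_equal(out2$epithelium$r, 30)
})

test_that("save/load round trip is exact on every field", {
  ep <- generate_epithelium(60, 9, 1.5, seed = 11)
  ep$fate[c(3, 7)] <- c(2L, 6L)
  ep$unit[c(3, 7)] <- c(1L, 1L)
  ep$target[c(3, 7)] <- c(20, 18.25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_epithelium(ep, path)
  ep2 <- read_epithelium(path)
  for (f in c("id", "x", "y", "r", "fate", "target", "unit"))
    expect_identical(ep2[[f]], ep[[f]], info = f)
  expect_identical(ep2$domain, ep$domain)
  expect_identical(ep2$avg_cell_size, ep$avg_cell_size)
})

test_that("malformed epithelium files produce format errors with context", {
  ep <- make_fixture("hex_patch", 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_epithelium(ep, path)
  lines <- readLines(path)
  # drop the radius column
  broken <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(lines[1], gsub("radius,", "", lines[2], fixed = TRUE),
               sub("^(([^,]*,){3})[^,]*,", "\\1", lines[-(1:2)])), broken)
  expect_error(read_epithelium(broken), "radius")
  nomagic <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines[-1], nomagic)
  expect_error(read_epithelium(nomagic), "header")
})

test_that("contact neighbors of a hexagonal center cell are the six ring cells", {
  ep <- make_fixture("ring_unit")
  nb <- neighbors(ep, 1L, mode = "contact")
  expect_identical(nb, 2:7)
  expect_identical(nb, brute_contact_neighbors(ep, 1L, 0.1 * ep$avg_cell_size))
  # symmetry: the center is a neighbour of each ring cell
  for (id in 2:7) expect_true(1L %in% neighbors(ep, id, mode = "contact"))
})

test_that("neighbor edge cases: single cell, zero radius, unknown id", {
  ep1 <- make_fixture("strip", 1)
  expect_length(neighbors(ep1, 1L, mode = "contact"), 0)
  ep <- make_fixture("ring_unit")
  expect_length(neighbors(ep, 1L, mode = "radius", radius = 0), 0)
  expect_error(neighbors(ep, 99L), "unknown")
})

test_that("delaunay neighbors match the brute-force circumcircle oracle", {
  skip_if_not_installed("deldir")
  set.seed(5)
  x <- runif(12, 0, 100); y <- runif(12, 0, 100)
  ep <- random_epithelium(12, avg = 3, sv = 0, seed = 5)
  ep$x <- x; ep$y <- y
  for (i in c(1L, 5L, 9L)) {
    got <- neighbors(ep, i, mode = "delaunay")
    expect_identical(got, brute_delaunay_neighbors(x, y, i))
  }
})
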