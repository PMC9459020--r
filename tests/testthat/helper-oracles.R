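# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain O(n^2) scans and literal greedy traces, used to
# cross-check the grid-accelerated implementations on small fixtures.

# maximum pairwise overlap depth by full scan
brute_max_overlap <- function(ep) {
  n <- length(ep$id)
  if (n < 2) return(0)
  mx <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((ep$x[i] - ep$x[j])^2 + (ep$y[i] - ep$y[j])^2)
      mx <- max(mx, ep$r[i] + ep$r[j] - d)
    }
  }
  mx
}

brute_overlap_sum <- function(ep) {
  n <- length(ep$id)
  if (n < 2) return(0)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((ep$x[i] - ep$x[j])^2 + (ep$y[i] - ep$y[j])^2)
      s <- s + max(0, ep$r[i] + ep$r[j] - d)
    }
  }
  s
}

# contact neighbours of one cell by full scan
brute_contact_neighbors <- function(ep, cell_id, slack) {
  i <- which(ep$id == cell_id)
  d <- sqrt((ep$x - ep$x[i])^2 + (ep$y - ep$y[i])^2)
  ok <- d <= ep$r + ep$r[i] + slack
  ok[i] <- FALSE
  sort(ep$id[ok])
}

# literal greedy founder selection trace
brute_select_founders <- function(ep, band_ids, founder_ids, excl_world,
                                  margin_world) {
  pos <- function(id) {
    i <- which(ep$id == id)
    c(ep$x[i], ep$y[i])
  }
  cand <- band_ids[vapply(band_ids, function(id) {
    i <- which(ep$id == id)
    ep$fate[i] == 1L &&
      min(ep$x[i] - ep$domain[1], ep$domain[2] - ep$x[i],
          ep$y[i] - ep$domain[3], ep$domain[4] - ep$y[i]) >= margin_world
  }, logical(1))]
  founders <- founder_ids
  chosen <- integer(0)
  mind_to <- function(id, set) {
    if (!length(set)) return(Inf)
    p <- pos(id)
    min(vapply(set, function(f) {
      q <- pos(f); sqrt(sum((p - q)^2))
    }, numeric(1)))
  }
  if (!length(founders) && length(cand)) {
    xs <- vapply(cand, function(id) ep$x[which(ep$id == id)], numeric(1))
    best <- cand[order(-xs, cand)][1]  # nearest right edge, ties lowest id
    chosen <- best
    founders <- c(founders, best)
    cand <- setdiff(cand, best)
  }
  repeat {
    if (!length(cand)) break
    md <- vapply(cand, mind_to, numeric(1), set = founders)
    ok <- md >= excl_world
    if (!any(ok)) break
    pool <- cand[ok]
    best <- pool[order(md[ok], pool)][1]
    chosen <- c(chosen, best)
    founders <- c(founders, best)
    cand <- setdiff(cand, best)
  }
  chosen
}

# nearest-neighbour wave recruitment by full scan
brute_recruit_wave <- function(ep, founder_id, count, maxd_world) {
  fi <- which(ep$id == founder_id)
  d <- sqrt((ep$x - ep$x[fi])^2 + (ep$y - ep$y[fi])^2)
  ok <- which(ep$fate == 1L & d <= maxd_world)
  ok <- ok[order(d[ok], ep$id[ok])]
  ep$id[utils::head(ok, count)]
}

# contact-layer border recruitment by BFS over the brute-force contact graph
brute_border_layers <- function(ep, seed_ids, n_layers, slack) {
  claimed <- seed_ids
  frontier <- seed_ids
  layers <- list()
  for (k in seq_len(n_layers)) {
    nb <- sort(unique(unlist(lapply(frontier, function(id)
      brute_contact_neighbors(ep, id, slack)))))
    nb <- nb[vapply(nb, function(id) ep$fate[which(ep$id == id)] == 1L,
                    logical(1))]
    nb <- setdiff(nb, claimed)
    layers[[k]] <- nb
    claimed <- c(claimed, nb)
    frontier <- nb
  }
  layers
}

# Delaunay neighbours of point i by circumcircle enumeration (tiny n only):
# i and j are Delaunay neighbours iff some triangle (i, j, k) has an empty
# circumcircle.
brute_delaunay_neighbors <- function(x, y, i) {
  n <- length(x)
  nb <- integer(0)
  for (j in seq_len(n)) {
    if (j == i) next
    found <- FALSE
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
      d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
      if (abs(d) < 1e-12) next
      ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / d
      uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / d
      rr <- sqrt((ax - ux)^2 + (ay - uy)^2)
      dmin <- min(sqrt((x[-c(i, j, k)] - ux)^2 + (y[-c(i, j, k)] - uy)^2))
      if (length(x) == 3 || dmin >= rr - 1e-9) { found <- TRUE; break }
    }
    if (found) nb <- c(nb, j)
  }
  sort(nb)
}

# a small random epithelium without any relaxation guarantees
random_epithelium <- function(n, avg = 10, sv = 1, side = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(side)) side <- ceiling(sqrt(n)) * 2 * avg
  ommatid:::new_epithelium(
    id = seq_len(n), x = runif(n, 0, side), y = runif(n, 0, side),
    r = pmax(rnorm(n, avg, sv), 0.2 * avg),
    fate = rep(1L, n), target = rep(avg, n), unit = rep(NA_integer_, n),
    domain = c(0, side, 0, side), avg_cell_size = avg)
}
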