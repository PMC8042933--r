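# Independent oracles used across the suite.  Each is deliberately naive:
# brute force or exhaustive enumeration, never sharing code with the package
# paths it checks.

# Nearest-point labels on a fine raster; adjacency = two labels occupying
# 4-neighbouring raster cells.  Oracle for the Voronoi adjacency graph.
raster_adjacency <- function(points, region, res = 220L) {
  xs <- seq(min(region[, 1]), max(region[, 1]), length.out = res)
  ys <- seq(min(region[, 2]), max(region[, 2]), length.out = res)
  gx <- matrix(rep(xs, each = length(ys)), length(ys))
  gy <- matrix(rep(ys, length(xs)), length(ys))
  lab <- matrix(0L, length(ys), length(xs))
  d2best <- matrix(Inf, length(ys), length(xs))
  for (i in seq_len(nrow(points))) {
    d2 <- (gx - points$x[i])^2 + (gy - points$y[i])^2
    upd <- d2 < d2best
    lab[upd] <- i
    d2best[upd] <- d2[upd]
  }
  edges <- unique(rbind(
    cbind(as.vector(lab[-1, ]), as.vector(lab[-nrow(lab), ])),
    cbind(as.vector(lab[, -1]), as.vector(lab[, -ncol(lab)]))))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  unique(t(apply(edges, 1, sort)))
}

# All-pairs shortest path lengths by exhaustive path enumeration (depth-first
# over simple paths) -- usable only on tiny graphs.
enumerate_shortest_paths <- function(n, edges) {
  adj <- lapply(seq_len(n), function(i)
    sort(unique(c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1]))))
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  explore <- function(path, target) {
    v <- path[length(path)]
    if (v == target) {
      s <- path[1]
      best[s, target] <<- min(best[s, target], length(path) - 1)
      return(invisible())
    }
    if (length(path) - 1 >= best[path[1], target]) return(invisible())
    for (w in adj[[v]]) if (!w %in% path) explore(c(path, w), target)
  }
  for (s in seq_len(n)) for (t in seq_len(n)) if (s != t) explore(s, t)
  best
}

# A hand-built three-nest season on a line: middle nest adjacent to both
# ends, ends not adjacent to each other (their cells are separated by the
# middle strip).
line_season <- function(dates = c(120L, 130L, 125L),
                        m_tarsus = c(18, 20, 19),
                        year = 1L) {
  nests <- data.frame(year = year, nest_id = c("A", "B", "C"),
                      x = c(0, 50, 100), y = c(0, 0, 0),
                      laying_date = dates,
                      male_id = c("M1", "M2", "M3"),
                      female_id = c("F1", "F2", "F3"),
                      female_status = "monogamous",
                      stringsAsFactors = FALSE)
  birds <- data.frame(year = year,
                      bird_id = c("M1", "M2", "M3", "F1", "F2", "F3"),
                      sex = rep(c("male", "female"), each = 3),
                      age = c(1, 2, 3, 1, 2, 3),
                      tarsus = c(m_tarsus, 19.2, 19.4, 19.6),
                      wing = c(79, 80, 81, 77, 78, 79),
                      forehead = c(40, 45, 50, NA, NA, NA),
                      blackness = c(50, 60, 70, NA, NA, NA),
                      stringsAsFactors = FALSE)
  tess <- build_tessellation(data.frame(id = nests$nest_id, x = nests$x, y = nests$y),
                             year = year)
  list(nests = nests, birds = birds, tess = tess)
}

# Small generator configuration for fast structural tests.
tiny_config <- function(...) {
  args <- list(n_seasons = 2L, n_boxes = 40L, extent = c(0, 1000, 0, 80))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Length of the boundary segment two territory cells share (0 for point
# contact), measured from the cell polygons themselves.
cell_shared_length <- function(tess, a, b) {
  xy <- tess$cells[[as.character(a)]]
  pa <- unlist(tess$points[tess$points$id == a, c("x", "y")])
  pb <- unlist(tess$points[tess$points$id == b, c("x", "y")])
  da <- sqrt((xy[, 1] - pa[1])^2 + (xy[, 2] - pa[2])^2)
  db <- sqrt((xy[, 1] - pb[1])^2 + (xy[, 2] - pb[2])^2)
  on <- abs(da - db) < 1e-6 * (1 + da)
  if (sum(on) < 2) return(0)
  v <- xy[on, , drop = FALSE]
  max(dist(v))
}

expect_setequal_pairs <- function(adj, expected) {
  got <- apply(adj, 1, function(r) paste(sort(r), collapse = "-"))
  want <- apply(expected, 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(got, want)
}
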