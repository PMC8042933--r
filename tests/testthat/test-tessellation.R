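# Territory tessellation, adjacency and neighbour orders.

test_that("two nests split the region along the perpendicular bisector", {
  tess <- build_tessellation(data.frame(id = c("a", "b"), x = c(25, 75), y = c(50, 50)),
                             bounding = "rect", extent = c(0, 100, 0, 100))
  expect_equal(sort(names(tess$cells)), c("a", "b"))
  expect_equal(unname(tess$areas[["a"]]), 5000, tolerance = 1e-9)
  expect_equal(unname(tess$areas[["b"]]), 5000, tolerance = 1e-9)
  expect_equal(nrow(tess$adjacency), 1L)
  expect_equal(neighbor_order(tess, "a", "b"), 1)
})

test_that("3x3 grid: centre cell is rook-adjacent to exactly its 4 neighbours", {
  g <- expand.grid(x = c(0, 10, 20), y = c(0, 10, 20))
  pts <- data.frame(id = paste0("n", 1:9), g)
  tess <- build_tessellation(pts, bounding = "rect", extent = c(-5, 25, -5, 25))
  centre <- "n5"
  nb <- neighborhood(tess, centre, 1)
  expect_setequal(nb, c("n2", "n4", "n6", "n8"))
  # raster nearest-neighbour oracle agrees
  oracle <- raster_adjacency(pts, tess$region, res = 240)
  idx <- setNames(seq_len(9), pts$id)
  pkg_edges <- cbind(idx[tess$adjacency$a], idx[tess$adjacency$b])
  expect_setequal_pairs(pkg_edges, oracle)
})

test_that("four corner nests meet diagonals only at a point: no adjacency", {
  pts <- data.frame(id = 1:4, x = c(0, 10, 0, 10), y = c(0, 0, 10, 10))
  tess <- build_tessellation(pts, bounding = "rect", extent = c(-2, 12, -2, 12))
  deg <- table(c(tess$adjacency$a, tess$adjacency$b))
  expect_true(all(deg == 2))
  expect_equal(nrow(tess$adjacency), 4L)
})

test_that("cell areas tile the bounding region", {
  pts <- data.frame(id = 1:40,
                    x = withr::with_seed(31, runif(40, 0, 300)),
                    y = withr::with_seed(32, runif(40, 0, 200)))
  for (bnd in c("hull", "rect")) {
    tess <- build_tessellation(pts, bounding = bnd,
                               extent = if (bnd == "rect") c(-10, 310, -10, 210))
    expect_equal(sum(tess$areas), polynest:::polygon_area(tess$region),
                 tolerance = 1e-6)
  }
})

test_that("adjacency is invariant under translation and rotation", {
  pts <- data.frame(id = 1:25,
                    x = withr::with_seed(41, runif(25, 0, 100)),
                    y = withr::with_seed(42, runif(25, 0, 100)))
  tess0 <- build_tessellation(pts)
  th <- 0.6
  rot <- data.frame(id = pts$id,
                    x = 500 + cos(th) * pts$x - sin(th) * pts$y,
                    y = -80 + sin(th) * pts$x + cos(th) * pts$y)
  tess1 <- build_tessellation(rot)
  key <- function(tt) sort(paste(pmin(tt$adjacency$a, tt$adjacency$b),
                                 pmax(tt$adjacency$a, tt$adjacency$b)))
  expect_identical(key(tess0), key(tess1))
})

test_that("neighbour orders match exhaustive path enumeration on small tessellations", {
  for (s in 1:6) {
    n <- 5 + (s %% 4)
    pts <- data.frame(id = seq_len(n),
                      x = withr::with_seed(100 + s, runif(n, 0, 60)),
                      y = withr::with_seed(200 + s, runif(n, 0, 60)))
    tess <- build_tessellation(pts)
    idx <- setNames(seq_len(n), tess$ids)
    edges <- cbind(idx[tess$adjacency$a], idx[tess$adjacency$b])
    oracle <- enumerate_shortest_paths(n, edges)
    got <- tess$order[as.character(seq_len(n)), as.character(seq_len(n))]
    expect_equal(unname(got), unname(oracle))
  }
})

test_that("neighbourhood rules: inclusive is the disjoint union of exact shells", {
  g <- expand.grid(x = seq(0, 40, 10), y = seq(0, 40, 10))
  pts <- data.frame(id = seq_len(nrow(g)), g)
  tess <- build_tessellation(pts, bounding = "rect", extent = c(-5, 45, -5, 45))
  centre <- as.character(which(g$x == 20 & g$y == 20))
  expect_setequal(neighborhood(tess, centre, 2, "inclusive"),
                  union(neighborhood(tess, centre, 1, "exact"),
                        neighborhood(tess, centre, 2, "exact")))
  expect_length(intersect(neighborhood(tess, centre, 1, "exact"),
                          neighborhood(tess, centre, 2, "exact")), 0)
  expect_setequal(neighborhood(tess, centre, 1, "inclusive"),
                  neighborhood(tess, centre, 1, "exact"))
})

test_that("3x3 grid neighbourhoods: inclusive k=2 is everyone, exact k=2 the corners", {
  g <- expand.grid(x = c(0, 10, 20), y = c(0, 10, 20))
  pts <- data.frame(id = paste0("n", 1:9), g)
  tess <- build_tessellation(pts, bounding = "rect", extent = c(-5, 25, -5, 25))
  expect_setequal(neighborhood(tess, "n5", 2, "inclusive"), paste0("n", c(1:4, 6:9)))
  expect_setequal(neighborhood(tess, "n5", 2, "exact"), paste0("n", c(1, 3, 7, 9)))
  expect_equal(neighbor_order(tess, "n1", "n9"), 4)  # corner to corner, rook moves
  expect_equal(neighbor_order(tess, "n1", "n1"), 0)
})

test_that("degenerate inputs are rejected", {
  expect_error(build_tessellation(data.frame(id = 1, x = 0, y = 0)), "at least 2")
  expect_error(build_tessellation(data.frame(id = 1:2, x = c(1, 1), y = c(2, 2))),
               "duplicate")
  expect_error(build_tessellation(data.frame(id = 1:2, x = c(1, 50), y = c(1, 1)),
                                  bounding = "rect", extent = c(0, 10, 0, 10)),
               "outside")
  tess <- build_tessellation(data.frame(id = 1:2, x = c(1, 5), y = c(1, 1)))
  expect_error(neighborhood(tess, "1", 0), "k must be")
  expect_error(neighbor_order(tess, "1", "zz"), "unknown")
})

test_that("tessellation exports valid GeoJSON", {
  tess <- build_tessellation(data.frame(id = c("a", "b", "c"),
                                        x = c(0, 30, 60), y = c(0, 20, 0)))
  f <- tempfile(fileext = ".geojson")
  tessellation_to_geojson(tess, f)
  gj <- jsonlite::read_json(f)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 3)
})
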