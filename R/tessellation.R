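## Thiessen (Voronoi) territory tessellation and neighbour orders.
##
## Each occupied nest defines a territory: the region of the plane closer to
## it than to any other occupied nest, clipped to a bounding region.  The
## tessellation is built by half-plane intersection: a cell starts as the
## bounding polygon and is cut by the perpendicular bisector against every
## other nest, nearest first, stopping as soon as no remaining nest can still
## cut the cell.  Every polygon edge carries the identity of the bisector (or
## bounding edge) that produced it, so territory adjacency -- a shared
## boundary segment of positive length -- falls directly out of the
## construction.  Point contacts (four-corner degeneracies) do not create
## adjacency.

# Clip convex polygon `poly` (list: xy matrix, tag per edge starting at each
# vertex) with the half-plane {p : (p - q) . nrm <= 0}.  The chord created by
# the cut is tagged `tag_new`.
clip_halfplane <- function(poly, q, nrm, tag_new) {
  xy <- poly$xy
  nv <- nrow(xy)
  d <- (xy[, 1L] - q[1L]) * nrm[1L] + (xy[, 2L] - q[2L]) * nrm[2L]
  inside <- d <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(list(xy = xy[0, , drop = FALSE], tag = integer(0)))
  vx <- numeric(nv + 2L); vy <- numeric(nv + 2L); tg <- integer(nv + 2L)
  k <- 0L
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    if (inside[i]) {
      k <- k + 1L; vx[k] <- xy[i, 1L]; vy[k] <- xy[i, 2L]; tg[k] <- poly$tag[i]
      if (!inside[j]) {                       # leaving: cut point starts chord
        t <- d[i] / (d[i] - d[j])
        k <- k + 1L
        vx[k] <- xy[i, 1L] + t * (xy[j, 1L] - xy[i, 1L])
        vy[k] <- xy[i, 2L] + t * (xy[j, 2L] - xy[i, 2L])
        tg[k] <- tag_new
      }
    } else if (inside[j]) {                   # entering: cut point resumes edge i
      t <- d[i] / (d[i] - d[j])
      k <- k + 1L
      vx[k] <- xy[i, 1L] + t * (xy[j, 1L] - xy[i, 1L])
      vy[k] <- xy[i, 2L] + t * (xy[j, 2L] - xy[i, 2L])
      tg[k] <- poly$tag[i]
    }
  }
  list(xy = cbind(vx[seq_len(k)], vy[seq_len(k)]), tag = tg[seq_len(k)])
}

polygon_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(xy[, 1L] * xy[j, 2L] - xy[j, 1L] * xy[, 2L])) / 2
}

# Bounding region as a convex polygon (counter-clockwise vertex matrix).
bounding_region <- function(pts, bounding, buffer, extent) {
  if (bounding == "rect") {
    if (is.null(extent)) {
      r <- buffer %||% median_nn_distance(pts)
      extent <- c(min(pts[, 1L]) - r, max(pts[, 1L]) + r,
                  min(pts[, 2L]) - r, max(pts[, 2L]) + r)
    }
    if (extent[2L] <= extent[1L] || extent[4L] <= extent[3L])
      stop_bad_arg("degenerate bounding extent")
    return(cbind(extent[c(1L, 2L, 2L, 1L)], extent[c(3L, 3L, 4L, 4L)]))
  }
  r <- buffer %||% median_nn_distance(pts)
  h <- grDevices::chull(pts)                   # clockwise vertex indices
  if (length(h) < 3L) {                        # collinear: expanded bounding box
    return(bounding_region(pts, "rect", r, NULL))
  }
  h <- rev(h)                                  # counter-clockwise
  hx <- pts[h, 1L]; hy <- pts[h, 2L]
  # big start rectangle, then cut by each hull edge pushed outward by r
  pad <- r + max(diff(range(pts[, 1L])), diff(range(pts[, 2L]))) + 1
  poly <- list(xy = cbind(c(min(hx) - pad, max(hx) + pad, max(hx) + pad, min(hx) - pad),
                          c(min(hy) - pad, min(hy) - pad, max(hy) + pad, max(hy) + pad)),
               tag = integer(4L))
  nh <- length(h)
  for (e in seq_len(nh)) {
    f <- if (e == nh) 1L else e + 1L
    ex <- hx[f] - hx[e]; ey <- hy[f] - hy[e]
    len <- sqrt(ex^2 + ey^2)
    if (len < 1e-12) next
    nrm <- c(ey, -ex) / len                    # outward normal for CCW polygon
    q <- c(hx[e] + nrm[1L] * r, hy[e] + nrm[2L] * r)
    poly <- clip_halfplane(poly, q, nrm, 0L)
  }
  poly$xy
}

median_nn_distance <- function(pts) {
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  stats::median(apply(d, 1L, min))
}

#' Build a Thiessen-polygon territory tessellation
#'
#' Partitions the bounding region among nests so that every location belongs
#' to the territory of its nearest nest, and derives the territory adjacency
#' graph: two territories are adjacent when their cells share a boundary
#' segment of positive length (greater than `adjacency_tol`; a shared corner
#' point is not adjacency).
#'
#' @param points A data frame with columns `id`, `x`, `y` (planar metres), one
#'   row per occupied nest.  Coordinates must be distinct.
#' @param bounding `"hull"` (default) clips cells to the convex hull of the
#'   nests buffered outward by `buffer`; `"rect"` clips to the rectangle
#'   `extent`.
#' @param buffer Hull buffer width in metres; defaults to the median
#'   nearest-neighbour distance between nests.
#' @param extent For `bounding = "rect"`: `c(xmin, xmax, ymin, ymax)`.
#' @param year Optional season label carried through to outputs.
#' @param adjacency_tol Minimum shared-edge length (m) that counts as
#'   adjacency.
#' @return An object of class `tessellation`: territory polygons (`cells`),
#'   their areas, the bounding `region`, the adjacency edge list and graph,
#'   and the matrix of neighbour orders (`order`, shortest path lengths on the
#'   adjacency graph).
#' @seealso [neighbor_order()], [neighborhood()]
#' @export
build_tessellation <- function(points, bounding = c("hull", "rect"), buffer = NULL,
                               extent = NULL, year = NULL, adjacency_tol = 1e-9) {
  bounding <- match.arg(bounding)
  if (!all(c("id", "x", "y") %in% names(points)))
    stop_bad_arg("`points` must have columns id, x, y")
  ids <- as.character(points$id)
  pts <- cbind(points$x, points$y)
  n <- nrow(pts)
  if (n < 2L) stop_bad_arg("at least 2 nests are required")
  if (anyDuplicated(ids)) stop_bad_arg("duplicate nest ids")
  if (anyDuplicated(pts[, 1L] + 1i * pts[, 2L]))
    stop_bad_arg("duplicate nest coordinates")
  region <- bounding_region(pts, bounding, buffer, extent)
  inreg <- point_in_convex(pts, region)
  if (!all(inreg)) stop_bad_arg("nest(s) outside the bounding region: ",
                                paste(ids[!inreg], collapse = ", "))

  d2 <- as.matrix(stats::dist(pts))^2
  cells <- vector("list", n)
  adj_i <- integer(0); adj_j <- integer(0)
  for (i in seq_len(n)) {
    poly <- list(xy = region, tag = rep(-1L, nrow(region)))
    ord <- order(d2[i, ])
    ord <- ord[ord != i]
    r2 <- max((poly$xy[, 1L] - pts[i, 1L])^2 + (poly$xy[, 2L] - pts[i, 2L])^2)
    for (j in ord) {
      if (d2[i, j] / 4 > r2) break
      mid <- (pts[i, ] + pts[j, ]) / 2
      nrm <- pts[j, ] - pts[i, ]
      nv <- nrow(poly$xy)
      poly <- clip_halfplane(poly, mid, nrm, j)
      if (nrow(poly$xy) != nv || any(poly$tag == j))
        r2 <- max((poly$xy[, 1L] - pts[i, 1L])^2 + (poly$xy[, 2L] - pts[i, 2L])^2)
    }
    cells[[i]] <- poly
    # neighbours: bisector edges of positive length
    xy <- poly$xy
    nv <- nrow(xy)
    if (nv >= 2L) {
      nxt <- c(2:nv, 1L)
      el <- sqrt((xy[nxt, 1L] - xy[, 1L])^2 + (xy[nxt, 2L] - xy[, 2L])^2)
      keep <- poly$tag > 0L & el > adjacency_tol
      if (any(keep)) {
        tj <- unique(poly$tag[keep])
        adj_i <- c(adj_i, rep.int(i, length(tj))); adj_j <- c(adj_j, tj)
      }
    }
  }
  # symmetrize (union: numerically a shared edge can fall below tol on one side)
  a <- unique(data.frame(i = pmin(adj_i, adj_j), j = pmax(adj_i, adj_j)))
  g <- igraph::graph_from_edgelist(cbind(ids[a$i], ids[a$j]), directed = FALSE)
  g <- g + igraph::vertices(setdiff(ids, igraph::V(g)$name))
  ord_mat <- igraph::distances(g)[ids, ids, drop = FALSE]
  areas <- vapply(cells, function(p) polygon_area(p$xy), numeric(1))
  names(cells) <- ids; names(areas) <- ids
  structure(list(year = year, ids = ids, points = points,
                 cells = lapply(cells, `[[`, "xy"), areas = areas,
                 region = region,
                 adjacency = data.frame(a = ids[a$i], b = ids[a$j]),
                 graph = g, order = ord_mat),
            class = "tessellation")
}

point_in_convex <- function(pts, region, tol = 1e-9) {
  nv <- nrow(region)
  ok <- rep(TRUE, nrow(pts))
  for (e in seq_len(nv)) {
    f <- if (e == nv) 1L else e + 1L
    ex <- region[f, 1L] - region[e, 1L]; ey <- region[f, 2L] - region[e, 2L]
    s <- (pts[, 1L] - region[e, 1L]) * ey - (pts[, 2L] - region[e, 2L]) * ex
    ok <- ok & s <= tol * (abs(ex) + abs(ey) + 1)
  }
  ok
}

#' @export
print.tessellation <- function(x, ...) {
  cat("Territory tessellation", if (!is.null(x$year)) paste0("(year ", x$year, ")"),
      "\n  nests:", length(x$ids),
      "\n  adjacencies:", nrow(x$adjacency),
      "\n  region area:", format(polygon_area(x$region), digits = 6), "m^2\n")
  invisible(x)
}

#' Neighbour order between two territories
#'
#' The neighbour order of two nests is the shortest path length between their
#' territories on the adjacency graph: 0 for a nest with itself, 1 for
#' territories sharing a boundary, 2 for neighbours-of-neighbours, and so on.
#'
#' @param tess A [build_tessellation()] result.
#' @param a,b Nest ids.
#' @return Integer order; `Inf` (with a warning) if the pair is unreachable.
#' @export
neighbor_order <- function(tess, a, b) {
  a <- as.character(a); b <- as.character(b)
  bad <- setdiff(c(a, b), tess$ids)
  if (length(bad)) stop_bad_arg("unknown nest id(s): ", paste(bad, collapse = ", "))
  o <- tess$order[cbind(a, b)]
  if (any(is.infinite(o))) warning("unreachable territory pair")
  o
}

#' Territory neighbourhood of a focal nest
#'
#' @param tess A [build_tessellation()] result.
#' @param focal Focal nest id (never part of its own neighbourhood).
#' @param k Neighbour order bound, `k >= 1`.
#' @param rule `"inclusive"`: all territories at order 1..k (the default
#'   neighbourhood definition); `"exact"`: territories at order exactly k.
#' @return Character vector of nest ids.
#' @export
neighborhood <- function(tess, focal, k, rule = c("inclusive", "exact")) {
  rule <- match.arg(rule)
  focal <- as.character(focal)
  if (!focal %in% tess$ids) stop_bad_arg("unknown nest id: ", focal)
  if (!is.numeric(k) || k < 1) stop_bad_arg("k must be >= 1")
  o <- tess$order[focal, ]
  ids <- tess$ids[if (rule == "inclusive") o >= 1 & o <= k else o == k]
  setdiff(ids, focal)
}

#' Export tessellation cells as GeoJSON and adjacency as a data frame
#'
#' @param tess A [build_tessellation()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
tessellation_to_geojson <- function(tess, path) {
  feats <- lapply(tess$ids, function(id) {
    xy <- tess$cells[[id]]
    ring <- rbind(xy, xy[1L, , drop = FALSE])
    list(type = "Feature",
         properties = list(nest_id = id, area_m2 = unname(tess$areas[[id]]),
                           year = tess$year),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(r) as.numeric(ring[r, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
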