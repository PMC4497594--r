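# Distance measures between district reference points: Euclidean,
# road-network shortest path, and least-cost travel time over a friction
# surface.

#' Euclidean distance matrix between centroids
#'
#' @param centroids data.frame with `district_id`, `x`, `y` (planar km).
#' @return symmetric matrix (km) with zero diagonal, dimnames = district ids.
#' @export
euclidean_matrix <- function(centroids) {
  assert_cols(centroids, c("district_id", "x", "y"), "centroids")
  stopifnot(all(is.finite(centroids$x)), all(is.finite(centroids$y)))
  D <- as.matrix(dist(cbind(centroids$x, centroids$y)))
  dimnames(D) <- list(centroids$district_id, centroids$district_id)
  D
}

#' Population-weighted district centroids
#'
#' The centroid of each district is the population-weighted mean of its
#' cell centres. Districts with zero total population fall back to the
#' unweighted (geometric) centroid of their cells, with a warning.
#' Optionally the centroid is snapped to the nearest road node.
#'
#' @param population `ascii_grid` of per-cell population.
#' @param district_mask `ascii_grid` of district indices (same shape).
#' @param ids district ids corresponding to mask values `1..n`; defaults to
#'   the sorted unique mask values as character.
#' @param road_nodes optional data.frame `node_id`, `x`, `y`; when given,
#'   centroids are moved to the nearest road node (ties to the lowest
#'   node id).
#' @return data.frame `district_id`, `x`, `y`, `variant`.
#' @export
population_weighted_centroids <- function(population, district_mask,
                                          ids = NULL, road_nodes = NULL) {
  stopifnot(inherits(population, "ascii_grid"),
            inherits(district_mask, "ascii_grid"))
  if (!all(dim(population$data) == dim(district_mask$data)) ||
      population$cellsize != district_mask$cellsize) {
    stopf("population and district_mask grids are not aligned")
  }
  cc <- grid_cell_centers(population)
  vals <- sort(unique(as.vector(district_mask$data)))
  vals <- vals[!is.na(vals)]
  ids <- ids %||% as.character(vals)
  xs <- numeric(length(vals)); ys <- numeric(length(vals))
  for (k in seq_along(vals)) {
    in_d <- which(district_mask$data == vals[k])
    w <- population$data[in_d]
    w[is.na(w)] <- 0
    if (sum(w) <= 0) {
      warning(sprintf("district %s has zero population; using geometric centroid",
                      ids[k]), call. = FALSE)
      w <- rep(1, length(in_d))
    }
    xs[k] <- sum(cc$x[in_d] * w) / sum(w)
    ys[k] <- sum(cc$y[in_d] * w) / sum(w)
  }
  out <- data.frame(district_id = ids, x = xs, y = ys,
                    variant = "population-weighted", stringsAsFactors = FALSE)
  if (!is.null(road_nodes)) {
    snap <- snap_to_nodes(out, road_nodes)
    out$x <- road_nodes$x[snap]
    out$y <- road_nodes$y[snap]
    out$variant <- "population-weighted, road-snapped"
  }
  out
}

# Index of the nearest node for each centroid; ties go to the lowest
# node_id (after sorting nodes by id the first minimum wins).
snap_to_nodes <- function(centroids, nodes) {
  ord <- order(nodes$node_id)
  nodes <- nodes[ord, , drop = FALSE]
  idx <- vapply(seq_len(nrow(centroids)), function(i) {
    d2 <- (nodes$x - centroids$x[i])^2 + (nodes$y - centroids$y[i])^2
    which.min(d2)
  }, integer(1))
  ord[idx]
}

#' Road-network distance matrix
#'
#' Shortest-path length (km) over an undirected road graph between the
#' nodes each centroid snaps to.
#'
#' @param edges data.frame `node_a`, `node_b`, `length_km`.
#' @param centroids data.frame `district_id`, `x`, `y`.
#' @param nodes optional data.frame `node_id`, `x`, `y` giving node
#'   coordinates for snapping; when NULL, district ids are assumed to be
#'   node ids directly.
#' @return matrix (km) with dimnames = district ids.
#' @export
road_distance_matrix <- function(edges, centroids, nodes = NULL) {
  assert_cols(edges, c("node_a", "node_b", "length_km"), "edges")
  if (any(edges$length_km <= 0)) stopf("road edge lengths must be positive")
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$node_a),
               to = as.character(edges$node_b)),
    directed = FALSE)
  igraph::E(g)$weight <- edges$length_km
  if (is.null(nodes)) {
    node_of <- centroids$district_id
    absent <- setdiff(node_of, igraph::V(g)$name)
    if (length(absent)) {
      stopf("district(s) not on the road network: %s",
            paste(absent, collapse = ", "))
    }
  } else {
    node_of <- nodes$node_id[snap_to_nodes(centroids, nodes)]
  }
  comp <- igraph::components(g)
  mem <- comp$membership[node_of]
  if (length(unique(mem)) > 1L) {
    grp <- split(centroids$district_id, mem)
    stopf("road network is disconnected over snapped centroids; components: %s",
          paste(vapply(grp, paste, character(1), collapse = ","),
                collapse = " | "))
  }
  D <- igraph::distances(g, v = node_of, to = node_of)
  dimnames(D) <- list(centroids$district_id, centroids$district_id)
  D
}

#' Derive a friction surface from land cover, slope and roads
#'
#' Per-cell traversal speed (km/h) is the land-class base speed damped by
#' slope, `speed = base[land] * exp(-slope_coef * slope)`; cells crossed by
#' a road edge are raised to at least `road_speed`. A base speed of 0 marks
#' the class impassable.
#'
#' @param land `ascii_grid` of integer land classes (1-based).
#' @param slope `ascii_grid` of slope (rise/run), same shape.
#' @param speeds base speed (km/h) per land class; defaults to walking-type
#'   speeds `c(4, 2, 5)` and recycles if more classes are present.
#' @param slope_coef slope damping coefficient (per unit rise/run).
#' @param roads,road_nodes optional road edge list and node coordinates;
#'   edges are rasterised onto the grid.
#' @param road_speed speed (km/h) assigned to road cells.
#' @return `ascii_grid` of speeds; impassable cells are 0.
#' @export
friction_surface <- function(land, slope, speeds = c(4, 2, 5),
                             slope_coef = 3, roads = NULL, road_nodes = NULL,
                             road_speed = 50) {
  stopifnot(inherits(land, "ascii_grid"), inherits(slope, "ascii_grid"))
  if (!all(dim(land$data) == dim(slope$data))) {
    stopf("land and slope grids are not aligned")
  }
  cls <- land$data
  k <- max(cls, na.rm = TRUE)
  base <- rep_len(speeds, k)
  v <- matrix(base[cls], nrow(cls), ncol(cls))
  v <- v * exp(-slope_coef * slope$data)
  v[base[cls] <= 0] <- 0
  if (!is.null(roads)) {
    stopifnot(!is.null(road_nodes))
    cs <- land$cellsize
    for (r in seq_len(nrow(roads))) {
      a <- match(roads$node_a[r], road_nodes$node_id)
      b <- match(roads$node_b[r], road_nodes$node_id)
      len <- sqrt((road_nodes$x[a] - road_nodes$x[b])^2 +
                    (road_nodes$y[a] - road_nodes$y[b])^2)
      t <- seq(0, 1, length.out = max(2L, ceiling(len / (cs / 2)) + 1L))
      px <- road_nodes$x[a] + t * (road_nodes$x[b] - road_nodes$x[a])
      py <- road_nodes$y[a] + t * (road_nodes$y[b] - road_nodes$y[a])
      rc <- grid_cell_of(land, px, py)
      v[rc] <- pmax(v[rc], road_speed)
    }
  }
  ascii_grid(v, land$cellsize, land$xll, land$yll)
}

#' Least-cost travel-time matrix over a friction surface
#'
#' Shortest travel time (hours) between the cells containing each centroid,
#' on the 8-connected cell graph. The cost of a move is the mean of the two
#' adjacent cell-crossing times, times sqrt(2) for diagonal moves. Routes
#' with no passable path get `Inf` with a warning.
#'
#' @param friction `ascii_grid` of speeds (km/h); cells with speed <= 0 or
#'   NA are impassable.
#' @param centroids data.frame `district_id`, `x`, `y`.
#' @return symmetric matrix of hours, dimnames = district ids.
#' @export
travel_time_matrix <- function(friction, centroids) {
  stopifnot(inherits(friction, "ascii_grid"))
  v <- friction$data
  nr <- nrow(v); nc <- ncol(v); cs <- friction$cellsize
  pass <- is.finite(v) & v > 0
  tcell <- cs / v            # hours to cross a full cell
  tcell[!pass] <- NA_real_
  id <- function(r, c) (c - 1L) * nr + r   # column-major cell index

  edge_pairs <- function(dr, dc) {
    rows <- seq_len(nr); cols <- seq_len(nc)
    rows <- rows[rows + dr >= 1 & rows + dr <= nr]
    cols <- cols[cols + dc >= 1 & cols + dc <= nc]
    if (!length(rows) || !length(cols)) return(NULL)
    r1 <- rep(rows, times = length(cols))
    c1 <- rep(cols, each = length(rows))
    r2 <- r1 + dr; c2 <- c1 + dc
    a <- id(r1, c1); b <- id(r2, c2)
    ok <- pass[a] & pass[b]
    if (!any(ok)) return(NULL)
    w <- (tcell[a[ok]] + tcell[b[ok]]) / 2
    if (dr != 0 && dc != 0) w <- w * sqrt(2)
    cbind(a[ok], b[ok], w)
  }
  dirs <- list(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))
  el <- do.call(rbind, lapply(dirs, function(d) edge_pairs(d[1], d[2])))
  if (is.null(el)) stopf("friction surface has no passable adjacent cells")
  g <- igraph::make_graph(edges = as.vector(t(el[, 1:2])), n = nr * nc,
                          directed = FALSE)
  rc <- grid_cell_of(friction, centroids$x, centroids$y)
  cells <- id(rc[, "row"], rc[, "col"])
  if (any(!pass[cells])) {
    stopf("centroid(s) fall on impassable cells: %s",
          paste(centroids$district_id[!pass[cells]], collapse = ", "))
  }
  D <- igraph::distances(g, v = cells, to = cells, weights = el[, 3])
  dimnames(D) <- list(centroids$district_id, centroids$district_id)
  if (any(is.infinite(D))) {
    warning("some routes have no passable path; travel time set to Inf",
            call. = FALSE)
  }
  D
}

#' Correlations among distance measures
#'
#' Pearson correlations of the off-diagonal entries of two or more distance
#' matrices over the same districts (finite entries only).
#'
#' @param measures named list of distance matrices with identical dimnames.
#' @return correlation matrix.
#' @export
distance_correlations <- function(measures) {
  stopifnot(length(measures) >= 2L)
  ids <- rownames(measures[[1]])
  off <- upper.tri(measures[[1]]) | lower.tri(measures[[1]])
  m <- sapply(measures, function(M) M[ids, ids][off])
  ok <- apply(is.finite(m), 1L, all)
  cor(m[ok, , drop = FALSE])
}

#' Approximate planar km coordinates from longitude/latitude
#'
#' Equirectangular projection about a reference latitude; adequate for
#' country-scale extents, documented as approximate.
#'
#' @param lon,lat coordinates in degrees.
#' @param lat0 reference latitude (defaults to the mean of `lat`).
#' @return data.frame `x`, `y` in km.
#' @export
lonlat_to_km <- function(lon, lat, lat0 = mean(lat)) {
  R <- 6371
  data.frame(x = R * cos(lat0 * pi / 180) * lon * pi / 180,
             y = R * lat * pi / 180)
}
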