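# Synthetic-data generators: districts, flows, rasters.
#
# These produce data with the statistical structure the downstream analysis
# assumes (heavy-tailed populations, distance-decaying Poisson flows,
# call-gapped subscriber diaries, friction rasters), with full ground truth
# retained, so the whole pipeline can be exercised without any real data.

#' Generate a synthetic district set
#'
#' Districts receive log-normal populations (heavy tail, mimicking the
#' contrast between a primate city and sparse rural regions) and planar km
#' coordinates on a square. A few "city" clusters are planted: the largest
#' districts seed the clusters and a fraction of the remaining districts are
#' scattered around them, so urban/rural spatial contrasts exist.
#'
#' @param n_districts number of districts (>= 2).
#' @param pop_meanlog,pop_sdlog parameters of the log-normal population law.
#' @param size_km side of the square study region, km.
#' @param n_cities number of planted city clusters.
#' @param cluster_frac fraction of non-seed districts placed near a cluster.
#' @param cluster_sd_km spread (km) of districts around their cluster seed.
#' @param min_spacing_km minimum distance between any two centroids.
#'   Districts are areal units that tile the country, so their reference
#'   points cannot be arbitrarily close; points violating the spacing are
#'   resampled.
#' @param seed master seed; every generator derives its own stream from it.
#' @return a `data.frame` with columns `district_id`, `population`, `x`, `y`.
#' @export
generate_districts <- function(n_districts = 69,
                               pop_meanlog = 12.61, pop_sdlog = 1.0,
                               size_km = 800, n_cities = 3,
                               cluster_frac = 0.35, cluster_sd_km = 30,
                               min_spacing_km = 20, seed = 1) {
  if (n_districts < 2) stopf("n_districts must be >= 2, got %d", n_districts)
  with_seed(stream_seed(seed, "districts"), {
    pop <- pmax(1, round(rlnorm(n_districts, pop_meanlog, pop_sdlog)))
    ord <- order(pop, decreasing = TRUE)
    pop <- pop[ord]
    x <- runif(n_districts, 0, size_km)
    y <- runif(n_districts, 0, size_km)
    n_cities <- min(n_cities, n_districts)
    if (n_cities > 0 && n_districts > n_cities) {
      rest <- seq.int(n_cities + 1L, n_districts)
      near <- rest[runif(length(rest)) < cluster_frac]
      if (length(near)) {
        seed_of <- sample.int(n_cities, length(near), replace = TRUE)
        x[near] <- pmin(pmax(x[seed_of] + rnorm(length(near), 0, cluster_sd_km), 0), size_km)
        y[near] <- pmin(pmax(y[seed_of] + rnorm(length(near), 0, cluster_sd_km), 0), size_km)
      }
    }
    # enforce the minimum spacing by resampling offenders (keeping them
    # near their cluster seed when they had one)
    for (attempt in seq_len(1000L)) {
      d <- as.matrix(dist(cbind(x, y)))
      diag(d) <- Inf
      bad <- which(apply(d, 1L, min) < min_spacing_km)
      bad <- bad[bad > 1L]   # never move the largest district
      if (!length(bad)) break
      idx <- bad[length(bad)]
      x[idx] <- runif(1, 0, size_km)
      y[idx] <- runif(1, 0, size_km)
    }
    if (length(bad)) stopf("could not satisfy min_spacing_km = %g with %d districts",
                           min_spacing_km, n_districts)
    data.frame(district_id = sprintf("D%02d", seq_len(n_districts)),
               population = pop, x = x, y = y,
               stringsAsFactors = FALSE)
  })
}

# Euclidean distance matrix straight from district coordinates.
district_distances <- function(districts) {
  d <- as.matrix(dist(cbind(districts$x, districts$y)))
  dimnames(d) <- list(districts$district_id, districts$district_id)
  d
}

#' Simulate origin-destination flows from a known interaction model
#'
#' Observed counts are independent Poisson draws around the truth-model mean
#' for every ordered pair of distinct districts. Optional multiplicative
#' log-normal route heterogeneity (mean-one) induces the overdispersion seen
#' in real flow tables.
#'
#' @param districts district set from [generate_districts()] (or any data
#'   frame with `district_id`, `population`, `x`, `y`).
#' @param truth a list: either `list(model = "gravity", alpha, beta, gamma,
#'   log_k)` or `list(model = "radiation", tct)`.
#' @param seed master seed.
#' @param distance optional distance matrix (km) to use instead of Euclidean
#'   centroid distance.
#' @param route_sdlog standard deviation of median-one log-normal route
#'   effects (so log-scale errors are centred at zero, the structure the
#'   downstream error diagnostics assume); 0 (default) gives pure Poisson
#'   sampling.
#' @param route_sdlog_halfvol volume scale damping the heterogeneity on
#'   busy routes: the effective SD is
#'   `route_sdlog / sqrt(1 + mean / route_sdlog_halfvol)`, emulating flow
#'   data whose largest volumes are the best described; `Inf` (default)
#'   keeps the SD constant across routes.
#' @return an OD table `data.frame`: `origin_id`, `dest_id`, `pop_orig`,
#'   `pop_dest`, `dist_euclid_km` (or the supplied measure), `trips`, plus a
#'   `truth_mean` column retaining the noiseless model mean.
#' @export
simulate_flows <- function(districts, truth, seed = 1, distance = NULL,
                           route_sdlog = 0, route_sdlog_halfvol = Inf) {
  ids <- districts$district_id
  n <- length(ids)
  if (n < 2) stopf("need at least 2 districts")
  D <- distance %||% district_distances(districts)
  D <- D[ids, ids]
  off <- upper.tri(D) | lower.tri(D)
  if (any(D[off] <= 0)) {
    stopf("zero or negative distance between distinct districts; degenerate geometry")
  }
  ij <- which(off, arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  i <- ij[, 1]; j <- ij[, 2]
  pop <- districts$population
  mu <- switch(truth$model,
    gravity = {
      stopifnot(all(is.finite(c(truth$alpha, truth$beta, truth$gamma, truth$log_k))))
      exp(truth$log_k + truth$alpha * log(pop[i]) + truth$beta * log(pop[j]) -
            truth$gamma * log(D[ij]))
    },
    radiation = {
      P <- radiation_matrix(pop, D, tct = truth$tct %||% 1)
      P[ij]
    },
    stopf("unknown truth model: %s", truth$model)
  )
  with_seed(stream_seed(seed, "flows"), {
    if (route_sdlog > 0) {
      sdl <- route_sdlog / sqrt(1 + mu / route_sdlog_halfvol)
      mu <- mu * rlnorm(length(mu), 0, sdl)
    }
    trips <- rpois(length(mu), mu)
  })
  data.frame(origin_id = ids[i], dest_id = ids[j],
             pop_orig = pop[i], pop_dest = pop[j],
             dist_euclid_km = D[ij], trips = trips, truth_mean = mu,
             stringsAsFactors = FALSE)
}

#' Generate aligned synthetic rasters and a road network
#'
#' Produces a population grid (district populations spread by Gaussian
#' kernels around their centroids), a district-mask grid (nearest centroid),
#' a land-class grid (smooth random patches), a slope grid, and a road edge
#' list connecting district centroids (k-nearest-neighbour graph augmented
#' to a single connected component).
#'
#' @param districts district set.
#' @param cell_km cell size, km.
#' @param margin_km margin added around the district bounding box.
#' @param n_land_classes number of land-cover classes.
#' @param road_k each district is linked to its `road_k` nearest neighbours.
#' @param road_windiness multiplier turning straight-line length into road
#'   length (>= 1).
#' @param seed master seed.
#' @return a list: `population`, `district_mask`, `land`, `slope` (all
#'   `ascii_grid`s, identical shape), `roads` (data.frame `node_a`, `node_b`,
#'   `length_km`) and `road_nodes` (data.frame `node_id`, `x`, `y`).
#' @export
generate_rasters <- function(districts, cell_km = 10, margin_km = 20,
                             n_land_classes = 3, road_k = 3,
                             road_windiness = 1.3, seed = 1) {
  xr <- range(districts$x); yr <- range(districts$y)
  xll <- xr[1] - margin_km; yll <- yr[1] - margin_km
  nc <- max(2L, ceiling((xr[2] - xr[1] + 2 * margin_km) / cell_km))
  nr <- max(2L, ceiling((yr[2] - yr[1] + 2 * margin_km) / cell_km))
  proto <- ascii_grid(matrix(0, nr, nc), cell_km, xll, yll)
  cc <- grid_cell_centers(proto)
  n <- nrow(districts)

  # district mask: nearest centroid
  d2 <- sapply(seq_len(n), function(k) {
    (cc$x - districts$x[k])^2 + (cc$y - districts$y[k])^2
  })
  mask <- matrix(max.col(-d2, ties.method = "first"), nr, nc)

  with_seed(stream_seed(seed, "rasters"), {
    # population: Gaussian kernel per district, renormalised to the
    # district total within its own cells
    popg <- matrix(0, nr, nc)
    bw2 <- (3 * cell_km)^2
    for (k in seq_len(n)) {
      w <- exp(-0.5 * d2[, k] / bw2) * runif(nr * nc, 0.5, 1.5)
      w[mask != k] <- 0
      s <- sum(w)
      if (s > 0) popg <- popg + matrix(w / s * districts$population[k], nr, nc)
    }
    # land classes: threshold a smoothed noise field
    noise <- matrix(rnorm(nr * nc), nr, nc)
    sm <- smooth_field(noise)
    qs <- quantile(sm, probs = seq_len(n_land_classes - 1) / n_land_classes)
    land <- matrix(findInterval(sm, qs) + 1, nr, nc)
    # slope: absolute gradient of another smooth field (rise per km)
    el <- smooth_field(matrix(rnorm(nr * nc), nr, nc)) * 500
    gx <- cbind(el[, -1], el[, nc]) - el
    gy <- rbind(el[-1, ], el[nr, ]) - el
    slope <- sqrt(gx^2 + gy^2) / cell_km / 1000  # rise/run, dimensionless
  })

  roads <- build_road_network(districts, k = road_k, windiness = road_windiness)

  list(
    population = ascii_grid(popg, cell_km, xll, yll),
    district_mask = ascii_grid(mask, cell_km, xll, yll),
    land = ascii_grid(land, cell_km, xll, yll),
    slope = ascii_grid(slope, cell_km, xll, yll),
    roads = roads,
    road_nodes = data.frame(node_id = districts$district_id,
                            x = districts$x, y = districts$y,
                            stringsAsFactors = FALSE)
  )
}

# 3x3 mean filter applied a few times (cheap smooth random field).
smooth_field <- function(m, passes = 3L) {
  nr <- nrow(m); nc <- ncol(m)
  for (p in seq_len(passes)) {
    up <- rbind(m[1, ], m[-nr, ]); dn <- rbind(m[-1, ], m[nr, ])
    lf <- cbind(m[, 1], m[, -nc]); rt <- cbind(m[, -1], m[, nc])
    m <- (m + up + dn + lf + rt) / 5
  }
  m
}

#' Build a synthetic road network over district centroids
#'
#' k-nearest-neighbour graph augmented with bridging edges until it forms a
#' single connected component. Undirected; each edge length is the
#' straight-line distance between its endpoints times a windiness factor
#' (optionally edge-specific via `windiness_fn(i, j)` on district indices),
#' so road distance always dominates Euclidean distance.
#'
#' @param districts district set.
#' @param k neighbours linked per district.
#' @param windiness scalar detour factor (>= 1).
#' @param windiness_fn optional function of two district indices returning
#'   the detour factor for that edge.
#' @return data.frame `node_a`, `node_b`, `length_km`.
#' @export
build_road_network <- function(districts, k = 3, windiness = 1.3,
                               windiness_fn = NULL) {
  ids <- districts$district_id
  n <- length(ids)
  D <- district_distances(districts)
  edges <- list()
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:min(n, k + 1L)]
    for (j in nb) {
      a <- min(i, j); b <- max(i, j)
      edges[[paste(a, b)]] <- c(a, b)
    }
  }
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(cbind(ids[em[, 1]], ids[em[, 2]]),
                                   directed = FALSE)
  g <- g + igraph::vertices(setdiff(ids, igraph::V(g)$name))
  comp <- igraph::components(g)
  while (comp$no > 1L) {
    m1 <- which(comp$membership[ids] == 1)
    m2 <- which(comp$membership[ids] != 1)
    sub <- D[m1, m2, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- m1[best[1]]; j <- m2[best[2]]
    em <- rbind(em, c(min(i, j), max(i, j)))
    g <- igraph::add_edges(g, c(ids[i], ids[j]))
    comp <- igraph::components(g)
  }
  em <- unique(em)
  wfun <- windiness_fn %||% function(i, j) windiness
  len <- vapply(seq_len(nrow(em)), function(r) {
    D[em[r, 1], em[r, 2]] * wfun(em[r, 1], em[r, 2])
  }, numeric(1))
  data.frame(node_a = ids[em[, 1]], node_b = ids[em[, 2]], length_km = len,
             stringsAsFactors = FALSE)
}
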