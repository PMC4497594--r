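# Euclidean, road and least-cost travel-time distance measures.

test_that("euclidean matrix: 3-4-5 triangle, equivariance, brute force", {
  cen <- data.frame(district_id = c("a", "b"), x = c(0, 3), y = c(0, 4))
  D <- euclidean_matrix(cen)
  expect_equal(D["a", "b"], 5)
  expect_equal(diag(D), c(a = 0, b = 0))

  set.seed(4)
  cen5 <- data.frame(district_id = letters[1:5], x = runif(5, 0, 100),
                     y = runif(5, 0, 100))
  D5 <- euclidean_matrix(cen5)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(D5[i, j], sqrt((cen5$x[i] - cen5$x[j])^2 +
                                  (cen5$y[i] - cen5$y[j])^2))
  }
  perm <- c(3, 1, 5, 2, 4)
  Dp <- euclidean_matrix(cen5[perm, ])
  expect_equal(Dp, D5[perm, perm])
  # triangle inequality on the random instance
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    expect_lte(D5[i, j], D5[i, k] + D5[k, j] + 1e-12)
  }
})

test_that("population-weighted centroids follow the mass", {
  mask <- ascii_grid(matrix(1, 2, 2), cellsize = 1)
  uni <- ascii_grid(matrix(5, 2, 2), cellsize = 1)
  c1 <- population_weighted_centroids(uni, mask, ids = "d1")
  expect_equal(c(c1$x, c1$y), c(1, 1))  # geometric centre of a 2x2 grid

  point <- ascii_grid(matrix(c(0, 0, 0, 7), 2, 2), cellsize = 1)
  c2 <- population_weighted_centroids(point, mask, ids = "d1")
  # all mass in row 2, col 2 -> that cell centre (x = 1.5, y = 0.5)
  expect_equal(c(c2$x, c2$y), c(1.5, 0.5))

  # two-cell district with weights 1 and 3 -> 3/4 of the way
  w <- ascii_grid(matrix(c(1, 3), 1, 2), cellsize = 1)
  m <- ascii_grid(matrix(1, 1, 2), cellsize = 1)
  c3 <- population_weighted_centroids(w, m, ids = "d1")
  expect_equal(c3$x, 0.5 + 0.75 * 1)
  expect_warning(
    population_weighted_centroids(ascii_grid(matrix(0, 1, 2), 1), m, ids = "z"),
    "zero population")
})

test_that("road distances are shortest paths and dominate Euclidean", {
  # chain a - b - c: distance a->c is the sum of the links
  edges <- data.frame(node_a = c("a", "b"), node_b = c("b", "c"),
                      length_km = c(3, 4))
  cen <- data.frame(district_id = c("a", "b", "c"), x = c(0, 3, 7), y = 0)
  D <- road_distance_matrix(edges, cen)
  expect_equal(D["a", "c"], 7)

  # triangle: direct long edge vs two short hops
  edges2 <- data.frame(node_a = c("a", "a", "b"), node_b = c("c", "b", "c"),
                       length_km = c(10, 3, 4))
  D2 <- road_distance_matrix(edges2, cen)
  expect_equal(D2["a", "c"], 7)  # min(10, 3 + 4)

  d <- generate_districts(n_districts = 12, seed = 19)
  roads <- build_road_network(d, k = 3, windiness = 1.25)
  Dr <- road_distance_matrix(roads, d[, c("district_id", "x", "y")])
  De <- euclidean_matrix(d[, c("district_id", "x", "y")])
  off <- upper.tri(Dr)
  expect_true(all(Dr[off] >= De[off] - 1e-9))

  # disconnected network errors with the components listed
  edges3 <- data.frame(node_a = c("a", "c"), node_b = c("b", "d"),
                       length_km = c(1, 1))
  cen4 <- data.frame(district_id = c("a", "b", "c"), x = c(0, 1, 2), y = 0)
  expect_error(road_distance_matrix(edges3, cen4), "disconnected")
})

test_that("uniform-speed straight line costs (n-1) cell crossings", {
  g <- ascii_grid(matrix(5, 3, 8), cellsize = 2)
  cen <- data.frame(district_id = c("a", "b"), x = c(1, 15), y = c(3, 3))
  tt <- travel_time_matrix(g, cen)
  expect_equal(tt["a", "b"], 7 * 2 / 5)
})

test_that("least-cost path through a barrier gap equals the hand-run Dijkstra", {
  v <- matrix(1, 5, 5)
  v[3, 1:4] <- 0  # impassable barrier with a gap at column 5
  g <- ascii_grid(v, cellsize = 1)
  cen <- data.frame(district_id = c("top", "bot"), x = c(0.5, 0.5),
                    y = c(4.5, 0.5))
  tt <- expect_warning(travel_time_matrix(g, cen), NA)
  # hand Dijkstra: (1,1)->(3,5) costs 2 + 2*sqrt(2), then (3,5)->(5,1)
  # the same; orthogonal move = 1 h, diagonal = sqrt(2) h at 1 km/h, 1 km
  expect_equal(tt["top", "bot"], 4 + 4 * sqrt(2))
})

test_that("uniform-grid travel times respect the 8-connectivity elongation bound", {
  g <- ascii_grid(matrix(4, 20, 20), cellsize = 1)
  set.seed(8)
  cen <- data.frame(district_id = sprintf("p%d", 1:6),
                    x = sample(0:19, 6) + 0.5, y = sample(0:19, 6) + 0.5)
  tt <- travel_time_matrix(g, cen)
  De <- euclidean_matrix(cen)
  off <- which(upper.tri(tt), arr.ind = TRUE)
  ratio <- tt[off] / (De[off] / 4)
  expect_true(all(ratio <= 1.0824 + 1e-9))
  expect_true(all(ratio >= 1 - 1e-9))
})

test_that("raising friction never shortens any travel time", {
  set.seed(12)
  v <- matrix(runif(100, 2, 8), 10, 10)
  g1 <- ascii_grid(v, cellsize = 1)
  v2 <- v
  v2[5, 5] <- v[5, 5] / 4  # slower cell = higher friction
  g2 <- ascii_grid(v2, cellsize = 1)
  cen <- data.frame(district_id = c("a", "b", "c"),
                    x = c(0.5, 9.5, 5.5), y = c(0.5, 9.5, 1.5))
  t1 <- travel_time_matrix(g1, cen)
  t2 <- travel_time_matrix(g2, cen)
  expect_true(all(t2 >= t1 - 1e-12))
})

test_that("no passable path yields Inf with a warning; blocked centroids error", {
  v <- matrix(1, 3, 3)
  v[, 2] <- 0
  g <- ascii_grid(v, cellsize = 1)
  cen <- data.frame(district_id = c("l", "r"), x = c(0.5, 2.5), y = c(1.5, 1.5))
  expect_warning(tt <- travel_time_matrix(g, cen), "no passable path")
  expect_true(is.infinite(tt["l", "r"]))
  cen2 <- data.frame(district_id = "m", x = 1.5, y = 1.5)
  expect_error(travel_time_matrix(g, cen2), "impassable")
})

test_that("friction surface combines land, slope and roads as documented", {
  land <- ascii_grid(matrix(1L, 4, 4), cellsize = 1)
  flat <- ascii_grid(matrix(0, 4, 4), cellsize = 1)
  f <- friction_surface(land, flat, speeds = c(4, 2))
  expect_true(all(f$data == 4))
  sl <- ascii_grid(matrix(0.1, 4, 4), cellsize = 1)
  f2 <- friction_surface(land, sl, speeds = c(4, 2), slope_coef = 3)
  expect_equal(unique(as.vector(f2$data)), 4 * exp(-0.3))
  nodes <- data.frame(node_id = c("a", "b"), x = c(0.5, 3.5), y = c(0.5, 0.5))
  roads <- data.frame(node_a = "a", node_b = "b", length_km = 3)
  f3 <- friction_surface(land, flat, speeds = c(4, 2), roads = roads,
                         road_nodes = nodes, road_speed = 50)
  expect_true(all(f3$data[4, ] == 50))   # bottom row carries the road
  expect_true(all(f3$data[1:3, ] == 4))
})

test_that("distance measures are positively correlated on a synthetic world", {
  d <- generate_districts(n_districts = 15, seed = 23)
  r <- generate_rasters(d, cell_km = 25, seed = 23)
  De <- euclidean_matrix(d[, c("district_id", "x", "y")])
  Dr <- road_distance_matrix(r$roads, d[, c("district_id", "x", "y")])
  fr <- friction_surface(r$land, r$slope, roads = r$roads,
                         road_nodes = r$road_nodes)
  Dt <- travel_time_matrix(fr, d[, c("district_id", "x", "y")])
  cm <- distance_correlations(list(euclid = De, road = Dr, time = Dt))
  expect_true(all(cm[upper.tri(cm)] > 0.5))
})
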