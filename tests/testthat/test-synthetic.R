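# Synthetic-data generators: determinism, statistical structure, ground
# truth consistency.

test_that("generate_districts handles the minimal case and rejects n < 2", {
  d <- generate_districts(n_districts = 2, seed = 1)
  expect_equal(nrow(d), 2L)
  expect_gt(dist(cbind(d$x, d$y))[1], 0)
  expect_error(generate_districts(n_districts = 1), "n_districts")
})

test_that("every generator is deterministic under a fixed seed", {
  d1 <- generate_districts(n_districts = 12, seed = 42)
  d2 <- generate_districts(n_districts = 12, seed = 42)
  expect_identical(d1, d2)
  truth <- list(model = "gravity", alpha = 1, beta = 1, gamma = 2, log_k = -10)
  expect_identical(simulate_flows(d1, truth, seed = 7),
                   simulate_flows(d2, truth, seed = 7))
  r1 <- generate_rasters(d1, cell_km = 40, seed = 9)
  r2 <- generate_rasters(d1, cell_km = 40, seed = 9)
  expect_identical(r1, r2)
  # generators draw from separate streams: changing the raster seed does
  # not change the flows
  expect_identical(simulate_flows(d1, truth, seed = 7),
                   simulate_flows(generate_districts(n_districts = 12, seed = 42),
                                  truth, seed = 7))
})

test_that("district populations follow the heavy-tailed law (CV oracle)", {
  meanlog <- 12.61; sdlog <- 1.0
  d <- generate_districts(n_districts = 69, pop_meanlog = meanlog,
                          pop_sdlog = sdlog, seed = 5)
  # brute-force large-sample draw from the same law
  set.seed(99)
  big <- rlnorm(2e5, meanlog, sdlog)
  cv_law <- sd(big) / mean(big)
  cv_emp <- sd(d$population) / mean(d$population)
  # n = 69 draws of a heavy-tailed law: CV is itself noisy, so compare the
  # average CV over seeds to the law's CV within +-20%
  cvs <- vapply(1:20, function(s) {
    p <- generate_districts(69, pop_meanlog = meanlog, pop_sdlog = sdlog,
                            seed = s)$population
    sd(p) / mean(p)
  }, numeric(1))
  expect_lt(abs(mean(cvs) - cv_law) / cv_law, 0.20)
  expect_true(is.finite(cv_emp))
})

test_that("simulate_flows concentrates on nearest neighbours as gamma grows", {
  d <- make_districts(pop = rep(100, 5), x = c(0, 0.8, 2, 3.5, 5),
                      y = rep(0, 5))
  near <- 0.8
  truth <- list(model = "gravity", alpha = 0, beta = 0, gamma = 50,
                log_k = 50 * log(near) + log(20))
  od <- simulate_flows(d, truth, seed = 3)
  far <- od$dist_euclid_km > near + 1e-9
  expect_true(all(od$trips[far] == 0))
  expect_gt(sum(od$trips[!far]), 0)
})

test_that("simulate_flows: zero truth mean gives zero counts; zero distance errors", {
  d <- make_districts(pop = c(10, 20, 30), x = c(0, 1, 2), y = c(0, 0, 0))
  truth <- list(model = "gravity", alpha = 0, beta = 0, gamma = 0,
                log_k = -1e6)
  od <- simulate_flows(d, truth, seed = 1)
  expect_true(all(od$trips == 0))
  d2 <- make_districts(pop = c(10, 20), x = c(1, 1), y = c(2, 2))
  expect_error(simulate_flows(d2, truth, seed = 1), "degenerate")
})

test_that("simulate_flows Poisson means match the truth (Monte-Carlo oracle)", {
  d <- generate_districts(n_districts = 5, seed = 21)
  truth <- list(model = "gravity", alpha = 0.8, beta = 0.8, gamma = 1.5,
                log_k = -8)
  base <- simulate_flows(d, truth, seed = 1)
  mu <- base$truth_mean
  reps <- 1000L
  tot <- matrix(0, nrow(base), 0)
  sums <- numeric(nrow(base))
  for (r in seq_len(reps)) {
    sums <- sums + simulate_flows(d, truth, seed = 1000 + r)$trips
  }
  mean_draw <- sums / reps
  se <- sqrt(mu / reps)
  keep <- mu > 0
  expect_true(all(abs(mean_draw[keep] - mu[keep]) <= 3 * se[keep] + 1e-9))
})

test_that("radiation-truth flows use the radiation mean law", {
  d <- generate_districts(n_districts = 6, seed = 8)
  od <- simulate_flows(d, list(model = "radiation", tct = 0.5), seed = 2)
  P <- radiation_predict(d, tct = 0.5)
  expect_equal(od$truth_mean,
               P[cbind(match(od$origin_id, rownames(P)),
                       match(od$dest_id, colnames(P)))])
})

test_that("generate_rasters yields aligned grids and a connected road net", {
  d <- generate_districts(n_districts = 10, seed = 4)
  r <- generate_rasters(d, cell_km = 40, seed = 4)
  dims <- lapply(r[c("population", "district_mask", "land", "slope")],
                 function(g) dim(g$data))
  expect_length(unique(dims), 1L)
  expect_equal(sum(r$population$data), sum(d$population), tolerance = 1e-6)
  g <- igraph::graph_from_data_frame(r$roads[, 1:2], directed = FALSE)
  expect_equal(igraph::components(g)$no, 1L)
  expect_true(all(r$roads$length_km > 0))
})

test_that("ascii grid round-trips through the Esri ASCII format", {
  g <- ascii_grid(matrix(c(1.5, 2, NA, 4, 5, 6), 2, 3), cellsize = 10,
                  xll = 3, yll = -2)
  p <- tempfile(fileext = ".asc")
  write_ascii_grid(g, p)
  g2 <- read_ascii_grid(p)
  expect_equal(g2$data, g$data)
  expect_equal(g2$cellsize, 10)
  expect_equal(g2$xll, 3)
  unlink(p)
})

test_that("diaries with call_prob = 1 reproduce the plan; non-travellers have no trips", {
  d <- generate_districts(n_districts = 4, seed = 6)
  plan <- simulate_travel_plan(d, subscribers_per_district = 2, n_days = 20,
                               p_travel = 0.15, seed = 6)
  di <- simulate_diaries(d, plan, call_prob = 1, towers_per_district = 1,
                         seed = 6)
  # every subscriber-day observed, and the tower maps back to the planned
  # district
  expect_equal(nrow(unique(di$records[, c("subscriber_id", "day")])),
               nrow(plan) * ncol(plan))
  obs_d <- di$tower_map$district_id[match(di$records$tower_id,
                                          di$tower_map$tower_id)]
  expect_identical(obs_d, plan[cbind(match(di$records$subscriber_id,
                                           rownames(plan)),
                                     di$records$day + 1L)])
  # a subscriber who never travels contributes no ground-truth trips
  stay <- rownames(plan)[apply(plan, 1, function(r) length(unique(r)) == 1L)]
  if (length(stay)) {
    expect_false(any(di$truth_trips$subscriber_id %in% stay))
  }
})

test_that("call_prob = 0.5 yields ~half the days with records (binomial oracle)", {
  d <- generate_districts(n_districts = 3, seed = 2)
  plan <- simulate_travel_plan(d, subscribers_per_district = 40, n_days = 50,
                               p_travel = 0, seed = 2)
  di <- simulate_diaries(d, plan, call_prob = 0.5, seed = 2)
  n_obs <- nrow(unique(di$records[, c("subscriber_id", "day")]))
  n_tot <- nrow(plan) * ncol(plan)
  p_hat <- n_obs / n_tot
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / n_tot))
})

test_that("call_prob = 0 for everyone warns about unobservable data", {
  d <- generate_districts(n_districts = 2, seed = 3)
  plan <- simulate_travel_plan(d, subscribers_per_district = 1, n_days = 5,
                               p_travel = 0, seed = 3)
  expect_warning(simulate_diaries(d, plan, call_prob = 0, seed = 3),
                 "no observable data")
})
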