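# Error diagnostics, exclusion rule, goodness of fit and model choice.

test_that("route errors are log differences on positive-positive routes", {
  od <- make_od(c("A", "B", "C"), c("B", "C", "A"), 1, 1, 1,
                c(10, 5, 0))
  pred <- c(10, 5 / exp(1), 3)
  e <- route_errors(od, pred)
  expect_equal(e$error, c(0, 1))
  expect_equal(attr(e, "zero_counts")[["zero_observed"]], 1L)

  set.seed(3)
  obs <- rpois(20, 50) + 1
  prd <- runif(20, 1, 100)
  od2 <- make_od(paste0("o", 1:20), paste0("d", 1:20), 1, 1, 1, obs)
  e2 <- route_errors(od2, prd)
  expect_equal(e2$error, log(obs) - log(prd))
})

test_that("the 2-SD rule flags extremes and is model-symmetric", {
  base <- data.frame(origin_id = paste0("o", 1:4), dest_id = paste0("d", 1:4),
                     observed = 1, predicted = 1, stringsAsFactors = FALSE)
  eg <- transform(base, error = c(0, 2.5, 2.5, -0.4), model = "g")
  er <- transform(base, error = c(0.1, 2.5, 1.0, -3.0), model = "r")
  fl <- flag_unmodelable(list(g = eg, r = er))
  expect_equal(fl$flag_g, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(fl$flag_r, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(fl$unmodelable, c(FALSE, TRUE, FALSE, FALSE))
  # relabelling the models permutes flags but never the unmodelable set
  fl2 <- flag_unmodelable(list(r = er, g = eg))
  expect_equal(fl2$unmodelable, fl$unmodelable)
  expect_equal(fl2$flag_g, fl$flag_g)
})

test_that("the empirical exclusion variant centres on the model's own errors", {
  base <- data.frame(origin_id = paste0("o", 1:40), dest_id = paste0("d", 1:40),
                     observed = 1, predicted = 1, stringsAsFactors = FALSE)
  set.seed(5)
  e <- transform(base, error = 5 + c(rnorm(39, 0, 0.1), 1.5), model = "g")
  fixed <- flag_unmodelable(list(g = e), rule = "fixed")
  empir <- flag_unmodelable(list(g = e), rule = "empirical")
  expect_true(all(fixed$flag_g))          # every error is > 2
  expect_equal(sum(empir$flag_g), 1L)     # only the shifted point stands out
})

test_that("KS statistic matches hand arithmetic and degenerate cases", {
  ks <- ks_normality(c(-1, 0, 1))
  expect_equal(ks$statistic, 1 / 3 - pnorm(-1), tolerance = 1e-12)

  expect_equal(ks_normality(rep(0, 25))$statistic, 0.5)

  set.seed(11)
  big <- rnorm(5000)
  expect_lt(ks_normality(big)$statistic, 0.05)
  expect_error(ks_normality(rnorm(2)), "at least 3")
})

test_that("fit statistics: perfect fit, Dice arithmetic, null self-comparison", {
  od <- make_od(paste0("o", 1:6), paste0("d", 1:6), 1, 1, 1,
                c(4, 9, 2, 7, 5, 11))
  perfect <- fit_statistics(od, od$trips, n_params = 0)
  expect_equal(perfect$reduction_deviance, 100)
  expect_true(all(perfect$dice == 1))
  expect_equal(perfect$ratio_pred_obs$mean, 1)

  one <- fit_statistics(make_od("A", "B", 1, 1, 1, 5), 3)
  expect_equal(one$dice, 0.75)

  null_pred <- rep(mean(od$trips), 6)
  null_rep <- fit_statistics(od, null_pred)
  expect_equal(null_rep$reduction_deviance, 0)

  const <- make_od(paste0("o", 1:5), paste0("d", 1:5), 1, 1, 1, rep(7, 5))
  expect_true(is.na(fit_statistics(const, rep(6, 5))$reduction_deviance))
})

test_that("deviance reduction of the gravity fit dominates nested restrictions", {
  d <- generate_districts(n_districts = 12, seed = 67)
  od <- simulate_flows(d, list(model = "gravity", alpha = 1.1, beta = 0.9,
                               gamma = 1.7, log_k = -13), seed = 67)
  full <- fit_gravity(od)
  restricted <- glm(trips ~ log(pop_orig) + log(pop_dest), poisson(),
                    data = od)
  rd_restricted <- 100 * (restricted$null.deviance - restricted$deviance) /
    restricted$null.deviance
  expect_gte(full$reduction_deviance, rd_restricted)
})

test_that("Dice aggregate ignores route order and detects exact agreement", {
  od <- make_od(paste0("o", 1:5), paste0("d", 1:5), 1, 1, 1, c(3, 8, 1, 6, 2))
  pred <- c(3, 9, 1, 5, 2)
  r1 <- fit_statistics(od, pred)
  perm <- c(4, 2, 5, 1, 3)
  r2 <- fit_statistics(od[perm, ], pred[perm])
  expect_equal(r1$dice_mean, r2$dice_mean)
  expect_lt(r1$dice_mean, 1)
  expect_equal(fit_statistics(od, od$trips)$dice_mean, 1)
})

test_that("winner labels pick the smaller absolute error, oracle-checked", {
  base <- data.frame(origin_id = paste0("o", 1:2), dest_id = paste0("d", 1:2),
                     observed = 1, predicted = 1, stringsAsFactors = FALSE)
  eg <- transform(base, error = c(0.1, -0.3), model = "g")
  er <- transform(base, error = c(0.3, 0.1), model = "r")
  w <- label_better_model(eg, er)
  expect_equal(w$winner, c("gravity", "radiation"))
  # symmetric swap flips the labels
  w2 <- label_better_model(er, eg)
  expect_equal(w2$winner, c("radiation", "gravity"))

  set.seed(13)
  n <- 60
  b2 <- data.frame(origin_id = paste0("o", 1:n), dest_id = paste0("d", 1:n),
                   observed = 1, predicted = 1, stringsAsFactors = FALSE)
  eg2 <- transform(b2, error = rnorm(n), model = "g")
  er2 <- transform(b2, error = rnorm(n), model = "r")
  w3 <- label_better_model(eg2, er2)
  brute <- ifelse(abs(eg2$error) <= abs(er2$error), "gravity", "radiation")
  expect_equal(w3$winner, brute)
})

test_that("choice logistic recovers a known law and flags separation", {
  set.seed(17)
  gm <- 10^runif(600, 2, 10)
  p <- plogis(-6 + 1 * log10(gm))
  win <- ifelse(runif(600) < p, "gravity", "radiation")
  ch <- fit_choice_logistic(win, gm)
  expect_true(ch$ci["b0", 1] <= -6 && -6 <= ch$ci["b0", 2])
  expect_true(ch$ci["b1", 1] <= 1 && 1 <= ch$ci["b1", 2])
  expect_gt(ch$b1, 0)
  # b1 > 0 makes the choice probability monotone in gm
  probs <- predict(ch, 10^seq(2, 10, length.out = 9))
  expect_true(all(diff(probs) > 0))
  expect_error(fit_choice_logistic(rep("gravity", 50), 10^runif(50, 2, 10)),
               "separation")
})

test_that("subset analysis: identity subset equals the full fit, tiny subsets skip", {
  d <- generate_districts(n_districts = 10, seed = 71)
  od <- simulate_flows(d, list(model = "gravity", alpha = 1, beta = 1,
                               gamma = 2, log_k = -12), seed = 71)
  full <- fit_gravity(od)
  subs <- list(all = rep(TRUE, nrow(od)),
               tiny = c(rep(TRUE, 3), rep(FALSE, nrow(od) - 3)))
  expect_warning(subset_analysis(od, subs), "skipped")
  res <- suppressWarnings(subset_analysis(od, subs))
  expect_equal(res$reduction_deviance[res$subset == "all"],
               full$reduction_deviance)
  expect_false("tiny" %in% res$subset)
  # complementary subsets partition the routes
  half <- seq_len(nrow(od)) <= nrow(od) / 2
  res2 <- subset_analysis(od, list(a = half, b = !half))
  expect_equal(sum(res2$n_routes), nrow(od))
})

test_that("planted rural road structure makes road distance win in rural areas", {
  d <- generate_districts(n_districts = 25, size_km = 500, seed = 11)
  cls <- district_classes(d)
  rural <- d$district_id[cls == "rural"]
  wf <- function(i, j) {
    if (d$district_id[i] %in% rural && d$district_id[j] %in% rural) 2.8 else 1.05
  }
  roads <- build_road_network(d, k = 4, windiness_fn = wf)
  Droad <- road_distance_matrix(roads, d[, c("district_id", "x", "y")])
  od <- simulate_flows(d, list(model = "gravity", alpha = 1, beta = 1,
                               gamma = 2, log_k = -11), seed = 12,
                       distance = Droad)
  names(od)[names(od) == "dist_euclid_km"] <- "dist_road_km"
  De <- euclidean_matrix(d[, c("district_id", "x", "y")])
  od$dist_euclid_km <- De[cbind(match(od$origin_id, rownames(De)),
                                match(od$dest_id, colnames(De)))]
  res <- subset_analysis(od, list(rural = od$origin_id %in% rural &
                                    od$dest_id %in% rural),
                         distance_cols = c("dist_euclid_km", "dist_road_km"))
  expect_gt(res$reduction_deviance[res$distance == "dist_road_km"],
            res$reduction_deviance[res$distance == "dist_euclid_km"])
})
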