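# Subscriber diary simulation: a travel plan (true district per subscriber
# per day), call records emitted only on days with calls, and the retained
# ground-truth trip list.

#' Simulate a per-subscriber travel plan
#'
#' Each subscriber has a home district. On any day at home they depart with
#' probability `p_travel`; trip durations are log-uniform on
#' `duration_range`, and the destination is drawn with weight
#' `pop_j^beta(dur) / d(h,j)^gamma(dur)`. The destination-attraction
#' exponent beta interpolates from `dest_beta[1]` (shortest trips) to
#' `dest_beta[2]` (longest), and the distance-decay exponent gamma from
#' `dist_gamma[1]` to `dist_gamma[2]`, so longer stays are planted to favour
#' large, far destinations — the qualitative duration trend the
#' stratified fits should recover.
#'
#' @param districts district set.
#' @param subscribers_per_district subscribers homed in each district.
#' @param n_days observation window length (days, 0-based indexing).
#' @param p_travel daily departure probability while at home.
#' @param duration_range min/max planned stay, days.
#' @param dest_beta,dist_gamma exponent endpoints (short-trip, long-trip).
#' @param seed master seed.
#' @return a character matrix (subscribers x days) of district ids, with
#'   rownames giving subscriber ids and attribute `home` the home district
#'   of each subscriber.
#' @export
simulate_travel_plan <- function(districts, subscribers_per_district = 10,
                                 n_days = 120, p_travel = 0.02,
                                 duration_range = c(1, 150),
                                 dest_beta = c(0.9, 1.9),
                                 dist_gamma = c(1.7, 1.1),
                                 seed = 1) {
  ids <- districts$district_id
  n <- length(ids)
  D <- district_distances(districts)
  pop <- districts$population
  n_sub <- n * subscribers_per_district
  home <- rep(seq_len(n), each = subscribers_per_district)
  sub_ids <- sprintf("S%05d", seq_len(n_sub))
  lo <- log(duration_range[1]); hi <- log(duration_range[2])
  plan <- matrix(0L, n_sub, n_days)
  with_seed(stream_seed(seed, "plan"), {
    for (s in seq_len(n_sub)) {
      h <- home[s]
      day <- 1L
      cur <- h
      until <- 0L  # last day (1-based) of a stay away from home
      while (day <= n_days) {
        if (cur != h && day > until) cur <- h
        if (cur == h && runif(1) < p_travel) {
          dur <- max(1L, round(exp(runif(1, lo, hi))))
          t <- (log(dur) - lo) / max(hi - lo, 1e-9)
          b <- dest_beta[1] + t * (dest_beta[2] - dest_beta[1])
          g <- dist_gamma[1] + t * (dist_gamma[2] - dist_gamma[1])
          w <- pop^b / D[h, ]^g
          w[h] <- 0
          cur <- sample.int(n, 1L, prob = w)
          until <- day + dur - 1L
          # place the traveller at the destination starting today
        }
        plan[s, day] <- cur
        day <- day + 1L
      }
    }
  })
  out <- matrix(ids[plan], n_sub, n_days, dimnames = list(sub_ids, NULL))
  attr(out, "home") <- ids[home]
  out
}

#' Simulate call-record diaries from a travel plan
#'
#' Emits call records only on subscriber-days with at least one call
#' (Bernoulli `call_prob`); each call is routed through a tower of the
#' day's true district (several towers per district supported, so the
#' majority-vote location logic is exercised). The ground-truth trip list
#' implied by the plan is retained for round-trip tests.
#'
#' @param districts district set.
#' @param plan travel plan from [simulate_travel_plan()] (or any character
#'   matrix of district ids, subscribers x days).
#' @param call_prob probability a subscriber makes >= 1 call on a day;
#'   scalar or per-subscriber vector.
#' @param towers_per_district towers serving each district.
#' @param mean_extra_calls mean number of calls beyond the first on a call
#'   day (Poisson).
#' @param missing_days optional integer vector of 0-based days to blank out
#'   of the record stream (e.g. a missing month), to test robustness.
#' @param seed master seed.
#' @return list with `records` (`subscriber_id`, `day`, `tower_id`),
#'   `tower_map` (`tower_id`, `district_id`), `truth_trips` (as
#'   [extract_trips()] output), `n_days`.
#' @export
simulate_diaries <- function(districts, plan, call_prob = 0.7,
                             towers_per_district = 2, mean_extra_calls = 0.8,
                             missing_days = NULL, seed = 1) {
  ids <- districts$district_id
  n_sub <- nrow(plan); n_days <- ncol(plan)
  call_prob <- rep_len(call_prob, n_sub)
  if (any(call_prob < 0 | call_prob > 1)) stopf("call_prob must lie in [0, 1]")
  if (all(call_prob == 0)) {
    warning("call_prob is 0 for every subscriber: no observable data",
            call. = FALSE)
  }
  tower_map <- data.frame(
    tower_id = as.vector(t(outer(ids, seq_len(towers_per_district),
                                 function(d, k) sprintf("T_%s_%d", d, k)))),
    district_id = rep(ids, each = towers_per_district),
    stringsAsFactors = FALSE
  )
  towers_of <- split(tower_map$tower_id, tower_map$district_id)
  recs <- with_seed(stream_seed(seed, "diaries"), {
    call_day <- matrix(runif(n_sub * n_days) < call_prob, n_sub, n_days)
    idx <- which(call_day, arr.ind = TRUE)
    if (nrow(idx)) {
      ncalls <- 1L + rpois(nrow(idx), mean_extra_calls)
      sub <- rep(rownames(plan)[idx[, 1]], ncalls)
      day <- rep(idx[, 2] - 1L, ncalls)
      dist <- rep(plan[idx], ncalls)
      tw <- vapply(dist, function(d) {
        tset <- towers_of[[d]]
        tset[sample.int(length(tset), 1L)]
      }, character(1))
      data.frame(subscriber_id = sub, day = day, tower_id = tw,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(subscriber_id = character(), day = integer(),
                 tower_id = character(), stringsAsFactors = FALSE)
    }
  })
  if (!is.null(missing_days)) {
    recs <- recs[!(recs$day %in% missing_days), , drop = FALSE]
  }
  recs <- recs[order(recs$subscriber_id, recs$day), , drop = FALSE]
  rownames(recs) <- NULL
  truth <- plan_truth_trips(plan)
  list(records = recs, tower_map = tower_map, truth_trips = truth,
       n_days = n_days)
}

# Ground-truth trips implied by a plan: a trip opens whenever the district
# changes from the previous day; duration is the run length of the stay in
# the visited district; runs cut off by the window end are flagged.
plan_truth_trips <- function(plan) {
  out <- vector("list", nrow(plan))
  for (s in seq_len(nrow(plan))) {
    seqd <- plan[s, ]
    r <- rle(seqd)
    k <- length(r$lengths)
    if (k <= 1L) {
      out[[s]] <- NULL
      next
    }
    starts <- cumsum(c(1L, r$lengths[-k]))
    out[[s]] <- data.frame(
      subscriber_id = rownames(plan)[s],
      origin = r$values[-k],
      dest = r$values[-1],
      start_day = starts[-1] - 1L,     # 0-based
      duration = r$lengths[-1],
      truncated = c(rep(FALSE, k - 2L), TRUE),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(subscriber_id = character(), origin = character(),
                      dest = character(), start_day = integer(),
                      duration = integer(), truncated = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}
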