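# From call records to daily locations, trips, duration strata and
# aggregated origin-destination tables.

#' Assign one district location per subscriber-day
#'
#' On a day with calls the subscriber is placed at the majority routing
#' tower; ties among the modal towers are broken uniformly at random (the
#' tie-break stream is keyed on subscriber and day, so re-running one
#' subscriber never reshuffles another). Call-free days inherit the most
#' recent assigned location; leading call-free days before a subscriber's
#' first call are dropped.
#'
#' @param records data.frame with `subscriber_id`, `day` (0-based integer),
#'   `tower_id`; one row per call.
#' @param tower_map data.frame mapping `tower_id` to `district_id`.
#' @param seed seed for tie-breaking.
#' @param n_days observation window length; days run over `[0, n_days)`.
#'   Defaults to `max(records$day) + 1`.
#' @return data.frame `subscriber_id`, `day`, `district_id`, one row per
#'   subscriber-day from the subscriber's first call day to the window end.
#' @export
assign_daily_locations <- function(records, tower_map, seed = 1,
                                   n_days = NULL) {
  assert_cols(records, c("subscriber_id", "day", "tower_id"), "records")
  assert_cols(tower_map, c("tower_id", "district_id"), "tower_map")
  unknown <- setdiff(unique(records$tower_id), tower_map$tower_id)
  if (length(unknown)) {
    stopf("tower(s) absent from tower_map: %s",
          paste(sort(unknown), collapse = ", "))
  }
  if (nrow(records) == 0L) {
    return(data.frame(subscriber_id = character(), day = integer(),
                      district_id = character(), stringsAsFactors = FALSE))
  }
  n_days <- n_days %||% (max(records$day) + 1L)

  # count calls per (subscriber, day, tower) via run lengths on the sorted
  # triples, then pick the majority tower per subscriber-day
  ord <- order(records$subscriber_id, records$day, records$tower_id)
  s <- records$subscriber_id[ord]
  dy <- records$day[ord]
  tw <- records$tower_id[ord]
  r <- rle(paste(s, dy, tw, sep = "\r"))
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  cnt <- r$lengths
  ts <- tw[starts]; ss <- s[starts]; ds <- dy[starts]
  # order triples by subscriber-day, descending count, tower id: the first
  # row of each group is the winner unless tied
  o2 <- order(ss, ds, -cnt, ts, method = "radix")
  ss <- ss[o2]; ds <- ds[o2]; cnt <- cnt[o2]; ts <- ts[o2]
  gkey <- paste(ss, ds, sep = "\r")
  first <- !duplicated(gkey)
  gi <- cumsum(first)
  topcnt <- cnt[first][gi]
  tied <- cnt == topcnt
  nties <- as.vector(rowsum(as.integer(tied), gi))
  winner <- ts[first]
  fpos <- which(first)
  for (g in which(nties > 1L)) {
    modal <- ts[fpos[g] + seq_len(nties[g]) - 1L]   # sorted tower ids
    pick <- (mix_key(seed, ss[fpos[g]], ds[fpos[g]]) %% nties[g]) + 1L
    winner[g] <- modal[pick]
  }
  day_sub <- ss[first]
  day_day <- ds[first]
  day_district <- tower_map$district_id[match(winner, tower_map$tower_id)]

  # carry forward per subscriber from the first call day to the window end
  sub_levels <- unique(day_sub)               # already sorted by construction
  sub_idx <- split(seq_along(day_sub), factor(day_sub, levels = sub_levels))
  first_day <- vapply(sub_idx, function(i) day_day[i[1]], numeric(1))
  lens <- as.integer(n_days - first_day)
  dist_out <- vector("list", length(sub_idx))
  for (k in seq_along(sub_idx)) {
    i <- sub_idx[[k]]
    days <- first_day[k]:(n_days - 1L)
    pos <- findInterval(days, day_day[i])
    dist_out[[k]] <- day_district[i][pos]
  }
  res <- data.frame(
    subscriber_id = rep(sub_levels, lens),
    day = as.integer(sequence(lens) - 1L + rep(first_day, lens)),
    district_id = unlist(dist_out, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  res
}

#' Extract trips from a daily location series
#'
#' A trip opens whenever the day's district differs from the previous
#' day's; its duration is the number of consecutive days then spent in the
#' visited district. Runs cut off by the end of the observation window are
#' emitted with `truncated = TRUE` (their full length is unobserved).
#'
#' @param series data.frame `subscriber_id`, `day`, `district_id` with one
#'   row per subscriber-day (days contiguous within subscriber).
#' @return data.frame `subscriber_id`, `origin`, `dest`, `start_day`,
#'   `duration`, `truncated`. Empty input gives an empty trip list.
#' @export
extract_trips <- function(series) {
  assert_cols(series, c("subscriber_id", "day", "district_id"), "series")
  empty <- data.frame(subscriber_id = character(), origin = character(),
                      dest = character(), start_day = integer(),
                      duration = integer(), truncated = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(series) == 0L) return(empty)
  series <- series[order(series$subscriber_id, series$day), , drop = FALSE]
  by_sub <- split(seq_len(nrow(series)), series$subscriber_id)
  out <- vector("list", length(by_sub))
  for (s in seq_along(by_sub)) {
    idx <- by_sub[[s]]
    days <- series$day[idx]
    if (any(diff(days) != 1L)) {
      stopf("days not contiguous for subscriber %s",
            series$subscriber_id[idx[1]])
    }
    r <- rle(series$district_id[idx])
    k <- length(r$lengths)
    if (k <= 1L) next
    starts <- cumsum(c(1L, r$lengths[-k]))
    out[[s]] <- data.frame(
      subscriber_id = series$subscriber_id[idx[1]],
      origin = r$values[-k],
      dest = r$values[-1],
      start_day = days[starts[-1]],
      duration = r$lengths[-1],
      truncated = c(rep(FALSE, k - 2L), TRUE),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}

#' Stratify trips by duration of stay
#'
#' Returns the unstratified `All` group plus six half-open duration bins.
#' With the default edges (days) the bins are: `Week` (< 14), `Biweek`
#' (14-29), `Month` (30-59), `Month2` (60-89), `Month3` (90-119) and
#' `Month4plus` (>= 120). `All` always contains every trip; the bins
#' exclude window-truncated trips by default because their durations are
#' censored.
#'
#' @param trips trip table from [extract_trips()].
#' @param edges increasing vector of five bin edges (days).
#' @param include_truncated put truncated trips into duration bins too.
#' @return named list of trip tables: `All`, `Week`, `Biweek`, `Month`,
#'   `Month2`, `Month3`, `Month4plus`.
#' @export
stratify_by_duration <- function(trips, edges = c(14, 30, 60, 90, 120),
                                 include_truncated = FALSE) {
  assert_cols(trips, c("duration"), "trips")
  if (any(trips$duration < 0)) stopf("negative trip duration in input")
  if (length(edges) != 5L || any(diff(edges) <= 0)) {
    stopf("edges must be five increasing duration cut points")
  }
  labels <- c("Week", "Biweek", "Month", "Month2", "Month3", "Month4plus")
  binnable <- if (include_truncated || !"truncated" %in% names(trips)) {
    rep(TRUE, nrow(trips))
  } else {
    !trips$truncated
  }
  bin <- findInterval(trips$duration, edges) + 1L  # 1..6
  out <- list(All = trips)
  for (b in seq_along(labels)) {
    out[[labels[b]]] <- trips[binnable & bin == b, , drop = FALSE]
  }
  out
}

#' Aggregate trips to an origin-destination table
#'
#' Counts trips per ordered district pair over the whole window, attaching
#' populations and a distance for each route. Within-district movements
#' never occur in a trip list (origin != destination by construction).
#'
#' @param trips trip table with `origin`, `dest`.
#' @param districts district set supplying `district_id`, `population` and
#'   (if `distance` is NULL) coordinates for Euclidean distance.
#' @param distance optional distance matrix (dimnames = district ids).
#' @param distance_name column name for the distance, default
#'   `"dist_euclid_km"`.
#' @param zero_fill include all ordered pairs of the district set with zero
#'   counts, not only pairs observed in `trips`.
#' @return OD table: `origin_id`, `dest_id`, `pop_orig`, `pop_dest`,
#'   distance column, `trips`.
#' @export
aggregate_od <- function(trips, districts, distance = NULL,
                         distance_name = "dist_euclid_km",
                         zero_fill = FALSE) {
  assert_cols(trips, c("origin", "dest"), "trips")
  assert_cols(districts, c("district_id", "population"), "districts")
  ids <- districts$district_id
  missing <- setdiff(unique(c(trips$origin, trips$dest)), ids)
  if (length(missing)) {
    stopf("no population/distance information for district(s): %s",
          paste(sort(missing), collapse = ", "))
  }
  D <- distance %||% district_distances(districts)
  if (zero_fill) {
    grid <- expand.grid(origin = ids, dest = ids, stringsAsFactors = FALSE)
    grid <- grid[grid$origin != grid$dest, ]
    key <- paste(grid$origin, grid$dest, sep = "\r")
  } else {
    key <- sort(unique(paste(trips$origin, trips$dest, sep = "\r")))
  }
  counts <- table(paste(trips$origin, trips$dest, sep = "\r"))
  parts <- strsplit(key, "\r", fixed = TRUE)
  o <- vapply(parts, `[`, character(1), 1L)
  d <- vapply(parts, `[`, character(1), 2L)
  n <- as.integer(counts[key])
  n[is.na(n)] <- 0L
  pop <- districts$population[match(o, ids)]
  popd <- districts$population[match(d, ids)]
  dv <- D[cbind(match(o, rownames(D)), match(d, colnames(D)))]
  if (any(is.na(dv)) || any(dv <= 0)) {
    bad <- paste(o[is.na(dv) | dv <= 0], d[is.na(dv) | dv <= 0], sep = "->")
    stopf("missing or nonpositive distance for route(s): %s",
          paste(head(bad, 10L), collapse = ", "))
  }
  od <- data.frame(origin_id = o, dest_id = d, pop_orig = pop,
                   pop_dest = popd, dist = dv, trips = n,
                   stringsAsFactors = FALSE)
  names(od)[names(od) == "dist"] <- distance_name
  od <- od[order(od$origin_id, od$dest_id), , drop = FALSE]
  rownames(od) <- NULL
  od
}
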