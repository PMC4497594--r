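# Reading, validating and writing route-level OD tables.

# Synonyms accepted for each canonical OD column (lower-cased, punctuation
# stripped before matching).
od_column_synonyms <- list(
  origin_id = c("origin_id", "origin", "from", "orig", "source", "i",
                "origindistrict", "origid"),
  dest_id = c("dest_id", "destination", "dest", "to", "target", "j",
              "destdistrict", "destinationid"),
  pop_orig = c("pop_orig", "poporigin", "popi", "originpop", "originpopulation",
               "populationorigin", "popo"),
  pop_dest = c("pop_dest", "popdestination", "popj", "destpop",
               "destinationpop", "destinationpopulation", "popd"),
  dist_euclid_km = c("dist_euclid_km", "disteuclidkm", "euclid", "distance",
                     "dist", "euclideandistance", "distkm", "euclideankm"),
  dist_road_km = c("dist_road_km", "roaddistance", "road", "distroadkm",
                   "roadkm"),
  dist_time_h = c("dist_time_h", "traveltime", "time", "disttimeh",
                  "traveltimehours", "timehours"),
  trips = c("trips", "n", "nij", "flow", "count", "journeys", "travel",
            "amountoftravel", "ntrips")
)

normalise_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read a route-level OD table from CSV
#'
#' Accepts a documented set of column synonyms (see
#' `mobflow:::od_column_synonyms`), maps them to the canonical layout, and
#' validates: numeric flows, non-negative integer trips, positive
#' populations and distances, no duplicated or within-district routes.
#'
#' @param path CSV file path.
#' @return canonical OD table (`origin_id`, `dest_id`, `pop_orig`,
#'   `pop_dest`, `dist_euclid_km` and any further distance columns,
#'   `trips`).
#' @export
read_od_table <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_od_table(canonicalise_od(raw))
}

canonicalise_od <- function(raw) {
  hdr <- normalise_header(names(raw))
  out <- raw
  for (canon in names(od_column_synonyms)) {
    hit <- which(hdr %in% normalise_header(od_column_synonyms[[canon]]))
    if (length(hit) > 1L) {
      stopf("ambiguous columns for '%s': %s", canon,
            paste(names(raw)[hit], collapse = ", "))
    }
    if (length(hit) == 1L) names(out)[hit] <- canon
  }
  out
}

#' Validate an OD table
#'
#' @param od data.frame in (or mappable to) the canonical layout.
#' @return the validated table, invisibly usable downstream.
#' @export
validate_od_table <- function(od) {
  required <- c("origin_id", "dest_id", "pop_orig", "pop_dest",
                "dist_euclid_km", "trips")
  assert_cols(od, required, "OD table")
  for (cl in c("pop_orig", "pop_dest", "dist_euclid_km", "trips")) {
    if (!is.numeric(od[[cl]])) stopf("column '%s' is not numeric", cl)
  }
  if (any(od$trips < 0) || any(od$trips != round(od$trips))) {
    stopf("trips must be non-negative integers")
  }
  if (any(od$pop_orig <= 0) || any(od$pop_dest <= 0)) {
    stopf("populations must be positive")
  }
  dcols <- intersect(c("dist_euclid_km", "dist_road_km", "dist_time_h"),
                     names(od))
  for (dc in dcols) {
    if (any(od[[dc]] <= 0)) stopf("distances in '%s' must be positive", dc)
  }
  if (any(od$origin_id == od$dest_id)) {
    stopf("within-district routes are not allowed in an OD table")
  }
  key <- paste(od$origin_id, od$dest_id)
  if (anyDuplicated(key)) {
    stopf("duplicated route row(s): %s",
          paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  od
}

#' Write an OD table to CSV
#'
#' @param od OD table.
#' @param path destination path.
#' @export
write_od_table <- function(od, path) {
  write.csv(od, path, row.names = FALSE)
  invisible(path)
}

# District set implied by an OD table (population must be consistent
# across its appearances).
districts_from_od <- function(od) {
  d1 <- data.frame(district_id = od$origin_id, population = od$pop_orig,
                   stringsAsFactors = FALSE)
  d2 <- data.frame(district_id = od$dest_id, population = od$pop_dest,
                   stringsAsFactors = FALSE)
  d <- unique(rbind(d1, d2))
  if (anyDuplicated(d$district_id)) {
    stopf("inconsistent populations for district(s): %s",
          paste(unique(d$district_id[duplicated(d$district_id)]),
                collapse = ", "))
  }
  d[order(d$district_id), , drop = FALSE]
}

# Dense distance matrix from the long OD layout (NA where absent).
distance_matrix_from_od <- function(od, distance_col = "dist_euclid_km") {
  ids <- sort(unique(c(od$origin_id, od$dest_id)))
  D <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  D[cbind(match(od$origin_id, ids), match(od$dest_id, ids))] <- od[[distance_col]]
  diag(D) <- 0
  miss <- which(is.na(D), arr.ind = TRUE)
  if (nrow(miss)) {
    # fill symmetric counterpart when only one direction is present
    D[miss] <- t(D)[miss]
  }
  D
}
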