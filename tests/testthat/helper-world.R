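# Small fixture builders used across test files.

# Hand-specified district set.
make_districts <- function(pop, x, y, ids = sprintf("D%02d", seq_along(pop))) {
  data.frame(district_id = ids, population = pop, x = x, y = y,
             stringsAsFactors = FALSE)
}

# Tiny OD table straight from explicit vectors.
make_od <- function(origin, dest, pop_o, pop_d, dist, trips) {
  data.frame(origin_id = origin, dest_id = dest, pop_orig = pop_o,
             pop_dest = pop_d, dist_euclid_km = dist, trips = trips,
             stringsAsFactors = FALSE)
}

# Call-record rows.
make_records <- function(subscriber, day, tower) {
  data.frame(subscriber_id = subscriber, day = day, tower_id = tower,
             stringsAsFactors = FALSE)
}

simple_tower_map <- function(towers, districts) {
  data.frame(tower_id = towers, district_id = districts,
             stringsAsFactors = FALSE)
}
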