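# Shared fixtures, built once per test session. Everything is generated in
# code; no files are read.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small landscape shared across tests
tiny_landscape <- function() {
  memo("tiny_landscape", function() {
    make_landscape(MAINLAND_PROPORTIONS, grid_spec(40, 40), seed = 7)
  })
}

# medium landscape for pipeline runs
mid_landscape <- function() {
  memo("mid_landscape", function() {
    make_landscape(MAINLAND_PROPORTIONS, grid_spec(80, 80), seed = 1)
  })
}

# a small two-regime population and its prepared matrix (used in several files)
small_population <- function() {
  memo("small_population", function() {
    cfg <- sim_config(4, default_regimes("two_state"), n_years = 1,
                      rng_seed = 11)
    pop <- simulate_population(mid_landscape(), cfg)
    dm <- prepare_daily_matrix(pop$tracks, mid_landscape())
    list(pop = pop, dm = dm)
  })
}

# track data.frame from raw coordinates at fixed intervals
make_track <- function(x, y, hours = seq_along(x) - 1, id = "a",
                       start = "2021-03-01") {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  data.frame(individual_id = id, timestamp = t0 + hours * 3600,
             x = x, y = y, stringsAsFactors = FALSE)
}

# a season segment built directly from a track
make_segment <- function(fixes, state = "annual", year = 2021) {
  structure(list(individual_id = fixes$individual_id[1], state = state,
                 year = year, fixes = fixes, n_locations = nrow(fixes)),
            class = "season_segment")
}

# ordinal day of a "dd mon" date in a non-leap year
day_of <- function(txt) ordinal_day(as.Date(paste0("2021-", txt)))
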