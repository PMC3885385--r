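#' Generate a species pool with temperature niches along an elevational gradient
#'
#' Each species gets a species temperature index (STI), a Gaussian occupancy
#' response along altitude (optimum, width, maximal occupancy), and an id.
#' STIs are strictly inversely ordered against niche optima, so that by
#' construction the community temperature index declines with altitude over
#' the gradient covered by the pool.
#'
#' The optimum span deliberately extends well beyond the altitudes of any
#' surveyed square so that the occupied STI window is never truncated by the
#' pool boundary; this keeps the CTI-altitude relationship close to linear
#' across the survey gradient. Niche widths narrow with optimum altitude
#' (from `niche_width[2]` at the lowest optimum to `niche_width[1]` at the
#' highest, with 10% multiplicative jitter): high-altitude specialists
#' occupy narrower elevational belts, which makes the community temperature
#' variation (CTV) decline with altitude while leaving the CTI-altitude
#' relationship linear.
#'
#' @param n_species Number of species to generate (may be 0).
#' @param sti_bounds Length-2 numeric, lower and upper STI bound. Use an
#'   Ellenberg-like `c(1, 5)` for plants or a degrees-Celsius scale such as
#'   `c(7, 16)` for butterflies/birds.
#' @param seed Integer seed; the same seed reproduces the pool exactly.
#' @param optimum_span Altitude span (m) over which niche optima are placed.
#' @param niche_width Length-2 numeric: Gaussian niche widths (m) ramp
#'   linearly from `niche_width[2]` for the lowest-altitude optimum down to
#'   `niche_width[1]` for the highest, with multiplicative jitter.
#' @param max_occupancy Range from which per-species maximal occupancy
#'   probabilities are drawn; each must lie in \[0, 1\].
#' @return A `data.frame` of class `species_pool` with columns `species_id`,
#'   `sti`, `niche_optimum_alt`, `niche_width`, `max_occupancy`.
#' @examples
#' pool <- generate_species_pool(50, sti_bounds = c(1, 5), seed = 1)
#' cor(pool$sti, pool$niche_optimum_alt)  # strongly negative by construction
#' @export
generate_species_pool <- function(n_species, sti_bounds = c(1, 5), seed = NULL,
                                  optimum_span = c(-1500, 4500),
                                  niche_width = c(200, 400),
                                  max_occupancy = c(0.3, 0.7)) {
  if (length(sti_bounds) != 2L || !all(is.finite(sti_bounds)) ||
      sti_bounds[1] >= sti_bounds[2]) {
    stop("`sti_bounds` must be a finite pair with min < max", call. = FALSE)
  }
  if (n_species < 0) stop("`n_species` must be >= 0", call. = FALSE)
  if (optimum_span[1] >= optimum_span[2]) {
    stop("`optimum_span` must have min < max", call. = FALSE)
  }
  if (any(niche_width <= 0)) stop("`niche_width` must be positive", call. = FALSE)
  if (any(max_occupancy < 0) || any(max_occupancy > 1)) {
    stop("`max_occupancy` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_species <- as.integer(n_species)

  sti <- sort(stats::runif(n_species, sti_bounds[1], sti_bounds[2]),
              decreasing = TRUE)
  opt <- sort(stats::runif(n_species, optimum_span[1], optimum_span[2]))
  # widths narrow towards high-altitude optima (declining CTV gradient)
  frac <- (opt - optimum_span[1]) / diff(optimum_span)
  width <- (niche_width[2] - (niche_width[2] - niche_width[1]) * frac) *
    stats::runif(n_species, 0.9, 1.1)
  pool <- data.frame(
    species_id = sprintf("sp%04d", seq_len(n_species)),
    sti = sti,
    niche_optimum_alt = opt,
    niche_width = width,
    max_occupancy = stats::runif(n_species, max_occupancy[1], max_occupancy[2]),
    stringsAsFactors = FALSE
  )
  class(pool) <- c("species_pool", "data.frame")
  pool
}

#' Define a community-shift scenario for the survey generator
#'
#' Encodes the monitoring design (number of 1-km2 squares, altitude span,
#' richness decline with altitude) and the community change imposed between
#' the two surveys: an uphill displacement of species optima whose size
#' varies linearly with altitude, so shifts can decay to zero or reverse at
#' high altitude.
#'
#' @param shift_at_reference Imposed uphill shift (m) at the reference
#'   altitude between survey 1 and survey 2.
#' @param shift_gradient Change of the imposed shift per metre of altitude;
#'   e.g. `-40/1850` makes a 40 m shift at 500 m decay to 0 at 2350 m.
#' @param detection_noise Per-visit false-negative probability in \[0, 1).
#' @param n_squares Number of sample squares (>= 2).
#' @param altitude_range Length-2 numeric span (m) of square mean altitudes.
#' @param richness_decay Exponential decline rate of occupancy (per m above
#'   the gradient base); > 0 makes expected richness decrease with altitude.
#' @param reference_altitude Altitude (m) at which `shift_at_reference` applies.
#' @param seed Integer seed used by [generate_surveys()].
#' @return A list of class `shift_scenario`.
#' @export
shift_scenario <- function(shift_at_reference = 0, shift_gradient = 0,
                           detection_noise = 0.1, n_squares = 214,
                           altitude_range = c(263, 2840),
                           richness_decay = 2e-4,
                           reference_altitude = 500, seed = NULL) {
  if (n_squares < 2) stop("`n_squares` must be >= 2", call. = FALSE)
  if (length(altitude_range) != 2L || altitude_range[1] >= altitude_range[2]) {
    stop("`altitude_range` must have min < max", call. = FALSE)
  }
  if (detection_noise < 0 || detection_noise >= 1) {
    stop("`detection_noise` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(shift_at_reference = shift_at_reference,
         shift_gradient = shift_gradient,
         detection_noise = detection_noise,
         n_squares = as.integer(n_squares),
         altitude_range = altitude_range,
         richness_decay = richness_decay,
         reference_altitude = reference_altitude,
         seed = seed),
    class = "shift_scenario"
  )
}

#' Evaluate the imposed community shift at given altitudes
#'
#' @param scenario A [shift_scenario()].
#' @param altitude Altitudes (m).
#' @return Imposed uphill shift (m) at each altitude.
#' @export
scenario_shift_at <- function(scenario, altitude) {
  scenario$shift_at_reference +
    scenario$shift_gradient * (altitude - scenario$reference_altitude)
}

#' Simulate a two-survey occurrence dataset on an elevational gradient
#'
#' Survey-1 occupancy of species *s* at a square of altitude *a* is the
#' Gaussian response `max_occupancy * exp(-(a - optimum)^2 / (2 width^2))`,
#' damped by `exp(-richness_decay * (a - min altitude))` so richness declines
#' with altitude. In survey 2 every species' effective optimum is raised by
#' the scenario shift evaluated at the square's altitude, which reproduces at
#' each square the survey-1 community from that many metres downhill (in
#' expectation). Presence is drawn independently per (square, survey);
#' detected presences are thinned by the false-negative probability.
#'
#' @param pool A [generate_species_pool()] result (nonempty).
#' @param scenario A [shift_scenario()].
#' @param squares Optional square table (`square_id`, `altitude_m`,
#'   `altitudinal_range_m`, `year_survey1`) to reuse across taxon groups so
#'   their communities are driven by the same altitude field; generated from
#'   the scenario when `NULL`.
#' @return A list of class `survey_dataset` with elements `occurrences`
#'   (`square_id`, `survey`, `year`, `species_id`) and `squares`
#'   (`square_id`, `altitude_m`, `altitudinal_range_m`, `year_survey1`,
#'   `year_survey2`).
#' @export
generate_surveys <- function(pool, scenario, squares = NULL) {
  if (!inherits(scenario, "shift_scenario")) {
    stop("`scenario` must be a shift_scenario", call. = FALSE)
  }
  if (nrow(pool) == 0L) stop("`pool` must contain at least one species", call. = FALSE)
  if (!is.null(scenario$seed)) set.seed(scenario$seed)

  if (is.null(squares)) squares <- simulate_squares(scenario)
  nsq <- nrow(squares)
  nsp <- nrow(pool)
  alt <- squares$altitude_m
  damp <- exp(-scenario$richness_decay * (alt - scenario$altitude_range[1]))

  occ_list <- vector("list", 2L)
  for (survey in 1:2) {
    shift <- if (survey == 2L) scenario_shift_at(scenario, alt) else 0
    # occupancy matrix: squares x species
    d <- outer(alt - shift, pool$niche_optimum_alt, "-")
    p <- sweep(exp(-(d^2) / (2 * rep(pool$niche_width^2, each = nsq))), 2,
               pool$max_occupancy, "*")
    p <- p * damp
    p <- p * (1 - scenario$detection_noise)
    present <- matrix(stats::rbinom(nsq * nsp, 1L, pmin(p, 1)), nsq, nsp)
    idx <- which(present == 1L, arr.ind = TRUE)
    year <- if (survey == 1L) squares$year_survey1 else squares$year_survey1 + 5L
    occ_list[[survey]] <- data.frame(
      square_id = squares$square_id[idx[, 1]],
      survey = rep(survey, nrow(idx)),
      year = year[idx[, 1]],
      species_id = pool$species_id[idx[, 2]],
      stringsAsFactors = FALSE
    )
  }
  occurrences <- do.call(rbind, occ_list)
  occurrences <- occurrences[order(occurrences$survey, occurrences$square_id,
                                   occurrences$species_id), , drop = FALSE]
  rownames(occurrences) <- NULL
  squares$year_survey2 <- squares$year_survey1 + 5L
  structure(list(occurrences = occurrences, squares = squares),
            class = "survey_dataset")
}

simulate_squares <- function(scenario) {
  nsq <- scenario$n_squares
  data.frame(
    square_id = sprintf("sq%03d", seq_len(nsq)),
    altitude_m = stats::runif(nsq, scenario$altitude_range[1],
                              scenario$altitude_range[2]),
    altitudinal_range_m = stats::runif(nsq, 30, 700),
    year_survey1 = sample(2003:2005, nsq, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' STI lookup table for a species pool
#'
#' @param pool A [generate_species_pool()] result.
#' @param group Group label (e.g. `"plants"`, `"butterflies"`, `"birds"`).
#' @return A `data.frame` with columns `species_id`, `group`, `sti`.
#' @export
sti_table <- function(pool, group = "group1") {
  data.frame(species_id = pool$species_id, group = group, sti = pool$sti,
             stringsAsFactors = FALSE)
}

#' Simulate monthly temperature series for a set of stations
#'
#' Monthly means are a seasonal baseline (annual cosine peaking in July)
#' plus an altitudinal lapse, a linear warming trend, station and year random
#' intercepts, and Gaussian measurement noise — the structure the
#' temperature-trend mixed model assumes.
#'
#' @param n_stations Number of stations (>= 1), spread evenly over
#'   `altitude_range`.
#' @param years Integer vector of calendar years.
#' @param trend_per_year Warming trend, degrees C per year.
#' @param lapse_rate Temperature change per metre altitude (degrees C/m,
#'   typically negative).
#' @param noise_sd SD of per-record measurement noise (degrees C).
#' @param station_sd,year_sd SDs of station and year random intercepts.
#' @param altitude_range Span (m) of station altitudes.
#' @param base_temp Annual-mean temperature at 0 m in the first year.
#' @param seasonal_amplitude Half-range of the seasonal cycle (degrees C).
#' @param seed Integer seed.
#' @return A `data.frame` of class `station_series` with columns
#'   `station_id`, `altitude_m`, `year`, `month`, `mean_temp_c`.
#' @export
generate_station_series <- function(n_stations = 14, years = 1995:2010,
                                    trend_per_year = 0.07,
                                    lapse_rate = -0.0055, noise_sd = 0.5,
                                    station_sd = 0.4, year_sd = 0.3,
                                    altitude_range = c(273, 2501),
                                    base_temp = 10, seasonal_amplitude = 9,
                                    seed = NULL) {
  if (n_stations < 1) stop("`n_stations` must be >= 1", call. = FALSE)
  if (length(years) < 1) stop("`years` must be nonempty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  altitudes <- if (n_stations == 1L) mean(altitude_range) else
    seq(altitude_range[1], altitude_range[2], length.out = n_stations)
  station_eff <- stats::rnorm(n_stations, 0, station_sd)
  year_eff <- stats::rnorm(length(years), 0, year_sd)

  grid <- expand.grid(month = 1:12, year = years,
                      station = seq_len(n_stations), KEEP.OUT.ATTRS = FALSE)
  seasonal <- seasonal_amplitude * cos(2 * pi * (grid$month - 7) / 12)
  temp <- base_temp + seasonal +
    lapse_rate * altitudes[grid$station] +
    trend_per_year * (grid$year - years[1]) +
    station_eff[grid$station] +
    year_eff[match(grid$year, years)] +
    stats::rnorm(nrow(grid), 0, noise_sd)
  out <- data.frame(
    station_id = sprintf("st%02d", grid$station),
    altitude_m = altitudes[grid$station],
    year = grid$year,
    month = grid$month,
    mean_temp_c = temp,
    stringsAsFactors = FALSE
  )
  class(out) <- c("station_series", "data.frame")
  out
}
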