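# Shared configuration for the analysis scripts: the emulated monitoring
# design and the three taxon groups.
#
# Every script takes --seed (default 1); all randomness derives from it.

library(thermocomm)

arg_seed <- function() {
  args <- commandArgs(trailingOnly = TRUE)
  i <- match("--seed", args)
  if (!is.na(i) && length(args) > i) as.integer(args[i + 1L]) else 1L
}

res_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

# Monitoring design: 214 1-km2 squares over 263-2840 m, two surveys five
# years apart, an imposed uphill community shift of 40 m at 500 m decaying
# to zero at the 2350 m tree line.
base_scenario <- function(seed) {
  shift_scenario(shift_at_reference = 40, shift_gradient = -40 / 1850,
                 n_squares = 214, altitude_range = c(263, 2840),
                 detection_noise = 0.1, richness_decay = 2e-4, seed = seed)
}

# Taxon groups: Ellenberg-like STIs for plants (1-5), degrees-C scales for
# butterflies and birds; pool density and occupancy tuned so survey-1
# richness matches the monitoring scheme (~220 plants, ~29 butterflies,
# ~33 birds per square) while expected CTI stays linear in altitude.
group_defs <- list(
  plants = list(n_species = 4000, sti_bounds = c(1, 5),
                max_occupancy = c(0.5, 0.7)),
  butterflies = list(n_species = 2000, sti_bounds = c(7, 16),
                     max_occupancy = c(0.10, 0.20)),
  birds = list(n_species = 2000, sti_bounds = c(8, 14),
               max_occupancy = c(0.12, 0.22))
)

# A-priori exclusions: wandering species do not reflect local thermal
# conditions. (Synthetic ids; stands in for the kind of list a curator
# would supply, e.g. migratory/wandering butterflies.)
exclusion_list <- character(0)
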