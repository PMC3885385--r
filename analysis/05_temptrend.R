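#!/usr/bin/env Rscript
# Air-temperature trends: aggregate monthly station series into summer
# (April-September) and coldest-month means, and fit the crossed
# random-intercept mixed model testing whether the warming trend depends on
# altitude.
#
# Reads results/data/stations.csv, writes results/temperature/.

source(file.path("analysis", "00_config.R"))
out <- res_dir("temperature")

tabs <- read_tables(file.path("results/data", "plants_occurrences.csv"),
                    file.path("results/data", "plants_squares.csv"),
                    stations = file.path("results/data", "stations.csv"))
stations <- tabs$stations

for (measure in c("summer", "coldest")) {
  vals <- if (measure == "summer") summer_mean(stations) else
    coldest_month_mean(stations)
  fit <- fit_temperature_lmm(vals)
  utils::write.csv(cbind(term = rownames(fit$coefficients),
                         fit$coefficients),
                   file.path(out, paste0(measure, "_lmm.csv")),
                   row.names = FALSE)
  cat("\n", measure, "temperature mixed model (station and year random",
      "intercepts):\n")
  print(fit)
  tr <- fit$coefficients["trend", ]
  ia <- fit$coefficients["altitude:trend", ]
  cat(sprintf("  trend %.3f degC/yr (t = %.2f, p = %.3f); trend x altitude %+0.2e (t = %.2f, p = %.2f)\n",
              tr$estimate, tr$t, tr$p, ia$estimate, ia$t, ia$p))
}
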