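#' Configuration for an end-to-end pipeline run
#'
#' @param groups Named list of group definitions for synthetic runs; each
#'   element is a list of [generate_species_pool()] arguments, at least
#'   `n_species` and `sti_bounds` (plants-like Ellenberg scale `c(1, 5)` or
#'   a degrees-C scale for mobile taxa).
#' @param scenario A [shift_scenario()] shared by all groups (communities of
#'   every group are driven by the same squares, mirroring a monitoring
#'   scheme that surveys all taxa on the same sites).
#' @param exclusions Character vector of species ids to exclude a priori.
#' @param indices Index kinds to analyse, subset of `c("cti", "ctv")`.
#' @param targets Reference altitudes (m) for predictions; defaults to
#'   500 (lowland reference) and 2350 (tree line).
#' @param B Bootstrap iterations.
#' @param seed Master seed; group-level seeds are derived from it.
#' @param station_args Optional list of arguments for
#'   [generate_station_series()]; `NULL` skips the temperature-trend stage.
#' @param out_dir Optional directory: intermediate tables are written as CSV.
#' @return A list of class `run_config`.
#' @export
run_config <- function(groups = list(
                         butterflies = list(n_species = 2000,
                                            sti_bounds = c(7, 16),
                                            max_occupancy = c(0.10, 0.20))),
                       scenario = shift_scenario(),
                       exclusions = character(0),
                       indices = c("cti", "ctv"),
                       targets = c(500, 2350),
                       B = 1000, seed = 1,
                       station_args = NULL,
                       out_dir = NULL) {
  out_of_span <- targets < scenario$altitude_range[1] |
    targets > scenario$altitude_range[2]
  if (any(out_of_span)) {
    warning("reference altitude(s) ",
            paste(targets[out_of_span], collapse = ", "),
            " lie outside the data's altitude span; predictions there are ",
            "extrapolations", call. = FALSE)
  }
  structure(list(groups = groups, scenario = scenario,
                 exclusions = exclusions, indices = match.arg(indices,
                   c("cti", "ctv"), several.ok = TRUE),
                 targets = targets, B = B, seed = seed,
                 station_args = station_args, out_dir = out_dir),
            class = "run_config")
}

#' Run the full community-thermal-shift pipeline on synthetic data
#'
#' For each taxon group: simulate (or reuse) occurrence surveys on a shared
#' set of squares, apply a-priori species exclusions, compute CTI/CTV index
#' tables, fit the first-survey index-altitude slope, standardize temporal
#' changes into metres, select the residual-variance structure by REML AIC,
#' backward-select the fixed effects by ML AIC, and bootstrap predictions at
#' the reference altitudes. Also computes the cross-taxon correlation matrix
#' of first-survey CTIs and, when station arguments are configured, the
#' temperature-trend mixed-model fits.
#'
#' All randomness is derived from `config$seed`, so reruns with the same
#' configuration reproduce every number exactly.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report`: per-group results (`slope`,
#'   `changes`, `variance`, `selection`, `bootstrap` per index), the
#'   cross-taxon correlations, the temperature fits, and the seeds used.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  group_names <- names(config$groups)
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  say("pipeline seed: ", seed)

  # shared squares so all groups see the same altitude field
  scenario <- config$scenario
  scenario$seed <- seed
  set.seed(seed)
  squares <- simulate_squares(scenario)

  groups <- list()
  for (gi in seq_along(config$groups)) {
    gname <- group_names[gi]
    gdef <- config$groups[[gi]]
    gseed <- seed + 1000L * gi
    say("group ", gname, ": seed ", gseed)
    pool <- do.call(generate_species_pool,
                    c(gdef, list(seed = gseed)))
    gscenario <- scenario
    gscenario$seed <- gseed + 1L
    dataset <- generate_surveys(pool, gscenario, squares = squares)
    dataset <- apply_exclusions(dataset, config$exclusions)
    sti <- sti_table(pool, gname)
    idx <- index_table(dataset, sti, gname)

    res <- list(pool = pool, dataset = dataset, indices = idx)
    for (index in config$indices) {
      changes <- standardized_changes(idx, index)
      n_dropped <- sum(idx$survey == 1) - nrow(changes)
      if (n_dropped > 0) say("group ", gname, " ", index, ": ", n_dropped,
                             " square(s) dropped")
      vsel <- select_variance_structure(changes)
      say("group ", gname, " ", index, ": variance structure '", vsel$kind,
          "' (REML AIC ", paste(names(vsel$aic),
                                round(vsel$aic, 2), sep = " = ",
                                collapse = ", "), ")")
      bsel <- backward_select(changes, vsel$variance)
      say("group ", gname, " ", index, ": selection path ",
          paste(bsel$path$step, collapse = " -> "))
      boot <- bootstrap_predictions(changes, bsel$spec, vsel$variance,
                                    targets = config$targets, B = config$B,
                                    seed = gseed + 2L)
      res[[index]] <- list(slope = attr(changes, "slope"),
                           changes = changes,
                           variance = vsel, selection = bsel,
                           bootstrap = boot)
    }
    groups[[gname]] <- res
  }

  # cross-taxon coherence of first-survey CTIs
  cross <- NULL
  if (length(groups) >= 2L) {
    cti1 <- lapply(groups, function(g) {
      s1 <- g$indices[g$indices$survey == 1L, ]
      s1$cti[match(squares$square_id, s1$square_id)]
    })
    pairs <- utils::combn(group_names, 2, simplify = FALSE)
    cross <- do.call(rbind, lapply(pairs, function(pr) {
      ct <- cross_taxon_correlation(cti1[[pr[1]]], cti1[[pr[2]]])
      data.frame(group_a = pr[1], group_b = pr[2], r = ct$r, t = ct$t,
                 df = ct$df, p = ct$p, stringsAsFactors = FALSE)
    }))
  }

  temperature <- NULL
  if (!is.null(config$station_args)) {
    st_seed <- seed + 99L
    say("station series seed: ", st_seed)
    stations <- do.call(generate_station_series,
                        c(config$station_args, list(seed = st_seed)))
    temperature <- list(
      stations = stations,
      summer = fit_temperature_lmm(summer_mean(stations)),
      coldest = fit_temperature_lmm(coldest_month_mean(stations))
    )
  }

  report <- structure(list(groups = groups, cross_taxon = cross,
                           temperature = temperature, squares = squares,
                           config = config, log = log_lines),
                      class = "run_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write the tables of a pipeline report to a directory
#'
#' @param report A `run_report`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$squares, file.path(dir, "squares.csv"),
                   row.names = FALSE)
  for (gname in names(report$groups)) {
    g <- report$groups[[gname]]
    utils::write.csv(g$indices, file.path(dir, paste0(gname, "_indices.csv")),
                     row.names = FALSE)
    for (index in intersect(c("cti", "ctv"), names(g))) {
      stem <- file.path(dir, paste0(gname, "_", index))
      utils::write.csv(g[[index]]$changes, paste0(stem, "_changes.csv"),
                       row.names = FALSE)
      utils::write.csv(g[[index]]$bootstrap$predictions,
                       paste0(stem, "_predictions.csv"), row.names = FALSE)
      coef_tab <- data.frame(term = names(g[[index]]$selection$fit$coefficients),
                             estimate = g[[index]]$selection$fit$coefficients,
                             se = g[[index]]$selection$fit$se)
      utils::write.csv(coef_tab, paste0(stem, "_coefficients.csv"),
                       row.names = FALSE)
    }
  }
  if (!is.null(report$cross_taxon)) {
    utils::write.csv(report$cross_taxon, file.path(dir, "cross_taxon.csv"),
                     row.names = FALSE)
  }
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Community thermal-shift pipeline report\n")
  cat("Groups:", paste(names(x$groups), collapse = ", "), "\n")
  for (gname in names(x$groups)) {
    g <- x$groups[[gname]]
    for (index in intersect(c("cti", "ctv"), names(g))) {
      cat("\n-- ", gname, " ", toupper(index),
          " (b = ", signif(g[[index]]$slope$b, 3), " per m, variance '",
          g[[index]]$variance$kind, "')\n", sep = "")
      print(g[[index]]$bootstrap)
    }
  }
  if (!is.null(x$cross_taxon)) {
    cat("\nCross-taxon survey-1 CTI correlations:\n")
    print(transform(x$cross_taxon, r = signif(r, 3), t = signif(t, 3),
                    p = signif(p, 3)))
  }
  invisible(x)
}
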