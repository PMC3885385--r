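#' Remove excluded species from a survey dataset
#'
#' Drops every occurrence of the listed species in every square and survey,
#' e.g. wandering butterfly species whose presence does not reflect local
#' thermal conditions. Unknown ids are ignored with a warning.
#'
#' @param dataset A `survey_dataset` (see [generate_surveys()] or
#'   [read_tables()]).
#' @param exclusion_list Character vector of species ids to drop.
#' @return The dataset with the listed species removed.
#' @export
apply_exclusions <- function(dataset, exclusion_list) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (length(exclusion_list) == 0L) return(dataset)
  unknown <- setdiff(exclusion_list, unique(dataset$occurrences$species_id))
  if (length(unknown) > 0L) {
    warning("exclusion list contains species absent from the dataset: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- !(dataset$occurrences$species_id %in% exclusion_list)
  dataset$occurrences <- dataset$occurrences[keep, , drop = FALSE]
  rownames(dataset$occurrences) <- NULL
  dataset
}

#' Community temperature index: mean STI of recorded species
#'
#' The unweighted arithmetic mean of the species temperature indices of the
#' species present; occurrence-based, so no abundance weighting. Undefined
#' (NA) for an empty community.
#'
#' @param member_stis Numeric STI values of the community members.
#' @return The CTI, or `NA_real_` if no species are present.
#' @export
compute_cti <- function(member_stis) {
  member_stis <- member_stis[!is.na(member_stis)]
  if (length(member_stis) == 0L) return(NA_real_)
  mean(member_stis)
}

#' Community temperature variation: SD of member STIs
#'
#' The sample standard deviation (divisor n - 1) of the species temperature
#' indices of the species present. Undefined (NA) for communities with fewer
#' than two species.
#'
#' @param member_stis Numeric STI values of the community members.
#' @return The CTV, or `NA_real_` if fewer than two species are present.
#' @export
compute_ctv <- function(member_stis) {
  member_stis <- member_stis[!is.na(member_stis)]
  if (length(member_stis) < 2L) return(NA_real_)
  stats::sd(member_stis)
}

#' Per-square, per-survey community index table
#'
#' Deduplicates occurrences to presence/absence, joins STIs, and computes
#' CTI, CTV and species richness for every (square, survey) combination of
#' one taxon group. A species occurring without an STI entry is a hard error
#' (silently dropping it would bias the CTI).
#'
#' @param dataset A `survey_dataset`.
#' @param sti STI lookup table with columns `species_id`, `group`, `sti`
#'   (see [sti_table()]).
#' @param group Group label selecting rows of `sti`; `NULL` uses the whole
#'   table.
#' @return A `data.frame` of class `community_indices`: one row per
#'   (square, survey) with `square_id`, `survey`, `year`, `group`, `cti`,
#'   `ctv`, `richness`, `altitude_m`, `altitudinal_range_m`. `cti` is NA for
#'   empty communities and `ctv` NA below richness 2; such squares are
#'   dropped from the corresponding downstream analyses.
#' @export
index_table <- function(dataset, sti, group = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (!is.null(group)) sti <- sti[sti$group %in% group, , drop = FALSE]
  occ <- dataset$occurrences
  occ <- unique(occ[c("square_id", "survey", "year", "species_id")])

  missing_sti <- setdiff(unique(occ$species_id), sti$species_id)
  if (length(missing_sti) > 0L) {
    stop("species without an STI value: ",
         paste(sort(missing_sti), collapse = ", "), call. = FALSE)
  }
  occ$sti <- sti$sti[match(occ$species_id, sti$species_id)]

  sq <- dataset$squares
  cells <- expand.grid(square_id = sq$square_id, survey = 1:2,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(s, v) paste(s, v, sep = "\r")
  split_sti <- split(occ$sti, key(occ$square_id, occ$survey))
  cell_key <- key(cells$square_id, cells$survey)
  out <- data.frame(
    square_id = cells$square_id,
    survey = cells$survey,
    year = ifelse(cells$survey == 1L,
                  sq$year_survey1[match(cells$square_id, sq$square_id)],
                  sq$year_survey2[match(cells$square_id, sq$square_id)]),
    group = if (is.null(group)) sti$group[1] else group[1],
    cti = vapply(cell_key, function(k) compute_cti(split_sti[[k]]), 0),
    ctv = vapply(cell_key, function(k) compute_ctv(split_sti[[k]]), 0),
    richness = vapply(cell_key, function(k) length(split_sti[[k]]), 0L),
    stringsAsFactors = FALSE
  )
  out$altitude_m <- sq$altitude_m[match(out$square_id, sq$square_id)]
  out$altitudinal_range_m <- sq$altitudinal_range_m[match(out$square_id,
                                                          sq$square_id)]
  out <- out[order(out$survey, out$square_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("community_indices", "data.frame")
  out
}

#' Pearson correlation between two per-square index vectors
#'
#' Cross-taxon coherence check: correlates, square by square, an index of one
#' taxon group with the same index of another. Reports the correlation r,
#' its t statistic \eqn{r \sqrt{n-2} / \sqrt{1-r^2}}, the degrees of freedom
#' n - 2, and the two-sided p-value from the t distribution.
#'
#' @param x,y Numeric vectors paired by square, equal length >= 3.
#' @return A list with elements `r`, `t`, `df`, `p`, `n`.
#' @export
cross_taxon_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(y) != n) {
    stop("need paired vectors of equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in input; correlation undefined", call. = FALSE)
    return(list(r = NA_real_, t = NA_real_, df = n - 2L, p = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  df <- n - 2L
  t <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(r = r, t = t, df = df, p = p, n = n)
}
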