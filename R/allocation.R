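#' Allocation engine configuration
#'
#' Options controlling how causes of death are extrapolated for cases
#' without an observed death. Defaults follow the published procedure:
#' lost cases take the observed cause distribution of their (site group x
#' stage) stratum in the year of follow-up in which they were lost;
#' survivors at the administrative end take the pooled distribution of
#' deaths in the final `tail_window_months` (48 = four years) of
#' attainable follow-up. Future death dates are never modelled.
#'
#' The published procedure is silent on empty cells, so a configurable
#' fallback chain handles them: the loss year's distribution, then the
#' adjacent years pooled (t-1..t+1), then the stratum pooled over all
#' years, then the site group pooled over stages, then the global
#' distribution. Every fallback use is logged.
#'
#' @param tail_window_months Width of the extrapolation window, counted
#'   back from the maximum attainable follow-up month in the dataset.
#' @param fallback_chain Ordered subset of `c("adjacent_years", "stratum",
#'   "site", "global")` tried after the primary distribution is empty.
#' @param mode `"fractional"` (deterministic fractional weights, the
#'   default: reproducible and exact in expectation) or `"sampled"` (one
#'   seeded draw per case, for sensitivity checks).
#' @param lost_mode `"loss_year"` (the literal reading: the distribution of
#'   the year in which the case was lost) or `"forward"` (deaths in all
#'   years at or after the loss year, weighted by observed counts).
#' @param seed Seed for `mode = "sampled"`.
#' @return A list of class `allocation_config`.
#' @export
allocation_config <- function(tail_window_months = 48,
                              fallback_chain = c("adjacent_years", "stratum",
                                                 "site", "global"),
                              mode = c("fractional", "sampled"),
                              lost_mode = c("loss_year", "forward"),
                              seed = NULL) {
  stopifnot(tail_window_months > 0)
  chain_ok <- fallback_chain %in% c("adjacent_years", "stratum", "site", "global")
  if (!all(chain_ok)) {
    stop("unknown fallback level(s): ",
         paste(fallback_chain[!chain_ok], collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      tail_window_months = tail_window_months,
      fallback_chain = fallback_chain,
      mode = match.arg(mode),
      lost_mode = match.arg(lost_mode),
      seed = seed
    ),
    class = "allocation_config"
  )
}

# normalize a set of classified deaths into a cause distribution
cause_distribution <- function(deaths) {
  if (nrow(deaths) == 0) {
    return(tibble::tibble(cause_major = character(0),
                          cause_detail = character(0),
                          n = integer(0), prop = numeric(0)))
  }
  deaths |>
    dplyr::count(cause_major, cause_detail, name = "n") |>
    dplyr::mutate(prop = n / sum(n))
}

#' Observed cause-of-death distributions by follow-up year
#'
#' For one (site group x stage) stratum, tabulates the observed deaths by
#' follow-up year and cause (at detail resolution) and normalizes within
#' each year. Years with no observed deaths are absent from the result;
#' the allocation fallback chain handles them. This is the per-year
#' distribution used to impute causes for cases lost to follow-up.
#'
#' @param cohort A classified cohort (see [classify_cohort()]).
#' @param site_group,stage The stratum.
#' @return A tibble `fu_year`, `cause_major`, `cause_detail`, `n`, `prop`
#'   with `prop` summing to 1 within each year.
#' @export
yearly_distributions <- function(cohort, site_group, stage) {
  check_stratum(site_group, stage)
  check_classified(cohort)
  deaths <- cohort[cohort$vital_status == "dead" &
                     cohort$site_group == site_group &
                     cohort$stage == stage, ]
  if (nrow(deaths) == 0) {
    return(tibble::tibble(fu_year = integer(0), cause_major = character(0),
                          cause_detail = character(0), n = integer(0),
                          prop = numeric(0)))
  }
  deaths |>
    dplyr::count(fu_year, cause_major, cause_detail, name = "n") |>
    dplyr::group_by(fu_year) |>
    dplyr::mutate(prop = n / sum(n)) |>
    dplyr::ungroup() |>
    dplyr::arrange(fu_year, cause_major, cause_detail)
}

#' Pooled cause distribution in the final window of follow-up
#'
#' The extrapolation distribution for cases still alive at the
#' administrative end of follow-up: the pooled cause mix of observed
#' deaths in the stratum whose follow-up month exceeds (maximum attainable
#' follow-up month - `window_months`). The default 48-month window is the
#' published "final four years" rule, justified by the plateau in
#' index-cancer death risk about 10 years after diagnosis (statistical
#' cure). An empty tail is returned as an empty distribution and triggers
#' the fallback chain during allocation.
#'
#' @inheritParams yearly_distributions
#' @param window_months Window width in months (default 48).
#' @param max_attainable Reference month for the window; defaults to the
#'   maximum follow-up month observed anywhere in the dataset.
#' @return A tibble `cause_major`, `cause_detail`, `n`, `prop`.
#' @export
tail_distribution <- function(cohort, site_group, stage, window_months = 48,
                              max_attainable = NULL) {
  stopifnot(window_months > 0)
  check_stratum(site_group, stage)
  check_classified(cohort)
  if (is.null(max_attainable)) max_attainable <- max(cohort$followup_months)
  threshold <- max_attainable - window_months
  deaths <- cohort[cohort$vital_status == "dead" &
                     cohort$site_group == site_group &
                     cohort$stage == stage &
                     cohort$followup_months > threshold, ]
  cause_distribution(deaths)
}

check_stratum <- function(site_group, stage) {
  if (!site_group %in% site_groups()$site_group) {
    stop("unknown site_group: ", site_group, call. = FALSE)
  }
  if (!stage %in% pm_stages()) stop("unknown stage: ", stage, call. = FALSE)
  invisible(TRUE)
}

check_classified <- function(cohort) {
  need <- c("cause_major", "cause_detail", "fu_year")
  if (!all(need %in% names(cohort))) {
    stop("cohort must be classified first; run classify_cohort()", call. = FALSE)
  }
  invisible(TRUE)
}

#' Allocate a cause of death to a single case
#'
#' The per-case allocation rule, exposed so small strata can be checked by
#' hand: an observed death gets weight 1 on its classified cause
#' (provenance `observed`); a case lost in follow-up year t gets the year-t
#' distribution (`imputed_lost`); a case alive at the administrative end
#' gets the tail distribution (`extrapolated_alive`). If the applicable
#' distribution is empty, `fallback` (a precomputed distribution tibble) is
#' used; with no fallback the allocation fails loudly rather than emitting
#' silent zeros.
#'
#' @param case A one-row classified case record.
#' @param yearly Year-by-year distributions from [yearly_distributions()].
#' @param tail Tail distribution from [tail_distribution()].
#' @param fallback Optional distribution tibble used when the primary
#'   distribution has no deaths.
#' @return A tibble `case_id`, `provenance`, `cause_major`, `cause_detail`,
#'   `weight` with weights summing to exactly 1.
#' @export
allocate_case <- function(case, yearly, tail, fallback = NULL) {
  stopifnot(nrow(case) == 1)
  take <- function(dist, provenance) {
    if (nrow(dist) == 0) dist <- fallback
    if (is.null(dist) || nrow(dist) == 0) {
      stop("no cause distribution available for stratum (", case$site_group,
           ", stage ", case$stage, "); fallback chain exhausted", call. = FALSE)
    }
    tibble::tibble(
      case_id = case$case_id, provenance = provenance,
      cause_major = dist$cause_major, cause_detail = dist$cause_detail,
      weight = dist$prop
    )
  }
  switch(case$vital_status,
    dead = tibble::tibble(
      case_id = case$case_id, provenance = "observed",
      cause_major = case$cause_major, cause_detail = case$cause_detail,
      weight = 1
    ),
    lost = take(yearly[yearly$fu_year == case$fu_year, ], "imputed_lost"),
    alive = take(tail, "extrapolated_alive"),
    stop("unknown vital_status: ", case$vital_status, call. = FALSE)
  )
}

#' Allocate causes of death across an entire cohort
#'
#' Follows every eligible case until death by observation or by
#' extrapolation: observed deaths keep their classified cause with weight
#' 1; cases lost to follow-up are imputed from the observed cause
#' distribution of their stratum in the year of loss; survivors at the
#' administrative end are extrapolated from the stratum's final-four-years
#' distribution. Fractional weights (the default mode) conserve mass
#' exactly: the weights for each case sum to 1, so allocated cause counts
#' sum to the number of cases, overall and within every stratum.
#'
#' @param cohort A classified cohort (see [classify_cohort()]), non-empty.
#' @param config An [allocation_config()].
#' @return An object of class `pm_allocation`: a list with `weights` (long
#'   tibble `case_id`, `provenance`, `cause_major`, `cause_detail`,
#'   `weight`), `provenance_summary` (per-stage fractions observed /
#'   imputed / extrapolated), `fallback_log` (one row per fallback use),
#'   and `config`.
#' @export
allocate_cohort <- function(cohort, config = allocation_config()) {
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  check_classified(cohort)
  deaths <- cohort[cohort$vital_status == "dead", ]
  max_attainable <- max(cohort$followup_months)
  threshold <- max_attainable - config$tail_window_months
  log_rows <- list()
  note_fallback <- function(site, stage, year, level, n_cases) {
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
      site_group = site, stage = stage,
      fu_year = ifelse(is.na(year), NA_integer_, year),
      level = level, n_cases = n_cases
    )
  }
  # ordered candidate death sets for one lookup; first non-empty wins
  lookup <- function(site, stage, year, kind) {
    in_stratum <- deaths$site_group == site & deaths$stage == stage
    primary <- if (kind == "lost") {
      if (config$lost_mode == "loss_year") {
        deaths[in_stratum & deaths$fu_year == year, ]
      } else {
        deaths[in_stratum & deaths$fu_year >= year, ]
      }
    } else {
      deaths[in_stratum & deaths$followup_months > threshold, ]
    }
    candidates <- list(primary = primary)
    for (lvl in config$fallback_chain) {
      candidates[[lvl]] <- switch(lvl,
        adjacent_years = if (kind == "lost") {
          deaths[in_stratum & abs(deaths$fu_year - year) <= 1, ]
        } else NULL,
        stratum = deaths[in_stratum, ],
        site = deaths[deaths$site_group == site, ],
        global = deaths
      )
    }
    for (lvl in names(candidates)) {
      d <- candidates[[lvl]]
      if (!is.null(d) && nrow(d) > 0) {
        return(list(dist = cause_distribution(d), level = lvl))
      }
    }
    stop("no cause distribution available for stratum (", site, ", stage ",
         stage, "); fallback chain exhausted", call. = FALSE)
  }

  observed_w <- deaths |>
    dplyr::transmute(case_id, provenance = "observed",
                     cause_major, cause_detail, weight = 1)

  expand_group <- function(sub, kind) {
    keys <- if (kind == "lost") {
      dplyr::distinct(sub, site_group, stage, fu_year)
    } else {
      dplyr::distinct(sub, site_group, stage) |>
        dplyr::mutate(fu_year = NA_integer_)
    }
    provenance <- if (kind == "lost") "imputed_lost" else "extrapolated_alive"
    out <- lapply(seq_len(nrow(keys)), function(i) {
      k <- keys[i, ]
      hit <- lookup(k$site_group, k$stage, k$fu_year, kind)
      ids <- sub$case_id[sub$site_group == k$site_group &
                           sub$stage == k$stage &
                           (kind != "lost" | sub$fu_year == k$fu_year)]
      if (hit$level != "primary") {
        note_fallback(k$site_group, k$stage, k$fu_year, hit$level, length(ids))
      }
      d <- hit$dist
      tibble::tibble(
        case_id = rep(ids, each = nrow(d)),
        provenance = provenance,
        cause_major = rep(d$cause_major, times = length(ids)),
        cause_detail = rep(d$cause_detail, times = length(ids)),
        weight = rep(d$prop, times = length(ids))
      )
    })
    dplyr::bind_rows(out)
  }

  lost_w <- expand_group(cohort[cohort$vital_status == "lost", ], "lost")
  alive_w <- expand_group(cohort[cohort$vital_status == "alive", ], "alive")
  weights <- dplyr::bind_rows(observed_w, lost_w, alive_w)

  if (config$mode == "sampled") {
    if (!is.null(config$seed)) set.seed(config$seed)
    weights <- weights |>
      dplyr::group_by(case_id) |>
      dplyr::slice_sample(n = 1, weight_by = weight) |>
      dplyr::ungroup() |>
      dplyr::mutate(weight = 1)
  }

  provenance_summary <- cohort |>
    dplyr::select(case_id, stage) |>
    dplyr::left_join(dplyr::distinct(weights, case_id, provenance),
                     by = "case_id") |>
    dplyr::count(stage, provenance, name = "n_cases") |>
    dplyr::group_by(stage) |>
    dplyr::mutate(fraction = n_cases / sum(n_cases)) |>
    dplyr::ungroup()

  structure(
    list(
      weights = weights,
      provenance_summary = provenance_summary,
      fallback_log = if (length(log_rows)) dplyr::bind_rows(log_rows) else
        tibble::tibble(site_group = character(0), stage = character(0),
                       fu_year = integer(0), level = character(0),
                       n_cases = integer(0)),
      config = config
    ),
    class = "pm_allocation"
  )
}

#' @export
print.pm_allocation <- function(x, ...) {
  n_cases <- length(unique(x$weights$case_id))
  cat("<pm_allocation>", n_cases, "cases;",
      nrow(x$fallback_log), "fallback lookups\n")
  print(x$provenance_summary)
  invisible(x)
}
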