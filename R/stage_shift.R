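#' Specify a stage-shift counterfactual scenario
#'
#' A scenario redistributes the stage at diagnosis of some cases and asks
#' how many index-cancer deaths would be expected if the shifted cases
#' experienced the cause-of-death mix of their target stage. `shifts` maps
#' each source stage to a probability vector over target stages, e.g.
#' `list(IV = c(III = 1))` or `list(IV = c(I = 1/3, II = 1/3, III = 1/3))`.
#' Cases with unknown/missing stage are never redistributed (their index
#' deaths stay in the percent-reduction denominator).
#'
#' @param name Scenario name.
#' @param shifts Named list: source stage -> named numeric vector of
#'   target-stage probabilities summing to 1.
#' @param scope Optional character vector of site groups the scenario runs
#'   over; defaults to all mutually exclusive (parent) rows in the table
#'   it is applied to.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, shifts, scope = NULL) {
  known <- setdiff(pm_stages(), "Unknown")
  for (s in names(shifts)) {
    if (!s %in% known) {
      stop("source stage must be a known stage (unknown-stage cases are never redistributed): ",
           s, call. = FALSE)
    }
    w <- shifts[[s]]
    if (!all(names(w) %in% known)) {
      stop("target stages must be known stages in scenario ", name, call. = FALSE)
    }
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      stop("target probabilities for stage ", s, " must be nonnegative and sum to 1",
           call. = FALSE)
    }
  }
  structure(list(name = name, shifts = shifts, scope = scope),
            class = "scenario_spec")
}

#' The three built-in stage-shift scenarios
#'
#' The two screening scenarios of the source analysis -- all stage IV
#' cancers detected at stage III, and stage IV cancers distributed equally
#' among stages I, II, and III -- plus the perfect-screening bound in
#' which every stage II--IV cancer is detected at stage I.
#'
#' @return A named list of three [scenario_spec()] objects:
#'   `shift_IV_to_III`, `shift_IV_to_I_II_III_equal`, `shift_all_to_I`.
#' @export
builtin_scenarios <- function() {
  list(
    shift_IV_to_III = scenario_spec(
      "shift_IV_to_III", list(IV = c(III = 1))
    ),
    shift_IV_to_I_II_III_equal = scenario_spec(
      "shift_IV_to_I_II_III_equal",
      list(IV = c(I = 1 / 3, II = 1 / 3, III = 1 / 3))
    ),
    shift_all_to_I = scenario_spec(
      "shift_all_to_I",
      list(II = c(I = 1), III = c(I = 1), IV = c(I = 1))
    )
  )
}

#' Run a stage-shift scenario on a mortality table
#'
#' For each site group g and source stage s with N total allocated deaths
#' (= total cases, since every case is followed to death by observation or
#' extrapolation) and D baseline index deaths, the counterfactual expected
#' index deaths are N x sum_t w(s -> t) p_index(g, t), where p_index(g, t)
#' is the index-death proportion of the target stage in the same table,
#' computed from unrounded counts. Deaths averted are D minus the
#' counterfactual, summed over the scope; the computation is run per site
#' group and summed, never on the pooled All-Types row (the two differ by
#' a Simpson-type effect, and the per-type sum is the published
#' definition). Counterfactual non-index-cancer and non-cancer death
#' expectations are recomputed from the target-stage proportions and
#' reported alongside.
#'
#' @param table A major-cause `mortality_table` (e.g. [tabulate_major()]
#'   output or [table2_fixture()]).
#' @param spec A [scenario_spec()].
#' @param denominator `"all_index_deaths"` (all stages including
#'   unknown/missing, the default, which reproduces the published percent
#'   reductions) or `"known_stage"`.
#' @param on_empty_target What to do when a target stage cell has no cases
#'   for some site group: `"error"` (the default; the published analysis
#'   never hits this on its full-scale table) or `"pooled_stages"` (use
#'   the site group's cause proportions pooled over known stages, logged
#'   in the result -- useful on small synthetic cohorts).
#' @return An object of class `scenario_result`: a list with `per_type`
#'   (per site group: baseline, counterfactual, averted index deaths and
#'   counterfactual non-index/non-cancer expectations), `total_averted`,
#'   `total_index_deaths`, `percent_reduction`, and
#'   `percent_reduction_rounded`.
#' @export
run_scenario <- function(table, spec,
                         denominator = c("all_index_deaths", "known_stage"),
                         on_empty_target = c("error", "pooled_stages")) {
  denominator <- match.arg(denominator)
  on_empty_target <- match.arg(on_empty_target)
  empty_targets <- list()
  scope <- spec$scope
  if (is.null(scope)) {
    # published definition: the mutually exclusive per-type rows, never the
    # pooled All-Types row or the overlapping subtype rows
    scope <- unique(table$site_group[table$row_type == "parent"])
  }
  tab <- tibble::as_tibble(table)[table$site_group %in% scope, ]
  cells <- tab |>
    dplyr::group_by(site_group, stage) |>
    dplyr::summarise(total = sum(count), .groups = "drop")
  wide <- tab |>
    dplyr::select(site_group, stage, cause, count) |>
    tidyr::pivot_wider(names_from = cause, values_from = count,
                       values_fill = 0) |>
    dplyr::left_join(cells, by = c("site_group", "stage"))
  for (col in c("index", "non_index_cancer", "non_cancer")) {
    if (!col %in% names(wide)) wide[[col]] <- 0
  }
  p_of <- function(g, t, cause) {
    row <- wide[wide$site_group == g & wide$stage == t, ]
    if (nrow(row) == 0 || row$total == 0) {
      if (on_empty_target == "pooled_stages") {
        pooled <- wide[wide$site_group == g &
                         wide$stage %in% c("I", "II", "III", "IV"), ]
        if (nrow(pooled) > 0 && sum(pooled$total) > 0) {
          empty_targets[[paste(g, t)]] <<- tibble::tibble(site_group = g, stage = t)
          return(sum(pooled[[cause]]) / sum(pooled$total))
        }
      }
      stop("scenario ", spec$name, ": target cell (", g, ", stage ", t,
           ") has no cases and no fallback applies", call. = FALSE)
    }
    row[[cause]] / row$total
  }
  per_type <- lapply(unique(wide$site_group), function(g) {
    base_index <- cf_index <- cf_non_index <- cf_non_cancer <- 0
    for (s in names(spec$shifts)) {
      row <- wide[wide$site_group == g & wide$stage == s, ]
      if (nrow(row) == 0 || row$total == 0) next  # nothing to shift
      w <- spec$shifts[[s]]
      base_index <- base_index + row$index
      cf_index <- cf_index +
        row$total * sum(w * vapply(names(w), p_of, numeric(1), g = g, cause = "index"))
      cf_non_index <- cf_non_index +
        row$total * sum(w * vapply(names(w), p_of, numeric(1), g = g, cause = "non_index_cancer"))
      cf_non_cancer <- cf_non_cancer +
        row$total * sum(w * vapply(names(w), p_of, numeric(1), g = g, cause = "non_cancer"))
    }
    tibble::tibble(
      site_group = g,
      baseline_index = base_index,
      counterfactual_index = cf_index,
      averted = base_index - cf_index,
      counterfactual_non_index = cf_non_index,
      counterfactual_non_cancer = cf_non_cancer
    )
  }) |> dplyr::bind_rows()
  denom_stages <- if (denominator == "known_stage") c("I", "II", "III", "IV") else pm_stages()
  total_index <- sum(wide$index[wide$stage %in% denom_stages])
  total_averted <- sum(per_type$averted)
  pct <- 100 * total_averted / total_index
  structure(
    list(
      name = spec$name,
      per_type = per_type,
      total_averted = total_averted,
      total_index_deaths = total_index,
      denominator = denominator,
      empty_target_fallbacks = dplyr::bind_rows(empty_targets),
      percent_reduction = pct,
      percent_reduction_rounded = round_half_up(pct)
    ),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>", x$name, "\n")
  cat(sprintf("  deaths averted: %.0f of %.0f index deaths (%.1f%%, rounds to %d%%)\n",
              x$total_averted, x$total_index_deaths, x$percent_reduction,
              as.integer(x$percent_reduction_rounded)))
  invisible(x)
}
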