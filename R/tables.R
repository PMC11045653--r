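#' Tabulate major causes of death by cancer type and stage
#'
#' Aggregates allocation weights into the central proportional-mortality
#' table: allocated death counts (real-valued before rounding) and
#' within-cell percentages of index cancer / non-index cancer / non-cancer
#' deaths for every (site group x stage) cell. Parent rows (e.g. "Breast,
#' All") are always reported; subtype rows (breast HR status, lung
#' small/non-small cell) are reported in addition when the cohort carries
#' subtype-level site groups, and are excluded from the "All Types"
#' aggregate to avoid double counting. Percentages are computed from
#' unrounded counts; displayed percentages are rounded half-up and may not
#' sum to 100 within a row.
#'
#' @param allocations A `pm_allocation` from [allocate_cohort()].
#' @param cases The cohort the allocation was computed from (one
#'   allocation per case; anything else is a contract error).
#' @return A tidy `mortality_table` tibble: `site_group`, `row_type`
#'   (`parent`/`subtype`/`all_types`), `stage`, `cause`, `count`, `pct`,
#'   `pct_rounded`.
#' @export
tabulate_major <- function(allocations, cases) {
  w <- check_alloc_cases(allocations, cases)
  if (nrow(w) == 0) return(new_mortality_table(empty_table(), "major"))
  w$parent <- parent_site(w$site_group)
  parent_rows <- w |>
    dplyr::group_by(site_group = parent, stage, cause = cause_major) |>
    dplyr::summarise(count = sum(weight), .groups = "drop") |>
    dplyr::mutate(row_type = "parent")
  subtype_rows <- w |>
    dplyr::filter(site_group != parent) |>
    dplyr::group_by(site_group, stage, cause = cause_major) |>
    dplyr::summarise(count = sum(weight), .groups = "drop") |>
    dplyr::mutate(row_type = "subtype")
  all_rows <- parent_rows |>
    dplyr::group_by(stage, cause) |>
    dplyr::summarise(count = sum(count), .groups = "drop") |>
    dplyr::mutate(site_group = "All Types", row_type = "all_types")
  out <- dplyr::bind_rows(all_rows, parent_rows, subtype_rows) |>
    add_percentages() |>
    dplyr::select(site_group, row_type, stage, cause, count, pct, pct_rounded)
  new_mortality_table(out, "major")
}

add_percentages <- function(tab) {
  tab |>
    dplyr::group_by(site_group, row_type, stage) |>
    dplyr::mutate(pct = 100 * count / sum(count),
                  pct_rounded = round_half_up(pct)) |>
    dplyr::ungroup()
}

empty_table <- function() {
  tibble::tibble(site_group = character(0), row_type = character(0),
                 stage = character(0), cause = character(0),
                 count = numeric(0), pct = numeric(0), pct_rounded = numeric(0))
}

new_mortality_table <- function(tab, resolution, stratifier = NULL) {
  structure(tab, class = c("mortality_table", class(tab)),
            resolution = resolution, stratifier = stratifier)
}

check_alloc_cases <- function(allocations, cases) {
  if (!inherits(allocations, "pm_allocation")) {
    stop("allocations must come from allocate_cohort()", call. = FALSE)
  }
  w <- allocations$weights
  if (!setequal(unique(w$case_id), cases$case_id)) {
    stop("allocations and cases do not describe the same cohort", call. = FALSE)
  }
  dplyr::left_join(
    w, dplyr::select(cases, case_id, site_group, stage,
                     dplyr::any_of(c("age_group", "sex", "race_ethnicity"))),
    by = "case_id"
  )
}

#' Tabulate detailed causes within one major category
#'
#' Restricts the allocation to non-index-cancer deaths (detail = the
#' non-index cancer site) or non-cancer deaths (detail = the grouped
#' non-cancer cause) and tabulates within-stage percentages across the
#' detailed causes. Causes are ordered by their frequency at stage I for
#' the All Types row, the display convention of the detailed-cause
#' figures.
#'
#' @inheritParams tabulate_major
#' @param major `"non_index_cancer"` or `"non_cancer"`.
#' @return A tidy `mortality_table` with `cause` at detail resolution;
#'   percentages are within the chosen major category.
#' @export
tabulate_detail <- function(allocations, cases,
                            major = c("non_index_cancer", "non_cancer")) {
  major <- match.arg(major)
  w <- check_alloc_cases(allocations, cases)
  w <- w[w$cause_major == major, ]
  if (nrow(w) == 0) return(new_mortality_table(empty_table(), major))
  w$parent <- parent_site(w$site_group)
  parent_rows <- w |>
    dplyr::group_by(site_group = parent, stage, cause = cause_detail) |>
    dplyr::summarise(count = sum(weight), .groups = "drop") |>
    dplyr::mutate(row_type = "parent")
  all_rows <- parent_rows |>
    dplyr::group_by(stage, cause) |>
    dplyr::summarise(count = sum(count), .groups = "drop") |>
    dplyr::mutate(site_group = "All Types", row_type = "all_types")
  out <- dplyr::bind_rows(all_rows, parent_rows) |> add_percentages()
  lead <- all_rows[all_rows$stage == "I", ]
  cause_order <- lead$cause[order(-lead$count)]
  cause_order <- c(cause_order, setdiff(unique(out$cause), cause_order))
  out <- out |>
    dplyr::mutate(cause = factor(cause, levels = cause_order)) |>
    dplyr::arrange(site_group, stage, cause) |>
    dplyr::mutate(cause = as.character(cause)) |>
    dplyr::select(site_group, row_type, stage, cause, count, pct, pct_rounded)
  new_mortality_table(out, major)
}

#' Tabulate major causes stratified by a demographic factor
#'
#' Produces one major-cause table per level of `age_group`, `sex`, or
#' `race_ethnicity`. The sex-stratified mode can exclude breast cancer and
#' sex-specific genital sites (cervix, ovary, uterus, prostate), the
#' convention for comparing men and women on a common site list.
#'
#' @inheritParams tabulate_major
#' @param stratifier One of `"age_group"`, `"sex"`, `"race_ethnicity"`.
#' @param exclude_sex_specific Drop breast and sex-specific sites
#'   (defaults to `TRUE` for the sex stratifier).
#' @return A tidy `mortality_table` with a leading `stratum_level` column.
#' @export
tabulate_stratified <- function(allocations, cases,
                                stratifier = c("age_group", "sex",
                                               "race_ethnicity"),
                                exclude_sex_specific = NULL) {
  if (length(stratifier) == 1 &&
      !stratifier %in% c("age_group", "sex", "race_ethnicity")) {
    stop("unknown stratifier: ", stratifier, call. = FALSE)
  }
  stratifier <- match.arg(stratifier)
  if (is.null(exclude_sex_specific)) exclude_sex_specific <- stratifier == "sex"
  if (!stratifier %in% names(cases)) {
    stop("stratifier column absent from cases: ", stratifier, call. = FALSE)
  }
  use <- cases
  if (exclude_sex_specific) {
    drop_parents <- c("Breast, All", "Cervix", "Ovary", "Uterus", "Prostate")
    use <- use[!parent_site(use$site_group) %in% drop_parents, ]
  }
  levels <- sort(unique(use[[stratifier]]))
  out <- dplyr::bind_rows(lapply(levels, function(lv) {
    sub <- use[use[[stratifier]] == lv, ]
    sub_w <- allocations$weights[allocations$weights$case_id %in% sub$case_id, ]
    sub_alloc <- structure(list(weights = sub_w), class = "pm_allocation")
    tab <- tabulate_major(sub_alloc, sub)
    dplyr::mutate(tab, stratum_level = lv, .before = 1)
  }))
  new_mortality_table(out, "major", stratifier = stratifier)
}

#' Stage distribution of index-cancer deaths
#'
#' Among allocated index-cancer deaths with known stage at diagnosis
#' (stages I--IV; unknown/missing stage is excluded), the percentage
#' diagnosed at each stage. Uses the "All Types" rows when present,
#' otherwise aggregates the parent rows.
#'
#' @param table A major-cause `mortality_table`.
#' @return A tibble `stage`, `count`, `pct`, `pct_rounded`.
#' @export
summarize_stage_of_index_deaths <- function(table) {
  rows <- if (any(table$row_type == "all_types")) {
    table[table$row_type == "all_types", ]
  } else {
    table[table$row_type == "parent", ] |>
      dplyr::group_by(stage, cause) |>
      dplyr::summarise(count = sum(count), .groups = "drop")
  }
  idx <- rows[rows$cause == "index" & rows$stage %in% c("I", "II", "III", "IV"), ]
  idx |>
    dplyr::group_by(stage) |>
    dplyr::summarise(count = sum(count), .groups = "drop") |>
    dplyr::mutate(pct = 100 * count / sum(count),
                  pct_rounded = round_half_up(pct)) |>
    dplyr::arrange(match(stage, pm_stages()))
}

#' Pool stages within a mortality table
#'
#' Re-aggregates counts over a set of stages (default I--II, the
#' early-stage pooling used for headline summaries such as "X% of deaths
#' after stage I--II cancer were due to the index cancer") and recomputes
#' within-row percentages from the pooled unrounded counts.
#'
#' @param table A `mortality_table`.
#' @param stages Stages to pool (default `c("I", "II")`).
#' @return A tibble `site_group`, `row_type`, `cause`, `count`, `pct`,
#'   `pct_rounded` for the pooled stage set.
#' @export
pool_stages <- function(table, stages = c("I", "II")) {
  table[table$stage %in% stages, ] |>
    dplyr::group_by(site_group, row_type, cause) |>
    dplyr::summarise(count = sum(count), .groups = "drop") |>
    dplyr::group_by(site_group, row_type) |>
    dplyr::mutate(pct = 100 * count / sum(count),
                  pct_rounded = round_half_up(pct)) |>
    dplyr::ungroup()
}

#' Render and write mortality tables
#'
#' `format_mortality_table()` pivots a tidy major-cause table into the
#' familiar wide layout (one row per site group x stage, count and rounded
#' percentage per cause). `write_mortality_table()` writes the tidy form
#' as CSV.
#'
#' @param table A `mortality_table`.
#' @return A wide tibble (format) or the path invisibly (write).
#' @export
format_mortality_table <- function(table) {
  tibble::as_tibble(table) |>
    dplyr::mutate(count = round_half_up(count)) |>
    dplyr::select(dplyr::any_of("stratum_level"), site_group, row_type, stage,
                  cause, count, pct_rounded) |>
    tidyr::pivot_wider(names_from = cause,
                       values_from = c(count, pct_rounded),
                       values_fill = 0)
}

#' @rdname format_mortality_table
#' @param path Output CSV path.
#' @export
write_mortality_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}
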