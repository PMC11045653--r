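#' Packaged reference tables from the published registry analysis
#'
#' The package ships transcriptions of the two summary tables of the
#' published SEER 17 proportional-mortality analysis (first primary
#' cancers, ages 50--84 at diagnosis in 2006--2010, followed through
#' 2020): the cohort-characteristics table (counts by stage for vital
#' status, age, sex, race/ethnicity, observed follow-up duration, and
#' index cancer type; cohort size 1,154,515) and the stage-specific
#' cause-of-death distribution (allocated index / non-index / non-cancer
#' death counts by index cancer type and stage). Transcription integrity
#' is verified by row-sum identities in the test suite: every
#' characteristic's stage columns sum to the same stage totals, and the
#' cause-table row totals match the characteristics table.
#'
#' A transcription note: the published "All Types" rows of the cause table
#' are not exactly the sums of the per-type rows (the source analysis
#' evidently extrapolated the pooled stratum directly), so the fixture
#' keeps both as printed; summaries use the All Types rows, scenario
#' calculations use the per-type rows.
#'
#' @return `table1_fixture()`: a tibble `characteristic`, `level`, `stage`,
#'   `n`, `pct_printed`. `table2_fixture()`: a tidy major-cause
#'   `mortality_table` with `count` as transcribed, recomputed `pct` /
#'   `pct_rounded`, and the printed percentage in `pct_printed`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_characteristics.csv",
                      package = "propmort")
  readr::read_csv(path, col_types = readr::cols(
    characteristic = readr::col_character(),
    level = readr::col_character(),
    stage = readr::col_character(),
    n = readr::col_double(),
    pct_printed = readr::col_double()
  ))
}

#' @rdname table1_fixture
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_cause_distribution.csv",
                      package = "propmort")
  wide <- readr::read_csv(path, col_types = readr::cols(
    site_group = readr::col_character(),
    row_type = readr::col_character(),
    stage = readr::col_character(),
    .default = readr::col_double()
  ))
  long <- wide |>
    tidyr::pivot_longer(
      cols = -c(site_group, row_type, stage),
      names_to = c("cause", ".value"),
      names_pattern = "(index|non_index|non_cancer)_(n|pct)"
    ) |>
    dplyr::mutate(cause = dplyr::recode(cause, non_index = "non_index_cancer"),
                  count = n, pct_printed = pct) |>
    dplyr::select(site_group, row_type, stage, cause, count, pct_printed) |>
    add_percentages() |>
    dplyr::select(site_group, row_type, stage, cause, count, pct, pct_rounded,
                  pct_printed)
  new_mortality_table(long, "major")
}

#' Cohort-level summaries from the characteristics table
#'
#' `cohort_size()` returns the total number of cases (alive + dead over
#' all stages). `survivor_fractions()` returns the percentage of cases
#' still alive at the end of observed follow-up, by stage and for the
#' pooled early stages I--II -- the quantities that motivate extrapolation
#' (roughly 60% alive after stage I--II, 32% after stage III, 9% after
#' stage IV).
#'
#' @param table1 A tibble from [table1_fixture()] (or same schema).
#' @return `cohort_size()`: a single number. `survivor_fractions()`: a
#'   tibble `stage`, `n_alive`, `n_total`, `pct`, `pct_rounded` including
#'   a pooled `"I-II"` row.
#' @export
cohort_size <- function(table1 = table1_fixture()) {
  vs <- table1[table1$characteristic == "vital_status", ]
  sum(vs$n)
}

#' @rdname cohort_size
#' @export
survivor_fractions <- function(table1 = table1_fixture()) {
  vs <- table1[table1$characteristic == "vital_status", ] |>
    tidyr::pivot_wider(id_cols = stage, names_from = level, values_from = n)
  pooled <- tibble::tibble(
    stage = "I-II",
    Alive = sum(vs$Alive[vs$stage %in% c("I", "II")]),
    Dead = sum(vs$Dead[vs$stage %in% c("I", "II")])
  )
  dplyr::bind_rows(vs, pooled) |>
    dplyr::transmute(stage, n_alive = Alive, n_total = Alive + Dead,
                     pct = 100 * n_alive / n_total,
                     pct_rounded = round_half_up(pct))
}
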