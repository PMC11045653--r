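#' Read and validate a registry case listing
#'
#' Reads a case-listing CSV with one row per first primary cancer case and
#' validates every field against the closed vocabularies. The schema is the
#' one written by [write_case_listing()]: `case_id`, `site_group`, `stage`,
#' `age_group`, `sex`, `race_ethnicity`, `dx_year`, `followup_months`,
#' `vital_status`, `cod_code`. Optional columns (`er_status`, `pr_status`,
#' `morphology`) are passed through for [assign_subtype()].
#'
#' Validation enforces the cohort contract: ages 50--84 at diagnosis (the
#' analysis excludes younger cases because of their heavy censoring), a
#' known stage label (with "Unknown" legal), non-negative follow-up, and a
#' detailed cause-of-death code present if and only if the case is dead.
#' Malformed rows are reported with their row numbers.
#'
#' @param path Path to the case-listing CSV.
#' @param vocabulary Cause vocabulary tibble, see [cause_vocabulary()].
#' @return A validated tibble of case records.
#' @export
read_case_listing <- function(path, vocabulary = cause_vocabulary()) {
  if (!file.exists(path)) stop("case listing not found: ", path, call. = FALSE)
  required <- c(
    "case_id", "site_group", "stage", "age_group", "sex", "race_ethnicity",
    "dx_year", "followup_months", "vital_status", "cod_code"
  )
  cases <- readr::read_csv(
    path,
    col_types = readr::cols(
      case_id = readr::col_character(),
      cod_code = readr::col_character(),
      dx_year = readr::col_integer(),
      followup_months = readr::col_integer(),
      .default = readr::col_character()
    ),
    locale = readr::locale(encoding = "UTF-8")
  )
  missing_cols <- setdiff(required, names(cases))
  if (length(missing_cols) > 0) {
    stop("case listing is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_case_records(cases, vocabulary)
  cases
}

# shared record validation; `cases` may come from file or the simulator
validate_case_records <- function(cases, vocabulary = cause_vocabulary()) {
  issues <- character(0)
  flag <- function(bad, what) {
    if (any(bad)) {
      rows <- which(bad)
      shown <- utils::head(rows, 5)
      issues <<- c(issues, sprintf(
        "%s (%d row(s), e.g. row %s)", what, length(rows),
        paste(shown, collapse = ", ")
      ))
    }
  }
  flag(!cases$stage %in% pm_stages(),
       sprintf("stage not one of {%s}", paste(pm_stages(), collapse = ", ")))
  flag(!cases$age_group %in% pm_age_groups(),
       "age_group outside the 50-84 diagnosis-age bands (younger cases are excluded from the cohort)")
  flag(!cases$vital_status %in% pm_vital_statuses(),
       sprintf("vital_status not one of {%s}", paste(pm_vital_statuses(), collapse = ", ")))
  flag(!cases$site_group %in% site_groups()$site_group, "unknown site_group")
  flag(is.na(cases$followup_months) | cases$followup_months < 0,
       "followup_months missing or negative")
  dead <- cases$vital_status == "dead"
  no_cod <- is.na(cases$cod_code) | cases$cod_code == ""
  flag(dead & no_cod, "vital_status 'dead' but cod_code empty")
  flag(!dead & !no_cod, "cod_code present for a non-death")
  flag(dead & !no_cod & !cases$cod_code %in% vocabulary$code,
       "cod_code outside the cause vocabulary")
  if (length(issues) > 0) {
    stop("invalid case records:\n  - ", paste(issues, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(cases)
}

#' Apply cohort eligibility rules
#'
#' Removes cases known to be dead but with a missing or unknown cause of
#' death (`cod_code == "cod_unknown"`), the only post-validation exclusion
#' in the analysis, and reports the excluded fraction. In the source
#' registry draw this exclusion removed 0.8% of cases.
#'
#' @param cases Validated case records from [read_case_listing()].
#' @return A list with `eligible` (the retained cases) and `exclusion_log`
#'   (a one-row tibble: `n_input`, `n_excluded`, `fraction_excluded`).
#' @export
apply_eligibility <- function(cases) {
  excl <- cases$vital_status == "dead" &
    !is.na(cases$cod_code) & cases$cod_code == "cod_unknown"
  eligible <- cases[!excl, , drop = FALSE]
  if (nrow(eligible) == 0) {
    warning("all cases excluded: cohort is empty", call. = FALSE)
  }
  list(
    eligible = eligible,
    exclusion_log = tibble::tibble(
      n_input = nrow(cases),
      n_excluded = sum(excl),
      fraction_excluded = ifelse(nrow(cases) > 0, sum(excl) / nrow(cases), 0)
    )
  )
}

#' Classify a death into index / non-index cancer / non-cancer
#'
#' Maps a detailed cause-of-death code, in the context of the case's index
#' site group, onto the three-way major classification plus a detailed
#' subtype: a cancer cause at the same anatomic site as the index cancer is
#' an index-cancer death (subtype groups match at the parent-site level, so
#' a lung-cancer death after "Lung, Small-Cell" is an index death); a
#' cancer cause at any other site is a non-index-cancer death with that
#' site as the detail; a non-cancer cause is grouped via
#' [group_noncancer()]. Same-site second primaries do not occur as a
#' registry convention, so the site match is unambiguous.
#'
#' @param cod_code Character vector of detailed cause codes (deaths only).
#' @param site_group Character vector of index site-group labels, recycled
#'   against `cod_code`.
#' @param vocabulary Cause vocabulary tibble.
#' @return A tibble with columns `cause_major` (one of `"index"`,
#'   `"non_index_cancer"`, `"non_cancer"`) and `cause_detail` (`NA` for
#'   index deaths).
#' @export
#' @examples
#' classify_cause("ca_lung", "Prostate")      # non-index cancer, lung
#' classify_cause("ca_breast", "Breast, All") # index
#' classify_cause("nc_heart", "Colon/Rectum") # non-cancer, heart disease
classify_cause <- function(cod_code, site_group, vocabulary = cause_vocabulary()) {
  if (length(site_group) == 1) site_group <- rep(site_group, length(cod_code))
  stopifnot(length(cod_code) == length(site_group))
  if (anyNA(cod_code)) {
    stop("classify_cause() requires an observed cause of death; cod_code is missing",
         call. = FALSE)
  }
  i <- match(cod_code, vocabulary$code)
  if (anyNA(i)) {
    stop("cod_code outside the cause vocabulary: ",
         paste(unique(cod_code[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  if (any(cod_code == "cod_unknown")) {
    stop("unknown-cause deaths must be removed by apply_eligibility() before classification",
         call. = FALSE)
  }
  is_cancer <- vocabulary$is_cancer[i]
  cod_site <- vocabulary$site_group[i]
  parent <- parent_site(site_group)
  major <- ifelse(!is_cancer, "non_cancer",
                  ifelse(cod_site == parent, "index", "non_index_cancer"))
  detail <- rep(NA_character_, length(cod_code))
  nc <- which(major == "non_cancer")
  if (length(nc) > 0) detail[nc] <- group_noncancer(cod_code[nc])
  ni <- which(major == "non_index_cancer")
  if (length(ni) > 0) detail[ni] <- cod_site[ni]
  tibble::tibble(cause_major = major, cause_detail = detail)
}

#' Classify all deaths in a cohort and derive follow-up years
#'
#' Convenience wrapper that attaches `cause_major`/`cause_detail` (for
#' deaths; `NA` otherwise) and the follow-up year `fu_year` to every case.
#' Follow-up year k covers months 12(k-1) < m <= 12k, with month 0 assigned
#' to year 1, mirroring the 0--12 / 13--24 month reporting bins.
#'
#' @param cases Eligible case records.
#' @param vocabulary Cause vocabulary tibble.
#' @return The input tibble with `cause_major`, `cause_detail`, and
#'   `fu_year` columns appended.
#' @export
classify_cohort <- function(cases, vocabulary = cause_vocabulary()) {
  cases$cause_major <- NA_character_
  cases$cause_detail <- NA_character_
  dead <- cases$vital_status == "dead"
  if (any(dead)) {
    cls <- classify_cause(cases$cod_code[dead], cases$site_group[dead], vocabulary)
    cases$cause_major[dead] <- cls$cause_major
    cases$cause_detail[dead] <- cls$cause_detail
  }
  cases$fu_year <- followup_year(cases$followup_months)
  cases
}

# month -> follow-up year; month 0 belongs to year 1
followup_year <- function(months) pmax(1L, as.integer(ceiling(months / 12)))

#' Subtype rules for breast and lung index cancers
#'
#' Breast cancers are refined by hormone-receptor (HR) status from raw
#' estrogen- and progesterone-receptor fields: HR-positive if either
#' receptor is positive, HR-negative if both are negative, HR-unknown
#' otherwise (the conventional HR definition). Lung cancers are refined to
#' small-cell vs non-small-cell by ICD-O-3 morphology code; the small-cell
#' set (8041--8045) is a documented placeholder and can be replaced.
#'
#' @param small_cell_morphology Integer vector of ICD-O-3 morphology codes
#'   treated as small-cell carcinoma.
#' @return A list with the rule components, for [assign_subtype()].
#' @export
subtype_rules <- function(small_cell_morphology = 8041:8045) {
  list(small_cell_morphology = as.integer(small_cell_morphology))
}

#' Refine breast and lung cases into subtype site groups
#'
#' Applies [subtype_rules()] to cases whose parent site is breast or lung,
#' returning the refined `site_group` while keeping the parent label in a
#' `parent_site` column so tabulations can report both the parent row
#' ("Breast, All") and the subtype rows. Calling this on any other site is
#' a contract error. Breast cases need `er_status`/`pr_status` columns
#' (values `"positive"`/`"negative"`/anything else = unknown); lung cases
#' need a numeric `morphology` column.
#'
#' @param cases Case records restricted to breast and/or lung parents.
#' @param rule Subtype rule list from [subtype_rules()].
#' @return `cases` with `site_group` refined and `parent_site` added.
#' @export
assign_subtype <- function(cases, rule = subtype_rules()) {
  parent <- parent_site(cases$site_group)
  if (!all(parent %in% c("Breast, All", "Lung, All"))) {
    stop("assign_subtype() applies only to breast and lung cases", call. = FALSE)
  }
  breast <- parent == "Breast, All"
  lung <- parent == "Lung, All"
  out <- cases
  if (any(breast)) {
    if (!all(c("er_status", "pr_status") %in% names(cases))) {
      stop("breast cases need er_status and pr_status columns", call. = FALSE)
    }
    er <- tolower(cases$er_status[breast])
    pr <- tolower(cases$pr_status[breast])
    hr <- ifelse(er == "positive" | pr == "positive", "Breast, HR-positive",
          ifelse(er == "negative" & pr == "negative", "Breast, HR-negative",
                 "Breast, HR-unknown"))
    out$site_group[breast] <- hr
  }
  if (any(lung)) {
    if (!"morphology" %in% names(cases)) {
      stop("lung cases need a morphology column", call. = FALSE)
    }
    morph <- as.integer(cases$morphology[lung])
    out$site_group[lung] <- ifelse(
      morph %in% rule$small_cell_morphology, "Lung, Small-Cell",
      "Lung, Non-Small-Cell"
    )
  }
  out$parent_site <- parent
  out
}
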