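#' Closed vocabularies: stages, site groups, and causes of death
#'
#' The analysis runs over closed vocabularies so that classification and
#' tabulation cannot silently invent categories. Stages follow AJCC 6th
#' edition groupings I--IV plus a combined "Unknown" level, which is a
#' legal value in its own right: brain/other nervous system cancer,
#' myeloma, and leukemia lack AJCC 6th edition staging criteria and are
#' always carried there.
#'
#' @return `pm_stages()` and `pm_age_groups()` return character vectors of
#'   legal levels, in display order.
#' @export
pm_stages <- function() c("I", "II", "III", "IV", "Unknown")

#' @rdname pm_stages
#' @export
pm_age_groups <- function() {
  lo <- seq(50, 80, by = 5)
  paste0(lo, "-", lo + 4)
}

#' @rdname pm_stages
#' @export
pm_sexes <- function() c("Male", "Female")

#' @rdname pm_stages
#' @export
pm_vital_statuses <- function() c("dead", "alive", "lost")

#' Index cancer site groups
#'
#' Returns the table of legal index-cancer site groups: the mutually
#' exclusive parent groups (including "Other Types", a real group rather
#' than a downstream residual) plus refined subtype groups for breast
#' (hormone-receptor status) and lung (small-cell vs non-small-cell
#' histology). Subtype groups map to a parent group; deaths are matched to
#' the index cancer at the parent level, so a lung-cancer death after an
#' index "Lung, Small-Cell" cancer is an index-cancer death.
#'
#' @return A tibble with columns `site_group`, `parent`, `subtype`
#'   (logical), and `cancer_code` (the cause-of-death code whose site
#'   matches the group).
#' @export
site_groups <- function() {
  parents <- c(
    "Bladder", "Breast, All", "Brain/Other Nervous System", "Cervix",
    "Colon/Rectum", "Esophagus", "Kidney", "Larynx", "Leukemia",
    "Liver/Intrahepatic Bile Duct", "Lung, All", "Lymphoma", "Melanoma",
    "Myeloma", "Oral Cavity/Pharynx", "Ovary", "Pancreas", "Prostate",
    "Stomach", "Thyroid", "Uterus", "Other Types"
  )
  codes <- c(
    "ca_bladder", "ca_breast", "ca_brain", "ca_cervix", "ca_colorectal",
    "ca_esophagus", "ca_kidney", "ca_larynx", "ca_leukemia", "ca_liver",
    "ca_lung", "ca_lymphoma", "ca_melanoma", "ca_myeloma", "ca_oral",
    "ca_ovary", "ca_pancreas", "ca_prostate", "ca_stomach", "ca_thyroid",
    "ca_uterus", "ca_other"
  )
  sub <- tibble::tibble(
    site_group = c(
      "Breast, HR-positive", "Breast, HR-negative", "Breast, HR-unknown",
      "Lung, Non-Small-Cell", "Lung, Small-Cell"
    ),
    parent = c(rep("Breast, All", 3), rep("Lung, All", 2))
  )
  out <- tibble::tibble(
    site_group = c(parents, sub$site_group),
    parent = c(parents, sub$parent),
    subtype = c(rep(FALSE, length(parents)), rep(TRUE, nrow(sub)))
  )
  out$cancer_code <- codes[match(out$parent, parents)]
  out
}

#' @rdname site_groups
#' @param x Character vector of site-group labels.
#' @return `parent_site()` returns the parent-level label for each input
#'   (identity for parent groups); `mutually_exclusive_sites()` returns the
#'   parent groups only.
#' @export
parent_site <- function(x) {
  sg <- site_groups()
  i <- match(x, sg$site_group)
  if (anyNA(i)) {
    stop("unknown site_group label(s): ",
         paste(unique(x[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  sg$parent[i]
}

#' @rdname site_groups
#' @export
mutually_exclusive_sites <- function() {
  sg <- site_groups()
  sg$site_group[!sg$subtype]
}

#' Cause-of-death vocabulary
#'
#' Reads the packaged mapping of detailed cause-of-death codes: each code
#' carries a human-readable label, a cancer flag, and, for cancer causes,
#' the index site group whose deaths it represents. The 26 standard
#' registry non-cancer causes are enumerated, plus a `cod_unknown` code for
#' deaths whose certificate cause is missing (these cases are removed by
#' [apply_eligibility()]). Registry dialects with different raw codes can
#' be mapped in by supplying an alternative file with the same columns.
#'
#' @param path Optional path to an alternative vocabulary CSV with columns
#'   `code`, `label`, `is_cancer`, `site_group`.
#' @return A tibble with one row per detailed cause code.
#' @export
cause_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cause_vocabulary.csv", package = "propmort")
  }
  vocab <- readr::read_csv(
    path,
    col_types = readr::cols(
      code = readr::col_character(),
      label = readr::col_character(),
      is_cancer = readr::col_logical(),
      site_group = readr::col_character()
    )
  )
  stopifnot(!anyDuplicated(vocab$code))
  vocab
}

#' Group detailed non-cancer causes of death
#'
#' Collapses the 26 standard registry non-cancer causes into the grouped
#' reporting vocabulary: tuberculosis, syphilis, and other
#' infectious/parasitic diseases become "Other Infectious Diseases" (with
#' septicemia kept separate); hypertension without heart disease,
#' atherosclerosis, aortic aneurysm/dissection, and other diseases of
#' arteries/arterioles/capillaries become "Other Circulatory Diseases"
#' (heart disease and cerebrovascular disease kept separate); accidents/
#' adverse effects and homicide/legal intervention become
#' "Accidents/External Causes" (suicide/self-injury kept separate); and
#' seven rare or ill-defined causes are pooled as "Other". All remaining
#' causes pass through under shortened display labels.
#'
#' @param detailed Character vector of detailed non-cancer cause labels, as
#'   in `cause_vocabulary()$label` (codes are also accepted).
#' @return Character vector of grouped cause labels.
#' @export
#' @examples
#' group_noncancer("Tuberculosis")
#' group_noncancer(c("Diseases of Heart", "Atherosclerosis"))
group_noncancer <- function(detailed) {
  map <- noncancer_group_map()
  vocab <- cause_vocabulary()
  # accept codes as well as labels
  is_code <- detailed %in% vocab$code
  detailed[is_code] <- vocab$label[match(detailed[is_code], vocab$code)]
  out <- map[detailed]
  if (anyNA(out)) {
    stop("unknown non-cancer cause(s): ",
         paste(unique(detailed[is.na(out)]), collapse = "; "), call. = FALSE)
  }
  unname(out)
}

# grouped label per detailed label; the closed grouped vocabulary is
# exactly the set of values here
noncancer_group_map <- function() {
  c(
    "Tuberculosis" = "Other Infectious Diseases",
    "Syphilis" = "Other Infectious Diseases",
    "Other Infectious and Parasitic Diseases" = "Other Infectious Diseases",
    "Septicemia" = "Septicemia",
    "Diabetes Mellitus" = "Diabetes",
    "Alzheimer Disease" = "Alzheimer Disease",
    "Diseases of Heart" = "Heart Disease",
    "Hypertension without Heart Disease" = "Other Circulatory Diseases",
    "Cerebrovascular Diseases" = "Cerebrovascular Diseases",
    "Atherosclerosis" = "Other Circulatory Diseases",
    "Aortic Aneurysm and Dissection" = "Other Circulatory Diseases",
    "Other Diseases of Arteries, Arterioles, Capillaries" = "Other Circulatory Diseases",
    "Pneumonia and Influenza" = "Pneumonia and Influenza",
    "Chronic Obstructive Pulmonary Disease" = "COPD",
    "Stomach and Duodenal Ulcers" = "Other",
    "Chronic Liver Disease and Cirrhosis" = "Chronic Liver Disease and Cirrhosis",
    "Nephritis, Nephrotic Syndrome and Nephrosis" = "Nephritis",
    "Complications of Pregnancy, Childbirth, Puerperium" = "Other",
    "Congenital Anomalies" = "Other",
    "Certain Conditions Originating in Perinatal Period" = "Other",
    "Symptoms, Signs and Ill-Defined Conditions" = "Other",
    "Accidents and Adverse Effects" = "Accidents/External Causes",
    "Suicide and Self-Inflicted Injury" = "Suicide/Self-Injury",
    "Homicide and Legal Intervention" = "Accidents/External Causes",
    "In Situ, Benign or Unknown Behavior Neoplasm" = "Other",
    "Other Cause of Death" = "Other"
  )
}

#' @rdname group_noncancer
#' @return `noncancer_groups()` returns the closed vocabulary of grouped
#'   non-cancer cause labels.
#' @export
noncancer_groups <- function() unique(unname(noncancer_group_map()))

# round half up: the display rounding used throughout table rendering;
# base round() is banker's and does not reproduce printed percentages
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
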