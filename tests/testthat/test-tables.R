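small_alloc <- function(cohort) allocate_cohort(classify_cohort(cohort))

test_that("major tabulation matches a hand tally on a small cohort", {
  cases <- dplyr::bind_rows(
    make_cases(3, cod = "ca_colorectal", id_prefix = "i"),
    make_cases(2, cod = "nc_heart", id_prefix = "h"),
    make_cases(1, cod = "ca_lung", id_prefix = "l"),
    make_cases(4, site = "Prostate", stage = "IV", cod = "ca_prostate",
               id_prefix = "p")
  )
  cl <- classify_cohort(cases)
  tab <- tabulate_major(small_alloc(cases), cl)
  cr <- tab[tab$site_group == "Colon/Rectum" & tab$stage == "III", ]
  expect_equal(stats::setNames(cr$count, cr$cause),
               c(index = 3, non_cancer = 2, non_index_cancer = 1))
  expect_equal(cr$pct[cr$cause == "index"], 50)
  pr <- tab[tab$site_group == "Prostate", ]
  expect_equal(pr$count, 4)
  expect_equal(pr$pct, 100)
  at <- tab[tab$row_type == "all_types", ]
  expect_equal(sum(at$count), 10)
  # single observed index death: count 1, 100%
  single <- make_cases(1)
  t1 <- tabulate_major(small_alloc(single), classify_cohort(single))
  expect_equal(t1$count[t1$row_type == "parent"], 1)
  expect_equal(t1$pct[t1$row_type == "parent"], 100)
  # empty cohort gives an empty table; mismatched inputs are contract errors
  expect_error(tabulate_major(small_alloc(cases), cl[1:3, ]),
               "same cohort")
})

test_that("detail tables are consistent with the major marginals", {
  coh <- simulate_cohort(default_cohort_params(n_cases = 2000, seed = 31))
  cl <- classify_cohort(apply_eligibility(coh$cases)$eligible)
  al <- allocate_cohort(cl)
  major <- tabulate_major(al, cl)
  for (m in c("non_index_cancer", "non_cancer")) {
    det <- tabulate_detail(al, cl, m)
    det_sum <- det |>
      dplyr::group_by(site_group, row_type, stage) |>
      dplyr::summarise(count = sum(count), .groups = "drop")
    j <- dplyr::inner_join(
      det_sum,
      major[major$cause == m, c("site_group", "row_type", "stage", "count")],
      by = c("site_group", "row_type", "stage"), suffix = c("_det", "_maj")
    )
    expect_gt(nrow(j), 0)
    expect_equal(j$count_det, j$count_maj)
    # within-stage percentages sum to 100 across detailed causes
    pct_sum <- det |>
      dplyr::group_by(site_group, row_type, stage) |>
      dplyr::summarise(s = sum(pct), .groups = "drop")
    expect_equal(pct_sum$s, rep(100, nrow(pct_sum)))
  }
})

test_that("detail causes are ordered by stage-I frequency", {
  coh <- simulate_cohort(default_cohort_params(n_cases = 3000, seed = 32))
  cl <- classify_cohort(apply_eligibility(coh$cases)$eligible)
  det <- tabulate_detail(allocate_cohort(cl), cl, "non_cancer")
  at1 <- det[det$row_type == "all_types" & det$stage == "I", ]
  expect_equal(at1$count, sort(at1$count, decreasing = TRUE))
})

test_that("all non-cancer deaths from one cause: 100% at every stage", {
  cases <- dplyr::bind_rows(
    make_cases(2, stage = "I", cod = "nc_heart", id_prefix = "a"),
    make_cases(2, stage = "IV", cod = "nc_heart", id_prefix = "b"),
    make_cases(2, stage = "I", cod = "ca_colorectal", id_prefix = "c")
  )
  cl <- classify_cohort(cases)
  det <- tabulate_detail(small_alloc(cases), cl, "non_cancer")
  expect_true(all(det$cause == "Heart Disease"))
  expect_true(all(det$pct == 100))
})

test_that("subtype rows add up to the parent row", {
  cases <- make_cases(60, site = "Breast, All", sex = "Female",
                      cod = "ca_breast")
  set.seed(6)
  cases$er_status <- sample(c("positive", "negative", "unknown"), 60, TRUE)
  cases$pr_status <- sample(c("positive", "negative"), 60, TRUE)
  cases <- assign_subtype(cases)
  cases$followup_months <- sample.int(100, 60, replace = TRUE)
  cases$vital_status <- sample(c("dead", "alive"), 60, TRUE)
  cases$cod_code[cases$vital_status == "alive"] <- NA
  cases$followup_months[cases$vital_status == "alive"] <- 179L
  cl <- classify_cohort(cases)
  tab <- tabulate_major(allocate_cohort(cl), cl)
  parent <- tab[tab$row_type == "parent", ]
  expect_equal(unique(parent$site_group), "Breast, All")
  sub_sum <- tab[tab$row_type == "subtype", ] |>
    dplyr::group_by(stage, cause) |>
    dplyr::summarise(count = sum(count), .groups = "drop")
  j <- dplyr::inner_join(parent, sub_sum, by = c("stage", "cause"),
                         suffix = c("_parent", "_sub"))
  expect_equal(j$count_parent, j$count_sub)
  # subtype rows are excluded from All Types (no double counting)
  expect_equal(sum(tab$count[tab$row_type == "all_types"]), 60)
})

test_that("stratified tables split by level and can drop sex-specific sites", {
  cases <- dplyr::bind_rows(
    make_cases(4, sex = "Male", id_prefix = "m"),
    make_cases(4, sex = "Female", id_prefix = "f"),
    make_cases(2, site = "Prostate", sex = "Male", cod = "ca_prostate",
               id_prefix = "p")
  )
  cl <- classify_cohort(cases)
  al <- small_alloc(cases)
  by_sex <- tabulate_stratified(al, cl, "sex")
  # prostate excluded; two identical strata give identical tables
  expect_false("Prostate" %in% by_sex$site_group)
  m <- by_sex[by_sex$stratum_level == "Male" & by_sex$row_type == "parent", ]
  f <- by_sex[by_sex$stratum_level == "Female" & by_sex$row_type == "parent", ]
  expect_equal(m$count, f$count)
  expect_equal(m$pct, f$pct)
  by_age <- tabulate_stratified(al, cl, "age_group")
  expect_equal(sum(by_age$count[by_age$row_type == "parent"]), 10)
  expect_error(tabulate_stratified(al, cl, "shoe_size"), "unknown stratifier")
})

test_that("non-cancer share rises with age at diagnosis in the default world", {
  coh <- simulate_cohort(default_cohort_params(n_cases = 20000, seed = 17))
  cl <- classify_cohort(apply_eligibility(coh$cases)$eligible)
  al <- allocate_cohort(cl)
  by_age <- tabulate_stratified(al, cl, "age_group")
  nc <- by_age[by_age$row_type == "all_types" & by_age$cause == "non_cancer" &
                 by_age$stage == "II", ]
  nc <- nc[order(nc$stratum_level), ]
  # age-increasing non-cancer hazard: compare youngest vs oldest band
  expect_lt(nc$pct[1], nc$pct[nrow(nc)])
})

test_that("stage distribution of index deaths sums and rounds correctly", {
  toy <- tibble::tibble(
    site_group = "All Types", row_type = "all_types",
    stage = c("I", "II", "III", "IV"),
    cause = "index", count = c(25, 25, 25, 25),
    pct = NA_real_, pct_rounded = NA_real_
  )
  s <- summarize_stage_of_index_deaths(toy)
  expect_equal(s$pct, rep(25, 4))
  one_stage <- toy[toy$stage == "III", ]
  expect_equal(summarize_stage_of_index_deaths(one_stage)$pct, 100)
})

test_that("display rounding is half-up", {
  expect_equal(propmort:::round_half_up(c(0.5, 1.5, 2.4, -0.4)),
               c(1, 2, 2, 0))
})
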