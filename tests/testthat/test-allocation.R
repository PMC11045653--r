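test_that("yearly distributions normalize observed deaths within each year", {
  cohort <- mixed_stratum()
  yd <- yearly_distributions(cohort, "Colon/Rectum", "III")
  # deaths: months 3, 10 (year 1, colorectal = index), 30, 30 (year 3,
  # heart), 170 (year 15, lung)
  y1 <- yd[yd$fu_year == 1, ]
  expect_equal(y1$prop, 1)
  expect_equal(y1$cause_major, "index")
  y3 <- yd[yd$fu_year == 3, ]
  expect_equal(y3$prop, 1)
  expect_equal(y3$cause_detail, "Heart Disease")
  expect_false(2 %in% yd$fu_year)  # no deaths, year absent
  # half/half normalization
  two <- classify_cohort(dplyr::bind_rows(
    make_cases(2, cod = "ca_colorectal", followup = 30, id_prefix = "x"),
    make_cases(2, cod = "nc_heart", followup = 30, id_prefix = "y")
  ))
  y <- yearly_distributions(two, "Colon/Rectum", "III")
  expect_equal(sort(y$prop), c(0.5, 0.5))
  expect_error(yearly_distributions(cohort, "Nonexistent Site", "III"),
               "unknown site_group")
  empty <- yearly_distributions(mixed_stratum(), "Kidney", "I")
  expect_equal(nrow(empty), 0)
})

test_that("tail distribution pools deaths in the final window", {
  # tail deaths {index 1, non_index 1, non_cancer 2} -> 0.25/0.25/0.5
  cohort <- classify_cohort(dplyr::bind_rows(
    make_cases(1, cod = "ca_colorectal", followup = 170, id_prefix = "a"),
    make_cases(1, cod = "ca_lung", followup = 160, id_prefix = "b"),
    make_cases(2, cod = "nc_heart", followup = c(140, 175), id_prefix = "c"),
    make_cases(1, cod = "nc_copd", followup = 20, id_prefix = "early"),
    make_cases(1, vital = "alive", cod = NA, followup = 179, id_prefix = "s")
  ))
  tl <- tail_distribution(cohort, "Colon/Rectum", "III", window_months = 48)
  expect_equal(sum(tl$n), 4)  # the month-20 death is outside the window
  got <- stats::setNames(tl$prop, tl$cause_major)
  expect_equal(got[["index"]], 0.25)
  expect_equal(got[["non_index_cancer"]], 0.25)
  expect_equal(got[["non_cancer"]], 0.5)
  # window covering the whole follow-up equals the overall distribution
  whole <- tail_distribution(cohort, "Colon/Rectum", "III",
                             window_months = 200)
  expect_equal(sum(whole$n), 5)
  expect_equal(whole$prop[whole$cause_detail == "COPD" &
                            !is.na(whole$cause_detail)], 0.2)
  # empty tail comes back empty and is handled by the fallback chain
  none <- tail_distribution(cohort, "Kidney", "I")
  expect_equal(nrow(none), 0)
})

test_that("allocate_case handles the three provenance branches", {
  cohort <- mixed_stratum()
  yd <- yearly_distributions(cohort, "Colon/Rectum", "III")
  tl <- tail_distribution(cohort, "Colon/Rectum", "III")
  dead <- cohort[cohort$vital_status == "dead", ][1, ]
  w <- allocate_case(dead, yd, tl)
  expect_equal(w$weight, 1)
  expect_equal(w$provenance, "observed")
  expect_equal(w$cause_major, "index")
  # lost in year 3: the year-3 distribution verbatim (here: all heart)
  lost <- cohort[cohort$vital_status == "lost", ]
  wl <- allocate_case(lost, yd, tl)
  expect_equal(wl$provenance, "imputed_lost")
  expect_equal(wl$weight, 1)
  expect_equal(wl$cause_detail, "Heart Disease")
  # alive: the tail distribution verbatim
  alive <- cohort[cohort$vital_status == "alive", ]
  wa <- allocate_case(alive, yd, tl)
  expect_equal(wa$provenance, rep("extrapolated_alive", nrow(wa)))
  expect_equal(sum(wa$weight), 1)
  expect_equal(wa$weight, tl$prop)
  # empty distribution without fallback fails loudly
  expect_error(allocate_case(alive, yd, tl[0, ]), "fallback chain exhausted")
  wf <- allocate_case(alive, yd, tl[0, ], fallback = tl)
  expect_equal(sum(wf$weight), 1)
})

test_that("zero censoring: allocation equals classification exactly", {
  cohort <- classify_cohort(dplyr::bind_rows(
    make_cases(5, cod = "ca_colorectal", followup = 20, id_prefix = "a"),
    make_cases(3, cod = "nc_heart", followup = 50, id_prefix = "b"),
    make_cases(2, cod = "ca_lung", followup = 100, id_prefix = "c")
  ))
  al <- allocate_cohort(cohort)
  expect_true(all(al$weights$provenance == "observed"))
  expect_true(all(al$weights$weight == 1))
  agg <- dplyr::count(al$weights, cause_major, wt = weight)
  expect_equal(agg$n[agg$cause_major == "index"], 5)
  expect_equal(agg$n[agg$cause_major == "non_cancer"], 3)
  expect_equal(agg$n[agg$cause_major == "non_index_cancer"], 2)
})

test_that("hand-computed allocation matches allocate_cohort on a small stratum", {
  # oracle: enumerate deaths per year, normalize, assign -- by hand
  cohort <- classify_cohort(dplyr::bind_rows(
    make_cases(2, cod = "ca_colorectal", followup = c(5, 11), id_prefix = "y1i"),
    make_cases(1, cod = "nc_heart", followup = 8, id_prefix = "y1h"),
    make_cases(1, cod = "ca_lung", followup = 30, id_prefix = "y3l"),
    make_cases(1, cod = "nc_heart", followup = 170, id_prefix = "taili"),
    make_cases(1, cod = "ca_colorectal", followup = 165, id_prefix = "tailh"),
    make_cases(2, vital = "lost", cod = NA, followup = c(6, 28), id_prefix = "lost"),
    make_cases(2, vital = "alive", cod = NA, followup = 179, id_prefix = "al")
  ))
  al <- allocate_cohort(cohort)
  w <- al$weights
  # lost in year 1: year-1 deaths are 2 index + 1 heart -> 2/3, 1/3
  l1 <- w[w$case_id == "lost1", ]
  expect_equal(stats::setNames(l1$weight, l1$cause_major),
               c(index = 2 / 3, non_cancer = 1 / 3))
  # lost in year 3: single year-3 death, lung -> weight 1
  l2 <- w[w$case_id == "lost2", ]
  expect_equal(l2$weight, 1)
  expect_equal(l2$cause_detail, "Lung, All")
  # alive: tail window is months > 179 - 48 = 131: one index + one heart
  for (id in c("al1", "al2")) {
    a <- w[w$case_id == id, ]
    expect_equal(stats::setNames(a$weight, a$cause_major),
                 c(index = 0.5, non_cancer = 0.5))
  }
  # mass conservation and observed-subset fidelity
  expect_equal(sum(w$weight), nrow(cohort))
  obs <- w[w$provenance == "observed", ]
  expect_equal(nrow(obs), 6)
  expect_true(all(obs$weight == 1))
})

test_that("fallback chain fills empty cells in order and is logged", {
  # stratum A has deaths only in year 1; a case lost in year 5 must fall
  # back (adjacent years empty too) to the stratum-pooled distribution
  cohort <- classify_cohort(dplyr::bind_rows(
    make_cases(2, cod = "ca_colorectal", followup = 5, id_prefix = "d"),
    make_cases(1, vital = "lost", cod = NA, followup = 55, id_prefix = "l")
  ))
  al <- allocate_cohort(cohort)
  expect_equal(nrow(al$fallback_log), 1)
  expect_equal(al$fallback_log$level, "stratum")
  lw <- al$weights[al$weights$case_id == "l1", ]
  expect_equal(lw$weight, 1)
  expect_equal(lw$cause_major, "index")

  # an all-censored stratum borrows from the site, then globally
  cohort2 <- classify_cohort(dplyr::bind_rows(
    make_cases(2, cod = "nc_heart", followup = 170, stage = "I", id_prefix = "d"),
    make_cases(1, vital = "alive", cod = NA, followup = 179, stage = "IV",
               id_prefix = "a")
  ))
  al2 <- allocate_cohort(cohort2)
  expect_equal(al2$fallback_log$level, "site")
  # no deaths anywhere: explicit error naming the stratum
  cohort3 <- classify_cohort(make_cases(2, vital = "alive", cod = NA,
                                        followup = 179))
  expect_error(allocate_cohort(cohort3), "Colon/Rectum.*fallback chain exhausted")
})

test_that("forward-looking lost-case mode pools deaths at or after the loss year", {
  cohort <- classify_cohort(dplyr::bind_rows(
    make_cases(1, cod = "ca_colorectal", followup = 5, id_prefix = "e"),
    make_cases(1, cod = "nc_heart", followup = 30, id_prefix = "m"),
    make_cases(1, cod = "ca_lung", followup = 60, id_prefix = "lt"),
    make_cases(1, vital = "lost", cod = NA, followup = 26, id_prefix = "l")
  ))
  al <- allocate_cohort(cohort, allocation_config(lost_mode = "forward"))
  lw <- al$weights[al$weights$case_id == "l1", ]
  # deaths in years >= 3: heart (year 3) and lung (year 5) -> 0.5 each
  expect_equal(sort(lw$cause_major), c("non_cancer", "non_index_cancer"))
  expect_equal(lw$weight, c(0.5, 0.5))
})

test_that("sampled mode draws a single seeded cause per case", {
  coh <- simulate_cohort(default_cohort_params(n_cases = 400, seed = 8))
  cl <- classify_cohort(apply_eligibility(coh$cases)$eligible)
  cfg <- allocation_config(mode = "sampled", seed = 99)
  a1 <- allocate_cohort(cl, cfg)
  a2 <- allocate_cohort(cl, cfg)
  expect_identical(a1$weights, a2$weights)
  expect_true(all(a1$weights$weight == 1))
  expect_equal(nrow(a1$weights), nrow(cl))
})

test_that("mass is conserved globally and per stratum on a simulated cohort", {
  coh <- simulate_cohort(default_cohort_params(n_cases = 2000, seed = 21))
  cl <- classify_cohort(apply_eligibility(coh$cases)$eligible)
  al <- allocate_cohort(cl)
  expect_equal(sum(al$weights$weight), nrow(cl))
  per_stratum <- al$weights |>
    dplyr::left_join(dplyr::select(cl, case_id, site_group, stage),
                     by = "case_id") |>
    dplyr::count(site_group, stage, wt = weight, name = "allocated")
  sizes <- dplyr::count(cl, site_group, stage, name = "n_cases")
  j <- dplyr::left_join(sizes, per_stratum, by = c("site_group", "stage"))
  expect_equal(j$allocated, as.numeric(j$n_cases))
})

test_that("provenance shares behave like a registry draw at synthetic scale", {
  # early stages are dominated by extrapolation, stage IV by observation
  # (the registry pattern is roughly 40/5/55 at stages I-II and 91/2/8 at IV)
  coh <- simulate_cohort(default_cohort_params(n_cases = 8000, seed = 7))
  cl <- classify_cohort(apply_eligibility(coh$cases)$eligible)
  al <- allocate_cohort(cl)
  ps <- tidyr::pivot_wider(al$provenance_summary, id_cols = stage,
                           names_from = provenance, values_from = fraction)
  early <- ps[ps$stage %in% c("I", "II"), ]
  expect_true(all(early$observed > 0.25 & early$observed < 0.5))
  expect_true(all(early$imputed_lost < 0.12))
  expect_true(all(early$extrapolated_alive > 0.45))
  late <- ps[ps$stage == "IV", ]
  expect_gt(late$observed, 0.8)
  expect_lt(late$extrapolated_alive, 0.15)
})
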