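# Shared test worlds and independent oracles.

# Brute-force per-year probability recursion: the closed-form cause-of-death
# distribution implied by a cell's yearly hazards for a case diagnosed in age
# band `band0`. Independent of the simulator: plain loops over years.
oracle_cause_distribution <- function(hazards, band0, years = 400,
                                      band_cap = 7) {
  causes <- hazards$cause
  prob <- stats::setNames(numeric(length(causes)), causes)
  surv <- 1
  for (y in seq_len(years)) {
    band <- min(band0 + (y - 1) %/% 5, band_cap)
    p <- numeric(length(causes))
    for (i in seq_along(causes)) {
      h <- hazards[i, ]
      if (!is.na(h$plateau_year) && y > h$plateau_year) {
        p[i] <- h$plateau_p
      } else {
        p[i] <- h$p * h$age_slope^band
      }
    }
    prob <- prob + surv * p
    surv <- surv * (1 - sum(p))
  }
  prob / sum(prob)
}

# Single-cell world: one (site_group, stage) stratum with the given hazards.
one_cell_params <- function(hazards, n_cases = 500, site = "Colon/Rectum",
                            stage = "III", seed = 1, loss_prob = 0,
                            max_followup_months = 179) {
  mixture <- tibble::tibble(site_group = site, stage = stage, weight = 1)
  h <- dplyr::mutate(hazards, site_group = site, stage = stage, .before = 1)
  cohort_params(n_cases, mixture, h, loss_prob = loss_prob,
                max_followup_months = max_followup_months, seed = seed)
}

# Hand-built classified cohort from compact arguments; defaults give a valid
# record so tests only state what matters.
make_cases <- function(n, site = "Colon/Rectum", stage = "III",
                       vital = "dead", cod = "ca_colorectal",
                       followup = 6, age = "65-69", sex = "Male",
                       race = "White, Non-Hispanic", id_prefix = "c") {
  tibble::tibble(
    case_id = paste0(id_prefix, seq_len(n)),
    site_group = site, stage = stage, age_group = age, sex = sex,
    race_ethnicity = race, dx_year = 2006L,
    followup_months = as.integer(followup),
    vital_status = vital,
    cod_code = ifelse(vital == "dead", cod, NA_character_)
  )
}

# A small mixed stratum used by several allocation tests: deaths in years
# 1-3, one lost case, one survivor.
mixed_stratum <- function() {
  cases <- dplyr::bind_rows(
    make_cases(2, cod = "ca_colorectal", followup = c(3, 10), id_prefix = "d1_"),
    make_cases(2, cod = "nc_heart", followup = c(30, 30), id_prefix = "d2_"),
    make_cases(1, cod = "ca_lung", followup = 170, id_prefix = "d3_"),
    make_cases(1, vital = "lost", cod = NA, followup = 30, id_prefix = "l_"),
    make_cases(1, vital = "alive", cod = NA, followup = 179, id_prefix = "a_")
  )
  classify_cohort(cases)
}

# Recovery world: six well-populated strata so each has a stable tail
# (>~100 observed deaths in the final four years); age-flat non-cancer
# hazards make the post-cure world time-stationary, the regime in which
# tail extrapolation is exactly calibrated.
recovery_cohort_params <- function(n_cases = 20000, seed = 11) {
  p <- default_cohort_params(n_cases = n_cases, seed = seed,
                             loss_prob = 0.02, age_flat = TRUE)
  keep <- paste(c("Breast, All", "Breast, All", "Colon/Rectum",
                  "Colon/Rectum", "Lung, All", "Other Types"),
                c("I", "II", "II", "IV", "III", "I"))
  key <- paste(p$mixture$site_group, p$mixture$stage)
  p$mixture$weight <- ifelse(key %in% keep, 1 / length(keep), 0)
  validate_cohort_params(p)
  p
}
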