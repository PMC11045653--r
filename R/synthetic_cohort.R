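#' Specify a cause-specific yearly death hazard
#'
#' One row of the generator's hazard model: a cause of death and its
#' baseline yearly death probability, with two optional time/age effects.
#' For the index cancer (`cause = "index"`), `plateau_year` models
#' statistical cure: from the year after `plateau_year` onwards the yearly
#' probability drops to the constant `plateau_p`, emulating the plateau in
#' index-cancer death risk seen roughly 10 years after diagnosis. For
#' non-cancer causes, `age_slope` is a multiplicative increase per attained
#' 5-year age band (band 50--54 = 1), so non-cancer mortality rises with
#' age at diagnosis and with time since diagnosis.
#'
#' @param cause `"index"` or a detailed cause code from
#'   [cause_vocabulary()] (the index cause code is derived from the
#'   stratum's site group).
#' @param p Baseline yearly death probability in \[0, 1\].
#' @param plateau_year Integer year after which the index probability is
#'   constant at `plateau_p`; `NULL` for a constant hazard.
#' @param plateau_p Reduced constant probability after the plateau year.
#' @param age_slope Multiplicative increase per 5-year attained-age band.
#' @return A one-row tibble; bind rows to build a hazard table.
#' @export
hazard_spec <- function(cause, p, plateau_year = NULL, plateau_p = NULL,
                        age_slope = 1) {
  stopifnot(length(cause) == 1, p >= 0, p <= 1, age_slope > 0)
  if (!is.null(plateau_year)) {
    stopifnot(plateau_year >= 1, !is.null(plateau_p), plateau_p >= 0, plateau_p <= 1)
  }
  tibble::tibble(
    cause = cause, p = p,
    plateau_year = ifelse(is.null(plateau_year), NA_integer_, as.integer(plateau_year)),
    plateau_p = ifelse(is.null(plateau_p), NA_real_, plateau_p),
    age_slope = age_slope
  )
}

#' Parameters of the synthetic registry cohort
#'
#' Bundles everything the generator needs: cohort size, the mixture over
#' (site group x stage) cells, demographic distributions, a hazard table,
#' administrative follow-up, and random censoring. Administrative censoring
#' emulates a fixed calendar end of follow-up: diagnosis years are drawn
#' uniformly from `dx_years` with a uniform diagnosis month, and each
#' case's administrative maximum is `max_followup_months` minus the elapsed
#' months since the first diagnosis year, giving the staggered follow-up
#' mix of a multi-year accrual window. Random loss to follow-up competes
#' with death within each year via sequential draws (death first).
#'
#' @param n_cases Number of cases to generate.
#' @param mixture Tibble `site_group`, `stage`, `weight` (nonnegative,
#'   normalized internally; must sum to a positive value).
#' @param hazards Tibble `site_group`, `stage`, plus the [hazard_spec()]
#'   columns, one row per cause per cell.
#' @param age_dist,sex_dist,race_dist Tibbles (`age_group`|`sex`|
#'   `race_ethnicity`, `weight`); defaults are mild versions of a US
#'   registry age mix. Sex is forced for sex-specific sites (breast,
#'   cervix, ovary, uterus female; prostate male).
#' @param max_followup_months Administrative maximum follow-up for the
#'   earliest diagnosis year (default 179 months = 14 years 11 months).
#' @param loss_prob Yearly probability of loss to follow-up, in \[0, 1).
#' @param dx_years Calendar years of diagnosis (default 2006--2010).
#' @param age_band_cap Attained-age band at which the age slope stops
#'   growing (default 7, i.e. ~85+); keeps yearly probability sums valid
#'   and makes the late-follow-up world quasi-stationary.
#' @param seed Integer random seed; identical parameters (including seed)
#'   give byte-identical cohorts.
#' @return A validated object of class `cohort_params`.
#' @export
cohort_params <- function(n_cases, mixture, hazards,
                          age_dist = NULL, sex_dist = NULL, race_dist = NULL,
                          max_followup_months = 179, loss_prob = 0.007,
                          dx_years = 2006:2010, age_band_cap = 7, seed = 1) {
  if (is.null(age_dist)) {
    age_dist <- tibble::tibble(
      age_group = pm_age_groups(),
      weight = c(0.12, 0.15, 0.16, 0.16, 0.15, 0.14, 0.12)
    )
  }
  if (is.null(sex_dist)) {
    sex_dist <- tibble::tibble(sex = pm_sexes(), weight = c(0.5, 0.5))
  }
  if (is.null(race_dist)) {
    race_dist <- tibble::tibble(
      race_ethnicity = c(
        "White, Non-Hispanic", "Black, Non-Hispanic", "Hispanic",
        "Asian American/Pacific Islander, Non-Hispanic",
        "American Indian/Alaska Native, Non-Hispanic",
        "Other/Unknown, Non-Hispanic"
      ),
      weight = c(0.70, 0.11, 0.09, 0.07, 0.01, 0.02)
    )
  }
  params <- structure(
    list(
      n_cases = as.integer(n_cases), mixture = mixture, hazards = hazards,
      age_dist = age_dist, sex_dist = sex_dist, race_dist = race_dist,
      max_followup_months = as.integer(max_followup_months),
      loss_prob = loss_prob, dx_years = as.integer(dx_years),
      age_band_cap = as.integer(age_band_cap), seed = as.integer(seed)
    ),
    class = "cohort_params"
  )
  validate_cohort_params(params)
  params
}

#' @rdname cohort_params
#' @param params A `cohort_params` object.
#' @export
validate_cohort_params <- function(params) {
  m <- params$mixture
  if (any(m$weight < 0) || sum(m$weight) <= 0) {
    stop("mixture weights must be nonnegative with a positive sum", call. = FALSE)
  }
  if (anyDuplicated(m[c("site_group", "stage")])) {
    stop("duplicated (site_group, stage) cells in mixture", call. = FALSE)
  }
  if (!all(m$stage %in% pm_stages())) stop("unknown stage in mixture", call. = FALSE)
  parent_site(m$site_group)  # errors on unknown sites
  if (params$max_followup_months <= 0) stop("max follow-up must be > 0", call. = FALSE)
  if (params$loss_prob < 0 || params$loss_prob >= 1) {
    stop("loss probability must be in [0, 1)", call. = FALSE)
  }
  vocab <- cause_vocabulary()
  sg <- site_groups()
  h <- params$hazards
  bad_cause <- !(h$cause == "index" | h$cause %in% vocab$code)
  if (any(bad_cause)) {
    stop("unknown hazard cause(s): ",
         paste(unique(h$cause[bad_cause]), collapse = ", "), call. = FALSE)
  }
  if (any(h$p < 0 | h$p > 1) ||
      any(!is.na(h$plateau_p) & (h$plateau_p < 0 | h$plateau_p > 1))) {
    stop("hazard probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.na(h$plateau_year) & h$plateau_year < 1)) {
    stop("plateau_year must be >= 1", call. = FALSE)
  }
  if (any(h$age_slope <= 0)) stop("age_slope must be positive", call. = FALSE)
  active <- m[m$weight > 0, ]
  for (k in seq_len(nrow(active))) {
    cell <- h[h$site_group == active$site_group[k] & h$stage == active$stage[k], ]
    cell_name <- paste0("(", active$site_group[k], ", stage ", active$stage[k], ")")
    if (nrow(cell) == 0) {
      stop("no hazards specified for cell ", cell_name, call. = FALSE)
    }
    if (sum(cell$cause == "index") > 1) {
      stop("more than one index hazard in cell ", cell_name, call. = FALSE)
    }
    own_code <- sg$cancer_code[match(active$site_group[k], sg$site_group)]
    if (own_code %in% cell$cause) {
      stop("cell ", cell_name, " lists its own cancer site as a non-index cause; ",
           "same-site second primary deaths do not occur by registry convention",
           call. = FALSE)
    }
    # worst-case yearly probability sum over years x attained-age bands
    worst <- sum(pmax(cell$p, ifelse(is.na(cell$plateau_p), 0, cell$plateau_p)) *
                   pmax(cell$age_slope, 1)^params$age_band_cap)
    if (worst > 1) {
      stop("yearly cause probabilities can sum to ", signif(worst, 4),
           " > 1 in cell ", cell_name, call. = FALSE)
    }
  }
  invisible(params)
}

#' Default synthetic world: a registry-like cohort at 1/100 scale
#'
#' A seven-site world (breast, prostate, lung, colon/rectum, pancreas,
#' melanoma, other) whose stage mixture, index-cancer lethality gradient,
#' cure plateau at year 10, and age-increasing non-cancer mortality are
#' chosen so that observed survivor fractions and cause mixes resemble a
#' 2006--2010 US registry draw followed through 2020 at roughly 1/100
#' scale. Unknown-stage cases receive stage-III-like index hazards. See the
#' methods vignette for the reasoning behind each number.
#'
#' @param n_cases Cohort size (default 11,500).
#' @param seed Random seed.
#' @param loss_prob Yearly loss-to-follow-up probability.
#' @param age_flat If `TRUE`, set every non-cancer age slope to 1 (a
#'   time-stationary world in which tail extrapolation is exactly
#'   calibrated); used by parameter-recovery checks.
#' @return A `cohort_params` object.
#' @export
default_cohort_params <- function(n_cases = 11500, seed = 1, loss_prob = 0.007,
                                  age_flat = FALSE) {
  sites <- c("Breast, All", "Prostate", "Lung, All", "Colon/Rectum",
             "Pancreas", "Melanoma", "Other Types")
  site_w <- c(0.140, 0.200, 0.135, 0.093, 0.027, 0.037, 0.368)
  stage_w <- rbind(
    c(0.48, 0.31, 0.11, 0.05, 0.05),    # breast
    c(0.001, 0.808, 0.071, 0.055, 0.065), # prostate: stage I rare
    c(0.17, 0.04, 0.235, 0.455, 0.10),  # lung
    c(0.24, 0.24, 0.24, 0.19, 0.09),    # colon/rectum
    c(0.06, 0.22, 0.08, 0.50, 0.14),    # pancreas
    c(0.68, 0.12, 0.06, 0.04, 0.10),    # melanoma
    c(0.25, 0.20, 0.15, 0.20, 0.20)     # other
  )
  mixture <- tibble::tibble(
    site_group = rep(sites, each = 5),
    stage = rep(pm_stages(), times = length(sites)),
    weight = as.vector(t(stage_w * site_w))
  )
  # index yearly death probability: stage gradient x site severity,
  # plateau (statistical cure) at year 10 with an 80% hazard reduction
  stage_base <- c(I = 0.012, II = 0.016, III = 0.055, IV = 0.17, Unknown = 0.055)
  severity <- c(0.60, 0.45, 2.2, 1.0, 5.0, 0.50, 1.0)
  names(severity) <- sites
  shared <- function(site) {
    ni <- tibble::tibble(
      cause = c("ca_lung", "ca_pancreas", "ca_colorectal", "ca_liver", "ca_other"),
      p = c(0.0020, 0.0006, 0.0007, 0.0004, 0.0013),
      plateau_year = NA_integer_, plateau_p = NA_real_, age_slope = 1
    )
    own <- site_groups()$cancer_code[match(site, site_groups()$site_group)]
    ni <- ni[ni$cause != own, ]
    # baselines are per band 50-54; chosen so that at the cohort's typical
    # attained band (~4.5, i.e. ~72 years) the cause-specific yearly
    # probabilities land near registry-like values (heart ~0.009 etc.)
    nc <- tibble::tibble(
      cause = c("nc_heart", "nc_copd", "nc_cerebrovascular", "nc_diabetes",
                "nc_alzheimer", "nc_septicemia", "nc_accidents",
                "nc_tuberculosis", "nc_other"),
      p = c(0.0028, 0.0015, 0.0005, 0.0006, 0.00008, 0.0002, 0.0007,
            0.0001, 0.0012),
      plateau_year = NA_integer_, plateau_p = NA_real_,
      age_slope = c(1.30, 1.20, 1.40, 1.20, 1.60, 1.25, 1.10, 1.00, 1.30)
    )
    if (age_flat) nc$age_slope <- 1
    dplyr::bind_rows(ni, nc)
  }
  hazards <- dplyr::bind_rows(lapply(sites, function(s) {
    dplyr::bind_rows(lapply(pm_stages(), function(st) {
      p_idx <- min(stage_base[[st]] * severity[[s]], 0.6)
      dplyr::bind_rows(
        hazard_spec("index", p_idx, plateau_year = 10, plateau_p = 0.2 * p_idx),
        shared(s)
      ) |>
        dplyr::mutate(site_group = s, stage = st, .before = 1)
    }))
  }))
  cohort_params(n_cases, mixture, hazards, loss_prob = loss_prob, seed = seed)
}

#' Simulate a registry-like cohort with known cause-of-death truth
#'
#' Draws one case listing from a [cohort_params()] world. Every case gets a
#' latent death time and cause (simulated from the cause-specific yearly
#' hazards regardless of censoring), then an observed record is derived by
#' censoring at loss to follow-up or the administrative end: vital status
#' `dead` (with the detailed cause code), `lost`, or `alive`. Deaths are
#' placed uniformly within their death year (month resolution). The latent
#' truth is returned as a side channel that the analysis pipeline never
#' reads; it exists so allocation can be validated by parameter recovery.
#'
#' @param params A `cohort_params` object (its `seed` fixes all draws).
#' @return An object of class `pm_cohort`: a list with `cases` (the case
#'   listing, schema of [read_case_listing()]), `truth` (`case_id`,
#'   `true_cause_code`, `true_cause_major`, `true_cause_detail`,
#'   `true_death_month`), and `params`.
#' @export
simulate_cohort <- function(params) {
  validate_cohort_params(params)
  set.seed(params$seed)
  n <- params$n_cases
  mix <- params$mixture[params$mixture$weight > 0, ]
  cell_id <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
  site <- mix$site_group[cell_id]
  stage <- mix$stage[cell_id]
  age_group <- sample(params$age_dist$age_group, n, replace = TRUE,
                      prob = params$age_dist$weight)
  band0 <- match(age_group, pm_age_groups()) - 1L
  sex <- sample(params$sex_dist$sex, n, replace = TRUE,
                prob = params$sex_dist$weight)
  female_sites <- c("Breast, All", "Breast, HR-positive", "Breast, HR-negative",
                    "Breast, HR-unknown", "Cervix", "Ovary", "Uterus")
  sex[site %in% female_sites] <- "Female"
  sex[site == "Prostate"] <- "Male"
  race <- sample(params$race_dist$race_ethnicity, n, replace = TRUE,
                 prob = params$race_dist$weight)
  dx_year <- sample(params$dx_years, n, replace = TRUE)
  dx_month <- sample.int(12L, n, replace = TRUE)
  admin_max <- pmax(
    1L,
    params$max_followup_months - 12L * (dx_year - min(params$dx_years)) -
      (dx_month - 1L)
  )

  latent <- simulate_latent_deaths(params, cell_id, band0)
  death_month <- 12L * (latent$death_year - 1L) + sample.int(12L, n, replace = TRUE)

  if (params$loss_prob > 0) {
    loss_year <- stats::rgeom(n, params$loss_prob) + 1L
    loss_month <- 12L * (loss_year - 1L) + sample.int(12L, n, replace = TRUE)
  } else {
    loss_year <- rep(Inf, n)
    loss_month <- rep(Inf, n)
  }
  # within a year death is drawn before loss, so loss censors only when it
  # falls in a strictly earlier year than the death
  loss_eff <- ifelse(loss_year < latent$death_year, loss_month, Inf)

  vital <- ifelse(loss_eff <= admin_max, "lost",
           ifelse(death_month <= admin_max, "dead", "alive"))
  followup <- as.integer(ifelse(vital == "lost", loss_eff,
                         ifelse(vital == "dead", death_month, admin_max)))
  cod <- ifelse(vital == "dead", latent$cause_code, NA_character_)

  cases <- tibble::tibble(
    case_id = sprintf("case_%07d", seq_len(n)),
    site_group = site, stage = stage, age_group = age_group, sex = sex,
    race_ethnicity = race, dx_year = as.integer(dx_year),
    followup_months = followup, vital_status = vital, cod_code = cod
  )
  cls <- classify_cause(latent$cause_code, site)
  truth <- tibble::tibble(
    case_id = cases$case_id,
    true_cause_code = latent$cause_code,
    true_cause_major = cls$cause_major,
    true_cause_detail = cls$cause_detail,
    true_death_month = death_month
  )
  structure(list(cases = cases, truth = truth, params = params),
            class = "pm_cohort")
}

# latent death year + cause for every case, ignoring censoring; horizon of
# 120 years with a forced terminal draw for (vanishingly rare) survivors
simulate_latent_deaths <- function(params, cell_id, band0, horizon = 120L) {
  n <- length(cell_id)
  mix <- params$mixture[params$mixture$weight > 0, ]
  sg <- site_groups()
  cap <- params$age_band_cap
  cells <- lapply(seq_len(nrow(mix)), function(k) {
    h <- params$hazards[params$hazards$site_group == mix$site_group[k] &
                          params$hazards$stage == mix$stage[k], ]
    codes <- ifelse(h$cause == "index",
                    sg$cancer_code[match(mix$site_group[k], sg$site_group)],
                    h$cause)
    # bands x causes matrices, pre and post the index plateau
    bands <- 0:cap
    slope <- outer(bands, h$age_slope, function(b, s) s^b)
    base <- matrix(h$p, nrow = length(bands), ncol = nrow(h), byrow = TRUE)
    pre <- base * slope
    post <- pre
    idx <- which(h$cause == "index")
    plateau <- if (length(idx) == 1 && !is.na(h$plateau_year[idx])) h$plateau_year[idx] else NA_integer_
    if (length(idx) == 1 && !is.na(plateau)) post[, idx] <- h$plateau_p[idx]
    list(codes = codes, pre = pre, post = post, plateau = plateau)
  })
  death_year <- rep(NA_integer_, n)
  cause_code <- rep(NA_character_, n)
  alive <- seq_len(n)
  for (y in seq_len(horizon)) {
    if (length(alive) == 0) break
    u <- stats::runif(length(alive))
    band <- pmin(band0[alive] + (y - 1L) %/% 5L, cap)
    died <- logical(length(alive))
    for (k in unique(cell_id[alive])) {
      in_cell <- which(cell_id[alive] == k)
      cl <- cells[[k]]
      M <- if (!is.na(cl$plateau) && y > cl$plateau) cl$post else cl$pre
      cum <- t(apply(M, 1, cumsum))
      if (ncol(M) == 1) cum <- matrix(M, ncol = 1)
      rows <- band[in_cell] + 1L
      cumc <- cum[rows, , drop = FALSE]
      uu <- u[in_cell]
      hit <- uu < cumc[, ncol(cumc)]
      if (any(hit)) {
        ci <- rowSums(uu[hit] > cumc[hit, , drop = FALSE]) + 1L
        gidx <- alive[in_cell[hit]]
        death_year[gidx] <- y
        cause_code[gidx] <- cl$codes[ci]
        died[in_cell] <- hit
      }
    }
    alive <- alive[!died]
  }
  if (length(alive) > 0) {
    # forced terminal draw at the horizon
    band <- pmin(band0[alive] + (horizon - 1L) %/% 5L, cap)
    for (k in unique(cell_id[alive])) {
      in_cell <- which(cell_id[alive] == k)
      cl <- cells[[k]]
      for (j in in_cell) {
        pr <- cl$post[band[j] + 1L, ]
        gidx <- alive[j]
        death_year[gidx] <- horizon
        cause_code[gidx] <- sample(cl$codes, 1, prob = pr / sum(pr))
      }
    }
  }
  list(death_year = death_year, cause_code = cause_code)
}

#' Write (and round-trip) a simulated case listing
#'
#' Writes the case listing in the CSV schema consumed by
#' [read_case_listing()]; the round trip is lossless, including non-ASCII
#' demographic labels (UTF-8 throughout). Writing an empty collection is an
#' error rather than an empty file. `write_truth_sidechannel()` writes the
#' latent-truth table to a separate file that the analysis pipeline never
#' reads.
#'
#' @param cases Case-record tibble (from [simulate_cohort()]`$cases` or
#'   compatible).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_case_listing <- function(cases, path) {
  if (is.null(cases) || nrow(cases) == 0) {
    stop("refusing to write an empty case listing", call. = FALSE)
  }
  readr::write_csv(cases, path, na = "")
  invisible(path)
}

#' @rdname write_case_listing
#' @param truth Truth side-channel tibble (from [simulate_cohort()]`$truth`).
#' @export
write_truth_sidechannel <- function(truth, path) {
  if (is.null(truth) || nrow(truth) == 0) {
    stop("refusing to write an empty truth side channel", call. = FALSE)
  }
  readr::write_csv(truth, path, na = "")
  invisible(path)
}
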