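#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the statistical frame of a community cohort study:
#' a baseline survey of older adults aged 60-89 (about half men) in 1979, a
#' second survey of the survivors ten years later, and mortality follow-up
#' through the end of 2014, by which time almost nobody (< 1%) is still
#' alive.  Mortality follows a Gompertz period life table modulated by each
#' subject's predictor values through a proportional-hazards-style effect on
#' the annual death probability, `q_i = 1 - (1 - q)^HR`, which stays a valid
#' probability for any hazard ratio `HR > 0`.
#'
#' A single latent standard-normal frailty factor, with per-variable loadings,
#' induces the mutual correlation among health-related predictors that real
#' survey variables show; it also (optionally) enters the hazard.
#'
#' @param n number of subjects.
#' @param baseline_year,end_of_study_year calendar frame of the follow-up.
#' @param wave2_offset years between the two survey waves.
#' @param age_range integer `c(min, max)` baseline age, sampled uniformly.
#' @param p_male probability of being male.
#' @param alpha_female,alpha_male,beta,cap Gompertz life-table parameters
#'   (see [gompertz_life_table()]); the table is generated over ages
#'   `age_range[1]` to `age_range[2] + (end_of_study_year - baseline_year)`.
#' @param effects named numeric vector of log hazard ratios per unit of the
#'   corresponding (centered) predictor.
#' @param effect_centers named numeric vector of centering constants.
#' @param frailty_loading log hazard ratio per unit of the latent frailty.
#' @param transition list with `drift` and `sd`: between waves each two-wave
#'   score moves by `round(N(-drift, sd))` in its favorable direction (so
#'   `drift > 0` biases transitions toward worsening), clipped to its range.
#' @param seed integer seed; the same config yields the identical cohort.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n = 1056L,
                       baseline_year = 1979L,
                       end_of_study_year = 2014L,
                       wave2_offset = 10L,
                       age_range = c(60L, 89L),
                       p_male = 0.498,
                       alpha_female = 2e-5, alpha_male = 3.5e-5,
                       beta = 0.095, cap = 0.7,
                       effects = c(srh = -0.20, smoking_years = 0.008,
                                   medications = 0.05,
                                   musculoskeletal = 0.15),
                       effect_centers = c(srh = 2, smoking_years = 13,
                                          medications = 1.6,
                                          musculoskeletal = 0.36),
                       frailty_loading = 0.25,
                       transition = list(drift = 0.7, sd = 1.0),
                       seed = 1L) {
  stopifnot(n >= 1, end_of_study_year >= baseline_year, wave2_offset >= 0,
            p_male >= 0, p_male <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Variable specifications of the synthetic predictor set
#'
#' A representative subset of a geriatric survey battery: self-rated health
#' (SRH, 0-4, higher better), years of education, years of regular smoking,
#' functional mobility (0-14), demanding functioning (0-12), activities of
#' daily living (ADL, 0-15), prescription-medication count, and a
#' musculoskeletal-disease indicator.  SRH, mobility, demanding functioning,
#' ADL and medications are measured at both waves and hence change-eligible.
#'
#' @return a specification data frame (see [variable_spec()]).
#' @export
default_variable_specs <- function() {
  rbind(
    variable_spec("srh", "ordinal", "higher_is_better", "both_waves", 0, 4),
    variable_spec("education_years", "continuous", "undirected",
                  "baseline_only", 0, 20),
    variable_spec("smoking_years", "continuous", "undirected",
                  "baseline_only", 0, 60),
    variable_spec("mobility", "ordinal", "higher_is_better", "both_waves",
                  0, 14),
    variable_spec("demanding", "ordinal", "higher_is_better", "both_waves",
                  0, 12),
    variable_spec("adl", "ordinal", "higher_is_better", "both_waves", 0, 15),
    variable_spec("medications", "continuous", "higher_is_worse",
                  "both_waves", 0, 15),
    variable_spec("musculoskeletal", "nominal", "undirected",
                  "baseline_only", NA, NA)
  )
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

draw_predictors <- function(n, z) {
  # SRH: five levels with realistic shares, worse SRH for frailer subjects
  latent <- 0.8 * z + stats::rnorm(n)
  thr <- stats::qnorm(cumsum(c(0.09, 0.28, 0.36, 0.19)), sd = sqrt(1.64))
  srh <- 4L - findInterval(latent, thr)
  data.frame(
    srh = srh,
    education_years = clip(round(stats::rlnorm(n, log(4), 0.6)), 0, 20),
    smoking_years = ifelse(stats::runif(n) < 0.40,
                           clip(round(stats::rnorm(n, 30, 12)), 1, 60), 0),
    mobility = stats::rbinom(n, 14, stats::plogis(1.2 - 0.5 * z)),
    demanding = stats::rbinom(n, 12, stats::plogis(1.0 - 0.5 * z)),
    adl = stats::rbinom(n, 15, stats::plogis(2.2 - 0.5 * z)),
    medications = clip(stats::rpois(n, exp(0.2 + 0.25 * z)), 0, 15),
    musculoskeletal = stats::rbinom(n, 1, stats::plogis(-0.6 + 0.3 * z))
  )
}

hazard_ratio <- function(predictors, z, cfg) {
  lhr <- cfg$frailty_loading * z
  for (v in names(cfg$effects)) {
    x <- predictors[[v]]
    ctr <- if (v %in% names(cfg$effect_centers)) cfg$effect_centers[[v]] else 0
    lhr <- lhr + cfg$effects[[v]] * (as.numeric(x) - ctr)
  }
  exp(lhr)
}

# Yearly death draws: subject i dies in calendar year y with probability
# 1 - (1 - q(sex, attained age, y))^HR_i.  Stops at end_of_study_year;
# survivors are censored (alive_at_end).
draw_deaths <- function(lt, sex, baseline_age, baseline_year,
                        end_year, hr) {
  n <- length(sex)
  death_year <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  for (yr in seq.int(baseline_year, end_year)) {
    idx <- which(alive)
    if (length(idx) == 0L) break
    age <- baseline_age[idx] + (yr - baseline_year)
    q <- death_prob(lt, sex[idx], age,
                    if (lt$period_only) NULL else rep.int(yr, length(idx)))
    q_i <- 1 - (1 - q)^hr[idx]
    die <- stats::runif(length(idx)) < q_i
    death_year[idx[die]] <- yr
    alive[idx[die]] <- FALSE
  }
  death_year
}

#' Simulate a baseline cohort with life-table mortality
#'
#' Draws subjects (sex, baseline age, latent frailty, wave-1 predictors),
#' assigns each a hazard ratio from the configured predictor effects, and
#' simulates yearly deaths from the life table modulated by that hazard ratio
#' until death or the end of the study.  With all effects and the frailty
#' loading zero (`HR = 1` for everyone) and no censoring window, the
#' resulting RPDs are uniform up to annual discretization — the null
#' calibration of the longevity statistic.
#'
#' @param cfg a [sim_config()].
#' @param lt optional [life_table()]; by default a Gompertz table is built
#'   from the config covering all attainable ages.
#' @return an object of class `rpd_sim`: list with `cohort` (data frame `id`,
#'   `sex`, `baseline_age`, `baseline_year`, `death_year`, `alive_at_end`,
#'   `end_of_study_year`), `predictors` (wave-1 values), `specs`, `hr`, `z`,
#'   `lt`, and `cfg`.
#' @export
simulate_cohort <- function(cfg, lt = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(lt)) {
    max_age <- cfg$age_range[2L] + (cfg$end_of_study_year - cfg$baseline_year)
    lt <- gompertz_life_table(cfg$alpha_female, cfg$alpha_male, cfg$beta,
                              age_range = c(cfg$age_range[1L], max_age),
                              cap = cfg$cap)
  }
  set.seed(cfg$seed)
  n <- cfg$n
  sex <- ifelse(stats::runif(n) < cfg$p_male, "m", "f")
  baseline_age <- sample(seq.int(cfg$age_range[1L], cfg$age_range[2L]), n,
                         replace = TRUE)
  z <- stats::rnorm(n)
  predictors <- draw_predictors(n, z)
  hr <- hazard_ratio(predictors, z, cfg)
  death_year <- draw_deaths(lt, sex, baseline_age, cfg$baseline_year,
                            cfg$end_of_study_year, hr)
  cohort <- data.frame(
    id = sprintf("s%05d", seq_len(n)),
    sex = sex,
    baseline_age = baseline_age,
    baseline_year = cfg$baseline_year,
    death_year = death_year,
    alive_at_end = is.na(death_year),
    end_of_study_year = cfg$end_of_study_year
  )
  structure(list(cohort = cohort, predictors = predictors,
                 specs = default_variable_specs(), hr = hr, z = z,
                 lt = lt, cfg = cfg),
            class = "rpd_sim")
}

#' @export
print.rpd_sim <- function(x, ...) {
  co <- x$cohort
  cat(sprintf(
    "Simulated cohort: n = %d, baseline %d (ages %d-%d), follow-up to %d\n",
    nrow(co), x$cfg$baseline_year, min(co$baseline_age),
    max(co$baseline_age), x$cfg$end_of_study_year))
  cat(sprintf("  %.2f%% male, %.2f%% alive at end of study\n",
              100 * mean(co$sex == "m"), 100 * mean(co$alive_at_end)))
  invisible(x)
}

#' Simulate the second survey wave among survivors
#'
#' Subjects alive at the wave-2 year receive transitioned values of every
#' two-wave variable: the score moves by `round(N(-drift, sd))` in its
#' favorable direction (a positive drift biases the population toward
#' worsening, as expected over ten years of aging), clipped to the variable's
#' range.  Subjects who died before wave 2 have an all-missing wave-2 row —
#' attrition by death, exactly as in a real re-survey.
#'
#' @param sim an [simulate_cohort()] result.
#' @param cfg optional override of `sim$cfg`.
#' @return a data frame with the two-wave columns (`NA` rows for
#'   non-survivors), same row order as the cohort.
#' @export
simulate_wave2 <- function(sim, cfg = sim$cfg) {
  stopifnot(inherits(sim, "rpd_sim"))
  wave2_year <- cfg$baseline_year + cfg$wave2_offset
  alive_w2 <- sim$cohort$alive_at_end |
    (!is.na(sim$cohort$death_year) & sim$cohort$death_year >= wave2_year)
  two <- sim$specs[sim$specs$waves == "both_waves", , drop = FALSE]
  set.seed(cfg$seed + 1L)
  n <- nrow(sim$cohort)
  out <- as.data.frame(matrix(NA_real_, n, nrow(two)))
  names(out) <- two$name
  ns <- sum(alive_w2)
  for (i in seq_len(nrow(two))) {
    sp <- two[i, ]
    w1 <- as.numeric(sim$predictors[[sp$name]][alive_w2])
    if (cfg$transition$sd == 0 && cfg$transition$drift == 0) {
      w2 <- w1
    } else {
      delta <- round(stats::rnorm(ns, -cfg$transition$drift,
                                  cfg$transition$sd))
      if (sp$direction == "higher_is_worse") delta <- -delta
      w2 <- w1 + delta
      if (!is.na(sp$min)) w2 <- clip(w2, sp$min, sp$max)
    }
    out[[sp$name]][alive_w2] <- w2
  }
  out
}

#' Cohorts with planted tree structure
#'
#' Generates a cohort whose mortality depends on predictors through known
#' threshold effects, for testing whether the tree recovers planted splits.
#' `"root_only"` plants one dominant effect: subjects with poor self-rated
#' health (`srh <= 1`) have hazard ratio 2.5.  `"two_level"` additionally
#' halves the hazard of better-rated subjects with nine or more years of
#' education, creating a second-level split inside the right branch.  All
#' other predictors are independent noise.  Everyone is followed to death
#' (no censoring), so the LRPD outcome is complete.
#'
#' @param level `"root_only"` or `"two_level"`.
#' @param n number of subjects.
#' @param seed integer seed.
#' @return a list with `data` (data frame: `lrpd` plus predictors `srh`,
#'   `education_years`, `smoking_years`, `mobility`, `noise`), `truth` (the
#'   planted variables and thresholds), and `cohort`.
#' @export
planted_tree_scenario <- function(level = c("root_only", "two_level"),
                                  n = 1000L, seed = 1L) {
  level <- match.arg(level)
  set.seed(seed)
  sex <- ifelse(stats::runif(n) < 0.5, "m", "f")
  baseline_age <- sample(60:89, n, replace = TRUE)
  baseline_year <- 1979L
  srh <- sample(0:4, n, replace = TRUE,
                prob = c(0.10, 0.15, 0.35, 0.25, 0.15))
  education_years <- clip(round(stats::rlnorm(n, log(4), 0.6)), 0, 20)
  predictors <- data.frame(
    srh = srh,
    education_years = education_years,
    smoking_years = ifelse(stats::runif(n) < 0.4,
                           clip(round(stats::rnorm(n, 30, 12)), 1, 60), 0),
    mobility = stats::rbinom(n, 14, 0.7),
    noise = stats::rnorm(n)
  )
  hr <- ifelse(srh <= 1, 2.5, 1.0)
  truth <- list(variables = "srh", thresholds = 1.5)
  if (level == "two_level") {
    hr <- hr * ifelse(srh > 1 & education_years >= 9, 0.5, 1.0)
    truth <- list(variables = c("srh", "education_years"),
                  thresholds = c(1.5, 8.5))
  }
  # follow everyone to death: extend the table far enough that survival past
  # its last age has negligible probability under the 0.7 hazard cap
  horizon <- 250L
  lt <- gompertz_life_table(age_range = c(60, 60 + horizon + 30), cap = 0.7)
  death_year <- draw_deaths(lt, sex, baseline_age, baseline_year,
                            baseline_year + horizon, hr)
  cohort <- data.frame(id = sprintf("p%05d", seq_len(n)), sex = sex,
                       baseline_age = baseline_age,
                       baseline_year = baseline_year,
                       death_year = death_year,
                       end_of_study_year = baseline_year + horizon)
  if (anyNA(death_year)) { # ~ impossible; keep y complete regardless
    keep <- !is.na(death_year)
    cohort <- cohort[keep, ]
    predictors <- predictors[keep, ]
  }
  rec <- compute_rpd(cohort, lt)
  data <- cbind(lrpd = rec$lrpd, predictors[seq_len(nrow(cohort)), ])
  list(data = data, truth = truth, cohort = cohort)
}
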