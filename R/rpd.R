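#' Realized probability of dying (RPD)
#'
#' RPD is an individual-level relative measure of longevity.  For a subject of
#' a given sex, baseline age and baseline calendar year who dies during
#' follow-up year `n`, it is the product of annual life-table survival factors
#'
#' \deqn{RPD = (1 - d_1)(1 - d_2)\cdots(1 - d_n)}
#'
#' where `d_i` is the life-table probability of dying in calendar year `i` of
#' follow-up at the subject's attained age.  RPD equals the proportion of the
#' subject's age- and sex-matched life-table cohort still alive at the end of
#' the subject's death year: values near 1 mean the subject died while most
#' peers were still alive (short relative survival), values near 0 mean the
#' subject outlived nearly all peers.  The baseline year counts as follow-up
#' year 1 and the death year contributes a full factor, so
#' `n = death_year - baseline_year + 1`.
#'
#' @param cohort a data frame with one row per subject and columns `id`,
#'   `sex`, `baseline_age`, `baseline_year`, `death_year` (`NA` for subjects
#'   alive at end of study) and, when any subject is censored,
#'   `end_of_study_year`.
#' @param lt a [life_table()] covering every subject's trajectory.
#' @return a data frame with columns `id`, `rpd`, `lrpd`, `imputed`,
#'   `n_years`.  `lrpd` is `NA` (with a warning) in the degenerate case
#'   `rpd == 1`, which can only arise from zero-hazard toy tables.
#'
#' @details `compute_rpd()` requires every subject to have a `death_year`;
#'   subjects alive at the end of study must go through
#'   [impute_rpd_censored()], which applies the standard imputation: the
#'   cumulative life-table survival from baseline through the final follow-up
#'   year, multiplied by 0.50 (the expected position within the still-alive
#'   remainder of the cohort).
#'
#' @seealso [compute_cohort_rpd()] for a whole cohort with mixed vital status.
#' @export
compute_rpd <- function(cohort, lt) {
  cohort <- validate_cohort(cohort, require_end = FALSE)
  if (anyNA(cohort$death_year)) {
    bad <- cohort$id[is.na(cohort$death_year)]
    stop("subject(s) alive at end of study: ", paste(bad, collapse = ", "),
         "; use impute_rpd_censored() for censored subjects")
  }
  n_years <- cohort$death_year - cohort$baseline_year + 1L
  rpd <- cumulative_survival(lt, cohort$sex, cohort$baseline_age,
                             cohort$baseline_year, n_years)
  rpd_record(cohort$id, rpd, imputed = FALSE, n_years = n_years)
}

#' Impute RPD for subjects alive at the end of the study
#'
#' A censored subject's RPD is imputed as the age- and sex-specific cumulative
#' probability of surviving from baseline through the final follow-up year,
#' multiplied by 0.50: the subject is placed at the median of the life-table
#' cohort fraction still alive at the end of the study.
#'
#' @inheritParams compute_rpd
#' @param variant `"cumulative"` (default) multiplies 0.50 by the cumulative
#'   survival from baseline through `end_of_study_year`; `"single_year"`
#'   multiplies 0.50 by the single-year survival probability in the final
#'   follow-up year only.  The cumulative reading keeps imputed values
#'   commensurate with observed RPDs (both are cohort fractions).
#' @return a data frame as in [compute_rpd()], with `imputed = TRUE`.
#' @export
impute_rpd_censored <- function(cohort, lt,
                                variant = c("cumulative", "single_year")) {
  variant <- match.arg(variant)
  cohort <- validate_cohort(cohort, require_end = TRUE)
  if (!all(is.na(cohort$death_year))) {
    bad <- cohort$id[!is.na(cohort$death_year)]
    stop("subject(s) with an observed death year: ",
         paste(bad, collapse = ", "), "; use compute_rpd() for deaths")
  }
  n_years <- cohort$end_of_study_year - cohort$baseline_year + 1L
  if (variant == "cumulative") {
    surv <- cumulative_survival(lt, cohort$sex, cohort$baseline_age,
                                cohort$baseline_year, n_years)
  } else {
    final_age <- cohort$baseline_age + n_years - 1L
    q <- death_prob(lt, cohort$sex, final_age,
                    if (lt$period_only) NULL else cohort$end_of_study_year)
    surv <- 1 - q
  }
  rpd_record(cohort$id, surv * 0.5, imputed = TRUE, n_years = n_years)
}

rpd_record <- function(id, rpd, imputed, n_years) {
  lrpd <- rep(NA_real_, length(rpd))
  ok <- rpd > 0 & rpd < 1
  if (any(!ok & !imputed)) {
    warning(sum(!ok), " subject(s) with RPD of exactly 0 or 1 (degenerate ",
            "life table); their LRPD is unrepresentable and set to NA")
  }
  lrpd[ok] <- logit_transform(rpd[ok])
  data.frame(id = id, rpd = rpd, lrpd = lrpd,
             imputed = rep_len(imputed, length(rpd)), n_years = n_years)
}

#' Logit transform of RPD
#'
#' `log(p / (1 - p))` with the natural logarithm.  The transformed value,
#' LRPD, is the regression tree's outcome: RPD is bounded in (0, 1) and close
#' to uniform under the null, so the logit spreads it over the real line.
#' Strictly increasing; negative LRPD means longer life than age/sex peers.
#'
#' @param p probabilities strictly inside (0, 1).
#' @return numeric vector of logits.
#' @export
logit_transform <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p >= 1)) {
    stop("logit_transform() requires 0 < p < 1 (no clamping is applied)")
  }
  log(p / (1 - p))
}

#' RPD and LRPD for a whole cohort
#'
#' Dispatches each subject to [compute_rpd()] (observed death) or
#' [impute_rpd_censored()] (alive at end of study) and summarizes the result.
#' Per-subject errors are collected and reported together with subject ids;
#' partial results are never returned silently.
#'
#' @inheritParams impute_rpd_censored
#' @return an object of class `rpd_cohort`: a list with `records` (data frame
#'   `id`, `rpd`, `lrpd`, `imputed`, `n_years`, in the input subject order) and
#'   `summary` (mean/sd/min/max of `rpd` and `lrpd`, subject counts, number
#'   imputed).
#' @export
compute_cohort_rpd <- function(cohort, lt,
                               variant = c("cumulative", "single_year")) {
  variant <- match.arg(variant)
  cohort <- validate_cohort(cohort, require_end = anyNA(cohort$death_year))
  dead <- !is.na(cohort$death_year)
  parts <- list()
  errs <- character()
  if (any(dead)) {
    parts$dead <- tryCatch(compute_rpd(cohort[dead, , drop = FALSE], lt),
                           error = function(e) {
                             errs[[length(errs) + 1L]] <<- conditionMessage(e)
                             NULL
                           })
  }
  if (any(!dead)) {
    parts$cens <- tryCatch(
      impute_rpd_censored(cohort[!dead, , drop = FALSE], lt, variant),
      error = function(e) {
        errs[[length(errs) + 1L]] <<- conditionMessage(e)
        NULL
      })
  }
  if (length(errs) > 0L) {
    stop("RPD computation failed:\n  ", paste(errs, collapse = "\n  "))
  }
  records <- do.call(rbind, unname(parts))
  records <- records[match(cohort$id, records$id), , drop = FALSE]
  rownames(records) <- NULL
  lr <- records$lrpd[!is.na(records$lrpd)]
  sd0 <- function(v) if (length(v) < 2L) 0 else stats::sd(v)
  summ <- list(
    n = nrow(records),
    n_imputed = sum(records$imputed),
    rpd_mean = mean(records$rpd), rpd_sd = sd0(records$rpd),
    rpd_range = range(records$rpd),
    lrpd_mean = mean(lr), lrpd_sd = sd0(lr), lrpd_range = range(lr)
  )
  structure(list(records = records, summary = summ), class = "rpd_cohort")
}

#' @export
print.rpd_cohort <- function(x, ...) {
  s <- x$summary
  cat("RPD for", s$n, "subjects (", s$n_imputed, "imputed )\n")
  cat(sprintf("  RPD : mean %.3f  sd %.3f  range [%.3f, %.3f]\n",
              s$rpd_mean, s$rpd_sd, s$rpd_range[1L], s$rpd_range[2L]))
  cat(sprintf("  LRPD: mean %.3f  sd %.3f  range [%.3f, %.3f]\n",
              s$lrpd_mean, s$lrpd_sd, s$lrpd_range[1L], s$lrpd_range[2L]))
  invisible(x)
}

validate_cohort <- function(cohort, require_end = TRUE) {
  req <- c("id", "sex", "baseline_age", "baseline_year")
  miss <- setdiff(req, names(cohort))
  if (length(miss) > 0L) {
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!("death_year" %in% names(cohort))) cohort$death_year <- NA_integer_
  if ("alive_at_end" %in% names(cohort)) {
    clash <- cohort$alive_at_end & !is.na(cohort$death_year)
    if (any(clash)) {
      stop("subject(s) flagged alive_at_end but carrying a death_year: ",
           paste(cohort$id[clash], collapse = ", "))
    }
    clash <- !cohort$alive_at_end & is.na(cohort$death_year)
    if (any(clash)) {
      stop("subject(s) neither dead nor alive_at_end: ",
           paste(cohort$id[clash], collapse = ", "))
    }
  }
  if (anyDuplicated(cohort$id)) {
    stop("duplicate subject id(s): ",
         paste(unique(cohort$id[duplicated(cohort$id)]), collapse = ", "))
  }
  dead <- !is.na(cohort$death_year)
  bad <- dead & cohort$death_year < cohort$baseline_year
  if (any(bad)) {
    stop("death_year before baseline_year for subject(s): ",
         paste(cohort$id[bad], collapse = ", "))
  }
  if ("end_of_study_year" %in% names(cohort)) {
    bad <- dead & cohort$death_year > cohort$end_of_study_year
    if (any(bad)) {
      stop("death_year after end_of_study_year for subject(s): ",
           paste(cohort$id[bad], collapse = ", "))
    }
  } else if (require_end && any(!dead)) {
    stop("cohort has censored subjects but no end_of_study_year column")
  }
  cohort
}
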