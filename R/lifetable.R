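#' Period life tables of annual death probabilities
#'
#' A `life_table` stores the annual probability of dying `qx` indexed by sex
#' (`"f"`/`"m"`), integer attained age, and (optionally) calendar year.  It is
#' the source of the expected-mortality terms in the realized probability of
#' dying: the probability that a person of a given age and sex dies within a
#' given calendar year.  A table without a year dimension is a *period-only*
#' table: the same schedule applies to every calendar year.
#'
#' @param data a data frame with columns `sex` (`"f"`/`"m"`, or `"female"`/
#'   `"male"`), `age` (integer years), `qx` (probability in `[0, 1]`) and
#'   optionally `year` (integer calendar year).
#' @return an object of class `life_table` with fields `q` (a 3-d array
#'   `age x year x sex` of probabilities), `ages`, `years` (`NA` when
#'   period-only), and `period_only`.
#'
#' @details Validation is strict: every `qx` must lie in `[0, 1]`, ages must be
#'   contiguous integers, the `(sex, age, year)` grid must be complete with no
#'   duplicated keys, and queries outside the declared ranges are hard errors —
#'   there is no extrapolation, silent or otherwise, because an extrapolated
#'   death probability would corrupt every downstream RPD unnoticed.
#'
#' @seealso [read_life_table()], [gompertz_life_table()], [death_prob()],
#'   [cumulative_survival()]
#' @export
life_table <- function(data) {
  req <- c("sex", "age", "qx")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0L) {
    stop("life table is missing column(s): ", paste(miss, collapse = ", "))
  }
  sex <- normalize_sex(data$sex)
  age <- data$age
  qx <- as.numeric(data$qx)
  if (anyNA(age) || any(age != as.integer(age))) {
    stop("life table ages must be integers")
  }
  age <- as.integer(age)
  bad <- which(is.na(qx) | qx < 0 | qx > 1)
  if (length(bad) > 0L) {
    stop(sprintf(
      "qx outside [0, 1] (or missing) at row %d: sex=%s age=%d qx=%s",
      bad[1L], sex[bad[1L]], age[bad[1L]], format(data$qx[bad[1L]])
    ))
  }
  period_only <- !("year" %in% names(data))
  if (period_only) {
    year <- rep.int(0L, nrow(data))
    years <- NA_integer_
  } else {
    year <- data$year
    if (anyNA(year) || any(year != as.integer(year))) {
      stop("life table years must be integers")
    }
    year <- as.integer(year)
    years <- seq.int(min(year), max(year))
  }
  ages <- seq.int(min(age), max(age))
  if (!identical(sort(unique(age)), ages)) {
    stop("life table ages are not contiguous over [",
         min(age), ", ", max(age), "]")
  }

  key <- paste(sex, age, year)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate life-table key (sex age year): ", dup)
  }
  ny <- if (period_only) 1L else length(years)
  q <- array(NA_real_, dim = c(length(ages), ny, 2L),
             dimnames = list(age = ages,
                             year = if (period_only) "period" else years,
                             sex = c("f", "m")))
  ai <- match(age, ages)
  yi <- if (period_only) rep.int(1L, length(age)) else match(year, years)
  si <- match(sex, c("f", "m"))
  q[cbind(ai, yi, si)] <- qx
  if (anyNA(q)) {
    hole <- which(is.na(q), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "life table has a gap at sex=%s age=%s year=%s",
      c("f", "m")[hole[3L]], ages[hole[1L]],
      if (period_only) "period" else years[hole[2L]]
    ))
  }
  structure(
    list(q = q, ages = ages, years = years, period_only = period_only),
    class = "life_table"
  )
}

#' @export
print.life_table <- function(x, ...) {
  cat("Period life table\n")
  cat("  ages : ", min(x$ages), "-", max(x$ages), "\n", sep = "")
  if (x$period_only) {
    cat("  years: single period (applies to all calendar years)\n")
  } else {
    cat("  years: ", min(x$years), "-", max(x$years), "\n", sep = "")
  }
  cat("  qx   : ", format(min(x$q), digits = 4), " - ",
      format(max(x$q), digits = 4), "\n", sep = "")
  invisible(x)
}

normalize_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  out <- ifelse(s %in% c("f", "female"), "f",
                ifelse(s %in% c("m", "male"), "m", NA_character_))
  if (anyNA(out)) {
    stop("unrecognized sex code(s): ",
         paste(unique(s[is.na(out)]), collapse = ", "),
         " (expected f/female or m/male)")
  }
  out
}

#' Read a life table from a delimited text file
#'
#' Reads a CSV/TSV life table with a header row.  Column names are resolved
#' through `dialect`, so HMD-style files (`Age`, `qx`, `Year`) and ad-hoc
#' exports can be read without editing the file.
#'
#' @param path path to a delimited text file.
#' @param dialect named character vector mapping the canonical names
#'   `sex`, `age`, `year`, `qx` to the column names used in the file.
#'   Matching is case-insensitive; `year` is optional (its absence makes the
#'   table period-only).
#' @param sep field separator; `NULL` (default) picks `","` or `"\t"` from the
#'   header line.
#' @return a [life_table()].
#' @export
read_life_table <- function(path,
                            dialect = c(sex = "sex", age = "age",
                                        year = "year", qx = "qx"),
                            sep = NULL) {
  if (!file.exists(path)) stop("life-table file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(raw))
  pick <- function(canon, required = TRUE) {
    want <- tolower(if (canon %in% names(dialect)) dialect[[canon]] else canon)
    i <- match(want, nm)
    if (is.na(i) && required) {
      stop("life-table file lacks a column for '", canon,
           "' (looked for '", want, "'); columns present: ",
           paste(names(raw), collapse = ", "))
    }
    i
  }
  df <- data.frame(sex = raw[[pick("sex")]],
                   age = raw[[pick("age")]],
                   qx = raw[[pick("qx")]])
  yi <- pick("year", required = FALSE)
  if (!is.na(yi)) df$year <- raw[[yi]]
  life_table(df)
}

#' Write a life table to a delimited text file
#'
#' Emits the same schema [read_life_table()] consumes (`sex,age[,year],qx`),
#' with `qx` at 10 significant digits so a text round-trip reproduces the
#' stored probabilities.
#'
#' @param lt a [life_table()].
#' @param path output file path.
#' @param sep field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path, sep = ",") {
  stopifnot(inherits(lt, "life_table"))
  grid <- expand.grid(age = lt$ages,
                      year = if (lt$period_only) 0L else lt$years,
                      sex = c("f", "m"), stringsAsFactors = FALSE)
  qx <- death_prob(lt, grid$sex, grid$age,
                   if (lt$period_only) NULL else grid$year)
  out <- data.frame(sex = grid$sex, age = grid$age)
  if (!lt$period_only) out$year <- grid$year
  out$qx <- signif(qx, 10)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

lt_index <- function(lt, sex, age, year) {
  sex <- normalize_sex(sex)
  ai <- match(age, lt$ages)
  if (anyNA(ai)) {
    j <- which(is.na(ai))[1L]
    stop(sprintf("age %s outside life-table range [%d, %d]",
                 format(age[j]), min(lt$ages), max(lt$ages)))
  }
  if (lt$period_only || is.null(year)) {
    yi <- rep.int(1L, length(ai))
  } else {
    yi <- match(year, lt$years)
    if (anyNA(yi)) {
      j <- which(is.na(yi))[1L]
      stop(sprintf("calendar year %s outside life-table range [%d, %d]",
                   format(year[j]), min(lt$years), max(lt$years)))
    }
  }
  si <- match(sex, c("f", "m"))
  cbind(ai, yi, si)
}

#' Annual death probability for a sex, age and calendar year
#'
#' Returns the stored `qx` exactly; all arguments are vectorized.  For a
#' period-only table the `year` argument is ignored.  Lookups outside the
#' declared age or year range are errors naming the offending key.
#'
#' @param lt a [life_table()].
#' @param sex `"f"`/`"m"` (or `"female"`/`"male"`).
#' @param age integer attained age(s).
#' @param year integer calendar year(s); may be `NULL` for period-only tables.
#' @return numeric vector of death probabilities.
#' @export
death_prob <- function(lt, sex, age, year = NULL) {
  stopifnot(inherits(lt, "life_table"))
  if (!lt$period_only && is.null(year)) {
    stop("this life table is year-specific: a calendar year is required")
  }
  lt$q[lt_index(lt, sex, age, year)]
}

#' Cumulative life-table survival along a subject's trajectory
#'
#' The probability that a member of the life-table population of the given sex,
#' starting at `baseline_age` in `baseline_year`, survives `n_years` complete
#' calendar years.  Attained age advances one year per calendar year, so year
#' `i` of follow-up uses `q(sex, baseline_age + i - 1, baseline_year + i - 1)`,
#' and the result is the product of the `n_years` survival factors `1 - q`.
#' `n_years = 0` returns 1 (empty product).  All arguments vectorize over
#' subjects.
#'
#' @inheritParams death_prob
#' @param baseline_age integer age(s) at baseline.
#' @param baseline_year integer calendar year(s) at baseline.
#' @param n_years integer number(s) of follow-up years, `>= 0`.
#' @return numeric vector of survival probabilities.
#' @export
cumulative_survival <- function(lt, sex, baseline_age, baseline_year, n_years) {
  stopifnot(inherits(lt, "life_table"))
  n <- max(length(sex), length(baseline_age), length(baseline_year),
           length(n_years))
  sex <- rep_len(normalize_sex(sex), n)
  baseline_age <- rep_len(as.integer(baseline_age), n)
  baseline_year <- rep_len(as.integer(baseline_year), n)
  n_years <- rep_len(as.integer(n_years), n)
  if (any(n_years < 0L)) stop("n_years must be >= 0")

  out <- rep.int(1, n)
  live <- which(n_years > 0L)
  if (length(live) == 0L) return(out)

  # flatten all per-subject year sequences into one indexed lookup, then take
  # grouped products in year order — bit-identical to multiplying the yearly
  # death_prob survival factors one at a time
  k <- n_years[live]
  subj <- rep.int(seq_along(live), k)
  step <- sequence(k) - 1L
  ages <- baseline_age[live][subj] + step
  yrs <- if (lt$period_only) NULL else baseline_year[live][subj] + step
  q <- death_prob(lt, sex[live][subj], ages, yrs)
  out[live] <- vapply(split(1 - q, subj), prod, numeric(1), USE.NAMES = FALSE)
  out
}

#' Generate a Gompertz period life table
#'
#' Builds a synthetic life table with `q(sex, age) = min(cap,
#' alpha_sex * exp(beta * age))`, the classical Gompertz law of mortality,
#' identical across calendar years.  This is the stand-in for a national
#' period table when exercising the pipeline on simulated cohorts.
#'
#' @param alpha_female,alpha_male baseline mortality level per sex (`> 0`).
#' @param beta exponential rate of mortality increase with age (`> 0`).
#' @param age_range integer vector `c(min_age, max_age)`.
#' @param year_range integer vector `c(min_year, max_year)`, or `NULL`
#'   (default) for a period-only table.
#' @param cap upper bound applied to `q` so it stays a valid probability
#'   (`0 < cap <= 1`).
#' @return a [life_table()].
#' @export
gompertz_life_table <- function(alpha_female = 2e-5, alpha_male = 3.5e-5,
                                beta = 0.095, age_range = c(60, 120),
                                year_range = NULL, cap = 0.7) {
  if (alpha_female <= 0 || alpha_male <= 0 || beta <= 0) {
    stop("Gompertz parameters alpha and beta must be positive")
  }
  if (cap <= 0 || cap > 1) stop("cap must lie in (0, 1]")
  ages <- seq.int(age_range[1L], age_range[2L])
  qf <- pmin(cap, alpha_female * exp(beta * ages))
  qm <- pmin(cap, alpha_male * exp(beta * ages))
  df <- data.frame(sex = rep(c("f", "m"), each = length(ages)),
                   age = rep(ages, 2L), qx = c(qf, qm))
  if (!is.null(year_range)) {
    years <- seq.int(year_range[1L], year_range[2L])
    df <- df[rep(seq_len(nrow(df)), times = length(years)), ]
    df$year <- rep(years, each = 2L * length(ages))
  }
  life_table(df)
}
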