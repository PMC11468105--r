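subject <- function(id = "a", sex = "f", baseline_age = 70,
                    baseline_year = 1979, death_year = NA_integer_,
                    end_of_study_year = 2014) {
  data.frame(id = id, sex = sex, baseline_age = baseline_age,
             baseline_year = baseline_year, death_year = death_year,
             end_of_study_year = end_of_study_year)
}

test_that("the two-year worked example gives RPD exactly 0.80", {
  lt <- worked_example_lt()
  rec <- compute_rpd(subject(death_year = 1980), lt)
  expect_equal(rec$rpd, 0.8, tolerance = 1e-12)
  expect_equal(rec$n_years, 2L)
  expect_false(rec$imputed)
  expect_equal(rec$lrpd, log(0.8 / 0.2))
})

test_that("compute_rpd handles degenerate hazards and enforces its contract", {
  lt0 <- toy_life_table(70:75, 0)
  expect_warning(rec <- compute_rpd(subject(death_year = 1981), lt0),
                 "unrepresentable")
  expect_identical(rec$rpd, 1.0)
  expect_true(is.na(rec$lrpd))

  lt5 <- toy_life_table(70:75, 0.5)
  rec <- compute_rpd(subject(death_year = 1981), lt5)
  expect_equal(rec$rpd, 0.125)

  expect_error(compute_rpd(subject(), lt5), "impute_rpd_censored")
  expect_error(impute_rpd_censored(subject(death_year = 1981), lt5),
               "compute_rpd")
})

test_that("compute_rpd agrees with a year-at-a-time oracle on random tables", {
  set.seed(21)
  for (i in 1:25) {
    lt <- random_life_table(ages = 60:90)
    a0 <- sample(60:75, 1)
    dy <- 1979 + sample(0:10, 1)
    s <- subject(sex = sample(c("f", "m"), 1), baseline_age = a0,
                 death_year = dy)
    rec <- compute_rpd(s, lt)
    expect_equal(rec$rpd, oracle_rpd(lt, s$sex, a0, 1979, dy))
    expect_equal(rec$n_years, dy - 1979 + 1)
  }
})

test_that("censored subjects get cumulative survival to end of study times 0.50", {
  # 5-year toy table with distinct hazards; hand-multiplied product
  qs <- c(0.10, 0.20, 0.05, 0.15, 0.30)
  lt <- toy_life_table(70:74, qs)
  s <- subject(end_of_study_year = 1983)
  rec <- impute_rpd_censored(s, lt)
  expect_equal(rec$rpd, prod(1 - qs) * 0.5, tolerance = 1e-12)
  expect_true(rec$imputed)
  expect_equal(rec$n_years, 5L)

  # zero-hazard table: imputed RPD is exactly 0.5
  lt0 <- toy_life_table(70:74, 0)
  expect_equal(impute_rpd_censored(s, lt0)$rpd, 0.5)

  # single-year variant uses only the final year's survival
  rec1 <- impute_rpd_censored(s, lt, variant = "single_year")
  expect_equal(rec1$rpd, (1 - 0.30) * 0.5, tolerance = 1e-12)

  # with positive hazards the imputed value undercuts a death in the final year
  dead <- compute_rpd(subject(death_year = 1983), lt)
  expect_lt(rec$rpd, dead$rpd)
})

test_that("logit transform is exact, antisymmetric, and strict on its domain", {
  expect_identical(logit_transform(0.5), 0)
  expect_equal(logit_transform(0.8), log(4))
  set.seed(5)
  p <- runif(50, 0.01, 0.99)
  expect_equal(logit_transform(p), -logit_transform(1 - p))
  expect_true(all(diff(logit_transform(sort(p))) > 0))
  expect_error(logit_transform(0), "0 < p < 1")
  expect_error(logit_transform(1), "0 < p < 1")
})

test_that("cohort-level RPD summarizes, dispatches and preserves order", {
  qs <- c(0.1, 0.2, 0.1, 0.2, 0.1)
  lt <- toy_life_table(70:74, qs)
  one <- compute_cohort_rpd(subject(death_year = 1980,
                                    end_of_study_year = 1983), lt)
  expect_equal(one$summary$rpd_mean, 0.9 * 0.8)
  expect_equal(one$summary$rpd_sd, 0)

  co <- rbind(subject("a", death_year = 1980, end_of_study_year = 1983),
              subject("b", death_year = 1982, end_of_study_year = 1983),
              subject("c", end_of_study_year = 1983))
  res <- compute_cohort_rpd(co, lt)
  expect_identical(res$records$id, c("a", "b", "c"))
  expect_identical(res$records$imputed, c(FALSE, FALSE, TRUE))
  expect_equal(res$summary$n_imputed, 1L)
  expect_equal(res$records$rpd[3], prod(1 - qs) * 0.5)

  # replication invariance of mean and sd
  co2 <- rbind(co, transform(co, id = paste0(id, "2")))
  res2 <- compute_cohort_rpd(co2, lt)
  expect_equal(res2$summary$rpd_mean, res$summary$rpd_mean)
  expect_equal(res2$summary$rpd_sd,
               sd(rep(res$records$rpd, 2)))
})

test_that("per-subject failures are reported with ids, not partially returned", {
  lt <- toy_life_table(70:74, 0.1)
  co <- rbind(subject("ok", death_year = 1980),
              subject("bad", baseline_age = 95, death_year = 1996))
  expect_error(compute_cohort_rpd(co, lt), "age 9[0-9] outside")
  expect_error(compute_cohort_rpd(subject("dup")[c(1, 1), ], lt), "duplicate")
  expect_error(
    compute_rpd(subject(death_year = 1950), lt), "before baseline")
})

test_that("RPD strictly decreases in death year under positive hazards", {
  lt <- toy_life_table(70:80, 0.1)
  recs <- compute_rpd(
    do.call(rbind, lapply(0:9, function(k) {
      subject(paste0("s", k), death_year = 1979 + k)
    })), lt)
  expect_true(all(diff(recs$rpd) < 0))
  expect_true(all(recs$rpd > 0 & recs$rpd <= 1))
})
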