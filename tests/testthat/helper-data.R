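# Fixture builders shared across test files.  Everything is generated in
# code; no data files.

# Two-sex life table on a contiguous age range, constant or per-age qx.
toy_life_table <- function(ages, qx, years = NULL) {
  qx <- rep_len(qx, length(ages))
  df <- data.frame(sex = rep(c("f", "m"), each = length(ages)),
                   age = rep(ages, 2L), qx = rep(qx, 2L))
  if (!is.null(years)) {
    df <- df[rep(seq_len(nrow(df)), length(years)), ]
    df$year <- rep(years, each = 2L * length(ages))
  }
  life_table(df)
}

# The worked-example table: death probability 0.1 in follow-up year 1 and
# 1/9 in year 2 along a subject's trajectory (baseline age 70 in 1979).
worked_example_lt <- function() {
  toy_life_table(ages = 70:71, qx = c(0.1, 1 / 9))
}

random_life_table <- function(ages = 60:80, max_q = 0.3) {
  toy_life_table(ages, stats::runif(length(ages), 0, max_q))
}

# Random mixed-type regression dataset for split/oracle tests.
random_mixed_data <- function(n, p = NULL, na_frac = 0.1, signal = TRUE) {
  if (is.null(p)) p <- sample(1:4, 1L)
  X <- data.frame(row.names = seq_len(n))
  for (j in seq_len(p)) {
    type <- sample(c("numeric", "integer", "nominal", "ordered"), 1L)
    x <- switch(type,
      numeric = stats::rnorm(n),
      integer = sample(0:6, n, replace = TRUE),
      nominal = factor(sample(LETTERS[seq_len(sample(2:5, 1L))], n,
                              replace = TRUE)),
      ordered = factor(sample(c("low", "mid", "high"), n, replace = TRUE),
                       levels = c("low", "mid", "high"), ordered = TRUE))
    if (na_frac > 0) x[stats::runif(n) < na_frac] <- NA
    X[[paste0("x", j)]] <- x
  }
  y <- stats::rnorm(n)
  if (signal && is.numeric(X$x1)) {
    y <- y + 2 * (!is.na(X$x1) & X$x1 > stats::median(X$x1, na.rm = TRUE))
  }
  cbind(y = y, X)
}

# Small simulated analysis dataset (complete LRPD + predictors).
small_fit_data <- function(n = 150, seed = 42) {
  sc <- planted_tree_scenario("root_only", n = n, seed = seed)
  sc$data
}
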