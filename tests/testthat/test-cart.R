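test_that("threshold split maximizes the SSE reduction at a midpoint", {
  res <- best_threshold_split(c(1, 2, 3, 4), c(0, 0, 10, 10))
  expect_equal(res$threshold, 2.5)
  expect_equal(res$sse_reduction, 100)
  expect_equal(c(res$n_left, res$n_right), c(2, 2))

  expect_null(best_threshold_split(1:4, rep(3, 4)))     # constant response
  expect_null(best_threshold_split(rep(2, 4), rnorm(4))) # constant predictor

  # minleafsize = n/2 leaves only the middle cut admissible
  res <- best_threshold_split(1:4, c(1, 2, 3, 4), minleafsize = 2)
  expect_equal(res$threshold, 2.5)

  # missing values are excluded from the evaluation
  res <- best_threshold_split(c(1, 2, 3, 4, NA), c(0, 0, 10, 10, 99))
  expect_equal(res$threshold, 2.5)
  expect_equal(res$sse_reduction, 100)
})

test_that("subset split equals the exhaustive subset oracle", {
  x <- factor(rep(c("A", "B", "C"), each = 4))
  y <- c(rep(0, 8), rep(10, 4))
  res <- best_subset_split(x, y)
  expect_setequal(res$left_set, c("A", "B"))
  expect_equal(res$sse_reduction, oracle_best_column(x, y))

  expect_null(best_subset_split(factor(rep("A", 5)), rnorm(5)))
  expect_null(best_subset_split(factor(c("A", "A", "B", "B")),
                                c(1, 3, 3, 1)))  # identical category means

  # two categories: the single possible split, iff admissible
  res <- best_subset_split(factor(c("A", "A", "B")), c(0, 0, 5))
  expect_identical(res$left_set, "A")
  expect_null(best_subset_split(factor(c("A", "A", "B")), c(0, 0, 5),
                                minleafsize = 2))

  set.seed(41)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    x <- factor(sample(LETTERS[1:k], 40, replace = TRUE))
    y <- rnorm(40) + 2 * (as.integer(x) %% 2)
    mls <- sample(1:3, 1)
    mine <- best_subset_split(x, y, mls)
    orac <- oracle_best_column(x, y, mls)
    if (is.null(mine)) {
      expect_lte(orac, 0)
    } else {
      expect_equal(mine$sse_reduction, orac, tolerance = 1e-10)
    }
  }
})

test_that("stopping rules produce leaves exactly when they should", {
  d <- data.frame(y = rep(1.5, 20), x = rnorm(20))
  fit <- rpd_tree(y ~ x, d)
  expect_equal(length(fit$nodes), 1L)          # minvariance stop
  expect_equal(predict(fit, d), rep(1.5, 20))

  d <- small_fit_data(200)
  stump <- rpd_tree(lrpd ~ ., d, tree_control(maxdepth = 1))
  expect_lte(length(stump$nodes), 3L)
  expect_equal(max(vapply(stump$nodes, `[[`, integer(1), "depth")), 1L)

  big <- rpd_tree(lrpd ~ ., d, tree_control(maxdepth = 10, minleafsize = 10))
  sizes <- vapply(Filter(function(n) is.null(n$children), big$nodes),
                  `[[`, integer(1), "n")
  expect_true(all(sizes >= 10))

  expect_error(rpd_tree(lrpd ~ ., transform(d, lrpd = NA_real_)),
               "missing response")
})

test_that("a planted two-level interaction is recovered structurally", {
  set.seed(43)
  n <- 1000
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 3 * (d$x1 > 0) + 1.5 * (d$x2 > 0) + rnorm(n, sd = 0.3)
  fit <- rpd_tree(y ~ x1 + x2, d, tree_control(maxdepth = 3))
  expect_identical(fit$nodes[["1"]]$rule$var, "x1")  # larger effect at root
  expect_setequal(unique(fit$importance$variable), c("x1", "x2"))
})

test_that("node-level statistics satisfy the partition identities", {
  d <- small_fit_data(300, seed = 7)
  fit <- rpd_tree(lrpd ~ ., d, tree_control(maxdepth = 4))
  for (nd in fit$nodes) {
    if (is.null(nd$children)) next
    l <- fit$nodes[[as.character(nd$children[1])]]
    r <- fit$nodes[[as.character(nd$children[2])]]
    expect_equal(nd$n, l$n + r$n)
    expect_gte(nd$sse + 1e-9, l$sse + r$sse)
    expect_equal(nd$mean * nd$n, l$mean * l$n + r$mean * r$n)
  }
})

test_that("surrogate routing follows agreement rank with majority fallback", {
  # x2 nearly duplicates x1, x3 is anti-correlated noise; make x1 missing
  set.seed(44)
  n <- 400
  x1 <- rnorm(n)
  x2 <- x1; flip <- sample(n, 20); x2[flip] <- -x2[flip]  # 95% agreement
  d <- data.frame(y = 2 * (x1 > 0) + rnorm(n, sd = 0.2), x1 = x1, x2 = x2,
                  x3 = rnorm(n))
  fit <- rpd_tree(y ~ x1 + x2 + x3, d, tree_control(maxdepth = 1))
  root <- fit$nodes[["1"]]
  expect_identical(root$rule$var, "x1")
  expect_identical(root$surrogates[[1]]$var, "x2")
  expect_gt(root$surrogates[[1]]$agreement, 0.9)

  # primary observed: the primary rule decides regardless of surrogates
  obs <- data.frame(x1 = c(-1, 1), x2 = c(5, -5), x3 = 0)
  expect_equal(predict(fit, obs, type = "leaf"), c(2L, 3L))
  # primary missing: the best surrogate decides
  mis <- data.frame(x1 = NA_real_, x2 = c(-1, 1), x3 = 0)
  expect_equal(predict(fit, mis, type = "leaf"), c(2L, 3L))
  # everything missing: the majority branch decides (a total function)
  all_na <- data.frame(x1 = NA_real_, x2 = NA_real_, x3 = NA_real_)
  maj <- predict(fit, all_na, type = "leaf")
  expect_identical(maj, if (root$majority == "left") 2L else 3L)
})

test_that("predictions are exactly the set of leaf means", {
  d <- small_fit_data(250, seed = 9)
  fit <- rpd_tree(lrpd ~ ., d, tree_control(maxdepth = 3))
  leaf_means <- sort(vapply(Filter(function(n) is.null(n$children),
                                   fit$nodes), `[[`, numeric(1), "mean"))
  expect_setequal(unique(predict(fit, d)), leaf_means)
  expect_equal(predict(fit, d), fit$fitted)
})

test_that("importance shares sum to 100 with per-variable split counts", {
  # single split: 100, count 1
  d <- data.frame(y = c(0, 0, 10, 10), x = 1:4, z = c(5, 5, 5, 5))
  fit <- rpd_tree(y ~ x + z, d, tree_control(maxdepth = 1))
  expect_equal(fit$importance$variable, "x")
  expect_equal(fit$importance$importance, 100)
  expect_equal(fit$importance$count, 1L)

  # single-leaf tree: empty table
  leafy <- rpd_tree(y ~ x, data.frame(y = rep(1, 5), x = 1:5))
  expect_equal(nrow(variable_importance(leafy)), 0L)

  # shares reproduce the hand-computed dSSE ratios and always sum to 100
  set.seed(45)
  for (i in 1:10) {
    d <- random_mixed_data(60, na_frac = 0)
    fit <- rpd_tree(y ~ ., d, tree_control(maxdepth = 3))
    imp <- variable_importance(fit)
    if (nrow(imp) == 0) next
    expect_equal(sum(imp$importance), 100, tolerance = 1e-9)
    internal <- Filter(function(n) !is.null(n$children), fit$nodes)
    vars <- vapply(internal, function(n) n$rule$var, character(1))
    red <- vapply(internal, function(n) n$sse_reduction, numeric(1))
    for (v in imp$variable) {
      expect_equal(imp$count[imp$variable == v], sum(vars == v))
      expect_equal(imp$importance[imp$variable == v],
                   100 * sum(red[vars == v]) / sum(red))
    }
  }
})

test_that("fit is deterministic and invariant to monotone transforms", {
  d <- small_fit_data(200, seed = 10)
  f1 <- rpd_tree(lrpd ~ ., d)
  f2 <- rpd_tree(lrpd ~ ., d)
  expect_identical(export_tree(f1, "json"), export_tree(f2, "json"))

  # cube the education score: thresholds move, leaf membership does not
  d2 <- transform(d, education_years = education_years^3)
  f3 <- rpd_tree(lrpd ~ ., d2)
  expect_identical(predict(f1, d, type = "leaf"),
                   predict(f3, d2, type = "leaf"))
})

test_that("every chosen split matches the exhaustive oracle (spot check)", {
  set.seed(46)
  for (i in 1:20) {
    d <- random_mixed_data(sample(10:50, 1))
    mls <- sample(1:3, 1)
    fit <- rpd_tree(y ~ ., d, tree_control(maxdepth = 3, minleafsize = mls))
    rows <- node_rows(fit, d)
    for (nd in fit$nodes) {
      idx <- rows[[as.character(nd$id)]]
      orac <- oracle_best_split(d[idx, -1, drop = FALSE], d$y[idx], mls)
      if (is.null(nd$children)) next
      expect_equal(nd$sse_reduction, orac, tolerance = 1e-8)
    }
  }
})

test_that("trees round-trip through JSON and render to dot and text", {
  d <- small_fit_data(150, seed = 12)
  fit <- rpd_tree(lrpd ~ ., d, tree_control(maxdepth = 3))
  js <- export_tree(fit, "json")
  back <- import_tree(js)
  expect_identical(export_tree(back, "json"), js)   # byte-identical
  expect_equal(predict(back, d), predict(fit, d))   # same routing

  stump <- rpd_tree(lrpd ~ ., d, tree_control(maxdepth = 1))
  expect_equal(length(import_tree(export_tree(stump, "json"))$nodes), 3L)
  expect_equal(sum(grepl("label=", strsplit(export_tree(stump, "dot"),
                                            "\n")[[1]]) &
                   !grepl("->", strsplit(export_tree(stump, "dot"),
                                         "\n")[[1]])), 3L)

  dot <- strsplit(export_tree(fit, "dot"), "\n")[[1]]
  expect_identical(dot[1], "digraph rpd_tree {")
  expect_identical(dot[length(dot)], "}")
  body <- dot[-c(1, 2, length(dot))]
  # every body line is a node or edge statement of the dot grammar
  expect_true(all(grepl(
    "^  n[0-9]+ (\\[label=\".*\"(, shape=oval)?\\]|-> n[0-9]+ \\[label=\"(yes|no)\"\\]);$",
    body)))

  txt <- export_tree(fit, "text")
  expect_match(txt, "n=\\d+ mean=")
  expect_error(export_tree(fit, "xml"), "should be one of")
})
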